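#' Simulate an additive phenotype from QTNs
#'
#' Draws `n_qtn` QTN markers uniformly without replacement, samples their
#' additive effects from a standard normal, forms the genetic value
#' `g = Z beta` from the 0/1/2 dosages, and adds Gaussian residuals whose
#' variance is set from the realized additive variance so that the sample
#' heritability targets `h2`: `V_E = V_A (1 - h2) / h2` with
#' `V_A = var(g)`.
#'
#' @param gm a complete [geno_matrix()].
#' @param n_qtn number of QTNs (default 20, the GWAS architecture; use 10
#'   for genomic prediction).
#' @param h2 target narrow-sense heritability in (0, 1), default 0.75.
#' @param seed random seed.
#' @return a list: `phenotype` (numeric vector), `qtn` (class `qtn_model`:
#'   `indices`, `effects`, `h2`, `V_A`, `V_E`, `genetic_values`).
#' @export
simulate_phenotype <- function(gm, n_qtn = 20, h2 = 0.75, seed) {
  validate_geno_matrix(gm)
  if (anyNA(gm$calls)) stopf("phenotype simulation needs a complete matrix")
  if (n_qtn > n_markers(gm)) stopf("n_qtn exceeds marker count")
  if (h2 <= 0 || h2 >= 1) stopf("h2 must be in (0, 1)")
  set.seed(seed)
  for (attempt in 1:10) {
    idx <- sort(sample.int(n_markers(gm), n_qtn))
    beta <- rnorm(n_qtn)
    g <- as.vector(gm$calls[, idx, drop = FALSE] %*% beta)
    V_A <- var(g)
    if (V_A > 0) break
    if (attempt == 10) stopf("all QTN draws monomorphic after 10 attempts")
  }
  V_E <- V_A * (1 - h2) / h2
  y <- g + rnorm(length(g), 0, sqrt(V_E))
  qtn <- structure(list(indices = idx, effects = beta, h2 = h2,
                        V_A = V_A, V_E = V_E, genetic_values = g),
                   class = "qtn_model")
  list(phenotype = y, qtn = qtn)
}

#' Single-marker GWAS scan
#'
#' Per marker, a two-sided t-test of the additive dosage slope in the
#' simple linear model `y = a + b * dosage + e`, computed in closed form
#' and vectorised over markers. Monomorphic markers get p = 1. (This scan
#' deliberately replaces multi-locus association models: the harness
#' evaluates imputation quality, not association methodology.)
#'
#' @param gm a complete [geno_matrix()].
#' @param phenotype numeric vector, one value per individual.
#' @return numeric vector of per-marker p-values.
#' @export
gwas_scan <- function(gm, phenotype) {
  validate_geno_matrix(gm)
  if (anyNA(gm$calls)) stopf("GWAS scan needs a complete matrix")
  n <- n_taxa(gm)
  if (length(phenotype) != n) stopf("phenotype length != individuals")
  if (var(phenotype) == 0) stopf("phenotype has zero variance")
  X <- gm$calls
  y <- phenotype - mean(phenotype)
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  Sxy <- as.vector(crossprod(X, y))  # centred y removes the mean term
  Syy <- sum(y^2)
  p <- rep(1, ncol(X))
  poly <- Sxx > 0
  b <- Sxy[poly] / Sxx[poly]
  rss <- pmax(Syy - b * Sxy[poly], 0)
  df <- n - 2
  se2 <- rss / (df * Sxx[poly])
  tstat <- ifelse(se2 > 0, b / sqrt(se2), Inf)
  p[poly] <- 2 * pt(-abs(tstat), df)
  p
}

#' Power, FDR and Type-I accounting for a QTN scan
#'
#' Detection rule: a marker is detected when its p-value is at or below
#' `threshold` (default Bonferroni `0.05 / markers`). Power is the detected
#' fraction of QTNs — with `n` QTNs each contributes `1/n` (e.g. 5% each
#' for 20 QTNs). Two false-discovery summaries are reported: `fdr`
#' (false positives over non-QTN markers — the definition used by the
#' matching-rate harness upstream) and `fdr_conventional`
#' (false positives over all detections). `type1` is false positives over
#' all markers.
#'
#' @param pvals per-marker p-values.
#' @param qtn_indices marker indices of the simulated QTNs.
#' @param threshold detection threshold (default `0.05 / length(pvals)`).
#' @return a list of class `gwas_eval`: `power`, `fdr`, `fdr_conventional`,
#'   `type1`, `n_detected`, `n_false`, `threshold`.
#' @export
power_fdr_type1 <- function(pvals, qtn_indices,
                            threshold = 0.05 / length(pvals)) {
  m <- length(pvals)
  if (any(qtn_indices < 1 | qtn_indices > m))
    stopf("qtn_indices outside the marker set")
  qtn_indices <- unique(qtn_indices)
  hit <- which(pvals <= threshold)
  tp <- sum(hit %in% qtn_indices)
  fp <- length(hit) - tp
  n_qtn <- length(qtn_indices)
  structure(list(power = tp / n_qtn,
                 fdr = fp / (m - n_qtn),
                 fdr_conventional = if (length(hit)) fp / length(hit) else 0,
                 type1 = fp / m,
                 n_detected = tp, n_false = fp, threshold = threshold),
            class = "gwas_eval")
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: dosages centred by twice the allele frequency,
#' `G = Z Z' / (2 * sum p (1 - p))`. Monomorphic markers are excluded.
#'
#' @param gm a complete [geno_matrix()] with >= 2 polymorphic markers.
#' @return a symmetric individuals x individuals matrix.
#' @export
vanraden_grm <- function(gm) {
  validate_geno_matrix(gm)
  if (anyNA(gm$calls)) stopf("GRM needs a complete matrix")
  p <- colMeans(gm$calls) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stopf("fewer than 2 polymorphic markers")
  Z <- sweep(gm$calls[, poly, drop = FALSE], 2, 2 * p[poly])
  G <- tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(G) <- list(gm$taxa, gm$taxa)
  G
}

#' GBLUP variance components and predictions by REML
#'
#' Fits the single-random-effect mixed model `y = mu + g + e`,
#' `g ~ N(0, sigma2_A G)`, `e ~ N(0, sigma2_E I)` on the individuals with
#' observed phenotypes. After one eigendecomposition of the training-block
#' GRM the restricted likelihood reduces to a 1-D profile over the variance
#' ratio `lambda = sigma2_A / sigma2_E`, maximised with
#' [stats::optimize()] on the log scale. Heritability is
#' `h2 = sigma2_A / (sigma2_A + sigma2_E) = lambda / (1 + lambda)`.
#' Individuals with `NA` phenotypes are predicted by BLUP of their genetic
#' values from the training records plus the estimated mean.
#'
#' @param G genomic relationship matrix (PSD up to jitter; `1e-8` is added
#'   to the diagonal when the smallest eigenvalue is negative).
#' @param phenotype numeric vector with `NA` for held-out individuals.
#' @param lambda_bounds log10 search interval for the variance ratio.
#' @return a list of class `gblup_fit`: `h2_hat`, `sigma2_A`, `sigma2_E`,
#'   `mu`, `loglik`, `predictions` (named, held-out individuals only),
#'   `lambda`.
#' @export
gblup_fit <- function(G, phenotype, lambda_bounds = c(-6, 6)) {
  n_all <- nrow(G)
  if (length(phenotype) != n_all) stopf("phenotype length != nrow(G)")
  train <- which(!is.na(phenotype))
  if (length(train) < 10) stopf("need >= 10 training individuals")
  y <- phenotype[train]
  if (var(y) == 0) stopf("training phenotype has zero variance")
  Gt <- G[train, train, drop = FALSE]
  eg <- eigen(Gt, symmetric = TRUE)
  if (min(eg$values) < 0) {
    Gt <- Gt + diag(1e-8, nrow(Gt))
    eg <- eigen(Gt, symmetric = TRUE)
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.vector(crossprod(U, y))
  xt <- as.vector(crossprod(U, rep(1, length(y))))
  n <- length(y)
  reml_ll <- function(log10_lambda) {
    lam <- 10^log10_lambda
    v <- lam * d + 1
    w <- 1 / v
    sxx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / sxx
    rss <- sum(w * (yt - xt * mu)^2)
    s2e <- rss / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * s2e) + 1) + sum(log(v)) + log(sxx))
  }
  opt <- optimize(reml_ll, lambda_bounds, maximum = TRUE, tol = 1e-8)
  if (!is.finite(opt$objective))
    stopf("REML did not converge (loglik = %s)", opt$objective)
  lam <- 10^opt$maximum
  v <- lam * d + 1
  w <- 1 / v
  sxx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / sxx
  s2e <- sum(w * (yt - xt * mu)^2) / (n - 1)
  s2a <- lam * s2e
  h2 <- lam / (1 + lam)
  # BLUP for held-out individuals: g_test = s2a * G[test, train] V^-1 (y - mu)
  test <- which(is.na(phenotype))
  preds <- NULL
  if (length(test)) {
    alpha <- U %*% (w * as.vector(crossprod(U, y - mu))) / s2e
    ghat <- as.vector(G[test, train, drop = FALSE] %*% alpha) * s2a
    preds <- setNames(mu + ghat, rownames(G)[test])
  }
  structure(list(h2_hat = h2, sigma2_A = s2a, sigma2_E = s2e, mu = mu,
                 loglik = opt$objective, predictions = preds, lambda = lam),
            class = "gblup_fit")
}

#' Cross-validated genomic prediction accuracy
#'
#' Per replicate, individuals are split into `folds` random equal subsets
#' (sizes differ by at most one); each fold's phenotypes are hidden in turn
#' and predicted by [gblup_fit()] trained on the remaining folds. Accuracy
#' is the Pearson correlation between the pooled predictions and the
#' phenotypes; the mean over replicates is reported.
#'
#' @param gm a complete [geno_matrix()] (used to build the GRM once), or a
#'   precomputed GRM matrix.
#' @param phenotype numeric vector.
#' @param folds number of folds (default 5).
#' @param replicates number of random re-partitions (default 30).
#' @param seed master seed.
#' @return a list of class `gblup_eval`: `accuracy` (mean), `h2_hat`
#'   (mean full-data estimate refit per replicate partition is identical,
#'   so estimated once), `per_replicate`, `folds`, `replicates`.
#' @export
cross_validate <- function(gm, phenotype, folds = 5, replicates = 30, seed) {
  G <- if (is.matrix(gm)) gm else vanraden_grm(gm)
  n <- nrow(G)
  if (n < 2 * folds) stopf("need at least %d individuals for %d folds", 2 * folds, folds)
  acc <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(child_seed(seed, r))
    fold_of <- sample(rep_len(seq_len(folds), n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      yf <- phenotype
      yf[fold_of == f] <- NA
      fit <- gblup_fit(G, yf)
      pred[fold_of == f] <- fit$predictions
    }
    if (sd(pred) == 0) {
      warnf("replicate %d: predictions have zero variance; skipped", r)
      acc[r] <- NA
    } else {
      acc[r] <- cor(pred, phenotype)
    }
  }
  h2_full <- gblup_fit(G, phenotype)$h2_hat
  structure(list(accuracy = mean(acc, na.rm = TRUE), h2_hat = h2_full,
                 per_replicate = acc, folds = folds, replicates = replicates),
            class = "gblup_eval")
}

#' Compare downstream analyses across matched genotype datasets
#'
#' Runs the GWAS power/FDR/Type-I harness and/or GBLUP
#' heritability + cross-validated prediction on a set of genotype matrices
#' with identical taxa and markers (typically the non-missing truth and one
#' or more imputed versions). Phenotypes are simulated once per replicate
#' from the first (reference) dataset with shared seeds, so every dataset
#' is evaluated against the same QTN architecture.
#'
#' @param datasets named list of complete [geno_matrix()] objects with
#'   identical dimensions and taxa; the first is the phenotype-generating
#'   reference.
#' @param gwas_replicates,gp_replicates replicate counts (0 disables that
#'   harness). Field defaults follow the study design this harness
#'   reproduces: 60 GWAS and 30 GP replicates.
#' @param n_qtn_gwas,n_qtn_gp QTN counts for the two harnesses.
#' @param h2 simulated heritability.
#' @param folds cross-validation folds.
#' @param cv_replicates partitions per GP replicate.
#' @param threshold GWAS detection threshold (default Bonferroni).
#' @param seed master seed.
#' @return a `data.frame`, one row per dataset x harness x replicate, with
#'   `power`, `fdr`, `fdr_conventional`, `type1`, `h2_hat`, `accuracy`
#'   (NA where not applicable).
#' @export
compare_datasets <- function(datasets, gwas_replicates = 60,
                             gp_replicates = 30, n_qtn_gwas = 20,
                             n_qtn_gp = 10, h2 = 0.75, folds = 5,
                             cv_replicates = 1, threshold = NULL, seed) {
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stopf("datasets must be a named list")
  ref <- datasets[[1]]
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    if (!identical(dim(d$calls), dim(ref$calls)) ||
        !identical(d$taxa, ref$taxa))
      stopf("dataset '%s' does not match the reference dimensions/taxa", nm)
  }
  thr <- threshold %||% (0.05 / n_markers(ref))
  rows <- list()
  for (r in seq_len(gwas_replicates)) {
    sim <- simulate_phenotype(ref, n_qtn = n_qtn_gwas, h2 = h2,
                              seed = child_seed(seed, r))
    for (nm in names(datasets)) {
      ev <- power_fdr_type1(gwas_scan(datasets[[nm]], sim$phenotype),
                            sim$qtn$indices, threshold = thr)
      rows[[length(rows) + 1L]] <-
        data.frame(dataset = nm, harness = "gwas", replicate = r,
                   power = ev$power, fdr = ev$fdr,
                   fdr_conventional = ev$fdr_conventional, type1 = ev$type1,
                   h2_hat = NA_real_, accuracy = NA_real_)
    }
  }
  grms <- lapply(datasets, vanraden_grm)
  for (r in seq_len(gp_replicates)) {
    sim <- simulate_phenotype(ref, n_qtn = n_qtn_gp, h2 = h2,
                              seed = child_seed(seed, 100000L + r))
    for (nm in names(datasets)) {
      cv <- cross_validate(grms[[nm]], sim$phenotype, folds = folds,
                           replicates = cv_replicates,
                           seed = child_seed(seed, 200000L + r))
      rows[[length(rows) + 1L]] <-
        data.frame(dataset = nm, harness = "gp", replicate = r,
                   power = NA_real_, fdr = NA_real_,
                   fdr_conventional = NA_real_, type1 = NA_real_,
                   h2_hat = cv$h2_hat, accuracy = cv$accuracy)
    }
  }
  do.call(rbind, rows)
}
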