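test_that("phenotype simulation hits the target heritability in expectation", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 100, n_markers = 800,
                        seed = 50)
  h2_real <- vapply(1:15, function(s) {
    sim <- simulate_phenotype(pop$genotypes, n_qtn = 20, h2 = 0.75, seed = s)
    var(sim$qtn$genetic_values) / var(sim$phenotype)
  }, numeric(1))
  expect_lt(abs(mean(h2_real) - 0.75), 0.1)
  # V_E follows the heritability ratio exactly
  sim <- simulate_phenotype(pop$genotypes, n_qtn = 10, h2 = 0.75, seed = 1)
  expect_equal(sim$qtn$V_E, sim$qtn$V_A * (1 - 0.75) / 0.75)
  # h2 -> 1 limit: phenotype = genetic value
  sim1 <- simulate_phenotype(pop$genotypes, n_qtn = 10, h2 = 1 - 1e-12, seed = 2)
  expect_equal(sim1$phenotype, sim1$qtn$genetic_values, tolerance = 1e-4)
})

test_that("scan p-value equals the closed-form regression t-test", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 40, n_markers = 30,
                        seed = 51)
  sim <- simulate_phenotype(pop$genotypes, n_qtn = 5, h2 = 0.5, seed = 3)
  p <- gwas_scan(pop$genotypes, sim$phenotype)
  for (j in c(1, 7, 30)) {
    x <- pop$genotypes$calls[, j]
    p_lm <- if (var(x) == 0) 1 else
      summary(lm(sim$phenotype ~ x))$coefficients[2, 4]
    expect_equal(p[j], p_lm, tolerance = 1e-10)
  }
})

test_that("null phenotypes give uniform p-values and calibrated type-I", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 60, n_markers = 5000,
                        recomb_rate = 0.5, pool_size = 120, seed = 52)
  set.seed(4)
  y <- rnorm(60)
  p <- gwas_scan(pop$genotypes, y)
  poly <- apply(pop$genotypes$calls, 2, var) > 0
  ks <- suppressWarnings(ks.test(p[poly], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(abs(mean(p[poly] <= 0.05) - 0.05) < 0.02)
})

test_that("a dominant QTN attains the minimum p-value", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 200, n_markers = 300,
                        recomb_rate = 0.5, pool_size = 400, seed = 53)
  set.seed(5)
  j <- 137L
  y <- 10 * pop$genotypes$calls[, j] + rnorm(200, 0, 0.1)
  p <- gwas_scan(pop$genotypes, y)
  expect_identical(which.min(p), j)
})

test_that("power/FDR/type-I follow the per-QTN accounting", {
  # 20 QTNs, exactly one detected, no false positives -> power 5%
  p <- rep(1, 1000)
  qtn <- seq(10, 200, by = 10)
  p[qtn[1]] <- 1e-9
  ev <- power_fdr_type1(p, qtn)
  expect_equal(ev$power, 0.05)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$type1, 0)
  # all markers detected
  ev2 <- power_fdr_type1(rep(0, 1000), qtn)
  expect_equal(ev2$power, 1)
  expect_equal(ev2$fdr, 1)
  expect_equal(ev2$type1, 980 / 1000)
  expect_equal(ev2$fdr_conventional, 980 / 1000)
})

test_that("accounting matches exhaustive counting on a hand-built vector", {
  p <- c(0.001, 0.2, 0.0004, 0.9, 0.01, 0.3, 0.002, 0.5, 0.04, 0.6)
  qtn <- c(3, 8)
  thr <- 0.01
  ev <- power_fdr_type1(p, qtn, threshold = thr)
  hits <- which(p <= thr)
  tp <- length(intersect(hits, qtn))
  fp <- length(setdiff(hits, qtn))
  expect_equal(ev$power, tp / 2)
  expect_equal(ev$fdr, fp / 8)
  expect_equal(ev$type1, fp / 10)
  expect_equal(ev$fdr_conventional, fp / length(hits))
  expect_error(power_fdr_type1(p, c(3, 99)), "outside")
})

test_that("fdr dominates type-I whenever QTNs exist", {
  set.seed(6)
  for (rep in 1:20) {
    p <- runif(50)
    qtn <- sample(50, 5)
    ev <- power_fdr_type1(p, qtn, threshold = 0.2)
    expect_gte(ev$fdr, ev$type1)
    expect_true(all(c(ev$power, ev$fdr, ev$type1) >= 0 &
                      c(ev$power, ev$fdr, ev$type1) <= 1))
  }
})

test_that("VanRaden GRM: symmetry, duplicates, and unit mean diagonal", {
  gm <- random_gm(6, 40, miss = 0, seed = 7)
  gm$calls[2, ] <- gm$calls[1, ]  # duplicate individuals
  G <- vanraden_grm(gm)
  expect_lt(max(abs(G - t(G))), 1e-12)
  expect_equal(G[1, 1], G[2, 2])
  expect_equal(G[1, 2], G[1, 1])
  diags <- vapply(1:5, function(s) {
    pop <- sim_population(n_subpops = 1, n_per_subpop = 50, n_markers = 600,
                          recomb_rate = 0.5, pool_size = 100, seed = 60 + s)
    mean(diag(vanraden_grm(pop$genotypes)))
  }, numeric(1))
  expect_lt(abs(mean(diags) - 1), 0.05)
  mono <- geno_matrix(matrix(2L, 4, 3), taxa = letters[1:4])
  expect_error(vanraden_grm(mono), "polymorphic")
})

test_that("h2 formula: variance components 3 and 1 give 0.75", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 80, n_markers = 500,
                        seed = 70)
  sim <- simulate_phenotype(pop$genotypes, n_qtn = 10, h2 = 0.75, seed = 8)
  expect_equal(sim$qtn$V_A / (sim$qtn$V_A + sim$qtn$V_E), 0.75)
  # and the REML parameterisation maps lambda to h2 = lambda / (1 + lambda)
  fit <- gblup_fit(vanraden_grm(pop$genotypes), sim$phenotype)
  expect_equal(fit$h2_hat, fit$sigma2_A / (fit$sigma2_A + fit$sigma2_E),
               tolerance = 1e-12)
})

test_that("REML optimum matches a grid search over the variance ratio", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 30, n_markers = 400,
                        seed = 71)
  sim <- simulate_phenotype(pop$genotypes, n_qtn = 10, h2 = 0.6, seed = 9)
  G <- vanraden_grm(pop$genotypes)
  fit <- gblup_fit(G, sim$phenotype)
  # independent profile-REML evaluation on a fine lambda grid
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- as.vector(crossprod(eg$vectors, sim$phenotype))
  xt <- as.vector(crossprod(eg$vectors, rep(1, 30)))
  ll <- function(lam) {
    v <- lam * d + 1; w <- 1 / v
    mu <- sum(w * xt * yt) / sum(w * xt^2)
    s2e <- sum(w * (yt - xt * mu)^2) / 29
    -0.5 * (29 * (log(2 * pi * s2e) + 1) + sum(log(v)) + log(sum(w * xt^2)))
  }
  grid <- 10^seq(-6, 6, length.out = 20000)
  best <- max(vapply(grid, ll, numeric(1)))
  expect_lt(abs(fit$loglik - best), 1e-6)
  expect_gte(fit$loglik, best - 1e-9)
})

test_that("pure-noise phenotypes yield near-zero heritability estimates", {
  low <- vapply(1:10, function(s) {
    pop <- sim_population(n_subpops = 1, n_per_subpop = 100, n_markers = 400,
                          seed = 80 + s)
    set.seed(s)
    gblup_fit(vanraden_grm(pop$genotypes), rnorm(100))$h2_hat
  }, numeric(1))
  expect_gte(sum(low < 0.15), 9)
})

test_that("cross-validation: perfect signal, permutation null, fold balance", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 100, n_markers = 500,
                        seed = 90)
  G <- vanraden_grm(pop$genotypes)
  sim <- simulate_phenotype(pop$genotypes, n_qtn = 10, h2 = 0.9, seed = 10)
  cv <- cross_validate(G, sim$phenotype, folds = 5, replicates = 3, seed = 11)
  expect_gt(cv$accuracy, 0.3)
  expect_true(abs(cv$accuracy) <= 1)
  # permutation null: mean accuracy over independent permutations near zero
  acc0 <- vapply(1:10, function(s) {
    set.seed(s)
    cross_validate(G, sample(sim$phenotype), folds = 5, replicates = 1,
                   seed = 13 + s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(acc0)), 0.1)
  # fold sizes differ by at most one
  set.seed(child_seed(11, 1))
  fold_of <- sample(rep_len(1:5, 100))
  expect_lte(diff(range(tabulate(fold_of))), 1)
})

test_that("dataset comparison is exact under self-comparison and has full cardinality", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 50, n_markers = 200,
                        seed = 95)
  gm <- pop$genotypes
  out <- compare_datasets(list(nd = gm, copy = gm), gwas_replicates = 3,
                          gp_replicates = 2, folds = 5, seed = 14)
  expect_identical(nrow(out), 2L * 3L + 2L * 2L)
  gw <- out[out$harness == "gwas", ]
  for (r in unique(gw$replicate)) {
    a <- gw[gw$replicate == r & gw$dataset == "nd", ]
    b <- gw[gw$replicate == r & gw$dataset == "copy", ]
    expect_equal(a$power, b$power)
    expect_equal(a$fdr, b$fdr)
    expect_equal(a$type1, b$type1)
  }
  gp <- out[out$harness == "gp", ]
  expect_equal(gp$h2_hat[gp$dataset == "nd"], gp$h2_hat[gp$dataset == "copy"])
  bad <- geno_matrix(gm$calls[1:10, ], taxa = gm$taxa[1:10],
                     markers = gm$markers)
  expect_error(compare_datasets(list(nd = gm, bad = bad), seed = 1),
               "dimensions")
})

test_that("truth dominates imputed data for GWAS power in the majority", {
  pop <- sim_population(n_subpops = 3, n_per_subpop = 15, n_markers = 400,
                        divergence = 0.3, seed = 96)
  mk <- mask_genotypes(pop$genotypes, 0.15, seed = 97)
  kid <- cluster_impute(mk$masked, seed = 98)$completed
  out <- compare_datasets(list(nd = pop$genotypes, kid = kid),
                          gwas_replicates = 10, gp_replicates = 0,
                          threshold = 0.001, seed = 99)
  gw <- out[out$harness == "gwas", ]
  nd_pow <- gw$power[gw$dataset == "nd"]
  kid_pow <- gw$power[gw$dataset == "kid"]
  expect_gte(mean(nd_pow >= kid_pow), 0.5)
})
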