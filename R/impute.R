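#' Haplotype-copying HMM parameters
#'
#' @param switch_prob per-adjacent-marker probability that a copied
#'   haplotype switches (recombination analogue), in (0, 1). The default is
#'   a flat 0.01 per interval; no genetic map is used because the panels
#'   handled here sit on a single pseudo-chromosome.
#' @param mismatch_prob per-marker probability that the emitted allele
#'   differs from the copied haplotype's allele (mutation/genotyping-error
#'   analogue), in (0, 0.5).
#' @param em_iters maximum phase-refinement sweeps when building a panel.
#' @param tol convergence tolerance (reserved; sweeps also stop when no
#'   phase flips occur).
#' @return a list of class `hmm_params`.
#' @export
hmm_params <- function(switch_prob = 0.01, mismatch_prob = 0.005,
                       em_iters = 10, tol = 1e-6) {
  if (switch_prob <= 0 || switch_prob >= 1) stopf("switch_prob must be in (0, 1)")
  if (mismatch_prob <= 0 || mismatch_prob >= 0.5)
    stopf("mismatch_prob must be in (0, 0.5)")
  structure(list(switch_prob = switch_prob, mismatch_prob = mismatch_prob,
                 em_iters = as.integer(em_iters), tol = tol),
            class = "hmm_params")
}

# best panel-match count for hap restricted to columns cols (observed only);
# returns list(score, row)
best_panel_match <- function(panel, hap, cols) {
  if (!length(cols)) return(list(score = 0, row = 1L))
  Pw <- panel[, cols, drop = FALSE]
  a <- hap[cols]
  matches <- as.vector(Pw %*% a + (1 - Pw) %*% (1 - a))
  r <- which.max(matches)
  list(score = matches[r], row = r)
}

#' Build a reference haplotype panel by iterative phasing
#'
#' Phases N individuals into 2N binary haplotypes. Heterozygote phases are
#' initialised at random; window-chained sweeps then re-phase each
#' individual against the panel of all other haplotypes, choosing for each
#' marker window the phase configuration (keep vs. switch the suffix) that
#' best matches some reference haplotype across the window and its left
#' context under the copying model. Markers where an individual is missing
#' contribute nothing to the score; after the final sweep those entries are
#' filled by copying the best-matching reference haplotype locally, so the
#' panel is fully binary.
#'
#' @param gm a [geno_matrix()] with >= 2 individuals.
#' @param params an [hmm_params()].
#' @param seed random seed (phase initialisation).
#' @param window phasing window length in markers.
#' @return a binary `2N x M` matrix of class `haplotype_panel`; rows
#'   `2i-1` and `2i` are the haplotype pair of individual `i`.
#' @export
build_haplotype_panel <- function(gm, params = hmm_params(), seed,
                                  window = 50) {
  validate_geno_matrix(gm)
  N <- n_taxa(gm); M <- n_markers(gm)
  if (N < 2) stopf("panel construction needs >= 2 individuals")
  set.seed(seed)
  G <- gm$calls
  p_hat <- colMeans(G, na.rm = TRUE) / 2
  p_hat[is.nan(p_hat)] <- 0.5
  H <- matrix(0, 2 * N, M)
  for (i in seq_len(N)) {
    g <- G[i, ]
    h1 <- h2 <- numeric(M)
    hom2 <- !is.na(g) & g == 2L
    h1[hom2] <- h2[hom2] <- 1
    het <- !is.na(g) & g == 1L
    if (any(het)) {
      flip <- rbinom(sum(het), 1L, 0.5)
      h1[het] <- flip
      h2[het] <- 1 - flip
    }
    mis <- is.na(g)
    if (any(mis)) {
      h1[mis] <- rbinom(sum(mis), 1L, p_hat[mis])
      h2[mis] <- rbinom(sum(mis), 1L, p_hat[mis])
    }
    H[2 * i - 1, ] <- h1
    H[2 * i, ] <- h2
  }
  win_start <- seq(1, M, by = window)
  n_win <- length(win_start)
  win_cols <- lapply(seq_len(n_win), function(w)
    win_start[w]:min(M, win_start[w] + window - 1L))
  obs_by_ind <- lapply(seq_len(N), function(i) !is.na(G[i, ]))
  for (it in seq_len(params$em_iters)) {
    flips <- 0L
    for (i in seq_len(N)) {
      ref <- H[-c(2 * i - 1, 2 * i), , drop = FALSE]
      h1 <- H[2 * i - 1, ]; h2 <- H[2 * i, ]
      obs <- obs_by_ind[[i]]
      if (n_win >= 2) {
        for (w in 2:n_win) {
          ctx <- c(win_cols[[w - 1]], win_cols[[w]])
          ctx <- ctx[obs[ctx]]
          if (length(ctx) < 2) next
          suffix <- win_cols[[w]][1]:M
          # candidate = swap haplotypes from this window onward
          c1 <- h1; c2 <- h2
          c1[suffix] <- h2[suffix]; c2[suffix] <- h1[suffix]
          keep <- best_panel_match(ref, h1, ctx)$score +
            best_panel_match(ref, h2, ctx)$score
          swp <- best_panel_match(ref, c1, ctx)$score +
            best_panel_match(ref, c2, ctx)$score
          if (swp > keep) {
            h1 <- c1; h2 <- c2
            flips <- flips + 1L
          }
        }
      }
      H[2 * i - 1, ] <- h1
      H[2 * i, ] <- h2
    }
    if (flips == 0L) break
  }
  # local copy-fill of haplotype entries at missing genotypes
  for (i in seq_len(N)) {
    mis <- !obs_by_ind[[i]]
    if (!any(mis)) next
    ref <- H[-c(2 * i - 1, 2 * i), , drop = FALSE]
    for (w in seq_len(n_win)) {
      cols <- win_cols[[w]]
      mcols <- cols[mis[cols]]
      if (!length(mcols)) next
      ocols <- cols[!mis[cols]]
      for (r in c(2 * i - 1, 2 * i)) {
        best <- best_panel_match(ref, H[r, ], ocols)$row
        H[r, mcols] <- ref[best, mcols]
      }
    }
  }
  storage.mode(H) <- "integer"
  structure(H, class = c("haplotype_panel", class(H)))
}

#' Diploid forward-backward posteriors for one individual
#'
#' Runs the haplotype-copying HMM over ordered reference-haplotype pairs:
#' uniform initial distribution, independent per-haplotype switching with
#' probability `switch_prob` to a uniformly chosen haplotype, and a
#' symmetric per-allele flip emission with probability `mismatch_prob`.
#' Missing markers emit probability 1. Genotype posteriors at the requested
#' markers are obtained by collapsing the pair-state posterior through the
#' emission model.
#'
#' @param obs integer genotype vector (0/1/2/NA) aligned to the panel.
#' @param panel a binary H x M haplotype matrix.
#' @param params an [hmm_params()].
#' @param at marker indices where posteriors are wanted (default: the
#'   missing markers of `obs`).
#' @return a list: `post` (3 x length(at) matrix of P(0), P(1), P(2)),
#'   `at`, and `loglik`.
#' @export
forward_backward <- function(obs, panel, params = hmm_params(),
                             at = which(is.na(obs))) {
  panel <- unclass(panel)
  storage.mode(panel) <- "integer"
  if (nrow(panel) < 1) stopf("empty haplotype panel")
  if (length(obs) != ncol(panel)) stopf("genotype length != panel markers")
  if (all(is.na(obs))) stopf("observation row has no non-missing call")
  at <- unname(at)
  g <- as.integer(obs)
  g[is.na(g)] <- -1L
  want <- integer(length(obs))
  want[at] <- 1L
  res <- .ls_forward_backward(panel, g, params$switch_prob,
                              params$mismatch_prob, want)
  list(post = res$post[, at, drop = FALSE], at = at, loglik = res$loglik)
}

#' Impute missing genotypes with the haplotype-copying HMM
#'
#' Builds a phased reference panel from all individuals, then imputes each
#' individual with missing calls by forward-backward against the panel
#' excluding that individual's own two haplotypes (leave-one-out). The
#' imputed call is the posterior argmax, ties broken toward the
#' heterozygote, then the major homozygote. To bound the O(H^2) pair-state
#' space, reference panels larger than `max_haplotypes` rows are randomly
#' subsampled (per-individual derived seed).
#'
#' @param gm a [geno_matrix()]; every marker must retain at least one
#'   non-missing call.
#' @param params an [hmm_params()].
#' @param seed random seed.
#' @param max_haplotypes reference-panel cap (default 200).
#' @return a list of class `imputation_result`: `completed` (a
#'   [geno_matrix()] with no missing calls), `posteriors` (data frame with
#'   columns `ind`, `marker`, `p0`, `p1`, `p2`), `engine` (`"hmm"`).
#' @export
impute_hmm <- function(gm, params = hmm_params(), seed,
                       max_haplotypes = 200) {
  validate_geno_matrix(gm)
  check_markers_informative(gm)
  miss_by_ind <- unname(which(rowSums(is.na(gm$calls)) > 0))
  if (!length(miss_by_ind))
    return(new_imputation_result(gm, empty_posteriors(), "hmm"))
  panel <- build_haplotype_panel(gm, params, seed = child_seed(seed, 1L))
  completed <- gm$calls
  posts <- vector("list", length(miss_by_ind))
  for (k in seq_along(miss_by_ind)) {
    i <- miss_by_ind[k]
    ref_rows <- setdiff(seq_len(nrow(panel)), c(2 * i - 1, 2 * i))
    if (length(ref_rows) > max_haplotypes) {
      set.seed(child_seed(seed, 1000L + i))
      ref_rows <- sort(sample(ref_rows, max_haplotypes))
    }
    fb <- forward_backward(gm$calls[i, ], unclass(panel)[ref_rows, , drop = FALSE],
                           params)
    calls <- apply(fb$post, 2, posterior_argmax)
    completed[i, fb$at] <- calls
    posts[[k]] <- data.frame(ind = i, marker = unname(fb$at),
                             p0 = fb$post[1, ], p1 = fb$post[2, ],
                             p2 = fb$post[3, ])
  }
  out <- gm
  out$calls <- completed
  new_imputation_result(out, do.call(rbind, posts), "hmm")
}

posterior_argmax <- function(p, tol = 1e-12) {
  cand <- which(p >= max(p) - tol) - 1L  # genotype codes
  for (g in c(1L, 0L, 2L)) if (g %in% cand) return(g)
  cand[1]
}

check_markers_informative <- function(gm) {
  allmiss <- colSums(!is.na(gm$calls)) == 0
  if (any(allmiss))
    stopf("marker(s) entirely missing: %s",
          paste(gm$markers$name[allmiss], collapse = ", "))
  invisible(gm)
}

new_imputation_result <- function(gm, posteriors, engine) {
  structure(list(completed = gm, posteriors = posteriors, engine = engine),
            class = "imputation_result")
}

empty_posteriors <- function() {
  data.frame(ind = integer(0), marker = integer(0),
             p0 = numeric(0), p1 = numeric(0), p2 = numeric(0))
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result [%s]: %d cells imputed over %d individuals\n",
              x$engine, nrow(x$posteriors), length(unique(x$posteriors$ind))))
  invisible(x)
}

#' Frequency-baseline imputation
#'
#' Control engine: each missing cell is filled with the most frequent
#' genotype at its marker (ties broken toward the lower numeric code);
#' posteriors are the empirical genotype frequencies.
#'
#' @inheritParams impute_hmm
#' @return an `imputation_result` with engine `"baseline"`.
#' @export
impute_baseline <- function(gm) {
  validate_geno_matrix(gm)
  check_markers_informative(gm)
  completed <- gm$calls
  posts <- list()
  mcols <- unname(which(colSums(is.na(gm$calls)) > 0))
  for (j in mcols) {
    col <- gm$calls[, j]
    obs <- col[!is.na(col)]
    cnt <- tabulate(obs + 1L, nbins = 3L)
    freq <- cnt / sum(cnt)
    modal <- which.max(cnt) - 1L  # which.max takes first max -> lower code
    rows <- unname(which(is.na(col)))
    completed[rows, j] <- modal
    posts[[length(posts) + 1L]] <-
      data.frame(ind = rows, marker = j,
                 p0 = freq[1], p1 = freq[2], p2 = freq[3])
  }
  out <- gm
  out$calls <- completed
  posts <- if (length(posts)) do.call(rbind, posts) else empty_posteriors()
  posts <- posts[order(posts$ind, posts$marker), , drop = FALSE]
  rownames(posts) <- NULL
  new_imputation_result(out, posts, "baseline")
}

#' Impute through an external Beagle jar
#'
#' Thin optional shell: writes the panel as VCF, invokes `java -jar
#' beagle.jar`, and parses the imputed VCF back, restoring the input taxa
#' order. Requires a Java runtime and the jar; neither is assumed present.
#'
#' @param gm a [geno_matrix()].
#' @param beagle_jar path to a Beagle 5.x jar.
#' @param workdir scratch directory for the VCF exchange files.
#' @param java java executable name/path.
#' @return an `imputation_result` with engine `"beagle-external"`.
#' @export
impute_beagle_external <- function(gm, beagle_jar,
                                   workdir = tempfile("beagle"),
                                   java = "java") {
  validate_geno_matrix(gm)
  if (!file.exists(beagle_jar))
    stopf("Beagle jar not found: %s (external backend unavailable)", beagle_jar)
  if (Sys.which(java) == "")
    stopf("no '%s' runtime on PATH (external backend unavailable)", java)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  in_vcf <- file.path(workdir, "target.vcf")
  out_prefix <- file.path(workdir, "imputed")
  write_geno_vcf(gm, in_vcf)
  status <- system2(java, c("-jar", shQuote(beagle_jar),
                            paste0("gt=", shQuote(in_vcf)),
                            paste0("out=", shQuote(out_prefix))),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0)
    stopf("Beagle exited with status %d:\n%s", code,
          paste(status, collapse = "\n"))
  out_vcf <- paste0(out_prefix, ".vcf.gz")
  if (!file.exists(out_vcf)) stopf("Beagle produced no output VCF")
  res <- read_geno_vcf(out_vcf)
  res <- reorder_taxa(res, gm$taxa)
  new_imputation_result(res, empty_posteriors(), "beagle-external")
}
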