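#' Simulate a structured diploid SNP panel
#'
#' Generates `n_subpops` diverged subpopulations from subpopulation-specific
#' founder haplotype pools. Ancestral allele frequencies are drawn from
#' Uniform(0.05, 0.95); subpopulation frequencies follow a Balding-Nichols
#' Beta model in which `divergence` plays the role of F_ST. Each
#' subpopulation gets `pool_size` founder haplotypes (per-site Bernoulli),
#' and every individual receives two mosaic haplotypes built by copying
#' founders with per-adjacent-marker switch probability `recomb_rate` —
#' mosaic copying keeps the long shared haplotype blocks that stratified
#' imputation exploits. Columns are oriented so that 0 is always the major
#' homozygote (flipping a column flips its haplotypes too, preserving the
#' haplotype-sum identity).
#'
#' @param n_subpops number of subpopulations (K_true).
#' @param n_per_subpop individuals per subpopulation.
#' @param n_markers marker count.
#' @param divergence between-subpopulation allele-frequency divergence in
#'   `[0, 1]` (F_ST analogue); 0 collapses to a homogeneous panel.
#' @param pool_size founder haplotypes per subpopulation.
#' @param recomb_rate per-adjacent-marker founder-switch probability in
#'   `[0, 0.5]`.
#' @param seed random seed (required; the generator is deterministic).
#' @return a list of class `sim_population`: `genotypes` (a complete
#'   [geno_matrix()]), `haplotypes` (a `2N x M` binary matrix, rows
#'   `2i-1`/`2i` belonging to individual `i`), and `subpop` (integer labels
#'   `1..n_subpops`).
#' @export
sim_population <- function(n_subpops = 3, n_per_subpop = 30,
                           n_markers = 10000, divergence = 0.3,
                           pool_size = 8, recomb_rate = 0.01, seed) {
  if (missing(seed)) stopf("sim_population() requires an explicit seed")
  stopifnot(n_subpops >= 1, n_per_subpop >= 1, n_markers >= 1, pool_size >= 1)
  if (divergence < 0 || divergence > 1) stopf("divergence must be in [0, 1]")
  if (recomb_rate < 0 || recomb_rate > 0.5) stopf("recomb_rate must be in [0, 0.5]")
  set.seed(seed)
  p_anc <- runif(n_markers, 0.05, 0.95)
  n_ind <- n_subpops * n_per_subpop
  H <- matrix(0L, 2L * n_ind, n_markers)
  labels <- rep(seq_len(n_subpops), each = n_per_subpop)
  for (s in seq_len(n_subpops)) {
    if (divergence == 0) {
      p_s <- p_anc
    } else {
      shape <- (1 - divergence) / divergence
      p_s <- rbeta(n_markers, p_anc * shape, (1 - p_anc) * shape)
    }
    founders <- matrix(rbinom(pool_size * n_markers, 1L, rep(p_s, each = pool_size)),
                       nrow = pool_size)
    hap_rows <- which(rep(labels == s, each = 2))
    for (r in hap_rows) {
      path <- mosaic_path(n_markers, pool_size, recomb_rate)
      H[r, ] <- founders[cbind(path, seq_len(n_markers))]
    }
  }
  calls <- H[seq(1, 2 * n_ind, by = 2), , drop = FALSE] +
    H[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
  # orient columns so the counted allele is the minor one (0 = major hom.)
  freq1 <- colMeans(H)
  flip <- freq1 > 0.5
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip]
    H[, flip] <- 1L - H[, flip]
  }
  gm <- geno_matrix(calls,
                    taxa = sprintf("ind%03d", seq_len(n_ind)),
                    markers = marker_table(paste0("M", seq_len(n_markers)),
                                           n_markers,
                                           allele_major = "A",
                                           allele_minor = "G"))
  structure(list(genotypes = gm, haplotypes = H, subpop = labels,
                 config = list(n_subpops = n_subpops,
                               n_per_subpop = n_per_subpop,
                               n_markers = n_markers, divergence = divergence,
                               pool_size = pool_size,
                               recomb_rate = recomb_rate, seed = seed)),
            class = "sim_population")
}

# founder index path for one mosaic haplotype
mosaic_path <- function(n_markers, pool_size, recomb_rate) {
  if (n_markers == 1 || recomb_rate == 0)
    return(rep(sample.int(pool_size, 1), n_markers))
  switches <- which(runif(n_markers - 1) < recomb_rate)
  bounds <- c(1L, switches + 1L, n_markers + 1L)
  seg_len <- diff(bounds)
  rep(sample.int(pool_size, length(seg_len), replace = TRUE), seg_len)
}

#' Randomly subsample markers
#'
#' Uniform subset without replacement; the original marker order is
#' preserved.
#'
#' @param gm a [geno_matrix()].
#' @param n number of markers to keep (`n <= n_markers`).
#' @param seed random seed.
#' @return a [geno_matrix()] with `n` columns.
#' @export
subset_markers <- function(gm, n, seed) {
  validate_geno_matrix(gm)
  if (n > n_markers(gm))
    stopf("cannot sample %d of %d markers", n, n_markers(gm))
  set.seed(seed)
  subset_geno(gm, j = sort(sample.int(n_markers(gm), n)))
}

#' Mask genotype cells for benchmarking
#'
#' Hides exactly `round(rate * cells)` entries sampled uniformly over all
#' cells, recording their positions and true values so the imputation
#' matching rate can be computed later. A re-draw rule guarantees no marker
#' ends up with every call missing (an all-missing column carries no
#' frequency information).
#'
#' @param gm a complete [geno_matrix()] (no missing calls).
#' @param rate target missing fraction, strictly between 0 and 1.
#' @param seed random seed.
#' @return a list: `masked` (the `geno_matrix` with cells set to `NA`) and
#'   `mask` (class `mask_spec`: `rate`, `cells` (2-column index matrix),
#'   `truth`, `seed`).
#' @export
mask_genotypes <- function(gm, rate, seed) {
  validate_geno_matrix(gm)
  if (anyNA(gm$calls)) stopf("mask_genotypes() needs a complete matrix")
  if (rate <= 0 || rate >= 1) stopf("rate must be in (0, 1)")
  set.seed(seed)
  n <- n_taxa(gm); m <- n_markers(gm)
  total <- n * m
  n_mask <- round(rate * total)
  if (n_mask >= total) stopf("rate masks every cell")
  idx <- sample.int(total, n_mask)
  masked <- logical(total)
  masked[idx] <- TRUE
  dim(masked) <- c(n, m)
  # re-draw rule: release one cell in any all-missing column, re-mask elsewhere
  guard <- 0L
  repeat {
    bad_cols <- which(colSums(masked) == n)
    if (!length(bad_cols)) break
    guard <- guard + 1L
    if (guard > 100L) stopf("mask re-draw failed; rate too close to 1?")
    for (j in bad_cols) {
      i <- sample.int(n, 1)
      masked[i, j] <- FALSE
    }
    free <- which(!masked & col(masked) %in% which(colSums(masked) < n - 1L))
    add <- sample(free, length(bad_cols))
    masked[add] <- TRUE
  }
  cells <- which(masked, arr.ind = TRUE)
  cells <- cells[order(cells[, 2], cells[, 1]), , drop = FALSE]
  truth <- gm$calls[cells]
  out <- gm
  out$calls[cells] <- NA_integer_
  spec <- structure(list(rate = rate, cells = unname(cells), truth = truth,
                         seed = seed),
                    class = "mask_spec")
  list(masked = out, mask = spec)
}

#' Restore masked cells from a mask specification
#'
#' Inverse of [mask_genotypes()]; mainly used to verify the masking
#' round-trip.
#'
#' @param gm the masked [geno_matrix()].
#' @param mask a `mask_spec`.
#' @return the `geno_matrix` with the hidden truths restored.
#' @export
unmask_genotypes <- function(gm, mask) {
  out <- gm
  out$calls[mask$cells] <- mask$truth
  out
}
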