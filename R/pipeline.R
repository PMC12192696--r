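#' Cluster-then-impute a genotype panel
#'
#' The six-stage stratified imputation pipeline: (A) validate the input;
#' (B) replace missing calls with the heterozygote placeholder and pick the
#' cluster count by silhouette-guided K-means; (C) split individuals by
#' cluster label; (D) impute every cluster independently (cluster jobs may
#' run concurrently; results are identical to sequential execution because
#' each cluster draws from its own derived seed); (E) collect the
#' per-cluster results; (F) reorder rows back to the original taxa order.
#'
#' `mode = "whole"` (or forcing `k = 1`) skips clustering and imputes the
#' whole panel at once — the single-reference-panel control.
#'
#' @param gm a [geno_matrix()].
#' @param params an [hmm_params()] for the HMM engine.
#' @param engine `"hmm"` or `"baseline"`.
#' @param mode `"cluster"` (stratified) or `"whole"` (single panel).
#' @param k_force optionally fix the cluster count instead of selecting it.
#' @param k_range,nstart silhouette search grid (see [select_k()]).
#' @param workers concurrency degree for the per-cluster jobs.
#' @param seed master seed; per-cluster child seeds are derived from it.
#' @param max_haplotypes per-cluster reference panel cap.
#' @return an `imputation_result` whose `completed` matrix is in the
#'   original taxa order, with extra fields `K_used`, `cluster_sizes` and
#'   `assignment` (the `cluster_assignment`, or `NULL` in whole mode).
#' @export
cluster_impute <- function(gm, params = hmm_params(),
                           engine = c("hmm", "baseline"),
                           mode = c("cluster", "whole"),
                           k_force = NULL, k_range = 2:10, nstart = 25,
                           workers = 1, seed, max_haplotypes = 200) {
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  validate_geno_matrix(gm)
  check_markers_informative(gm)
  assignment <- NULL
  if (mode == "whole" || identical(k_force, 1L) || identical(k_force, 1)) {
    labels <- rep(1L, n_taxa(gm))
    K <- 1L
  } else {
    X <- fill_for_clustering(gm)
    if (!is.null(k_force)) {
      fit <- kmeans_fit(X, k_force, nstart = nstart,
                        seed = child_seed(seed, 9000L + k_force))
      merged <- merge_small_clusters(X, fit$labels, fit$centers, 3)
      labels <- merged$labels
      K <- merged$K
    } else {
      assignment <- select_k(X, k_range = k_range, nstart = nstart,
                             seed = child_seed(seed, 9999L))
      labels <- assignment$labels
      K <- assignment$K
    }
  }
  groups <- split(seq_len(n_taxa(gm)), labels)
  run_one <- function(j) {
    rows <- groups[[j]]
    sub <- subset_geno(gm, i = rows)
    sub <- fill_uninformative_markers(sub, gm)
    res <- switch(engine,
                  hmm = impute_hmm(sub, params, seed = child_seed(seed, j),
                                   max_haplotypes = max_haplotypes),
                  baseline = impute_baseline(sub))
    res$posteriors$ind <- rows[res$posteriors$ind]
    res
  }
  cluster_results <- tryCatch({
    if (workers > 1 && .Platform$OS.type == "unix") {
      parallel::mclapply(seq_along(groups), run_one, mc.cores = workers)
    } else {
      lapply(seq_along(groups), run_one)
    }
  }, error = function(e) stopf("cluster imputation failed: %s", conditionMessage(e)))
  for (j in seq_along(cluster_results)) {
    if (inherits(cluster_results[[j]], "try-error") ||
        !inherits(cluster_results[[j]], "imputation_result"))
      stopf("imputation failed in cluster %d: %s", j,
            as.character(cluster_results[[j]]))
  }
  merged_gm <- do.call(rbind, lapply(cluster_results, function(r) r$completed$calls))
  merged_taxa <- unlist(lapply(cluster_results, function(r) r$completed$taxa))
  out <- reorder_taxa(geno_matrix(merged_gm, taxa = merged_taxa,
                                  markers = gm$markers), gm$taxa)
  posts <- do.call(rbind, lapply(cluster_results, function(r) r$posteriors))
  posts <- posts[order(posts$ind, posts$marker), , drop = FALSE]
  rownames(posts) <- NULL
  res <- new_imputation_result(out, posts, engine)
  res$K_used <- K
  res$cluster_sizes <- as.integer(lengths(groups))
  res$assignment <- assignment
  res
}

# markers with zero non-missing calls inside a cluster are pre-filled from
# the whole-panel modal genotype (fallback; the whole panel always has
# information there)
fill_uninformative_markers <- function(sub, whole) {
  dead <- which(colSums(!is.na(sub$calls)) == 0)
  if (!length(dead)) return(sub)
  for (j in dead) {
    obs <- whole$calls[, j]
    cnt <- tabulate(obs[!is.na(obs)] + 1L, nbins = 3L)
    sub$calls[, j] <- which.max(cnt) - 1L
  }
  sub
}

#' Imputation matching rate
#'
#' `R_match = N_correct / N_total`: the number of masked genotypes whose
#' imputed value exactly equals the hidden truth, divided by the number of
#' masked genotypes. Heterozygotes get no partial credit.
#'
#' @param result an `imputation_result` (or a completed [geno_matrix()]).
#' @param mask a `mask_spec` from [mask_genotypes()].
#' @return the matching rate in `[0, 1]`.
#' @export
matching_rate <- function(result, mask) {
  gm <- if (inherits(result, "imputation_result")) result$completed else result
  if (nrow(mask$cells) == 0) stopf("matching rate undefined for an empty mask")
  imputed <- gm$calls[mask$cells]
  if (anyNA(imputed)) stopf("masked cells not all imputed")
  mean(imputed == mask$truth)
}

#' Factorial imputation benchmark
#'
#' Simulates a structured panel, then for every combination of marker
#' subset size, mask rate, replicate and engine mode, masks the panel,
#' imputes it and records the matching rate and wall time (wall time spans
#' data input through matching-rate computation). Per-cell seeds are
#' derived from the master seed via a counter scheme, so adding replicates
#' never perturbs earlier ones.
#'
#' @param sim_cfg named list of [sim_population()] arguments (without
#'   `seed`).
#' @param subset_sizes marker subset sizes to test.
#' @param mask_rates missingness rates to test.
#' @param replicates replicate count per cell.
#' @param modes engine modes: subset of `c("cluster", "whole")`.
#' @param params an [hmm_params()].
#' @param workers concurrency degree passed to [cluster_impute()].
#' @param seed master seed.
#' @return a `data.frame` with one row per run: `engine`, `n_markers`,
#'   `mask_rate`, `replicate`, `r_match`, `wall_time`, `K_used`.
#' @export
run_benchmark <- function(sim_cfg = list(), subset_sizes, mask_rates,
                          replicates = 30, modes = c("cluster", "whole"),
                          params = hmm_params(), workers = 1, seed) {
  grid <- expand.grid(mode = modes, n_markers = subset_sizes,
                      mask_rate = mask_rates, replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rw <- grid[g, ]
    # cell seed depends on (size, rate, replicate) but not mode, so the two
    # modes see identical masked data
    cell <- child_seed(seed, rw$replicate * 10000L +
                         match(rw$n_markers, subset_sizes) * 100L +
                         match(rw$mask_rate, mask_rates))
    t0 <- proc.time()[["elapsed"]]
    pop <- do.call(sim_population, c(sim_cfg, list(seed = child_seed(cell, 1L))))
    gm <- subset_markers(pop$genotypes, rw$n_markers, seed = child_seed(cell, 2L))
    mk <- mask_genotypes(gm, rw$mask_rate, seed = child_seed(cell, 3L))
    res <- cluster_impute(mk$masked, params = params, mode = rw$mode,
                          workers = workers, seed = child_seed(cell, 4L))
    rm_ <- matching_rate(res, mk$mask)
    wall <- proc.time()[["elapsed"]] - t0
    rows[[g]] <- data.frame(engine = rw$mode, n_markers = rw$n_markers,
                            mask_rate = rw$mask_rate, replicate = rw$replicate,
                            r_match = rm_, wall_time = wall,
                            K_used = res$K_used)
  }
  do.call(rbind, rows)
}

#' Summarise a benchmark table
#'
#' Mean and standard deviation of the matching rate and wall time per
#' engine x subset-size x mask-rate cell.
#'
#' @param records output of [run_benchmark()].
#' @return an aggregated `data.frame`.
#' @export
summarize_benchmark <- function(records) {
  agg <- aggregate(cbind(r_match, wall_time) ~ engine + n_markers + mask_rate,
                   data = records, FUN = mean)
  sds <- aggregate(cbind(r_match, wall_time) ~ engine + n_markers + mask_rate,
                   data = records, FUN = sd)
  names(agg)[4:5] <- c("r_match_mean", "wall_time_mean")
  agg$r_match_sd <- sds$r_match
  agg$wall_time_sd <- sds$wall_time
  agg
}

#' Haplotype-count complexity report
#'
#' The stratified strategy reduces the haplotype diversity each HMM must
#' model: whole-panel cost scales with the number of distinct haplotypes N,
#' stratified cost with N_1 + ... + N_K over the clusters. This report
#' counts distinct haplotypes over fixed-length marker windows for the
#' whole panel and for each cluster panel and returns the ratio
#' `N / sum(N_i)` per window.
#'
#' @param whole_panel binary haplotype matrix for the full population.
#' @param cluster_panels list of binary haplotype matrices, one per cluster.
#' @param window window length in markers.
#' @return a `data.frame` with one row per window: `window`, `start`,
#'   `end`, `n_whole`, `n_cluster_sum`, `ratio`.
#' @export
haplotype_count_report <- function(whole_panel, cluster_panels, window = 50) {
  M <- ncol(whole_panel)
  starts <- seq(1, M, by = window)
  count_distinct <- function(P, cols)
    nrow(unique(unclass(P)[, cols, drop = FALSE]))
  rows <- lapply(seq_along(starts), function(w) {
    cols <- starts[w]:min(M, starts[w] + window - 1L)
    n_whole <- count_distinct(whole_panel, cols)
    n_sub <- sum(vapply(cluster_panels, count_distinct, numeric(1), cols = cols))
    data.frame(window = w, start = cols[1], end = cols[length(cols)],
               n_whole = n_whole, n_cluster_sum = n_sub,
               ratio = n_whole / n_sub)
  })
  do.call(rbind, rows)
}
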