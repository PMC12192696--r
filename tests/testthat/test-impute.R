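test_that("forward-backward matches exhaustive path enumeration", {
  params <- hmm_params(switch_prob = 0.1, mismatch_prob = 0.01)
  set.seed(600)
  for (H in 1:3) {
    for (M in 2:4) {
      panel <- matrix(rbinom(H * M, 1, 0.5), H, M)
      obs <- sample(c(0L, 1L, 2L, NA), M, replace = TRUE)
      if (all(is.na(obs))) obs[1] <- 1L
      if (!anyNA(obs)) obs[M] <- NA
      fb <- forward_backward(obs, panel, params)
      bf <- brute_force_posteriors(panel, obs, 0.1, 0.01, at = fb$at)
      expect_lt(max(abs(fb$post - bf)), 1e-10)
    }
  }
})

test_that("single-haplotype panel with tiny mismatch forces the doubled allele", {
  params <- hmm_params(switch_prob = 0.05, mismatch_prob = 1e-9)
  panel <- matrix(c(1L, 0L, 1L), 1, 3)
  obs <- c(NA, 0L, NA)
  fb <- forward_backward(obs, panel, params)
  expect_equal(fb$post[3, 1], 1, tolerance = 1e-6)  # 2 * h[1] = 2
  expect_equal(fb$post[3, 2], 1, tolerance = 1e-6)  # 2 * h[3] = 2
})

test_that("posteriors are normalised at every missing cell", {
  set.seed(12)
  panel <- matrix(rbinom(40 * 30, 1, 0.5), 40, 30)
  obs <- sample(c(0:2, NA), 30, replace = TRUE)
  obs[1] <- 0L
  fb <- forward_backward(obs, panel, hmm_params())
  expect_true(all(abs(colSums(fb$post) - 1) < 1e-9))
  expect_error(forward_backward(rep(NA_integer_, 30), panel, hmm_params()),
               "non-missing")
})

test_that("panel construction: forced haplotypes, diploid row count, truth recovery", {
  # all homozygous: phasing is forced
  gm <- geno_matrix(matrix(c(0L, 2L, 2L, 0L, 0L, 2L), 2, 3),
                    taxa = c("a", "b"))
  panel <- build_haplotype_panel(gm, seed = 1)
  expect_identical(nrow(panel), 4L)
  expect_identical(unname(unclass(panel)[1, ] + unclass(panel)[2, ]),
                   unname(gm$calls[1, ]))
  expect_error(build_haplotype_panel(subset_geno(gm, i = 1), seed = 1),
               ">= 2 individuals")

  # shared-founder population: recovered haplotypes should mostly match truth
  pop <- sim_population(n_subpops = 1, n_per_subpop = 20, n_markers = 300,
                        pool_size = 4, recomb_rate = 0.005, seed = 44)
  panel <- build_haplotype_panel(pop$genotypes, seed = 2)
  expect_identical(nrow(panel), 40L)
  # genotype consistency invariant
  hsum <- unclass(panel)[seq(1, 39, 2), ] + unclass(panel)[seq(2, 40, 2), ]
  expect_identical(unname(hsum), unname(pop$genotypes$calls))
  # phase quality: per individual, best orientation-wise agreement with truth
  agree <- vapply(1:20, function(i) {
    t1 <- pop$haplotypes[2 * i - 1, ]; t2 <- pop$haplotypes[2 * i, ]
    e1 <- unclass(panel)[2 * i - 1, ]; e2 <- unclass(panel)[2 * i, ]
    max(mean(e1 == t1) + mean(e2 == t2), mean(e1 == t2) + mean(e2 == t1)) / 2
  }, numeric(1))
  expect_gt(mean(agree), 0.9)
})

test_that("impute_hmm is a no-op on complete data and never alters observed calls", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 10, n_markers = 100,
                        seed = 3)
  res <- impute_hmm(pop$genotypes, seed = 1)
  expect_identical(res$completed$calls, pop$genotypes$calls)
  expect_identical(nrow(res$posteriors), 0L)

  mk <- mask_genotypes(pop$genotypes, 0.1, seed = 5)
  res2 <- impute_hmm(mk$masked, seed = 1)
  obs <- !is.na(mk$masked$calls)
  expect_identical(res2$completed$calls[obs], mk$masked$calls[obs])
  expect_false(anyNA(res2$completed$calls))
  # posterior triples sum to 1 and argmax equals the imputed call
  p <- as.matrix(res2$posteriors[, c("p0", "p1", "p2")])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  calls <- res2$completed$calls[cbind(res2$posteriors$ind,
                                      res2$posteriors$marker)]
  expect_identical(calls, max.col(p) - 1L)
})

test_that("entirely missing markers are rejected by name", {
  gm <- geno_matrix(matrix(c(0L, 1L, NA, NA), 2, 2), taxa = c("a", "b"))
  expect_error(impute_hmm(gm, seed = 1), "M2")
  expect_error(impute_baseline(gm), "M2")
})

test_that("HMM beats the frequency baseline on haplotype-structured data", {
  wins <- vapply(1:5, function(s) {
    pop <- sim_population(n_subpops = 1, n_per_subpop = 25, n_markers = 400,
                          recomb_rate = 0.01, seed = 700 + s)
    mk <- mask_genotypes(pop$genotypes, 0.1, seed = 800 + s)
    r_hmm <- matching_rate(impute_hmm(mk$masked, seed = s), mk$mask)
    r_base <- matching_rate(impute_baseline(mk$masked), mk$mask)
    r_hmm > r_base
  }, logical(1))
  expect_true(all(wins))
})

test_that("high-confidence posteriors are at least as accurate as the rest", {
  pop <- sim_population(n_subpops = 1, n_per_subpop = 25, n_markers = 500,
                        seed = 900)
  mk <- mask_genotypes(pop$genotypes, 0.15, seed = 901)
  res <- impute_hmm(mk$masked, seed = 902)
  p <- as.matrix(res$posteriors[, c("p0", "p1", "p2")])
  pmax_ <- apply(p, 1, max)
  truth_map <- array(NA_integer_, dim(pop$genotypes$calls))
  truth_map[mk$mask$cells] <- mk$mask$truth
  truth <- truth_map[cbind(res$posteriors$ind, res$posteriors$marker)]
  called <- max.col(p) - 1L
  hi <- pmax_ >= 0.95
  if (any(hi) && any(!hi)) {
    expect_gte(mean(called[hi] == truth[hi]), mean(called[!hi] == truth[!hi]))
  } else {
    succeed("confidence strata degenerate on this draw")
  }
})

test_that("baseline fills the modal genotype with documented tie-break and frequencies", {
  gm <- geno_matrix(matrix(c(0L, 0L, 2L, NA), 4, 1),
                    taxa = c("a", "b", "c", "d"))
  res <- impute_baseline(gm)
  expect_identical(res$completed$calls[4, 1], 0L)
  expect_equal(unlist(res$posteriors[1, c("p0", "p1", "p2")], use.names = FALSE),
               c(2 / 3, 0, 1 / 3))
  # tie 0 vs 2 -> lower code
  gm2 <- geno_matrix(matrix(c(0L, 2L, NA), 3, 1), taxa = c("a", "b", "c"))
  expect_identical(impute_baseline(gm2)$completed$calls[3, 1], 0L)
})

test_that("external Beagle backend fails cleanly when the jar is absent", {
  gm <- random_gm(3, 4, miss = 0.1, seed = 1)
  expect_error(impute_beagle_external(gm, beagle_jar = "/nonexistent/beagle.jar"),
               "not found")
})
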