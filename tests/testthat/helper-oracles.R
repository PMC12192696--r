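# Independent oracles and fixture builders used across the suite.

# random geno_matrix with optional missingness
random_gm <- function(n, m, miss = 0.1, seed, with_alleles = FALSE) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) {
    # keep at least one observed call per column
    idx <- which(matrix(runif(n * m) < miss, n, m))
    calls[idx] <- NA
    for (j in which(colSums(!is.na(calls)) == 0))
      calls[sample.int(n, 1), j] <- sample(0:2, 1)
  }
  mk <- if (with_alleles) {
    pairs <- t(replicate(m, sample(c("A", "C", "G", "T"), 2)))
    stratimpute:::marker_table(paste0("M", 1:m), m,
                               allele_major = pairs[, 1],
                               allele_minor = pairs[, 2])
  } else NULL
  geno_matrix(calls, taxa = sprintf("tx%03d", 1:n), markers = mk)
}

# exhaustive path-sum oracle for the diploid copying HMM: enumerates every
# ordered-pair state sequence and accumulates path probabilities directly
brute_force_posteriors <- function(panel, obs, switch_prob, mismatch_prob,
                                   at = which(is.na(obs))) {
  H <- nrow(panel); M <- ncol(panel)
  s <- switch_prob; e <- mismatch_prob
  states <- expand.grid(a = 1:H, b = 1:H)
  n_st <- nrow(states)
  tr <- function(x, y) (1 - s) * (x == y) + s / H
  emit <- function(g, xa, xb) {
    q <- function(u, x) ifelse(u == x, 1 - e, e)
    if (is.na(g)) return(1)
    if (g == 0) q(0, xa) * q(0, xb)
    else if (g == 2) q(1, xa) * q(1, xb)
    else q(0, xa) * q(1, xb) + q(1, xa) * q(0, xb)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(n_st)), M)))
  out <- matrix(0, 3, length(at))
  for (p in seq_len(nrow(paths))) {
    z <- paths[p, ]
    pr <- 1 / n_st
    for (m in seq_len(M)) {
      if (m > 1)
        pr <- pr * tr(states$a[z[m - 1]], states$a[z[m]]) *
          tr(states$b[z[m - 1]], states$b[z[m]])
      pr <- pr * emit(obs[m], panel[states$a[z[m]], m], panel[states$b[z[m]], m])
    }
    for (k in seq_along(at)) {
      m <- at[k]
      xa <- panel[states$a[z[m]], m]; xb <- panel[states$b[z[m]], m]
      for (g in 0:2)
        out[g + 1, k] <- out[g + 1, k] + pr * emit(g, xa, xb)
    }
  }
  sweep(out, 2, colSums(out), "/")
}

# Weir-Cockerham two-level F_ST estimator over subpopulation allele counts
wc_fst <- function(calls, labels) {
  r <- length(unique(labels))
  num <- den <- 0
  for (j in seq_len(ncol(calls))) {
    ni <- tabulate(labels) * 2                         # allele counts
    pi <- vapply(sort(unique(labels)),
                 function(s) mean(calls[labels == s, j]) / 2, numeric(1))
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    msp <- s2 * nbar
    # within-subpop heterozygosity from genotypes
    hbar <- sum(ni * vapply(sort(unique(labels)),
                            function(s) mean(calls[labels == s, j] == 1),
                            numeric(1))) / sum(ni)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# hand silhouette for small instances: direct double loop over the formula
silhouette_by_hand <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
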