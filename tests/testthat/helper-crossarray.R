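# Shared helpers for the test suite. Oracles here deliberately re-derive
# results with plain base R (loops, direct formulas) rather than calling the
# package's own code paths.

# Build a "normalized_matrix" object directly from an M matrix.
make_norm <- function(M, A = NULL, n_spots = NULL) {
  if (is.null(rownames(M))) rownames(M) <- sprintf("P%04d", seq_len(nrow(M)))
  if (is.null(A)) A <- matrix(10, nrow(M), ncol(M), dimnames = dimnames(M))
  if (is.null(n_spots))
    n_spots <- matrix(2, nrow(M), ncol(M), dimnames = dimnames(M))
  structure(list(M = M, A = A, n_spots = n_spots,
                 signal = rep(TRUE, nrow(M))),
            class = "normalized_matrix")
}

# Independent Pearson chi-squared oracle for a 2x2 presence table:
# cell-by-cell loop, expected counts from marginals.
oracle_chisq_2x2 <- function(fg_present, fg_absent, bg_present, bg_absent) {
  obs <- matrix(c(fg_present, fg_absent, bg_present, bg_absent), 2, 2)
  n <- sum(obs)
  chi2 <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / n
    if (e > 0) chi2 <- chi2 + (obs[i, j] - e)^2 / e
  }
  chi2
}

# Independent chi-squared oracle for a KxK table, p-value by numerical
# integration of the chi-squared density.
oracle_contingency <- function(obs) {
  n <- sum(obs)
  chi2 <- 0
  for (i in seq_len(nrow(obs))) for (j in seq_len(ncol(obs))) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / n
    if (e > 0) chi2 <- chi2 + (obs[i, j] - e)^2 / e
  }
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  p <- 1 - stats::integrate(stats::dchisq, 0, chi2, df = df,
                            rel.tol = 1e-12)$value
  list(chi2 = chi2, p = p)
}

# Exhaustive scan: number of occurrences of a word in a sequence, both
# strands (plain string matching).
oracle_count_occurrences <- function(seqs, word) {
  rc <- crossarray::revcomp(word)
  count1 <- function(s, w) {
    hits <- gregexpr(w, s, fixed = TRUE)[[1]]
    sum(hits > 0)
  }
  sum(vapply(seqs, function(s) count1(s, word) +
               if (rc != word) count1(s, rc) else 0L, numeric(1)))
}

oracle_presence <- function(seqs, word) {
  rc <- crossarray::revcomp(word)
  vapply(seqs, function(s) grepl(word, s, fixed = TRUE) ||
           grepl(rc, s, fixed = TRUE), logical(1))
}

# Step-by-step independent recomputation of the full DE chain from a raw
# spot table (filter -> M/A -> lowess -> block centering -> dye-swap
# averaging -> pooled trimmed variance test).
oracle_de_chain <- function(spots, span = 0.3, iterations = 4L,
                            trim = c(0.025, 0.975), alpha = 0.05) {
  sp <- spots[spots$valid & spots$ch1 > 0 & spots$ch2 > 0, ]
  sp$M <- log2(sp$ch1 / sp$ch2)
  sp$A <- (log2(sp$ch1) + log2(sp$ch2)) / 2
  parts <- list()
  for (a in unique(sp$array)) {
    s <- sp[sp$array == a, ]
    o <- order(s$A)
    lo <- stats::lowess(s$A, s$M, f = span, iter = iterations - 1L)
    fitted <- numeric(nrow(s))
    fitted[o] <- lo$y
    s$M <- s$M - fitted
    for (b in unique(s$block)) {
      sel <- s$block == b
      s$M[sel] <- s$M[sel] - stats::median(s$M[sel])
    }
    parts[[a]] <- s
  }
  sp <- do.call(rbind, parts)
  sp$Mtc <- ifelse(sp$orientation == "swapped", -sp$M, sp$M)

  probes <- sort(unique(sp$probe))
  reps <- sort(unique(sp$bio_rep))
  n <- length(reps)
  rows <- list()
  for (p in probes) {
    mm <- aa <- kk <- rep(NA_real_, n)
    for (r in seq_along(reps)) {
      sel <- sp$probe == p & sp$bio_rep == reps[r]
      if (any(sel)) {
        mm[r] <- mean(sp$Mtc[sel]); aa[r] <- mean(sp$A[sel])
        kk[r] <- sum(sel)
      }
    }
    if (all(!is.na(mm)))
      rows[[p]] <- data.frame(probe = p, mean_M = mean(mm),
                              A_mean = mean(aa),
                              s2 = stats::var(mm), w = sum(1 / kk))
  }
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  s2_spot <- tab$s2 * n / tab$w
  band <- stats::quantile(s2_spot, trim)
  kept <- s2_spot >= band[1] & s2_spot <= band[2]
  k_df <- n - 1
  q <- stats::qchisq(trim, df = k_df)
  atten <- (stats::pchisq(q[2], df = k_df + 2) -
              stats::pchisq(q[1], df = k_df + 2)) / (trim[2] - trim[1])
  s2_trim <- mean(s2_spot[kept]) / atten
  e1 <- k_df * (stats::pchisq(q[2], k_df + 2) - stats::pchisq(q[1], k_df + 2)) /
    (trim[2] - trim[1])
  e2 <- k_df * (k_df + 2) *
    (stats::pchisq(q[2], k_df + 4) - stats::pchisq(q[1], k_df + 4)) /
    (trim[2] - trim[1])
  df_eff <- 2 * sum(kept) / (e2 / e1^2 - 1)
  stat <- tab$mean_M / sqrt(s2_trim * tab$w / n^2)
  p_raw <- 2 * stats::pt(-abs(stat), df_eff)
  p_bonf <- pmin(1, p_raw * m)
  tab$stat <- stat
  tab$p_raw <- p_raw
  tab$p_bonferroni <- p_bonf
  tab$class <- ifelse(p_bonf < alpha & tab$mean_M > 0, "UP",
                      ifelse(p_bonf < alpha & tab$mean_M < 0, "DOWN", "NC"))
  rownames(tab) <- NULL
  tab
}

# Small DE experiment used across tests.
quick_sim <- function(seed, n_probes = 1000, treatments = "t", ...) {
  simulate_experiment(generator_config(n_probes = n_probes, n_blocks = 4,
                                       treatments = treatments, seed = seed,
                                       ...))
}
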