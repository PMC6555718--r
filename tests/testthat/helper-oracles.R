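# Independent oracles shared across suites. Each recomputes a quantity by a
# route deliberately different from the package implementation: brute-force
# pair counting for AUC, dense-grid scanning for the Youden optimum,
# hypergeometric tail summation for Fisher, assignment enumeration for the
# rank-sum null, and a literal transcription of the staging rules.

auc_allpairs <- function(lower, higher) {
  total <- 0
  for (l in lower) {
    for (h in higher) {
      total <- total + (h < l) + 0.5 * (h == l)
    }
  }
  total / (length(lower) * length(higher))
}

youden_grid_max <- function(lower, higher, step = 0.01) {
  grid <- seq(min(c(lower, higher)) - step,
              max(c(lower, higher)) + 2 * step, by = step)
  j <- vapply(grid, function(t) mean(higher < t) + mean(lower >= t) - 1, 0)
  list(j = max(j), argmax = grid[j >= max(j) - 1e-12])
}

fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

ranksum_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  ws <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# Literal transcription of the clinical staging rules (consciousness mapping
# with the vital-signs override); NA marks an inconsistent record.
expected_stage <- function(gcs, avpu, vitals_absent) {
  if (vitals_absent) {
    if ((!is.na(gcs) && gcs == 3) || (is.na(gcs) && identical(avpu, "U"))) {
      return(4L)
    }
    return(NA_integer_)
  }
  if (!is.na(gcs)) {
    if (gcs == 15) return(1L)
    if (gcs > 8) return(2L)
    return(3L)
  }
  switch(avpu, A = 1L, V = 2L, P = 3L, U = 3L)
}

# Single-stage variant of the default generator configuration: same
# temperature spec, all mass on one clinical stage.
single_stage_config <- function(stage, n, seed) {
  cfg <- default_config(n_total = n, seed = seed)
  mix <- rep(0, 4)
  mix[stage] <- 1
  cfg$stage_mix_by_source <- rbind(hospital = mix, literature = mix)
  cfg
}
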