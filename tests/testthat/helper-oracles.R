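# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# direct-probability CCF posterior (no log space); returns NULL whenever any
# intermediate product leaves the normal double range (a partially
# underflowed naive likelihood is silently inaccurate, not just zero)
naive_ccf_posterior <- function(t_alt, t_depth, purity, local_cn,
                                grid = seq(0.01, 1, by = 0.01)) {
  ev <- purity * grid / (2 * (1 - purity) + purity * local_cn)
  a <- ev^t_alt
  b <- (1 - ev)^(t_depth - t_alt)
  cf <- choose(t_depth, t_alt)
  if (!is.finite(cf) || any(a < .Machine$double.xmin) ||
      any(b < .Machine$double.xmin)) return(NULL)
  like <- cf * a * b
  s <- sum(like)
  if (!is.finite(s) || s == 0) return(NULL)
  like / s
}

# exact upper-tail probability of the permutation null: P(C >= c1) where C is
# the clonal count of n mutations drawn without replacement from a background
# with K clonal of N total
hyper_tail <- function(c1, n, K, N) {
  stats::phyper(c1 - 1, K, N - K, n, lower.tail = FALSE)
}

# two-group log-rank by direct O-E / V summation over pooled event times
logrank_oracle <- function(times, events, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_tot <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d_tot * n1 / n_tot
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  (o1 - e1)^2 / v
}

# exhaustive partial-likelihood grid search for a single binary covariate,
# Efron handling of ties; returns the maximizing coefficient
cox_grid_oracle <- function(x, times, events, grid = seq(-5, 5, by = 1e-3)) {
  loglik <- vapply(grid, function(beta) {
    ll <- 0
    for (t in sort(unique(times[events == 1]))) {
      dead <- which(times == t & events == 1)
      risk <- which(times >= t)
      d <- length(dead)
      eta_risk <- sum(exp(beta * x[risk]))
      eta_dead <- sum(exp(beta * x[dead]))
      ll <- ll + beta * sum(x[dead])
      for (l in seq_len(d) - 1)
        ll <- ll - log(eta_risk - (l / d) * eta_dead)
    }
    ll
  }, numeric(1))
  grid[which.max(loglik)]
}

# classical two-sided Fisher exact p for a 2x2 table by hypergeometric sums
fisher_2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small handcrafted cohort exercising every annotation exclusion reason
toy_bundle <- function() {
  mutations <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S2", "S3"),
    gene = c("G1", "G1", "G2", "G1", "G2", "G1"),
    chrom = c("1", "1", "X", "1", "2", "1"),
    pos = c(50L, 60L, 50L, 50L, 500L, 50L),
    variant_class = c("Missense_Mutation", "Silent", "Missense_Mutation",
                      "Nonsense_Mutation", "Missense_Mutation",
                      "Missense_Mutation"),
    t_alt = c(30L, 10L, 10L, 10L, 20L, 25L),
    t_depth = c(100L, 100L, 100L, 100L, 100L, 100L),
    stringsAsFactors = FALSE)
  segments <- data.frame(
    sample_id = c("S1", "S2", "S2", "S3"),
    chrom = c("1", "1", "2", "1"),
    start = c(1L, 1L, 400L, 1L),
    end = c(100L, 100L, 600L, 100L),
    absolute_cn = c(2L, 2L, 0L, 3L),
    stringsAsFactors = FALSE)
  purities <- data.frame(sample_id = c("S1", "S2"),
                         purity = c(0.6, 0.5), stringsAsFactors = FALSE)
  clinical <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    age = c(55, 70, 61, 80),
    sex = c("female", "male", "female", "male"),
    msi_status = c("MSI", "MSS", "MSS", "MSS"),
    tumour_site = c("left-sided", "right-sided", "left-sided", "right-sided"),
    ajcc_stage = c("1", "3", "2", "4"),
    t_stage = c("T1", "T3", "T2", "T4"),
    n_stage = c("N0", "N1", "N0", "N2"),
    m_stage = c("M0", "M0", "M0", "M1"),
    os_time = c(24, 10, 36, 5),
    os_event = c(0L, 1L, 0L, 1L),
    stringsAsFactors = FALSE)
  cohort_bundle(mutations, segments, purities, clinical)
}

# write a minimal MAF-style file from a data.frame of raw column values
write_raw_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
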