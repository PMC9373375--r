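#' Discrete CCF grid
#'
#' The cancer cell fraction (CCF) is estimated on a uniform grid of 100 values
#' from 0.01 to 1.00 inclusive (step 0.01). The grid is exposed so that the
#' resolution can be changed, but all defaults assume the 100-point grid.
#'
#' @param n Number of grid points.
#' @param lo,hi First and last grid value.
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
#' @examples
#' g <- ccf_grid()
#' length(g); g[1]; g[100]
ccf_grid <- function(n = 100L, lo = 0.01, hi = 1.00) {
  if (n < 2L || lo <= 0 || hi <= lo) stop("invalid CCF grid specification")
  seq(lo, hi, length.out = n)
}

#' Expected variant allele frequency under the purity/copy-number model
#'
#' For a mutation present at `multiplicity` copies per cancer cell in a sample
#' of purity `purity`, with local tumor copy number `local_cn` and normal copy
#' number `normal_cn` (2 for autosomes), the expected VAF at cancer cell
#' fraction `ccf` is
#' \deqn{VAF = purity * ccf * m / (normal_cn * (1 - purity) + purity * local_cn)}
#'
#' @param purity Tumor purity in (0, 1]. Vectorized.
#' @param ccf Cancer cell fraction in (0, 1]. Vectorized.
#' @param local_cn Integer local tumor copy number (>= 0).
#' @param normal_cn Local copy number in normal cells; 2 for autosomes.
#' @param multiplicity Copies of the mutant allele per cancer cell; fixed at 1
#'   by default to avoid overcalling subclonality.
#' @return Expected VAF, in \[0, 1\] for `multiplicity <= local_cn`.
#' @export
#' @examples
#' expected_vaf(1, 1, 2)      # 0.5: pure diploid heterozygous
#' expected_vaf(0.5, 1, 2)    # 0.25
#' expected_vaf(0.6, 0.5, 3)  # 0.3 / 2.6
expected_vaf <- function(purity, ccf, local_cn, normal_cn = 2, multiplicity = 1) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(ccf <= 0 | ccf > 1)) stop("ccf must be in (0, 1]")
  if (any(local_cn < 0)) stop("local_cn must be >= 0")
  denom <- normal_cn * (1 - purity) + purity * local_cn
  if (any(denom == 0)) stop("degenerate site: purity 1 with zero tumor copies")
  purity * ccf * multiplicity / denom
}

#' Posterior distribution of the cancer cell fraction of one mutation
#'
#' Computes the binomial likelihood of the observed alt read count at every
#' grid CCF value and normalizes it into a discrete posterior. Likelihoods are
#' evaluated in log space with max-subtraction so deep sites do not underflow.
#'
#' Summaries stored on the object:
#' * `map_ccf` — grid value with maximal posterior mass, ties broken toward
#'   the larger value (biases toward clonal).
#' * `ci_low`, `ci_high` — equal-tailed credible bounds: the first grid values
#'   whose cumulative mass reaches `(1-ci_level)/2` and `1-(1-ci_level)/2`.
#' * `p_subclonal` — posterior mass at grid values strictly below
#'   `subclonal_ccf` (i.e. P(CCF < 0.9) with the defaults).
#'
#' @param t_alt Alt-supporting read count (0 <= t_alt <= t_depth).
#' @param t_depth Total depth (>= 1).
#' @param purity Tumor purity in (0, 1].
#' @param local_cn Local tumor copy number (>= 1 to be scorable).
#' @param grid CCF grid (see [ccf_grid()]).
#' @param normal_cn,multiplicity See [expected_vaf()].
#' @param ci_level Credible-interval level, default 0.95.
#' @param subclonal_ccf CCF threshold defining "subclonal" mass, default 0.9.
#' @return An object of class `ccf_posterior`.
#' @export
#' @examples
#' p <- ccf_posterior(25, 100, purity = 0.5, local_cn = 2)
#' p$map_ccf  # 1.00: observed VAF matches the clonal expectation
ccf_posterior <- function(t_alt, t_depth, purity, local_cn,
                          grid = ccf_grid(), normal_cn = 2, multiplicity = 1,
                          ci_level = 0.95, subclonal_ccf = 0.9) {
  if (length(t_alt) != 1L || length(t_depth) != 1L)
    stop("ccf_posterior scores one mutation; use call_clonality() for cohorts")
  if (is.na(t_alt) || is.na(t_depth) || t_depth < 1 || t_alt < 0 || t_alt > t_depth)
    stop("invalid read counts: t_alt=", t_alt, " t_depth=", t_depth)
  ev <- expected_vaf(purity, grid, local_cn, normal_cn, multiplicity)
  ll <- stats::dbinom(t_alt, t_depth, pmin(ev, 1), log = TRUE)
  m <- max(ll)
  if (!is.finite(m))
    stop("degenerate posterior (all likelihoods zero) for t_alt=", t_alt,
         " t_depth=", t_depth, " purity=", purity, " local_cn=", local_cn)
  w <- exp(ll - m)
  probs <- w / sum(w)
  out <- list(grid = grid, probs = probs,
              purity = purity, local_cn = local_cn,
              t_alt = t_alt, t_depth = t_depth,
              ci_level = ci_level, subclonal_ccf = subclonal_ccf)
  out <- c(out, .posterior_summaries(grid, probs, ci_level, subclonal_ccf))
  structure(out, class = "ccf_posterior")
}

# shared by ccf_posterior() and the vectorized cohort caller
.posterior_summaries <- function(grid, probs, ci_level, subclonal_ccf) {
  imap <- max(which(probs == max(probs)))  # tie toward larger CCF
  cum <- cumsum(probs)
  alpha <- (1 - ci_level) / 2
  ilo <- which(cum >= alpha - 1e-12)[1]
  ihi <- which(cum >= 1 - alpha - 1e-12)[1]
  list(map_ccf = grid[imap],
       ci_low = grid[ilo], ci_high = grid[ihi],
       ci_high_at_top = (ihi == length(grid)),
       p_subclonal = sum(probs[grid < subclonal_ccf - 1e-9]))
}

#' @export
print.ccf_posterior <- function(x, ...) {
  cat("CCF posterior (", x$t_alt, "/", x$t_depth, " reads, purity ",
      format(x$purity, digits = 3), ", local CN ", x$local_cn, ")\n", sep = "")
  cat("  MAP CCF: ", format(x$map_ccf, digits = 3),
      "   ", format(100 * x$ci_level), "% CI: [",
      format(x$ci_low, digits = 3), ", ", format(x$ci_high, digits = 3), "]\n",
      sep = "")
  cat("  P(CCF < ", format(x$subclonal_ccf), ") = ",
      format(x$p_subclonal, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ccf_posterior <- function(x, ...) {
  graphics::plot(x$grid, x$probs, type = "h", xlab = "CCF",
                 ylab = "posterior mass", ...)
  graphics::abline(v = x$map_ccf, lty = 2)
  invisible(x)
}

#' Classify a mutation as clonal or subclonal
#'
#' A mutation is subclonal when its 95% credible interval does not reach the
#' top grid value (the interval "cannot overlap 1") AND the posterior
#' probability that its CCF is below the subclonal threshold exceeds 0.5.
#' Otherwise it is clonal.
#'
#' @param posterior A `ccf_posterior` object.
#' @param p_subclonal_cut Probability cut on P(CCF < threshold), default 0.5.
#' @return `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(posterior, p_subclonal_cut = 0.5) {
  stopifnot(inherits(posterior, "ccf_posterior"))
  if (!posterior$ci_high_at_top && posterior$p_subclonal > p_subclonal_cut)
    "subclonal" else "clonal"
}

#' Kolmogorov-Smirnov test of CCF uniformity
#'
#' Tests a gene's MAP CCF values against the Uniform(0,1) distribution.
#' With fewer than 3 values the result is flagged not evaluable.
#'
#' @param ccf_values Numeric vector of CCF values in (0, 1\].
#' @return List with `statistic`, `p_value`, `n`, `evaluable`.
#' @export
ks_uniformity <- function(ccf_values) {
  ccf_values <- ccf_values[!is.na(ccf_values)]
  n <- length(ccf_values)
  if (n < 3L)
    return(list(statistic = NA_real_, p_value = NA_real_, n = n, evaluable = FALSE))
  kt <- suppressWarnings(stats::ks.test(ccf_values, "punif"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value, n = n,
       evaluable = TRUE)
}
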