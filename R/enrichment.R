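#' Benjamini-Hochberg FDR adjustment
#'
#' Thin, named wrapper over `stats::p.adjust(method = "BH")` so the FDR
#' procedure used across the package is a single, swappable choice.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Q-values (same length and order).
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Permutation test of per-gene clonal / subclonal enrichment
#'
#' For a gene with `n = c1 + s1` classified non-silent mutations (`c1` clonal,
#' `s1` subclonal), each permutation draws `n` mutations without replacement
#' from the cohort-wide background of classified labels and counts the clonal
#' draws `c*`. The clonal-enrichment p-value is
#' `(#\{c* >= c1\} + 1) / (n_perm + 1)`, and analogously for subclonal
#' enrichment with `s* = n - c*`; since `c*` determines the clonal ratio
#' `c1/s1` monotonically at fixed `n`, this is equivalent to comparing ratios.
#' The at-least-as-extreme convention with the +1 correction is used so that
#' p-values are never exactly 0, which would break FDR control.
#'
#' @param gene_counts Data.frame with columns `gene`, `c1`, `s1` (e.g. the
#'   `gene_summary` of [call_clonality()]).
#' @param background_labels Character vector of clonality labels
#'   (`"clonal"`/`"subclonal"`) of all classified non-silent mutations
#'   cohort-wide. By default genes' own mutations remain in the pool.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; one stream is used for all genes in input order.
#' @param replace Sample the background with replacement instead (default
#'   FALSE: permutations draw mutations, not labels).
#' @return Data.frame of class `enrichment_result`, one row per gene:
#'   `n`, `c1`, `s1`, `clonal_ratio`, `subclonal_ratio` (Inf when the
#'   denominator count is 0), `p_clonal`, `p_subclonal`, `q_clonal`,
#'   `q_subclonal`, `n_perm`, `seed`.
#' @export
enrichment_test <- function(gene_counts, background_labels, n_perm = 1000,
                            seed = 7, replace = FALSE) {
  stopifnot(all(c("gene", "c1", "s1") %in% names(gene_counts)))
  bg <- background_labels == "clonal"
  N <- length(bg)
  n_gene <- gene_counts$c1 + gene_counts$s1
  if (any(n_gene < 1)) stop("every gene needs at least one classified mutation")
  if (!replace && any(n_gene > N))
    stop("gene mutation count exceeds background size (", N, ")")
  set.seed(seed)
  p_c <- p_s <- numeric(nrow(gene_counts))
  for (g in seq_len(nrow(gene_counts))) {
    n <- n_gene[g]
    cstar <- integer(n_perm)
    for (b in seq_len(n_perm))
      cstar[b] <- sum(bg[sample.int(N, n, replace = replace)])
    p_c[g] <- (sum(cstar >= gene_counts$c1[g]) + 1) / (n_perm + 1)
    p_s[g] <- (sum((n - cstar) >= gene_counts$s1[g]) + 1) / (n_perm + 1)
  }
  out <- data.frame(gene = gene_counts$gene, n = n_gene,
                    c1 = gene_counts$c1, s1 = gene_counts$s1,
                    clonal_ratio = ifelse(gene_counts$s1 > 0,
                                          gene_counts$c1 / gene_counts$s1, Inf),
                    subclonal_ratio = ifelse(gene_counts$c1 > 0,
                                             gene_counts$s1 / gene_counts$c1, Inf),
                    p_clonal = p_c, p_subclonal = p_s,
                    q_clonal = fdr_adjust(p_c), q_subclonal = fdr_adjust(p_s),
                    n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Gene enrichment from a set of clonality calls
#'
#' Convenience wrapper: builds the per-gene counts and the cohort-wide
#' background from a [call_clonality()] result and runs [enrichment_test()].
#'
#' @param calls A `clonality_calls` object.
#' @inheritParams enrichment_test
#' @return See [enrichment_test()].
#' @export
gene_enrichment <- function(calls, n_perm = 1000, seed = 7, replace = FALSE) {
  stopifnot(inherits(calls, "clonality_calls"))
  enrichment_test(calls$gene_summary, calls$calls$label,
                  n_perm = n_perm, seed = seed, replace = replace)
}
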