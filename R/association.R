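#' Collapse per-mutation calls to one category per patient and gene
#'
#' A patient is `"WT"` for a gene with no classified mutation, `"clonal"` with
#' only clonal mutations, `"subclonal"` with only subclonal ones; carriers of
#' both collapse according to `rule` (default clonal-dominant, i.e. `"clonal"`).
#'
#' @param calls A `clonality_calls` object.
#' @param samples Character vector defining the cohort (default: the samples
#'   of the `patient_architecture` table, i.e. all purity/clinical samples).
#' @param rule `"clonal-dominant"` or `"subclonal-dominant"`.
#' @return Data.frame: `sample_id` plus one column per gene with values in
#'   `{clonal, subclonal, WT}`.
#' @export
patient_gene_category <- function(calls, samples = NULL,
                                  rule = c("clonal-dominant",
                                           "subclonal-dominant")) {
  stopifnot(inherits(calls, "clonality_calls"))
  rule <- match.arg(rule)
  arch <- calls$patient_architecture
  if (!is.null(samples)) {
    arch <- arch[match(samples, arch$sample_id), , drop = FALSE]
    arch$sample_id <- samples
    arch[is.na(arch)] <- "WT"  # samples never seen in calls are wild type
  }
  both_to <- if (rule == "clonal-dominant") "clonal" else "subclonal"
  out <- arch
  for (j in setdiff(names(out), "sample_id")) {
    v <- out[[j]]
    v[v == "both"] <- both_to
    v[v == "clonal-only"] <- "clonal"
    v[v == "subclonal-only"] <- "subclonal"
    out[[j]] <- v
  }
  rownames(out) <- NULL
  out
}

# log probability of an r x c table under the fixed-margins hypergeometric null
.log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

#' Fisher's exact test for 2 x k contingency tables
#'
#' Two-sided exact p-value under the conditional hypergeometric null with both
#' margins fixed (for k > 2 this is the Freeman-Halton extension): all tables
#' with the observed margins are enumerated and the probabilities of tables no
#' more probable than the observed one are summed. Rows and columns with zero
#' margin are dropped first. When the number of tables exceeds
#' `max_tables`, a seeded Monte-Carlo estimate over `mc_draws` margin-
#' preserving tables is returned instead and flagged.
#'
#' @param tab Integer matrix with 2 rows (after zero-margin dropping) and
#'   2 or more columns.
#' @param max_tables Enumeration size bound before switching to Monte Carlo.
#' @param mc_draws Monte-Carlo draws (>= 1e5 by default).
#' @param seed Seed for the Monte-Carlo estimator.
#' @return List with `p_value`, `method` (`"fisher-exact"` or
#'   `"fisher-montecarlo"`), `evaluable`.
#' @export
#' @examples
#' fisher_exact_2xk(rbind(c(129, 17, 108), c(163, 6, 108)))$p_value  # ~0.016
fisher_exact_2xk <- function(tab, max_tables = 2e6, mc_draws = 1e5, seed = 1) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(p_value = NA_real_, method = "degenerate", evaluable = FALSE))
  if (nrow(tab) != 2L) stop("fisher_exact_2xk expects 2 rows")
  r <- rowSums(tab); cs <- colSums(tab)
  k <- length(cs)
  lp_obs <- .log_table_prob(tab)
  n_tables <- prod(pmin(r[1], cs) + 1)
  if (n_tables <= max_tables) {
    # enumerate first-row cells x1..x(k-1); the last is fixed by the margin
    free <- vector("list", k - 1L)
    for (j in seq_len(k - 1L)) free[[j]] <- 0:min(r[1], cs[j])
    grid <- as.matrix(expand.grid(free))
    last <- r[1] - rowSums(grid)
    ok <- last >= 0 & last <= cs[k]
    grid <- cbind(grid[ok, , drop = FALSE], last[ok])
    # row-2 cells must also be feasible: col margin minus row-1 cell >= 0
    row2 <- matrix(cs, nrow(grid), k, byrow = TRUE) - grid
    ok2 <- rowSums(row2 < 0) == 0
    grid <- grid[ok2, , drop = FALSE]; row2 <- row2[ok2, , drop = FALSE]
    lp <- .log_table_prob_rows(grid, row2, r, cs)
    p <- sum(exp(lp[lp <= lp_obs + 1e-7]))
    list(p_value = min(1, p), method = "fisher-exact", evaluable = TRUE)
  } else {
    set.seed(seed)
    sims <- stats::r2dtable(mc_draws, r, cs)
    lp <- vapply(sims, .log_table_prob, numeric(1))
    p <- (sum(lp <= lp_obs + 1e-7) + 1) / (mc_draws + 1)
    list(p_value = p, method = "fisher-montecarlo", evaluable = TRUE)
  }
}

# vectorized log table probability for enumerated 2 x k tables
.log_table_prob_rows <- function(row1, row2, r, cs) {
  const <- sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(sum(r))
  const - rowSums(lfactorial(row1)) - rowSums(lfactorial(row2))
}

# binarizations of the clinical table used across the association and
# survival scans; age is split at the cohort median
.binarize_clinical <- function(clinical) {
  med <- stats::median(clinical$age, na.rm = TRUE)
  list(
    age = list(levels = c(sprintf("<%s", format(med)),
                          sprintf(">=%s", format(med))),
               value = ifelse(clinical$age < med, 1L, 2L)),
    sex = list(levels = c("female", "male"),
               value = match(clinical$sex, c("female", "male"))),
    msi_status = list(levels = c("MSI", "MSS"),
                      value = match(clinical$msi_status, c("MSI", "MSS"))),
    tumour_site = list(levels = c("right-sided", "left-sided"),
                       value = match(clinical$tumour_site,
                                     c("right-sided", "left-sided"))),
    ajcc_stage = list(levels = c("stage1/2", "stage3/4"),
                      value = ifelse(clinical$ajcc_stage %in% c("1", "2"), 1L,
                                     ifelse(clinical$ajcc_stage %in% c("3", "4"),
                                            2L, NA_integer_))),
    t_stage = list(levels = c("T1/T2", "T3/T4"),
                   value = ifelse(clinical$t_stage %in% c("T1", "T2"), 1L,
                                  ifelse(clinical$t_stage %in% c("T3", "T4"),
                                         2L, NA_integer_))),
    n_stage = list(levels = c("N0", "N1/N2"),
                   value = ifelse(clinical$n_stage == "N0", 1L,
                                  ifelse(clinical$n_stage %in% c("N1", "N2"),
                                         2L, NA_integer_))),
    m_stage = list(levels = c("M0", "M1"),
                   value = match(clinical$m_stage, c("M0", "M1"))))
}

#' Scan gene clonality against clinicopathological variables
#'
#' For every eligible gene (at least `min_patients` clonal carriers AND at
#' least `min_patients` subclonal carriers) and every binarized clinical
#' variable (age split at the cohort median, AJCC 1/2 vs 3/4, T1/2 vs T3/4,
#' N0 vs N1/2, M0 vs M1, MSI vs MSS, right vs left, female vs male), builds
#' the 2 (clinical) x 3 (clonal / subclonal / WT) table and applies
#' [fisher_exact_2xk()]. Patients missing the clinical variable are dropped
#' from that one test only. Ineligible genes are flagged, not dropped.
#'
#' @param categories Output of [patient_gene_category()].
#' @param clinical Clinical table ([read_clinical()] format).
#' @param min_patients Eligibility threshold (default 5).
#' @return List with `results` (data.frame: `gene`, `variable`, `p_value`,
#'   `neglog2_p`, `method`, `eligible`) and `neglog2p_matrix` (genes x
#'   variables, eligible genes only).
#' @export
association_scan <- function(categories, clinical, min_patients = 5) {
  genes <- setdiff(names(categories), "sample_id")
  idx <- match(categories$sample_id, clinical$sample_id)
  clin <- clinical[idx, , drop = FALSE]
  bins <- .binarize_clinical(clin)
  res <- list()
  for (gene in genes) {
    cat_g <- factor(categories[[gene]], levels = c("clonal", "subclonal", "WT"))
    eligible <- sum(cat_g == "clonal") >= min_patients &&
      sum(cat_g == "subclonal") >= min_patients
    for (v in names(bins)) {
      p <- NA_real_; method <- NA_character_
      if (eligible) {
        bv <- bins[[v]]
        keep <- !is.na(bv$value) & !is.na(cat_g)
        tab <- table(factor(bv$value[keep], levels = 1:2, labels = bv$levels),
                     cat_g[keep])
        ft <- fisher_exact_2xk(tab)
        p <- ft$p_value; method <- ft$method
      }
      res[[length(res) + 1L]] <-
        data.frame(gene = gene, variable = v, p_value = p,
                   neglog2_p = ifelse(is.na(p), NA_real_, -log2(p)),
                   method = method, eligible = eligible,
                   stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  el <- unique(results$gene[results$eligible])
  mat <- matrix(NA_real_, length(el), length(bins),
                dimnames = list(el, names(bins)))
  for (i in seq_len(nrow(results)))
    if (results$eligible[i])
      mat[results$gene[i], results$variable[i]] <- results$neglog2_p[i]
  list(results = results, neglog2p_matrix = mat)
}

#' Compare per-patient mutation burdens between two clinical groups
#'
#' Two-sided comparison of a per-patient count (e.g. number of clonal or
#' subclonal mutations) between the two levels of a binary grouping, by
#' equal-variance Student's t-test or Wilcoxon rank-sum test. Groups with
#' fewer than 2 patients make the test not evaluable.
#'
#' @param counts Numeric vector, one value per patient.
#' @param group Vector with exactly two non-missing levels.
#' @param method `"t-test"` or `"wilcoxon"`.
#' @return List with `p_value`, `estimate` (group means), `method`,
#'   `evaluable`.
#' @export
burden_compare <- function(counts, group, method = c("t-test", "wilcoxon")) {
  method <- match.arg(method)
  keep <- !is.na(counts) & !is.na(group)
  counts <- counts[keep]; group <- factor(as.character(group[keep]))
  if (nlevels(group) != 2L || min(table(group)) < 2L)
    return(list(p_value = NA_real_, estimate = NULL, method = method,
                evaluable = FALSE))
  x <- counts[group == levels(group)[1]]
  y <- counts[group == levels(group)[2]]
  p <- if (method == "t-test") {
    if (stats::var(x) + stats::var(y) == 0 && mean(x) == mean(y)) 1
    else stats::t.test(x, y, var.equal = TRUE)$p.value
  } else suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  list(p_value = p,
       estimate = stats::setNames(c(mean(x), mean(y)), levels(group)),
       method = method, evaluable = TRUE)
}

.indel_classes <- c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                    "In_Frame_Ins")

#' Test whether a mutation type is preferentially clonal or subclonal
#'
#' Per gene, builds the 2x2 table of mutation type (indel vs other, and
#' nonsense vs other) against clonality label and applies the exact test.
#' Genes whose mutations do not span both type levels (or both labels) are
#' flagged not evaluable for that comparison.
#'
#' @param calls A `clonality_calls` object.
#' @return Data.frame: `gene`, `comparison` (`"indel"`/`"nonsense"`),
#'   `p_value`, `evaluable`.
#' @export
mutation_type_vs_clonality <- function(calls) {
  stopifnot(inherits(calls, "clonality_calls"))
  df <- calls$calls
  out <- list()
  for (gene in sort(unique(df$gene))) {
    dg <- df[df$gene == gene, , drop = FALSE]
    for (cmp in c("indel", "nonsense")) {
      is_type <- if (cmp == "indel") dg$variant_class %in% .indel_classes
                 else dg$variant_class == "Nonsense_Mutation"
      evaluable <- length(unique(is_type)) == 2L &&
        length(unique(dg$label)) == 2L
      p <- NA_real_
      if (evaluable) {
        tab <- table(factor(is_type, levels = c(TRUE, FALSE)),
                     factor(dg$label, levels = c("clonal", "subclonal")))
        p <- fisher_exact_2xk(tab)$p_value
      }
      out[[length(out) + 1L]] <- data.frame(gene = gene, comparison = cmp,
                                            p_value = p, evaluable = evaluable,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
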