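#' Attach purity and local copy number to each mutation
#'
#' Joins each mutation to its sample's purity and to the copy-number segment
#' covering its position (1-based inclusive on both sides). Mutations that
#' cannot be scored are excluded — not an error — and itemized by reason:
#' `no-purity`, `no-segment`, `non-autosome` (unless `autosomes_only = FALSE`)
#' or `homozygous-deletion` (local copy number 0: a point mutation cannot
#' reside on zero copies).
#'
#' @param bundle A `cohort_bundle`.
#' @param autosomes_only Exclude mutations on non-autosomal chromosomes
#'   (default TRUE; the normal copy number is fixed at 2, which only holds
#'   for autosomes).
#' @return List with `mutations` (input columns plus `purity`, `local_cn`)
#'   and `skip_report` (data.frame `reason`, `n`).
#' @export
annotate_mutations <- function(bundle, autosomes_only = TRUE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  mut <- bundle$mutations
  seg <- bundle$segments
  pur <- bundle$purities
  reason <- rep(NA_character_, nrow(mut))

  if (autosomes_only) {
    autos <- as.character(1:22)
    reason[!(mut$chrom %in% autos)] <- "non-autosome"
  }
  pidx <- match(mut$sample_id, pur$sample_id)
  reason[is.na(reason) & is.na(pidx)] <- "no-purity"

  local_cn <- rep(NA_integer_, nrow(mut))
  skey <- paste(seg$sample_id, seg$chrom)
  mkey <- paste(mut$sample_id, mut$chrom)
  for (k in unique(mkey)) {
    mi <- which(mkey == k)
    si <- which(skey == k)
    if (length(si) == 0L) next
    # segments are non-overlapping; findInterval on starts, then bound check
    o <- si[order(seg$start[si])]
    j <- findInterval(mut$pos[mi], seg$start[o])
    ok <- j >= 1L & ifelse(j >= 1L, mut$pos[mi] <= seg$end[o][pmax(j, 1L)], FALSE)
    local_cn[mi[ok]] <- seg$absolute_cn[o][j[ok]]
  }
  reason[is.na(reason) & is.na(local_cn)] <- "no-segment"
  reason[is.na(reason) & local_cn == 0L] <- "homozygous-deletion"

  keep <- is.na(reason)
  out <- mut[keep, , drop = FALSE]
  out$purity <- pur$purity[pidx[keep]]
  out$local_cn <- local_cn[keep]
  rownames(out) <- NULL
  skip <- table(factor(reason[!keep],
                       levels = c("non-autosome", "no-purity", "no-segment",
                                  "homozygous-deletion")))
  list(mutations = out,
       skip_report = data.frame(reason = names(skip), n = as.integer(skip),
                                stringsAsFactors = FALSE))
}

#' Call clonality for every non-silent mutation in a cohort
#'
#' The cohort-level entry point of the CCF model: filters to non-silent
#' mutations, annotates purity and local copy number, computes the grid
#' posterior of every mutation and classifies it clonal or subclonal, then
#' tallies per-gene clonal/subclonal counts and per patient-gene architecture
#' categories (clonal-only / subclonal-only / both / WT).
#'
#' @param bundle A `cohort_bundle`.
#' @param classes Variant classes counted as non-silent
#'   (default [nonsilent_classes()]).
#' @param grid CCF grid.
#' @param ci_level Credible-interval level (default 0.95).
#' @param subclonal_ccf CCF threshold for P(subclonal) (default 0.9).
#' @param p_subclonal_cut Probability cut for the subclonal call (default 0.5).
#' @param autosomes_only Passed to [annotate_mutations()].
#' @return Object of class `clonality_calls`: list with
#'   * `calls` — one row per classified mutation (`map_ccf`, `ci_low`,
#'     `ci_high`, `p_subclonal`, `label`, `purity`, `local_cn`, ...),
#'   * `gene_summary` — per gene `c1` (clonal), `s1` (subclonal) and patient
#'     category counts,
#'   * `patient_architecture` — samples x genes category matrix (as a
#'     data.frame of `sample_id`, gene columns),
#'   * `skip_report`, and the thresholds used.
#' @export
call_clonality <- function(bundle, classes = nonsilent_classes(),
                           grid = ccf_grid(), ci_level = 0.95,
                           subclonal_ccf = 0.9, p_subclonal_cut = 0.5,
                           autosomes_only = TRUE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  ns <- bundle
  n_total <- nrow(ns$mutations)
  ns$mutations <- ns$mutations[ns$mutations$variant_class %in% classes, ,
                               drop = FALSE]
  n_silent <- n_total - nrow(ns$mutations)
  ann <- annotate_mutations(ns, autosomes_only = autosomes_only)
  mut <- ann$mutations

  m <- nrow(mut)
  map_ccf <- ci_low <- ci_high <- p_sub <- numeric(m)
  at_top <- logical(m)
  for (i in seq_len(m)) {
    ev <- expected_vaf(mut$purity[i], grid, mut$local_cn[i])
    ll <- stats::dbinom(mut$t_alt[i], mut$t_depth[i], pmin(ev, 1), log = TRUE)
    mx <- max(ll)
    if (!is.finite(mx))
      stop("degenerate posterior for mutation ", mut$sample_id[i], ":",
           mut$gene[i], ":", mut$pos[i])
    w <- exp(ll - mx)
    s <- .posterior_summaries(grid, w / sum(w), ci_level, subclonal_ccf)
    map_ccf[i] <- s$map_ccf; ci_low[i] <- s$ci_low; ci_high[i] <- s$ci_high
    p_sub[i] <- s$p_subclonal; at_top[i] <- s$ci_high_at_top
  }
  label <- ifelse(!at_top & p_sub > p_subclonal_cut, "subclonal", "clonal")
  calls <- cbind(mut,
                 data.frame(map_ccf = map_ccf, ci_low = ci_low,
                            ci_high = ci_high, p_subclonal = p_sub,
                            label = label, stringsAsFactors = FALSE))

  samples <- sort(unique(c(bundle$purities$sample_id,
                           bundle$clinical$sample_id)))
  genes <- sort(unique(calls$gene))
  arch <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  gs <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    cg <- calls[calls$gene == genes[k], , drop = FALSE]
    has_c <- samples %in% cg$sample_id[cg$label == "clonal"]
    has_s <- samples %in% cg$sample_id[cg$label == "subclonal"]
    cat_k <- ifelse(has_c & has_s, "both",
                    ifelse(has_c, "clonal-only",
                           ifelse(has_s, "subclonal-only", "WT")))
    arch[[genes[k]]] <- cat_k
    gs[[k]] <- data.frame(gene = genes[k],
                          c1 = sum(cg$label == "clonal"),
                          s1 = sum(cg$label == "subclonal"),
                          patients_clonal_only = sum(cat_k == "clonal-only"),
                          patients_subclonal_only = sum(cat_k == "subclonal-only"),
                          patients_both = sum(cat_k == "both"),
                          patients_wt = sum(cat_k == "WT"),
                          stringsAsFactors = FALSE)
  }
  gene_summary <- if (length(gs)) do.call(rbind, gs) else
    data.frame(gene = character(), c1 = integer(), s1 = integer(),
               patients_clonal_only = integer(),
               patients_subclonal_only = integer(),
               patients_both = integer(), patients_wt = integer())
  skip <- rbind(data.frame(reason = "silent-class", n = n_silent),
                ann$skip_report)
  structure(list(calls = calls, gene_summary = gene_summary,
                 patient_architecture = arch, skip_report = skip,
                 ci_level = ci_level, subclonal_ccf = subclonal_ccf,
                 p_subclonal_cut = p_subclonal_cut),
            class = "clonality_calls")
}

#' @export
print.clonality_calls <- function(x, ...) {
  cat("Clonality calls:", nrow(x$calls), "classified non-silent mutations (",
      sum(x$calls$label == "clonal"), "clonal /",
      sum(x$calls$label == "subclonal"), "subclonal ) in",
      length(unique(x$calls$sample_id)), "samples,",
      nrow(x$gene_summary), "genes\n")
  ex <- x$skip_report[x$skip_report$n > 0, , drop = FALSE]
  if (nrow(ex))
    cat("  excluded:", paste(sprintf("%s=%d", ex$reason, ex$n),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.clonality_calls <- function(object, ...) {
  gs <- object$gene_summary
  gs$clonal_fraction <- ifelse(gs$c1 + gs$s1 > 0, gs$c1 / (gs$c1 + gs$s1), NA)
  structure(list(n_mutations = nrow(object$calls),
                 n_clonal = sum(object$calls$label == "clonal"),
                 n_subclonal = sum(object$calls$label == "subclonal"),
                 gene_summary = gs[order(-(gs$c1 + gs$s1)), , drop = FALSE],
                 skip_report = object$skip_report),
            class = "summary.clonality_calls")
}

#' @export
print.summary.clonality_calls <- function(x, ...) {
  cat("Cohort clonality summary\n")
  cat("  mutations classified:", x$n_mutations,
      sprintf("(%d clonal, %d subclonal; clonal fraction %.3f)\n",
              x$n_clonal, x$n_subclonal, x$n_clonal / max(1, x$n_mutations)))
  cat("  top genes by mutation count:\n")
  print(utils::head(x$gene_summary, 10), row.names = FALSE)
  invisible(x)
}
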