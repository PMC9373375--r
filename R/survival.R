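#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = death, 0 = censored).
#' @param group Optional group label stored on the result.
#' @return Object of class `survival_curve`: data.frame with `time`
#'   (observed event times), `n_risk`, `n_event`, `surv`, plus a `group`
#'   attribute.
#' @export
km_estimate <- function(times, events, group = NULL) {
  if (any(times < 0)) stop("negative survival times")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep])
  attr(out, "group") <- group
  attr(out, "n") <- length(times)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times (via `survival::survdiff`).
#'
#' @param times,events As in [km_estimate()].
#' @param group Group membership, at least 2 non-empty groups.
#' @return List with `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(as.character(group))
  if (nlevels(group) < 2L || any(table(group) == 0))
    stop("log-rank needs >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

# detect monotone-likelihood / zero-event covariate levels after the fit
.infinite_ci <- function(coef, se) {
  !is.finite(coef) | !is.finite(se) | abs(coef) > 15 | se > 100
}

#' Cox proportional-hazards fit with per-covariate hazard ratios
#'
#' Fits a proportional-hazards model (partial likelihood, Efron ties) on a
#' complete-case covariate table and reports the hazard ratio, Wald 95%
#' confidence interval and Wald p-value for every column. Gene clonality is
#' expected to enter as two dummies against wild type (see
#' [clonality_dummies()]). Covariate levels with monotone likelihood (for
#' instance zero events in a level) are flagged `infinite_ci` rather than
#' failing, mirroring the 0 / 0-Inf rows such models print.
#'
#' @param covariates Data.frame of numeric (dummy-coded) covariates.
#' @param times,events Survival outcome.
#' @param stage Label stored on the result (`"univariate"`, `"multivariate"`,
#'   `"stepwise"`, ...).
#' @return Object of class `cox_result`: data.frame with `term`, `coef`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`, `infinite_ci`; attributes `fit`
#'   (the `coxph` object), `stage`, `n`, `schoenfeld_p` (global
#'   proportional-hazards diagnostic, reported, not enforced).
#' @export
cox_fit <- function(covariates, times, events, stage = "multivariate") {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(times))
  cc <- stats::complete.cases(covariates) & !is.na(times) & !is.na(events)
  X <- covariates[cc, , drop = FALSE]
  y <- survival::Surv(times[cc], events[cc])
  fit <- survival::coxph(y ~ ., data = X, ties = "efron")
  s <- summary(fit)
  coefs <- s$coefficients
  inf <- .infinite_ci(coefs[, "coef"], coefs[, "se(coef)"])
  out <- data.frame(term = rownames(coefs),
                    coef = coefs[, "coef"],
                    hr = exp(coefs[, "coef"]),
                    ci_low = exp(coefs[, "coef"] - 1.96 * coefs[, "se(coef)"]),
                    ci_high = exp(coefs[, "coef"] + 1.96 * coefs[, "se(coef)"]),
                    p_value = coefs[, "Pr(>|z|)"],
                    infinite_ci = inf,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  zph_p <- tryCatch(
    as.numeric(survival::cox.zph(fit)$table["GLOBAL", "p"]),
    error = function(e) NA_real_)
  structure(out, fit = fit, stage = stage, n = sum(cc),
            schoenfeld_p = zph_p, class = c("cox_result", "data.frame"))
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards fit (", attr(x, "stage"), ", n = ",
      attr(x, "n"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$hr <- signif(df$hr, 3); df$ci_low <- signif(df$ci_low, 3)
  df$ci_high <- signif(df$ci_high, 3); df$p_value <- signif(df$p_value, 3)
  print(df[, c("term", "hr", "ci_low", "ci_high", "p_value", "infinite_ci")],
        row.names = FALSE)
  if (is.finite(attr(x, "schoenfeld_p")))
    cat("Global Schoenfeld proportionality p =",
        signif(attr(x, "schoenfeld_p"), 3), "\n")
  invisible(x)
}

#' Dummy-code a three-level clonality category against wild type
#'
#' @param category Character vector in `{clonal, subclonal, WT}`.
#' @param gene Gene name used to label the columns.
#' @return Data.frame with columns `<gene>_subclonal_vs_WT` and
#'   `<gene>_clonal_vs_WT`.
#' @export
clonality_dummies <- function(category, gene) {
  out <- data.frame(as.integer(category == "subclonal"),
                    as.integer(category == "clonal"))
  names(out) <- paste0(gene, c("_subclonal_vs_WT", "_clonal_vs_WT"))
  out
}

#' Backward stepwise elimination for Cox models
#'
#' Starting from the full model, repeatedly drops the least significant
#' removal unit (by likelihood-ratio test of dropping it) whose p-value
#' exceeds `threshold`, refitting after each removal, until every remaining
#' unit is significant. Units group columns that must leave jointly —
#' a gene's two clonality dummies are removed together, since the procedure
#' removes genes, not half-genes.
#'
#' @param covariates Data.frame of numeric covariates (full model).
#' @param times,events Survival outcome.
#' @param threshold Stay threshold on the unit p-value (default 0.05).
#' @param units Named list mapping unit name to column names removed jointly;
#'   defaults to one unit per column, with `<gene>_*_vs_WT` pairs grouped.
#' @return A `cox_result` for the final model (stage `"stepwise"`), with
#'   attributes `eliminated` (unit names, in removal order) and `retained`.
#'   An empty final model is returned as a zero-row result flagged via the
#'   `empty_model` attribute.
#' @export
stepwise_backward <- function(covariates, times, events, threshold = 0.05,
                              units = NULL) {
  if (is.null(units)) units <- .default_units(names(covariates))
  cc <- stats::complete.cases(covariates) & !is.na(times) & !is.na(events)
  X <- covariates[cc, , drop = FALSE]
  tt <- times[cc]; ee <- events[cc]
  active <- names(units)
  eliminated <- character(0)
  repeat {
    cols <- unlist(units[active], use.names = FALSE)
    if (length(cols) == 0L) break
    full <- survival::coxph(survival::Surv(tt, ee) ~ .,
                            data = X[, cols, drop = FALSE], ties = "efron")
    pu <- vapply(active, function(u) {
      rest <- setdiff(cols, units[[u]])
      red <- if (length(rest))
        survival::coxph(survival::Surv(tt, ee) ~ .,
                        data = X[, rest, drop = FALSE], ties = "efron")
      else survival::coxph(survival::Surv(tt, ee) ~ 1)
      lr <- 2 * (full$loglik[2] - if (length(rest)) red$loglik[2]
                 else red$loglik[1])
      stats::pchisq(max(lr, 0), df = length(units[[u]]), lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pu)
    if (pu[worst] <= threshold) break
    eliminated <- c(eliminated, active[worst])
    active <- active[-worst]
  }
  if (length(active) == 0L) {
    out <- data.frame(term = character(), coef = numeric(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), infinite_ci = logical())
    return(structure(out, stage = "stepwise", n = sum(cc),
                     eliminated = eliminated, retained = character(0),
                     empty_model = TRUE, schoenfeld_p = NA_real_,
                     class = c("cox_result", "data.frame")))
  }
  cols <- unlist(units[active], use.names = FALSE)
  res <- cox_fit(X[, cols, drop = FALSE], tt, ee, stage = "stepwise")
  attr(res, "eliminated") <- eliminated
  attr(res, "retained") <- active
  attr(res, "empty_model") <- FALSE
  res
}

# group <gene>_subclonal_vs_WT / <gene>_clonal_vs_WT pairs into joint units
.default_units <- function(cols) {
  units <- list()
  done <- character(0)
  for (cl in cols) {
    if (cl %in% done) next
    if (grepl("_(subclonal|clonal)_vs_WT$", cl)) {
      gene <- sub("_(subclonal|clonal)_vs_WT$", "", cl)
      pair <- cols[startsWith(cols, paste0(gene, "_")) &
                     grepl("_vs_WT$", cols)]
      units[[gene]] <- pair
      done <- c(done, pair)
    } else {
      units[[cl]] <- cl
      done <- c(done, cl)
    }
  }
  units
}

#' Bootstrap stability of the stepwise Cox model
#'
#' Resamples patients with replacement `B` times, reruns
#' [stepwise_backward()] on each replicate and reports, per removal unit, the
#' fraction of successful replicates in which the unit is retained.
#' Replicates whose fit fails are counted and excluded from the denominator.
#'
#' @inheritParams stepwise_backward
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `inclusion_frequency` (named numeric per unit),
#'   `n_failed`, `B`, `seed`.
#' @export
bootstrap_stability <- function(covariates, times, events, B = 1000, seed = 7,
                                threshold = 0.05, units = NULL) {
  if (is.null(units)) units <- .default_units(names(covariates))
  set.seed(seed)
  n <- nrow(covariates)
  kept <- stats::setNames(numeric(length(units)), names(units))
  n_ok <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      suppressWarnings(stepwise_backward(covariates[idx, , drop = FALSE],
                                         times[idx], events[idx],
                                         threshold = threshold, units = units)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    ret <- attr(res, "retained")
    kept[ret] <- kept[ret] + 1
  }
  list(inclusion_frequency = if (n_ok > 0) kept / n_ok else kept * NA,
       n_failed = B - n_ok, B = B, seed = seed)
}

#' Per-gene three-group survival scan
#'
#' For every eligible gene (at least `min_patients` clonal AND subclonal
#' carriers), compares overall survival across the clonal / subclonal / WT
#' categories: overall three-group log-rank p-value plus the three pairwise
#' tests. An optional subgroup restriction (`"msi"`, `"stage12"`,
#' `"right"`) filters patients before testing; a pairwise test whose
#' subgroup empties a category is flagged not evaluable (NA).
#'
#' @param categories Output of [patient_gene_category()].
#' @param clinical Clinical table.
#' @param min_patients Eligibility threshold (default 5).
#' @param subgroup Optional: `"msi"`, `"stage12"` or `"right"`.
#' @return Data.frame: `gene`, `eligible`, `p_overall`,
#'   `p_clonal_vs_wt`, `p_subclonal_vs_wt`, `p_clonal_vs_subclonal`.
#' @export
gene_survival_scan <- function(categories, clinical, min_patients = 5,
                               subgroup = NULL) {
  idx <- match(categories$sample_id, clinical$sample_id)
  clin <- clinical[idx, , drop = FALSE]
  keep <- !is.na(clin$os_time) & !is.na(clin$os_event)
  if (!is.null(subgroup)) {
    keep <- keep & switch(subgroup,
      msi = clin$msi_status %in% "MSI",
      stage12 = clin$ajcc_stage %in% c("1", "2"),
      right = clin$tumour_site %in% "right-sided",
      stop("unknown subgroup: ", subgroup))
  }
  genes <- setdiff(names(categories), "sample_id")
  # eligibility is cohort-wide (pre-subgroup), as in the driver-gene filter
  out <- list()
  pair_p <- function(cat_v, a, b, tt, ee) {
    sel <- cat_v %in% c(a, b)
    if (length(unique(cat_v[sel])) < 2L) return(NA_real_)
    logrank_test(tt[sel], ee[sel], cat_v[sel])$p_value
  }
  for (gene in genes) {
    cat_all <- categories[[gene]]
    eligible <- sum(cat_all == "clonal") >= min_patients &&
      sum(cat_all == "subclonal") >= min_patients
    p_ov <- p_cw <- p_sw <- p_cs <- NA_real_
    if (eligible) {
      cat_v <- cat_all[keep]
      tt <- clin$os_time[keep]; ee <- clin$os_event[keep]
      if (length(unique(cat_v)) >= 2L)
        p_ov <- logrank_test(tt, ee, cat_v)$p_value
      p_cw <- pair_p(cat_v, "clonal", "WT", tt, ee)
      p_sw <- pair_p(cat_v, "subclonal", "WT", tt, ee)
      p_cs <- pair_p(cat_v, "clonal", "subclonal", tt, ee)
    }
    out[[length(out) + 1L]] <-
      data.frame(gene = gene, eligible = eligible, p_overall = p_ov,
                 p_clonal_vs_wt = p_cw, p_subclonal_vs_wt = p_sw,
                 p_clonal_vs_subclonal = p_cs, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
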