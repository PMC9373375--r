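#' Simulation configuration for synthetic cohorts
#'
#' Builds and validates the configuration consumed by [simulate_cohort()].
#' The defaults emulate a TCGA-style colorectal exome cohort: 536 patients, a
#' small panel of recurrently mutated driver genes with predominantly clonal
#' mutations (cohort-wide clonal fraction around 0.8), purity drawn uniformly
#' from (0.3, 0.95), exome-like depth (Poisson mean 100, truncated at 30),
#' 15% MSI-prevalence with a 3x hypermutation multiplier, and exponential
#' survival with configurable clonality log-hazard effects.
#'
#' @param n_patients Number of patients.
#' @param genes Data.frame with columns `gene`, `rate` (per-patient mutation
#'   probability) and `clonal_bias` (probability that a mutation is clonal,
#'   i.e. true CCF = 1).
#' @param purity_range Length-2 numeric, uniform purity range in (0, 1].
#' @param depth_mean Poisson mean of sequencing depth.
#' @param depth_floor Minimum depth; the Poisson is truncated here.
#' @param subclonal_ccf_range Range of true subclonal CCFs; must sit strictly
#'   inside (0, 0.9) so truth labels agree with the 0.9 classification
#'   threshold.
#' @param cn_states Data.frame with columns `cn` (non-negative integers) and
#'   `prob` (summing to 1): local absolute copy-number states.
#' @param msi_prevalence Fraction of MSI patients.
#' @param msi_rate_mult Multiplier on gene mutation rates in MSI patients
#'   (hypermutation); capped so rates stay below 0.95.
#' @param msi_link Optional list `list(gene=, odds=)`: multiplies the odds
#'   that a mutation in `gene` is subclonal for MSI patients, creating a
#'   clonality-by-MSI association with known effect size.
#' @param loghr_effects Data.frame with columns `gene`, `label` (`"clonal"` or
#'   `"subclonal"`), `loghr`: per-patient log hazard added when the patient's
#'   true category for `gene` equals `label`.
#' @param clinical_loghr Named numeric; recognized names: `age_high` (age >=
#'   67.5) and `m1` (M1 stage).
#' @param base_hazard Baseline exponential hazard (per month);
#'   default log(2)/60, i.e. 60-month baseline median survival.
#' @param censor_rate Target fraction of censored patients; censoring times
#'   are independent exponentials calibrated to this rate.
#' @param both_rate Probability that a clonally mutated patient-gene also
#'   carries a second, subclonal mutation (off by default: one mutation per
#'   gene per patient).
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 536,
                       genes = default_gene_panel(),
                       purity_range = c(0.3, 0.95),
                       depth_mean = 100, depth_floor = 30,
                       subclonal_ccf_range = c(0.1, 0.8),
                       cn_states = data.frame(cn = c(1L, 2L, 3L, 4L),
                                              prob = c(0.1, 0.6, 0.2, 0.1)),
                       msi_prevalence = 0.15, msi_rate_mult = 3,
                       msi_link = list(gene = "ANK1", odds = 3),
                       loghr_effects = data.frame(gene = "ANK1",
                                                  label = "subclonal",
                                                  loghr = log(3)),
                       clinical_loghr = c(age_high = log(2)),
                       base_hazard = log(2) / 60,
                       censor_rate = 0.55,
                       both_rate = 0,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), genes = genes,
              purity_range = purity_range, depth_mean = depth_mean,
              depth_floor = depth_floor,
              subclonal_ccf_range = subclonal_ccf_range,
              cn_states = cn_states, msi_prevalence = msi_prevalence,
              msi_rate_mult = msi_rate_mult, msi_link = msi_link,
              loghr_effects = loghr_effects, clinical_loghr = clinical_loghr,
              base_hazard = base_hazard, censor_rate = censor_rate,
              both_rate = both_rate, seed = as.integer(seed))
  errs <- character()
  if (cfg$n_patients < 1L) errs <- c(errs, "n_patients must be >= 1")
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    errs <- c(errs, "genes must be a non-empty data.frame")
  else {
    if (any(genes$rate < 0 | genes$rate > 1))
      errs <- c(errs, "gene rates must be in [0, 1]")
    if (any(genes$clonal_bias < 0 | genes$clonal_bias > 1))
      errs <- c(errs, "clonal_bias must be in [0, 1]")
  }
  if (purity_range[1] <= 0 || purity_range[2] > 1 ||
      purity_range[1] > purity_range[2])
    errs <- c(errs, "purity_range must satisfy 0 < low <= high <= 1")
  if (subclonal_ccf_range[1] <= 0 || subclonal_ccf_range[2] >= 0.9 ||
      subclonal_ccf_range[1] > subclonal_ccf_range[2])
    errs <- c(errs, "subclonal_ccf_range must lie strictly inside (0, 0.9)")
  if (abs(sum(cn_states$prob) - 1) > 1e-8 || any(cn_states$prob < 0))
    errs <- c(errs, "cn_states$prob must be non-negative and sum to 1")
  if (any(cn_states$cn < 0)) errs <- c(errs, "cn_states$cn must be >= 0")
  if (censor_rate < 0 || censor_rate >= 1)
    errs <- c(errs, "censor_rate must be in [0, 1)")
  if (depth_mean <= 0 || depth_floor < 1)
    errs <- c(errs, "depth_mean must be > 0 and depth_floor >= 1")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  structure(cfg, class = "sim_config")
}

#' Default driver-gene panel for the simulator
#'
#' Twelve genes with mutation rates and clonal biases chosen to mimic the
#' mutation-frequency spectrum of colorectal driver genes (frequent, mostly
#' clonal TP53/APC/KRAS down to infrequent, substantially subclonal genes),
#' yielding a cohort-wide clonal fraction of roughly 0.8.
#'
#' @return Data.frame with columns `gene`, `rate`, `clonal_bias`.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("TP53", "APC", "KRAS", "PIK3CA", "FBXW7", "SMAD4",
             "BRAF", "ARID1A", "BCL9L", "CASP8", "SMAD2", "ANK1"),
    rate = c(0.55, 0.70, 0.40, 0.25, 0.15, 0.12,
             0.12, 0.10, 0.07, 0.06, 0.05, 0.05),
    clonal_bias = c(0.92, 0.82, 0.92, 0.85, 0.82, 0.75,
                    0.90, 0.78, 0.75, 0.70, 0.65, 0.45),
    stringsAsFactors = FALSE)
}

#' Simulate tumor read counts for one or more mutations
#'
#' Draws alt read counts from the binomial observation model that the CCF
#' posterior inverts: `t_alt ~ Binomial(depth, expected_vaf(...))`.
#'
#' @param true_ccf True cancer cell fraction(s) in (0, 1].
#' @param purity Tumor purity in (0, 1].
#' @param local_cn Local tumor copy number (>= 1).
#' @param depth Total depth (>= 1).
#' @return Data.frame with columns `t_alt`, `t_depth`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_reads(0.4, purity = 0.5, local_cn = 2, depth = 100)
simulate_reads <- function(true_ccf, purity, local_cn, depth) {
  if (any(depth < 1)) stop("depth must be >= 1")
  if (any(local_cn < 1)) stop("local_cn must be >= 1 for a scorable site")
  ev <- expected_vaf(purity, true_ccf, local_cn)
  if (any(ev < 0 | ev > 1)) stop("expected VAF outside [0, 1]")
  n <- max(length(true_ccf), length(purity), length(local_cn), length(depth))
  data.frame(t_alt = stats::rbinom(n, depth, ev), t_depth = rep_len(depth, n))
}

.rpois_trunc <- function(n, mean, floor) {
  d <- stats::rpois(n, mean)
  while (any(d < floor)) d[d < floor] <- stats::rpois(sum(d < floor), mean)
  d
}

.variant_class_probs <- c(Missense_Mutation = 0.58, Nonsense_Mutation = 0.12,
                          Frame_Shift_Del = 0.08, Frame_Shift_Ins = 0.05,
                          In_Frame_Del = 0.03, Splice_Site = 0.06,
                          Silent = 0.08)

#' Simulate a cohort with known clonal ground truth
#'
#' Generates, per patient: a uniform purity; per gene, a mutation with the
#' gene's rate (multiplied in MSI patients), clonal with the gene's bias
#' (clonal means true CCF = 1, else CCF ~ Uniform over the subclonal range);
#' truncated-Poisson depth; a local copy-number state with a matching SEG
#' segment covering the site; clinical covariates with the configured
#' clonality associations; and exponential survival times whose hazard is
#' multiplied by `exp(loghr)` for each configured (gene, clonality) category
#' the patient belongs to, with independent exponential censoring calibrated
#' to the configured censoring rate.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`. The output is fully
#'   reproducible from the seed.
#' @return List with elements `bundle` (a [cohort_bundle()]) and `truth`
#'   (data.frame of per-mutation ground truth: `sample_id`, `gene`, `chrom`,
#'   `pos`, `true_ccf`, `true_label`, `local_cn`, `purity`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_patients
  genes <- config$genes
  ids <- sprintf("P%04d", seq_len(n))
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])

  # clinical covariates
  age <- pmin(90, pmax(30, round(stats::rnorm(n, 67.5, 11))))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.47, 0.53))
  msi <- stats::rbinom(n, 1, config$msi_prevalence) == 1
  site <- ifelse(stats::runif(n) < ifelse(msi, 0.70, 0.35),
                 "right-sided", "left-sided")
  ajcc <- sample(c("1", "2", "3", "4"), n, replace = TRUE,
                 prob = c(0.18, 0.38, 0.29, 0.15))
  t_stage <- ifelse(ajcc == "1",
                    sample(c("T1", "T2"), n, replace = TRUE),
                    sample(c("T2", "T3", "T4"), n, replace = TRUE,
                           prob = c(0.1, 0.7, 0.2)))
  n_stage <- ifelse(ajcc %in% c("1", "2"), "N0",
                    sample(c("N1", "N2"), n, replace = TRUE,
                           prob = c(0.6, 0.4)))
  m_stage <- ifelse(ajcc == "4", "M1", "M0")

  # mutations, one gene locus per chromosome slot; segments per patient-gene
  mut <- list(); tru <- list(); seg <- list()
  for (g in seq_len(nrow(genes))) {
    gene <- genes$gene[g]
    chrom <- as.character(((g - 1L) %% 22L) + 1L)
    pos <- 1e7 * (1 + (g - 1L) %/% 22L)
    rate <- pmin(0.95, genes$rate[g] * ifelse(msi, config$msi_rate_mult, 1))
    has <- stats::rbinom(n, 1, rate) == 1
    if (!any(has)) next
    idx <- which(has)
    p_sub <- rep(1 - genes$clonal_bias[g], length(idx))
    if (!is.null(config$msi_link) && identical(config$msi_link$gene, gene)) {
      odds <- p_sub / (1 - p_sub) *
        ifelse(msi[idx], config$msi_link$odds, 1)
      p_sub <- odds / (1 + odds)
    }
    subcl <- stats::rbinom(length(idx), 1, p_sub) == 1
    second <- config$both_rate > 0 & !subcl &
      stats::rbinom(length(idx), 1, config$both_rate) == 1
    cn <- sample(config$cn_states$cn, length(idx), replace = TRUE,
                 prob = config$cn_states$prob)
    cn <- pmax(cn, 1L)  # a point mutation needs at least one tumor copy
    mk <- function(which_idx, offset, is_sub, cn_use) {
      m <- length(which_idx)
      if (m == 0L) return(NULL)
      ccf <- ifelse(is_sub,
                    stats::runif(m, config$subclonal_ccf_range[1],
                                 config$subclonal_ccf_range[2]), 1)
      depth <- .rpois_trunc(m, config$depth_mean, config$depth_floor)
      t_alt <- stats::rbinom(m, depth,
                             expected_vaf(purity[which_idx], ccf, cn_use))
      vc <- sample(names(.variant_class_probs), m, replace = TRUE,
                   prob = .variant_class_probs)
      list(mut = data.frame(sample_id = ids[which_idx], gene = gene,
                            chrom = chrom, pos = pos + offset,
                            variant_class = vc, t_alt = t_alt,
                            t_depth = depth, stringsAsFactors = FALSE),
           tru = data.frame(sample_id = ids[which_idx], gene = gene,
                            chrom = chrom, pos = pos + offset,
                            true_ccf = ccf,
                            true_label = ifelse(is_sub, "subclonal", "clonal"),
                            local_cn = cn_use, purity = purity[which_idx],
                            stringsAsFactors = FALSE))
    }
    first <- mk(idx, 0L, subcl, cn)
    extra <- mk(idx[second], 100L, rep(TRUE, sum(second)), cn[second])
    mut[[length(mut) + 1L]] <- first$mut; tru[[length(tru) + 1L]] <- first$tru
    if (!is.null(extra)) {
      mut[[length(mut) + 1L]] <- extra$mut
      tru[[length(tru) + 1L]] <- extra$tru
    }
    seg[[length(seg) + 1L]] <- data.frame(sample_id = ids[idx], chrom = chrom,
                                          start = pos - 5e4, end = pos + 5e4,
                                          absolute_cn = cn,
                                          stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, mut)
  truth <- do.call(rbind, tru)
  segments <- do.call(rbind, seg)
  if (is.null(mutations))
    stop("configuration produced zero mutations; increase rates or patients")
  o <- order(mutations$sample_id, mutations$gene, mutations$pos)
  mutations <- mutations[o, , drop = FALSE]; rownames(mutations) <- NULL
  o <- order(truth$sample_id, truth$gene, truth$pos)
  truth <- truth[o, , drop = FALSE]; rownames(truth) <- NULL
  segments <- segments[order(segments$sample_id, as.integer(segments$chrom),
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL

  # survival: exponential with clonality and clinical log-hazard effects
  loghr <- rep(0, n)
  eff <- config$loghr_effects
  if (!is.null(eff) && nrow(eff)) {
    truth_cat <- .truth_categories(truth, ids)
    for (k in seq_len(nrow(eff))) {
      in_cat <- truth_cat[[eff$gene[k]]] == eff$label[k]
      if (!is.null(in_cat)) loghr <- loghr + ifelse(in_cat, eff$loghr[k], 0)
    }
  }
  cl <- config$clinical_loghr
  if (!is.null(cl)) {
    if ("age_high" %in% names(cl)) loghr <- loghr + cl["age_high"] * (age >= 67.5)
    if ("m1" %in% names(cl)) loghr <- loghr + cl["m1"] * (m_stage == "M1")
  }
  hazard <- config$base_hazard * exp(loghr)
  t_event <- stats::rexp(n, hazard)
  r <- config$censor_rate
  if (r > 0) {
    cens_rate <- mean(hazard) * r / (1 - r)
    t_cens <- stats::rexp(n, cens_rate)
  } else t_cens <- rep(Inf, n)
  os_time <- round(pmin(t_event, t_cens), 3)
  os_event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(sample_id = ids, age = age, sex = sex,
                         msi_status = ifelse(msi, "MSI", "MSS"),
                         tumour_site = site, ajcc_stage = ajcc,
                         t_stage = t_stage, n_stage = n_stage,
                         m_stage = m_stage, os_time = os_time,
                         os_event = os_event, stringsAsFactors = FALSE)
  purities <- data.frame(sample_id = ids, purity = round(purity, 4),
                         stringsAsFactors = FALSE)
  # read counts were drawn with full-precision purity; re-scoring uses the
  # rounded table, a <1e-4 perturbation far below read-count noise
  list(bundle = cohort_bundle(mutations, segments, purities, clinical),
       truth = truth)
}

# per-patient true category per gene (clonal-dominant collapse), keyed list
.truth_categories <- function(truth, ids) {
  out <- list()
  for (gene in unique(truth$gene)) {
    tg <- truth[truth$gene == gene, , drop = FALSE]
    has_c <- ids %in% tg$sample_id[tg$true_label == "clonal"]
    has_s <- ids %in% tg$sample_id[tg$true_label == "subclonal"]
    out[[gene]] <- ifelse(has_c, "clonal", ifelse(has_s, "subclonal", "WT"))
  }
  out
}

#' Write a simulated cohort to a directory of TSVs
#'
#' Emits the four cohort tables in the formats of the package readers, plus
#' `truth.tsv` with the per-mutation ground truth. Files are re-readable with
#' [read_cohort()]; output under a fixed seed is byte-stable across runs.
#'
#' @param bundle A `cohort_bundle`.
#' @param truth Truth data.frame from [simulate_cohort()] (or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(bundle, truth, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(mutations = file.path(out_dir, "mutations.maf.tsv"),
             segments = file.path(out_dir, "segments.seg.tsv"),
             purity = file.path(out_dir, "purity.tsv"),
             clinical = file.path(out_dir, "clinical.tsv"))
  write_maf(bundle$mutations, paths["mutations"])
  write_segments(bundle$segments, paths["segments"])
  write_purity(bundle$purities, paths["purity"])
  write_clinical(bundle$clinical, paths["clinical"])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(out_dir, "truth.tsv"))
    .write_tsv(truth, paths["truth"])
  }
  invisible(paths)
}
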