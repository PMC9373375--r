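#' Default pipeline configuration
#'
#' @return Named list of pipeline defaults: simulation on (536-patient
#'   synthetic cohort), all stages enabled, the classification thresholds
#'   (CCF 0.9, probability 0.5, CI level 0.95), 1000 permutations, the
#'   5-patient eligibility filter, bootstrap off, seed 1.
#' @export
default_pipeline_config <- function() {
  list(simulate = TRUE, sim = list(), input_dir = NULL,
       stages = c("ccf", "enrich", "assoc", "survival"),
       subclonal_ccf = 0.9, p_subclonal = 0.5, ci_level = 0.95,
       n_perm = 1000, min_patients = 5, boot = 0,
       both_rule = "clonal-dominant", seed = 1L)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list, fills every default, and reports all
#' violations at once rather than stopping at the first. The configuration is
#' never partially applied: if any violation is found, `errors` is non-empty
#' and `run_pipeline()` refuses the config.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return List with `config` (normalized) and `errors` (character vector,
#'   empty when valid).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  errs <- character()
  chk01 <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      errs <<- c(errs, sprintf("%s must be in (0,1)", name))
  }
  chk01("subclonal_ccf"); chk01("p_subclonal"); chk01("ci_level")
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 1)
    errs <- c(errs, "n_perm must be a positive integer")
  if (!is.numeric(cfg$min_patients) || cfg$min_patients < 1)
    errs <- c(errs, "min_patients must be a positive integer")
  if (!is.numeric(cfg$boot) || cfg$boot < 0)
    errs <- c(errs, "boot must be a non-negative integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errs <- c(errs, "seed must be a single integer")
  else cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(cfg$stages, c("ccf", "enrich", "assoc", "survival"))
  if (length(bad))
    errs <- c(errs, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (!isTRUE(cfg$simulate) &&
      (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir)))
    errs <- c(errs, "input_dir must exist when simulate is off")
  if (!cfg$both_rule %in% c("clonal-dominant", "subclonal-dominant"))
    errs <- c(errs, "both_rule must be clonal-dominant or subclonal-dominant")
  list(config = cfg, errors = errs)
}

# clinical covariate dummies shared by the pipeline Cox stage
.clinical_covariates <- function(clinical) {
  data.frame(
    age_high = as.integer(clinical$age >= stats::median(clinical$age,
                                                        na.rm = TRUE)),
    sex_male = as.integer(clinical$sex == "male"),
    site_left = as.integer(clinical$tumour_site == "left-sided"),
    msi = as.integer(clinical$msi_status == "MSI"),
    stage34 = as.integer(clinical$ajcc_stage %in% c("3", "4")),
    t34 = as.integer(clinical$t_stage %in% c("T3", "T4")),
    n12 = as.integer(clinical$n_stage %in% c("N1", "N2")),
    m1 = as.integer(clinical$m_stage == "M1"))
}

#' Run the full clonality pipeline
#'
#' Orchestrates simulate (or read) -> CCF calling -> enrichment ->
#' clinical association -> survival, writing every stage's tables under
#' `out_dir` together with `run.log` (per-stage record counts and skip
#' reasons) and `manifest.tsv` (file -> md5 checksum). A rerun with the same
#' config and seed reproduces byte-identical TSVs. A stage failure stops the
#' run naming the stage; tables already written are retained and the manifest
#' carries a `failed` marker for the stage.
#'
#' @param config A config accepted by [validate_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest data.frame (`file`, `md5`, `stage`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  v <- validate_config(config)
  if (length(v$errors))
    stop("invalid pipeline config:\n  ", paste(v$errors, collapse = "\n  "))
  cfg <- v$config
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  files <- character(0); stages_of <- character(0)
  add_file <- function(path, stage) {
    files <<- c(files, path); stages_of <<- c(stages_of, stage)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      add_file(NA_character_, paste0(name, ":failed"))
      .write_manifest(files, stages_of, out_dir)
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- cohort ---------------------------------------------------------------
  bundle <- NULL
  run_stage("cohort", {
    if (isTRUE(cfg$simulate)) {
      sc <- do.call(sim_config, cfg$sim)
      sim <- simulate_cohort(sc, seed = cfg$seed)
      bundle <- sim$bundle
      paths <- write_cohort(sim$bundle, sim$truth,
                            file.path(out_dir, "cohort"))
      for (p in paths) add_file(p, "cohort")
      logmsg("cohort: simulated ", nrow(bundle$clinical), " patients, ",
             nrow(bundle$mutations), " mutations (seed ", cfg$seed, ")")
    } else {
      bundle <- read_cohort(cfg$input_dir)
      logmsg("cohort: read ", nrow(bundle$clinical), " patients, ",
             nrow(bundle$mutations), " mutations from ", cfg$input_dir)
    }
  })

  calls <- NULL
  if ("ccf" %in% cfg$stages) run_stage("ccf", {
    calls <- call_clonality(bundle, ci_level = cfg$ci_level,
                             subclonal_ccf = cfg$subclonal_ccf,
                             p_subclonal_cut = cfg$p_subclonal)
    add_file(.write_tsv(calls$calls, file.path(out_dir, "calls.tsv")), "ccf")
    add_file(.write_tsv(calls$gene_summary,
                        file.path(out_dir, "gene_summary.tsv")), "ccf")
    add_file(.write_tsv(calls$patient_architecture,
                        file.path(out_dir, "patient_architecture.tsv")), "ccf")
    add_file(.write_tsv(calls$skip_report,
                        file.path(out_dir, "skip_report.tsv")), "ccf")
    logmsg("ccf: classified ", nrow(calls$calls), " mutations (",
           sum(calls$calls$label == "clonal"), " clonal / ",
           sum(calls$calls$label == "subclonal"), " subclonal); skipped ",
           sum(calls$skip_report$n))
  }) else logmsg("ccf: stage disabled")

  if ("enrich" %in% cfg$stages && !is.null(calls)) run_stage("enrich", {
    enr <- gene_enrichment(calls, n_perm = cfg$n_perm, seed = cfg$seed)
    add_file(.write_tsv(enr, file.path(out_dir, "enrichment.tsv")), "enrich")
    logmsg("enrich: ", nrow(enr), " genes, ", cfg$n_perm, " permutations")
  }) else logmsg("enrich: stage disabled")

  if ("assoc" %in% cfg$stages && !is.null(calls)) run_stage("assoc", {
    categories <- patient_gene_category(calls,
                                        samples = bundle$clinical$sample_id,
                                        rule = cfg$both_rule)
    scan <- association_scan(categories, bundle$clinical,
                             min_patients = cfg$min_patients)
    add_file(.write_tsv(scan$results,
                        file.path(out_dir, "associations.tsv")), "assoc")
    mat <- data.frame(gene = rownames(scan$neglog2p_matrix),
                      scan$neglog2p_matrix, check.names = FALSE)
    add_file(.write_tsv(mat, file.path(out_dir, "neglog2p_matrix.tsv")),
             "assoc")
    add_file(.write_tsv(.burden_table(calls, bundle$clinical),
                        file.path(out_dir, "burden_tests.tsv")), "assoc")
    add_file(.write_tsv(mutation_type_vs_clonality(calls),
                        file.path(out_dir, "mutation_type_tests.tsv")),
             "assoc")
    logmsg("assoc: ", sum(scan$results$eligible), " eligible gene-variable ",
           "tests of ", nrow(scan$results))
  }) else logmsg("assoc: stage disabled")

  if ("survival" %in% cfg$stages && !is.null(calls)) run_stage("survival", {
    categories <- patient_gene_category(calls,
                                        samples = bundle$clinical$sample_id,
                                        rule = cfg$both_rule)
    km <- gene_survival_scan(categories, bundle$clinical,
                             min_patients = cfg$min_patients)
    add_file(.write_tsv(km, file.path(out_dir, "km_logrank.tsv")), "survival")
    hit_genes <- km$gene[km$eligible & !is.na(km$p_overall) &
                           km$p_overall < 0.05]
    logmsg("survival: ", sum(km$eligible), " eligible genes, ",
           length(hit_genes), " with three-group log-rank p < 0.05")
    clin <- bundle$clinical
    covs <- .clinical_covariates(clin)
    for (g in hit_genes)
      covs <- cbind(covs, clonality_dummies(
        categories[[g]][match(clin$sample_id, categories$sample_id)], g))
    units <- .default_units(names(covs))
    uni <- do.call(rbind, lapply(names(units), function(u) {
      r <- cox_fit(covs[, units[[u]], drop = FALSE], clin$os_time,
                   clin$os_event, stage = "univariate")
      as.data.frame(r)
    }))
    add_file(.write_tsv(uni, file.path(out_dir, "cox_univariate.tsv")),
             "survival")
    multi <- cox_fit(covs, clin$os_time, clin$os_event)
    add_file(.write_tsv(as.data.frame(multi),
                        file.path(out_dir, "cox_multivariate.tsv")),
             "survival")
    step <- stepwise_backward(covs, clin$os_time, clin$os_event,
                              units = units)
    add_file(.write_tsv(as.data.frame(step),
                        file.path(out_dir, "cox_stepwise.tsv")), "survival")
    logmsg("survival: stepwise retained [",
           paste(attr(step, "retained"), collapse = ", "), "]")
    if (cfg$boot > 0) {
      bs <- bootstrap_stability(covs, clin$os_time, clin$os_event,
                                B = cfg$boot, seed = cfg$seed, units = units)
      add_file(.write_tsv(
        data.frame(unit = names(bs$inclusion_frequency),
                   inclusion_frequency = bs$inclusion_frequency),
        file.path(out_dir, "bootstrap_inclusion.tsv")), "survival")
      logmsg("survival: bootstrap B=", bs$B, ", ", bs$n_failed,
             " failed replicates")
    }
  }) else logmsg("survival: stage disabled")

  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest <- .write_manifest(files, stages_of, out_dir)
  invisible(manifest)
}

.write_manifest <- function(files, stages, out_dir) {
  ok <- !is.na(files)
  manifest <- data.frame(
    file = c(basename(files[ok]), stages[!ok]),
    md5 = c(unname(tools::md5sum(files[ok])),
            rep("failed", sum(!ok))),
    stage = c(stages[ok], rep("failed", sum(!ok))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

# per-patient clonal/subclonal burden vs each binary clinical variable
.burden_table <- function(calls, clinical, method = "t-test") {
  ids <- clinical$sample_id
  n_clonal <- vapply(ids, function(s)
    sum(calls$calls$sample_id == s & calls$calls$label == "clonal"),
    numeric(1))
  n_sub <- vapply(ids, function(s)
    sum(calls$calls$sample_id == s & calls$calls$label == "subclonal"),
    numeric(1))
  bins <- .binarize_clinical(clinical)
  out <- list()
  for (v in names(bins)) {
    grp <- bins[[v]]$levels[bins[[v]]$value]
    for (ct in c("clonal", "subclonal")) {
      counts <- if (ct == "clonal") n_clonal else n_sub
      bc <- burden_compare(counts, grp, method = method)
      out[[length(out) + 1L]] <-
        data.frame(count_type = ct, variable = v, p_value = bc$p_value,
                   method = method, evaluable = bc$evaluable,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
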