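#' @title Readers and writers for the cohort tables
#' @description MAF-style mutations, SEG-style absolute copy-number segments,
#'   per-sample purity and per-patient clinical tables. All files are
#'   tab-separated with a header row; missing values are encoded as "NA".
#'   Coordinates are 1-based and inclusive on both the MAF and SEG side
#'   (TCGA convention), so interval lookups need no off-by-one adjustment.
#' @name cohort_io
NULL

.maf_required <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                   "Variant_Classification", "t_alt_count",
                   "Tumor_Sample_Barcode")

#' Default non-silent variant classification whitelist
#'
#' Mutation classes counted as non-silent in all analyses. Configurable
#' wherever it is consumed; silent/UTR/intron/IGR classes are excluded.
#'
#' @return Character vector of variant classes.
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Nonstop_Mutation", "Translation_Start_Site")
}

.int_or_na <- function(x) suppressWarnings(as.integer(round(as.numeric(x))))

#' Read a MAF-style somatic mutation table
#'
#' Requires the TCGA column names `Hugo_Symbol`, `Chromosome`,
#' `Start_Position`, `Variant_Classification`, `t_alt_count`,
#' `Tumor_Sample_Barcode` and either `t_depth` or `t_ref_count` (depth is then
#' `t_alt + t_ref`). Rows whose read counts or position do not parse as valid
#' integers (including `t_alt > t_depth`) are dropped and counted in the skip
#' report attached as `attr(x, "skip_report")`.
#'
#' @param path Path to a tab-separated MAF-style file.
#' @return A data.frame with columns `sample_id`, `gene`, `chrom`, `pos`,
#'   `variant_class`, `t_alt`, `t_depth`, plus a `skip_report` attribute
#'   (named integer vector; `n_input` rows = `nrow(x)` + sum of skips).
#' @export
read_maf <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0L) stop("empty MAF file: ", path)
  for (col in .maf_required)
    if (!col %in% names(raw)) stop("MAF file missing required column: ", col)
  if (!"t_depth" %in% names(raw) && !"t_ref_count" %in% names(raw))
    stop("MAF file missing required column: t_depth (or t_ref_count)")
  t_alt <- .int_or_na(raw[["t_alt_count"]])
  t_depth <- if ("t_depth" %in% names(raw)) .int_or_na(raw[["t_depth"]])
             else t_alt + .int_or_na(raw[["t_ref_count"]])
  pos <- .int_or_na(raw[["Start_Position"]])
  bad_counts <- is.na(t_alt) | is.na(t_depth) | t_alt < 0 | t_depth < 1 |
    t_alt > t_depth
  bad_pos <- !bad_counts & (is.na(pos) | pos < 1)
  keep <- !bad_counts & !bad_pos
  out <- data.frame(sample_id = as.character(raw[["Tumor_Sample_Barcode"]])[keep],
                    gene = as.character(raw[["Hugo_Symbol"]])[keep],
                    chrom = .norm_chrom(raw[["Chromosome"]])[keep],
                    pos = pos[keep],
                    variant_class = as.character(raw[["Variant_Classification"]])[keep],
                    t_alt = t_alt[keep],
                    t_depth = t_depth[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skip_report") <- c(n_input = nrow(raw),
                                bad_counts = sum(bad_counts),
                                bad_position = sum(bad_pos))
  out
}

.norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Write mutations back to MAF-style TSV
#'
#' Inverse of [read_maf()]: `read_maf(write_maf(x, f))` reproduces `x`
#' field-by-field.
#'
#' @param mutations Data.frame as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  out <- data.frame(Hugo_Symbol = mutations$gene,
                    Chromosome = mutations$chrom,
                    Start_Position = mutations$pos,
                    Variant_Classification = mutations$variant_class,
                    t_alt_count = mutations$t_alt,
                    t_ref_count = mutations$t_depth - mutations$t_alt,
                    Tumor_Sample_Barcode = mutations$sample_id)
  .write_tsv(out, path)
}

#' Read a SEG-style absolute copy-number table
#'
#' Columns `sample`, `chrom`, `start`, `end`, `absolute_cn`. The copy number
#' must be a non-negative integer (this is ABSOLUTE-style output, not a log2
#' ratio). Segments are returned sorted by (sample, chrom, start); overlapping
#' segments within one sample and chromosome are a hard error.
#'
#' @param path Path to the tab-separated segment file.
#' @return Data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `absolute_cn`.
#' @export
read_segments <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample", "chrom", "start", "end", "absolute_cn"))
    if (!col %in% names(raw)) stop("segment file missing required column: ", col)
  cn_num <- suppressWarnings(as.numeric(raw$absolute_cn))
  if (any(is.na(cn_num)) || any(abs(cn_num - round(cn_num)) > 1e-8))
    stop("absolute_cn must be a non-negative integer (got e.g. ",
         raw$absolute_cn[which(is.na(cn_num) | abs(cn_num - round(cn_num)) > 1e-8)[1]],
         ")")
  out <- data.frame(sample_id = as.character(raw$sample),
                    chrom = .norm_chrom(raw$chrom),
                    start = .int_or_na(raw$start),
                    end = .int_or_na(raw$end),
                    absolute_cn = as.integer(round(cn_num)),
                    stringsAsFactors = FALSE)
  if (any(out$absolute_cn < 0)) stop("absolute_cn must be >= 0")
  if (any(is.na(out$start) | is.na(out$end) | out$start > out$end))
    stop("segment start/end invalid (need 1-based inclusive start <= end)")
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  key <- paste(out$sample_id, out$chrom)
  for (k in unique(key)) {
    s <- out[key == k, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)])) {
      i <- which(s$start[-1] <= s$end[-nrow(s)])[1]
      stop("overlapping segments for ", k, ": [", s$start[i], "-", s$end[i],
           "] and [", s$start[i + 1], "-", s$end[i + 1], "]")
    }
  }
  out
}

#' @rdname read_segments
#' @param segments Data.frame as returned by [read_segments()].
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = segments$start, end = segments$end,
                    absolute_cn = segments$absolute_cn)
  .write_tsv(out, path)
}

#' Read the per-sample tumor purity table
#'
#' Columns `sample`, `purity`. Purity must lie in (0, 1]; duplicated samples
#' are a hard error.
#'
#' @param path Path to the tab-separated purity file.
#' @return Data.frame with columns `sample_id`, `purity`.
#' @export
read_purity <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample", "purity"))
    if (!col %in% names(raw)) stop("purity file missing required column: ", col)
  if (anyDuplicated(raw$sample))
    stop("duplicate sample_id in purity table: ",
         raw$sample[duplicated(raw$sample)][1])
  p <- suppressWarnings(as.numeric(raw$purity))
  if (any(is.na(p) | p <= 0 | p > 1))
    stop("purity must be in (0, 1]; offending value: ",
         raw$purity[which(is.na(p) | p <= 0 | p > 1)[1]])
  data.frame(sample_id = as.character(raw$sample), purity = p,
             stringsAsFactors = FALSE)
}

#' @rdname read_purity
#' @param purities Data.frame as returned by [read_purity()].
#' @export
write_purity <- function(purities, path) {
  .write_tsv(data.frame(sample = purities$sample_id, purity = purities$purity),
             path)
}

.clinical_domains <- list(
  sex = c("female", "male"),
  msi_status = c("MSI", "MSS"),
  tumour_site = c("left-sided", "right-sided"),
  ajcc_stage = c("1", "2", "3", "4"),
  t_stage = c("T1", "T2", "T3", "T4"),
  n_stage = c("N0", "N1", "N2"),
  m_stage = c("M0", "M1"))

#' Read the per-patient clinical table
#'
#' Columns `sample`, `age`, `sex`, `msi_status`, `tumour_site`, `ajcc_stage`,
#' `t_stage`, `n_stage`, `m_stage`, `os_time`, `os_event`. Categorical values
#' outside their domain (and negative follow-up times) are recorded as missing;
#' the number of such coercions is attached as `attr(x, "n_invalid")`.
#' Duplicated samples are a hard error.
#'
#' @param path Path to the tab-separated clinical file.
#' @return Data.frame keyed by `sample_id`, with an `n_invalid` attribute.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample", "age", "sex", "msi_status", "tumour_site", "ajcc_stage",
            "t_stage", "n_stage", "m_stage", "os_time", "os_event")
  for (col in need)
    if (!col %in% names(raw)) stop("clinical file missing required column: ", col)
  if (anyDuplicated(raw$sample))
    stop("duplicate sample_id in clinical table: ",
         raw$sample[duplicated(raw$sample)][1])
  n_invalid <- 0L
  out <- data.frame(sample_id = as.character(raw$sample),
                    age = suppressWarnings(as.numeric(raw$age)),
                    stringsAsFactors = FALSE)
  for (col in names(.clinical_domains)) {
    v <- as.character(raw[[col]])
    bad <- !is.na(v) & v != "NA" & !(v %in% .clinical_domains[[col]])
    n_invalid <- n_invalid + sum(bad)
    v[bad | v == "NA"] <- NA_character_
    out[[col]] <- v
  }
  os_time <- suppressWarnings(as.numeric(raw$os_time))
  bad_t <- !is.na(os_time) & os_time < 0
  n_invalid <- n_invalid + sum(bad_t)
  os_time[bad_t] <- NA_real_
  os_event <- suppressWarnings(as.integer(raw$os_event))
  bad_e <- !is.na(os_event) & !(os_event %in% c(0L, 1L))
  n_invalid <- n_invalid + sum(bad_e)
  os_event[bad_e] <- NA_integer_
  out$os_time <- os_time
  out$os_event <- os_event
  if (n_invalid > 0L)
    warning(n_invalid, " clinical value(s) outside their domain set to NA")
  attr(out, "n_invalid") <- n_invalid
  out
}

#' @rdname read_clinical
#' @param clinical Data.frame as returned by [read_clinical()].
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  names(out)[names(out) == "sample_id"] <- "sample"
  .write_tsv(out, path)
}

#' Bundle the four cohort tables into one object
#'
#' Joins nothing and copies nothing; it simply validates that the four tables
#' are structurally consistent. Mutations whose sample has no purity record
#' are flagged (they will be excluded, with a reason, by
#' [annotate_mutations()]).
#'
#' @param mutations,segments,purities,clinical The four tables from the
#'   readers above (or from [simulate_cohort()]).
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(mutations, segments, purities, clinical) {
  stopifnot(is.data.frame(mutations), is.data.frame(segments),
            is.data.frame(purities), is.data.frame(clinical))
  unresolved <- setdiff(unique(mutations$sample_id), purities$sample_id)
  structure(list(mutations = mutations, segments = segments,
                 purities = purities, clinical = clinical,
                 unresolved_samples = unresolved),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Cohort bundle:", nrow(x$mutations), "mutations,",
      nrow(x$segments), "segments,", nrow(x$purities), "purity records,",
      nrow(x$clinical), "clinical records\n")
  if (length(x$unresolved_samples))
    cat("  samples without purity:", length(x$unresolved_samples), "\n")
  invisible(x)
}

#' Read a cohort from a directory of TSVs
#'
#' Expects the file names written by [write_cohort()]: `mutations.maf.tsv`,
#' `segments.seg.tsv`, `purity.tsv`, `clinical.tsv`.
#'
#' @param dir Directory containing the four tables.
#' @return A `cohort_bundle`.
#' @export
read_cohort <- function(dir) {
  cohort_bundle(read_maf(file.path(dir, "mutations.maf.tsv")),
                read_segments(file.path(dir, "segments.seg.tsv")),
                read_purity(file.path(dir, "purity.tsv")),
                read_clinical(file.path(dir, "clinical.tsv")))
}

# deterministic TSV writer: numerics at 6 significant digits, NA as "NA"
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.6g", signif(v, 6))
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
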