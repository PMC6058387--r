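#' @title Tabular input/output for methylation artifacts
#' @description Readers and writers for beta-value matrices, sample sheets,
#'   probe annotation and ranked result tables. All files are UTF-8 text with
#'   the delimiter auto-detected from tab or comma on read; written output is
#'   always tab-separated. Missing beta values are encoded as empty cells.
#' @name io
NULL

.CELL_FRACTIONS <- c("neuron", "glia", "bulk")
.SEXES          <- c("female", "male")
.DIAGNOSES      <- c("control", "AD")
.REGIONS        <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR",
                     "intergenic")
.CHROMOSOMES    <- c(as.character(1:22), "X", "Y")

# Roman numerals 0/I..VI accepted alongside Arabic 0-6; canonical form integer.
.BRAAK_MAP <- c("0" = 0L, "I" = 1L, "II" = 2L, "III" = 3L, "IV" = 4L,
                "V" = 5L, "VI" = 6L, "1" = 1L, "2" = 2L, "3" = 3L,
                "4" = 4L, "5" = 5L, "6" = 6L)

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort_parse(sprintf("empty file: %s", path))
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

parse_braak <- function(x) {
  tok <- toupper(trimws(as.character(x)))
  out <- .BRAAK_MAP[tok]
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    abort_format(sprintf(
      "invalid Braak stage token(s): %s (accepted: 0-6 or 0, I..VI)",
      paste(bad, collapse = ", ")))
  }
  unname(out)
}

#' Read a beta-value matrix
#'
#' Reads a probes x samples table of methylation beta values. The first
#' column holds probe identifiers, the header holds sample identifiers.
#' Values must lie in \[0, 1\]; empty cells become `NA`.
#'
#' @param path Path to a TSV or CSV file (delimiter auto-detected).
#' @return A numeric matrix with probe IDs as rownames and sample IDs as
#'   colnames.
#' @export
read_beta_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort_parse("beta matrix needs a probe column and >= 1 sample column")
  probes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(probes)) abort_format("duplicate probe ids in beta matrix")
  if (anyDuplicated(samples)) abort_format("duplicate sample ids in beta matrix")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_parse(sprintf("non-numeric beta value '%s' at probe %s, sample %s",
                        vals[bad[1L, 1L], bad[1L, 2L]],
                        probes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  }
  dimnames(num) <- list(probes, samples)
  validate_beta_matrix(num)
  num
}

#' Write a beta-value matrix
#'
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @param path Output path; written tab-separated with full precision.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  fmt <- format(beta, digits = 17, trim = TRUE, scientific = TRUE)
  fmt[is.na(beta)] <- ""  # empty cell, not a sentinel
  df <- data.frame(probe_id = rownames(beta), fmt, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate a beta-value matrix
#'
#' Checks the container contract: numeric matrix, unique probe/sample ids,
#' all non-missing values within \[0, 1\].
#'
#' @param beta Candidate matrix.
#' @return The matrix, invisibly, on success.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta))
    abort_format("beta matrix must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    abort_format("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta))) abort_format("duplicate probe ids")
  if (anyDuplicated(colnames(beta))) abort_format("duplicate sample ids")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    abort_format(sprintf("beta values outside [0,1]: range %.4g..%.4g",
                         rng[1L], rng[2L]))
  invisible(beta)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `cohort`, `cell_fraction`, `age`, `sex`,
#' `braak`, `diagnosis`, `batch`; optional `true_neuron_prop` (synthetic
#' ground truth, bulk samples only). Categorical fields are normalized to
#' canonical tokens; Braak stages may be Arabic 0-6 or Roman 0, I..VI.
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated `data.frame`, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  required <- c("sample_id", "cohort", "cell_fraction", "age", "sex",
                "braak", "diagnosis", "batch")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L)
    abort_format(sprintf("sample sheet missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  sheet <- data.frame(
    sample_id     = as.character(df$sample_id),
    cohort        = as.character(df$cohort),
    cell_fraction = tolower(trimws(as.character(df$cell_fraction))),
    age           = as.numeric(df$age),
    sex           = tolower(trimws(as.character(df$sex))),
    braak         = parse_braak(df$braak),
    diagnosis     = as.character(df$diagnosis),
    batch         = as.character(df$batch),
    stringsAsFactors = FALSE
  )
  dx <- tolower(trimws(sheet$diagnosis))
  sheet$diagnosis <- ifelse(dx == "ad", "AD", dx)
  if ("true_neuron_prop" %in% colnames(df))
    sheet$true_neuron_prop <- as.numeric(df$true_neuron_prop)
  validate_sample_sheet(sheet)
  sheet
}

#' Write a sample sheet
#' @param sheet A validated sample sheet.
#' @param path Output path (tab-separated).
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a sample sheet
#'
#' Enforces unique sample ids, canonical categorical tokens, Braak in 0-6,
#' non-negative age, and that `true_neuron_prop` (if present) is only set for
#' bulk samples and lies in \[0, 1\].
#'
#' @param sheet Candidate sample sheet `data.frame`.
#' @return The sheet, invisibly, on success.
#' @export
validate_sample_sheet <- function(sheet) {
  if (!is.data.frame(sheet)) abort_format("sample sheet must be a data.frame")
  if (anyDuplicated(sheet$sample_id)) abort_format("duplicate sample ids")
  bad_cf <- setdiff(unique(sheet$cell_fraction), .CELL_FRACTIONS)
  if (length(bad_cf) > 0L)
    abort_format(sprintf("unknown cell_fraction token(s): %s (accepted: %s)",
                         paste(bad_cf, collapse = ", "),
                         paste(.CELL_FRACTIONS, collapse = ", ")))
  bad_sex <- setdiff(unique(sheet$sex), .SEXES)
  if (length(bad_sex) > 0L)
    abort_format(sprintf("unknown sex token(s): %s (accepted: %s)",
                         paste(bad_sex, collapse = ", "),
                         paste(.SEXES, collapse = ", ")))
  bad_dx <- setdiff(unique(sheet$diagnosis), .DIAGNOSES)
  if (length(bad_dx) > 0L)
    abort_format(sprintf("unknown diagnosis token(s): %s (accepted: %s)",
                         paste(bad_dx, collapse = ", "),
                         paste(.DIAGNOSES, collapse = ", ")))
  if (any(is.na(sheet$age)) || any(sheet$age < 0))
    abort_format("age must be non-negative and non-missing")
  if (any(!sheet$braak %in% 0:6)) abort_format("braak must be in 0..6")
  if ("true_neuron_prop" %in% colnames(sheet)) {
    set <- !is.na(sheet$true_neuron_prop)
    if (any(set & sheet$cell_fraction != "bulk"))
      abort_format("true_neuron_prop may only be set for bulk samples")
    if (any(sheet$true_neuron_prop[set] < 0 | sheet$true_neuron_prop[set] > 1))
      abort_format("true_neuron_prop must be in [0,1]")
  }
  invisible(sheet)
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, `chromosome`, `position` (1-based), optional `gene`
#' and `region`. An empty/missing region is classified `intergenic`; the
#' `autosomal` flag is derived from the chromosome label.
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated annotation `data.frame`.
#' @export
read_probe_annotation <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("NA", ""))
  required <- c("probe_id", "chromosome", "position")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L)
    abort_format(sprintf("probe annotation missing column(s): %s",
                         paste(missing, collapse = ", ")))
  ann <- data.frame(
    probe_id   = as.character(df$probe_id),
    chromosome = toupper(trimws(as.character(df$chromosome))),
    position   = as.integer(df$position),
    gene       = if ("gene" %in% colnames(df)) as.character(df$gene) else NA_character_,
    region     = if ("region" %in% colnames(df)) as.character(df$region) else NA_character_,
    stringsAsFactors = FALSE
  )
  ann$region[is.na(ann$region) | ann$region == ""] <- "intergenic"
  ann$autosomal <- ann$chromosome %in% as.character(1:22)
  validate_probe_annotation(ann)
  ann
}

#' Write a probe annotation table
#' @param annotation A validated annotation `data.frame`.
#' @param path Output path (tab-separated).
#' @export
write_probe_annotation <- function(annotation, path) {
  validate_probe_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a probe annotation table
#' @param ann Candidate annotation `data.frame`.
#' @return The annotation, invisibly, on success.
#' @export
validate_probe_annotation <- function(ann) {
  if (!is.data.frame(ann)) abort_format("annotation must be a data.frame")
  if (anyDuplicated(ann$probe_id)) abort_format("duplicate probe ids in annotation")
  bad_chr <- setdiff(unique(ann$chromosome), .CHROMOSOMES)
  if (length(bad_chr) > 0L)
    abort_format(sprintf("unknown chromosome label(s): %s",
                         paste(bad_chr, collapse = ", ")))
  if (any(is.na(ann$position)) || any(ann$position <= 0L))
    abort_format("position must be a positive 1-based integer")
  bad_rg <- setdiff(unique(ann$region), .REGIONS)
  if (length(bad_rg) > 0L)
    abort_format(sprintf("unknown region class(es): %s",
                         paste(bad_rg, collapse = ", ")))
  if (!identical(ann$autosomal, ann$chromosome %in% as.character(1:22)))
    abort_format("autosomal flag inconsistent with chromosome")
  invisible(ann)
}

#' Write a ranked result table
#'
#' Serializes a differential-methylation or meta-analysis result table
#' (must carry a `rank` column) to a tab-separated file. P-value-like columns
#' are written in scientific notation with four significant digits; when
#' annotation is supplied, locus columns (chromosome, position, gene, region)
#' are merged in, mirroring the conventional layout
#' rank / p / probe / locus / FDR.
#'
#' @param results Ranked result `data.frame` (from [run_ewas()],
#'   [celltype_ttest()] or [combine_cell_types()]).
#' @param path Output path.
#' @param annotation Optional probe annotation to merge locus columns from.
#' @export
write_results_table <- function(results, path, annotation = NULL) {
  if (!is.data.frame(results) || !"probe_id" %in% colnames(results))
    abort_contract("results must be a data.frame with a probe_id column")
  if (!"rank" %in% colnames(results))
    abort_contract("results are unranked: a rank column is required")
  out <- results[order(results$rank), , drop = FALSE]
  if (!is.null(annotation)) {
    keep <- c("probe_id", "chromosome", "position", "gene", "region")
    out <- merge(out, annotation[, keep], by = "probe_id", sort = FALSE)
    out <- out[order(out$rank), , drop = FALSE]
  }
  lead <- intersect(c("rank", "p_combined", "p_neuron", "p_glia", "p"),
                    colnames(out))
  rest <- setdiff(colnames(out), lead)
  out <- out[, c(lead, rest), drop = FALSE]
  sci <- intersect(c("p", "p_combined", "p_neuron", "p_glia", "bonferroni_p",
                     "fdr_q", "effect", "se", "chi_sq"), colnames(out))
  for (cn in sci) out[[cn]] <- formatC(out[[cn]], format = "E", digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#' @param path Path to the table.
#' @return A `data.frame` with numeric statistic columns.
#' @export
read_results_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "\"",
                          na.strings = c("NA", ""))
  num <- intersect(c("rank", "p", "p_combined", "p_neuron", "p_glia",
                     "bonferroni_p", "fdr_q", "effect", "se", "chi_sq",
                     "statistic", "df", "position"), colnames(df))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  df
}
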