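QUANT_COLS <- c("athlete_id", "arm", "occasion", "batch_id",
                "injection_order", "is_qc", "protein_id", "intensity")

#' Read or write a long-format quantitation table
#'
#' The interchange format is a delimited text file (TSV by default; comma
#' delimiters are detected automatically) with one row per measured feature
#' per injection and required columns `athlete_id`, `arm`, `occasion`,
#' `batch_id`, `injection_order`, `is_qc`, `protein_id`, `intensity`
#' (`peptide_id` optional, other columns preserved).  Validation rejects
#' missing columns, non-positive intensities, occasion or arm labels
#' outside the closed study vocabulary, and duplicate (sample, feature)
#' keys, naming the offenders.
#'
#' @param path file path.
#' @return `read_quant_table()` returns the validated data frame;
#'   `write_quant_table()` returns `path` invisibly.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = c("NA", ""))
  ## an all-NA peptide_id column reads back as logical
  if ("peptide_id" %in% names(tbl) && is.logical(tbl$peptide_id))
    tbl$peptide_id <- as.character(tbl$peptide_id)
  validate_quant_table(tbl)
}

#' @rdname read_quant_table
#' @param quant a quantitation table.
#' @export
write_quant_table <- function(quant, path) {
  validate_quant_table(quant)
  utils::write.table(quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_quant_table
#' @param check_positive require strictly positive intensities (raw scale);
#'   disabled internally for log-scale tables.
#' @export
validate_quant_table <- function(quant, check_positive = TRUE) {
  missing_cols <- setdiff(QUANT_COLS, names(quant))
  if (length(missing_cols))
    stop("quantitation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"peptide_id" %in% names(quant)) quant$peptide_id <- NA_character_
  quant$is_qc <- as.integer(quant$is_qc)
  bad_int <- !is.finite(quant$intensity) |
    (check_positive & quant$intensity <= 0)
  if (any(bad_int))
    stop("non-positive or non-finite intensity at row(s): ",
         paste(utils::head(which(bad_int), 5), collapse = ", "),
         call. = FALSE)
  study <- quant$is_qc == 0L
  bad_occ <- study & !quant$occasion %in% OCCASIONS
  if (any(bad_occ))
    stop("unknown occasion label(s): ",
         paste(unique(quant$occasion[bad_occ]), collapse = ", "),
         call. = FALSE)
  bad_arm <- study & !quant$arm %in% ARMS
  if (any(bad_arm))
    stop("unknown arm label(s): ",
         paste(unique(quant$arm[bad_arm]), collapse = ", "), call. = FALSE)
  feat <- ifelse(is.na(quant$peptide_id), quant$protein_id, quant$peptide_id)
  key <- ifelse(study,
                paste(quant$athlete_id, quant$arm, quant$occasion, feat),
                paste("QC", quant$batch_id, quant$injection_order, feat))
  if (anyDuplicated(key))
    stop("duplicate (sample, feature) key(s), e.g.: ",
         paste(utils::head(unique(key[duplicated(key)]), 3),
               collapse = "; "), call. = FALSE)
  quant
}

sample_key <- function(quant) {
  ifelse(quant$is_qc == 1L,
         paste0(quant$batch_id, "_QC", quant$injection_order),
         paste(quant$athlete_id, quant$arm, quant$occasion, sep = "_"))
}

#' Assemble a protein-by-sample matrix from a quantitation table
#'
#' Pivots a protein-level quantitation table (run [rollup_top3()] first if
#' `peptide_id` is populated) into a `protein_matrix`: proteins in rows,
#' samples (study + QC injections) in columns, values on the natural-log
#' scale, with the sample metadata carried alongside.
#'
#' @param quant a protein-level quantitation table; the `intensity` column
#'   holds raw intensities, or log-intensities already if
#'   `log_intensity = TRUE` (the convention of [rollup_top3()] output).
#' @param log_intensity whether `intensity` is already on the log scale.
#' @return An object of class `protein_matrix`: list with `values` (numeric
#'   matrix, log scale unless later normalized), `scale` (`"log"` or
#'   `"normalized"`), `samples` (metadata data frame, one row per column)
#'   and `technical_cv` (filled by [compute_technical_cv()]).
#' @export
quant_to_matrix <- function(quant, log_intensity = FALSE) {
  if ("log_intensity" %in% names(quant) && !"intensity" %in% names(quant)) {
    quant$intensity <- quant$log_intensity
    quant$log_intensity <- NULL
    log_intensity <- TRUE
  }
  quant <- validate_quant_table(quant, check_positive = !log_intensity)
  if (any(!is.na(quant$peptide_id)))
    stop("table has peptide-level rows; run rollup_top3() first",
         call. = FALSE)
  sk <- sample_key(quant)
  samples <- unique(data.frame(sample_id = sk,
                               athlete_id = quant$athlete_id,
                               arm = quant$arm, occasion = quant$occasion,
                               batch_id = quant$batch_id,
                               injection_order = quant$injection_order,
                               is_qc = quant$is_qc,
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$is_qc, samples$batch_id,
                           samples$sample_id), ]
  rownames(samples) <- NULL
  prot <- sort(unique(quant$protein_id))
  vals <- matrix(NA_real_, length(prot), nrow(samples),
                 dimnames = list(prot, samples$sample_id))
  vals[cbind(match(quant$protein_id, prot),
             match(sk, samples$sample_id))] <-
    if (log_intensity) quant$intensity else log(quant$intensity)
  structure(list(values = vals, scale = "log", samples = samples,
                 technical_cv = NULL),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat("Protein matrix:", nrow(x$values), "proteins x", ncol(x$values),
      "samples (", sum(x$samples$is_qc == 1L), "QC ), scale =", x$scale,
      "\n")
  if (!is.null(x$technical_cv))
    cat("  technical CV: median",
        signif(stats::median(x$technical_cv, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Write a protein matrix and its technical CVs to TSV
#'
#' @param pm a `protein_matrix`.
#' @param matrix_path,cv_path output paths (`cv_path` optional).
#' @return `matrix_path`, invisibly.
#' @export
write_protein_matrix <- function(pm, matrix_path, cv_path = NULL) {
  stopifnot(inherits(pm, "protein_matrix"))
  out <- data.frame(protein_id = rownames(pm$values),
                    format(as.data.frame(pm$values), digits = 12,
                           trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cv_path) && !is.null(pm$technical_cv))
    utils::write.table(
      data.frame(protein_id = names(pm$technical_cv),
                 technical_cv = unname(pm$technical_cv)),
      cv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}
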