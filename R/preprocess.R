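#' Top-3 peptide-to-protein rollup
#'
#' For every protein the three most abundant peptides (all of them when
#' fewer than three were identified) are used for quantitation.  Peptides
#' are ranked once per protein by their mean intensity across all study
#' samples, so the contributing peptide set is fixed across samples; ties
#' are broken lexicographically by `peptide_id`.  The protein quantity in
#' each sample is the mean of the selected peptides' log-intensities
#' (equivalently, the log of their geometric mean).
#'
#' @param quant a peptide-level quantitation table (`peptide_id`
#'   populated, intensities > 0).
#' @param k maximum number of peptides per protein (default 3).
#' @return A protein-level table with the same metadata columns and a
#'   `log_intensity` quantity column (natural-log scale).  Proteins with
#'   zero peptide records are excluded with a warning.
#' @examples
#' d <- make_design(2, seed = 1)
#' a <- make_archetypes(0, 0, 2, seed = 1)
#' q <- explode_peptides(generate_dataset(d, a, seed = 1)$quant, 5)
#' head(rollup_top3(q))
#' @export
rollup_top3 <- function(quant, k = 3L) {
  quant <- validate_quant_table(quant)
  if (all(is.na(quant$peptide_id)))
    stop("peptide_id is empty; table is already protein level",
         call. = FALSE)
  orphan <- is.na(quant$peptide_id)
  if (any(orphan)) {
    warning("excluding ", sum(orphan),
            " record(s) with missing peptide_id")
    quant <- quant[!orphan, ]
  }

  ## rank peptides by mean intensity over study samples only
  study <- quant[quant$is_qc == 0L, ]
  pep_mean <- tapply(study$intensity, study$peptide_id, mean)
  pep_prot <- tapply(quant$protein_id, quant$peptide_id,
                     function(p) p[[1]])
  peps <- names(pep_mean)
  ord <- order(pep_prot[peps], -pep_mean[peps], peps)
  ranked <- peps[ord]
  keep <- unlist(lapply(split(ranked, pep_prot[ranked]),
                        utils::head, n = k), use.names = FALSE)

  sel <- quant[quant$peptide_id %in% keep, ]
  key <- paste(sample_key(sel), sel$protein_id, sep = "\r")
  agg <- tapply(log(sel$intensity), key, mean)
  first <- sel[!duplicated(key), c("athlete_id", "arm", "occasion",
                                   "batch_id", "injection_order", "is_qc",
                                   "protein_id")]
  first$log_intensity <- as.numeric(agg[paste(sample_key(first),
                                              first$protein_id,
                                              sep = "\r")])
  first$peptide_id <- NA_character_
  rownames(first) <- NULL
  first
}

#' Empirical-Bayes batch-effect correction
#'
#' Location-scale batch adjustment on the log scale, in the ComBat style:
#' each protein is standardized against its across-batch grand mean and
#' pooled variance, per-batch location and scale parameters are estimated
#' and shrunk toward their across-protein moments by parametric empirical
#' Bayes (normal prior on locations, inverse-gamma on scale factors), and
#' every record in a batch -- study and QC alike -- is adjusted with the
#' shrunken parameters.  With a single batch there is nothing to correct
#' and the matrix is returned unchanged with a message.
#'
#' @param pm a `protein_matrix` on the log scale.
#' @param eb use empirical-Bayes shrinkage (default) or the raw per-batch
#'   estimates.
#' @return The corrected `protein_matrix` (same dimensions and metadata).
#' @export
correct_batch_effects <- function(pm, eb = TRUE) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (pm$scale != "log")
    stop("batch correction expects a log-scale matrix", call. = FALSE)
  batch <- pm$samples$batch_id
  batches <- unique(batch)
  if (length(batches) < 2L) {
    message("single batch; batch correction is a no-op")
    return(pm)
  }
  counts <- table(batch)
  if (any(counts < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)

  X <- pm$values

  ## standardize each protein against the batch-design fit: weighted grand
  ## mean of per-batch means, pooled variance of within-batch residuals
  batch_means <- sapply(batches, function(b)
    rowMeans(X[, batch == b, drop = FALSE], na.rm = TRUE))
  w <- as.numeric(counts[batches]) / sum(counts)
  stand_mean <- drop(batch_means %*% w)
  resid <- X - batch_means[, match(batch, batches), drop = FALSE]
  pooled_var <- rowSums(resid^2, na.rm = TRUE) /
    pmax(rowSums(!is.na(X)) - 1, 1)
  pooled_sd <- sqrt(pmax(pooled_var, .Machine$double.eps))
  Z <- (X - stand_mean) / pooled_sd

  adj <- X
  gamma_hat <- sapply(batches, function(b)
    rowMeans(Z[, batch == b, drop = FALSE], na.rm = TRUE))
  delta_hat <- sapply(batches, function(b)
    apply(Z[, batch == b, drop = FALSE], 1, stats::var, na.rm = TRUE))
  delta_hat[!is.finite(delta_hat) | delta_hat <= 0] <- 1

  if (eb) {
    ## parametric EB: normal prior for gamma, inverse-gamma for delta,
    ## hyperparameters by method of moments across proteins
    for (j in seq_along(batches)) {
      g <- gamma_hat[, j]; d <- delta_hat[, j]
      nb <- sum(batch == batches[j])
      g_bar <- mean(g); t2 <- stats::var(g)
      if (!is.finite(t2) || t2 < 1e-12) {
        gamma_star <- rep(g_bar, length(g))
      } else {
        gamma_star <- (nb * t2 * g + d * g_bar) / (nb * t2 + d)
      }
      m <- mean(d); v <- stats::var(d)
      if (!is.finite(v) || v < 1e-12) {
        delta_star <- rep(m, length(d))
      } else {
        a_prior <- (2 * v + m^2) / v
        b_prior <- (m * v + m^3) / v
        delta_star <- (b_prior + 0.5 * (nb - 1) * d) /
          (a_prior + (nb - 1) / 2 - 1)
      }
      gamma_hat[, j] <- gamma_star
      delta_hat[, j] <- pmax(delta_star, 1e-8)
    }
  }
  for (j in seq_along(batches)) {
    cols <- batch == batches[j]
    adj[, cols] <- (Z[, cols, drop = FALSE] - gamma_hat[, j]) /
      sqrt(delta_hat[, j])
  }
  pm$values <- adj * pooled_sd + stand_mean
  pm
}

#' Row-max normalization
#'
#' Divides each protein's raw intensities by that protein's maximum across
#' all samples, so every row has maximum exactly 1 and values in (0, 1].
#' Operates on the raw intensity scale: a log-scale matrix is
#' back-transformed first.  Idempotent, and invariant to rescaling any row
#' by a positive constant.
#'
#' @param pm a `protein_matrix` (log or already-normalized scale).
#' @return The `protein_matrix` with `scale = "normalized"`.
#' @export
normalize_row_max <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  vals <- if (pm$scale == "log") exp(pm$values) else pm$values
  rmax <- apply(vals, 1, max, na.rm = TRUE)
  bad <- !is.finite(rmax) | rmax <= 0
  if (any(bad))
    stop("row(s) with non-positive maximum: ",
         paste(utils::head(rownames(vals)[bad], 5), collapse = ", "),
         call. = FALSE)
  pm$values <- vals / rmax
  pm$scale <- "normalized"
  pm
}

#' Technical CV from pooled-QC injections
#'
#' The technical coefficient of variation of each protein, computed from
#' the repeated injections of the pooled QC sample across all batches.
#' The primary mode (`"raw"`) is the plain CV of the QC raw intensities,
#' `sd/mean` (sample sd, n-1 denominator), on the pre-normalization
#' intensity scale, computed within each batch and pooled across batches
#' as the root mean square of the per-batch CVs.  Computing the CV
#' intra-batch isolates injection-to-injection (technical) dispersion:
#' because each athlete is one batch, any between-batch spread left in
#' the QC records after correction reflects the athlete/batch confound,
#' not instrument precision.  The alternative mode (`"zscore"`) z-scores
#' each protein across all samples (study + QC) first and reports
#' `sd(z_QC) / |mean(z_QC)|` over all QC records; it is exposed for
#' sensitivity analysis but is unstable when the QC mean z-score is near
#' zero.
#'
#' @param pm a `protein_matrix` on the log scale (i.e. before
#'   normalization; typically after batch correction).
#' @param mode `"raw"` (default) or `"zscore"`.
#' @return The `protein_matrix` with `technical_cv` filled: a named vector
#'   with one CV per protein, `NA` where fewer than 2 QC observations
#'   exist (such proteins are gated at the strict significance level
#'   downstream).
#' @export
compute_technical_cv <- function(pm, mode = c("raw", "zscore")) {
  stopifnot(inherits(pm, "protein_matrix"))
  mode <- match.arg(mode)
  qc <- pm$samples$is_qc == 1L
  if (!any(qc))
    stop("no QC samples in matrix; cannot compute technical CV",
         call. = FALSE)
  vals <- if (pm$scale == "log") exp(pm$values) else pm$values
  qc_batch <- pm$samples$batch_id[qc]
  cv <- apply(vals, 1, function(v) {
    q <- v[qc]
    fin <- is.finite(q)
    if (sum(fin) < 2L) return(NA_real_)
    if (mode == "raw") {
      per_batch <- vapply(split(q[fin], qc_batch[fin]), function(x)
        if (length(x) >= 2L) stats::sd(x) / mean(x) else NA_real_,
        numeric(1))
      per_batch <- per_batch[is.finite(per_batch)]
      if (!length(per_batch)) return(NA_real_)
      sqrt(mean(per_batch^2))
    } else {
      z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
      zq <- z[qc]
      stats::sd(zq) / abs(mean(zq))
    }
  })
  if (any(is.na(cv)))
    message(sum(is.na(cv)),
            " protein(s) with < 2 QC observations; CV undefined",
            " (strict alpha will apply)")
  pm$technical_cv <- cv
  pm
}

#' One-call preprocessing
#'
#' Fixed pipeline order: top-3 rollup (when the table is peptide level),
#' batch correction on the log scale, technical-CV computation from the
#' corrected intensities, then row-max normalization.
#'
#' @param quant a quantitation table (peptide or protein level).
#' @param batch_correction apply [correct_batch_effects()] (default TRUE).
#' @param cv_mode passed to [compute_technical_cv()].
#' @return A normalized `protein_matrix` with `technical_cv` filled.
#' @export
preprocess_quant <- function(quant, batch_correction = TRUE,
                             cv_mode = c("raw", "zscore")) {
  cv_mode <- match.arg(cv_mode)
  if (any(!is.na(quant$peptide_id))) quant <- rollup_top3(quant)
  pm <- quant_to_matrix(quant)
  if (batch_correction && length(unique(pm$samples$batch_id)) > 1L)
    pm <- correct_batch_effects(pm)
  pm <- compute_technical_cv(pm, mode = cv_mode)
  normalize_row_max(pm)
}
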