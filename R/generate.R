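#' Noise model for the synthetic quantitation table
#'
#' Intensities are generated lognormal: all components below act additively
#' on the natural-log scale, so the emitted raw intensities are strictly
#' positive and right-skewed, as label-free MS intensities are.  The
#' technical standard deviation is calibrated from the target technical CV
#' through the lognormal relation `cv = sqrt(exp(sd^2) - 1)`.
#'
#' @param baseline_log_mean,baseline_log_sd mean and spread (log scale) of
#'   per-protein baseline abundances across the proteome.
#' @param athlete_sd between-athlete random-effect sd (log scale).
#' @param batch_location_sd sd of the additive per-batch location shift
#'   (log scale); one batch per athlete.
#' @param batch_scale_sd sd (log scale) of the per-batch multiplier on the
#'   technical noise sd, giving batches with mildly different precision.
#' @param technical_cv_target target coefficient of variation of technical
#'   (pooled-QC) replicates on the raw intensity scale.
#' @param missing_rate fraction of study records dropped completely at
#'   random (default 0; QC records are never dropped).
#' @return An object of class `noise_model` (a validated list; element
#'   `technical_sd` holds the calibrated log-scale sd).
#' @examples
#' noise_model(technical_cv_target = 0.10)$technical_sd
#' @export
noise_model <- function(baseline_log_mean = 14,
                        baseline_log_sd = 1,
                        athlete_sd = 0.3,
                        batch_location_sd = 0.2,
                        batch_scale_sd = 0.05,
                        technical_cv_target = 0.10,
                        missing_rate = 0) {
  sds <- c(baseline_log_sd = baseline_log_sd, athlete_sd = athlete_sd,
           batch_location_sd = batch_location_sd,
           batch_scale_sd = batch_scale_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("noise sd parameters must be finite and >= 0", call. = FALSE)
  if (!is.finite(technical_cv_target) || technical_cv_target < 0)
    stop("technical_cv_target must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 athlete_sd = athlete_sd,
                 batch_location_sd = batch_location_sd,
                 batch_scale_sd = batch_scale_sd,
                 technical_cv_target = technical_cv_target,
                 technical_sd = sqrt(log(1 + technical_cv_target^2)),
                 missing_rate = missing_rate),
            class = "noise_model")
}

#' Generate a synthetic quantitation table with ground truth
#'
#' Emits one intensity per (athlete, arm, occasion, protein) study record
#' plus 4 pooled-QC records per batch per protein, under the design of
#' [make_design()] and the planted archetypes of [make_archetypes()].  The
#' pooled-QC sample is the same per-protein grand-mean material in every
#' batch; its injections differ only by technical noise (and carry the
#' batch's location/scale effect, as any injection in that batch does).
#' Planted effects are multiplicative fold-changes applied at the
#' archetype's affected occasions, exercise arm only, in a per-(protein,
#' athlete) Bernoulli `responder_prevalence` subset of athletes.
#'
#' @param design a `study_design` from [make_design()].
#' @param archetypes a `protein_archetypes` data frame.
#' @param noise a `noise_model`.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return A list with elements `quant` (the long-format quantitation data
#'   frame with columns `athlete_id`, `arm`, `occasion`, `batch_id`,
#'   `injection_order`, `is_qc`, `protein_id`, `peptide_id`, `intensity`)
#'   and `truth` (the ground-truth ledger: one row per protein with its
#'   class, effect size, affected occasions, and the comma-separated
#'   responder athletes).
#' @examples
#' d <- make_design(4, seed = 1)
#' a <- make_archetypes(1, 1, 2, seed = 1)
#' g <- generate_dataset(d, a, noise_model(), seed = 1)
#' head(g$quant)
#' @export
generate_dataset <- function(design, archetypes, noise = noise_model(),
                             seed = 1L) {
  validate_design(design)
  stopifnot(inherits(archetypes, "protein_archetypes"),
            inherits(noise, "noise_model"))
  set.seed(as.integer(seed))

  athletes <- design$athletes
  batches <- unique(design$batch_of)
  n_ath <- length(athletes)
  n_prot <- nrow(archetypes)
  prot <- archetypes$protein_id

  ## protein-level baselines, athlete effects, batch effects (log scale)
  baseline <- stats::rnorm(n_prot, noise$baseline_log_mean,
                           noise$baseline_log_sd)
  names(baseline) <- prot
  ath_eff <- matrix(stats::rnorm(n_prot * n_ath, 0, noise$athlete_sd),
                    n_prot, n_ath, dimnames = list(prot, athletes))
  batch_loc <- matrix(stats::rnorm(n_prot * n_ath, 0,
                                   noise$batch_location_sd),
                      n_prot, n_ath, dimnames = list(prot, batches))
  batch_scale <- exp(stats::rnorm(n_ath, 0, noise$batch_scale_sd))
  names(batch_scale) <- batches

  ## responder draw: per protein, per athlete
  responder <- matrix(stats::rbinom(n_prot * n_ath, 1L,
                                    rep(archetypes$responder_prevalence,
                                        n_ath)) == 1L,
                      n_prot, n_ath, dimnames = list(prot, athletes))
  responder[archetypes$klass == "null", ] <- FALSE

  sched <- design$schedule
  n_rec <- nrow(sched)

  ## study records: replicate the schedule per protein
  study <- sched[rep(seq_len(n_rec), times = n_prot), ]
  study$protein_id <- rep(prot, each = n_rec)
  study$is_qc <- 0L

  pi <- match(study$protein_id, prot)
  ai <- match(study$athlete_id, athletes)
  bi <- match(study$batch_id, batches)
  mu <- baseline[pi] + ath_eff[cbind(pi, ai)] + batch_loc[cbind(pi, bi)]

  aff_lookup <- matrix(FALSE, n_prot, length(OCCASIONS),
                       dimnames = list(prot, OCCASIONS))
  for (i in seq_len(n_prot))
    aff_lookup[i, archetypes$affected_occasions[[i]]] <- TRUE
  hit <- study$arm == "exercise" &
    aff_lookup[cbind(pi, match(study$occasion, OCCASIONS))] &
    responder[cbind(pi, ai)]
  mu <- mu + ifelse(hit, log(archetypes$effect_size[pi]), 0)

  tech <- stats::rnorm(nrow(study), 0, noise$technical_sd) *
    batch_scale[study$batch_id]
  study$intensity <- exp(mu + tech)

  ## QC records: 4 injections per batch per protein; pooled material is the
  ## protein grand mean, shifted by the batch location effect
  qc <- expand.grid(injection_order = design$qc_slots,
                    batch_id = batches, protein_id = prot,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qpi <- match(qc$protein_id, prot)
  qbi <- match(qc$batch_id, batches)
  qc_mu <- baseline[qpi] + batch_loc[cbind(qpi, qbi)]
  qc_tech <- stats::rnorm(nrow(qc), 0, noise$technical_sd) *
    batch_scale[qc$batch_id]
  qc$intensity <- exp(qc_mu + qc_tech)
  qc$athlete_id <- NA_character_
  qc$arm <- NA_character_
  qc$occasion <- NA_character_
  qc$is_qc <- 1L

  cols <- c("athlete_id", "arm", "occasion", "batch_id", "injection_order",
            "is_qc", "protein_id", "intensity")
  quant <- rbind(study[, cols], qc[, cols])
  if (noise$missing_rate > 0) {
    drop <- quant$is_qc == 0L &
      stats::runif(nrow(quant)) < noise$missing_rate
    quant <- quant[!drop, ]
  }
  quant$peptide_id <- NA_character_
  quant <- quant[order(quant$is_qc, quant$protein_id, quant$batch_id,
                       quant$injection_order),
                 c("athlete_id", "arm", "occasion", "batch_id",
                   "injection_order", "is_qc", "protein_id", "peptide_id",
                   "intensity")]
  rownames(quant) <- NULL

  truth <- data.frame(
    protein_id = prot,
    klass = archetypes$klass,
    effect_size = archetypes$effect_size,
    affected_occasions = vapply(archetypes$affected_occasions,
                                paste, "", collapse = ","),
    responders = vapply(seq_len(n_prot), function(i)
      paste(athletes[responder[i, ]], collapse = ","), ""),
    stringsAsFactors = FALSE)

  list(quant = quant, truth = truth)
}

#' Expand a protein-level table into peptides
#'
#' Utility for exercising the top-3 rollup: replaces each protein record by
#' `n_peptides` peptide records whose log-intensities are the protein's
#' log-intensity plus a fixed per-peptide ionization offset (so peptide
#' abundance ranks are stable across samples) plus independent noise.
#'
#' @param quant a protein-level quantitation table.
#' @param n_peptides peptides per protein.
#' @param peptide_log_sd sd of the fixed per-peptide offsets (log scale).
#' @param peptide_noise_sd sd of independent per-record peptide noise.
#' @param seed integer seed.
#' @return A peptide-level quantitation table (`peptide_id` populated).
#' @export
explode_peptides <- function(quant, n_peptides = 5, peptide_log_sd = 1,
                             peptide_noise_sd = 0.05, seed = 1L) {
  stopifnot(n_peptides >= 1)
  set.seed(as.integer(seed))
  prot <- unique(quant$protein_id)
  offs <- matrix(stats::rnorm(length(prot) * n_peptides, 0, peptide_log_sd),
                 length(prot), n_peptides, dimnames = list(prot, NULL))
  idx <- rep(seq_len(nrow(quant)), each = n_peptides)
  out <- quant[idx, ]
  k <- rep(seq_len(n_peptides), times = nrow(quant))
  out$peptide_id <- sprintf("%s_pep%02d", out$protein_id, k)
  out$intensity <- exp(log(out$intensity) +
                       offs[cbind(match(out$protein_id, prot), k)] +
                       stats::rnorm(nrow(out), 0, peptide_noise_sd))
  rownames(out) <- NULL
  out
}
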