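#' Build the crossover study design
#'
#' Constructs the sampling and measurement schedule of the two-arm
#' randomized crossover study: each athlete completes both an exercise arm
#' and a rest arm, each arm sampled at 8 occasions (pre and post on days
#' 1-3, plus two recovery mornings `R1`/`R2`), giving 16 study samples per
#' athlete.  Each athlete's 16 samples form one mass-spectrometry batch in
#' which the study samples are injected in randomized order, framed and
#' interleaved by 4 pooled-QC injections (before the batch, after it, and
#' twice during it).
#'
#' @param n_athletes number of athletes (>= 1).
#' @param seed integer seed; the arm-order randomization and the
#'   within-batch injection order are reproducible given the seed.
#' @return An object of class `study_design`: a list with elements
#'   `n_athletes`, `athletes`, `arms`, `occasions`, `arm_order` (named
#'   character, `"exercise_first"` or `"rest_first"`, counterbalanced),
#'   `batch_of` (named character, athlete -> batch), `qc_slots` (injection
#'   positions of the 4 QC samples within the 20-injection batch), and
#'   `schedule` (data frame of study records with columns `athlete_id`,
#'   `arm`, `occasion`, `batch_id`, `injection_order`).
#' @examples
#' d <- make_design(10, seed = 1)
#' nrow(d$schedule)  # 160 study records
#' @export
make_design <- function(n_athletes, seed = 1L) {
  if (!is.numeric(n_athletes) || length(n_athletes) != 1L ||
      is.na(n_athletes) || n_athletes < 1 || n_athletes != round(n_athletes))
    stop("invalid design: n_athletes must be a single integer >= 1",
         call. = FALSE)
  n_athletes <- as.integer(n_athletes)
  set.seed(as.integer(seed))

  athletes <- sprintf("A%02d", seq_len(n_athletes))
  batches <- sprintf("B%02d", seq_len(n_athletes))
  names(batches) <- athletes

  ## counterbalanced arm order: half exercise-first (the extra athlete, if
  ## n is odd, is assigned at random)
  n_ex_first <- floor(n_athletes / 2) +
    (n_athletes %% 2 == 1) * stats::rbinom(1L, 1L, 0.5)
  order_pool <- sample(athletes)
  arm_order <- stats::setNames(
    ifelse(athletes %in% order_pool[seq_len(n_ex_first)],
           "exercise_first", "rest_first"),
    athletes)

  ## 20 injections per batch: QC before (1), two interior, QC after (20)
  qc_slots <- c(1L, 7L, 14L, 20L)
  study_slots <- setdiff(seq_len(20L), qc_slots)

  grid <- expand.grid(occasion = OCCASIONS, arm = ARMS,
                      athlete_id = athletes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("athlete_id", "arm", "occasion")]
  inj <- unlist(lapply(athletes, function(a) sample(study_slots)),
                use.names = FALSE)
  grid$batch_id <- batches[grid$athlete_id]
  grid$injection_order <- inj
  grid <- grid[order(grid$athlete_id, grid$injection_order), ]
  rownames(grid) <- NULL

  structure(list(n_athletes = n_athletes,
                 athletes = athletes,
                 arms = ARMS,
                 occasions = OCCASIONS,
                 arm_order = arm_order,
                 batch_of = batches,
                 qc_slots = qc_slots,
                 schedule = grid),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Crossover study design\n")
  cat("  athletes:       ", x$n_athletes, "\n")
  cat("  arms:           ", paste(x$arms, collapse = ", "), "\n")
  cat("  occasions/arm:  ", length(x$occasions), "\n")
  cat("  study samples:  ", nrow(x$schedule), "\n")
  cat("  QC injections:  ", length(x$qc_slots), "per batch x",
      length(unique(x$batch_of)), "batches\n")
  tab <- table(x$arm_order)
  cat("  arm order:      ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  with(design, {
    stopifnot(nrow(schedule) == n_athletes * 16L,
              length(qc_slots) == 4L,
              all(table(schedule$athlete_id) == 16L),
              abs(sum(arm_order == "exercise_first") -
                  sum(arm_order == "rest_first")) <= 1L)
  })
  invisible(design)
}

#' Define planted protein response archetypes
#'
#' Each archetype describes how one simulated protein responds to the
#' exercise arm: `acute` proteins rise immediately post-exercise on each of
#' the three exercise days (`D1post`, `D2post`, `D3post`), `chronic`
#' proteins rise only on the recovery mornings (by default both `R1` and
#' `R2`), and `null` proteins do not respond at all.  The effect is a
#' multiplicative fold-change on the raw intensity scale and is present in
#' a `responder_prevalence` fraction of athletes (drawn per protein and per
#' athlete when the dataset is generated).
#'
#' @param n_acute,n_chronic,n_null archetype counts (>= 0).
#' @param effect_size fold-change (> 0) applied at affected occasions in
#'   the exercise arm; ignored (forced to 1) for null proteins.
#' @param responder_prevalence fraction of athletes carrying the effect;
#'   defaults to 0.8.
#' @param chronic_occasions which recovery occasions chronic proteins
#'   affect; a non-empty subset of `c("R1", "R2")`.
#' @param technical_cv_target intended coefficient of variation of
#'   technical (QC) replicates, recorded with each archetype.
#' @param seed integer seed (protein id assignment is deterministic; kept
#'   for interface symmetry with the other generators).
#' @return A data frame of class `protein_archetypes` with one row per
#'   protein: `protein_id`, `klass`, `effect_size`, `responder_prevalence`,
#'   `technical_cv_target`, and `affected_occasions` (list column).
#' @examples
#' make_archetypes(2, 3, 0, effect_size = 1.5, seed = 3)
#' @export
make_archetypes <- function(n_acute, n_chronic, n_null,
                            effect_size = 2,
                            responder_prevalence = 0.8,
                            chronic_occasions = c("R1", "R2"),
                            technical_cv_target = 0.10,
                            seed = 1L) {
  counts <- c(n_acute = n_acute, n_chronic = n_chronic, n_null = n_null)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("archetype counts must be non-negative integers", call. = FALSE)
  if (!is.finite(effect_size) || effect_size <= 0)
    stop("effect_size must be > 0", call. = FALSE)
  if (responder_prevalence <= 0 || responder_prevalence > 1)
    stop("responder_prevalence must be in (0, 1]", call. = FALSE)
  chronic_occasions <- match.arg(chronic_occasions, c("R1", "R2"),
                                 several.ok = TRUE)
  set.seed(as.integer(seed))

  n <- sum(counts)
  klass <- rep(c("acute", "chronic", "null"), times = counts)
  out <- data.frame(
    protein_id = sprintf("P%04d", seq_len(n)),
    klass = klass,
    effect_size = ifelse(klass == "null", 1, effect_size),
    responder_prevalence = responder_prevalence,
    technical_cv_target = technical_cv_target,
    stringsAsFactors = FALSE)
  out$affected_occasions <- lapply(klass, function(k)
    switch(k,
           acute = c("D1post", "D2post", "D3post"),
           chronic = chronic_occasions,
           null = character(0)))
  class(out) <- c("protein_archetypes", "data.frame")
  out
}
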