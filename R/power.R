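#' Configuration for the crossover power simulation
#'
#' Defaults mirror the original design exploration: cohort sizes 10 to 50
#' in steps of 10, effects present in 80% of athletes, and a Bonferroni
#' correction sized for a final five-protein panel (test level
#' 0.05 / panel size).  The effect size is expressed in units of the
#' technical standard deviation and must be chosen by the user — the
#' simulation reports power across whatever effect grid is supplied.
#'
#' @param n_grid ascending cohort sizes.
#' @param effect_size effect magnitudes in technical-sd units (one or
#'   more; 0 gives the size of the test under the null).
#' @param responder_prevalence fraction of athletes carrying the effect.
#' @param panel_size_for_bonferroni divisor of the 0.05 test level.
#' @param n_proteins number of proteins the technical variance is drawn
#'   from when `technical_sd` is supplied as a vector (metadata only).
#' @param reps Monte-Carlo replicates per (n, effect) cell.
#' @param contrast which contrast the simulation powers (default the
#'   day-1 acute contrast).
#' @param seed integer seed.
#' @return A validated `power_config` list.
#' @export
power_config <- function(n_grid = c(10L, 20L, 30L, 40L, 50L),
                         effect_size = 1,
                         responder_prevalence = 0.8,
                         panel_size_for_bonferroni = 5L,
                         n_proteins = 12L,
                         reps = 500L,
                         contrast = "acute_d1",
                         seed = 1L) {
  if (any(diff(n_grid) <= 0) || any(n_grid < 2))
    stop("n_grid must be ascending cohort sizes >= 2", call. = FALSE)
  if (responder_prevalence <= 0 || responder_prevalence > 1)
    stop("responder_prevalence must be in (0, 1]", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  stopifnot(contrast %in% CONTRAST_IDS, panel_size_for_bonferroni >= 1)
  structure(list(n_grid = as.integer(n_grid),
                 effect_size = as.numeric(effect_size),
                 responder_prevalence = responder_prevalence,
                 panel_size_for_bonferroni =
                   as.integer(panel_size_for_bonferroni),
                 n_proteins = as.integer(n_proteins),
                 reps = as.integer(reps),
                 contrast = contrast,
                 seed = as.integer(seed)),
            class = "power_config")
}

#' Mixed-model power simulation for the crossover design
#'
#' For each cohort size and effect size, simulates plain-normal data on
#' the full 16-cell crossover grid — a random athlete intercept plus
#' technical noise — plants the effect (a shift of `effect_size` times
#' the technical sd) at the tested contrast's affected occasions in a
#' responder subset of athletes, fits a linear mixed model (random
#' intercept per athlete, time-by-condition categorical fixed effect) via
#' [lme4::lmer()], and tests the contrast at the Bonferroni-adjusted
#' level `0.05 / panel_size_for_bonferroni`.  Power is the rejection
#' fraction over replicates.
#'
#' @param config a [power_config()].
#' @param technical_sd technical standard deviation of the simulated data
#'   (scalar > 0), e.g. calibrated from pooled-QC replicates.
#' @param athlete_sd between-athlete random-intercept sd; defaults to the
#'   technical sd (it cancels from the within-athlete contrast).
#' @return A data frame of class `power_curve`: one row per (n,
#'   effect_size) with `power`, `mc_se` (= sqrt(p(1-p)/reps)), `reps`,
#'   and `alpha` (the Bonferroni-adjusted test level).
#' @examples
#' \donttest{
#' pc <- power_config(n_grid = c(10L, 20L), effect_size = 1, reps = 50L)
#' simulate_power(pc, technical_sd = 0.1)
#' }
#' @export
simulate_power <- function(config, technical_sd, athlete_sd = NULL) {
  stopifnot(inherits(config, "power_config"))
  if (!is.numeric(technical_sd) || length(technical_sd) != 1L ||
      technical_sd <= 0)
    stop("technical_sd must be a single value > 0", call. = FALSE)
  if (is.null(athlete_sd)) athlete_sd <- technical_sd
  set.seed(config$seed)
  alpha <- 0.05 / config$panel_size_for_bonferroni

  affected <- switch(config$contrast,
                     acute_d1 = ,
                     acute_d2 = ,
                     acute_d3 = c("D1post", "D2post", "D3post"),
                     recovery_r1 = ,
                     recovery_r2 = c("R1", "R2"))
  L <- contrast_vectors("d1pre")[[config$contrast]]

  grid <- expand.grid(n = config$n_grid, effect_size = config$effect_size,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    n <- grid$n[g]; eff <- grid$effect_size[g]
    cells <- expand.grid(occasion = OCCASIONS, arm = ARMS,
                         athlete = factor(seq_len(n)),
                         KEEP.OUT.ATTRS = FALSE)
    cells$level <- factor(paste(cells$occasion, cells$arm, sep = ":"),
                          levels = names(L))
    planted <- cells$arm == "exercise" & cells$occasion %in% affected
    Lmat <- L[levels(cells$level)]
    df_t <- 15L * (n - 1L)  # within-athlete residual df, balanced design
    rej <- vapply(seq_len(config$reps), function(r) {
      intercept <- stats::rnorm(n, 0, athlete_sd)
      y <- intercept[as.integer(cells$athlete)] +
        stats::rnorm(nrow(cells), 0, technical_sd)
      responder <- stats::runif(n) < config$responder_prevalence
      y <- y + eff * technical_sd * planted *
        responder[as.integer(cells$athlete)]
      fit <- suppressMessages(lme4::lmer(
        y ~ 0 + level + (1 | athlete),
        data = cbind(cells, y = y), REML = TRUE,
        control = lme4::lmerControl(calc.derivs = FALSE,
                                    check.conv.singular = "ignore")))
      b <- lme4::fixef(fit)
      V <- as.matrix(stats::vcov(fit))
      est <- sum(Lmat * b)
      se <- sqrt(drop(t(Lmat) %*% V %*% Lmat))
      p <- 2 * stats::pt(-abs(est / se), df = df_t)
      p <= alpha
    }, logical(1))
    p_hat <- mean(rej)
    data.frame(n = n, effect_size = eff, power = p_hat,
               mc_se = sqrt(p_hat * (1 - p_hat) / config$reps),
               reps = config$reps, alpha = alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Tabulate (and optionally plot) a power curve
#'
#' @param curve a `power_curve` from [simulate_power()].
#' @param path optional TSV output path.
#' @param plot draw a base-graphics power-vs-n plot (one line per effect
#'   size) on the active device.
#' @return The curve data frame, invisibly.
#' @export
report_power <- function(curve, path = NULL, plot = FALSE) {
  stopifnot(inherits(curve, "power_curve"), nrow(curve) >= 1L)
  if (!is.null(path))
    utils::write.table(curve, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (plot) {
    effs <- sort(unique(curve$effect_size))
    graphics::plot(NULL, xlim = range(curve$n), ylim = c(0, 1),
                   xlab = "athletes", ylab = "power",
                   main = "Crossover power simulation")
    for (i in seq_along(effs)) {
      cc <- curve[curve$effect_size == effs[i], ]
      graphics::lines(cc$n, cc$power, type = "b", col = i, pch = 16)
    }
    graphics::legend("bottomright", legend = paste("effect", effs),
                     col = seq_along(effs), lty = 1, pch = 16, bty = "n")
  }
  invisible(curve)
}
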