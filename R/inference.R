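#' CV-gated significance threshold
#'
#' The per-protein significance level is gated on the protein's technical
#' coefficient of variation in the pooled-QC replicates: proteins whose CV
#' exceeds 15% are held to the stricter level 0.01, all others to 0.05.
#' "Exceeds" is a strict inequality, so a CV of exactly 0.15 keeps the
#' default level.  Proteins with an undefined CV (fewer than 2 QC
#' observations) are conservatively gated at the strict level.
#'
#' @param cv technical CV (fraction, >= 0); vectorized; `NA` allowed.
#' @param gate an [alpha_gate()].
#' @return The significance level(s), `gate$alpha_strict` or
#'   `gate$alpha_default`.
#' @examples
#' select_alpha(c(0.20, 0.10, 0.15, NA))
#' @export
select_alpha <- function(cv, gate = alpha_gate()) {
  if (any(is.finite(cv) & cv < 0))
    stop("cv must be >= 0", call. = FALSE)
  ifelse(is.na(cv) | cv > gate$cv_threshold,
         gate$alpha_strict, gate$alpha_default)
}

#' @rdname select_alpha
#' @param cv_threshold CV above which the strict level applies.
#' @param alpha_strict,alpha_default the two significance levels.
#' @export
alpha_gate <- function(cv_threshold = 0.15, alpha_strict = 0.01,
                       alpha_default = 0.05) {
  stopifnot(alpha_strict < alpha_default,
            alpha_strict > 0, alpha_default < 1, cv_threshold >= 0)
  list(cv_threshold = cv_threshold, alpha_strict = alpha_strict,
       alpha_default = alpha_default)
}

#' Fit the per-protein repeated-measures marginal model
#'
#' Fits a gaussian marginal (GEE-style) model of one protein's normalized
#' intensity on the time-by-condition interaction as a single categorical
#' predictor (16 levels = 8 occasions x 2 arms), with athletes as
#' clusters, an exchangeable (default) or independence working
#' correlation, and a bias-reduced cluster-robust sandwich covariance
#' suitable for the small number of clusters.  Tests downstream use a t
#' reference with (athletes - 1) degrees of freedom.
#'
#' @param values named numeric vector of the protein's per-sample values
#'   (study samples only), or a single row of a normalized
#'   `protein_matrix`.
#' @param samples sample metadata with `athlete_id`, `arm`, `occasion`.
#' @param correlation working correlation structure.
#' @return A `protein_fit` list: `beta` (named by `occasion:arm` level),
#'   `vcov`, `df`, `rho`, `converged`, `levels_present`.
#' @export
fit_protein_model <- function(values, samples,
                              correlation = c("exchangeable",
                                              "independence")) {
  correlation <- match.arg(correlation)
  keep <- samples$is_qc == 0L & is.finite(values)
  v <- values[keep]; s <- samples[keep, ]
  if (length(unique(s$athlete_id)) < 3L)
    stop("need >= 3 athletes to fit the marginal model", call. = FALSE)
  if (any(table(s$athlete_id) < 2L))
    stop("every athlete must contribute >= 2 occasions", call. = FALSE)
  lev <- factor(paste(s$occasion, s$arm, sep = ":"),
                levels = as.vector(outer(OCCASIONS, ARMS, paste,
                                         sep = ":")))
  X <- stats::model.matrix(~ 0 + lev)
  colnames(X) <- levels(lev)
  fit <- tryCatch(
    gee_gaussian(v, X, s$athlete_id, corstr = correlation),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(converged = FALSE, beta = NULL, vcov = NULL,
                          df = NA_integer_, rho = NA_real_,
                          levels_present = levels(lev)[table(lev) > 0]),
                     class = "protein_fit"))
  names(fit$beta) <- colnames(X)
  dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  fit$levels_present <- levels(lev)[table(lev) > 0]
  structure(fit, class = "protein_fit")
}

contrast_vectors <- function(recovery_baseline = c("d1pre", "none")) {
  recovery_baseline <- match.arg(recovery_baseline)
  lev <- as.vector(outer(OCCASIONS, ARMS, paste, sep = ":"))
  L <- function(...) {
    v <- stats::setNames(numeric(length(lev)), lev)
    w <- c(...)
    v[names(w)] <- w
    v
  }
  out <- list(
    acute_d1 = L("D1post:exercise" = 1, "D1pre:exercise" = -1,
                 "D1post:rest" = -1, "D1pre:rest" = 1),
    acute_d2 = L("D2post:exercise" = 1, "D2pre:exercise" = -1,
                 "D2post:rest" = -1, "D2pre:rest" = 1),
    acute_d3 = L("D3post:exercise" = 1, "D3pre:exercise" = -1,
                 "D3post:rest" = -1, "D3pre:rest" = 1))
  if (recovery_baseline == "d1pre") {
    out$recovery_r1 <- L("R1:exercise" = 1, "D1pre:exercise" = -1,
                         "R1:rest" = -1, "D1pre:rest" = 1)
    out$recovery_r2 <- L("R2:exercise" = 1, "D1pre:exercise" = -1,
                         "R2:rest" = -1, "D1pre:rest" = 1)
  } else {
    out$recovery_r1 <- L("R1:exercise" = 1, "R1:rest" = -1)
    out$recovery_r2 <- L("R2:exercise" = 1, "R2:rest" = -1)
  }
  out
}

#' Time-by-condition contrasts for one protein fit
#'
#' Computes the five reported difference-of-differences contrasts from the
#' 16 time-by-condition level means: `acute_dK` is the pre-to-post change
#' on exercise day K minus the matching change in the rest arm;
#' `recovery_rK` is recovery morning K relative to the day-1 pre baseline,
#' exercise minus rest (or the unbaselined `RK` exercise-minus-rest
#' difference with `recovery_baseline = "none"`).  Standard errors come
#' from the cluster-robust sandwich covariance; raw p-values use a t
#' reference with (athletes - 1) df.
#'
#' @param fit a `protein_fit` from [fit_protein_model()].
#' @param recovery_baseline `"d1pre"` (default) or `"none"`.
#' @return A data frame with one row per contrast: `contrast`, `estimate`,
#'   `se`, `tstat`, `df`, `p_raw`, `direction`, `status` (`"ok"`,
#'   `"not_estimable"`, or `"not_converged"`).
#' @export
compute_contrasts <- function(fit, recovery_baseline = c("d1pre", "none")) {
  recovery_baseline <- match.arg(recovery_baseline)
  Ls <- contrast_vectors(recovery_baseline)
  out <- data.frame(contrast = names(Ls), estimate = NA_real_,
                    se = NA_real_, tstat = NA_real_,
                    df = if (is.null(fit$df)) NA_integer_ else fit$df,
                    p_raw = NA_real_, direction = NA_integer_,
                    status = "not_converged", stringsAsFactors = FALSE)
  if (!isTRUE(fit$converged)) return(out)
  for (i in seq_along(Ls)) {
    L <- Ls[[i]]
    need <- names(L)[L != 0]
    if (any(!need %in% fit$levels_present) ||
        any(is.na(fit$beta[need]))) {
      out$status[i] <- "not_estimable"
      next
    }
    nz <- which(L != 0)
    est <- sum(L[nz] * fit$beta[nz])
    se <- sqrt(max(drop(t(L[nz]) %*% fit$vcov[nz, nz] %*% L[nz]), 0))
    tt <- if (se > 0) est / se
          else if (abs(est) < 1e-12) 0 else sign(est) * Inf
    out$estimate[i] <- est
    out$se[i] <- se
    out$tstat[i] <- tt
    out$p_raw[i] <- 2 * stats::pt(-abs(tt), df = fit$df)
    out$direction[i] <- sign(est)
    out$status[i] <- "ok"
  }
  out
}

#' Multiplicity adjustment for the time-by-condition contrasts
#'
#' The pairwise-comparison family behind the reported contrasts is the
#' full set of time-by-condition level comparisons; `"tukey"` (default)
#' adjusts each contrast's t statistic against the studentized-range
#' distribution for the 16-level family, `"bonferroni5"` instead applies a
#' Bonferroni factor for the five reported contrasts.  Adjusted p-values
#' are clipped to be at least the raw p-value (strictly larger whenever
#' the family has more than one member).
#'
#' @param contrasts a contrast data frame from [compute_contrasts()].
#' @param method `"tukey"` or `"bonferroni5"`.
#' @param n_levels size of the level family for the studentized range.
#' @return The data frame with a `p_adjusted` column added.
#' @export
adjust_tukey <- function(contrasts, method = c("tukey", "bonferroni5"),
                         n_levels = 16L) {
  method <- match.arg(method)
  ok <- contrasts$status == "ok"
  p_adj <- rep(NA_real_, nrow(contrasts))
  if (method == "tukey") {
    n_est <- sum(ok)
    if (n_est <= 1L) {
      p_adj[ok] <- contrasts$p_raw[ok]
    } else {
      p_adj[ok] <- stats::ptukey(sqrt(2) * abs(contrasts$tstat[ok]),
                                 nmeans = n_levels,
                                 df = contrasts$df[ok],
                                 lower.tail = FALSE)
    }
  } else {
    p_adj[ok] <- pmin(1, contrasts$p_raw[ok] * 5)
  }
  contrasts$p_adjusted <- pmin(1, pmax(p_adj, contrasts$p_raw))
  contrasts
}

#' Per-protein contrast analysis over a normalized matrix
#'
#' Loops [fit_protein_model()], [compute_contrasts()] and [adjust_tukey()]
#' over every protein of a normalized matrix and attaches the CV-gated
#' significance level of each protein.
#'
#' @param pm a normalized `protein_matrix` with `technical_cv` filled
#'   (see [preprocess_quant()]).
#' @param gate an [alpha_gate()].
#' @param correlation,adjust,recovery_baseline analysis modes (see
#'   [fit_protein_model()], [adjust_tukey()], [compute_contrasts()]).
#' @return A data frame with one row per (protein, contrast):
#'   `protein_id`, `contrast`, `estimate`, `se`, `tstat`, `df`, `p_raw`,
#'   `p_adjusted`, `direction`, `alpha_used`, `technical_cv`, `status`.
#'   The analysis modes are recorded in attribute `"modes"`.
#' @export
analyze_proteins <- function(pm, gate = alpha_gate(),
                             correlation = c("exchangeable",
                                             "independence"),
                             adjust = c("bonferroni5", "tukey"),
                             recovery_baseline = c("d1pre", "none")) {
  stopifnot(inherits(pm, "protein_matrix"))
  correlation <- match.arg(correlation)
  adjust <- match.arg(adjust)
  recovery_baseline <- match.arg(recovery_baseline)
  cv <- pm$technical_cv
  if (is.null(cv)) {
    cv <- rep(NA_real_, nrow(pm$values))
    names(cv) <- rownames(pm$values)
  }
  alpha <- select_alpha(cv, gate)

  res <- lapply(rownames(pm$values), function(p) {
    fit <- fit_protein_model(pm$values[p, ], pm$samples,
                             correlation = correlation)
    cc <- adjust_tukey(compute_contrasts(fit, recovery_baseline),
                       method = adjust)
    cc$protein_id <- p
    cc
  })
  out <- do.call(rbind, res)
  out$alpha_used <- alpha[out$protein_id]
  out$technical_cv <- unname(cv[out$protein_id])
  out <- out[, c("protein_id", "contrast", "estimate", "se", "tstat", "df",
                 "p_raw", "p_adjusted", "direction", "alpha_used",
                 "technical_cv", "status")]
  rownames(out) <- NULL
  attr(out, "modes") <- list(correlation = correlation, adjust = adjust,
                             recovery_baseline = recovery_baseline)
  out
}
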