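#' Temporal-pattern classification of one protein
#'
#' Applies the biomarker-cluster rules to a protein's five adjusted
#' contrasts at the protein's (CV-gated) significance level:
#' \describe{
#'   \item{acute_sustained}{all three acute contrasts significantly
#'     positive — the protein rises pre-to-post on each exercise day.}
#'   \item{chronic_FOR}{at least one recovery contrast significantly
#'     positive, and the acute evidence compatible with "no acute
#'     response": in `strict` mode (default) no acute contrast may be
#'     significant in either direction; in `lenient` mode at most one
#'     acute contrast may be significantly positive.}
#'   \item{acute_day1}{the day-1 acute contrast significantly positive
#'     (when neither pattern above applies).}
#'   \item{none}{anything else, including proteins with non-estimable or
#'     non-converged contrasts.}
#' }
#' `acute_sustained` takes precedence over `acute_day1`; a protein is
#' never assigned both an acute label and `chronic_FOR` (in `lenient`
#' mode, where a single acute day plus a recovery rise satisfies both
#' patterns, the chronic/FOR label wins, as the chronic definition
#' explicitly tolerates one exercise-day elevation).
#'
#' @param contrasts the five-contrast data frame of one protein (from
#'   [analyze_proteins()] or [compute_contrasts()] + [adjust_tukey()]).
#' @param alpha significance level in (0, 1).
#' @param mode `"strict"` or `"lenient"`.
#' @return A one-row data frame: `label`, `alpha_used`, `rule_mode`, the
#'   per-contrast evidence (`"+"` significant positive, `"-"` significant
#'   negative, `"."` not significant, `"?"` not estimable), and `status`.
#' @export
classify_protein <- function(contrasts, alpha, mode = c("strict",
                                                        "lenient")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  stopifnot(setequal(contrasts$contrast, CONTRAST_IDS))
  cc <- contrasts[match(CONTRAST_IDS, contrasts$contrast), ]

  ok <- cc$status == "ok"
  sig <- ok & !is.na(cc$p_adjusted) & cc$p_adjusted <= alpha
  sig_pos <- sig & cc$estimate > 0
  ev <- ifelse(!ok, "?", ifelse(sig_pos, "+", ifelse(sig, "-", ".")))
  names(ev) <- cc$contrast

  acute <- seq_len(3L)
  recov <- 4:5
  label <- "none"
  status <- if (all(ok)) "ok" else "incomplete_evidence"
  if (all(ok)) {
    chronic_ok <- any(sig_pos[recov]) &&
      (if (mode == "strict") !any(sig[acute]) else sum(sig_pos[acute]) <= 1)
    if (all(sig_pos[acute])) {
      label <- "acute_sustained"
    } else if (chronic_ok) {
      label <- "chronic_FOR"
    } else if (sig_pos[1L]) {
      label <- "acute_day1"
    }
  }
  out <- data.frame(label = label, alpha_used = alpha, rule_mode = mode,
                    t(ev), status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify every protein in a contrast table
#'
#' @param contrasts the long contrast data frame from
#'   [analyze_proteins()] (must carry `alpha_used`).
#' @param mode rule mode, see [classify_protein()].
#' @return A data frame of class `protein_classifications`, one row per
#'   protein, sorted by protein id.
#' @export
classify_proteins <- function(contrasts, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot("alpha_used" %in% names(contrasts))
  if (!nrow(contrasts)) {
    out <- data.frame(protein_id = character(), label = character(),
                      alpha_used = numeric(), rule_mode = character(),
                      status = character(), stringsAsFactors = FALSE)
    class(out) <- c("protein_classifications", "data.frame")
    return(out)
  }
  parts <- split(contrasts, contrasts$protein_id)
  out <- do.call(rbind, lapply(names(parts), function(p) {
    cc <- parts[[p]]
    cbind(data.frame(protein_id = p, stringsAsFactors = FALSE),
          classify_protein(cc, alpha = cc$alpha_used[1L], mode = mode))
  }))
  out <- out[order(out$protein_id), ]
  rownames(out) <- NULL
  class(out) <- c("protein_classifications", "data.frame")
  out
}

#' Cluster summary report
#'
#' Counts per label plus the per-protein table sorted by label then
#' protein id.  The annotation columns (`literature_support`,
#' `biological_plausibility`) mirror the manual narrowing criteria of the
#' original selection workflow; they are always emitted empty — those
#' judgements are not automated.
#'
#' @param classifications a `protein_classifications` data frame.
#' @return A list with `counts` (named integer vector over all four
#'   labels) and `table` (the annotated per-protein data frame).
#' @export
summarize_clusters <- function(classifications) {
  counts <- stats::setNames(integer(length(CLASS_LABELS)), CLASS_LABELS)
  tab <- as.data.frame(classifications)
  if (nrow(tab)) {
    t0 <- table(factor(tab$label, levels = CLASS_LABELS))
    counts[names(t0)] <- as.integer(t0)
    tab <- tab[order(factor(tab$label, levels = CLASS_LABELS),
                     tab$protein_id), ]
  }
  tab$literature_support <- character(nrow(tab))
  tab$biological_plausibility <- character(nrow(tab))
  rownames(tab) <- NULL
  list(counts = counts, table = tab)
}

#' Score classifications against a ground-truth ledger
#'
#' Computes, per planted archetype class, the recovery rates of the
#' classifier: sensitivity of `acute_sustained` among planted acute
#' proteins, sensitivity of `chronic_FOR` among planted chronic proteins,
#' and the per-label false-positive rate among planted null proteins.
#'
#' @param classifications a `protein_classifications` data frame.
#' @param truth the truth ledger from [generate_dataset()].
#' @return A list: `sensitivity_acute`, `sensitivity_chronic`,
#'   `fpr_by_label` (named over non-`none` labels), and the underlying
#'   confusion table `confusion`.
#' @export
evaluate_classifications <- function(classifications, truth) {
  m <- merge(as.data.frame(classifications)[, c("protein_id", "label")],
             truth[, c("protein_id", "klass")], by = "protein_id")
  confusion <- table(planted = m$klass,
                     label = factor(m$label, levels = CLASS_LABELS))
  sens_acute <- if (any(m$klass == "acute"))
    mean(m$label[m$klass == "acute"] == "acute_sustained") else NA_real_
  sens_chronic <- if (any(m$klass == "chronic"))
    mean(m$label[m$klass == "chronic"] == "chronic_FOR") else NA_real_
  nulls <- m$label[m$klass == "null"]
  fpr <- if (length(nulls))
    vapply(setdiff(CLASS_LABELS, "none"),
           function(l) mean(nulls == l), numeric(1))
  else stats::setNames(rep(NA_real_, 3),
                       setdiff(CLASS_LABELS, "none"))
  list(sensitivity_acute = sens_acute,
       sensitivity_chronic = sens_chronic,
       fpr_by_label = fpr,
       confusion = confusion)
}
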