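#' Pipeline configuration
#'
#' Builds and validates the end-to-end configuration consumed by
#' [run_pipeline()].  Unknown keys are rejected.  The configuration
#' round-trips through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param simulate generate the input table (TRUE) or read it from
#'   `input` (FALSE).
#' @param input path to a quantitation table (required when
#'   `simulate = FALSE`).
#' @param n_athletes,n_acute,n_chronic,n_null,effect_size,prevalence,tech_cv
#'   simulation scenario (used when `simulate = TRUE`).
#' @param seed single integer driving all randomness in the run.
#' @param cv_mode technical-CV mode, `"raw"` or `"zscore"`.
#' @param batch_correction apply batch correction.
#' @param correlation,adjust_mode,recovery_baseline analysis modes (see
#'   [analyze_proteins()]).
#' @param rule_mode classification rule mode (see [classify_protein()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, input = NULL,
                            n_athletes = 10L, n_acute = 20L,
                            n_chronic = 20L, n_null = 160L,
                            effect_size = 2, prevalence = 0.8,
                            tech_cv = 0.10, seed = 1L,
                            cv_mode = "raw", batch_correction = TRUE,
                            correlation = "exchangeable",
                            adjust_mode = "bonferroni5",
                            recovery_baseline = "d1pre",
                            rule_mode = "strict") {
  cfg <- list(simulate = isTRUE(simulate), input = input,
              n_athletes = as.integer(n_athletes),
              n_acute = as.integer(n_acute),
              n_chronic = as.integer(n_chronic),
              n_null = as.integer(n_null),
              effect_size = as.numeric(effect_size),
              prevalence = as.numeric(prevalence),
              tech_cv = as.numeric(tech_cv),
              seed = as.integer(seed),
              cv_mode = match.arg(cv_mode, c("raw", "zscore")),
              batch_correction = isTRUE(batch_correction),
              correlation = match.arg(correlation,
                                      c("exchangeable", "independence")),
              adjust_mode = match.arg(adjust_mode,
                                      c("bonferroni5", "tukey")),
              recovery_baseline = match.arg(recovery_baseline,
                                            c("d1pre", "none")),
              rule_mode = match.arg(rule_mode, c("strict", "lenient")))
  if (!cfg$simulate && (is.null(cfg$input) || !nzchar(cfg$input)))
    stop("config error: simulate = FALSE requires an input path",
         call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' Executes (optionally) simulate, then preprocess, analyze and classify,
#' writing every artifact plus a manifest to `out_dir`: the quantitation
#' table and truth ledger (simulation runs), the normalized protein
#' matrix and per-protein technical CVs, the contrast table, the
#' classification table, a JSON cluster summary (including
#' sensitivity/FPR against the truth ledger when one exists), and
#' `manifest.json` recording the configuration, seed, package version and
#' MD5 hashes of all artifacts.  A given configuration and seed
#' reproduce every artifact byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts (`quant`,
#'   `truth`, `matrix`, `contrasts`, `classifications`, `summary`,
#'   `paths`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  paths <- list()

  truth <- NULL
  if (config$simulate) {
    say("simulating: ", config$n_athletes, " athletes, ",
        config$n_acute, "/", config$n_chronic, "/", config$n_null,
        " acute/chronic/null proteins, effect ", config$effect_size,
        "x, prevalence ", config$prevalence)
    design <- make_design(config$n_athletes, seed = config$seed)
    arche <- make_archetypes(config$n_acute, config$n_chronic,
                             config$n_null,
                             effect_size = config$effect_size,
                             responder_prevalence = config$prevalence,
                             technical_cv_target = config$tech_cv,
                             seed = config$seed + 1L)
    gen <- generate_dataset(design, arche,
                            noise_model(technical_cv_target =
                                          config$tech_cv),
                            seed = config$seed + 2L)
    quant <- gen$quant
    truth <- gen$truth
    paths$quant <- file.path(out_dir, "quant.tsv")
    write_quant_table(quant, paths$quant)
    paths$truth <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    say("reading ", config$input)
    quant <- read_quant_table(config$input)
  }

  say("preprocessing (cv_mode = ", config$cv_mode,
      ", batch_correction = ", config$batch_correction, ")")
  pm <- preprocess_quant(quant, batch_correction = config$batch_correction,
                         cv_mode = config$cv_mode)
  paths$matrix <- file.path(out_dir, "matrix.tsv")
  paths$cv <- file.path(out_dir, "technical_cv.tsv")
  write_protein_matrix(pm, paths$matrix, paths$cv)

  say("analyzing (correlation = ", config$correlation,
      ", adjust = ", config$adjust_mode,
      ", recovery_baseline = ", config$recovery_baseline, ")")
  contrasts <- analyze_proteins(pm,
                                correlation = config$correlation,
                                adjust = config$adjust_mode,
                                recovery_baseline =
                                  config$recovery_baseline)
  paths$contrasts <- file.path(out_dir, "contrasts.tsv")
  utils::write.table(format_num(contrasts), paths$contrasts, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("classifying (rule_mode = ", config$rule_mode, ")")
  cls <- classify_proteins(contrasts, mode = config$rule_mode)
  paths$classifications <- file.path(out_dir, "classifications.tsv")
  utils::write.table(as.data.frame(cls), paths$classifications,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- summarize_clusters(cls)
  summary_out <- list(counts = as.list(summary$counts),
                      modes = list(cv_mode = config$cv_mode,
                                   correlation = config$correlation,
                                   adjust = config$adjust_mode,
                                   recovery_baseline =
                                     config$recovery_baseline,
                                   rule_mode = config$rule_mode))
  if (!is.null(truth)) {
    ev <- evaluate_classifications(cls, truth)
    summary_out$recovery <- list(
      sensitivity_acute = ev$sensitivity_acute,
      sensitivity_chronic = ev$sensitivity_chronic,
      fpr_by_label = as.list(ev$fpr_by_label))
  }
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_out, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("forpanel")),
                   artifact_md5 = as.list(
                     tools::md5sum(unlist(paths))))
  names(manifest$artifact_md5) <- basename(unlist(paths))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote ", length(paths), " artifacts to ", out_dir)

  invisible(list(quant = quant, truth = truth, matrix = pm,
                 contrasts = contrasts, classifications = cls,
                 summary = summary_out, paths = paths))
}

## fixed-format numeric columns so artifacts are byte-stable
format_num <- function(df, digits = 12) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g")))
  df
}
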