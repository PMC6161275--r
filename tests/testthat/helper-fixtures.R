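## Shared fixture builders.  Everything is generated in code; sizes are
## kept small except where a check is explicitly about calibration.

## A generated dataset under the default study conditions.
tiny_dataset <- function(n_athletes = 4, n_acute = 1, n_chronic = 1,
                         n_null = 2, effect_size = 2, seed = 42,
                         noise = noise_model()) {
  d <- make_design(n_athletes, seed = seed)
  a <- make_archetypes(n_acute, n_chronic, n_null,
                       effect_size = effect_size, seed = seed + 1)
  c(generate_dataset(d, a, noise, seed = seed + 2),
    list(design = d, archetypes = a))
}

## Hand-built protein-level quantitation table on a full crossover grid,
## with a deterministic intensity function of (protein, athlete, arm,
## occasion).  No QC rows unless add_qc is TRUE.
grid_quant <- function(n_athletes = 3, proteins = "P1",
                       intensity_fun = function(p, ath, arm, occ) 100,
                       add_qc = FALSE, qc_values = c(100, 100, 100, 100)) {
  occ <- forpanel:::OCCASIONS
  arms <- forpanel:::ARMS
  g <- expand.grid(occasion = occ, arm = arms,
                   athlete_id = sprintf("A%02d", seq_len(n_athletes)),
                   protein_id = proteins,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$batch_id <- sub("A", "B", g$athlete_id)
  ## injection order is a property of the sample: identical across the
  ## proteins measured in the same injection
  g$injection_order <- ave(seq_len(nrow(g)),
                           paste(g$batch_id, g$protein_id),
                           FUN = seq_along)
  g$is_qc <- 0L
  g$peptide_id <- NA_character_
  g$intensity <- mapply(intensity_fun, g$protein_id, g$athlete_id,
                        g$arm, g$occasion)
  if (add_qc) {
    qc <- expand.grid(injection_order = 100 + seq_along(qc_values),
                      batch_id = unique(g$batch_id),
                      protein_id = proteins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    qc$athlete_id <- NA_character_
    qc$arm <- NA_character_
    qc$occasion <- NA_character_
    qc$is_qc <- 1L
    qc$peptide_id <- NA_character_
    qc$intensity <- rep(qc_values, length.out = nrow(qc))
    g <- rbind(g[names(qc)], qc)
  }
  g
}

## A five-row contrast evidence table for classifier rule tests.
## signs: named vector over the five contrast ids with "+", "-" or "."
evidence <- function(signs, alpha = 0.05) {
  ids <- forpanel:::CONTRAST_IDS
  stopifnot(setequal(names(signs), ids))
  s <- signs[ids]
  data.frame(contrast = ids,
             estimate = ifelse(s == "-", -1, 1) * 0.3,
             se = 0.05, tstat = 6, df = 9,
             p_raw = ifelse(s == ".", 0.6, alpha / 2),
             p_adjusted = ifelse(s == ".", 0.9, alpha / 2),
             direction = ifelse(s == "-", -1L, 1L),
             status = "ok", stringsAsFactors = FALSE)
}

## Exact paired sign-flip permutation test for the acute_d1 contrast:
## per-athlete difference-of-differences, statistic = mean, all 2^n
## within-athlete arm-label swaps enumerated.
perm_test_acute_d1 <- function(pm, protein) {
  s <- pm$samples
  keep <- s$is_qc == 0L
  v <- pm$values[protein, keep]
  s <- s[keep, ]
  cell <- function(ath, occ, arm)
    v[s$athlete_id == ath & s$occasion == occ & s$arm == arm]
  ath <- unique(s$athlete_id)
  d <- vapply(ath, function(a)
    (cell(a, "D1post", "exercise") - cell(a, "D1pre", "exercise")) -
    (cell(a, "D1post", "rest") - cell(a, "D1pre", "rest")),
    numeric(1))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_stats <- abs(signs %*% d) / n
  mean(null_stats >= abs(mean(d)) - 1e-12)
}
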