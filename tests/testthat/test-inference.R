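test_that("technical CV matches hand computation and flags undefined", {
  q <- grid_quant(n_athletes = 1, add_qc = TRUE,
                  qc_values = c(90, 100, 110, 100))
  pm <- compute_technical_cv(quant_to_matrix(q))
  expect_equal(unname(pm$technical_cv["P1"]),
               stats::sd(c(90, 100, 110, 100)) / 100, tolerance = 1e-10)
  ## equal QC values -> CV 0
  q0 <- grid_quant(n_athletes = 1, add_qc = TRUE,
                   qc_values = c(100, 100, 100, 100))
  expect_equal(unname(compute_technical_cv(
    quant_to_matrix(q0))$technical_cv["P1"]), 0)
  ## one QC record -> undefined, with a notice
  q1 <- grid_quant(n_athletes = 1, add_qc = TRUE, qc_values = 100)
  expect_message(pm1 <- compute_technical_cv(quant_to_matrix(q1)),
                 "undefined")
  expect_true(is.na(pm1$technical_cv["P1"]))
})

test_that("generator-calibrated CV lands near its target", {
  meds <- vapply(1:10, function(s) {
    g <- tiny_dataset(n_athletes = 6, n_acute = 0, n_chronic = 0,
                      n_null = 10, seed = 100 + s)
    pm <- compute_technical_cv(correct_batch_effects(
      quant_to_matrix(g$quant)))
    stats::median(pm$technical_cv)
  }, numeric(1))
  expect_true(all(meds > 0.07 & meds < 0.13))
})

test_that("zscore CV mode is exposed and non-negative", {
  g <- tiny_dataset(n_athletes = 4, seed = 8)
  pm <- compute_technical_cv(quant_to_matrix(g$quant), mode = "zscore")
  expect_true(all(pm$technical_cv >= 0))
})

test_that("the CV gate selects the documented significance levels", {
  expect_equal(select_alpha(0.20), 0.01)
  expect_equal(select_alpha(0.10), 0.05)
  expect_equal(select_alpha(0.15), 0.05)  # 'exceeds' is strict
  expect_equal(select_alpha(NA), 0.01)    # undefined CV -> conservative
  expect_equal(select_alpha(c(0.2, 0.1, NA)), c(0.01, 0.05, 0.01))
  expect_error(select_alpha(-0.1), "cv")
  expect_error(alpha_gate(alpha_strict = 0.1, alpha_default = 0.05))
})

test_that("constant response gives zero contrasts; planted separation is
          detected at any reasonable alpha", {
  q <- grid_quant(n_athletes = 4)
  pm <- normalize_row_max(quant_to_matrix(q))
  fit <- fit_protein_model(pm$values[1, ], pm$samples)
  cc <- compute_contrasts(fit)
  expect_equal(cc$estimate, rep(0, 5), tolerance = 1e-12)

  ## strong planted acute effect, no technical noise, with tiny athlete
  ## jitter so the sandwich variance is positive but negligible
  q2 <- grid_quant(
    n_athletes = 5,
    intensity_fun = function(p, ath, arm, occ) {
      jit <- exp(stats::rnorm(1, 0, 1e-6))
      base <- 100 * jit
      if (arm == "exercise" && occ %in% c("D1post", "D2post", "D3post"))
        base * 5 else base
    })
  pm2 <- normalize_row_max(quant_to_matrix(q2))
  fit2 <- fit_protein_model(pm2$values[1, ], pm2$samples)
  cc2 <- adjust_tukey(compute_contrasts(fit2), method = "tukey")
  acute <- cc2$contrast %in% c("acute_d1", "acute_d2", "acute_d3")
  expect_true(all(cc2$estimate[acute] > 0))
  expect_true(all(cc2$p_adjusted[acute] < 1e-6))
})

test_that("contrast estimates are antisymmetric under arm relabeling", {
  g <- tiny_dataset(n_athletes = 5, n_acute = 1, n_chronic = 1,
                    n_null = 1, seed = 17)
  pm <- preprocess_quant(g$quant)
  fit <- fit_protein_model(pm$values[1, ], pm$samples)
  cc <- compute_contrasts(fit)
  swapped <- pm
  swapped$samples$arm <- c(exercise = "rest",
                           rest = "exercise")[pm$samples$arm]
  fit_sw <- fit_protein_model(pm$values[1, ], swapped$samples)
  cc_sw <- compute_contrasts(fit_sw)
  expect_equal(cc_sw$estimate, -cc$estimate, tolerance = 1e-8)
})

test_that("estimates are invariant to athlete relabeling and row order", {
  g <- tiny_dataset(n_athletes = 5, seed = 23)
  pm <- preprocess_quant(g$quant)
  fit <- fit_protein_model(pm$values[2, ], pm$samples)
  cc <- compute_contrasts(fit)

  perm <- sample(ncol(pm$values))
  fit_p <- fit_protein_model(pm$values[2, perm], pm$samples[perm, ])
  expect_equal(compute_contrasts(fit_p)$estimate, cc$estimate,
               tolerance = 1e-8)

  relab <- pm$samples
  map <- stats::setNames(sprintf("Z%02d", seq_len(5)),
                         sort(unique(stats::na.omit(relab$athlete_id))))
  relab$athlete_id[relab$is_qc == 0] <-
    map[relab$athlete_id[relab$is_qc == 0]]
  fit_r <- fit_protein_model(pm$values[2, ], relab)
  expect_equal(compute_contrasts(fit_r)$estimate, cc$estimate,
               tolerance = 1e-8)
})

test_that("toy level means reproduce the hand-computed acute_d1 estimate", {
  ## every athlete shows D1pre=0.5 -> D1post=0.9 under exercise and
  ## 0.5 -> 0.6 under rest: acute_d1 = (0.9-0.5) - (0.6-0.5) = 0.3
  q <- grid_quant(
    n_athletes = 3,
    intensity_fun = function(p, ath, arm, occ) {
      if (occ == "D1post") return(ifelse(arm == "exercise", 0.9, 0.6))
      0.5
    })
  pm <- quant_to_matrix(q)
  pm$values <- exp(pm$values)  # work on the raw scale directly
  pm$scale <- "normalized"
  fit <- fit_protein_model(pm$values[1, ], pm$samples)
  cc <- compute_contrasts(fit)
  expect_equal(cc$estimate[cc$contrast == "acute_d1"], 0.3,
               tolerance = 1e-10)
})

test_that("GEE cell means agree with OLS on the balanced design", {
  g <- tiny_dataset(n_athletes = 6, seed = 29)
  pm <- preprocess_quant(g$quant)
  s <- pm$samples[pm$samples$is_qc == 0, ]
  v <- pm$values[1, pm$samples$is_qc == 0]
  fit <- fit_protein_model(pm$values[1, ], pm$samples)
  cellmeans <- tapply(v, paste(s$occasion, s$arm, sep = ":"), mean)
  expect_equal(unname(fit$beta[names(cellmeans)]), as.vector(cellmeans),
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$df, 5)
})

test_that("multiplicity adjustment is monotone and respects family size", {
  g <- tiny_dataset(n_athletes = 5, seed = 41)
  pm <- preprocess_quant(g$quant)
  fit <- fit_protein_model(pm$values[1, ], pm$samples)
  cc <- compute_contrasts(fit)
  tk <- adjust_tukey(cc, method = "tukey")
  b5 <- adjust_tukey(cc, method = "bonferroni5")
  expect_true(all(tk$p_adjusted >= tk$p_raw))
  expect_true(all(b5$p_adjusted >= b5$p_raw))
  expect_true(all(tk$p_adjusted <= 1 & b5$p_adjusted <= 1))
  ## studentized-range family of 16 inflates a 0.04 raw p well above 0.04
  mid <- which.min(abs(cc$p_raw - stats::median(cc$p_raw)))
  expect_gt(tk$p_adjusted[mid], cc$p_raw[mid])
  ## family of one: single estimable contrast keeps its raw p
  one <- cc[1, ]
  expect_equal(adjust_tukey(one, method = "tukey")$p_adjusted, one$p_raw)
  ## ceiling: raw p of 1 stays 1
  ceil <- cc
  ceil$p_raw <- 1; ceil$tstat <- 0
  expect_equal(adjust_tukey(ceil, method = "tukey")$p_adjusted,
               rep(1, 5))
})

test_that("missing levels yield flagged, not silent, contrasts", {
  q <- grid_quant(n_athletes = 4)
  q <- q[!(q$occasion == "R2" & q$arm == "exercise"), ]
  pm <- quant_to_matrix(q)
  fit <- fit_protein_model(pm$values[1, ], pm$samples)
  cc <- compute_contrasts(fit)
  expect_equal(cc$status[cc$contrast == "recovery_r2"], "not_estimable")
  expect_true(all(cc$status[cc$contrast != "recovery_r2"] == "ok"))
})

test_that("small designs are rejected with informative errors", {
  q <- grid_quant(n_athletes = 2)
  pm <- quant_to_matrix(q)
  expect_error(fit_protein_model(pm$values[1, ], pm$samples),
               ">= 3 athletes")
})
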