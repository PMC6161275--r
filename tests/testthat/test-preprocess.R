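test_that("rollup uses exactly the 3 most abundant of 5 peptides", {
  q <- grid_quant(n_athletes = 2)
  ## 5 peptides with mean abundances 10 > 8 > 6 > 4 > 2 (constant across
  ## samples): only the top 3 should contribute
  pep <- do.call(rbind, lapply(1:5, function(k) {
    p <- q
    p$peptide_id <- sprintf("P1_pep%d", k)
    p$intensity <- c(10, 8, 6, 4, 2)[k]
    p
  }))
  out <- rollup_top3(pep)
  expect_equal(nrow(out), 32)
  expect_equal(unique(out$log_intensity), mean(log(c(10, 8, 6))),
               tolerance = 1e-12)
})

test_that("rollup keeps both peptides when only two exist", {
  q <- grid_quant(n_athletes = 1)
  pep <- do.call(rbind, lapply(1:2, function(k) {
    p <- q
    p$peptide_id <- sprintf("P1_pep%d", k)
    p$intensity <- c(50, 10)[k]
    p
  }))
  out <- rollup_top3(pep)
  expect_equal(unique(out$log_intensity), mean(log(c(50, 10))),
               tolerance = 1e-12)
})

test_that("single-peptide rollup is the identity on the log scale", {
  q <- grid_quant(n_athletes = 1)
  q$peptide_id <- "P1_pep1"
  out <- rollup_top3(q)
  expect_equal(unique(out$log_intensity), log(100), tolerance = 1e-12)
})

test_that("peptide ranking ties break lexicographically by peptide_id", {
  q <- grid_quant(n_athletes = 1)
  pep <- do.call(rbind, lapply(c("b", "a", "c", "d"), function(k) {
    p <- q
    p$peptide_id <- paste0("pep_", k)
    p$intensity <- 10  # four-way tie in mean abundance
    p
  }))
  pep$intensity[pep$peptide_id == "pep_d"] <- 10  # still tied
  out <- rollup_top3(pep)
  ## top 3 after tie-break are pep_a, pep_b, pep_c; all constant 10
  expect_equal(unique(out$log_intensity), log(10), tolerance = 1e-12)
  ## make the excluded peptide detectable: bump pep_d only
  pep2 <- pep
  pep2$intensity[pep2$peptide_id == "pep_d"] <- 10 - 1e-9
  out2 <- rollup_top3(pep2)
  expect_equal(unique(out2$log_intensity), log(10), tolerance = 1e-12)
})

test_that("rollup preserves peptide-set stability across samples", {
  ## peptide ranks are by across-study-sample mean, so a peptide that is
  ## occasionally the most intense in single samples still stays excluded
  g <- tiny_dataset(n_athletes = 3, n_acute = 0, n_chronic = 0, n_null = 3)
  pep <- explode_peptides(g$quant, n_peptides = 5, seed = 7)
  out <- rollup_top3(pep)
  expect_equal(nrow(out), nrow(g$quant))
  expect_true(all(is.na(out$peptide_id)))
})

test_that("pure location batch effect is removed", {
  occ <- forpanel:::OCCASIONS
  base <- stats::rnorm(32, 0, 1)  # same within-batch noise per protein
  q <- grid_quant(n_athletes = 2, proteins = c("P1", "P2", "P3"),
                  intensity_fun = function(p, ath, arm, occ) 1)
  shift <- ifelse(q$batch_id == "B02", 0.7, 0)  # constant delta
  off <- c(P1 = 0, P2 = 1, P3 = 2)[q$protein_id]
  idx <- ave(seq_len(nrow(q)), q$protein_id, FUN = seq_along)
  q$intensity <- exp(10 + off + base[idx] + shift)
  pm <- correct_batch_effects(quant_to_matrix(q))
  for (p in c("P1", "P2", "P3")) {
    m1 <- mean(pm$values[p, pm$samples$batch_id == "B01"])
    m2 <- mean(pm$values[p, pm$samples$batch_id == "B02"])
    expect_lt(abs(m1 - m2), 1e-8)
  }
})

test_that("batch correction is a no-op on a single batch", {
  q <- grid_quant(n_athletes = 1,
                  intensity_fun = function(p, a, arm, o) exp(rnorm(1, 10)))
  pm <- quant_to_matrix(q)
  expect_message(out <- correct_batch_effects(pm), "no-op")
  expect_identical(out$values, pm$values)
})

test_that("batch correction errors on a single-sample batch", {
  q <- grid_quant(n_athletes = 2)
  q <- q[!(q$batch_id == "B02" & q$injection_order > 1), ]
  expect_error(correct_batch_effects(quant_to_matrix(q)), "B02")
})

test_that("batch correction reduces between-batch variance on QC records", {
  worse <- 0
  for (s in 1:20) {
    d <- make_design(6, seed = s)
    a <- make_archetypes(0, 0, 8, seed = s)
    nm <- noise_model(batch_location_sd = 0.4)
    q <- generate_dataset(d, a, nm, seed = s)$quant
    pm0 <- quant_to_matrix(q)
    pm1 <- correct_batch_effects(pm0)
    qc <- pm0$samples$is_qc == 1
    msb <- function(pm) {
      v <- pm$values[, qc, drop = FALSE]
      b <- pm0$samples$batch_id[qc]
      mean(apply(v, 1, function(x) stats::var(tapply(x, b, mean))))
    }
    if (msb(pm1) >= msb(pm0)) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("EB batch correction tracks ComBat on a seeded dataset", {
  g <- tiny_dataset(n_athletes = 5, n_acute = 0, n_chronic = 0,
                    n_null = 30, seed = 21)
  pm <- quant_to_matrix(g$quant)
  ours <- correct_batch_effects(pm)$values
  ref <- sva::ComBat(dat = pm$values, batch = pm$samples$batch_id,
                     par.prior = TRUE, prior.plots = FALSE)
  ## same adjustment up to EB-variant differences: high agreement and a
  ## large reduction vs the uncorrected distance
  expect_gt(stats::cor(as.vector(ours), as.vector(ref)), 0.999)
  expect_lt(mean(abs(ours - ref)), 0.5 * mean(abs(pm$values - ref)))
})

test_that("row-max normalization invariants hold", {
  q <- grid_quant(n_athletes = 2, proteins = c("P1", "P2"),
                  intensity_fun = function(p, a, arm, o)
                    exp(stats::rnorm(1, 3)))
  pm <- normalize_row_max(quant_to_matrix(q))
  expect_equal(unname(apply(pm$values, 1, max)), c(1, 1))
  expect_true(all(pm$values > 0 & pm$values <= 1))
  ## idempotence
  expect_equal(normalize_row_max(pm)$values, pm$values)
  ## scale equivariance: rescaling a row leaves the output unchanged
  q2 <- q
  q2$intensity[q2$protein_id == "P2"] <-
    q2$intensity[q2$protein_id == "P2"] * 37.5
  pm2 <- normalize_row_max(quant_to_matrix(q2))
  expect_equal(pm2$values, pm$values, tolerance = 1e-12)
})

test_that("row-max normalization handles direct arithmetic and errors", {
  ## row [2, 4, 8] -> [0.25, 0.5, 1]
  pm <- structure(list(
    values = log(matrix(c(2, 4, 8), 1, 3,
                        dimnames = list("P1", c("s1", "s2", "s3")))),
    scale = "log",
    samples = data.frame(sample_id = c("s1", "s2", "s3"), is_qc = 0L),
    technical_cv = NULL), class = "protein_matrix")
  out <- normalize_row_max(pm)
  expect_equal(unname(out$values[1, ]), c(0.25, 0.5, 1))
  ## constant row -> all ones
  pm$values[1, ] <- log(7)
  expect_equal(unname(normalize_row_max(pm)$values[1, ]), c(1, 1, 1))
})

test_that("preprocessing order is rollup -> batch -> normalize", {
  g <- tiny_dataset(n_athletes = 4, seed = 31)
  pep <- explode_peptides(g$quant, n_peptides = 4, seed = 31)
  pm <- preprocess_quant(pep)
  expect_equal(pm$scale, "normalized")
  expect_equal(nrow(pm$values), 4)
  expect_false(is.null(pm$technical_cv))
  expect_true(all(apply(pm$values, 1, max) == 1))
})
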