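# Session flags, the eight-category truth table, ensemble fractions and
# reactivation statistics.

test_that("session outcomes map to context flags", {
  f <- session_flags("SAC", "DAC")
  expect_equal(unlist(f), c(a1 = TRUE, a2 = TRUE, b = TRUE))
  f2 <- session_flags("none", "SAC_DELAYED")
  expect_equal(unlist(f2), c(a1 = FALSE, a2 = FALSE, b = TRUE))
  f3 <- session_flags(NA, "none")
  expect_equal(unlist(f3), c(a1 = FALSE, a2 = FALSE, b = FALSE))
  # first-session double activation still only flags context A once
  f4 <- session_flags("DAC", "SAC")
  expect_equal(unlist(f4), c(a1 = TRUE, a2 = TRUE, b = FALSE))
  expect_error(session_flags("SAC", "WAT"), "unknown model kind")
})

test_that("categorisation is the exact eight-row truth table", {
  expect_equal(categorize(1, 1, 1), 1)
  expect_equal(categorize(1, 1, 0), 2)
  expect_equal(categorize(1, 0, 0), 3)
  expect_equal(categorize(0, 1, 0), 4)
  expect_equal(categorize(0, 0, 1), 5)
  expect_equal(categorize(1, 0, 1), 6)
  expect_equal(categorize(0, 1, 1), 7)
  expect_equal(categorize(0, 0, 0), 8)
  # bijection: all 8 triples hit all 8 categories exactly once
  g <- expand.grid(a1 = 0:1, a2 = 0:1, b = 0:1)
  cats <- categorize(g$a1, g$a2, g$b)
  expect_setequal(cats, 1:8)
  expect_equal(anyDuplicated(cats), 0)
})

test_that("ensemble fractions and overlaps are consistent", {
  # every ROI active in session 1 only
  cl3 <- classify_cells(data.frame(roi_id = letters[1:5],
                                   is1_kind = "SAC", is2_kind = "none"))
  fr3 <- ensemble_fractions(cl3)
  expect_equal(fr3$frac_is1, 1)
  expect_equal(fr3$frac_is2, 0)
  expect_equal(fr3$frac_overlap, 0)
  # a single all-context ROI
  cl1 <- classify_cells(data.frame(roi_id = "a", is1_kind = "SAC",
                                   is2_kind = "DAC"))
  fr1 <- ensemble_fractions(cl1)
  expect_equal(fr1$frac_is1, 1)
  expect_equal(fr1$frac_overlap, 1)
  expect_equal(fr1$frac_a2_also_a1, 1)
  expect_error(ensemble_fractions(cl1[0, ]), "no ROIs")
  # fractions from a known mix stay within binomial bounds and sum checks
  set.seed(421)
  fr <- c(0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1, 0.2)
  ds <- gen_dual_session_dataset(300, fr, seed = 33)
  cl <- classify_cells(data.frame(roi_id = ds$truth$roi_id,
                                  is1_kind = ds$truth$is1_kind,
                                  is2_kind = ds$truth$is2_kind))
  expect_equal(cl$category, ds$truth$category)
  f <- ensemble_fractions(cl)
  expect_equal(f$frac_is1, sum(fr[c(1, 2, 3, 6)]), tolerance = 0.01)
  expect_lte(f$frac_overlap, min(f$frac_is1, f$frac_is2))
  expect_true(all(unlist(f[-1]) >= 0 & unlist(f[-1]) <= 1))
  # category fractions over all ROIs sum to one
  expect_equal(sum(table(cl$category)) / nrow(cl), 1)
})

test_that("chance overlap is the product of fractional activations", {
  expect_equal(chance_overlap(0.44, 0.42), 0.1848)
  expect_equal(chance_overlap(0, 0.9), 0)
  expect_equal(chance_overlap(1, 0.37), 0.37)
  expect_error(chance_overlap(1.2, 0.5))
})

test_that("double-activation fractions are compared across conditions", {
  # degenerate pools: all dual-condition cells DAC, all single-condition SAC
  out <- data.frame(
    replicate = rep(c("m1", "m2"), each = 6),
    condition = rep(c("dual", "single"), 6),
    model_kind = rep(c("DAC", "SAC"), 6)
  )
  r <- dac_fraction_comparison(out)
  expect_equal(r$frac_dac_dual, 1)
  expect_equal(r$frac_dac_single, 0)
  # identical per-replicate fractions in both conditions: one-tailed p = 0.5
  out2 <- do.call(rbind, lapply(1:3, function(m) {
    n_dac <- c(4, 5, 6)[m]
    do.call(rbind, lapply(c("dual", "single"), function(cond) {
      data.frame(replicate = paste0("m", m), condition = cond,
                 model_kind = rep(c("DAC", "SAC"), c(n_dac, 10 - n_dac)))
    }))
  }))
  r2 <- dac_fraction_comparison(out2)
  expect_equal(r2$p_value, 0.5, tolerance = 1e-8)
  # a built-in difference like the observed one is detected
  set.seed(422)
  mk <- function(rep_id, cond, frac, n) {
    data.frame(replicate = rep_id, condition = cond,
               model_kind = ifelse(runif(n) < frac, "DAC", "SAC"))
  }
  out3 <- do.call(rbind, c(
    lapply(c("m1", "m2", "m3"), mk, cond = "dual", frac = 0.58, n = 120),
    lapply(c("m1", "m2", "m3"), mk, cond = "single", frac = 0.13, n = 120)
  ))
  r3 <- dac_fraction_comparison(out3)
  expect_equal(r3$frac_dac_dual, 0.58, tolerance = 0.1)
  expect_equal(r3$frac_dac_single, 0.13, tolerance = 0.08)
  expect_lt(r3$p_value, 0.05)
  # fractions are still reported when replicates are too few for a test
  r4 <- dac_fraction_comparison(out3[out3$replicate == "m1", ])
  expect_true(is.na(r4$p_value))
  expect_false(is.na(r4$frac_dac_dual))
})

test_that("reactivation probability is binned by first-session amplitude", {
  is1 <- data.frame(roi_id = sprintf("r%02d", 1:40),
                    amplitude_du = seq(250, 250 + 39 * 100, by = 100))
  # all refit
  all_fit <- data.frame(roi_id = is1$roi_id, refit = TRUE)
  r <- reactivation_probability(is1, all_fit)
  expect_true(all(r$bins$probability == 1))
  expect_true(is.na(r$correlation))
  # none refit
  none <- data.frame(roi_id = is1$roi_id, refit = FALSE)
  r0 <- reactivation_probability(is1, none)
  expect_true(all(r0$bins$probability == 0))
  expect_equal(sum(r0$bins$n_bin), 40)
  # refit probability rising with amplitude gives a positive correlation
  set.seed(423)
  is1b <- data.frame(roi_id = sprintf("s%03d", 1:400),
                     amplitude_du = runif(400, 0, 4000))
  pfit <- pmin(is1b$amplitude_du / 4000, 1)
  is2b <- data.frame(roi_id = is1b$roi_id, refit = runif(400) < pfit,
                     adj_r_sq = runif(400, 0.5, 1))
  rb <- reactivation_probability(is1b, is2b)
  expect_gt(rb$correlation, 0.6)
  expect_true(all(rb$bins$n_fit <= rb$bins$n_bin))
  expect_true(is.finite(rb$adj_r2_slope))
  expect_error(reactivation_probability(is1[0, ], all_fit), "no activated")
})
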