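# Levenberg-Marquardt fitting, goodness of fit, and AIC model selection.

test_that("goodness-of-fit statistics match direct arithmetic", {
  expect_equal(adjusted_r_squared(0, 10, 17, 3), 1)
  expect_lte(adjusted_r_squared(10, 10, 17, 3), 0)
  # spreadsheet oracle: 1 - (rss/(n-p-1)) / (tss/(n-1))
  expect_equal(adjusted_r_squared(0.04 * 50, 50, 17, 3),
               1 - 0.04 * 16 / 13, tolerance = 1e-12)
  expect_warning(r2 <- adjusted_r_squared(1, 0, 17, 3), "undefined")
  expect_true(is.na(r2))

  expect_equal(aic_ls(1700, 17, 3), 17 * log(100) + 8, tolerance = 1e-12)
  # one extra parameter costs 2; halving the rss gains n ln 2
  expect_equal(aic_ls(1234, 20, 4) - aic_ls(1234, 20, 3), 2)
  expect_equal(aic_ls(500, 20, 3) - aic_ls(1000, 20, 3), -20 * log(2))
  expect_identical(aic_ls(0, 17, 3), -Inf)
  # small-sample correction adds 2k(k+1)/(n-k-1)
  expect_equal(aic_ls(1700, 17, 3, corrected = TRUE) - aic_ls(1700, 17, 3),
               2 * 4 * 5 / 12)
})

test_that("noiseless printed parameter sets are recovered exactly", {
  for (r in single_exposure_rows()) {
    f <- fit_sac(gen_trace("SAC", sac_from_row(r), is1_protocol()))
    expect_true(f$converged)
    expect_false(f$degenerate_rates)
    expect_lt(max_param_rel_err(f, r), 1e-3)
  }
  for (r in dual_exposure_sac_rows()) {
    f <- fit_sac(gen_trace("SAC", sac_from_row(r), is2_protocol()))
    expect_lt(max_param_rel_err(f, r), 1e-3)
  }
  for (r in dual_exposure_dac_rows()) {
    f <- fit_dac(gen_trace("DAC", dac_from_row(r), is2_protocol()))
    expect_lt(max_param_rel_err(f, r), 1e-3)
  }
})

test_that("recovery is robust to the choice of initialisation", {
  r <- single_exposure_rows()$cell28
  tr <- gen_trace("SAC", sac_from_row(r), is1_protocol())
  ref <- fit_sac(tr)
  set.seed(411)
  for (i in 1:20) {
    cfg <- fit_config(kf_init = runif(1, 0.002, 0.3),
                      kd_init = runif(1, 0.001, 0.1))
    f <- fit_sac(tr, cfg)
    expect_lt(abs(f$params$kf - ref$params$kf) / ref$params$kf, 1e-3)
    expect_lt(abs(f$params$kd - ref$params$kd) / ref$params$kd, 1e-3)
  }
})

test_that("fits report finite positive standard errors under noise", {
  r <- single_exposure_rows()$cell501
  tr <- gen_trace("SAC", sac_from_row(r), is1_protocol(),
                  noise_model(scale = 0.01, seed = 3))
  f <- fit_sac(tr)
  expect_true(f$converged)
  expect_true(all(is.finite(f$stderr)) && all(f$stderr > 0))
  fd <- fit_dac(gen_trace("DAC", dac_from_row(dual_exposure_dac_rows()$cell328),
                          is2_protocol(), noise_model(scale = 0.01, seed = 4)))
  expect_true(all(is.finite(fd$stderr)) && all(fd$stderr > 0))
})

test_that("near-equal rates trigger the shared-rate refit", {
  # an equal-rate truth has an unidentifiable (kf, kd) split; the fitter
  # reports the shared-rate limit model instead
  p <- kinetic_params(900, 0.02, 0.02)
  f <- fit_sac(gen_trace("SAC", p, is1_protocol()))
  expect_true(f$converged)
  expect_true(f$degenerate_rates)
  expect_equal(f$params$kf, f$params$kd)
  expect_equal(f$params$kf, 0.02, tolerance = 1e-3)
  expect_equal(f$n_params, 2)
  # under noise the fit remains usable whether or not the refit triggers
  fn <- fit_sac(gen_trace("SAC", p, is1_protocol(),
                          noise_model(scale = 0.02, seed = 12)))
  expect_true(fn$converged && fn$identifiable)
  tp_hat <- time_to_peak(fn$params)
  expect_equal(tp_hat, 50, tolerance = 0.1)
})

test_that("degenerate traces yield no activated-cell fit", {
  proto <- is1_protocol()
  zero <- fluorescence_trace("z", proto$time_points,
                             rep(0, 17) + 1e-9 * seq_len(17))
  f <- fit_sac(zero)
  expect_true(!f$converged || is.na(f$adj_r2) || f$adj_r2 < 0.5 ||
                f$params$amplitude < 1e-6)
  set.seed(99)
  flat <- fluorescence_trace("n", proto$time_points, rnorm(17, 0, 5))
  sel <- fit_session(flat, c("SAC"))$selected
  expect_null(sel)
  expect_error(fit_sac(fluorescence_trace("s", c(1, 2, 3), c(0, 1, 2))),
               "at least 5")
})

test_that("model selection prefers the generating model", {
  cfg <- fit_config()
  # noiseless single-activation trace: the simpler model wins on AIC
  tr <- gen_trace("SAC", kinetic_params(1500, 0.0369, 0.016), is2_protocol())
  res <- fit_session(tr, c("SAC", "DAC"), cfg)
  expect_equal(res$selected$model_kind, "SAC")
  # a double-activation trace with a clear second event selects DAC
  trd <- gen_trace("DAC", dual_activation_params(1500, 0.0369, 0.016, 60),
                   is2_protocol(), noise_model(scale = 0.02, seed = 15))
  resd <- fit_session(trd, c("SAC", "SAC_DELAYED", "DAC"), cfg)
  expect_equal(resd$selected$model_kind, "DAC")
  expect_error(select_model(list()), "empty")
})

test_that("raising the activation threshold never adds activated cells", {
  set.seed(413)
  proto <- is1_protocol()
  active_at <- function(thr, traces) {
    vapply(traces, function(tr) {
      !is.null(fit_session(tr, "SAC", fit_config(adj_r2_threshold = thr))$selected)
    }, logical(1))
  }
  traces <- lapply(1:12, function(i) {
    A <- runif(1, 20, 2000)
    gen_trace("SAC", kinetic_params(A, 0.0369, 0.016), proto,
              noise_model("gaussian_additive", scale = 40))
  })
  lo <- active_at(0.3, traces)
  mid <- active_at(0.5, traces)
  hi <- active_at(0.8, traces)
  expect_true(all(mid <= lo))
  expect_true(all(hi <= mid))
})

test_that("fit tables carry the published column layout", {
  fits <- list(
    fit_sac(gen_trace("SAC", sac_from_row(single_exposure_rows()$cell28),
                      is1_protocol())),
    fit_dac(gen_trace("DAC", dac_from_row(dual_exposure_dac_rows()$cell420),
                      is2_protocol()))
  )
  tab <- fit_results_table(fits)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("amplitude_du", "amplitude_err", "kf_per_min", "kf_err",
                    "kd_per_min", "kd_err", "td_min", "td_err", "adj_r_sq",
                    "aic", "model_kind", "converged") %in% names(tab)))
  expect_true(is.na(tab$td_min[1]))
  expect_equal(tab$td_min[2], 88.38919, tolerance = 1e-3)
})
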