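# Trace, population and dual-session generators and their determinism.

test_that("noiseless traces sample the model exactly", {
  p <- kinetic_params(1, 0.1, 0.02)
  tr <- gen_trace("SAC", p, is1_protocol())
  expect_s3_class(tr, "fluorescence_trace")
  expect_equal(tr$time_points, seq(20, 180, by = 10))
  expect_equal(tr$values, sac_value(tr$time_points, p))
  # protocol grid containing t = 0 starts at zero fluorescence
  proto0 <- sampling_protocol("p0", c(0, 10, 20, 30, 40))
  expect_identical(gen_trace("SAC", p, proto0)$values[1], 0)
  # DAC equals SAC before the second event
  pd <- dual_activation_params(1000, 0.05, 0.01, 60)
  trd <- gen_trace("DAC", pd, is1_protocol())
  trs <- gen_trace("SAC", pd, is1_protocol())
  pre <- trd$time_points < 60
  expect_equal(trd$values[pre], trs$values[pre])
  # inactive cells are pure noise about zero
  tri <- gen_trace("INACTIVE", NULL, is1_protocol(),
                   noise_model("gaussian_additive", scale = 2, seed = 8))
  expect_true(all(abs(tri$values) < 10))
})

test_that("generation is bit-identical under a fixed seed", {
  p <- kinetic_params(800, 0.0369, 0.016)
  nz <- noise_model(scale = 0.05, seed = 77)
  expect_identical(gen_trace("SAC", p, is1_protocol(), nz)$values,
                   gen_trace("SAC", p, is1_protocol(), nz)$values)
  pop1 <- gen_population(20, 0.6, 0.2, seed = 5)
  pop2 <- gen_population(20, 0.6, 0.2, seed = 5)
  expect_identical(pop1$truth, pop2$truth)
  expect_identical(traces_to_table(pop1$traces), traces_to_table(pop2$traces))
  tr1 <- single_nucleus_truth()
  s1 <- gen_image_stack(tr1, is1_protocol(), fov = c(96, 96), z_slices = 9,
                        jitter = 2, noise = noise_model(scale = 0.02),
                        seed = 9)
  s2 <- gen_image_stack(tr1, is1_protocol(), fov = c(96, 96), z_slices = 9,
                        jitter = 2, noise = noise_model(scale = 0.02),
                        seed = 9)
  expect_identical(s1$stacks, s2$stacks)
})

test_that("population generator honours fractions and distributions", {
  pop <- gen_population(100, fraction_sac = 1, seed = 31)
  expect_equal(nrow(pop$truth), 100)
  expect_true(all(pop$truth$model_kind == "SAC"))
  empty <- gen_population(0)
  expect_length(empty$traces, 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(gen_population(10, 0.8, 0.5), "fractions")
  # empirical mean of drawn kf within 3 standard errors of the target
  pop2 <- gen_population(500, 1, seed = 32)
  se <- 0.01 / sqrt(500)  # drawing sd of the kf distribution
  expect_lt(abs(mean(pop2$truth$kf) - 0.0369), 3 * se)
  expect_true(all(pop2$truth$kf > 0 & pop2$truth$kd > 0))
  expect_true(all(pop2$truth$amplitude >= 500 & pop2$truth$amplitude <= 5000))
})

test_that("traces round-trip through the long-table format", {
  pop <- gen_population(7, 0.5, 0.3, seed = 44,
                        noise = noise_model(scale = 0.05))
  tab <- traces_to_table(pop$traces)
  expect_equal(nrow(tab), 7 * 17)
  back <- table_to_traces(tab)
  expect_equal(names(back), pop$truth$roi_id)
  expect_equal(back[[3]]$values, pop$traces[[3]]$values)
})

test_that("dual-session generator realises the intended categories", {
  expect_error(gen_dual_session_dataset(10, rep(0.2, 8)), "summing to 1")
  # all cells in the all-contexts category: second session is the
  # two-event profile with the 60-min inter-context delay
  ds <- gen_dual_session_dataset(12, c(1, rep(0, 7)), noise = no_noise(),
                                 seed = 21)
  expect_true(all(ds$truth$category == 1))
  expect_true(all(ds$truth$is2_kind == "DAC"))
  t2 <- is2_protocol()$time_points
  i <- 4
  pd <- dual_activation_params(ds$truth$amplitude[i], ds$truth$kf[i],
                               ds$truth$kd[i], 60)
  expect_equal(ds$is2_traces[[i]]$values, dac_value(t2, pd))
  # never-activated category: no trace rises above the noise
  ds8 <- gen_dual_session_dataset(12, c(rep(0, 7), 1),
                                  noise = noise_model("gaussian_additive",
                                                      scale = 3),
                                  seed = 22)
  allv <- c(traces_to_table(ds8$is1_traces)$value_du,
            traces_to_table(ds8$is2_traces)$value_du)
  expect_true(all(abs(allv) < 3 * 3 * 1.5))
  # a mixed configuration reproduces the requested counts exactly
  fr <- c(0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1, 0.2)
  dsm <- gen_dual_session_dataset(50, fr, seed = 23)
  expect_equal(as.integer(table(factor(dsm$truth$category, levels = 1:8))),
               as.integer(50 * fr))
})

test_that("rendered stacks agree with the trace generator", {
  truth <- single_nucleus_truth(amplitude = 1500)
  proto <- is1_protocol()
  st <- gen_image_stack(truth, proto, fov = c(96, 96), z_slices = 15)
  clean <- sac_value(proto$time_points,
                     kinetic_params(1500, truth$kf, truth$kd))
  # voxel maximum tracks baseline + model value within discretisation
  vmax <- vapply(st$stacks, max, numeric(1))
  expect_equal(vmax, 50 + clean, tolerance = 0.01)
  # empty truth renders pure baseline
  st0 <- gen_image_stack(empty_truth_with_geometry(), proto,
                         fov = c(32, 32), z_slices = 5)
  expect_true(all(vapply(st0$stacks, function(v) all(v == 50), logical(1))))
})

test_that("tiff round trip preserves stacks and manifest", {
  truth <- single_nucleus_truth(fov = c(48, 48), z_slices = 7)
  proto <- sampling_protocol("mini", c(30, 60, 90))
  st <- gen_image_stack(truth, proto, fov = c(48, 48), z_slices = 7)
  dir <- withr::local_tempdir()
  manifest <- write_stack_tiffs(st, dir, prefix = "mini")
  expect_true(all(file.exists(file.path(dir, manifest$filename))))
  back <- read_stack_tiffs(dir, file.path(dir, "mini_manifest.csv"))
  expect_equal(back$time_points, proto$time_points)
  expect_equal(back$stacks[[2]], st$stacks[[2]], tolerance = 1e-6)
})
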