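# ROI re-centering, z profiles, Gaussian peak estimation and full trace
# extraction against generator ground truth.

make_blob_stack <- function(center, value = 600, baseline = 50,
                            dims = c(64, 64, 15), diameter = 20) {
  sigma <- diameter / (2 * sqrt(2 * log(2)))
  vol <- array(baseline, dim = dims)
  gx <- exp(-((seq_len(dims[1]) - 1 - center[1])^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(dims[2]) - 1 - center[2])^2) / (2 * sigma^2))
  gz <- exp(-((seq_len(dims[3]) - 1 - center[3])^2) / (2 * sigma^2))
  vol + value * (gx %o% gy %o% gz)
}

test_that("re-centering finds the blob centre of mass", {
  vol <- make_blob_stack(c(31, 33, 7))
  roi <- roi_spec("r", c(31, 33, 7), 10)
  rc <- recenter_roi(vol, roi)
  expect_lt(sqrt(sum((rc$center[1:2] - c(31, 33))^2)), 0.1)
  # blob shifted +3 px in x relative to the nominal centre
  vol_sh <- make_blob_stack(c(34, 33, 7))
  rc_sh <- recenter_roi(vol_sh, roi)
  expect_lt(abs(rc_sh$center[1] - 34), 0.5)
  expect_lt(abs(rc_sh$center[2] - 33), 0.5)
  expect_equal(rc_sh$shift[["dx"]], rc_sh$center[1] - 31)
  # a uniform region is flagged and left unchanged
  flat <- array(7, dim = c(64, 64, 15))
  rc_flat <- recenter_roi(flat, roi)
  expect_equal(rc_flat$center, roi$center)
  expect_true("recenter_flat" %in% rc_flat$flags)
  # the input ROI is never modified
  expect_equal(roi$center, c(31, 33, 7))
})

test_that("z profiles average the ROI footprint per slice", {
  const <- array(12.5, dim = c(32, 32, 9))
  roi <- roi_spec("r", c(15, 15, 4), 6)
  prof <- z_mean_profile(const, roi)
  expect_equal(prof$mean_intensity, rep(12.5, 9))
  # Gaussian blob produces a Gaussian z profile with the generator sigma
  vol <- make_blob_stack(c(31, 33, 7), dims = c(64, 64, 15))
  prof2 <- z_mean_profile(vol, roi_spec("r", c(31, 33, 7), 10))
  zf <- fit_gaussian_z(prof2)
  expect_true(zf$converged)
  expect_equal(zf$sigma, 20 / (2 * sqrt(2 * log(2))), tolerance = 0.02)
  expect_equal(zf$z_center, 7, tolerance = 0.02)
  # single-slice stack degrades to its own maximum, flagged
  single <- array(3, dim = c(32, 32, 1))
  prof1 <- z_mean_profile(single, roi)
  expect_length(prof1$mean_intensity, 1)
  zf1 <- fit_gaussian_z(prof1)
  expect_false(zf1$converged)
  expect_equal(zf1$peak_value, 3)
})

test_that("gaussian z fit recovers exact profiles and handles flats", {
  z <- 0:20
  y <- 50 + 500 * exp(-(z - 10)^2 / (2 * 3^2))
  prof <- structure(list(z_positions = z, mean_intensity = y),
                    class = "z_profile")
  zf <- fit_gaussian_z(prof)
  expect_equal(zf$offset, 50, tolerance = 1e-6)
  expect_equal(zf$height, 500, tolerance = 1e-6)
  expect_equal(zf$z_center, 10, tolerance = 1e-6)
  expect_equal(zf$sigma, 3, tolerance = 1e-6)
  expect_equal(zf$peak_value, 550, tolerance = 1e-6)
  flat <- structure(list(z_positions = z, mean_intensity = rep(80, 21)),
                    class = "z_profile")
  zff <- fit_gaussian_z(flat)
  expect_equal(zff$peak_value, 80, tolerance = 1e-3)
})

test_that("extracted traces match generator truth", {
  truth <- single_nucleus_truth(amplitude = 1000)
  proto <- is1_protocol()
  clean <- sac_value(proto$time_points,
                     kinetic_params(1000, truth$kf, truth$kd))
  st <- gen_image_stack(truth, proto, fov = c(96, 96), z_slices = 15)
  roi <- roi_spec("c1", c(truth$x, truth$y, truth$z), truth$diameter / 2)
  tr <- extract_trace(st$stacks, roi, proto)
  expect_lt(max(abs(tr$values - clean) / pmax(clean, 1)), 0.02)
  # idempotence
  tr2 <- extract_trace(st$stacks, roi, proto)
  expect_identical(tr$values, tr2$values)
  # per-time-point rigid jitter is absorbed by re-centering
  stj <- gen_image_stack(truth, proto, fov = c(96, 96), z_slices = 15,
                         jitter = 3, seed = 6)
  trj <- extract_trace(stj$stacks, roi, proto)
  expect_lt(max(abs(trj$values - tr$values) / pmax(clean, 1)), 0.03)
  # an inactive nucleus stays at zero after background subtraction
  truth0 <- truth
  truth0$model_kind <- "INACTIVE"
  st0 <- gen_image_stack(truth0, proto, fov = c(96, 96), z_slices = 15,
                         noise = noise_model("gaussian_additive", scale = 2),
                         seed = 7)
  tr0 <- extract_trace(st0$stacks, roi, proto)
  expect_true(all(abs(tr0$values) < 3 * 2 * lateral_scale_for_tests()))
})

test_that("extraction responds linearly and ignores constant offsets", {
  truth <- single_nucleus_truth(amplitude = 800)
  proto <- sampling_protocol("mini", seq(20, 120, by = 20))
  st <- gen_image_stack(truth, proto, fov = c(96, 96), z_slices = 15)
  roi <- roi_spec("c1", c(truth$x, truth$y, truth$z), 10)
  tr <- extract_trace(st$stacks, roi, proto)
  # scaling every voxel (signal and background) scales the trace
  st_scaled <- lapply(st$stacks, function(v) v * 3)
  tr3 <- extract_trace(st_scaled, roi, proto)
  expect_equal(tr3$values, 3 * tr$values, tolerance = 1e-3)
  # adding a constant to every voxel is absorbed by background subtraction
  st_off <- lapply(st$stacks, function(v) v + 200)
  troff <- extract_trace(st_off, roi, proto)
  expect_lt(max(abs(troff$values - tr$values)) / max(tr$values), 0.005)
})

test_that("missing stacks are reported with their time points", {
  truth <- single_nucleus_truth()
  proto <- sampling_protocol("mini", c(30, 60, 90))
  st <- gen_image_stack(truth, proto, fov = c(96, 96), z_slices = 9)
  roi <- roi_spec("c1", c(truth$x, truth$y, truth$z), 10)
  broken <- st$stacks
  broken[2] <- list(NULL)
  expect_error(extract_trace(broken, roi, proto), "60")
  expect_error(extract_trace(st$stacks[1:2], roi, proto), "per time point")
})
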