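# Rendering synthetic 4D image stacks (x, y, z, t) from a population truth
# table: nuclei as isotropic 3D Gaussian blobs whose peak follows the
# kinetic model, with optional rigid per-time-point jitter and noise.
#
# Coordinate convention: continuous 0-based voxel coordinates, x fastest;
# the centre of 1-based array voxel [i, j, k] is (i-1, j-1, k-1).

#' Attach nucleus geometry to a population truth table
#'
#' Places nuclei on a jittered grid inside the field of view with a
#' margin of at least one diameter from every edge, and records diameter
#' and baseline so that stacks and traces generated from the same truth
#' are mutually consistent.
#'
#' @param truth Truth data frame from [gen_population()] or
#'   [gen_dual_session_dataset()].
#' @param fov Field of view `c(nx, ny)` in pixels.
#' @param z_slices Number of z slices.
#' @param diameter Nucleus diameter (lateral Gaussian FWHM), pixels;
#'   default 20, the apparent size of a nucleus at this magnification.
#' @param baseline Background fluorescence, D.U.
#' @param seed Optional integer seed for the placement jitter.
#' @return The truth table with columns `x`, `y`, `z`, `diameter`,
#'   `baseline` appended.
#' @export
add_nucleus_geometry <- function(truth, fov = c(160, 160), z_slices = 15,
                                 diameter = 20, baseline = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  margin <- diameter
  span <- fov - 2 * margin
  if (any(span <= 0)) stop("field of view too small for the margin",
                           call. = FALSE)
  # three-diameter grid spacing keeps the Gaussian halo of one nucleus
  # (substantial out to ~1.5 diameters) out of its neighbours' measurement
  # annuli
  spacing <- 3 * diameter
  per_row <- max(1, floor(span[1] / spacing))
  per_col <- max(1, floor(span[2] / spacing))
  if (n > per_row * per_col) {
    stop(sprintf("cannot place %d nuclei in a %dx%d field at diameter %g",
                 n, fov[1], fov[2], diameter), call. = FALSE)
  }
  idx <- seq_len(n) - 1
  gx <- margin + (idx %% per_row) * spacing + spacing / 2
  gy <- margin + (idx %/% per_row) * spacing + spacing / 2
  truth$x <- gx + stats::runif(n, -2, 2)
  truth$y <- gy + stats::runif(n, -2, 2)
  truth$z <- (z_slices - 1) / 2 + stats::runif(n, -1, 1)
  truth$diameter <- diameter
  truth$baseline <- baseline
  truth
}

# FWHM -> Gaussian sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Gaussian blob window (indices and values) for one nucleus, evaluated
# inside a +/- 4 sigma box; the caller adds it into the volume in place
blob_window <- function(dims, cx, cy, cz, value, sigma_l, sigma_z) {
  wx <- max(1, ceiling(cx + 1 - 4 * sigma_l)):min(dims[1], floor(cx + 1 + 4 * sigma_l))
  wy <- max(1, ceiling(cy + 1 - 4 * sigma_l)):min(dims[2], floor(cy + 1 + 4 * sigma_l))
  wz <- max(1, ceiling(cz + 1 - 4 * sigma_z)):min(dims[3], floor(cz + 1 + 4 * sigma_z))
  gx <- exp(-((wx - 1 - cx)^2) / (2 * sigma_l^2))
  gy <- exp(-((wy - 1 - cy)^2) / (2 * sigma_l^2))
  gz <- exp(-((wz - 1 - cz)^2) / (2 * sigma_z^2))
  list(wx = wx, wy = wy, wz = wz, blob = value * (gx %o% gy %o% gz))
}

#' Render a synthetic 4D image stack from a truth table
#'
#' One 3D volume per protocol time point. Each nucleus is an isotropic 3D
#' Gaussian blob with lateral FWHM equal to its diameter whose peak voxel
#' intensity at time t is `baseline + model value(t)`. A rigid lateral
#' jitter (uniform within `[-jitter, jitter]` px per axis, shared by all
#' nuclei at a time point) exercises the ROI re-centering step
#' downstream. The returned ROI table holds the nominal (unjittered)
#' centres with radius `diameter / 2`.
#'
#' @param truth Truth table with geometry columns (see
#'   [add_nucleus_geometry()]).
#' @param protocol A [sampling_protocol()].
#' @param fov Field of view `c(nx, ny)`, pixels.
#' @param z_slices Number of z slices.
#' @param psf_sigma Additional optical blur sigma, px, added in quadrature
#'   to the nucleus sigma (default 0).
#' @param axial_fwhm Axial FWHM of the blob, px; defaults to the nucleus
#'   diameter (isotropic).
#' @param jitter Maximum rigid lateral shift per time point, px.
#' @param noise A [noise_model()] applied voxel-wise.
#' @param seed Optional integer seed (jitter and noise).
#' @return List with `stacks` (list of 3D arrays, one per time point),
#'   `roi_table` (roi_id, x, y, z, radius), `time_points`, `shifts`
#'   (per-time-point applied jitter) and `baseline`.
#' @export
gen_image_stack <- function(truth, protocol, fov = c(160, 160), z_slices = 15,
                            psf_sigma = 0, axial_fwhm = NULL, jitter = 0,
                            noise = no_noise(), seed = NULL) {
  stopifnot(inherits(protocol, "sampling_protocol"))
  if (!is.null(seed)) set.seed(seed)
  noise$seed <- NULL
  n <- nrow(truth)
  baseline <- if (n > 0) truth$baseline[1] else 50
  if (n > 0) {
    need <- c("x", "y", "z", "diameter", "baseline", "model_kind",
              "amplitude", "kf", "kd")
    missing <- setdiff(need, names(truth))
    if (length(missing) > 0) {
      stop("truth table lacks columns: ", paste(missing, collapse = ", "),
           "; run add_nucleus_geometry() first", call. = FALSE)
    }
    # neighbours closer than one diameter contaminate each other's ROI
    if (n > 1) {
      dmat <- as.matrix(stats::dist(truth[, c("x", "y")]))
      diag(dmat) <- Inf
      if (min(dmat) < max(truth$diameter)) {
        warning("some nuclei are closer than one diameter; their traces may overlap")
      }
    }
  }
  tp <- protocol$time_points
  shifts <- matrix(0, nrow = length(tp), ncol = 2,
                   dimnames = list(NULL, c("dx", "dy")))
  if (jitter > 0) {
    shifts[, 1] <- stats::runif(length(tp), -jitter, jitter)
    shifts[, 2] <- stats::runif(length(tp), -jitter, jitter)
  }
  stacks <- vector("list", length(tp))
  for (ti in seq_along(tp)) {
    vol <- array(baseline, dim = c(fov[1], fov[2], z_slices))
    for (i in seq_len(n)) {
      value <- switch(truth$model_kind[i],
        SAC = sac_value_raw(tp[ti], truth$amplitude[i], truth$kf[i], truth$kd[i]),
        DAC = dac_value_raw(tp[ti], truth$amplitude[i], truth$kf[i],
                            truth$kd[i], truth$td[i]),
        SAC_DELAYED = if (tp[ti] >= 60)
          sac_value_raw(tp[ti] - 60, truth$amplitude[i], truth$kf[i],
                        truth$kd[i]) else 0,
        INACTIVE = 0
      )
      if (value <= 0) next
      sigma_l <- sqrt(fwhm_to_sigma(truth$diameter[i])^2 + psf_sigma^2)
      sigma_z <- fwhm_to_sigma(if (is.null(axial_fwhm)) truth$diameter[i]
                               else axial_fwhm)
      b <- blob_window(dim(vol), truth$x[i] + shifts[ti, 1],
                       truth$y[i] + shifts[ti, 2], truth$z[i],
                       value, sigma_l, sigma_z)
      vol[b$wx, b$wy, b$wz] <- vol[b$wx, b$wy, b$wz] + b$blob
    }
    if (noise$scale > 0 || noise$floor > 0) {
      vol <- array(apply_noise(as.vector(vol), noise), dim = dim(vol))
    }
    stacks[[ti]] <- vol
  }
  roi_table <- if (n > 0) {
    data.frame(roi_id = truth$roi_id, x = truth$x, y = truth$y, z = truth$z,
               radius = truth$diameter / 2, stringsAsFactors = FALSE)
  } else {
    data.frame(roi_id = character(), x = numeric(), y = numeric(),
               z = numeric(), radius = numeric())
  }
  list(stacks = stacks, roi_table = roi_table, time_points = tp,
       shifts = shifts, baseline = baseline)
}

#' Write a stack series as multi-page TIFF files with a manifest
#'
#' One 32-bit float multi-page TIFF per time point (pages are z slices;
#' intensities stored as D.U. / `scale` so they fit the unit range), plus
#' a manifest CSV mapping time to file.
#'
#' @param stack_set Result of [gen_image_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param scale Intensity divisor bringing D.U. into `[0, 1]` for
#'   storage (default 65535); recorded in the manifest.
#' @return Invisibly, the manifest data frame (time_min, filename, scale).
#' @export
write_stack_tiffs <- function(stack_set, dir, prefix = "stack", scale = 65535) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(stack_set$time_points))
  for (ti in seq_along(stack_set$time_points)) {
    vol <- stack_set$stacks[[ti]]
    pages <- lapply(seq_len(dim(vol)[3]), function(k) {
      # tiff expects row-major matrices in [0,1]; store y as rows
      t(vol[, , k]) / scale
    })
    files[ti] <- sprintf("%s_t%03d.tif", prefix, ti)
    tiff::writeTIFF(pages, file.path(dir, files[ti]), bits.per.sample = 32L)
  }
  manifest <- data.frame(time_min = stack_set$time_points, filename = files,
                         scale = scale, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a stack series written by [write_stack_tiffs()]
#'
#' @param dir Directory holding the TIFFs and manifest.
#' @param manifest Manifest data frame or path to the manifest CSV.
#' @return List with `stacks` (3D arrays in D.U.) and `time_points`.
#' @export
read_stack_tiffs <- function(dir, manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stacks <- lapply(seq_len(nrow(manifest)), function(ti) {
    pages <- tiff::readTIFF(file.path(dir, manifest$filename[ti]), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vol <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) vol[, , k] <- t(pages[[k]])
    vol * manifest$scale[ti]
  })
  list(stacks = stacks, time_points = manifest$time_min)
}
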