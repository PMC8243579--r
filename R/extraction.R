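# Converting a 4D stack plus ROI table into per-cell fluorescence traces:
# centre-of-mass ROI re-centering, mean-intensity z profiles, Gaussian
# z-profile peak estimation, and background subtraction.
#
# ROIs are shifted to follow the cell; images are never resampled or
# registered. Coordinates are continuous 0-based voxel indices (the centre
# of 1-based array voxel [i, j, k] is (i-1, j-1, k-1)); the ROI footprint
# is the set of pixels whose centre lies strictly within `radius` of the
# ROI centre, laterally.

#' Region-of-interest specification
#'
#' @param roi_id Label.
#' @param center Nucleus centre `c(x, y, z)` in 0-based voxel coordinates
#'   (z in slices).
#' @param radius Lateral ROI radius, pixels; > 0.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(roi_id, center, radius) {
  stopifnot(length(center) == 3, all(is.finite(center)), radius > 0)
  structure(list(roi_id = as.character(roi_id),
                 center = as.numeric(center), radius = radius,
                 flags = character()),
            class = "roi_spec")
}

# lateral footprint of an ROI: 1-based array indices and mask
roi_footprint <- function(dims, center, radius) {
  xr <- max(1, ceiling(center[1] + 1 - radius)):min(dims[1], floor(center[1] + 1 + radius))
  yr <- max(1, ceiling(center[2] + 1 - radius)):min(dims[2], floor(center[2] + 1 + radius))
  if (length(xr) == 0 || length(yr) == 0) {
    stop("ROI footprint lies outside the image", call. = FALSE)
  }
  dx <- xr - 1 - center[1]
  dy <- yr - 1 - center[2]
  mask <- outer(dx^2, dy^2, "+") < radius^2
  list(xr = xr, yr = yr, mask = mask)
}

# z slices spanned by the ROI (its centre +/- radius)
roi_z_range <- function(dims, center, radius) {
  max(1, ceiling(center[3] + 1 - radius)):min(dims[3], floor(center[3] + 1 + radius))
}

#' Re-centre an ROI on the local centre of mass
#'
#' Corrects frame-to-frame misalignment by moving the ROI centre to the
#' intensity-weighted centroid of the pixels within `search_radius` of
#' the nominal centre, computed on the maximum-intensity projection over
#' the ROI's z range. The local minimum is subtracted before weighting so
#' a uniform background does not bias the centroid. A flat neighbourhood
#' (no intensity contrast) leaves the centre unchanged and flags the ROI.
#'
#' @param stack 3D array (x, y, z) at one time point.
#' @param roi A [roi_spec()].
#' @param search_radius Search radius, px; defaults to the ROI radius.
#' @param iterations Centroid refinement passes (default 3): a blob that
#'   is off-centre in the search disc gives a centroid biased towards the
#'   disc centre; re-centering the disc on each estimate removes the bias.
#' @return A new [roi_spec()] with the updated lateral centre; fields
#'   `shift` (dx, dy) and `flags` record what happened. The input ROI is
#'   not modified. The total displacement is capped at `search_radius`.
#' @export
recenter_roi <- function(stack, roi, search_radius = roi$radius,
                         iterations = 3) {
  dims <- dim(stack)
  zr <- roi_z_range(dims, roi$center, roi$radius)
  out <- roi_spec(roi$roi_id, roi$center, roi$radius)
  out$flags <- roi$flags
  centre <- roi$center[1:2]
  for (it in seq_len(iterations)) {
    fp <- roi_footprint(dims, c(centre, roi$center[3]), search_radius)
    # maximum-intensity projection restricted to the search window
    w <- Reduce(pmax, lapply(zr, function(k) {
      stack[fp$xr, fp$yr, k, drop = FALSE][, , 1]
    }))
    w <- matrix(w, nrow = length(fp$xr))
    w[!fp$mask] <- NA
    rng <- range(w, na.rm = TRUE)
    if (!all(is.finite(rng)) || diff(rng) <= 0) {
      if (it == 1) {
        out$flags <- c(out$flags, "recenter_flat")
        out$shift <- c(dx = 0, dy = 0)
        return(out)
      }
      break
    }
    w <- w - rng[1]
    w[is.na(w)] <- 0
    new_centre <- c(sum(w * (fp$xr - 1)), sum(t(w) * (fp$yr - 1))) / sum(w)
    moved <- sqrt(sum((new_centre - centre)^2))
    centre <- new_centre
    if (moved < 0.01) break
  }
  # never move further than the search radius from the nominal centre
  disp <- centre - roi$center[1:2]
  d <- sqrt(sum(disp^2))
  if (d > search_radius) {
    disp <- disp * search_radius / d
    centre <- roi$center[1:2] + disp
  }
  out$center[1:2] <- centre
  out$shift <- c(dx = disp[[1]], dy = disp[[2]])
  out
}

#' Mean-intensity z profile of an ROI
#'
#' For each z slice, the mean intensity over the circular lateral ROI
#' footprint.
#'
#' @param stack 3D array (x, y, z) at one time point.
#' @param roi A [roi_spec()].
#' @return An object of class `z_profile`: list with `z_positions`
#'   (0-based slice indices) and `mean_intensity` (D.U.).
#' @export
z_mean_profile <- function(stack, roi) {
  dims <- dim(stack)
  fp <- roi_footprint(dims, roi$center, roi$radius)
  if (!any(fp$mask)) stop("empty ROI footprint", call. = FALSE)
  prof <- vapply(seq_len(dims[3]), function(k) {
    sl <- stack[fp$xr, fp$yr, k, drop = FALSE][, , 1]
    mean(sl[fp$mask])
  }, numeric(1))
  structure(list(z_positions = seq_len(dims[3]) - 1, mean_intensity = prof),
            class = "z_profile")
}

#' Gaussian fit to a z profile
#'
#' Least-squares fit of `offset + height * exp(-(z - z0)^2 / (2 sigma^2))`
#' to the per-slice mean intensities; the profile's peak
#' (`offset + height`) estimates the ROI activity at that time point.
#' With fewer than 5 profile points, or when the fit fails, the maximum
#' of the profile is returned instead and the result flagged.
#'
#' @param profile A [z_mean_profile()] result.
#' @return List with `peak_value`, `z_center`, `sigma`, `offset`,
#'   `height`, `converged` and `flags`.
#' @export
fit_gaussian_z <- function(profile) {
  stopifnot(inherits(profile, "z_profile"))
  z <- profile$z_positions
  y <- profile$mean_intensity
  fallback <- list(peak_value = max(y), z_center = z[which.max(y)],
                   sigma = NA_real_, offset = min(y),
                   height = max(y) - min(y), converged = FALSE,
                   flags = "zfit_fallback_max")
  if (length(z) < 5) return(fallback)
  d <- data.frame(z = z, y = y)
  fit <- safe_nlsLM(
    y ~ offset + height * exp(-(z - z0)^2 / (2 * sigma^2)), d,
    start = list(offset = min(y), height = max(y) - min(y),
                 z0 = z[which.max(y)], sigma = max(length(z) / 4, 1)),
    lower = c(-Inf, 0, min(z) - length(z), 1e-3),
    upper = c(Inf, Inf, max(z) + length(z), Inf),
    maxiter = 100
  )
  if (is.null(fit)) return(fallback)
  est <- stats::coef(fit)
  list(peak_value = unname(est["offset"] + est["height"]),
       z_center = unname(est["z0"]), sigma = unname(est["sigma"]),
       offset = unname(est["offset"]), height = unname(est["height"]),
       converged = TRUE, flags = character())
}

# Lateral disc-averaging correction: the z profile averages the blob over
# the ROI disc, attenuating its peak; for a Gaussian nucleus with lateral
# FWHM equal to the ROI diameter the attenuation is exactly 1 / (2 ln 2).
# The annulus background estimate additionally carries the nucleus halo at
# the annulus' median radius sqrt(6.5) r, i.e. 2^-6.5 of the peak, which
# the subtraction removes from the signal; both follow from the same
# convention, so the combined factor is closed-form.
lateral_disc_correction <- function(background_method = "annulus") {
  disc_mean <- 1 / (2 * log(2))
  halo <- if (background_method == "annulus") 2^-6.5 else 0
  1 / (disc_mean - halo)
}

#' Extract a fluorescence trace from a stack series
#'
#' Per time point: re-centre the ROI on its centre of mass, compute the
#' mean-intensity z profile, estimate the profile peak by a Gaussian fit,
#' subtract the background, and rescale the disc-averaged signal to the
#' nucleus peak (assuming a Gaussian nucleus with FWHM equal to the ROI
#' diameter). Background is the median intensity of an annulus one to two
#' radii outside the ROI over its z range, or the global volume median.
#'
#' @param stacks List of 3D arrays, one per protocol time point (e.g.
#'   `gen_image_stack()$stacks` or [read_stack_tiffs()]).
#' @param roi A [roi_spec()] (nominal centre at the first time point).
#' @param protocol A [sampling_protocol()] with one time point per stack.
#' @param background_method `"annulus"` (default) or `"global"`.
#' @param recenter Re-centre the ROI at each time point (default TRUE).
#' @param correct_disc_averaging Rescale by the lateral disc-averaging
#'   factor so extracted values sit on the blob-peak intensity scale
#'   (default TRUE).
#' @return A [fluorescence_trace()]; attribute `diagnostics` holds a data
#'   frame of per-time-point background, re-centering shifts and flags.
#' @export
extract_trace <- function(stacks, roi, protocol,
                          background_method = c("annulus", "global"),
                          recenter = TRUE, correct_disc_averaging = TRUE) {
  background_method <- match.arg(background_method)
  stopifnot(inherits(protocol, "sampling_protocol"))
  tp <- protocol$time_points
  if (length(stacks) != length(tp)) {
    stop(sprintf("need one stack per time point: %d stacks for %d points",
                 length(stacks), length(tp)), call. = FALSE)
  }
  missing <- which(vapply(stacks, is.null, logical(1)))
  if (length(missing) > 0) {
    stop("missing stacks for time points (min): ",
         paste(tp[missing], collapse = ", "), call. = FALSE)
  }
  scale <- if (correct_disc_averaging)
    lateral_disc_correction(background_method) else 1
  values <- background <- dx <- dy <- numeric(length(tp))
  flags <- character(length(tp))
  current <- roi
  for (ti in seq_along(tp)) {
    vol <- stacks[[ti]]
    current <- roi_spec(current$roi_id, c(roi$center[1], roi$center[2],
                                          roi$center[3]), roi$radius)
    if (recenter) current <- recenter_roi(vol, current)
    prof <- z_mean_profile(vol, current)
    zfit <- fit_gaussian_z(prof)
    bg <- roi_background(vol, current, background_method)
    values[ti] <- (zfit$peak_value - bg) * scale
    background[ti] <- bg
    dx[ti] <- if (recenter) current$shift[["dx"]] else 0
    dy[ti] <- if (recenter) current$shift[["dy"]] else 0
    flags[ti] <- paste(c(current$flags, zfit$flags), collapse = ";")
  }
  tr <- fluorescence_trace(roi$roi_id, tp, values, background)
  attr(tr, "diagnostics") <- data.frame(
    time_min = tp, background_du = background, recenter_dx = dx,
    recenter_dy = dy, flags = flags, stringsAsFactors = FALSE)
  tr
}

# background estimate for one ROI at one time point
roi_background <- function(stack, roi, method) {
  if (method == "global") return(stats::median(stack))
  dims <- dim(stack)
  outer_fp <- roi_footprint(dims, roi$center, 3 * roi$radius)
  dx <- outer_fp$xr - 1 - roi$center[1]
  dy <- outer_fp$yr - 1 - roi$center[2]
  d2 <- outer(dx^2, dy^2, "+")
  # one to two radii beyond the ROI boundary, clear of the nucleus halo
  annulus <- d2 >= (2 * roi$radius)^2 & d2 < (3 * roi$radius)^2
  if (!any(annulus)) return(stats::median(stack))
  zr <- roi_z_range(dims, roi$center, roi$radius)
  vals <- vapply(zr, function(k) {
    sl <- stack[outer_fp$xr, outer_fp$yr, k, drop = FALSE][, , 1]
    stats::median(sl[annulus])
  }, numeric(1))
  stats::median(vals)
}

#' Extract traces for every ROI in a table
#'
#' @param stacks List of 3D arrays, one per time point.
#' @param roi_table Data frame with columns roi_id, x, y, z, radius.
#' @param protocol A [sampling_protocol()].
#' @param ... Passed to [extract_trace()].
#' @return Named list of [fluorescence_trace()] objects.
#' @export
extract_all_traces <- function(stacks, roi_table, protocol, ...) {
  out <- lapply(seq_len(nrow(roi_table)), function(i) {
    roi <- roi_spec(roi_table$roi_id[i],
                    c(roi_table$x[i], roi_table$y[i], roi_table$z[i]),
                    roi_table$radius[i])
    extract_trace(stacks, roi, protocol, ...)
  })
  names(out) <- roi_table$roi_id
  out
}
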