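# Synthetic fluorescence traces with known ground truth.
#
# The generators emulate the two in vivo imaging protocols: IS1 samples
# 20-180 min after the single context exposure, IS2 samples 90-300 min
# after the first of two exposures 60 min apart, both at ~10 min intervals.

#' Imaging-session sampling protocol
#'
#' @param name Session label, e.g. `"IS1"`.
#' @param time_points Strictly increasing imaging times, minutes
#'   (laboratory time, 0 = first triggering event of the session).
#' @param context_events Optional data frame (`label`, `time`) of context
#'   exposures within the session.
#' @return An object of class `sampling_protocol`.
#' @export
#' @examples
#' is1_protocol()
#' is2_protocol()
sampling_protocol <- function(name, time_points,
                              context_events = data.frame(label = character(),
                                                          time = numeric())) {
  if (!is.numeric(time_points) || length(time_points) == 0 ||
      any(!is.finite(time_points)) || any(time_points < 0)) {
    stop("'time_points' must be non-negative finite numbers", call. = FALSE)
  }
  if (is.unsorted(time_points, strictly = TRUE)) {
    stop("'time_points' must be strictly increasing", call. = FALSE)
  }
  if (nrow(context_events) > 0 && any(context_events$time < 0)) {
    stop("context event times must be >= 0", call. = FALSE)
  }
  structure(list(name = name, time_points = as.numeric(time_points),
                 context_events = context_events),
            class = "sampling_protocol")
}

#' @export
print.sampling_protocol <- function(x, ...) {
  cat(sprintf("Sampling protocol '%s': %d time points, %g-%g min\n",
              x$name, length(x$time_points),
              min(x$time_points), max(x$time_points)))
  if (nrow(x$context_events) > 0) {
    cat("  context events:",
        paste(sprintf("%s@%g min", x$context_events$label,
                      x$context_events$time), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default first imaging session (single context exposure)
#'
#' Imaging 20-180 min after the context-A exposure at 10-min intervals.
#' @return A [sampling_protocol()].
#' @export
is1_protocol <- function() {
  sampling_protocol("IS1", seq(20, 180, by = 10),
                    data.frame(label = "CtxtA", time = 0))
}

#' Default second imaging session (dual context exposure)
#'
#' Context A at 0 min, context B at 60 min, imaging 90-300 min at 10-min
#' intervals.
#' @return A [sampling_protocol()].
#' @export
is2_protocol <- function() {
  sampling_protocol("IS2", seq(90, 300, by = 10),
                    data.frame(label = c("CtxtA", "CtxtB"), time = c(0, 60)))
}

#' Measurement noise model
#'
#' @param kind One of `"gaussian_multiplicative"` (sd = `scale` x signal),
#'   `"gaussian_additive"` (sd = `scale` D.U.) or `"poisson"` (counts with
#'   mean = signal). All kinds add an optional additive Gaussian noise floor
#'   of sd `floor` D.U., representing detector noise independent of signal.
#' @param scale Noise scale: a dimensionless fraction for the
#'   multiplicative kind, D.U. otherwise; >= 0.
#' @param floor Additive noise floor sd, D.U.; >= 0 (default 0).
#' @param seed Optional integer seed making generation reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian_multiplicative",
                                 "gaussian_additive", "poisson"),
                        scale = 0.05, floor = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale < 0) {
    stop("'scale' must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) || floor < 0) {
    stop("'floor' must be a single number >= 0", call. = FALSE)
  }
  structure(list(kind = kind, scale = scale, floor = floor, seed = seed),
            class = "noise_model")
}

#' Zero-noise model (traces equal the model exactly)
#' @return A [noise_model()] with scale and floor 0.
#' @export
no_noise <- function() noise_model("gaussian_additive", scale = 0, floor = 0)

# apply a noise model to noiseless signal values
apply_noise <- function(values, noise) {
  n <- length(values)
  out <- switch(noise$kind,
    gaussian_multiplicative = values * (1 + stats::rnorm(n, 0, noise$scale)),
    gaussian_additive = values + stats::rnorm(n, 0, noise$scale),
    poisson = stats::rpois(n, lambda = pmax(values, 0))
  )
  if (noise$floor > 0) out <- out + stats::rnorm(n, 0, noise$floor)
  out
}

#' Fluorescence trace container
#'
#' A background-referenced per-ROI time series in detector units.
#'
#' @param roi_id ROI label.
#' @param time_points Strictly increasing times, minutes.
#' @param values Fluorescence values, D.U. (background already subtracted).
#' @param background Background level(s) subtracted, D.U. (scalar or one
#'   per time point; informational).
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(roi_id, time_points, values, background = 0) {
  if (length(time_points) != length(values)) {
    stop("'time_points' and 'values' must have equal length", call. = FALSE)
  }
  if (is.unsorted(time_points, strictly = TRUE)) {
    stop("'time_points' must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("trace values must be finite", call. = FALSE)
  structure(list(roi_id = as.character(roi_id),
                 time_points = as.numeric(time_points),
                 values = as.numeric(values),
                 background = background),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace '%s': %d points, %g-%g min, peak %.4g D.U.\n",
              x$roi_id, length(x$values), min(x$time_points),
              max(x$time_points), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.fluorescence_trace <- function(x, ...) {
  data.frame(roi_id = x$roi_id, time_min = x$time_points,
             value_du = x$values, stringsAsFactors = FALSE)
}

#' Generate one synthetic fluorescence trace
#'
#' Samples the kinetic model at the protocol's time points and applies
#' measurement noise. `"INACTIVE"` cells yield a baseline-only (noise
#' floor) trace.
#'
#' @param model_kind `"SAC"`, `"DAC"` or `"INACTIVE"`.
#' @param params [kinetic_params()] for SAC, [dual_activation_params()] for
#'   DAC; ignored for INACTIVE.
#' @param protocol A [sampling_protocol()].
#' @param noise A [noise_model()]; its `seed`, when set, makes the trace
#'   reproducible.
#' @param roi_id ROI label for the resulting trace.
#' @return A [fluorescence_trace()].
#' @export
#' @examples
#' p <- kinetic_params(1000, 0.0369, 0.0062)
#' tr <- gen_trace("SAC", p, is1_protocol(), noise_model(scale = 0.05, seed = 1))
gen_trace <- function(model_kind = c("SAC", "DAC", "INACTIVE"),
                      params = NULL, protocol, noise = no_noise(),
                      roi_id = "roi_1") {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(protocol, "sampling_protocol"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  t <- protocol$time_points
  clean <- switch(model_kind,
    SAC = sac_value(t, params),
    DAC = dac_value(t, params),
    INACTIVE = rep(0, length(t))
  )
  fluorescence_trace(roi_id, t, apply_noise(clean, noise))
}

# default per-cell rate-constant distributions: Gaussians centred at the
# short-half-life construct population means (kf 0.0369 min^-1; kd at the
# faster decay component, 0.016 min^-1), truncated positive
default_rate_distributions <- function() {
  list(kf = c(mean = 0.0369, sd = 0.01),
       kd = c(mean = 0.016, sd = 0.002))
}

# draw n positive values from a (possibly degenerate) Gaussian
draw_truncated_gaussian <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Generate a synthetic cell population with ground truth
#'
#' Draws per-cell kinetic parameters i.i.d. from Gaussian rate
#' distributions (truncated at zero) and uniform amplitudes, then
#' synthesises one trace per cell.
#'
#' @param n_cells Number of cells.
#' @param fraction_sac,fraction_dac Fractions of single- and
#'   double-activation cells in `[0, 1]`, summing to <= 1; the remainder is
#'   inactive.
#' @param rate_distributions List with elements `kf` and `kd`, each
#'   `c(mean =, sd =)` in min^-1; `sd = 0` gives a fixed rate. Defaults to
#'   Gaussians centred at the short-half-life construct population means
#'   (kf 0.0369, kd 0.016 min^-1 -- the faster decay component).
#' @param amplitude_range Uniform amplitude range in D.U. (default
#'   500-5000, the scale of observed single-cell responses).
#' @param td Second-activation time for DAC cells, minutes (default 60,
#'   the inter-context interval).
#' @param protocol A [sampling_protocol()].
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#' @return A list with `traces` (list of [fluorescence_trace()]) and
#'   `truth` (data frame: roi_id, model_kind, amplitude, kf, kd, td).
#' @export
gen_population <- function(n_cells, fraction_sac = 1, fraction_dac = 0,
                           rate_distributions = default_rate_distributions(),
                           amplitude_range = c(500, 5000), td = 60,
                           protocol = is1_protocol(), noise = no_noise(),
                           seed = NULL) {
  if (fraction_sac < 0 || fraction_dac < 0 ||
      fraction_sac > 1 || fraction_dac > 1 ||
      fraction_sac + fraction_dac > 1 + 1e-12) {
    stop("model-kind fractions must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # population-level seeding governs all draws; a per-trace noise seed would
  # repeat the same noise realisation for every cell
  noise$seed <- NULL
  if (n_cells == 0) {
    return(list(traces = list(), truth = empty_truth()))
  }
  n_sac <- round(n_cells * fraction_sac)
  n_dac <- round(n_cells * fraction_dac)
  if (n_sac + n_dac > n_cells) n_dac <- n_cells - n_sac
  kinds <- c(rep("SAC", n_sac), rep("DAC", n_dac),
             rep("INACTIVE", n_cells - n_sac - n_dac))
  kf <- draw_truncated_gaussian(n_cells, rate_distributions$kf["mean"],
                                rate_distributions$kf["sd"])
  kd <- draw_truncated_gaussian(n_cells, rate_distributions$kd["mean"],
                                rate_distributions$kd["sd"])
  amplitude <- stats::runif(n_cells, amplitude_range[1], amplitude_range[2])
  truth <- data.frame(
    roi_id = sprintf("cell_%04d", seq_len(n_cells)),
    model_kind = kinds,
    amplitude = ifelse(kinds == "INACTIVE", 0, amplitude),
    kf = kf, kd = kd,
    td = ifelse(kinds == "DAC", td, NA_real_),
    stringsAsFactors = FALSE
  )
  traces <- lapply(seq_len(n_cells), function(i) {
    params <- switch(kinds[i],
      SAC = kinetic_params(amplitude[i], kf[i], kd[i]),
      DAC = dual_activation_params(amplitude[i], kf[i], kd[i], td),
      INACTIVE = NULL
    )
    gen_trace(kinds[i], params, protocol, noise, roi_id = truth$roi_id[i])
  })
  list(traces = traces, truth = truth)
}

empty_truth <- function() {
  data.frame(roi_id = character(), model_kind = character(),
             amplitude = numeric(), kf = numeric(), kd = numeric(),
             td = numeric(), stringsAsFactors = FALSE)
}

# Table of the eight context-representation categories: activation flags
# (a1 = CtxtA in IS1, a2 = CtxtA in IS2, b = CtxtB in IS2) per category.
category_flag_table <- function() {
  data.frame(
    category = 1:8,
    a1 = c(1, 1, 1, 0, 0, 1, 0, 0),
    a2 = c(1, 1, 0, 1, 0, 0, 1, 0),
    b  = c(1, 0, 0, 0, 1, 1, 1, 0)
  )
}

#' Generate a dual-session dataset with per-cell category ground truth
#'
#' Builds IS1 and IS2 traces for a population whose cells are assigned to
#' the eight context-representation categories. Per category, the IS1
#' trace is a single-activation profile (when the cell responded to
#' context A on day one) or baseline, and the IS2 trace is a
#' single-activation profile from the context-A exposure (origin 0 min),
#' from the context-B exposure (origin 60 min), a double-activation
#' profile with `td = 60` min (both exposures), or baseline.
#'
#' @param n_cells Number of cells.
#' @param category_fractions Numeric vector of length 8 summing to 1: the
#'   intended mix over categories 1-8.
#' @param rate_distributions,amplitude_range As in [gen_population()].
#' @param noise A [noise_model()].
#' @param is1,is2 Session protocols.
#' @param seed Optional integer seed.
#' @return List with `is1_traces`, `is2_traces` (lists of traces) and
#'   `truth` (roi_id, category, a1, a2, b, amplitude, kf, kd per session
#'   model kinds).
#' @export
gen_dual_session_dataset <- function(n_cells,
                                     category_fractions,
                                     rate_distributions = default_rate_distributions(),
                                     amplitude_range = c(500, 5000),
                                     noise = noise_model(scale = 0.05),
                                     is1 = is1_protocol(), is2 = is2_protocol(),
                                     seed = NULL) {
  if (length(category_fractions) != 8 ||
      abs(sum(category_fractions) - 1) > 1e-8 || any(category_fractions < 0)) {
    stop("'category_fractions' must be 8 non-negative numbers summing to 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  noise$seed <- NULL
  counts <- round(n_cells * category_fractions)
  # adjust rounding drift on the largest class
  drift <- n_cells - sum(counts)
  if (drift != 0) counts[which.max(counts)] <- counts[which.max(counts)] + drift
  category <- rep(1:8, counts)
  flags <- category_flag_table()[category, ]
  kf <- draw_truncated_gaussian(n_cells, rate_distributions$kf["mean"],
                                rate_distributions$kf["sd"])
  kd <- draw_truncated_gaussian(n_cells, rate_distributions$kd["mean"],
                                rate_distributions$kd["sd"])
  amplitude <- stats::runif(n_cells, amplitude_range[1], amplitude_range[2])
  roi_id <- sprintf("cell_%04d", seq_len(n_cells))

  is1_kind <- ifelse(flags$a1 == 1, "SAC", "INACTIVE")
  is2_kind <- ifelse(flags$a2 == 1 & flags$b == 1, "DAC",
              ifelse(flags$a2 == 1, "SAC",
              ifelse(flags$b == 1, "SAC_DELAYED", "INACTIVE")))

  make_trace <- function(i, kind, protocol) {
    p <- kinetic_params(amplitude[i], kf[i], kd[i])
    switch(kind,
      SAC = gen_trace("SAC", p, protocol, noise, roi_id = roi_id[i]),
      DAC = gen_trace("DAC",
                      dual_activation_params(amplitude[i], kf[i], kd[i], 60),
                      protocol, noise, roi_id = roi_id[i]),
      SAC_DELAYED = {
        # activation at 60 min: shift the time origin of the model
        t <- protocol$time_points
        clean <- ifelse(t >= 60, sac_value_raw(pmax(t - 60, 0),
                                               amplitude[i], kf[i], kd[i]), 0)
        fluorescence_trace(roi_id[i], t, apply_noise(clean, noise))
      },
      INACTIVE = gen_trace("INACTIVE", NULL, protocol, noise,
                           roi_id = roi_id[i])
    )
  }
  is1_traces <- lapply(seq_len(n_cells), function(i) make_trace(i, is1_kind[i], is1))
  is2_traces <- lapply(seq_len(n_cells), function(i) make_trace(i, is2_kind[i], is2))

  truth <- data.frame(roi_id = roi_id, category = category,
                      a1 = flags$a1, a2 = flags$a2, b = flags$b,
                      is1_kind = is1_kind, is2_kind = is2_kind,
                      amplitude = amplitude, kf = kf, kd = kd,
                      stringsAsFactors = FALSE)
  list(is1_traces = is1_traces, is2_traces = is2_traces, truth = truth)
}

#' Convert a list of traces to a long data frame
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @return Data frame with columns roi_id, time_min, value_du.
#' @export
traces_to_table <- function(traces) {
  do.call(rbind, lapply(traces, as.data.frame))
}

#' Rebuild trace objects from a long table
#'
#' @param tab Data frame with columns roi_id, time_min, value_du.
#' @return Named list of [fluorescence_trace()] objects.
#' @export
table_to_traces <- function(tab) {
  stopifnot(all(c("roi_id", "time_min", "value_du") %in% names(tab)))
  split_tab <- split(tab, tab$roi_id)
  out <- lapply(split_tab, function(d) {
    d <- d[order(d$time_min), ]
    fluorescence_trace(d$roi_id[1], d$time_min, d$value_du)
  })
  out[unique(tab$roi_id)]
}
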