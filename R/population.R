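# Population-level distributions of fitted rate constants and peak times:
# frequency histograms, Gaussian curve fits to the retained bins, and
# AIC-based choice between one- and two-component models.

#' Frequency histogram of a fitted parameter
#'
#' Uniform bins from 0 to the maximum value; only bins whose count
#' exceeds `min_count` are retained for the downstream Gaussian curve
#' fit, suppressing sparsely populated tails.
#'
#' @param values Finite parameter values (e.g. per-cell kf), at least one.
#' @param bin_width Bin width, same units as `values`.
#' @param min_count Retention threshold: bins with `count > min_count`
#'   enter the modality fit (default 10).
#' @return An object of class `param_histogram`: list with `bin_edges`,
#'   `bin_centers`, `counts`, `retained` (logical mask), `bin_width`,
#'   `min_count`, `n`.
#' @export
build_histogram <- function(values, bin_width, min_count = 10) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to histogram", call. = FALSE)
  stopifnot(bin_width > 0)
  edges <- seq(0, max(values) + bin_width, by = bin_width)
  counts <- graphics::hist(values, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, retained = counts > min_count,
                 bin_width = bin_width, min_count = min_count,
                 n = length(values)),
            class = "param_histogram")
}

#' @export
print.param_histogram <- function(x, ...) {
  cat(sprintf("Parameter histogram: n = %d, %d bins (width %g), %d retained (count > %d)\n",
              x$n, length(x$counts), x$bin_width, sum(x$retained), x$min_count))
  invisible(x)
}

# Least-squares Gaussian curve fit to (center, count) pairs. Component
# centres are confined to the neighbourhood of the data and component sds
# bounded below by half a bin width: a sub-bin component is meaningless on
# binned counts and would only chase single-bin noise.
fit_gaussian_counts <- function(x, y, n_components, bin_width = NULL) {
  stopifnot(n_components %in% c(1, 2))
  d <- data.frame(x = x, y = y)
  xr <- range(x)
  span <- max(diff(xr), max(xr) * 0.1)
  m_lo <- xr[1] - span
  m_hi <- xr[2] + span
  if (is.null(bin_width)) bin_width <- min(diff(sort(unique(x))))
  s_lo <- bin_width / 2
  if (n_components == 1) {
    start <- list(a1 = max(y), m1 = x[which.max(y)],
                  s1 = max(diff(xr) / 4, 1e-8))
    fit <- safe_nlsLM(y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)), d, start,
                      lower = c(0, m_lo, s_lo),
                      upper = c(Inf, m_hi, Inf),
                      maxiter = 200)
  } else {
    # seed the two components at the lower and upper thirds of the range;
    # component centres are confined to the neighbourhood of the data
    start <- list(a1 = max(y), m1 = xr[1] + diff(xr) / 3,
                  s1 = max(diff(xr) / 6, 1e-8),
                  a2 = max(y) / 2, m2 = xr[1] + 2 * diff(xr) / 3,
                  s2 = max(diff(xr) / 6, 1e-8))
    fit <- safe_nlsLM(y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
                        a2 * exp(-(x - m2)^2 / (2 * s2^2)), d, start,
                      lower = c(0, m_lo, s_lo, 0, m_lo, s_lo),
                      upper = c(Inf, m_hi, Inf, Inf, m_hi, Inf),
                      maxiter = 400)
  }
  if (is.null(fit)) return(NULL)
  parts <- nls_summary_parts(fit)
  est <- parts$est
  p <- 3 * n_components
  n <- length(y)
  comps <- if (n_components == 1) {
    data.frame(mean = est["m1"], sd = est["s1"], height = est["a1"])
  } else {
    cmp <- data.frame(mean = c(est["m1"], est["m2"]),
                      sd = c(est["s1"], est["s2"]),
                      height = c(est["a1"], est["a2"]))
    cmp[order(cmp$mean), ]
  }
  rownames(comps) <- NULL
  tss <- sum((y - mean(y))^2)
  # small-sample corrected AIC: the two-component model spends 6
  # parameters on typically 10-20 retained bins
  list(n_components = n_components, components = comps,
       stderr = parts$se, rss = parts$rss,
       aic = aic_ls(parts$rss, n, p, corrected = TRUE),
       adj_r2 = if (n > p + 1 && tss > 0)
         adjusted_r_squared(parts$rss, tss, n, p) else NA_real_)
}

#' Choose histogram modality by AIC
#'
#' Fits one- and two-component Gaussian curves to the retained histogram
#' bins by least squares and returns the model with the lower AIC. When
#' too few bins are retained for the two-component fit (or it fails to
#' converge), the one-component fit is returned without comparison and
#' flagged.
#'
#' @param hist A [build_histogram()] result. At least 5 retained bins are
#'   required for the one-component fit and 7 for the two-component fit.
#' @return An object of class `modality_fit`: the selected fit
#'   (`n_components`, `components` data frame with mean/sd/height, `rss`,
#'   `aic`, `adj_r2`) plus `aic_1`, `aic_2` (candidate AICs, `NA` when
#'   unavailable) and `compared` (logical).
#' @export
fit_modality <- function(hist) {
  stopifnot(inherits(hist, "param_histogram"))
  x <- hist$bin_centers[hist$retained]
  y <- hist$counts[hist$retained]
  if (length(x) < 5) {
    stop("need at least 5 retained bins for the modality fit", call. = FALSE)
  }
  f1 <- fit_gaussian_counts(x, y, 1, hist$bin_width)
  if (is.null(f1)) stop("one-component Gaussian fit failed", call. = FALSE)
  f2 <- if (length(x) >= 7) fit_gaussian_counts(x, y, 2, hist$bin_width)
        else NULL
  compared <- !is.null(f2)
  selected <- if (compared && f2$aic < f1$aic) f2 else f1
  structure(c(selected,
              list(aic_1 = f1$aic, aic_2 = if (compared) f2$aic else NA_real_,
                   compared = compared)),
            class = "modality_fit")
}

#' @export
print.modality_fit <- function(x, ...) {
  cat(sprintf("Gaussian modality fit: %d component(s) selected%s\n",
              x$n_components,
              if (!x$compared) " (two-component fit unavailable)" else ""))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  component %d: mean %.5g, sd %.4g, height %.4g\n",
                i, x$components$mean[i], x$components$sd[i],
                x$components$height[i]))
  }
  cat(sprintf("  AIC (1 comp) %.4g, AIC (2 comp) %s; Adj-R-sq %.4f\n",
              x$aic_1, if (is.na(x$aic_2)) "NA" else sprintf("%.4g", x$aic_2),
              x$adj_r2))
  invisible(x)
}

# default bin widths giving 10-20 retained bins at a few hundred cells
default_bin_widths <- function() {
  c(kf = 0.005, kd = 0.002, tmax = 5)
}

#' Per-cell peak-time distribution
#'
#' Derives the time to maximal response for every fitted cell from its
#' rate constants, histograms the values and fits modality. The separate
#' single-evaluation quantity `tmax_at_mean_rates` — the peak time of the
#' profile built from the population-mean rate constants — is reported
#' distinctly; it need not coincide with the histogram's fitted mean
#' because the peak time is a nonlinear function of the rates.
#'
#' @param fit_results Data frame with columns `kf_per_min`, `kd_per_min`
#'   (e.g. from [fit_results_table()]); rows with non-finite rates are
#'   dropped, degenerate-rate cells use the `1/k` limit.
#' @param bin_width Histogram bin width, minutes.
#' @param min_count Bin retention threshold.
#' @return List with `tmax` (per-cell values, minutes), `histogram`,
#'   `modality` (`NULL` when too few retained bins) and
#'   `tmax_at_mean_rates`.
#' @export
derive_tmax_distribution <- function(fit_results,
                                     bin_width = default_bin_widths()[["tmax"]],
                                     min_count = 10) {
  stopifnot(all(c("kf_per_min", "kd_per_min") %in% names(fit_results)))
  ok <- is.finite(fit_results$kf_per_min) & is.finite(fit_results$kd_per_min) &
    fit_results$kf_per_min > 0 & fit_results$kd_per_min > 0
  kf <- fit_results$kf_per_min[ok]
  kd <- fit_results$kd_per_min[ok]
  if (length(kf) == 0) stop("no cells with valid rates", call. = FALSE)
  tmax <- vapply(seq_along(kf), function(i) {
    time_to_peak(kinetic_params(1, kf[i], kd[i]))
  }, numeric(1))
  hist <- build_histogram(tmax, bin_width, min_count)
  modality <- if (sum(hist$retained) >= 5) fit_modality(hist) else NULL
  list(tmax = tmax, histogram = hist, modality = modality,
       tmax_at_mean_rates = time_to_peak(kinetic_params(1, mean(kf), mean(kd))))
}
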