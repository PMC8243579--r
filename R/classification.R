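# Combining per-session model selections into context-activation flags,
# the eight-category classification, and ensemble-level statistics.

#' Context-activation flags from the two sessions' selected models
#'
#' Maps the selected model of each imaging session to the three context
#' flags: `a1` (context A, first session), `a2` (context A, second
#' session) and `b` (context B, second session). A first-session
#' single- or double-activation fit sets `a1`; in the second session a
#' single-activation fit at origin 0 sets `a2`, the 60-min-delayed
#' single-activation fit sets `b`, and a double-activation fit sets both.
#' A session with no surviving fit contributes no flags.
#'
#' @param is1_kind,is2_kind Selected model kind per session: one of
#'   `"SAC"`, `"SAC_DELAYED"`, `"DAC"` or `"none"`/`NA` when no model
#'   survived selection. Vectorised.
#' @return Data frame with logical columns `a1`, `a2`, `b`.
#' @export
#' @examples
#' session_flags("SAC", "DAC")          # active in all three contexts
#' session_flags("none", "SAC_DELAYED") # context B only
session_flags <- function(is1_kind, is2_kind) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "INACTIVE"] <- "none"
    bad <- !x %in% c("SAC", "SAC_DELAYED", "DAC", "none")
    if (any(bad)) stop("unknown model kind: ", paste(unique(x[bad]),
                       collapse = ", "), call. = FALSE)
    x
  }
  is1 <- norm(is1_kind)
  is2 <- norm(is2_kind)
  if (length(is1) != length(is2)) {
    stop("'is1_kind' and 'is2_kind' must have equal length", call. = FALSE)
  }
  data.frame(a1 = is1 %in% c("SAC", "DAC"),
             a2 = is2 %in% c("SAC", "DAC"),
             b = is2 %in% c("SAC_DELAYED", "DAC"))
}

#' The eight context-representation categories
#'
#' Classifies the context-activation triple `(a1, a2, b)` into one of the
#' eight categories; the mapping is a bijection between the 2^3 triples
#' and categories 1-8:
#'
#' | category | a1 | a2 | b | meaning |
#' |---|---|---|---|---|
#' | 1 | 1 | 1 | 1 | present in all contexts |
#' | 2 | 1 | 1 | 0 | present in context A only (both sessions) |
#' | 3 | 1 | 0 | 0 | present in session-1 context A only |
#' | 4 | 0 | 1 | 0 | present in session-2 context A only |
#' | 5 | 0 | 0 | 1 | present in context B only |
#' | 6 | 1 | 0 | 1 | session-1 context A and context B |
#' | 7 | 0 | 1 | 1 | session-2 context A and context B |
#' | 8 | 0 | 0 | 0 | not activated in any context |
#'
#' @param a1,a2,b Logical (or 0/1) context-activation flags; vectorised.
#' @return Integer category vector (1-8).
#' @export
#' @examples
#' categorize(1, 1, 1)  # 1
#' categorize(1, 0, 1)  # 6
#' categorize(0, 0, 0)  # 8
categorize <- function(a1, a2, b) {
  a1 <- as.logical(a1); a2 <- as.logical(a2); b <- as.logical(b)
  if (any(is.na(c(a1, a2, b)))) stop("flags must be TRUE/FALSE", call. = FALSE)
  tab <- category_flag_table()
  key <- paste(as.integer(a1), as.integer(a2), as.integer(b))
  tab_key <- paste(tab$a1, tab$a2, tab$b)
  tab$category[match(key, tab_key)]
}

#' Classify every ROI from its two per-session outcomes
#'
#' @param outcomes Data frame with columns `roi_id`, `is1_kind`,
#'   `is2_kind` (selected model kind per session, `"none"` when no fit
#'   survived).
#' @return Data frame with `roi_id`, flags `a1`, `a2`, `b`, and
#'   `category`.
#' @export
classify_cells <- function(outcomes) {
  stopifnot(all(c("roi_id", "is1_kind", "is2_kind") %in% names(outcomes)))
  flags <- session_flags(outcomes$is1_kind, outcomes$is2_kind)
  data.frame(roi_id = outcomes$roi_id, flags,
             category = categorize(flags$a1, flags$a2, flags$b),
             stringsAsFactors = FALSE)
}

#' Ensemble fractions and session overlap
#'
#' Session-activation and per-context fractions over all ROIs, the
#' session overlap, and the conditional reactivation fractions. Overlap
#' is reported both normalised to total ROIs and to the per-session
#' activated counts.
#'
#' @param classification Data frame from [classify_cells()] (columns
#'   `a1`, `a2`, `b` at minimum).
#' @return Named list of fractions: `frac_is1`, `frac_is2`,
#'   `frac_overlap` (active in both sessions / total),
#'   `frac_overlap_of_is1`, `frac_overlap_of_is2` (normalised to each
#'   session's activated cells), per-context `frac_a1`, `frac_a2`,
#'   `frac_b`, the cross-context overlap `frac_a1_and_b`, and the
#'   conditional fractions `frac_a2_also_a1` (context-A session-2 cells
#'   also in context-A session-1), `frac_a1_also_b`, `frac_a2_also_b`.
#' @export
ensemble_fractions <- function(classification) {
  cl <- classification
  stopifnot(all(c("a1", "a2", "b") %in% names(cl)))
  n <- nrow(cl)
  if (n == 0) stop("no ROIs to summarise", call. = FALSE)
  act1 <- cl$a1
  act2 <- cl$a2 | cl$b
  cond <- function(num, den) if (sum(den) == 0) NA_real_ else sum(num & den) / sum(den)
  list(
    n_rois = n,
    frac_is1 = mean(act1),
    frac_is2 = mean(act2),
    frac_overlap = mean(act1 & act2),
    frac_overlap_of_is1 = cond(act2, act1),
    frac_overlap_of_is2 = cond(act1, act2),
    frac_a1 = mean(cl$a1),
    frac_a2 = mean(cl$a2),
    frac_b = mean(cl$b),
    frac_a1_and_b = mean(cl$a1 & cl$b),
    frac_a2_also_a1 = cond(cl$a1, cl$a2),
    frac_a1_also_b = cond(cl$b, cl$a1),
    frac_a2_also_b = cond(cl$b, cl$a2)
  )
}

#' Chance overlap of two independently drawn ensembles
#'
#' Expected overlap fraction when membership in the two ensembles is
#' independent: the product of the two fractional activations.
#'
#' @param frac_a,frac_b Fractional activation of the two ensembles, in
#'   `[0, 1]`.
#' @return The product.
#' @export
#' @examples
#' chance_overlap(0.44, 0.42)  # 0.1848
chance_overlap <- function(frac_a, frac_b) {
  stopifnot(all(frac_a >= 0 & frac_a <= 1), all(frac_b >= 0 & frac_b <= 1))
  frac_a * frac_b
}

#' Compare double-activation fractions between exposure conditions
#'
#' Among activated cells, the fraction fitting the double-activation
#' profile is computed per replicate (animal) for the dual-exposure
#' condition (second session after two context exposures 60 min apart)
#' and the single-exposure condition, and compared by a one-tailed
#' Welch two-sample t test (dual > single).
#'
#' @param outcomes Data frame with columns `replicate`, `condition`
#'   (`"dual"` or `"single"`), and `model_kind` (selected model of each
#'   activated cell: `"SAC"`, `"SAC_DELAYED"` or `"DAC"`).
#' @return List with `frac_dac_dual`, `frac_dac_single` (pooled
#'   fractions), `per_replicate` (data frame of per-replicate fractions)
#'   and `p_value` (one-tailed; `NA` with fewer than 2 replicates in
#'   either group).
#' @export
dac_fraction_comparison <- function(outcomes) {
  stopifnot(all(c("replicate", "condition", "model_kind") %in% names(outcomes)))
  stopifnot(all(outcomes$condition %in% c("dual", "single")))
  act <- outcomes[outcomes$model_kind %in% c("SAC", "SAC_DELAYED", "DAC"), ]
  pooled <- function(cond) {
    x <- act[act$condition == cond, ]
    if (nrow(x) == 0) return(NA_real_)
    mean(x$model_kind == "DAC")
  }
  per_rep <- do.call(rbind, lapply(split(act, act[c("replicate", "condition")],
                                         drop = TRUE), function(x) {
    data.frame(replicate = x$replicate[1], condition = x$condition[1],
               frac_dac = mean(x$model_kind == "DAC"),
               n_activated = nrow(x), stringsAsFactors = FALSE)
  }))
  rownames(per_rep) <- NULL
  dual <- per_rep$frac_dac[per_rep$condition == "dual"]
  single <- per_rep$frac_dac[per_rep$condition == "single"]
  p <- if (length(dual) >= 2 && length(single) >= 2) {
    # degenerate case (all per-replicate fractions identical within a
    # group on both sides) has no defined t statistic
    tryCatch(stats::t.test(dual, single, alternative = "greater")$p.value,
             error = function(e) NA_real_)
  } else NA_real_
  list(frac_dac_dual = pooled("dual"), frac_dac_single = pooled("single"),
       per_replicate = per_rep, p_value = p)
}

#' Amplitude-binned reactivation probability
#'
#' Bins first-session activated cells by their fitted amplitude into
#' half-open intervals `[k*bin, (k+1)*bin)` and computes, per bin, the
#' fraction whose second-session trace fits an activation model
#' (N_fit / N_bin). Also returns the Pearson correlation of bin centre
#' against probability, and the slope of second-session adjusted
#' R-squared against amplitude as a bias control.
#'
#' @param is1_results Data frame of first-session activated cells:
#'   `roi_id`, `amplitude_du`.
#' @param is2_results Data frame with `roi_id`, `refit` (logical: does
#'   the second session fit an activation model), and optionally
#'   `adj_r_sq` of the second-session fit for the bias control.
#' @param bin_size Amplitude bin width, D.U. (default 500).
#' @return List with `bins` (data frame: amplitude_lo, amplitude_hi,
#'   n_bin, n_fit, probability; empty bins omitted), `correlation`
#'   (Pearson r, `NA` when the probabilities have zero variance) and
#'   `adj_r2_slope` (per-D.U. slope, `NA` when unavailable).
#' @export
reactivation_probability <- function(is1_results, is2_results,
                                     bin_size = 500) {
  stopifnot(all(c("roi_id", "amplitude_du") %in% names(is1_results)),
            all(c("roi_id", "refit") %in% names(is2_results)),
            bin_size > 0)
  if (nrow(is1_results) == 0) stop("no activated first-session cells",
                                   call. = FALSE)
  m <- merge(is1_results, is2_results, by = "roi_id")
  if (nrow(m) == 0) stop("no ROIs common to both sessions", call. = FALSE)
  idx <- floor(m$amplitude_du / bin_size)
  bins <- do.call(rbind, lapply(sort(unique(idx)), function(k) {
    sel <- idx == k
    data.frame(amplitude_lo = k * bin_size, amplitude_hi = (k + 1) * bin_size,
               n_bin = sum(sel), n_fit = sum(m$refit[sel]),
               probability = mean(m$refit[sel]))
  }))
  correlation <- if (nrow(bins) >= 3 && stats::sd(bins$probability) > 0) {
    centres <- (bins$amplitude_lo + bins$amplitude_hi) / 2
    stats::cor(centres, bins$probability)
  } else NA_real_
  slope <- NA_real_
  if ("adj_r_sq" %in% names(m) && sum(is.finite(m$adj_r_sq)) >= 3) {
    ok <- is.finite(m$adj_r_sq)
    slope <- unname(stats::coef(stats::lm(m$adj_r_sq[ok] ~ m$amplitude_du[ok]))[2])
  }
  list(bins = bins, correlation = correlation, adj_r2_slope = slope)
}
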