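# Pipeline commands tying the stages together: simulate -> extract -> fit
# -> classify -> report. Each command reads/writes plain CSV/JSON/YAML
# files with a provenance header, so runs are diff-able and reproducible.

pkg_version <- function() {
  as.character(utils::packageVersion("iegkinetics"))
}

# tiny FNV-1a hash of a config (provenance header only); arithmetic kept
# in doubles below 2^53 so no integer overflow occurs
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(ch %% 256))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

output_header <- function(config) {
  c(sprintf("# iegkinetics %s", pkg_version()),
    sprintf("# seed: %s", ifelse(is.null(config$seed), "NA", config$seed)),
    sprintf("# config: %s", config_hash(config)))
}

#' Write a table as CSV with a provenance header
#'
#' Header lines start with `#` and record package version, seed and a
#' config hash; [read_output_csv()] skips them.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @param config Pipeline config list (for the header).
#' @return Invisibly, `path`.
#' @export
write_output_csv <- function(tab, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_output_csv()]
#' @param path File path.
#' @return Data frame.
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' A complete configuration for the simulate/extract/fit/classify/report
#' pipeline; fields may be overridden by a YAML file or a named list.
#'
#' @param overrides Named list (possibly nested) of fields to override,
#'   or a path to a YAML file with the same structure.
#' @return Config list with components `seed`, `out_dir`, `simulate`
#'   (n_cells, category_fractions, noise, image rendering options),
#'   `fit` (initialisations, threshold, per-session candidate sets),
#'   `report` (histogram bin widths, reactivation bin size).
#' @export
pipeline_config <- function(overrides = NULL) {
  config <- list(
    seed = 1L,
    out_dir = "ieg_out",
    simulate = list(
      n_cells = 200,
      category_fractions = c(0.10, 0.10, 0.15, 0.10, 0.15, 0.10, 0.10, 0.20),
      noise = list(kind = "gaussian_multiplicative", scale = 0.05, floor = 10),
      amplitude_range = c(500, 5000),
      render_images = FALSE,
      fov = c(160, 160), z_slices = 15, diameter = 20, baseline = 50,
      jitter = 0
    ),
    fit = list(
      kf_init = 0.01, kd_init = 0.001, td_init = 60,
      adj_r2_threshold = 0.5, delay_offset = 60,
      candidates_is1 = c("SAC"),
      candidates_is2 = c("SAC", "SAC_DELAYED", "DAC")
    ),
    report = list(
      kf_bin_width = 0.005, kd_bin_width = 0.002, tmax_bin_width = 5,
      min_count = 10, reactivation_bin_size = 500
    )
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  modify_list_deep(config, overrides)
}

modify_list_deep <- function(base, overrides) {
  if (is.null(overrides)) return(base)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

config_noise <- function(config) {
  noise_model(config$simulate$noise$kind, config$simulate$noise$scale,
              config$simulate$noise$floor)
}

config_fit <- function(config) {
  fit_config(kf_init = config$fit$kf_init, kd_init = config$fit$kd_init,
             td_init = config$fit$td_init,
             adj_r2_threshold = config$fit$adj_r2_threshold,
             delay_offset = config$fit$delay_offset)
}

#' Simulate a dual-session dataset to disk
#'
#' Generates a dual-session population with the configured category mix
#' and writes per-session trace CSVs plus the ground-truth table; with
#' `simulate$render_images = TRUE` also renders per-time-point TIFF
#' stacks with ROI table and manifest for both sessions.
#'
#' @param config A [pipeline_config()] (list or YAML path accepted).
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(config = pipeline_config()) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  ds <- gen_dual_session_dataset(
    n_cells = sim$n_cells, category_fractions = sim$category_fractions,
    amplitude_range = sim$amplitude_range, noise = config_noise(config),
    seed = config$seed
  )
  paths <- list(
    truth = file.path(config$out_dir, "truth.csv"),
    is1_traces = file.path(config$out_dir, "is1_traces.csv"),
    is2_traces = file.path(config$out_dir, "is2_traces.csv")
  )
  write_output_csv(ds$truth, paths$truth, config)
  write_output_csv(traces_to_table(ds$is1_traces), paths$is1_traces, config)
  write_output_csv(traces_to_table(ds$is2_traces), paths$is2_traces, config)
  if (isTRUE(sim$render_images)) {
    for (session in c("is1", "is2")) {
      proto <- if (session == "is1") is1_protocol() else is2_protocol()
      kind_col <- paste0(session, "_kind")
      truth_s <- ds$truth
      truth_s$model_kind <- truth_s[[kind_col]]
      truth_s$td <- ifelse(truth_s$model_kind == "DAC", 60, NA_real_)
      truth_s <- add_nucleus_geometry(truth_s, fov = sim$fov,
                                      z_slices = sim$z_slices,
                                      diameter = sim$diameter,
                                      baseline = sim$baseline,
                                      seed = config$seed)
      stack_set <- gen_image_stack(truth_s, proto, fov = sim$fov,
                                   z_slices = sim$z_slices,
                                   jitter = sim$jitter,
                                   noise = config_noise(config),
                                   seed = config$seed + 1L)
      sdir <- file.path(config$out_dir, paste0(session, "_stacks"))
      write_stack_tiffs(stack_set, sdir, prefix = session)
      write_output_csv(stack_set$roi_table,
                       file.path(sdir, paste0(session, "_rois.csv")), config)
      paths[[paste0(session, "_stacks")]] <- sdir
    }
  }
  invisible(paths)
}

#' Extract traces from rendered stacks
#'
#' Reads the TIFF stacks, manifest and ROI table written by
#' [cmd_simulate()] (or equivalent acquisition output) and writes one
#' trace CSV per session.
#'
#' @param config A [pipeline_config()].
#' @param sessions Session names to process.
#' @return Invisibly, the written trace CSV paths.
#' @export
cmd_extract <- function(config = pipeline_config(),
                        sessions = c("is1", "is2")) {
  config <- pipeline_config(config)
  paths <- list()
  for (session in sessions) {
    sdir <- file.path(config$out_dir, paste0(session, "_stacks"))
    if (!dir.exists(sdir)) stop("no stack directory: ", sdir, call. = FALSE)
    manifest <- utils::read.csv(file.path(sdir, paste0(session, "_manifest.csv")))
    rois <- read_output_csv(file.path(sdir, paste0(session, "_rois.csv")))
    proto <- if (session == "is1") is1_protocol() else is2_protocol()
    if (!isTRUE(all.equal(sort(manifest$time_min), proto$time_points))) {
      missing <- setdiff(proto$time_points, manifest$time_min)
      if (length(missing) > 0) {
        stop("manifest lacks time points (min): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
    series <- read_stack_tiffs(sdir, manifest[order(manifest$time_min), ])
    traces <- extract_all_traces(series$stacks, rois, proto)
    out <- file.path(config$out_dir, paste0(session, "_traces_extracted.csv"))
    write_output_csv(traces_to_table(traces), out, config)
    paths[[session]] <- out
  }
  invisible(paths)
}

#' Fit candidate models to every trace of both sessions
#'
#' Reads the per-session trace CSVs, runs the configured candidate set
#' per ROI (first session: single-activation; second session:
#' single-activation at both time origins plus double-activation),
#' selects per session by AIC, and writes fit-results CSVs in the
#' published table layout plus a `selected` column.
#'
#' @param config A [pipeline_config()].
#' @param traces_suffix Suffix of the trace files to read (default
#'   `"_traces.csv"`, i.e. the simulated traces; use
#'   `"_traces_extracted.csv"` after [cmd_extract()]).
#' @return Invisibly, the written fit-results CSV paths.
#' @export
cmd_fit <- function(config = pipeline_config(),
                    traces_suffix = "_traces.csv") {
  config <- pipeline_config(config)
  fc <- config_fit(config)
  paths <- list()
  for (session in c("is1", "is2")) {
    tab <- read_output_csv(file.path(config$out_dir,
                                     paste0(session, traces_suffix)))
    traces <- table_to_traces(tab)
    candidates <- if (session == "is1") config$fit$candidates_is1
                  else config$fit$candidates_is2
    rows <- lapply(traces, function(tr) {
      res <- fit_session(tr, candidates, fc)
      out <- fit_results_table(res$fits)
      out$selected <- !is.null(res$selected) &
        out$model_kind == (if (is.null(res$selected)) "" else
                           res$selected$model_kind)
      out
    })
    tab_out <- do.call(rbind, rows)
    rownames(tab_out) <- NULL
    out <- file.path(config$out_dir, paste0(session, "_fits.csv"))
    write_output_csv(tab_out, out, config)
    paths[[session]] <- out
  }
  invisible(paths)
}

# selected model kind per ROI from a fits table ("none" when nothing survived)
selected_kinds <- function(fits, rois) {
  sel <- fits[fits$selected, ]
  kind <- sel$model_kind[match(rois, sel$roi_id)]
  kind[is.na(kind)] <- "none"
  kind
}

#' Classify every ROI and write ensemble fractions
#'
#' Combines the two sessions' selected models into context flags and the
#' eight-category classification; writes the classification CSV and the
#' ensemble-fractions JSON (including the chance overlap).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, list with the classification data frame and the
#'   fractions list.
#' @export
cmd_classify <- function(config = pipeline_config()) {
  config <- pipeline_config(config)
  is1 <- read_output_csv(file.path(config$out_dir, "is1_fits.csv"))
  is2 <- read_output_csv(file.path(config$out_dir, "is2_fits.csv"))
  rois <- unique(c(is1$roi_id, is2$roi_id))
  outcomes <- data.frame(roi_id = rois,
                         is1_kind = selected_kinds(is1, rois),
                         is2_kind = selected_kinds(is2, rois),
                         stringsAsFactors = FALSE)
  cl <- classify_cells(outcomes)
  write_output_csv(cl, file.path(config$out_dir, "classification.csv"), config)
  fr <- ensemble_fractions(cl)
  fr$chance_overlap_a1_b <- chance_overlap(fr$frac_a1, fr$frac_b)
  jsonlite::write_json(fr, file.path(config$out_dir, "fractions.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(classification = cl, fractions = fr))
}

#' Population report: parameter histograms and reactivation probability
#'
#' From the selected fits, builds kf/kd/peak-time histograms with
#' Gaussian modality fits, and the amplitude-binned reactivation
#' probability; writes histogram and reactivation CSVs plus a modality
#' JSON.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, list with histogram, modality and reactivation
#'   results.
#' @export
cmd_report <- function(config = pipeline_config()) {
  config <- pipeline_config(config)
  rep_cfg <- config$report
  is1 <- read_output_csv(file.path(config$out_dir, "is1_fits.csv"))
  is2 <- read_output_csv(file.path(config$out_dir, "is2_fits.csv"))
  sel <- rbind(is1[is1$selected, ], is2[is2$selected, ])

  hists <- list()
  modality <- list()
  for (par in c("kf", "kd")) {
    values <- sel[[paste0(par, "_per_min")]]
    bw <- rep_cfg[[paste0(par, "_bin_width")]]
    h <- build_histogram(values[is.finite(values)], bw, rep_cfg$min_count)
    hists[[par]] <- data.frame(parameter = par,
                               bin_center = h$bin_centers,
                               count = h$counts, retained = h$retained)
    modality[[par]] <- if (sum(h$retained) >= 5) {
      m <- fit_modality(h)
      list(n_components = m$n_components,
           means = m$components$mean, sds = m$components$sd,
           aic_1 = m$aic_1, aic_2 = m$aic_2, adj_r2 = m$adj_r2)
    } else list(n_components = NA, note = "too few retained bins")
  }
  tmax <- derive_tmax_distribution(sel, rep_cfg$tmax_bin_width,
                                   rep_cfg$min_count)
  hists$tmax <- data.frame(parameter = "tmax",
                           bin_center = tmax$histogram$bin_centers,
                           count = tmax$histogram$counts,
                           retained = tmax$histogram$retained)
  modality$tmax <- if (!is.null(tmax$modality)) {
    list(n_components = tmax$modality$n_components,
         means = tmax$modality$components$mean,
         sds = tmax$modality$components$sd,
         tmax_at_mean_rates = tmax$tmax_at_mean_rates)
  } else list(n_components = NA,
              tmax_at_mean_rates = tmax$tmax_at_mean_rates)

  write_output_csv(do.call(rbind, hists),
                   file.path(config$out_dir, "histograms.csv"), config)
  jsonlite::write_json(modality, file.path(config$out_dir, "modality.json"),
                       auto_unbox = TRUE, digits = NA)

  # reactivation: first-session activated cells, refit status in session 2
  is1_sel <- is1[is1$selected, c("roi_id", "amplitude_du")]
  react <- NULL
  if (nrow(is1_sel) > 0) {
    is2_best <- stats::aggregate(selected ~ roi_id, data = is2, FUN = any)
    adj <- is2[is2$selected, c("roi_id", "adj_r_sq")]
    is2_status <- merge(data.frame(roi_id = is2_best$roi_id,
                                   refit = is2_best$selected), adj,
                        by = "roi_id", all.x = TRUE)
    react <- reactivation_probability(is1_sel, is2_status,
                                      rep_cfg$reactivation_bin_size)
    write_output_csv(react$bins,
                     file.path(config$out_dir, "reactivation_bins.csv"),
                     config)
  }
  invisible(list(histograms = hists, modality = modality,
                 reactivation = react))
}

#' Command-line entry point
#'
#' Dispatches `simulate | extract | fit | classify | report | all` with
#' flags `--config <yaml>`, `--seed <int>`, `--out-dir <dir>`,
#' `--verbose`. Installed as the `ieg-pipeline` script
#' (`system.file("scripts", "ieg-pipeline", package = "iegkinetics")`).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit code, invisibly (0 on success).
#' @export
ieg_pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ieg-pipeline <simulate|extract|fit|classify|report|all>",
    "[--config file.yaml] [--seed N] [--out-dir DIR] [--verbose]")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  args <- args[-1]
  opt <- list(config = NULL, seed = NULL, out_dir = NULL, verbose = FALSE)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--config") { opt$config <- args[i + 1]; i <- i + 2 }
    else if (a == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
    else if (a == "--out-dir") { opt$out_dir <- args[i + 1]; i <- i + 2 }
    else if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1 }
    else { message("unknown argument: ", a, "\n", usage); return(invisible(1L)) }
  }
  config <- tryCatch(pipeline_config(opt$config),
                     error = function(e) { message(e$message); NULL })
  if (is.null(config)) return(invisible(1L))
  if (!is.null(opt$seed)) config$seed <- opt$seed
  if (!is.null(opt$out_dir)) config$out_dir <- opt$out_dir
  say <- function(...) if (opt$verbose) message(...)
  run <- function() {
    switch(cmd,
      simulate = cmd_simulate(config),
      extract = cmd_extract(config),
      fit = cmd_fit(config),
      classify = cmd_classify(config),
      report = cmd_report(config),
      all = {
        say("simulate"); cmd_simulate(config)
        say("fit"); cmd_fit(config)
        say("classify"); cmd_classify(config)
        say("report"); cmd_report(config)
      },
      stop("unknown command '", cmd, "'\n", usage, call. = FALSE)
    )
  }
  code <- tryCatch({ run(); 0L },
                   error = function(e) { message("error: ", e$message); 1L })
  invisible(code)
}
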