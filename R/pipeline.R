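#' Configure an end-to-end pipeline run
#'
#' Bundles every knob of a run: the input mode (synthetic scenes generated
#' per group, or stacks read from disk), which channels and ROI class sets
#' to analyze, the orientation validity gate, the statistical test family
#' and significance threshold, the output directory, and the master seed
#' from which all per-sample seeds are derived.
#'
#' @param mode `"synthetic"` or `"stacks"`.
#' @param groups For synthetic mode: named list, one entry per group
#'   (e.g. `WT`, `KO`), each a list with `n` (samples; the alias
#'   `n_samples` is also accepted and is the YAML-safe spelling, since
#'   YAML 1.1 reads a bare `n` key as a boolean) and optional `spec`
#'   (a named list of [scene_spec()] overrides).
#' @param stack_paths For stacks mode: data frame with columns `stack`,
#'   `labels`, `group`, `sample_id`.
#' @param channels Channels analyzed for ROI intensity / compartment
#'   ratios.
#' @param roi_sets Named list of tissue-class sets for ROI statistics and
#'   orientation histograms.
#' @param epsilon,epsilon_quantile Orientation validity gate, see
#'   [fibre_angle_map()]. When both are `NULL` (default) the gate is
#'   estimated per image from the background noise floor
#'   ([noise_floor_epsilon()]).
#' @param roi_erode_px Pixels of ROI erosion before orientation
#'   histogramming (see [erode_mask()]); default 1, the Sobel stencil
#'   radius.
#' @param tests Subset of `c("mann_whitney_u", "t_test")`; default the
#'   nonparametric test, both in verbose configurations.
#' @param alpha Significance threshold (default 0.1).
#' @param welch Welch variant for the t test.
#' @param out_dir Output directory for CSV reports and the JSON-lines log.
#' @param seed Master seed (integer).
#' @param write_scenes Also write each synthetic scene to `out_dir` as a
#'   multipage TIFF + label TIFF + spec YAML.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "stacks"),
                       groups = list(WT = list(n = 3), KO = list(n = 3)),
                       stack_paths = NULL,
                       channels = c("SHG_PAR", "SHG_PERP",
                                    "SRS_2850", "SRS_2920"),
                       roi_sets = list(
                         mineralized = c("cortical", "trabecular"),
                         cortical = "cortical",
                         trabecular = "trabecular"),
                       epsilon = NULL, epsilon_quantile = NULL,
                       roi_erode_px = 1L,
                       tests = "mann_whitney_u",
                       alpha = 0.1, welch = FALSE,
                       out_dir = tempfile("nlobone_run_"),
                       seed = 1L, write_scenes = FALSE) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  if (mode == "synthetic" && length(groups) < 1)
    abort("synthetic mode needs at least one group")
  if (mode == "stacks" &&
      (is.null(stack_paths) || nrow(stack_paths) < 1))
    abort("stacks mode needs stack_paths")
  tests <- match.arg(tests, c("mann_whitney_u", "t_test"), several.ok = TRUE)
  structure(list(mode = mode, groups = groups, stack_paths = stack_paths,
                 channels = channels, roi_sets = roi_sets,
                 epsilon = epsilon, epsilon_quantile = epsilon_quantile,
                 roi_erode_px = as.integer(roi_erode_px),
                 tests = tests, alpha = alpha, welch = welch,
                 out_dir = out_dir, seed = as.integer(seed),
                 write_scenes = write_scenes),
            class = "run_config")
}

# internal: deterministic per-sample seed derived from the master seed
sample_seed <- function(master, group_index, sample_index) {
  (master + 7919L * group_index + 104729L * sample_index) %% 2000000000L
}

#' Analyze one co-registered stack
#'
#' Runs the per-sample analysis chain: ROI intensity statistics for each
#' configured channel and ROI class set, orientation histograms and
#' baseline-plus-Gaussian fits for each SHG polarization and bone class,
#' and bone:marrow composition ratios for the SRS channels.
#'
#' @param stack A [multimodal_stack()].
#' @param labels Matching label map.
#' @param config A [run_config()].
#' @param group Group tag stored with the results.
#' @return List of tibbles: `roi_intensity`, `ratios`, `histograms`
#'   (long form), `fits` (one [glance.fibre_fit()] row each).
#' @export
analyze_stack <- function(stack, labels, config = run_config(),
                          group = NA_character_) {
  sid <- stack$sample_id
  chans <- intersect(config$channels, names(stack$channels))

  roi_rows <- purrr::map_dfr(chans, function(ch) {
    purrr::map_dfr(names(config$roi_sets), function(rs) {
      roi_mean_intensity(stack$channels[[ch]], labels,
                         config$roi_sets[[rs]], sample_id = sid) |>
        dplyr::mutate(roi_set = rs, group = group)
    })
  })

  srs <- intersect(c("SRS_2850", "SRS_2920"), chans)
  ratio_rows <- purrr::map_dfr(srs, function(ch)
    bone_marrow_ratio(stack$channels[[ch]], labels, sample_id = sid)) |>
    dplyr::mutate(group = group)

  shg <- intersect(c("SHG_PAR", "SHG_PERP"), chans)
  hist_rows <- list(); fit_rows <- list()
  for (ch in shg) {
    pol <- if (ch == "SHG_PAR") "par" else "perp"
    grad <- sobel_gradients(stack$channels[[ch]])
    eps <- config$epsilon
    if (is.null(eps) && is.null(config$epsilon_quantile))
      eps <- noise_floor_epsilon(grad, labels)
    am <- fibre_angle_map(grad, epsilon = eps,
                          epsilon_quantile = config$epsilon_quantile)
    for (rs in intersect(c("cortical", "trabecular"),
                         names(config$roi_sets))) {
      h <- orientation_histogram(am, labels, config$roi_sets[[rs]],
                                 sample_id = sid, polarization = pol,
                                 erode_px = config$roi_erode_px %||% 1L)
      hist_rows[[paste(ch, rs)]] <- h |>
        dplyr::mutate(sample_id = sid, roi_set = rs, polarization = pol,
                      group = group)
      fit_rows[[paste(ch, rs)]] <- glance(fit_orientation_model(h)) |>
        dplyr::mutate(group = group)
    }
  }

  list(roi_intensity = roi_rows, ratios = ratio_rows,
       histograms = dplyr::bind_rows(hist_rows),
       fits = dplyr::bind_rows(fit_rows))
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) every sample, runs [analyze_stack()] on each,
#' averages the orientation-fit parameters per (group x bone class x
#' polarization) condition into summary tables, compares groups on the
#' mineralized-bone SHG intensity per polarization and on the bone:marrow
#' SRS ratios per channel, and writes all results as CSV files plus a
#' JSON-lines log into `config$out_dir`. Fully deterministic for a fixed
#' config (identical reruns produce byte-identical CSVs).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `roi_intensity`, `ratios`, `histograms`,
#'   `fits`, `fit_summary`, `comparisons`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.jsonl")
  log_line <- function(...) {
    cat(jsonlite::toJSON(list(...), auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  unlink(log_path)
  log_line(event = "start", mode = config$mode, seed = config$seed,
           alpha = config$alpha, tests = config$tests,
           package = as.character(utils::packageVersion("nlobone")),
           timestamp = format(Sys.time(), tz = "UTC"))

  samples <- list()
  if (config$mode == "synthetic") {
    gi <- 0L
    for (gname in names(config$groups)) {
      gi <- gi + 1L
      gdef <- config$groups[[gname]]
      for (j in seq_len(gdef$n_samples %||% gdef$n %||% 1L)) {
        sid <- sprintf("%s_%02d", gname, j)
        seed_ij <- sample_seed(config$seed, gi, j)
        args <- utils::modifyList(gdef$spec %||% list(),
                                  list(seed = seed_ij))
        spec <- do.call(scene_spec, args)
        scene <- withCallingHandlers(
          render_scene(spec, sample_id = sid, genotype = gname),
          error = function(e) abort(paste0("stage generate, sample ", sid,
                                           ": ", conditionMessage(e))))
        if (isTRUE(config$write_scenes)) {
          write_stack(scene$stack,
                      file.path(config$out_dir, paste0(sid, ".tif")))
          write_label_map(scene$labels,
                          file.path(config$out_dir, paste0(sid, "_labels.tif")))
          write_scene_spec(spec,
                           file.path(config$out_dir, paste0(sid, "_spec.yml")))
        }
        log_line(event = "generate", sample_id = sid, group = gname,
                 seed = seed_ij)
        samples[[sid]] <- list(stack = scene$stack, labels = scene$labels,
                               group = gname)
      }
    }
  } else {
    for (i in seq_len(nrow(config$stack_paths))) {
      row <- config$stack_paths[i, ]
      sid <- row$sample_id %||% basename(row$stack)
      stack <- read_stack(row$stack)
      stack$sample_id <- sid
      samples[[sid]] <- list(stack = stack,
                             labels = read_label_map(row$labels),
                             group = row$group)
      log_line(event = "load", sample_id = sid, group = row$group)
    }
  }

  results <- purrr::imap(samples, function(smp, sid) {
    tryCatch(analyze_stack(smp$stack, smp$labels, config, group = smp$group),
             error = function(e) abort(paste0("stage analyze, sample ", sid,
                                              ": ", conditionMessage(e))))
  })

  roi <- purrr::map_dfr(results, "roi_intensity")
  ratios <- purrr::map_dfr(results, "ratios")
  hists <- purrr::map_dfr(results, "histograms")
  fits <- purrr::map_dfr(results, "fits")

  # condition-level fit table: average parameters across samples per cell,
  # then arrange as the per-polarization summary table
  fit_summary <- NULL
  if (nrow(fits)) {
    cell_means <- fits |>
      dplyr::group_by(.data$group, .data$roi, .data$polarization) |>
      dplyr::summarise(dplyr::across(c("A", "theta0", "sigma", "B",
                                       "r_squared", "alignment_ratio"),
                                     mean), .groups = "drop") |>
      dplyr::rename(genotype = "group")
    fit_summary <- summarize_fits(cell_means)
  }

  comparisons <- NULL
  if (length(samples) && length(unique(purrr::map_chr(samples, "group"))) == 2) {
    cmp <- list()
    shg_bone <- roi |>
      dplyr::filter(.data$roi_set == "mineralized",
                    .data$channel_id %in% c("SHG_PAR", "SHG_PERP"))
    for (ch in unique(shg_bone$channel_id)) {
      d <- shg_bone[shg_bone$channel_id == ch, ]
      cmp[[paste0("shg_", ch)]] <- compare_groups(
        d, "mean_intensity", group = "group", tests = config$tests,
        alpha = config$alpha, welch = config$welch) |>
        dplyr::mutate(metric = paste0("mean_bone_intensity_", ch))
    }
    for (ch in unique(ratios$channel_id)) {
      d <- ratios[ratios$channel_id == ch, ]
      cmp[[paste0("ratio_", ch)]] <- compare_groups(
        d, "ratio", group = "group", tests = config$tests,
        alpha = config$alpha, welch = config$welch) |>
        dplyr::mutate(metric = paste0("bone_marrow_ratio_", ch))
    }
    comparisons <- dplyr::bind_rows(cmp)
  }

  wcsv <- function(x, name) {
    if (!is.null(x) && nrow(x))
      readr::write_csv(x, file.path(config$out_dir, name))
  }
  wcsv(roi, "roi_intensity.csv")
  wcsv(ratios, "compartment_ratios.csv")
  wcsv(hists, "orientation_histograms.csv")
  wcsv(fits, "fit_parameters.csv")
  if (!is.null(fit_summary))
    for (pol in unique(fit_summary$polarization))
      wcsv(fit_summary[fit_summary$polarization == pol, ],
           sprintf("fit_summary_%s.csv", pol))
  wcsv(comparisons, "group_comparisons.csv")
  log_line(event = "done", n_samples = length(samples))

  invisible(list(roi_intensity = roi, ratios = ratios, histograms = hists,
                 fits = fits, fit_summary = fit_summary,
                 comparisons = comparisons, out_dir = config$out_dir))
}
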