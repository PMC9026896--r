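#' Read a cohort burden table from CSV
#'
#' Expects the interchange header `mouse_id,group,day,area_mm2` with an
#' optional `nodule_count` column. Rows with non-positive days or negative
#' areas are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return A tibble of burden records.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cohort CSV not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("mouse_id", "group", "day", "area_mm2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Cohort CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("Cohort CSV contains no records.")
  bad_day <- which(!is.finite(df$day) | df$day <= 0)
  bad_area <- which(!is.finite(df$area_mm2) | df$area_mm2 < 0)
  bad <- sort(union(bad_day, bad_area))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed cohort rows (non-positive day or negative area) at line(s): %s",
      paste(bad + 1L, collapse = ", ")  # +1 for the header line
    ))
  }
  if (!"nodule_count" %in% names(df)) df$nodule_count <- NA_integer_
  df
}

#' @rdname read_cohort_csv
#' @param data Cohort data frame (columns `mouse_id`, `group`, `day`,
#'   `area_mm2`, optionally `nodule_count`).
#' @export
write_cohort_csv <- function(data, path) {
  cols <- intersect(c("mouse_id", "group", "day", "area_mm2", "nodule_count"),
                    names(data))
  readr::write_csv(data[, cols], path)
  invisible(path)
}

pipeline_stages <- c("simulate", "quant", "fit", "project", "compare", "phago")

stage_abort <- function(stage, msg) {
  abort(sprintf("Pipeline stage '%s' failed: %s", stage, msg))
}

#' Run the simulate/quantify/fit/project/compare pipeline
#'
#' Executes the requested stages in canonical order from a single config
#' (a nested list or the path to a YAML file), writing each stage's outputs
#' plus a manifest into the output directory. Stage seeds derive
#' deterministically from the global seed, so a re-run with the same config
#' reproduces every output byte-identically.
#'
#' Config blocks (all optional except the blocks of requested stages):
#' * `stages`: subset of simulate, quant, fit, project, compare, phago.
#' * `seed`: global integer seed (default 1).
#' * `simulate$cohorts`: list of [cohort_spec()] argument lists.
#' * `quant`: `image_dir` of RGB PNGs, `mm_per_px`, optional `min_px`.
#' * `fit`: `family`; fits each group in the cohort table.
#' * `project`: `calibrate_group` (whose fit supplies the frozen exponent),
#'   `family`, `threshold_mm2` (default 300), optional `day` filter.
#' * `compare`: `groups`, exactly two group labels to test by log-rank.
#' * `phago`: `trajectory` ([trajectory_spec()] args) and `window`.
#'
#' @param config Nested list or YAML file path.
#' @param output_dir Overrides `config$output_dir`.
#' @return The manifest, invisibly (also written as `manifest.yaml`).
#' @examples
#' cfg <- list(
#'   stages = c("simulate", "fit"), seed = 1,
#'   simulate = list(cohorts = list(list(group_label = "ctrl"))),
#'   fit = list(family = "power"),
#'   output_dir = tempfile("run")
#' )
#' mf <- run_pipeline(cfg)
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages <- config$stages %||% "simulate"
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out_dir <- output_dir %||% config$output_dir %||% "lungburden_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  manifest <- list(
    package = "lungburden",
    version = as.character(utils::packageVersion("lungburden")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stages = as.list(stages),
    parameters = list(),
    outputs = list()
  )
  cohort <- NULL
  fits <- NULL

  for (stage in stages) {
    message(sprintf("[lungburden] stage %s", stage))
    if (stage == "simulate") {
      blocks <- config$simulate$cohorts
      if (is.null(blocks)) stage_abort(stage, "no `simulate$cohorts` block in config")
      cohort <- purrr::imap_dfr(blocks, function(args, i) {
        args$seed <- args$seed %||% (seed + as.integer(i))
        simulate_cohort(do.call(cohort_spec, args))
      })
      path <- file.path(out_dir, "cohorts.csv")
      write_cohort_csv(cohort, path)
      manifest$parameters$simulate <- blocks
      manifest$outputs$cohorts <- path
    } else if (stage == "quant") {
      q <- config$quant
      if (is.null(q$image_dir)) stage_abort(stage, "no `quant$image_dir` in config")
      if (!dir.exists(q$image_dir)) {
        stage_abort(stage, sprintf("image directory not found: %s", q$image_dir))
      }
      files <- list.files(q$image_dir, pattern = "\\.png$", full.names = TRUE)
      if (length(files) == 0) stage_abort(stage, "no PNG images found")
      rows <- purrr::map_dfr(files, function(f) {
        img <- read_lobe_png(f, mm_per_px = q$mm_per_px %||% 0.05)
        dplyr::bind_cols(tibble(file = basename(f)),
                         quantify_lobe(img, min_px = q$min_px %||% 5))
      })
      path <- file.path(out_dir, "quant.csv")
      readr::write_csv(rows, path)
      manifest$parameters$quant <- q
      manifest$outputs$quant <- path
    } else if (stage == "fit") {
      cohort <- cohort %||% pipeline_input_cohort(config, out_dir, stage)
      family <- config$fit$family %||% "power"
      fits <- cohort |>
        dplyr::group_by(.data$group) |>
        dplyr::group_map(~ fit_growth(.x, family = family), .keep = TRUE)
      names(fits) <- sort(unique(cohort$group))
      path <- file.path(out_dir, "fits.json")
      jsonlite::write_json(
        purrr::map(fits, ~ list(
          family = .x$family, A0 = .x$amplitude, exponent = .x$exponent,
          stderr = .x$stderr_exponent, n_obs = .x$n_obs,
          n_zero_excluded = .x$n_zero_excluded
        )),
        path, auto_unbox = TRUE, digits = NA
      )
      manifest$parameters$fit <- list(family = family)
      manifest$outputs$fits <- path
    } else if (stage == "project") {
      cohort <- cohort %||% pipeline_input_cohort(config, out_dir, stage)
      pr <- config$project %||% list()
      if (is.null(fits)) stage_abort(stage, "no upstream `fit` stage results")
      cal_group <- pr$calibrate_group %||% names(fits)[1]
      if (!cal_group %in% names(fits)) {
        stage_abort(stage, sprintf("no fit for calibration group '%s'", cal_group))
      }
      cfg <- projection_config(
        family = pr$family %||% fits[[cal_group]]$family,
        exponent = fits[[cal_group]]$exponent,
        threshold_mm2 = pr$threshold_mm2 %||% 300
      )
      records <- cohort
      if (!is.null(pr$day)) records <- dplyr::filter(records, .data$day %in% pr$day)
      proj <- records |>
        dplyr::group_split(.data$group) |>
        purrr::map_dfr(~ project_cohort(.x, cfg))
      class(proj) <- c("projection", class(tibble()))
      attr(proj, "config") <- cfg
      path <- file.path(out_dir, "projections.csv")
      readr::write_csv(as_tibble(proj), path)
      for (g in unique(proj$group)) {
        sub <- proj[proj$group == g, ]
        km <- build_km(sub$km_time, sub$km_event)
        readr::write_csv(as_tibble(km), file.path(out_dir, sprintf("km_%s.csv", g)))
      }
      manifest$parameters$project <- list(
        family = cfg$family, exponent = cfg$exponent,
        threshold_mm2 = cfg$threshold_mm2, calibrate_group = cal_group
      )
      manifest$outputs$projections <- path
    } else if (stage == "compare") {
      groups <- config$compare$groups
      proj_path <- file.path(out_dir, "projections.csv")
      if (!file.exists(proj_path)) {
        stage_abort(stage, "no upstream `project` stage output (projections.csv)")
      }
      proj <- readr::read_csv(proj_path, show_col_types = FALSE)
      groups <- groups %||% unique(proj$group)
      if (length(groups) != 2) stage_abort(stage, "need exactly two groups to compare")
      a <- proj[proj$group == groups[1], ]
      b <- proj[proj$group == groups[2], ]
      if (nrow(a) == 0 || nrow(b) == 0) {
        stage_abort(stage, "a comparison group has no projected mice")
      }
      lr <- logrank_test(a$km_time, b$km_time, a$km_event, b$km_event)
      path <- file.path(out_dir, "compare.json")
      jsonlite::write_json(
        list(groups = groups, chi_square = lr$statistic, p_value = lr$p_value),
        path, auto_unbox = TRUE, digits = NA
      )
      manifest$parameters$compare <- list(groups = groups)
      manifest$outputs$compare <- path
    } else if (stage == "phago") {
      ph <- config$phago %||% list()
      targs <- ph$trajectory %||% list()
      targs$seed <- targs$seed %||% (seed + 97L)
      traj <- simulate_trajectory(do.call(trajectory_spec, targs))
      dec <- fit_decay(traj, window = ph$window %||% c(0, 8))
      path <- file.path(out_dir, "phago.json")
      jsonlite::write_json(
        list(tau_days = dec$tau, slope_per_day = dec$slope, n_obs = dec$n_obs),
        path, auto_unbox = TRUE, digits = NA
      )
      manifest$parameters$phago <- ph
      manifest$outputs$phago <- path
    }
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}

pipeline_input_cohort <- function(config, out_dir, stage) {
  path <- config$input %||% file.path(out_dir, "cohorts.csv")
  if (!file.exists(path)) {
    stage_abort(stage, sprintf("missing upstream cohort table: %s", path))
  }
  read_cohort_csv(path)
}
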