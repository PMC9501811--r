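#' Read and filter occurrence records
#'
#' Reads a comma-delimited occurrence table (GBIF-style columns `species`,
#' `lon`, `lat`, `coordinate_uncertainty_m`, plus any pre-extracted climate
#' columns) and applies the coordinate-quality filter: rows with missing
#' coordinates, coordinates outside valid ranges, or coordinate uncertainty
#' at or above `uncertainty_max_m` are dropped ("less than 1 km" is a
#' strict inequality, so exactly 1000 m is rejected under the default).
#'
#' @param path file path, or a tibble already in memory.
#' @param uncertainty_max_m uncertainty cutoff in metres.
#' @return the filtered tibble; per-species retained counts are reported
#'   via a message.
#' @export
read_occurrences <- function(path, uncertainty_max_m = 1000) {
  occ <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("species", "lon", "lat", "coordinate_uncertainty_m")
  miss <- setdiff(required, names(occ))
  if (length(miss) > 0)
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  n0 <- nrow(occ)
  bad_coord <- is.na(occ$lon) | is.na(occ$lat) |
    abs(occ$lon) > 180 | abs(occ$lat) > 90
  if (any(bad_coord))
    inform(sprintf("%d row(s) rejected: missing or out-of-range coordinates",
                   sum(bad_coord)))
  keep <- !bad_coord & !is.na(occ$coordinate_uncertainty_m) &
    occ$coordinate_uncertainty_m < uncertainty_max_m
  out <- occ[keep, ]
  counts <- dplyr::count(out, .data$species)
  inform(paste0("retained ", nrow(out), "/", n0, " occurrences (",
                paste(counts$species, counts$n, sep = ": ",
                      collapse = "; "), ")"))
  empty <- setdiff(unique(occ$species), unique(out$species))
  if (length(empty) > 0)
    warn(paste0("no occurrences left after filtering for: ",
                paste(empty, collapse = ", ")))
  out
}

#' Read survey plot tables and derive observed UELs
#'
#' Expects columns `plot`, `elevation`, `year`, `species`, `present`
#' (logical or 0/1); an optional `road` column is allowed. Exact duplicate
#' rows are removed with a warning. The observed UEL of a species in a
#' year is the highest plot elevation with a detection, taken across roads
#' (two partially overlapping roads contribute a single per-species
#' maximum).
#'
#' @param path file path, or a tibble already in memory.
#' @return a list with the deduplicated `plots` tibble and `uel`: one row
#'   per species and year with `uel_observed`.
#' @export
read_plots <- function(path) {
  plots <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("plot", "elevation", "year", "species", "present")
  miss <- setdiff(required, names(plots))
  if (length(miss) > 0)
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(plots)) {
    warn(sprintf("%d duplicated plot row(s) removed",
                 nrow(plots) - nrow(dplyr::distinct(plots))))
    plots <- dplyr::distinct(plots)
  }
  uel <- plots |>
    dplyr::filter(as.logical(.data$present)) |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::summarise(uel_observed = max(.data$elevation), .groups = "drop")
  list(plots = plots, uel = uel)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the workflow with range validation: the
#' occurrence-filter cutoff, niche level and grid resolution, HOF fitting
#' controls, the resampling design, seeds, and the statistical flags.
#' Round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param uncertainty_max_m occurrence coordinate-uncertainty cutoff (m).
#' @param niche_level retained niche density mass in (0, 1].
#' @param grid_R environmental grid resolution (cells per axis).
#' @param hof_min_presences minimum presences for a fittable series.
#' @param hof_n_starts multi-start count per HOF model type.
#' @param resample_frac stratum fraction per replicate.
#' @param resample_reps number of resampling replicates.
#' @param seed master integer seed.
#' @param paired_wilcoxon use the signed-rank variant for the temporal test.
#' @param density_correction availability-correct the occurrence density.
#' @param stability_threshold temporal-change stability threshold (m).
#' @param paths named list of file paths (`occurrences`, `background`,
#'   `regional`, `plots`, `out_dir`), all optional.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(uncertainty_max_m = 1000, niche_level = 0.99,
                            grid_R = 100, hof_min_presences = 5,
                            hof_n_starts = 10, resample_frac = 0.25,
                            resample_reps = 100, seed = 1,
                            paired_wilcoxon = FALSE,
                            density_correction = FALSE,
                            stability_threshold = 0, paths = list()) {
  stopifnot(uncertainty_max_m > 0, niche_level > 0, niche_level <= 1,
            grid_R >= 10, hof_min_presences >= 1, hof_n_starts >= 1,
            resample_frac > 0, resample_frac <= 1, resample_reps >= 1,
            stability_threshold >= 0, is.logical(paired_wilcoxon),
            is.logical(density_correction), is.list(paths))
  structure(list(uncertainty_max_m = uncertainty_max_m,
                 niche_level = niche_level, grid_R = as.integer(grid_R),
                 hof_min_presences = as.integer(hof_min_presences),
                 hof_n_starts = as.integer(hof_n_starts),
                 resample_frac = resample_frac,
                 resample_reps = as.integer(resample_reps),
                 seed = as.integer(seed),
                 paired_wilcoxon = paired_wilcoxon,
                 density_correction = density_correction,
                 stability_threshold = stability_threshold,
                 paths = paths),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$paths <- raw$paths %||% list()
  do.call(pipeline_config, raw)
}

pipeline_write <- function(out_dir, name, tbl) {
  if (is.null(out_dir)) return(invisible(NULL))
  readr::write_csv(tbl, file.path(out_dir, paste0(name, ".csv")))
}

#' Run the full equilibrium workflow
#'
#' Orchestrates the four prediction steps and the comparative statistics:
#' occurrence filtering, PCA environmental-space calibration on the global
#' background, per-species niche delineation and regional suitability
#' classification, HOF fitting with stratified resampling of the
#' presence/absence series, equilibrium classification against the
#' observed UELs, and finally the temporal Wilcoxon test,
#' observed-vs-predicted regression and (when traits are given) the trait
#' ANOVA. Species that fail a stage (too few occurrences, unfittable
#' series) are recorded in the skip log and do not affect the others.
#'
#' @param config a [pipeline_config()].
#' @param occurrences,background,regional,plots,traits in-memory tibbles;
#'   any left `NULL` is read from `config$paths`. `regional` must carry the
#'   climate columns and `elevation`.
#' @param out_dir optional output directory; when given, every intermediate
#'   table plus a run manifest (seeds, parameters, failure point) is
#'   written as delimited text.
#' @return a list with `results` (one equilibrium row per fittable
#'   species), `predictions`, `uel` (observed limits per epoch), `stats`
#'   (wilcoxon / regression / traits), `skipped`, and the `manifest`.
#' @export
run_pipeline <- function(config, occurrences = NULL, background = NULL,
                         regional = NULL, plots = NULL, traits = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  out_dir <- out_dir %||% p$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, parameters = unclass(config),
                   started = format(Sys.time()), status = "running",
                   failed_stage = NULL)
  finish <- function(res) {
    manifest$status <- "complete"
    res$manifest <- manifest
    if (!is.null(out_dir))
      yaml::write_yaml(manifest[c("seed", "status", "failed_stage")],
                       file.path(out_dir, "manifest.yml"))
    res
  }

  occurrences <- occurrences %||% readr::read_csv(p$occurrences,
                                                  show_col_types = FALSE)
  if ("coordinate_uncertainty_m" %in% names(occurrences))
    occurrences <- read_occurrences(occurrences, config$uncertainty_max_m)
  background <- background %||% readr::read_csv(p$background,
                                                show_col_types = FALSE)
  regional <- regional %||% readr::read_csv(p$regional,
                                            show_col_types = FALSE)
  surveys <- read_plots(plots %||% p$plots)
  uel_tbl <- surveys$uel
  last_year <- max(uel_tbl$year)

  pca <- env_pca(background)
  bg_scores <- project_env(pca, background)
  reg_scores <- project_env(pca, regional)

  species <- sort(unique(occurrences$species))
  skipped <- character(0)
  predictions <- list()
  results <- list()
  for (sp in species) {
    occ_sp <- dplyr::filter(occurrences, .data$species == sp)
    occ_scores <- project_env(pca, occ_sp)
    grid <- build_env_grid(bg_scores, occ_scores, R = config$grid_R,
                           min_occurrences = config$hof_min_presences,
                           correction = config$density_correction)
    if (is.null(grid)) {
      skipped <- c(skipped, sp)
      next
    }
    niche <- delineate_niche(grid, level = config$niche_level)
    suit <- classify_points(niche, grid, reg_scores) |> attach_elevation()
    pa <- make_pa_series(suit)
    obs <- uel_tbl$uel_observed[uel_tbl$species == sp &
                                  uel_tbl$year == last_year]
    pred <- tryCatch(
      resample_ob(pa, frac = config$resample_frac,
                  n_reps = config$resample_reps, seed = config$seed,
                  n_starts = config$hof_n_starts,
                  min_presences = config$hof_min_presences,
                  species = sp),
      uelshift_unfittable = function(e) {
        inform(sprintf("species '%s' unfittable: %s", sp,
                       conditionMessage(e)))
        NULL
      })
    if (is.null(pred)) {
      skipped <- c(skipped, sp)
      next
    }
    predictions[[sp]] <- pred
    if (length(obs) == 1)
      results[[sp]] <- classify_equilibrium(obs, pred, species = sp)
    pipeline_write(out_dir, paste0("pa_", sp), pa)
  }
  results <- dplyr::bind_rows(results)
  manifest$skipped <- skipped

  stats_out <- list()
  wide <- tidyr::pivot_wider(uel_tbl, names_from = "year",
                             values_from = "uel_observed",
                             names_prefix = "uel_")
  years <- sort(unique(uel_tbl$year))
  if (length(years) >= 2) {
    first_col <- paste0("uel_", years[1])
    last_col <- paste0("uel_", last_year)
    both <- wide[!is.na(wide[[first_col]]) & !is.na(wide[[last_col]]), ]
    if (nrow(both) >= 3) {
      stats_out$wilcoxon <- wilcoxon_uel(both[[first_col]],
                                         both[[last_col]],
                                         paired = config$paired_wilcoxon)
      stats_out$change <- classify_change(
        both, uel_first = .data[[first_col]], uel_last = .data[[last_col]],
        stability_threshold = config$stability_threshold)
    }
  }
  if (nrow(results) >= 3)
    stats_out$regression <- regress_obs_pred(results)
  if (!is.null(traits) && nrow(results) >= 3) {
    td <- dplyr::inner_join(results, traits, by = "species")
    if (nrow(td) > 6)
      stats_out$traits <- trait_model(td, response = .data$delta_std)
  }

  if (!is.null(out_dir)) {
    pipeline_write(out_dir, "background_scores", bg_scores)
    pipeline_write(out_dir, "regional_scores", reg_scores)
    pipeline_write(out_dir, "observed_uel", uel_tbl)
    if (nrow(results) > 0) pipeline_write(out_dir, "results", results)
    ob_tbl <- purrr::imap_dfr(predictions, function(pr, sp)
      tibble::tibble(species = sp, rep = seq_along(pr$ob_samples),
                     ob = pr$ob_samples))
    if (nrow(ob_tbl) > 0) pipeline_write(out_dir, "ob_samples", ob_tbl)
  }
  finish(list(results = results, predictions = predictions, uel = uel_tbl,
              stats = stats_out, skipped = skipped, pca = pca))
}
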