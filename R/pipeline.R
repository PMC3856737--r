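#' End-to-end analysis pipeline
#'
#' Orchestrates the full multi-scale analysis over synthetic inputs:
#' landscape generation, patch delineation, dispersal-threshold connectivity
#' at the six standard distances, stone-component distances, plot occupancy
#' and station inventories, microhabitat model selection, plot-level
#' nonparametric tests and the QDA table. Each stage writes plain-text
#' outputs (CSV / ESRI ASCII) into `out_dir` together with a JSON manifest
#' recording the seed, a config digest and the digests of every output file.
#'
#' @name pipeline_cli
NULL

#' Flag and optionally merge plots that fall in the same forest patch
#'
#' After (re-)delineation, plots can end up in one patch; the analysis then
#' treats them as a single sampling unit (counts and trap nights pooled).
#'
#' @param plots data frame with `plot_id`, `patch_id`, and optionally
#'   `vole_count`, `trap_nights`.
#' @param merge merge co-located plots (default `TRUE`) or only flag them.
#' @return `plots` with a logical `shared_patch` column; merged when asked.
#' @export
merge_plots_in_patch <- function(plots, merge = TRUE) {
  dup <- duplicated(plots$patch_id) | duplicated(plots$patch_id, fromLast = TRUE)
  plots$shared_patch <- dup
  if (!merge || !any(dup)) return(plots)
  out <- lapply(split(plots, plots$patch_id), function(g) {
    r <- g[1, , drop = FALSE]
    if (nrow(g) > 1) {
      if (!is.null(g$vole_count)) r$vole_count <- sum(g$vole_count)
      if (!is.null(g$trap_nights)) r$trap_nights <- sum(g$trap_nights)
    }
    r
  })
  out <- do.call(rbind, out)
  out <- out[order(out$plot_id), ]
  rownames(out) <- NULL
  out
}

#' Read a synthetic-study configuration from a YAML file
#'
#' The file holds any subset of the [synthetic_config()] arguments as
#' top-level keys; unspecified fields keep their defaults. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return A `synthetic_config`.
#' @export
config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(synthetic_config, vals)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # canonical text form, stable across sessions
  writeLines(paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), sep = "="), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on a synthetic landscape
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created; wiped of this run's partial
#'   outputs on failure).
#' @param thresholds dispersal thresholds in metres.
#' @param candidate_variables covariates entered into the all-subsets
#'   microhabitat dredge; defaults to the prefilter survivors, truncated to
#'   the first `max_candidates` in inventory order if there are more.
#' @param max_candidates cap on dredged covariates (default 12; 2^12 models).
#' @param nAGQ passed to the mixed-model fits.
#' @param write_rasters also write the age / land-class / stone / label /
#'   accumulated-cost rasters as ESRI ASCII (default `TRUE`).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         thresholds = c(250, 500, 1000, 1500, 2000, 3000),
                         candidate_variables = NULL, max_candidates = 12,
                         nAGQ = 1, write_rasters = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!length(thresholds) || any(thresholds <= 0))
    stop("pipeline stage 'validate' failed: threshold list empty or non-positive")
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name, raster = FALSE) {
    path <- file.path(out_dir, name)
    if (raster) write_esri_ascii(obj, path)
    else utils::write.csv(obj, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  }
  res <- tryCatch({
    land <- pipeline_stage("generate_landscape", generate_landscape(config))
    patches <- pipeline_stage("label_patches", label_patches(land$age, min_age = 60))
    ptab <- patch_table(patches)
    emit(ptab, "patch_table.csv")
    dmat <- pipeline_stage("patch_distances",
                           patch_distance_matrix(patches, max_distance = max(thresholds)))
    conn <- pipeline_stage("connectivity",
                           connectivity_table(patches, thresholds, dist_matrix = dmat))
    for (d in unique(conn$d))
      emit(conn[conn$d == d, ], sprintf("connectivity_d%04d.csv", d))
    fields <- pipeline_stage("stone_fields", stone_fields_from_raster(land$stone))
    comps <- pipeline_stage("stone_components",
                            filter_components(build_stone_components(fields, 1000), 100))
    surf <- cost_surface(land$landclass)
    plots <- pipeline_stage("place_plots", place_plots(patches, config))
    plots <- merge_plots_in_patch(plots)
    sd_tab <- pipeline_stage("stone_distances",
                             plot_to_component_distances(plots, comps, surf))
    plots <- merge(plots, sd_tab, by = "plot_id")
    cd <- conn[conn$d == config$conn_distance, c("patch_id", "C")]
    if (!nrow(cd)) stop("pipeline stage 'connectivity' failed: conn_distance not in thresholds")
    plots <- merge(plots, cd, by = "patch_id")
    plots <- plots[order(plots$plot_id), ]
    plots <- pipeline_stage("simulate_occupancy", simulate_occupancy(plots, config))
    emit(plots, "plot_table.csv")
    stations <- pipeline_stage("simulate_stations", simulate_stations(plots, config))
    emit(stations, "station_table.csv")
    # microhabitat model selection
    keep1 <- collinearity_filter(stations)
    keep2 <- variance_filter(stations, variables = keep1)
    cand <- if (is.null(candidate_variables)) utils::head(keep2, max_candidates)
            else candidate_variables
    dr <- pipeline_stage("dredge", dredge_stations(stations, cand, nAGQ = nAGQ))
    emit(as.data.frame(dr), "candidate_models.csv")
    avg <- model_average(dr)
    emit(avg, "model_averaged.csv")
    # plot-level comparisons
    occ <- plots$occupied == 1
    mw <- function(v) {
      if (all(occ) || !any(occ)) return(c(U = NA, p = NA))
      unlist(mann_whitney(plots[[v]][occ], plots[[v]][!occ]))
    }
    tests <- rbind(
      data.frame(variable = "area_ha", t(mw("area_ha"))),
      data.frame(variable = "C", t(mw("C"))),
      data.frame(variable = "euclid_m", t(mw("euclid_m"))),
      data.frame(variable = "lcp_cost", t(mw("lcp_cost"))))
    within <- plots$euclid_m <= 1500
    tab <- matrix(c(sum(within & occ), sum(!within & occ),
                    sum(within & !occ), sum(!within & !occ)), 2, byrow = TRUE)
    tests <- rbind(tests,
                   data.frame(variable = "within_1500m", U = NA, p = fisher_exact(tab)))
    emit(tests, "plot_tests.csv")
    # density correlations (log density vs log predictors)
    dens <- lapply(c(area = "area_ha", C = "C"), function(v)
      tryCatch(pearson_corr(plots[[v]], plots$density, "log", "log"),
               error = function(e) list(r = NA, p = NA, n = NA)))
    emit(data.frame(predictor = names(dens),
                    r = vapply(dens, `[[`, 0, "r"),
                    p = vapply(dens, `[[`, 0, "p")), "density_correlations.csv")
    # QDA on landscape predictors
    qt <- tryCatch(
      qda_table(plots, "occupied",
                list(area = "area_ha", C = "C", lcp = "lcp_cost",
                     `area+C` = c("area_ha", "C"),
                     `area+C+lcp` = c("area_ha", "C", "lcp_cost"))),
      error = function(e) data.frame(predictors = NA, note = conditionMessage(e)))
    emit(qt, "qda_table.csv")
    if (write_rasters) {
      emit(land$age, "age.asc", raster = TRUE)
      emit(land$landclass, "landclass.asc", raster = TRUE)
      emit(land$stone, "stone.asc", raster = TRUE)
      emit(patch_label_raster(patches, land$age), "patch_labels.asc", raster = TRUE)
    }
    manifest <- list(
      seed = config$seed,
      config_md5 = config_digest(config),
      package_version = as.character(utils::packageVersion("volescape")),
      thresholds = thresholds,
      outputs = as.list(tools::md5sum(sort(written))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(landscape = land, patches = patches, connectivity = conn,
         components = comps, plots = plots, stations = stations,
         models = dr, averaged = avg, tests = tests, qda = qt,
         manifest = manifest)
  }, error = on_fail)
  invisible(res)
}
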