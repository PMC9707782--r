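#' Pipeline configuration
#'
#' Defaults mirror the study: a 30-minute independence gap, 150 m covariate
#' and 500 m conflict buffers, UTC-8 civil time, 1000 permutation-null
#' iterations for the nocturnality test and 999 for Moran's I.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param gap Independence gap in minutes.
#' @param utc_offset Local civil offset from UTC (hours).
#' @param buffer_covariate,buffer_conflict Buffer radii in metres.
#' @param n_boot Nocturnality null iterations.
#' @param n_perm Moran's I permutations.
#' @param n_starts,nagq Optimization starts and quadrature nodes for model
#'   fits.
#' @param model_sets Which candidate sets to fit: any of `"habitat"`
#'   (the spatial habitat-use set) and `"seasonal"` (the seasonal
#'   conflict-probability set).
#' @param truth Optional [truth_config()] used when no input data are
#'   supplied.
#' @return List of class `btk_config`.
#' @export
pipeline_config <- function(seed = 1, gap = 30, utc_offset = -8,
                            buffer_covariate = 150, buffer_conflict = 500,
                            n_boot = 1000, n_perm = 999,
                            n_starts = 2, nagq = 15,
                            model_sets = c("habitat", "seasonal"),
                            truth = NULL) {
  structure(as.list(environment()), class = "btk_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; `truth:` keys
#' override [truth_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `btk_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  truth_args <- y$truth %||% list()
  y$truth <- NULL
  cfg_args <- y[names(y) %in% names(formals(pipeline_config))]
  bad <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(bad) > 0) {
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- do.call(pipeline_config, cfg_args)
  if (length(truth_args) > 0) {
    cfg$truth <- do.call(truth_config, truth_args)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a study bundle: independence filtering and
#' diel classification of the raw records, the site-month count/effort
#' table and detection rates, covariate standardization and collinearity
#' screening, both candidate-model comparisons, the nocturnality analysis,
#' and the Moran's I residual diagnostic. Each stage's table is written as
#' CSV to `out_dir` together with a JSON manifest recording seeds and the
#' configuration hash. Partial outputs are removed if a stage fails.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param bundle A `btk_bundle`; generated from `config$truth` when `NULL`.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         bundle = NULL) {
  stopifnot(inherits(config, "btk_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit({
    if (!ok && length(written) > 0) unlink(written)
  })
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  if (is.null(bundle)) {
    truth <- config$truth %||% truth_config(seed = config$seed)
    bundle <- generate_study(truth)
  }

  # stage: events
  events <- independent_events(bundle$records, gap = config$gap)
  events <- classify_diel(events, bundle$deployments,
                          utc_offset = config$utc_offset)
  emit(dplyr::select(events, "site_id", "event_time", "diel", "stratum"),
       "events.csv")

  # stage: site-month table
  site_months <- monthly_counts(events, bundle$deployments,
                                utc_offset = config$utc_offset)
  site_months <- detection_rate(site_months)
  emit(site_months, "site_month.csv")

  # stage: covariates (join, standardize, collinearity screen)
  model_tab <- site_months |>
    dplyr::select("site_id", "month", "stratum", "count", "effort",
                  "season") |>
    dplyr::left_join(dplyr::select(bundle$covariates, -"stratum", -"season"),
                     by = c("site_id", "month"))
  model_tab <- standardize(model_tab,
                           cols = c("HD", "RD", "TD", "Ele", "DUrb", "DAg",
                                    "DW", "EVI", "Con", "conflict_prob"))
  screen <- collinearity_screen(
    model_tab, cols = c("HD", "RD", "TD", "Ele", "DUrb", "DAg", "DW", "EVI"))
  emit(tidyr::pivot_longer(model_tab, cols = -c("site_id", "month",
                                                "stratum", "season"),
                           names_to = "variable", values_to = "value"),
       "covariates.csv")
  emit(screen, "collinearity.csv")

  fits <- list()
  comparisons <- list()
  if ("habitat" %in% config$model_sets) {
    fits$habitat <- purrr::map(
      table1_model_set(),
      function(s) fit_zinb(model_tab, s, n_starts = config$n_starts,
                           seed = config$seed, nagq = config$nagq))
    comparisons$habitat <- compare_models(fits$habitat)
    emit(comparisons$habitat, "comparison_habitat.csv")
    emit(purrr::map_dfr(fits$habitat, tidy, .id = "model"),
         "fits_habitat.csv")
  }
  if ("seasonal" %in% config$model_sets) {
    fits$seasonal <- fit_table2(model_tab, n_starts = config$n_starts,
                                seed = config$seed, nagq = config$nagq)
    comparisons$seasonal <- compare_models(fits$seasonal)
    emit(comparisons$seasonal, "comparison_seasonal.csv")
    emit(purrr::map_dfr(fits$seasonal, tidy, .id = "model"),
         "fits_seasonal.csv")
  }

  # stage: nocturnality
  noct <- nocturnality_analysis(events, n_iter = config$n_boot,
                                seed = config$seed)
  emit(noct, "nocturnality.csv")

  # stage: spatial diagnostic on the best habitat-use model
  moran <- NULL
  if (length(fits) > 0) {
    all_fits <- purrr::flatten(unname(fits))
    best <- all_fits[[which.min(vapply(all_fits, function(f) f$AICc,
                                       numeric(1)))]]
    res <- site_residuals(best, model_tab)
    res <- dplyr::left_join(res, bundle$sites[c("site_id", "x", "y")],
                            by = "site_id")
    moran <- morans_i(res$residual, res[c("x", "y")],
                      n_perm = config$n_perm, seed = config$seed)
    emit(moran, "moran.csv")
  }

  manifest <- list(
    package = "beartrack",
    version = as.character(utils::packageVersion("beartrack")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "truth")]),
    bundle_seed = bundle$truth$seed,
    n_events = nrow(events),
    files = basename(written),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  written <- c(written, manifest_path)
  ok <- TRUE
  invisible(list(
    out_dir = out_dir, files = written, events = events,
    site_months = site_months, model_table = model_tab,
    collinearity = screen, fits = fits, comparisons = comparisons,
    nocturnality = noct, moran = moran, manifest = manifest
  ))
}

#' Read and validate a detections CSV
#'
#' Expected columns: `site_id`, `timestamp` (ISO-8601 with offset),
#' `species`. Schema violations are reported with row numbers.
#'
#' @param path CSV path.
#' @return Tibble with parsed timestamps (POSIXct, UTC).
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "timestamp", "species")
  if (!all(need %in% names(d))) {
    stop("detections file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  fmts <- c("%Y-%m-%dT%H:%M:%S%z", "%Y-%m-%d %H:%M:%S%z",
            "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")
  ts <- as.POSIXct(rep(NA_real_, nrow(d)), origin = "1970-01-01", tz = "UTC")
  for (fmt in fmts) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(d$timestamp[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts) & !is.na(d$timestamp))
  if (length(bad) > 0) {
    stop("unparseable timestamps at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(site_id = as.character(d$site_id), timestamp = ts,
                 species = d$species)
}

#' Read and validate a deployments CSV
#'
#' Expected columns: `site_id`, `lat`, `lon`, `stratum`, `month`
#' (`YYYY-MM`), `active_days`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_deployments <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "lat", "lon", "stratum", "month", "active_days")
  if (!all(need %in% names(d))) {
    stop("deployments file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  bad <- which(d$active_days > days_in_month(d$month) | d$active_days < 0)
  if (length(bad) > 0) {
    stop("active_days outside 0..days-in-month at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(d)
}
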