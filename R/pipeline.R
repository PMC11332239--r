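#' Run the full attractiveness pipeline from a config
#'
#' Orchestrates quantify -> consensus -> prepare -> fit -> validate from a
#' single configuration (an R list or a YAML file path). The config sets
#' exactly one input source: a simulation `scenario` (parameters for
#' [simulate_scenario()]) or real `inputs` (paths to an image directory, a
#' ratings CSV and a traits CSV). All stage outputs are written as CSV under
#' `output_dir` together with a JSON manifest recording the seed, package
#' version and MD5 checksum of every output file; reruns with the same
#' config and seed reproduce the checksums exactly.
#'
#' Config fields (all optional unless noted): `scenario` (list; see
#' [simulate_scenario()]) or `inputs` (list with `images_dir`, `ratings`,
#' `traits`) -- exactly one required; `output_dir` (required); `seed`
#' (default 1); `grid` (list `a_bins`, `b_bins`, `L_bins`); `models`
#' (battery selection, default `"main"`); `screen_threshold`;
#' `write_images` (write the synthetic PNGs, default `FALSE`).
#'
#' @param config A named list or the path of a YAML file.
#' @return A list of class `pipeline_result`: `profiles`, `estimates`,
#'   `prepared`, `fits`, `diagnostics`, `summaries` (family- and
#'   order-level), `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(!is.list(config), "config must be a list or a YAML path")
  has_scn <- !is.null(config$scenario)
  has_inp <- !is.null(config$inputs)
  abort_if(has_scn == has_inp,
           "config must set exactly one of 'scenario' and 'inputs'")
  abort_if(is.null(config$output_dir), "config must set 'output_dir'")
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  g <- config$grid %||% list()
  grid <- lab_grid(a_bins = g$a_bins %||% 12, b_bins = g$b_bins %||% 12,
                   L_bins = g$L_bins %||% 4)
  models <- config$models %||% "main"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- inputs ------------------------------------------------------------
  if (has_scn) {
    scn_args <- config$scenario
    tx <- scn_args$taxonomy %||% list()
    spec <- taxonomy_spec(
      n_orders = tx$n_orders %||% 3,
      families_per_order = unlist(tx$families_per_order %||% 2),
      genera_per_family = unlist(tx$genera_per_family %||% 2),
      species_per_genus = unlist(tx$species_per_genus %||% 4),
      dichromatic_fraction = tx$dichromatic_fraction %||% 0.3,
      seed = seed)
    scenario <- stage("simulate", simulate_scenario(
      spec, image_size = scn_args$image_size %||% 32, seed = seed))
    images <- scenario$images
    ratings <- scenario$ratings
    traits <- scenario$traits
    if (isTRUE(config$write_images)) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (nm in names(images)) {
        write_plumage_png(images[[nm]],
                          file.path(img_dir, paste0(gsub(":", "_", nm), ".png")))
      }
    }
  } else {
    inp <- config$inputs
    abort_if(is.null(inp$images_dir) || is.null(inp$ratings) || is.null(inp$traits),
             "inputs must set images_dir, ratings and traits")
    files <- sort(list.files(inp$images_dir, pattern = "\\.png$",
                             full.names = TRUE))
    abort_if(length(files) == 0, "no PNG images found in images_dir")
    images <- stage("load", lapply(files, read_plumage_png))
    names(images) <- sub("\\.png$", "", basename(files))
    names(images) <- sub("_(male|female|undefined)$", ":\\1", names(images))
    ratings <- tibble::as_tibble(utils::read.csv(inp$ratings))
    traits <- tibble::as_tibble(utils::read.csv(inp$traits))
    scenario <- NULL
  }

  # --- stages ------------------------------------------------------------
  profiles <- stage("quantify", color_profile(images, grid = grid))
  estimates <- stage("consensus", fit_consensus(ratings))
  prepared <- stage("prepare", prepare_traits(
    traits, profiles = profiles, estimates = estimates,
    screen_threshold = config$screen_threshold %||% 0.6))
  fits <- stage("fit", run_model_battery(prepared, models = models))
  diagnostics <- stage("validate", if (length(fits)) validate(fits[[1]]))
  summaries <- stage("report", list(
    family = grouped_summary(estimates, level = "family"),
    order = grouped_summary(estimates, level = "order")
  ))

  # --- outputs -----------------------------------------------------------
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    path
  }
  paths <- c(
    wr(profiles, "color_profiles.csv"),
    wr(estimates, "estimates.csv"),
    wr(prepared[, !vapply(prepared, is.list, logical(1))], "prepared_traits.csv"),
    wr(effect_table(fits), "effects.csv"),
    wr(attr(prepared, "screen")$report, "collinearity_report.csv"),
    wr(summaries$family, "summary_family.csv"),
    wr(summaries$order, "summary_order.csv")
  )
  if (!is.null(diagnostics)) {
    paths <- c(paths, wr(tibble::tibble(residual = diagnostics$residuals,
                                        fitted = diagnostics$fitted),
                         "residuals.csv"))
  }
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("plumagescore")),
    grid = list(a_bins = grid$a_bins, b_bins = grid$b_bins,
                L_bins = grid$L_bins),
    models = as.list(models),
    n_units = nrow(profiles),
    n_ratings = nrow(ratings),
    checksums = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                        basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(profiles = profiles, estimates = estimates,
                 prepared = prepared, fits = fits,
                 diagnostics = diagnostics, summaries = summaries,
                 manifest = manifest, scenario = scenario,
                 output_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d units, %d model fit(s), outputs in %s\n",
              nrow(x$profiles), length(x$fits), x$output_dir))
  invisible(x)
}

#' Group-level summaries of attractiveness scores or residuals
#'
#' Per family or per order: mean, SD and count of a score column, e.g. raw
#' consensus scores, or model residuals joined onto the table.
#'
#' @param estimates A table with taxonomy columns and the value column.
#' @param level `"family"` or `"order"`.
#' @param value Name of the column to summarise (default `"raw_score"`).
#' @return A tibble with `level` column, `mean`, `sd`, `n`.
#' @export
grouped_summary <- function(estimates, level = c("family", "order"),
                            value = "raw_score") {
  level <- match.arg(level)
  abort_if(is.null(estimates[[level]]),
           sprintf("estimates lack a '%s' column", level))
  abort_if(is.null(estimates[[value]]),
           sprintf("estimates lack a '%s' column", value))
  dplyr::summarise(
    dplyr::group_by(estimates, dplyr::across(dplyr::all_of(level))),
    mean = mean(.data[[value]], na.rm = TRUE),
    sd = stats::sd(.data[[value]], na.rm = TRUE),
    n = dplyr::n(), .groups = "drop")
}
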