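#' Assemble the model-ready predictor table
#'
#' Joins the species-trait table with colour profiles and consensus
#' attractiveness estimates (both keyed by the species x sex `unit`), then
#' applies the standard preparation: residual ornament allometry for beak
#' and tail, categorical reclassification of IUCN / trophic / migration raw
#' labels, absolute latitude, log transforms of body mass and range size,
#' and z-scaling of all continuous predictors. Finishes with a collinearity
#' screen; colour diversity (`loci`) is on the documented drop list because
#' it correlates strongly with several colour proportions, and is analysed
#' in a separate model instead.
#'
#' @param traits Raw trait table: one row per unit with `unit`, taxonomy
#'   columns, `body_mass` (g), `beak_length`, `tail_length` (mm), `crest`
#'   (0-3), and optionally `range_size` (km^2), `latitude`, `iucn_raw`,
#'   `trophic_raw`, `migration_raw`.
#' @param profiles Output of [color_profile()] (joined by `unit`); may be
#'   `NULL` if colour columns are already present.
#' @param estimates Output of [fit_consensus()] (provides `response`); may
#'   be `NULL` if `traits` already carries a response.
#' @param screen_threshold Absolute Pearson correlation threshold for the
#'   collinearity report (default 0.6).
#' @param drop Documented predictor drop list for the screen (default
#'   `"loci"`).
#' @return The prepared tibble with attributes `scaling` (from
#'   [transform_and_scale()]) and `screen` (a `collinearity_screen`).
#' @export
prepare_traits <- function(traits, profiles = NULL, estimates = NULL,
                           screen_threshold = 0.6, drop = "loci") {
  abort_if(is.null(traits$unit), "traits must carry a 'unit' column")
  d <- tibble::as_tibble(traits)
  if (!is.null(profiles)) {
    d <- dplyr::left_join(d, profiles, by = "unit",
                          suffix = c(".true", ""))
  }
  if (!is.null(estimates)) {
    est <- estimates[, c("unit", "raw_score", "response", "se", "n_ratings")]
    d <- dplyr::left_join(d, est, by = "unit", suffix = c(".true", ""))
  }
  if (!is.null(d$beak_length)) {
    d$rel_beak <- relative_ornament(d$beak_length, d$body_mass)
  }
  if (!is.null(d$tail_length)) {
    d$rel_tail <- relative_ornament(d$tail_length, d$body_mass)
  }
  if (!is.null(d$iucn_raw)) d$iucn <- reclassify_iucn(d$iucn_raw)
  if (!is.null(d$trophic_raw)) d$trophic <- reclassify_trophic(d$trophic_raw)
  if (!is.null(d$migration_raw)) {
    d$migration <- reclassify_migration(d$migration_raw)
  }
  if (!is.null(d$latitude)) d$abs_latitude <- abs(d$latitude)

  log_vars <- intersect(c("body_mass", "range_size"), names(d))
  cont <- intersect(c("body_mass", "crest", "rel_beak", "rel_tail",
                      "elaboration", PLUMAGE_CATEGORIES,
                      paste0("light_", SPLITTABLE_CATEGORIES),
                      paste0("dark_", SPLITTABLE_CATEGORIES),
                      "loci", "range_size", "abs_latitude"),
                    names(d))
  cont <- cont[vapply(cont, function(v) {
    s <- stats::sd(d[[v]], na.rm = TRUE); is.finite(s) && s > 0
  }, logical(1))]
  d <- transform_and_scale(d, log_vars = intersect(log_vars, cont),
                           abs_vars = character(), scale_vars = cont)
  screen_vars <- intersect(c("body_mass", "crest", "rel_beak", "rel_tail",
                             "elaboration", PLUMAGE_CATEGORIES, "loci",
                             "range_size", "abs_latitude"), cont)
  scr <- collinearity_screen(d, vars = screen_vars,
                             threshold = screen_threshold, drop = drop)
  attr(d, "screen") <- scr
  d
}
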