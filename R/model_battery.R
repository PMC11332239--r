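# Standard column conventions for prepared analysis tables; the battery
# builds all model formulas from these names.
MAIN_TERMS <- c("sex", "body_mass", "crest", "rel_beak", "rel_tail",
                "elaboration", "black", "white", "yellow", "blue", "red",
                "green")
EXTRA_TERMS <- c("trophic", "iucn", "range_size", "abs_latitude", "migration")
TAXO_RE <- c("order", "family", "genus", "species_id")

battery_formula <- function(fixed, random = TAXO_RE) {
  stats::as.formula(paste(
    "response ~", paste(fixed, collapse = " + "),
    if (length(random)) paste("+", paste(sprintf("(1 | %s)", random),
                                         collapse = " + ")) else ""))
}

#' Fit the full battery of attractiveness models
#'
#' Fits the main model (sex, body mass, crest, relative beak and tail
#' length, colour elaboration and the six focal colour proportions, with
#' taxonomic random intercepts), the extended model (adding trophic level,
#' IUCN status, range size, absolute latitude and migration), three
#' sex-subset models (dropping the sex term and the species random factor),
#' dark- and light-colour variants (replacing red, blue and green by their
#' dark or light forms), a colour-diversity model (colours replaced by the
#' number of occupied loci) and a dull-colours model (colours replaced by
#' brown, grey, rufous and purple).
#'
#' @param data A prepared analysis table (see [prepare_traits()] /
#'   [simulate_scenario()]): one row per species x sex unit with a
#'   `response` in (0,1), z-scaled continuous predictors under the standard
#'   names, a `sex` column, and taxonomy columns `order`, `family`,
#'   `genus`, `species_id`. `"undefined"` is set as the sex reference
#'   class.
#' @param models Character vector choosing which fits to run.
#' @param control Passed to [beta_glmm()].
#' @return Named list of `beta_glmm` fits (class `model_battery`). Empty
#'   subsets are skipped with a message.
#' @export
run_model_battery <- function(data,
                              models = c("main", "extended", "males",
                                         "females", "undefined", "dark",
                                         "light", "loci", "dull"),
                              control = beta_glmm_control()) {
  models <- match.arg(models, several.ok = TRUE)
  abort_if(is.null(data$response), "data must carry a 'response' column")
  data$sex <- factor(data$sex, levels = c("undefined", "male", "female"))
  have <- function(v) all(v %in% names(data))
  use_terms <- function(tt) tt[vapply(tt, function(v) {
    !is.null(data[[v]]) && length(unique(data[[v]])) > 1
  }, logical(1))]

  fits <- list()
  run <- function(name, fixed, random = TAXO_RE, subset = NULL) {
    d <- if (is.null(subset)) data else data[subset, , drop = FALSE]
    if (nrow(d) == 0) {
      message(sprintf("model '%s': empty subset, skipped", name))
      return(invisible(NULL))
    }
    fixed <- use_terms(fixed)
    fits[[name]] <<- beta_glmm(battery_formula(fixed, random), d,
                               control = control)
  }

  if ("main" %in% models) run("main", MAIN_TERMS)
  if ("extended" %in% models && have(EXTRA_TERMS)) {
    run("extended", c(MAIN_TERMS[1], EXTRA_TERMS, MAIN_TERMS[-1]))
  }
  subset_terms <- setdiff(MAIN_TERMS, "sex")
  subset_re <- setdiff(TAXO_RE, "species_id")
  sex_of <- c(males = "male", females = "female", undefined = "undefined")
  for (s in intersect(models, names(sex_of))) {
    run(s, subset_terms, subset_re, subset = data$sex == sex_of[[s]])
  }
  tone_terms <- function(tone) {
    c(setdiff(MAIN_TERMS, c("blue", "red", "green")),
      paste0(tone, "_", c("blue", "red", "green")))
  }
  if ("dark" %in% models && have(paste0("dark_", c("blue", "red", "green")))) {
    run("dark", tone_terms("dark"))
  }
  if ("light" %in% models && have(paste0("light_", c("blue", "red", "green")))) {
    run("light", tone_terms("light"))
  }
  colour_terms <- c("black", "white", "yellow", "blue", "red", "green")
  if ("loci" %in% models && have("loci")) {
    run("loci", c(setdiff(MAIN_TERMS, colour_terms), "loci"))
  }
  if ("dull" %in% models && have(c("brown", "grey", "rufous", "purple"))) {
    run("dull", c(setdiff(MAIN_TERMS, colour_terms),
                  "brown", "grey", "rufous", "purple"))
  }
  structure(fits, class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat(sprintf("model battery: %d fit(s)\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-10s n = %5d, logLik = %10.2f, converged = %s\n",
                nm, x[[nm]]$n, x[[nm]]$logLik, x[[nm]]$converged))
  }
  invisible(x)
}

#' Tidy coefficient table for one or more fits
#'
#' @param fits A `beta_glmm` fit or a `model_battery`.
#' @return A tibble with columns `model`, `term`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `z`, `p`.
#' @export
effect_table <- function(fits) {
  if (inherits(fits, "beta_glmm")) fits <- list(fit = fits)
  dplyr::bind_rows(lapply(names(fits), function(nm) {
    dplyr::mutate(fits[[nm]]$coefficients, model = nm, .before = 1)
  }))
}
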