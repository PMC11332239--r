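#' Transform a raw consensus score to the unit interval
#'
#' Consensus scores live on 0..9 (converted from the original 1..10 rating
#' scale); dividing by 10 gives a response on \[0, 0.9\] suitable for a beta
#' model. Because the transform can attain exactly 0, boundary values are
#' squeezed with the standard compression `(y * (n - 1) + 0.5) / n`, where
#' `n` is the number of scores in the panel. By default only boundary values
#' (0 or 1 after division) are squeezed, keeping interior scores exactly
#' `raw / 10`; `squeeze = "all"` applies the compression to every value.
#'
#' @param raw Numeric scores in `[0, 9]`.
#' @param n Panel size used in the squeeze (default `length(raw)`).
#' @param squeeze `"boundary"` (default) or `"all"`.
#' @return Values strictly inside (0, 1).
#' @examples
#' transform_response(9)            # 0.9
#' transform_response(0, n = 100)   # 0.005
#' @export
transform_response <- function(raw, n = length(raw),
                               squeeze = c("boundary", "all")) {
  squeeze <- match.arg(squeeze)
  abort_if(any(raw < 0 | raw > 9, na.rm = TRUE),
           "raw scores must lie in [0, 9]")
  y <- raw / 10
  sq <- function(v) (v * (n - 1) + 0.5) / n
  if (squeeze == "all") y <- sq(y) else {
    hit <- y <= 0 | y >= 1
    y[hit] <- sq(y[hit])
  }
  y
}

majority_level <- function(x) names(which.max(table(x)))

#' Estimate consensus attractiveness scores from raw ratings
#'
#' Fits a Gaussian linear mixed model (ML) to the integer 1..10 ratings with
#' fixed effects for photo quality, rater language and sex, and random
#' intercepts for photo and for the species x sex unit plus genus, family
#' and order. The per-unit consensus score is the model prediction at
#' reference conditions -- best photo quality (5) and the majority language
#' -- plus the unit's (and its taxonomy's) BLUPs. The likelihood of the
#' original crowd-consensus model is not public; the Gaussian LMM here is a
#' documented approximation of its stated structure.
#'
#' Terms without variation in the data (e.g. a single language) are dropped
#' automatically; a response with zero variance short-circuits to the
#' trivial per-unit mean.
#'
#' @param ratings Rating table with columns `rating`, `photo_quality`,
#'   `rater_language`, `photo_id`, `species_id`, `sex` and optionally
#'   `genus`, `family`, `order` (see [simulate_ratings()]).
#' @param reference_quality Photo quality at which scores are predicted
#'   (default 5, the best).
#' @param squeeze Passed to [transform_response()].
#' @return A tibble of class `attractiveness_estimates`, one row per
#'   species x sex unit: `species_id`, `sex`, `unit`, taxonomy columns if
#'   present, `raw_score` in `[0, 9]`, `response` in (0, 1), `se` (standard
#'   error of the unit prediction on the raw scale), `n_ratings`. The lme4
#'   fit is attached as attribute `fit`.
#' @export
fit_consensus <- function(ratings, reference_quality = 5,
                          squeeze = c("boundary", "all")) {
  squeeze <- match.arg(squeeze)
  needed <- c("rating", "photo_id", "species_id", "sex")
  missing <- setdiff(needed, names(ratings))
  abort_if(length(missing) > 0,
           paste("ratings table lacks columns:", paste(missing, collapse = ", ")))
  abort_if(any(ratings$rating < 1 | ratings$rating > 10),
           "ratings must lie in 1..10")
  ratings$unit <- ratings$unit %||% paste(ratings$species_id, ratings$sex, sep = ":")

  units <- dplyr::distinct(
    ratings[, intersect(c("unit", "species_id", "sex", "genus", "family",
                          "order"), names(ratings))])
  nr <- dplyr::count(ratings, .data$unit, name = "n_ratings")
  units <- dplyr::left_join(units, nr, by = "unit")

  # degenerate panel: no variance to model
  if (stats::var(ratings$rating) == 0) {
    units$raw_score <- ratings$rating[1] - 1
    units$se <- 0
    units$response <- transform_response(units$raw_score, n = nrow(units),
                                         squeeze = squeeze)
    class(units) <- c("attractiveness_estimates", class(units))
    return(units)
  }

  has_var <- function(v) !is.null(ratings[[v]]) &&
    length(unique(ratings[[v]])) > 1
  fixed <- c(if (has_var("photo_quality")) "photo_quality",
             if (has_var("rater_language")) "rater_language",
             if (has_var("sex")) "sex")
  rand <- c("photo_id", "unit",
            intersect(c("genus", "family", "order"), names(ratings)))
  rand <- rand[vapply(rand, has_var, logical(1))]
  fml <- stats::as.formula(paste(
    "rating ~", paste(c("1", fixed), collapse = " + "), "+",
    paste(sprintf("(1 | %s)", rand), collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = ratings, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))

  fe <- lme4::fixef(fit)
  pred <- rep(unname(fe["(Intercept)"]), nrow(units))
  if ("photo_quality" %in% fixed) {
    pred <- pred + unname(fe["photo_quality"]) * reference_quality
  }
  if ("rater_language" %in% fixed) {
    ref_lang <- majority_level(ratings$rater_language)
    coefn <- paste0("rater_language", ref_lang)
    if (coefn %in% names(fe)) pred <- pred + unname(fe[coefn])
  }
  if ("sex" %in% fixed) {
    coefn <- paste0("sex", units$sex)
    pred <- pred + ifelse(coefn %in% names(fe), fe[coefn], 0)
  }
  re <- lme4::ranef(fit, condVar = TRUE)
  condvar <- rep(0, nrow(units))
  for (g in intersect(names(re), c("unit", "genus", "family", "order"))) {
    u <- re[[g]]
    pos <- match(units[[g]], rownames(u))
    pred <- pred + ifelse(is.na(pos), 0, u[pos, 1])
    if (g == "unit") {
      pv <- attr(u, "postVar")
      condvar <- ifelse(is.na(pos), NA_real_, pv[1, 1, pos])
    }
  }
  units$raw_score <- clamp(pred - 1, 0, 9)
  units$se <- sqrt(condvar)
  units$response <- transform_response(units$raw_score, n = nrow(units),
                                       squeeze = squeeze)
  attr(units, "fit") <- fit
  class(units) <- c("attractiveness_estimates", class(units))
  units
}
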