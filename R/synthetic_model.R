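#' Simulate attractiveness responses from a beta mixed model
#'
#' Draws a response on (0,1) from the same generative structure the fitting
#' module assumes: logit of the mean is a linear combination of trait
#' columns plus independent Gaussian random intercepts for order, family,
#' genus and species, and the response is Beta(mu * phi, (1 - mu) * phi).
#'
#' @param traits A tibble containing the predictor columns named in `beta`,
#'   a `sex` column (optional) and taxonomy columns (`order`, `family`,
#'   `genus`, `species_id`) for any grouping named in `sigma`.
#' @param beta Named numeric vector of coefficients on (numeric) trait
#'   columns.
#' @param intercept Fixed intercept on the logit scale (default 0).
#' @param sex_effect Named numeric vector, e.g. `c(male = 0.2, female =
#'   0.1)`; `"undefined"` is the reference and contributes 0.
#' @param sigma Named vector of random-intercept standard deviations over a
#'   subset of `c("order", "family", "genus", "species_id")`; all must be
#'   >= 0.
#' @param phi Beta precision, > 0.
#' @param seed Integer seed (independent stream).
#' @return `traits` with added columns `eta` (linear predictor), `mu` and
#'   `response`; the attribute `truth` stores the drawn random intercepts
#'   per group level. Responses lie strictly in (0,1); a mean that hits the
#'   boundary numerically is clamped with a warning.
#' @export
simulate_attractiveness <- function(traits, beta, intercept = 0,
                                    sex_effect = c(male = 0, female = 0),
                                    sigma = c(order = 0.3, family = 0.2,
                                              genus = 0.2, species_id = 0.3),
                                    phi = 30, seed = 1L) {
  abort_if(any(sigma < 0), "all random-effect standard deviations must be >= 0")
  abort_if(phi <= 0, "phi must be > 0")
  missing_cols <- setdiff(names(beta), names(traits))
  abort_if(length(missing_cols) > 0,
           paste("traits table lacks columns:", paste(missing_cols, collapse = ", ")))
  set.seed(sub_seed(seed, "attractiveness"))

  eta <- rep(intercept, nrow(traits))
  for (v in names(beta)) eta <- eta + beta[[v]] * traits[[v]]
  if (!is.null(traits$sex) && length(sex_effect)) {
    eff <- c(sex_effect, undefined = 0)
    eta <- eta + unname(eff[traits$sex])
  }
  truth <- list()
  for (g in names(sigma)) {
    abort_if(is.null(traits[[g]]), sprintf("grouping column '%s' missing", g))
    lev <- sort(unique(traits[[g]]))
    u <- stats::rnorm(length(lev), 0, sigma[[g]])
    names(u) <- lev
    truth[[g]] <- u
    eta <- eta + u[traits[[g]]]
  }
  mu <- stats::plogis(eta)
  if (any(mu <= 0 | mu >= 1)) {
    warning("simulated mean hit the (0,1) boundary numerically; clamped")
    mu <- clamp(mu, 1e-12, 1 - 1e-12)
  }
  y <- stats::rbeta(nrow(traits), mu * phi, (1 - mu) * phi)
  y <- clamp(y, .Machine$double.eps, 1 - .Machine$double.eps)
  out <- dplyr::mutate(traits, eta = unname(eta), mu = unname(mu),
                       response = y)
  attr(out, "truth") <- list(intercepts = truth, beta = beta,
                             intercept = intercept, sex_effect = sex_effect,
                             sigma = sigma, phi = phi)
  out
}

# Truncated Poisson on [lo, hi] by rejection; lambda chosen as the target
# mean (bias from truncation is small for the default 5 on [1, 15]).
rtrunc_pois <- function(n, lambda, lo, hi) {
  out <- integer(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rpois(length(need), lambda)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a crowd-rating table
#'
#' Emulates a citizen-science rating campaign: each species x sex unit has a
#' handful of photos (truncated-Poisson count on 1..15, mean ~5, matching
#' the observed per-species photo counts of large photo archives); each
#' photo has a user-assessed quality score 1-5 and a photo-level effect;
#' raters have a language-specific offset. The emitted integer rating on
#' 1..10 is an affine map of the true attractiveness plus these effects and
#' noise, rounded and clipped. The true-rating mechanism of real users is
#' unknown; this affine stand-in is a documented convention.
#'
#' @param scores Tibble with columns `species_id`, `sex`, `unit`, taxonomy
#'   columns, and `response` (truth on (0,1)); typically the output of
#'   [simulate_attractiveness()].
#' @param n_raters Number of raters (>= 1).
#' @param mean_photos Target mean photos per unit (default 5).
#' @param photo_range Inclusive photo-count range, default `c(1, 15)`.
#' @param ratings_per_photo Ratings drawn per photo (>= 1).
#' @param quality_effect Additive effect per quality point below 5 (a photo
#'   of quality q contributes `quality_effect * (q - 5)`).
#' @param language_effects Named numeric vector of per-language offsets;
#'   raters are assigned languages uniformly.
#' @param photo_sd Standard deviation of the photo-level random effect.
#' @param noise_sd Standard deviation of the per-rating noise.
#' @param seed Integer seed (independent stream).
#' @return A tibble of rating records: `rater_id`, `rater_language`,
#'   `photo_id`, `photo_quality`, `species_id`, `sex`, `unit`, taxonomy
#'   columns, `rating` (integer 1..10). Attribute `truth` stores per-photo
#'   and per-rater effects.
#' @export
simulate_ratings <- function(scores, n_raters = 50, mean_photos = 5,
                             photo_range = c(1, 15), ratings_per_photo = 5,
                             quality_effect = 0.1,
                             language_effects = c(en = 0, fi = 0.2, es = -0.2),
                             photo_sd = 0.3, noise_sd = 1, seed = 1L) {
  abort_if(n_raters < 1 || ratings_per_photo < 1,
           "n_raters and ratings_per_photo must be >= 1")
  abort_if(is.null(scores$response) || is.null(scores$unit),
           "scores must carry 'unit' and 'response' columns")
  set.seed(sub_seed(seed, "ratings"))

  raters <- tibble::tibble(
    rater_id = sprintf("rater_%04d", seq_len(n_raters)),
    rater_language = sample(names(language_effects), n_raters, replace = TRUE)
  )
  n_photo <- rtrunc_pois(nrow(scores), mean_photos, photo_range[1], photo_range[2])
  photos <- scores[rep(seq_len(nrow(scores)), n_photo), ]
  photos$photo_id <- sprintf("photo_%06d", seq_len(nrow(photos)))
  photos$photo_quality <- sample(1:5, nrow(photos), replace = TRUE,
                                 prob = c(0.05, 0.1, 0.2, 0.3, 0.35))
  photos$photo_effect <- stats::rnorm(nrow(photos), 0, photo_sd)

  recs <- photos[rep(seq_len(nrow(photos)), each = ratings_per_photo), ]
  ri <- sample.int(n_raters, nrow(recs), replace = TRUE)
  recs$rater_id <- raters$rater_id[ri]
  recs$rater_language <- raters$rater_language[ri]
  raw <- 1 + 9 * recs$response +
    quality_effect * (recs$photo_quality - 5) +
    unname(language_effects[recs$rater_language]) +
    recs$photo_effect +
    stats::rnorm(nrow(recs), 0, noise_sd)
  recs$rating <- as.integer(clamp(round(raw), 1, 10))

  keep <- intersect(c("rater_id", "rater_language", "photo_id", "photo_quality",
                      "species_id", "sex", "unit", "order", "family", "genus",
                      "rating"), names(recs))
  out <- tibble::as_tibble(recs[, keep])
  attr(out, "truth") <- list(
    photo_effects = stats::setNames(photos$photo_effect, photos$photo_id),
    language_effects = language_effects,
    quality_effect = quality_effect,
    raters = raters
  )
  out
}
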