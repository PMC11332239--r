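#' Simulate a complete analysis scenario with known ground truth
#'
#' Generates everything the pipeline consumes: a taxonomy, one plumage image
#' per species x sex unit with known colour composition, a raw species-trait
#' table, attractiveness truth simulated from the beta mixed model, and a
#' crowd-rating table. All downstream stages can therefore be checked
#' against exact or statistical ground truth.
#'
#' Generator defaults state the emulated world once: photo counts are
#' truncated-Poisson with mean 5 on 1..15; ratings are on the integer 1..10
#' scale; colour mixes are Dirichlet-distributed with most mass on dull
#' colours (brown, grey, black, white) so the panel's global average colour
#' is a brown-grey; body mass is log-normal (median 50 g) and ornament
#' lengths follow a power law in mass with log-normal scatter.
#'
#' @param spec A [taxonomy_spec()] describing the panel.
#' @param image_size Side of the square synthetic illustrations, in pixels.
#' @param beta Named coefficients (on z-scaled predictors) of the
#'   attractiveness model; defaults are signed like typical aesthetic
#'   preferences (more red/blue/elaboration, less black/white, smaller
#'   birds, longer crests/tails more attractive).
#' @param sigma,phi Random-intercept SDs and beta precision of the
#'   generative model.
#' @param rating_args List of overrides passed to [simulate_ratings()].
#' @param seed Integer base seed; sub-streams are split per generator.
#' @return A list of class `plumage_scenario`: `taxonomy`, `images` (named
#'   list), `traits` (raw trait table incl. true colour proportions),
#'   `scores` (trait table + `response` truth), `ratings`, `prepared`
#'   (model-ready predictor table used to build the truth), and `params`.
#' @export
simulate_scenario <- function(spec = taxonomy_spec(3, 2, 2, 4,
                                                   dichromatic_fraction = 0.3,
                                                   seed = 1L),
                              image_size = 32,
                              beta = c(body_mass = -0.15, crest = 0.1,
                                       rel_beak = 0, rel_tail = 0.1,
                                       elaboration = 0.3, black = -0.1,
                                       white = -0.1, yellow = 0, blue = 0.2,
                                       red = 0.2, green = 0.05),
                              sigma = c(order = 0.3, family = 0.2,
                                        genus = 0.2, species_id = 0.3),
                              phi = 30,
                              rating_args = list(),
                              seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  seed <- spec$seed
  taxonomy <- generate_taxonomy(spec)
  n <- nrow(taxonomy)

  # --- true colour mixes (Dirichlet over tone-resolved keys) -------------
  set.seed(sub_seed(seed, "colours"))
  keys <- c("black", "white", "yellow",
            paste0("light_", SPLITTABLE_CATEGORIES),
            paste0("dark_", SPLITTABLE_CATEGORIES))
  conc <- stats::setNames(rep(0.3, length(keys)), keys)
  conc[c("black", "white", "light_brown", "dark_brown", "light_grey",
         "dark_grey")] <- 2
  mixes <- matrix(stats::rgamma(n * length(keys), shape = rep(conc, each = n)),
                  nrow = n, dimnames = list(taxonomy$unit, keys))
  # sparse palettes: each unit carries only a few colour keys, so colour
  # diversity varies across units
  for (i in seq_len(n)) {
    n_keys <- sample(3:10, 1)
    keep <- sample(length(keys), n_keys, prob = conc)
    mixes[i, -keep] <- 0
  }
  mixes <- mixes / rowSums(mixes)

  # --- images -------------------------------------------------------------
  palette <- category_colors()
  keys <- intersect(keys, palette$key)
  mixes <- mixes[, keys, drop = FALSE] / rowSums(mixes[, keys, drop = FALSE])
  images <- lapply(seq_len(n), function(i) {
    generate_plumage_image(mixes[i, ], layout = "blob", size = image_size,
                           seed = sub_seed(seed, i), palette = palette)
  })
  names(images) <- taxonomy$unit

  # --- raw trait table ----------------------------------------------------
  set.seed(sub_seed(seed, "traits"))
  n_sp <- length(unique(taxonomy$species_id))
  sp <- tibble::tibble(
    species_id = sort(unique(taxonomy$species_id)),
    body_mass = stats::rlnorm(n_sp, log(50), 1),
    range_size = stats::rlnorm(n_sp, log(5e5), 1.5),
    latitude = stats::runif(n_sp, -60, 70),
    iucn_raw = sample(c("Least Concern", "Near Threatened", "Vulnerable",
                        "Endangered", "Critically Endangered",
                        "Data Deficient", "Not Evaluated"), n_sp, TRUE,
                      prob = c(0.6, 0.1, 0.1, 0.07, 0.03, 0.05, 0.05)),
    trophic_raw = sample(c("Carnivore", "Invertivore", "Scavenger",
                           "Omnivore", "Herbivore"), n_sp, TRUE,
                         prob = c(0.15, 0.3, 0.05, 0.3, 0.2)),
    migration_raw = sample(c("Resident", "Partial migrant", "Full migrant"),
                           n_sp, TRUE, prob = c(0.5, 0.25, 0.25))
  )
  sp$beak_length <- exp(log(12) + 0.33 * (log(sp$body_mass) - log(50)) +
                          stats::rnorm(n_sp, 0, 0.2))
  sp$tail_length <- exp(log(70) + 0.33 * (log(sp$body_mass) - log(50)) +
                          stats::rnorm(n_sp, 0, 0.25))
  traits <- dplyr::left_join(taxonomy, sp, by = "species_id")
  traits$crest <- sample(0:3, n, TRUE, prob = c(0.7, 0.15, 0.1, 0.05))

  # true per-unit category proportions and derived colour metrics
  cat_of <- sub("^(light|dark)_", "", keys)
  for (cat in PLUMAGE_CATEGORIES) {
    traits[[cat]] <- rowSums(mixes[, cat_of == cat, drop = FALSE])
  }
  pal_lab <- as.matrix(palette[match(keys, palette$key), c("L", "a", "b")])
  gm <- colMeans(mixes %*% pal_lab)
  traits$elaboration <- as.numeric(
    mixes %*% sqrt(rowSums(sweep(pal_lab, 2, gm)^2)))
  traits$loci <- rowSums(mixes > 0)

  # --- prepared predictors and attractiveness truth ----------------------
  prepared <- traits
  prepared$rel_beak <- relative_ornament(prepared$beak_length, prepared$body_mass)
  prepared$rel_tail <- relative_ornament(prepared$tail_length, prepared$body_mass)
  zcols <- c("body_mass", "crest", "rel_beak", "rel_tail", "elaboration",
             PLUMAGE_CATEGORIES, "loci")
  prepared <- transform_and_scale(prepared, log_vars = "body_mass",
                                  scale_vars = zcols)
  scores <- simulate_attractiveness(prepared, beta = beta,
                                    sex_effect = c(male = 0.15, female = 0.05),
                                    sigma = sigma, phi = phi,
                                    seed = sub_seed(seed, "response"))

  ratings <- do.call(simulate_ratings,
                     c(list(scores = scores, seed = sub_seed(seed, "ratings")),
                       rating_args))

  structure(list(taxonomy = taxonomy, images = images, traits = traits,
                 prepared = prepared, scores = scores, ratings = ratings,
                 mixes = mixes, global_mean_true = gm,
                 params = list(spec = spec, beta = beta, sigma = sigma,
                               phi = phi, seed = seed)),
            class = "plumage_scenario")
}

#' @export
print.plumage_scenario <- function(x, ...) {
  cat(sprintf("plumage_scenario: %d units (%d species), %d ratings, seed %d\n",
              nrow(x$taxonomy), length(unique(x$taxonomy$species_id)),
              nrow(x$ratings), x$params$seed))
  invisible(x)
}
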