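test_that("taxonomy generation counts rows exactly and is deterministic", {
  # minimal case: one monomorphic species
  t1 <- generate_taxonomy(taxonomy_spec(1, 1, 1, 1, dichromatic_fraction = 0))
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$sex, "undefined")
  # 2 orders x 2 families x 2 genera x 2 species, all dichromatic -> 32 rows
  t2 <- generate_taxonomy(taxonomy_spec(2, 2, 2, 2, dichromatic_fraction = 1))
  expect_identical(nrow(t2), 32L)
  expect_identical(length(unique(t2$species_id)), 16L)
  expect_setequal(unique(t2$sex), c("male", "female"))
  # same spec, same seed -> identical tables
  spec <- taxonomy_spec(3, c(1, 3), c(1, 4), c(2, 5),
                        dichromatic_fraction = 0.4, seed = 99)
  expect_identical(generate_taxonomy(spec), generate_taxonomy(spec))
  # every species has exactly one genus -> family -> order path
  paths <- dplyr::distinct(t2[, c("species_id", "genus", "family", "order")])
  expect_identical(nrow(paths), 16L)
  expect_error(taxonomy_spec(0, 1, 1, 1), "positive")
  expect_error(taxonomy_spec(1, 1, 1, 1, dichromatic_fraction = 2), "0, 1")
})

test_that("generated images honour the requested colour mix within a pixel", {
  pal <- category_colors()
  # pure blue: one occupied cell, expected diversity 1
  img <- generate_plumage_image(c(blue = 1), layout = "stripe", size = 20,
                                palette = pal)
  expect_identical(attr(img, "expected_diversity"), 1L)
  h <- build_histogram(rgb_to_lab(img))
  expect_identical(nrow(h), 1L)
  m <- default_category_map()
  expect_equal(unname(categorize(h, m)["blue"]), 1)
  # half red / half black on 100x100 -> 5000/5000 within rounding
  img2 <- generate_plumage_image(c(red = 0.5, black = 0.5), layout = "stripe",
                                 size = 100, palette = pal)
  cats <- categorize(build_histogram(rgb_to_lab(img2)), m)
  expect_equal(unname(cats["red"]) * 10000, 5000, tolerance = 1)
  expect_equal(unname(cats["black"]) * 10000, 5000, tolerance = 1)
  expect_error(generate_plumage_image(c(chartreuse = 1), palette = pal),
               "unknown")
  expect_error(generate_plumage_image(c(red = 0.4), palette = pal), "simplex")
})

test_that("every generated image round-trips to its stored expected histogram", {
  pal <- category_colors()
  keys <- pal$key
  set.seed(123)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    mix <- setNames(as.numeric(rmultinom(1, 50, rep(1, k))) / 50,
                    sample(keys, k))
    mix <- mix[mix > 0]
    layout <- sample(c("stripe", "blob"), 1)
    img <- generate_plumage_image(mix, layout = layout, size = 24, seed = i,
                                  palette = pal)
    expected <- attr(img, "expected_histogram")
    got <- build_histogram(rgb_to_lab(img))
    expect_identical(as.data.frame(got[, c("a_bin", "b_bin", "L_bin", "count")]),
                     as.data.frame(expected[, c("a_bin", "b_bin", "L_bin", "count")]))
  }
})

test_that("attractiveness simulation matches its stated distribution", {
  tax <- generate_taxonomy(taxonomy_spec(1, 1, 1, 1, dichromatic_fraction = 0))
  d <- tax[rep(1, 10000), ]
  d$x <- 0
  # all effects zero -> mean response 1/2 within MC error
  sim <- simulate_attractiveness(d, beta = c(x = 0), sigma = c(),
                                 phi = 30, seed = 5)
  expect_equal(mean(sim$response), 0.5, tolerance = 0.01)
  expect_true(all(sim$response > 0 & sim$response < 1))
  # monotone link: a positive coefficient induces positive correlation
  d$blue <- rnorm(nrow(d))
  sim2 <- simulate_attractiveness(d, beta = c(blue = 1), sigma = c(),
                                  phi = 30, seed = 5)
  expect_gt(cor(d$blue, sim2$response), 0.5)
  # re-simulation oracle: identical seed reproduces the same draws as a
  # from-scratch script using the stored truth
  tax5 <- generate_taxonomy(taxonomy_spec(2, 2, 2, 2, dichromatic_fraction = 0.5,
                                          seed = 3))
  tax5$x <- seq_len(nrow(tax5)) / nrow(tax5)
  sim5 <- simulate_attractiveness(tax5, beta = c(x = 0.5),
                                  sigma = c(order = 0.3), phi = 25, seed = 77)
  truth <- attr(sim5, "truth")
  set.seed(plumagescore:::sub_seed(77, "attractiveness"))
  u <- rnorm(length(unique(tax5$order)), 0, 0.3)  # same stream, same order
  eta <- 0.5 * tax5$x + u[match(tax5$order, sort(unique(tax5$order)))] +
    c(male = 0, female = 0, undefined = 0)[tax5$sex]
  mu <- plogis(eta)
  y <- rbeta(nrow(tax5), mu * 25, (1 - mu) * 25)
  expect_equal(sim5$response, y, tolerance = 1e-12)
  expect_equal(unname(truth$intercepts$order), u, tolerance = 1e-12)
  expect_error(simulate_attractiveness(tax5, beta = c(x = 0), phi = -1),
               "phi")
})

test_that("simulated ratings follow the rating-scale contract", {
  tax <- generate_taxonomy(taxonomy_spec(2, 2, 2, 3, dichromatic_fraction = 0.3,
                                         seed = 8))
  tax$x <- 0
  scores <- simulate_attractiveness(tax, beta = c(x = 0), sigma = c(),
                                    phi = 30, seed = 8)
  r <- simulate_ratings(scores, n_raters = 30, seed = 8)
  expect_true(all(r$rating %in% 1:10))
  expect_true(all(r$photo_quality %in% 1:5))
  # zero noise and zero photo/quality/language effects -> the rating is a
  # deterministic monotone function of the truth
  r0 <- simulate_ratings(scores, n_raters = 10, ratings_per_photo = 2,
                         quality_effect = 0, language_effects = c(en = 0),
                         photo_sd = 0, noise_sd = 0, seed = 9)
  truth0 <- scores$response[match(r0$unit, scores$unit)]
  expect_equal(r0$rating, as.integer(pmin(pmax(round(1 + 9 * truth0), 1), 10)))
  expect_true(all(diff(r0$rating[order(truth0)]) >= 0))
  # photo counts per unit centre near the target mean of 5, within 1..15
  big <- scores[rep(1, 400), ]
  big$unit <- sprintf("u%03d", seq_len(nrow(big)))
  rb <- simulate_ratings(big, n_raters = 20, ratings_per_photo = 1, seed = 10)
  counts <- table(sub("^.*(photo_)", "\\1", rb$photo_id))
  per_unit <- tapply(rb$photo_id, rb$unit, function(x) length(unique(x)))
  expect_equal(mean(per_unit), 5, tolerance = 0.3)
  expect_true(all(per_unit >= 1 & per_unit <= 15))
  # per-photo mean ratings equal an independently recomputed group mean
  means_pkg <- tapply(r$rating, r$photo_id, mean)
  means_dp <- dplyr::summarise(dplyr::group_by(r, photo_id),
                               m = mean(rating))
  expect_equal(as.numeric(means_pkg[means_dp$photo_id]), means_dp$m)
  expect_error(simulate_ratings(scores, n_raters = 0), ">= 1")
})

test_that("the full scenario is deterministic under a fixed seed", {
  spec <- taxonomy_spec(2, 2, 2, 2, dichromatic_fraction = 0.3, seed = 31)
  s1 <- simulate_scenario(spec, image_size = 16)
  s2 <- simulate_scenario(spec, image_size = 16)
  expect_identical(s1$taxonomy, s2$taxonomy)
  expect_identical(s1$ratings, s2$ratings)
  expect_identical(lapply(s1$images, function(i) i$rgb),
                   lapply(s2$images, function(i) i$rgb))
  expect_equal(s1$scores$response, s2$scores$response)
})
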