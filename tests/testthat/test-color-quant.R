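test_that("sRGB -> Lab hits the white point, black, and the colourimetry oracle", {
  lab <- rgb_to_lab(matrix(c(255, 255, 255,
                             0, 0, 0,
                             255, 0, 0), ncol = 3, byrow = TRUE))
  expect_equal(unname(lab[1, "L"]), 100, tolerance = 1e-6)
  expect_lt(max(abs(lab[1, c("a", "b")])), 0.05)
  expect_equal(unname(lab[2, "L"]), 0, tolerance = 1e-6)
  expect_equal(unname(lab[3, ]), unname(oracle_srgb_to_lab(c(255, 0, 0))),
               tolerance = 1e-3)
  # a sample of arbitrary pixels matches the closed-form oracle
  set.seed(7)
  px <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  got <- rgb_to_lab(px)
  for (i in seq_len(nrow(px))) {
    expect_equal(unname(got[i, ]), unname(oracle_srgb_to_lab(px[i, ])),
                 tolerance = 1e-3)
  }
  expect_error(rgb_to_lab(plumage_image(array(0, c(2, 2, 3)),
                                        matrix(FALSE, 2, 2))),
               "foreground")
})

test_that("histograms equal brute-force per-pixel binning", {
  g <- lab_grid()
  # single colour -> one occupied cell with proportion 1
  h1 <- build_histogram(matrix(rep(c(50, 10, 10), 20), ncol = 3, byrow = TRUE), g)
  expect_identical(nrow(h1), 1L)
  expect_equal(h1$prop, 1)
  # random pixels: bit-exact agreement with the nested-loop oracle
  set.seed(11)
  lab <- cbind(runif(10000, 0, 100), runif(10000, -110, 110),
               runif(10000, -110, 110))
  h <- build_histogram(lab, g)
  expect_identical(hist_to_counts(h, g), oracle_bin_counts(lab, g))
  expect_equal(sum(h$prop), 1, tolerance = 1e-9)
  expect_true(all(h$prop >= 0))
  expect_lte(nrow(h), n_cells(g))
})

test_that("pixel order never changes any output", {
  g <- lab_grid()
  set.seed(3)
  lab <- cbind(runif(2000, 0, 100), runif(2000, -80, 80), runif(2000, -80, 80))
  m <- default_category_map(g)
  h <- build_histogram(lab, g)
  hp <- build_histogram(lab[sample(nrow(lab)), ], g)
  expect_identical(as.data.frame(h), as.data.frame(hp))
  expect_identical(categorize(h, m), categorize(hp, m))
})

test_that("categorize is additive, mass-conserving, and matches cell accumulation", {
  g <- lab_grid()
  m <- default_category_map(g)
  # construct a histogram with 0.3 in a blue cell and 0.7 in a grey cell
  blue_cell <- m[m$category == "blue", ][1, ]
  grey_cell <- m[m$category == "grey", ][1, ]
  cc <- cell_centroids(g)
  pick <- function(cell) as.numeric(
    cc[cc$a_bin == cell$a_bin & cc$b_bin == cell$b_bin & cc$L_bin == cell$L_bin,
       c("L", "a", "b")])
  lab <- rbind(matrix(rep(pick(blue_cell), 3), ncol = 3, byrow = TRUE),
               matrix(rep(pick(grey_cell), 7), ncol = 3, byrow = TRUE))
  cats <- categorize(build_histogram(lab, g), m)
  expect_equal(unname(cats["blue"]), 0.3)
  expect_equal(unname(cats["grey"]), 0.7)
  expect_equal(sum(cats), 1, tolerance = 1e-9)
  # random histograms: category sums equal brute-force accumulation over cells
  set.seed(5)
  for (rep in 1:5) {
    lab <- cbind(runif(500, 0, 100), runif(500, -100, 100), runif(500, -100, 100))
    h <- build_histogram(lab, g)
    cats <- categorize(h, m)
    key <- paste(m$a_bin, m$b_bin, m$L_bin)
    acc <- setNames(numeric(10), sort(unique(m$category)))
    for (i in seq_len(nrow(h))) {
      cat_i <- m$category[match(paste(h$a_bin[i], h$b_bin[i], h$L_bin[i]), key)]
      acc[cat_i] <- acc[cat_i] + h$prop[i]
    }
    expect_equal(cats[sort(names(cats))], acc[sort(names(acc))],
                 tolerance = 1e-12)
    expect_equal(sum(cats), 1, tolerance = 1e-9)
  }
})

test_that("light + dark reconciles with category totals for all 7 colours", {
  g <- lab_grid()
  m <- default_category_map(g)
  set.seed(9)
  for (rep in 1:5) {
    lab <- cbind(runif(800, 0, 100), runif(800, -100, 100), runif(800, -100, 100))
    h <- build_histogram(lab, g)
    cats <- categorize(h, m)
    ld <- split_light_dark(h, m)
    expect_equal(ld$light + ld$dark, ld$total, tolerance = 1e-12)
    expect_equal(ld$total, unname(cats[ld$category]), tolerance = 1e-12)
  }
})

test_that("light/dark split follows the L bins for a constructed case", {
  g <- lab_grid()
  m <- default_category_map(g)
  blue_dark <- m[m$category == "blue" & m$tone == "dark", ][1, ]
  blue_light <- m[m$category == "blue" & m$tone == "light", ][1, ]
  cc <- cell_centroids(g)
  pick <- function(cell) as.numeric(
    cc[cc$a_bin == cell$a_bin & cc$b_bin == cell$b_bin & cc$L_bin == cell$L_bin,
       c("L", "a", "b")])
  lab <- rbind(matrix(rep(pick(blue_dark), 4), ncol = 3, byrow = TRUE),
               matrix(rep(pick(blue_light), 6), ncol = 3, byrow = TRUE))
  ld <- split_light_dark(build_histogram(lab, g), m)
  expect_equal(ld$dark[ld$category == "blue"], 0.4)
  expect_equal(ld$light[ld$category == "blue"], 0.6)
  # all blue in the top L bin -> light blue equals total blue
  lab2 <- matrix(rep(pick(blue_light), 5), ncol = 3, byrow = TRUE)
  ld2 <- split_light_dark(build_histogram(lab2, g), m)
  expect_equal(ld2$light[ld2$category == "blue"], 1)
  expect_equal(ld2$dark[ld2$category == "blue"], 0)
})

test_that("colour diversity counts occupied loci, spanning the realistic range", {
  g <- lab_grid()
  cc <- cell_centroids(g)
  # pixels placed in exactly 5 distinct cells -> 5
  idx <- c(1, 50, 200, 400, 570)
  lab5 <- as.matrix(cc[rep(idx, each = 3), c("L", "a", "b")])
  expect_identical(colour_diversity(build_histogram(lab5, g)), 5L)
  expect_identical(colour_diversity(build_histogram(lab5[1:3, , drop = FALSE], g)), 1L)
  # a panel constructed to span 12..141 occupied cells reproduces its design
  set.seed(21)
  target <- c(12, 30, 48, 90, 141)
  got <- vapply(target, function(k) {
    cells <- sample(576, k)
    lab <- as.matrix(cc[rep(cells, each = 2), c("L", "a", "b")])
    colour_diversity(build_histogram(lab, g))
  }, integer(1))
  expect_identical(got, as.integer(target))
  # occupancy threshold suppresses speckle
  lab_mix <- as.matrix(cc[c(rep(1, 999), 2), c("L", "a", "b")])
  h <- build_histogram(lab_mix, g)
  expect_identical(colour_diversity(h), 2L)
  expect_identical(colour_diversity(h, min_prop = 0.01), 1L)
})

test_that("colour elaboration has its closed-form values", {
  g <- lab_grid()
  cc <- cell_centroids(g)
  gm <- as.numeric(cc[100, c("L", "a", "b")])
  # species whose only colour equals the global mean -> 0
  h0 <- build_histogram(matrix(rep(gm, 5), ncol = 3, byrow = TRUE), g)
  expect_equal(colour_elaboration(h0, gm), 0)
  # single colour at distance d -> exactly d
  other <- as.numeric(cc[400, c("L", "a", "b")])
  d <- sqrt(sum((other - gm)^2))
  h1 <- build_histogram(matrix(rep(other, 4), ncol = 3, byrow = TRUE), g)
  expect_equal(colour_elaboration(h1, gm), d, tolerance = 1e-12)
  # two colours with weights (w, 1-w) -> w d1 + (1-w) d2
  c1 <- as.numeric(cc[30, c("L", "a", "b")])
  c2 <- as.numeric(cc[500, c("L", "a", "b")])
  d1 <- sqrt(sum((c1 - gm)^2)); d2 <- sqrt(sum((c2 - gm)^2))
  lab <- rbind(matrix(rep(c1, 3), ncol = 3, byrow = TRUE),
               matrix(rep(c2, 7), ncol = 3, byrow = TRUE))
  expect_equal(colour_elaboration(build_histogram(lab, g), gm),
               0.3 * d1 + 0.7 * d2, tolerance = 1e-12)
  expect_error(colour_elaboration(h1, NULL), "global mean")
})

test_that("elaboration is translation-equivariant in Lab space", {
  # shifting all colours and the global mean by one grid cell leaves the
  # proportion-weighted distance unchanged (cell centroids shift rigidly)
  g <- lab_grid()
  cc <- cell_centroids(g)
  set.seed(13)
  ok_rows <- which(cc$a_bin <= 11 & cc$b_bin <= 11 & cc$L_bin <= 3)
  cells <- sample(ok_rows, 20)  # shifted cells must stay inside the grid
  lab <- as.matrix(cc[rep(cells, times = sample(1:5, 20, TRUE)),
                      c("L", "a", "b")])
  gm <- c(50, 0, 0)
  e1 <- colour_elaboration(build_histogram(lab, g), gm)
  shift <- c(25, 220 / 12, 220 / 12)  # exactly one bin on each axis
  lab2 <- sweep(lab, 2, shift, "+")
  e2 <- colour_elaboration(build_histogram(lab2, g), gm + shift)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("category map round-trips through CSV and is validated", {
  g <- lab_grid()
  m <- default_category_map(g)
  path <- tempfile(fileext = ".csv")
  write_category_map(m, path)
  m2 <- read_category_map(path)
  expect_equal(as.data.frame(m), as.data.frame(m2))
  # a map with a missing cell is rejected
  h <- build_histogram(matrix(c(50, 0, 0), ncol = 3), g)
  m_miss <- m[!(m$a_bin == h$a_bin[1] & m$b_bin == h$b_bin[1] &
                  m$L_bin == h$L_bin[1]), ]
  expect_error(categorize(h, m_miss), "unmapped")
})
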