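test_that("without random terms the fit matches an independent ML beta regression", {
  set.seed(17)
  n <- 400
  X <- cbind(1, rnorm(n), rnorm(n))
  mu <- plogis(drop(X %*% c(0.2, 0.5, -0.3)))
  d <- data.frame(x1 = X[, 2], x2 = X[, 3], y = rbeta(n, mu * 15, (1 - mu) * 15))
  fit <- beta_glmm(y ~ x1 + x2, d)
  oracle <- oracle_beta_ml(X, d$y)
  expect_lt(max(abs(fit$coefficients$estimate - oracle$beta)), 1e-4)
  expect_equal(fit$phi, oracle$phi, tolerance = 1e-3)
  expect_equal(fit$logLik, -oracle$nll, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$coefficients$ci_lo < fit$coefficients$estimate &
                    fit$coefficients$estimate < fit$coefficients$ci_hi))
})

test_that("the response must be strictly inside (0,1)", {
  d <- data.frame(y = c(0.2, 0.5, 1), x = 1:3)
  expect_error(beta_glmm(y ~ x, d), "boundary")
})

test_that("an intercept-only model on symmetric data recovers logit mean zero", {
  set.seed(23)
  d <- data.frame(y = rbeta(4000, 12, 12),
                  g = rep(sprintf("g%02d", 1:20), each = 200))
  fit <- beta_glmm(y ~ 1 + (1 | g), d)
  expect_lt(abs(fit$coefficients$estimate[1]), 3 * fit$coefficients$se[1] + 0.02)
  expect_equal(fit$phi, 24, tolerance = 0.15)
})

test_that("a two-level mixed fit recovers simulated parameters", {
  tax <- generate_taxonomy(taxonomy_spec(6, 2, 3, 8, dichromatic_fraction = 0,
                                         seed = 12))
  tax <- make_sim_panel(tax, c("x1", "x2"), seed = 12)
  sim <- simulate_attractiveness(tax, beta = c(x1 = 0.4, x2 = -0.25),
                                 intercept = 0.1,
                                 sigma = c(order = 0.3, species_id = 0.3),
                                 phi = 25, seed = 12)
  fit <- beta_glmm(response ~ x1 + x2 + (1 | order) + (1 | species_id), sim)
  est <- coef(fit)
  expect_equal(unname(est["x1"]), 0.4, tolerance = 0.25)
  expect_equal(unname(est["x2"]), -0.25, tolerance = 0.25)
  expect_equal(unname(fit$phi), 25, tolerance = 0.4)
  expect_true(all(fit$sigma > 0))
  # BLUP lists are complete and named
  expect_length(fit$u$order, 6)
  expect_length(fit$u$species_id, length(unique(tax$species_id)))
})

test_that("with true variance zero the mixed fit collapses to the fixed fit", {
  set.seed(31)
  n <- 600
  d <- data.frame(x = rnorm(n), g = rep(sprintf("g%02d", 1:30), each = 20))
  mu <- plogis(0.3 + 0.5 * d$x)
  d$y <- rbeta(n, mu * 20, (1 - mu) * 20)
  plain <- beta_glmm(y ~ x, d)
  mixed <- beta_glmm(y ~ x + (1 | g), d)
  expect_lt(unname(mixed$sigma["g"]), 0.06)
  expect_lt(max(abs(coef(mixed) - coef(plain))), 0.01)
  expect_lt(abs(mixed$logLik - plain$logLik), 1)
})

test_that("the optimised likelihood is at least the likelihood at the truth", {
  tax <- generate_taxonomy(taxonomy_spec(5, 2, 2, 8, dichromatic_fraction = 0,
                                         seed = 19))
  tax <- make_sim_panel(tax, "x1", seed = 19)
  sim <- simulate_attractiveness(tax, beta = c(x1 = 0.3), intercept = 0,
                                 sigma = c(order = 0.3, species_id = 0.3),
                                 phi = 30, seed = 19)
  fml <- response ~ x1 + (1 | order) + (1 | species_id)
  fit <- beta_glmm(fml, sim)
  at_truth <- beta_glmm(fml, sim, evaluate = TRUE,
                        start = list(beta = c(0, 0.3),
                                     log_sigma = log(c(0.3, 0.3)),
                                     log_phi = log(30)))
  expect_gte(fit$logLik, at_truth$logLik - 1e-6)
})

test_that("rescaling a predictor rescales its coefficient inversely", {
  set.seed(41)
  n <- 500
  d <- data.frame(x = rnorm(n), g = rep(sprintf("g%02d", 1:25), each = 20))
  mu <- plogis(0.4 * d$x + rnorm(25, 0, 0.2)[as.integer(factor(d$g))])
  d$y <- pmin(pmax(rbeta(n, mu * 20, (1 - mu) * 20), 1e-6), 1 - 1e-6)
  d$x_scaled <- d$x * 4
  f1 <- beta_glmm(y ~ x + (1 | g), d)
  f2 <- beta_glmm(y ~ x_scaled + (1 | g), d)
  expect_equal(unname(coef(f2)["x_scaled"]), unname(coef(f1)["x"]) / 4,
               tolerance = 1e-4)
})

test_that("richer nested models never lose log-likelihood", {
  scn <- simulate_scenario(taxonomy_spec(3, 2, 2, 4, dichromatic_fraction = 0.3,
                                         seed = 61), image_size = 16)
  d <- scn$scores
  d$sex <- factor(d$sex, levels = c("undefined", "male", "female"))
  f_small <- beta_glmm(response ~ elaboration + blue + red +
                         (1 | order) + (1 | species_id), d)
  f_big <- beta_glmm(response ~ elaboration + blue + red + body_mass + crest +
                       (1 | order) + (1 | species_id), d)
  expect_gte(f_big$logLik, f_small$logLik - 1e-4)
})

test_that("quantile residual diagnostics behave under truth and misfit", {
  set.seed(53)
  n <- 600
  x <- rnorm(n)
  mu <- plogis(0.3 * x)
  ok <- data.frame(x = x, y = rbeta(n, mu * 20, (1 - mu) * 20))
  fit_ok <- beta_glmm(y ~ x, ok)
  v_ok <- validate(fit_ok)
  expect_length(v_ok$residuals, n)
  # well-specified: uniform PIT in most replicates
  pvals <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    xs <- rnorm(400)
    ms <- plogis(0.3 * xs)
    ds <- data.frame(x = xs, y = rbeta(400, ms * 20, (1 - ms) * 20))
    validate(beta_glmm(y ~ x, ds))$ks$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 8)
  # heavy-tailed contamination is flagged
  bad <- ok
  idx <- sample(n, 120)
  bad$y[idx] <- rbeta(120, 0.15, 0.15)
  bad$y <- pmin(pmax(bad$y, 1e-9), 1 - 1e-9)
  v_bad <- validate(beta_glmm(y ~ x, bad))
  expect_lt(v_bad$ks$p.value, 0.05)
  # grouped residual summaries
  v_g <- validate(fit_ok, group = rep(c("A", "B"), length.out = n))
  expect_identical(nrow(v_g$by_group), 2L)
  expect_identical(sum(v_g$by_group$n), as.integer(n))
})

test_that("the model battery fits the documented variants and skips empty subsets", {
  scn <- simulate_scenario(taxonomy_spec(3, 2, 2, 4, dichromatic_fraction = 0,
                                         seed = 71), image_size = 16)
  prof <- color_profile(scn$images)
  est <- fit_consensus(scn$ratings)
  prep <- prepare_traits(scn$traits, profiles = prof, estimates = est)
  expect_message(
    fits <- run_model_battery(prep, models = c("main", "males", "undefined",
                                               "loci")),
    "empty subset")
  # monomorphic-only data: no male rows, undefined subset equals the full data
  expect_null(fits$males)
  expect_identical(fits$undefined$n, nrow(prep))
  expect_true(all(c("main", "undefined", "loci") %in% names(fits)))
  expect_true("loci" %in% fits$loci$coefficients$term)
  # sex has a single level here, so the main model drops the term
  expect_false(any(grepl("^sex", fits$main$coefficients$term)))
  tab <- effect_table(fits)
  expect_true(all(c("model", "term", "estimate", "ci_lo", "ci_hi") %in%
                    names(tab)))
})

test_that("a positive diversity effect is recovered by the loci model", {
  tax <- generate_taxonomy(taxonomy_spec(5, 2, 3, 6, dichromatic_fraction = 0,
                                         seed = 81))
  vars <- c("body_mass", "crest", "rel_beak", "rel_tail", "elaboration",
            "black", "white", "yellow", "blue", "red", "green", "loci")
  tax <- make_sim_panel(tax, vars, seed = 81)
  sim <- simulate_attractiveness(tax, beta = c(loci = 0.5),
                                 sigma = c(order = 0.2, species_id = 0.2),
                                 phi = 25, seed = 81)
  fits <- run_model_battery(sim, models = "loci")
  est <- fits$loci$coefficients
  expect_gt(est$estimate[est$term == "loci"], 0.3)
})
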