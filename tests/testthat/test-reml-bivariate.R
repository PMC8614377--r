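test_that("a duplicated trait with tiny jitter gives phenotypic correlation ~ 1", {
  set.seed(88)
  d <- breeding_design(years = "y", lines_per_year = 15,
                       queens_per_year = 150, weeks_per_year = 5)
  ped <- generate_pedigree(d, seed = 41)
  A <- compute_kinship(ped)
  ph <- simulate_phenotypes(ped, A, univariate_trait_model(0.4, sigma2_p = 10),
                            d, seed = 42)
  ph$y2 <- ph$y + stats::rnorm(nrow(ph), sd = 0.01 * stats::sd(ph$y))
  fit <- suppressWarnings(fit_bivariate(ph, A, c("y", "y2")))
  expect_gte(correlations(fit)$r_p, 0.99)
})

test_that("zero genetic correlation is estimated near zero", {
  d <- breeding_design(years = "y", lines_per_year = 100,
                       queens_per_year = 1000, weeks_per_year = 5)
  ped <- generate_pedigree(d, seed = 51)
  A <- compute_kinship(ped)
  G <- diag(c(4, 2))                       # r_g = 0 by construction
  R <- matrix(c(6, 1.2, 1.2, 3), 2, 2)
  m <- trait_model(c("t1", "t2"), c(0, 0), G, R)
  ph <- simulate_phenotypes(ped, A, m, d, seed = 52)
  fit <- suppressWarnings(fit_bivariate(ph, A, c("t1", "t2")))
  expect_lte(abs(correlations(fit)$r_g), 0.15)
})

test_that("trait-wise missingness is handled by cell-level deletion", {
  set.seed(61)
  d <- breeding_design(years = "y", lines_per_year = 15,
                       queens_per_year = 147, weeks_per_year = 5)
  ped <- generate_pedigree(d, seed = 61)
  A <- compute_kinship(ped)
  G <- matrix(c(4, 1, 1, 2), 2, 2)
  R <- matrix(c(6, 0.5, 0.5, 3), 2, 2)
  m <- trait_model(c("t1", "t2"), c(0, 0), G, R,
                   missing_rates = c(t2 = 4 / 147))
  ph <- simulate_phenotypes(ped, A, m, d, seed = 62)
  n2 <- sum(!is.na(ph$t2))
  expect_lt(n2, 148)
  fit <- suppressWarnings(fit_bivariate(ph, A, c("t1", "t2")))
  expect_equal(fit$n_used, c(147L, n2))
  expect_true(all(is.finite(fit$varcomp)))
  expect_true(fit$converged)
  # the missing-cell likelihood agrees with a brute-force evaluation
  expect_lt(abs(reml_loglik_bivariate(ph, A, c("t1", "t2"), G, R) -
                brute_bi_ll(ph, A, c("t1", "t2"), G, R)), 1e-6)
  # and so does the complete-record spectral path
  cc <- ph[!is.na(ph$t2), ]
  expect_lt(abs(reml_loglik_bivariate(cc, A, c("t1", "t2"), G, R) -
                brute_bi_ll(cc, A, c("t1", "t2"), G, R)), 1e-6)
})

test_that("bivariate logL at block-diagonal components equals the sum of univariate logLs", {
  set.seed(71)
  d <- breeding_design(years = "y", lines_per_year = 20,
                       queens_per_year = 300, weeks_per_year = 5)
  ped <- generate_pedigree(d, seed = 71)
  A <- compute_kinship(ped)
  G <- matrix(c(4, 1, 1, 2), 2, 2)
  R <- matrix(c(6, 0.5, 0.5, 3), 2, 2)
  m <- trait_model(c("t1", "t2"), c(10, 20), G, R)
  ph <- simulate_phenotypes(ped, A, m, d, seed = 72)
  f1 <- fit_univariate(ph, A, "t1")
  f2 <- fit_univariate(ph, A, "t2")
  Gd <- diag(c(f1$varcomp[["sigma2_a"]], f2$varcomp[["sigma2_a"]]))
  Rd <- diag(c(f1$varcomp[["sigma2_e"]], f2$varcomp[["sigma2_e"]]))
  ll <- reml_loglik_bivariate(ph, A, c("t1", "t2"), Gd, Rd)
  expect_lt(abs(ll - (f1$logL + f2$logL)), 1e-6)
})

test_that("correlations recover generating values and algebraic edge cases", {
  # edge cases straight from the definitions, via a constructed fit
  fake <- structure(list(kind = "bivariate", traits = c("a", "b"),
                         varcomp = c(g11 = 1, g12 = 1, g22 = 1,
                                     r11 = 2, r12 = 0, r22 = 2),
                         vcov = diag(6) * 0.01, boundary = FALSE),
                    class = "bee_fit")
  co <- correlations(fake)
  expect_equal(co$r_g, 1)
  expect_equal(co$r_p, 1 / 3)
  fake$varcomp <- c(g11 = 1, g12 = 0, g22 = 1, r11 = 2, r12 = 0, r22 = 2)
  co0 <- correlations(fake)
  expect_equal(co0$r_g, 0)
  expect_equal(co0$r_p, 0)
  # zero genetic variance: r_g undefined, reported with reason
  fake$varcomp <- c(g11 = 0, g12 = 0, g22 = 1, r11 = 2, r12 = 0, r22 = 2)
  coz <- correlations(fake)
  expect_true(is.na(coz$r_g))
  expect_match(coz$reason, "zero genetic variance")
  # a bivariate fit on data with known G and R
  set.seed(81)
  d <- breeding_design(years = "y", lines_per_year = 40,
                       queens_per_year = 800, weeks_per_year = 5)
  ped <- generate_pedigree(d, seed = 81)
  A <- compute_kinship(ped)
  G <- matrix(c(4, 2.4, 2.4, 4), 2, 2)     # r_g = 0.6
  R <- matrix(c(4, 0.8, 0.8, 4), 2, 2)     # r_p = 0.4
  m <- trait_model(c("t1", "t2"), c(0, 0), G, R)
  ph <- simulate_phenotypes(ped, A, m, d, seed = 82)
  fit <- suppressWarnings(fit_bivariate(ph, A, c("t1", "t2")))
  co_fit <- correlations(fit)
  expect_lt(abs(co_fit$r_g - 0.6), 3 * max(co_fit$se_g, 0.05))
  expect_lt(abs(co_fit$r_p - 0.4), 3 * max(co_fit$se_p, 0.03))
})

test_that("the fitted diameter-volume phenotypic correlation matches the cube-transform theory", {
  d <- breeding_design(years = "y", lines_per_year = 50,
                       queens_per_year = 2000, weeks_per_year = 1)
  ped <- generate_pedigree(d, seed = 91)
  A <- compute_kinship(ped)
  m <- trait_model("sd", 1.32, matrix(0.17 * 0.18^2), matrix(0.83 * 0.18^2),
                   week_effect_sd = 0, derive_volume = TRUE,
                   measurement_sd = 0)
  ph <- simulate_phenotypes(ped, A, m, d, seed = 92)
  fit <- suppressWarnings(fit_bivariate(ph, A, c("sd", "sv")))
  expect_lt(abs(correlations(fit)$r_p - cube_corr_theory(1.32, 0.18)), 0.01)
})
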