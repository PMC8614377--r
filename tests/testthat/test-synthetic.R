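test_that("the default design yields 147 phenotyped queens from 17 lines over 2 years", {
  ped <- generate_pedigree(breeding_design(), seed = 1)
  ids <- phenotyped_ids(ped)
  expect_length(ids, 147L)
  yr <- ped$queens$year[match(ids, ped$queens$id)]
  expect_equal(as.integer(table(yr)[c("2017", "2018")]), c(70L, 77L))
  dams <- unique(ped$queens$dam_id[match(ids, ped$queens$id)])
  expect_length(dams, 17L)
  # one sire group per maternal line, drawing on that year's DPQ pool
  grps <- unique(ped$queens$sire_group_id[match(ids, ped$queens$id)])
  expect_length(grps, 17L)
  expect_true(all(ped$groups$n_drones[match(grps, ped$groups$group_id)] == 12L))
})

test_that("pedigree generation is seed-deterministic", {
  d <- breeding_design()
  p1 <- generate_pedigree(d, seed = 5)
  p2 <- generate_pedigree(d, seed = 5)
  expect_identical(p1$queens, p2$queens)
  expect_identical(p1$dpq, p2$dpq)
  expect_error(generate_pedigree(
    breeding_design(lines_per_year = 0)), "design_error")
})

test_that("a 1-line, 1-queen, depth-0 design gives one queen with founder parents", {
  d <- breeding_design(years = "y", lines_per_year = 1, queens_per_year = 1,
                       weeks_per_year = 1, shared_ancestor_depth = 0)
  ped <- generate_pedigree(d, seed = 1)
  ids <- phenotyped_ids(ped)
  expect_length(ids, 1L)
  q <- ped$queens[match(ids, ped$queens$id), ]
  dam <- ped$queens[match(q$dam_id, ped$queens$id), ]
  expect_true(is.na(dam$dam_id))  # dam is a founder
  dpq <- ped$queens[match(ped$dpq[[q$sire_group_id]], ped$queens$id), ]
  expect_true(all(is.na(dpq$dam_id)))  # DPQs are founders
})

test_that("zero-variance model returns the means exactly and phenotypes are seed-stable", {
  d <- breeding_design(years = "y", lines_per_year = 2, queens_per_year = 20,
                       weeks_per_year = 3)
  ped <- generate_pedigree(d, seed = 2)
  A <- compute_kinship(ped)
  m0 <- trait_model(c("t1", "t2"), c(5, -3), matrix(0, 2, 2),
                    matrix(0, 2, 2), week_effect_sd = 0)
  ph <- simulate_phenotypes(ped, A, m0, d, seed = 3)
  expect_equal(ph$t1, rep(5, 20))
  expect_equal(ph$t2, rep(-3, 20))
  m1 <- univariate_trait_model(0.4, sigma2_p = 4)
  a <- simulate_phenotypes(ped, A, m1, d, seed = 9)
  b <- simulate_phenotypes(ped, A, m1, d, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_phenotypes(ped, A, m1, d, seed = 10)
  expect_false(identical(a$y, c_$y))
  # week classes stay within the queen's year
  dd <- breeding_design()
  pedd <- generate_pedigree(dd, seed = 4)
  Ad <- compute_kinship(pedd)
  phd <- simulate_phenotypes(pedd, Ad, m1, dd, seed = 5)
  expect_true(all(startsWith(phd$week, phd$year)))
})

test_that("offspring phenotype regresses on dam breeding value with slope ~ 0.5", {
  # dam-offspring additive relationship is 1/2, so for y = a + e the
  # regression of offspring phenotype on the dam's breeding value has
  # slope cov(a_o, a_d)/var(a_d) = 0.5 regardless of h2
  n <- 800
  founders <- data.frame(id = c(sprintf("P%03d", 1:n), sprintf("D%03d", 1:n)),
                         dam_id = NA_character_,
                         sire_group_id = NA_character_)
  g <- data.frame(group_id = sprintf("S%03d", 1:n),
                  dpq_ids = sprintf("P%03d", 1:n),
                  n_drones = 1, pool_id = "p")
  off <- data.frame(id = sprintf("O%03d", 1:n),
                    dam_id = sprintf("D%03d", 1:n),
                    sire_group_id = sprintf("S%03d", 1:n))
  q <- rbind(founders, off)
  q$role <- c(rep("founder", n), rep("phenotyped", n), rep("phenotyped", n))
  ped <- bee_pedigree(q, g)
  A <- compute_kinship(ped)
  d <- breeding_design(years = "y", lines_per_year = 1,
                       queens_per_year = 2 * n, weeks_per_year = 1)
  m <- univariate_trait_model(0.5, sigma2_p = 2, week_effect_sd = 0)
  ph <- simulate_phenotypes(ped, A, m, d, seed = 21)
  bv <- attr(ph, "breeding_values")
  dam_bv <- bv[sprintf("D%03d", 1:n), 1]
  off_y <- ph$y[match(sprintf("O%03d", 1:n), ph$queen_id)]
  fit <- stats::lm(off_y ~ dam_bv)
  slope <- stats::coef(fit)[["dam_bv"]]
  se <- summary(fit)$coefficients["dam_bv", "Std. Error"]
  expect_lt(abs(slope - 0.5), 3 * se)
})

test_that("breeding values honour A: variance scale and zero genetic correlation", {
  d <- breeding_design(years = "y", lines_per_year = 20,
                       queens_per_year = 400, weeks_per_year = 1)
  ped <- generate_pedigree(d, seed = 31)
  A <- compute_kinship(ped)
  G <- diag(c(4, 9))
  m <- trait_model(c("t1", "t2"), c(0, 0), G, diag(2), week_effect_sd = 0)
  ph <- simulate_phenotypes(ped, A, m, d, seed = 32)
  bv <- attr(ph, "breeding_values")
  ids <- rownames(bv)
  Abar <- mean(diag(phenotyped_submatrix(A, ids)$A))
  # E[var across queens] ~ sigma2_a * mean(diag A); loose 3-ish envelope
  expect_lt(abs(mean(bv[, 1]^2) / (4 * Abar) - 1), 0.35)
  expect_lt(abs(mean(bv[, 2]^2) / (9 * Abar) - 1), 0.35)
  # r_g = 0 in G: sample correlation of the BV vectors near 0
  r <- stats::cor(bv[, 1], bv[, 2])
  expect_lt(abs(r), 3 / sqrt(nrow(bv) - 3) + 0.15)  # families reduce the
  # effective sample size, hence the widened envelope
})

test_that("spermatheca volume follows the sphere formula", {
  v <- derive_spermatheca_volume(c(1, 1, 1))
  expect_equal(v$mean_diameter, 1)
  expect_equal(v$volume, pi / 6)
  v2 <- derive_spermatheca_volume(c(1.30, 1.32, 1.34))
  expect_equal(v2$mean_diameter, 1.32)
  expect_equal(v2$volume, pi / 6 * 1.32^3, tolerance = 1e-12)
  expect_equal(round(v2$volume, 4), 1.2043)
  # replicate order is irrelevant
  expect_equal(derive_spermatheca_volume(c(1.34, 1.30, 1.32)), v2)
  # matrix form, one row per queen
  vm <- derive_spermatheca_volume(rbind(c(1, 1, 1), c(1.30, 1.32, 1.34)))
  expect_equal(vm$volume, c(pi / 6, v2$volume))
  expect_error(derive_spermatheca_volume(c(1, -1, 1)), "measurement_error")
  expect_error(derive_spermatheca_volume(c(1, NA, 1)), "measurement_error")
})

test_that("diameter and derived volume are almost perfectly correlated", {
  set.seed(101)
  dvec <- stats::rnorm(10000, 1.32, 0.18)
  vol <- pi / 6 * dvec^3
  r <- stats::cor(dvec, vol)
  expect_gt(r, 0.97)
  expect_lt(abs(r - cube_corr_theory(1.32, 0.18)), 0.01)
})

test_that("defect flags are Bernoulli with the requested rates", {
  d <- breeding_design(years = "y", lines_per_year = 2, queens_per_year = 20,
                       weeks_per_year = 2)
  ped <- generate_pedigree(d, seed = 3)
  A <- compute_kinship(ped)
  ph <- simulate_phenotypes(ped, A, univariate_trait_model(0.3), d, seed = 4)
  none <- inject_defect_flags(ph, c(x = 0), seed = 5)
  expect_false(any(none$defect_x))
  all_ <- inject_defect_flags(ph, c(x = 1), seed = 5)
  expect_true(all(all_$defect_x))
  expect_error(inject_defect_flags(ph, c(x = 1.2)), "defect_rate_error")
  # prevalence at rate 0.16 over n = 1e5 within 3 binomial SEs
  big <- data.frame(queen_id = as.character(1:1e5))
  big <- inject_defect_flags(big, c(gut = 0.16), seed = 6)
  se <- sqrt(0.16 * 0.84 / 1e5)
  expect_lt(abs(mean(big$defect_gut) - 0.16), 3 * se)
  # reproducible
  big2 <- inject_defect_flags(data.frame(queen_id = as.character(1:1e5)),
                              c(gut = 0.16), seed = 6)
  expect_identical(big$defect_gut, big2$defect_gut)
})

test_that("per-trait missingness is applied and the table round-trips as CSV", {
  d <- breeding_design(years = "y", lines_per_year = 5, queens_per_year = 200,
                       weeks_per_year = 3)
  ped <- generate_pedigree(d, seed = 7)
  A <- compute_kinship(ped)
  m <- trait_model("y", 0, matrix(0.5), matrix(0.5),
                   missing_rates = c(y = 0.25))
  ph <- simulate_phenotypes(ped, A, m, d, seed = 8)
  miss <- sum(is.na(ph$y))
  expect_lt(abs(miss / 200 - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
  f <- tempfile(fileext = ".csv")
  write_phenotypes(ph, f)
  ph2 <- read_phenotypes(f)
  expect_equal(ph2$y, ph$y)
  expect_equal(ph2$week, ph$week)
})
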