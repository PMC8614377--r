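test_that("REML matches the closed-form ANOVA estimator on a balanced sib design", {
  set.seed(21)
  s <- 30; k <- 10
  ped <- ped_balanced_sibs(s, k)
  A <- compute_kinship(ped)
  ids <- sort(grep("^O", A$ids, value = TRUE))
  a_w <- A$A[ids[1], ids[2]]
  expect_equal(a_w, 0.75)
  ph <- sim_on_A(A, ids, sigma2_a = 1, sigma2_e = 1)
  fit <- fit_univariate(ph, A, "y")
  expect_true(fit$converged)
  expect_false(fit$boundary)

  # balanced one-way ANOVA estimator, independent of the fit code
  fam <- rep(seq_len(s), each = k)
  m <- tapply(ph$y, fam, mean)
  MSB <- k * sum((m - mean(ph$y))^2) / (s - 1)
  MSW <- sum((ph$y - m[fam])^2) / (s * (k - 1))
  sa_anova <- (MSB - MSW) / (k * a_w)
  se_anova <- MSW - (1 - a_w) * sa_anova
  expect_lt(abs(fit$varcomp[["sigma2_a"]] - sa_anova) / sa_anova, 1e-4)
  expect_lt(abs(fit$varcomp[["sigma2_e"]] - se_anova) / se_anova, 1e-4)
})

test_that("reported logL matches a brute-force likelihood evaluation", {
  set.seed(33)
  ped <- ped_balanced_sibs(12, 6)
  A <- compute_kinship(ped)
  ids <- grep("^O", A$ids, value = TRUE)
  ph <- sim_on_A(A, ids, 2, 3)
  ph$week <- rep(c("w1", "w2", "w3"), length.out = nrow(ph))
  fit <- fit_univariate(ph, A, "y")
  X <- stats::model.matrix(~factor(ph$week))
  Am <- phenotyped_submatrix(A, ph$queen_id)$A
  ll <- brute_reml_ll(ph$y, X, Am, fit$varcomp[["sigma2_a"]],
                      fit$varcomp[["sigma2_e"]])
  expect_lt(abs(ll - fit$logL), 1e-6)
  # and the exported evaluator agrees with the brute force at other points
  for (sa in c(0.5, 2, 5)) {
    expect_lt(abs(reml_loglik_univariate(ph, A, "y", sa, 1.7) -
                  brute_reml_ll(ph$y, X, Am, sa, 1.7)), 1e-6)
  }
})

test_that("null genetic variance collapses to the zero boundary", {
  # sigma2_a = 0 truth: estimates pile up at the boundary, and the mean
  # h2 over a few replicate datasets stays near zero
  set.seed(44)
  ped <- ped_balanced_sibs(100, 10)
  A <- compute_kinship(ped)
  ids <- grep("^O", A$ids, value = TRUE)
  fits <- lapply(1:5, function(r) {
    ph <- data.frame(queen_id = ids,
                     week = rep(sprintf("w%d", 1:5), 200),
                     y = stats::rnorm(1000, sd = sqrt(10)))
    suppressWarnings(fit_univariate(ph, A, "y"))
  })
  h2s <- vapply(fits, function(f) heritability(f)$h2, 0)
  expect_lte(mean(h2s), 0.02)
  # the variance floor engages on at least some replicates
  expect_gte(sum(vapply(fits, `[[`, TRUE, "boundary")), 1L)
})

test_that("restricted logL is invariant to reference level, record order and shift", {
  set.seed(55)
  ped <- ped_balanced_sibs(15, 8)
  A <- compute_kinship(ped)
  ids <- grep("^O", A$ids, value = TRUE)
  ph <- sim_on_A(A, ids, 1.5, 2)
  ph$week <- rep(c("w1", "w2", "w3", "w4"), length.out = nrow(ph))
  f0 <- fit_univariate(ph, A, "y")
  # relabelled week classes (different reference level, same partition)
  ph_rl <- ph
  ph_rl$week <- c(w1 = "z9", w2 = "a1", w3 = "m5", w4 = "b2")[ph$week]
  f_rl <- fit_univariate(ph_rl, A, "y")
  expect_equal(f_rl$logL, f0$logL, tolerance = 1e-7)
  expect_equal(f_rl$varcomp, f0$varcomp, tolerance = 1e-5)
  # shuffled record order
  ph_sh <- ph[sample(nrow(ph)), ]
  f_sh <- fit_univariate(ph_sh, A, "y")
  expect_equal(f_sh$logL, f0$logL, tolerance = 1e-7)
  expect_equal(f_sh$varcomp, f0$varcomp, tolerance = 1e-5)
  # constant shift of y is absorbed by the fixed effects
  ph_c <- ph
  ph_c$y <- ph$y + 100
  f_c <- fit_univariate(ph_c, A, "y")
  expect_equal(f_c$logL, f0$logL, tolerance = 1e-7)
  expect_equal(f_c$varcomp, f0$varcomp, tolerance = 1e-5)
})

test_that("A = I with single records is flagged as non-identifiable", {
  set.seed(66)
  ids <- sprintf("q%03d", 1:150)
  AI <- amatrix_from(diag(150), ids)
  ph <- data.frame(queen_id = ids,
                   week = rep(sprintf("w%d", 1:5), 30),
                   y = stats::rnorm(150))
  expect_warning(fit <- fit_univariate(ph, AI, "y"), "identifiable")
  expect_false(fit$identifiable)
  # a structured A must not be flagged
  ped <- ped_balanced_sibs(20, 8)
  A <- compute_kinship(ped)
  ids2 <- grep("^O", A$ids, value = TRUE)
  ph2 <- sim_on_A(A, ids2, 1, 1)
  fit2 <- fit_univariate(ph2, A, "y")
  expect_true(fit2$identifiable)
})

test_that("heritability and its delta-method SE behave", {
  fake <- structure(list(kind = "univariate", trait = "t",
                         varcomp = c(sigma2_a = 50, sigma2_e = 50),
                         vcov = diag(c(25, 25)), boundary = FALSE),
                    class = "bee_fit")
  h <- heritability(fake)
  expect_equal(h$h2, 0.5)
  # gradient (se, -sa)/tot^2 = (0.005, -0.005); SE = sqrt(2 * 25) * 0.005
  expect_equal(h$se, sqrt(50) * 0.005, tolerance = 1e-12)
  fake$varcomp <- c(sigma2_a = 0, sigma2_e = 100)
  expect_equal(heritability(fake)$h2, 0)
  fake$varcomp <- c(sigma2_a = 0, sigma2_e = 0)
  expect_error(heritability(fake), "zero total variance")
})

test_that("delta-method SE of h2 agrees with a parametric bootstrap", {
  set.seed(77)
  ped <- ped_balanced_sibs(20, 10)
  A <- compute_kinship(ped)
  ids <- grep("^O", A$ids, value = TRUE)
  Asub <- phenotyped_submatrix(A, ids)$A
  L <- t(chol(Asub + diag(1e-10, length(ids))))
  simy <- function(sa, se) drop(L %*% stats::rnorm(length(ids))) * sqrt(sa) +
    stats::rnorm(length(ids)) * sqrt(se)
  ph0 <- data.frame(queen_id = ids, week = "w", y = simy(1, 1))
  f0 <- fit_univariate(ph0, A, "y")
  h0 <- heritability(f0)
  boot <- replicate(200, {
    ph <- data.frame(queen_id = ids, week = "w",
                     y = simy(f0$varcomp[[1]], f0$varcomp[[2]]))
    heritability(suppressWarnings(fit_univariate(ph, A, "y")))$h2
  })
  expect_lt(abs(h0$se - stats::sd(boot)) / stats::sd(boot), 0.20)
})

test_that("degenerate inputs raise named errors", {
  ped <- ped_balanced_sibs(3, 2)
  A <- compute_kinship(ped)
  ids <- grep("^O", A$ids, value = TRUE)
  ph <- data.frame(queen_id = ids, week = "w", y = stats::rnorm(6))
  expect_error(fit_univariate(ph, A, "y"), "fewer than 10")
  expect_error(fit_univariate(ph, A, "nope"), "trait not in phenotype table")
  ph$week[1] <- NA
  expect_error(uni_data <- fit_univariate(ph, A, "y"), "")
})
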