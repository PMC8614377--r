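# Pedigree fixtures, all built in code.

# super-sister pair: one dam, sire group of a single drone (D = 1) whose
# DPQ mother is an unrelated founder
ped_supersisters <- function() {
  q <- data.frame(id = c("M", "D", "Q1", "Q2"),
                  dam_id = c(NA, NA, "D", "D"),
                  sire_group_id = c(NA, NA, "S", "S"))
  g <- data.frame(group_id = "S", dpq_ids = "M", n_drones = 1,
                  pool_id = "p")
  bee_pedigree(q, g)
}

# sisters: same dam, one group of D = 12 drones from 12 unrelated founder
# DPQ mothers
ped_sisters12 <- function() {
  q <- data.frame(id = c(sprintf("M%02d", 1:12), "D", "Q1", "Q2"),
                  dam_id = c(rep(NA, 13), "D", "D"),
                  sire_group_id = c(rep(NA, 13), "S", "S"))
  g <- data.frame(group_id = "S",
                  dpq_ids = paste(sprintf("M%02d", 1:12), collapse = ";"),
                  n_drones = 12, pool_id = "p")
  bee_pedigree(q, g)
}

# balanced super-sister families: s matings (one dam + one D = 1 drone
# from a family-specific founder DPQ), k daughters each; block A with
# within-family a = 0.75 and zero between families
ped_balanced_sibs <- function(s, k) {
  founders <- data.frame(id = c(sprintf("P%02d", 1:s), sprintf("D%02d", 1:s)),
                         dam_id = NA_character_,
                         sire_group_id = NA_character_)
  g <- data.frame(group_id = sprintf("S%02d", 1:s),
                  dpq_ids = sprintf("P%02d", 1:s),
                  n_drones = 1, pool_id = sprintf("p%02d", 1:s))
  off <- do.call(rbind, lapply(1:s, function(i)
    data.frame(id = sprintf("O%02d_%02d", i, 1:k),
               dam_id = sprintf("D%02d", i),
               sire_group_id = sprintf("S%02d", i))))
  bee_pedigree(rbind(founders, off), g)
}

# random multi-generation station pedigree: every mating gets its own
# sire group; groups draw 2-4 DPQ mothers from a shared pool
ped_random_station <- function(seed, n_dpq = 6, n_dams = 6, n_gens = 2,
                               off_per_mating = 3, D = 5) {
  set.seed(seed)
  dpq <- sprintf("P%02d", 1:n_dpq)
  q <- data.frame(id = c(dpq, sprintf("F%02d", 1:n_dams)),
                  dam_id = NA_character_, sire_group_id = NA_character_)
  g <- data.frame(group_id = character(), dpq_ids = character(),
                  n_drones = integer(), pool_id = character())
  dams <- sprintf("F%02d", 1:n_dams)
  k <- 0
  for (gen in 1:n_gens) {
    newq <- character()
    for (dm in dams) {
      k <- k + 1
      gid <- sprintf("S%03d", k)
      g <- rbind(g, data.frame(group_id = gid,
                               dpq_ids = paste(sample(dpq, sample(2:4, 1)),
                                               collapse = ";"),
                               n_drones = D, pool_id = "p1"))
      for (o in 1:off_per_mating) {
        id <- sprintf("Q%d_%03d_%d", gen, k, o)
        q <- rbind(q, data.frame(id = id, dam_id = dm, sire_group_id = gid))
        newq <- c(newq, id)
      }
    }
    dams <- sample(newq, min(n_dams, length(newq)))
  }
  bee_pedigree(q, g)
}

# wrap a plain relationship matrix (for constructed-A tests)
amatrix_from <- function(M, ids = rownames(M)) {
  dimnames(M) <- list(ids, ids)
  structure(list(ids = ids, A = M, f = stats::setNames(diag(M) - 1, ids)),
            class = "bee_amatrix")
}

# draw phenotypes y = Xb + u + e directly on a given A (no generator)
sim_on_A <- function(A, ids, sigma2_a, sigma2_e, week = "w") {
  n <- length(ids)
  L <- t(chol(A$A[ids, ids] + diag(1e-10, n)))
  y <- drop(L %*% stats::rnorm(n)) * sqrt(sigma2_a) +
    stats::rnorm(n) * sqrt(sigma2_e)
  data.frame(queen_id = ids, week = week, y = y)
}

# brute-force restricted log-likelihood: direct determinants and solves,
# shares no code with the package evaluator
brute_reml_ll <- function(y, X, Am, sigma2_a, sigma2_e) {
  V <- sigma2_a * Am + sigma2_e * diag(nrow(Am))
  n <- nrow(Am)
  p <- ncol(X)
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  b <- solve(M, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  drop(-0.5 * ((n - p) * log(2 * pi) +
               determinant(V)$modulus + determinant(M)$modulus +
               t(r) %*% Vi %*% r))
}

# brute-force bivariate restricted log-likelihood over observed
# (queen, trait) cells: dense V by the covariance definition, direct
# solves and determinants; independent of the package's spectral and
# cell-deletion code paths
brute_bi_ll <- function(ph, Afull, traits, G, R) {
  k1 <- !is.na(ph[[traits[1]]])
  k2 <- !is.na(ph[[traits[2]]])
  ids1 <- as.character(ph$queen_id[k1])
  ids2 <- as.character(ph$queen_id[k2])
  y <- c(ph[[traits[1]]][k1], ph[[traits[2]]][k2])
  Xof <- function(w) {
    f <- factor(w)
    if (nlevels(f) < 2) matrix(1, length(w), 1) else stats::model.matrix(~f)
  }
  X1 <- Xof(ph$week[k1]); X2 <- Xof(ph$week[k2])
  X <- rbind(cbind(X1, matrix(0, nrow(X1), ncol(X2))),
             cbind(matrix(0, nrow(X2), ncol(X1)), X2))
  M <- Afull$A
  same <- outer(ids1, ids2, "==")
  V12 <- G[1, 2] * M[ids1, ids2] + R[1, 2] * same
  V <- rbind(cbind(G[1, 1] * M[ids1, ids1] + R[1, 1] * diag(length(ids1)),
                   V12),
             cbind(t(V12),
                   G[2, 2] * M[ids2, ids2] + R[2, 2] * diag(length(ids2))))
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  Mx <- t(X) %*% Vi %*% X
  b <- solve(Mx, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  drop(-0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
               determinant(Mx)$modulus + t(r) %*% Vi %*% r))
}

# closed-form Pearson correlation between a Gaussian variable and its
# cube (volume ~ d^3): 3(mu^2+s2)/sqrt(9 mu^4 + 36 mu^2 s2 + 15 s2^2)
cube_corr_theory <- function(mu, sigma) {
  s2 <- sigma^2
  3 * (mu^2 + s2) / sqrt(9 * mu^4 + 36 * mu^2 * s2 + 15 * s2^2)
}
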