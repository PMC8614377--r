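#' @name reml
#' @title REML animal models for single-record queen phenotypes
#'
#' @description
#' The animal model is y = X b + a + e with one record per queen, a week
#' -of-year fixed-effect design X, breeding values a ~ N(0, sigma2_a A)
#' and residuals e ~ N(0, sigma2_e I).  Variance components maximize the
#' restricted log-likelihood
#' \deqn{l_R = -1/2 [ (n-p) log 2\pi + log|V| + log|X' V^{-1} X| + y' P y ]}
#' with V = sigma2_a A + sigma2_e I and P the usual REML projection.
#' A single spectral decomposition of A per dataset reduces every
#' likelihood evaluation to diagonal (univariate) or 2x2-block
#' (bivariate, complete records) algebra; with trait-wise missingness the
#' bivariate V is assembled densely over the observed (queen, trait)
#' cells only.
NULL

# ---- design helpers --------------------------------------------------

# week-class fixed-effect design; intercept-only fallback for < 2 classes
week_design <- function(week) {
  f <- factor(week)
  if (nlevels(f) < 2L) {
    X <- matrix(1, length(week), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- stats::model.matrix(~f)
    colnames(X) <- c("(Intercept)", paste0("week", levels(f)[-1L]))
  }
  if (qr(X)$rank < ncol(X))
    stop("singular_design_error: collinear week classes", call. = FALSE)
  X
}

uni_data <- function(pheno, A, trait, week = "week") {
  if (!trait %in% names(pheno))
    stop("model_error: trait not in phenotype table: ", trait, call. = FALSE)
  keep <- !is.na(pheno[[trait]])
  ids <- as.character(pheno$queen_id[keep])
  y <- as.numeric(pheno[[trait]][keep])
  wk <- if (week %in% names(pheno)) pheno[[week]][keep] else rep("w", sum(keep))
  if (anyNA(wk))
    stop("model_error: phenotyped queen without week class", call. = FALSE)
  X <- week_design(wk)
  list(ids = ids, y = y, X = X, n = length(y))
}

# restricted log-likelihood in spectral coordinates; d = Var eigenvalues
reml_core <- function(yt, Xt, d) {
  w <- 1 / d
  Q <- Xt * w
  M <- crossprod(Xt, Q)
  cM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cM)) return(NULL)
  u <- crossprod(Q, yt)
  beta <- backsolve(cM, forwardsolve(t(cM), u))
  r <- yt - Xt %*% beta
  py <- r * w
  yPy <- sum(yt * py)
  n <- length(yt); p <- ncol(Xt)
  ll <- -0.5 * ((n - p) * log(2 * pi) + sum(log(d)) +
                2 * sum(log(diag(cM))) + yPy)
  list(ll = ll, beta = beta, py = py, w = w, Q = Q, M = M, cM = cM)
}

#' Evaluate the univariate restricted log-likelihood
#'
#' Direct evaluation of l_R at given variance components, for model
#' assessment and cross-checking; independent code paths (brute-force
#' determinant/solve) should agree with this to high precision.
#'
#' @param pheno phenotype table with \code{queen_id}, week column, trait
#' @param A a \code{\link{bee_amatrix}} covering the phenotyped queens
#' @param trait trait name
#' @param sigma2_a,sigma2_e variance components (sigma2_e > 0)
#' @param week name of the week-class column
#' @return the restricted log-likelihood (constant included)
#' @export
reml_loglik_univariate <- function(pheno, A, trait, sigma2_a, sigma2_e,
                                   week = "week") {
  dat <- uni_data(pheno, A, trait, week)
  As <- phenotyped_submatrix(A, dat$ids)
  e <- eigen(As$A, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  yt <- crossprod(e$vectors, dat$y)
  Xt <- crossprod(e$vectors, dat$X)
  out <- reml_core(yt, Xt, sigma2_a * lam + sigma2_e)
  if (is.null(out)) stop("model_error: singular X'V^{-1}X", call. = FALSE)
  out$ll
}

#' Fit the univariate animal model by REML
#'
#' Maximizes l_R over (sigma2_a, sigma2_e) on the log-variance scale
#' (quasi-Newton ascent with analytic gradients), floors variances at
#' 1e-8 of the phenotypic variance with a boundary flag, and reports the
#' observed-information covariance of the estimates from central finite
#' differences of l_R (relative step 1e-4).  A near-singular information
#' matrix (as with A = I, where only sigma2_a + sigma2_e is identified
#' from single records) is flagged via \code{identifiable = FALSE}.
#'
#' @param pheno phenotype table (\code{queen_id}, week column, traits)
#' @param A a \code{\link{bee_amatrix}} covering the phenotyped queens
#' @param trait trait name
#' @param week week-class column name; fewer than 2 classes fall back to
#'   an intercept-only design
#' @return a \code{bee_fit} list: \code{varcomp} (sigma2_a, sigma2_e),
#'   \code{logL}, \code{vcov} (2x2, component scale), \code{converged},
#'   \code{boundary}, \code{identifiable}, \code{n_used}, \code{trait}
#' @export
fit_univariate <- function(pheno, A, trait, week = "week") {
  dat <- uni_data(pheno, A, trait, week)
  if (dat$n < 10L)
    stop("model_error: fewer than 10 non-missing records for ", trait,
         call. = FALSE)
  As <- phenotyped_submatrix(A, dat$ids)
  e <- eigen(As$A, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, dat$y))
  Xt <- crossprod(e$vectors, dat$X)
  vp <- stats::var(dat$y)
  floor_v <- 1e-8 * vp

  nll <- function(th) {
    s <- exp(th)
    out <- reml_core(yt, Xt, s[1L] * lam + s[2L])
    if (is.null(out)) return(1e10)
    -out$ll
  }
  ngr <- function(th) {
    s <- exp(th)
    out <- reml_core(yt, Xt, s[1L] * lam + s[2L])
    if (is.null(out)) return(c(0, 0))
    g <- numeric(2L)
    for (ci in 1:2) {
      cvec <- if (ci == 1L) lam else rep(1, length(lam))
      T1 <- sum(cvec * out$w)
      B <- crossprod(out$Q, out$Q * cvec)
      T2 <- sum(diag(backsolve(out$cM, forwardsolve(t(out$cM), B))))
      T3 <- sum(cvec * out$py^2)
      g[ci] <- -0.5 * (T1 - T2 - T3)   # d l / d sigma2_c
    }
    -g * s   # chain rule to log scale, negated
  }

  lower <- rep(log(floor_v), 2L)
  upper <- rep(log(1e3 * vp + floor_v), 2L)
  start <- log(pmax(c(vp / 2, vp / 2), floor_v * 2))
  opt <- stats::optim(start, nll, ngr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 10, pgtol = 1e-12,
                                     maxit = 200L))
  if (opt$convergence != 0L) {
    # line-search failures near flat regions: polish derivative-free
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 500L, reltol = 1e-12))
    if (opt2$value <= opt$value) {
      opt$par <- pmin(pmax(opt2$par, lower), upper)
      opt$value <- nll(opt$par)
      opt$convergence <- opt2$convergence
    }
  }
  converged <- opt$convergence == 0L
  if (!converged)
    warning("fit_univariate: optimizer did not converge (code ",
            opt$convergence, ") for trait ", trait, call. = FALSE)
  s <- exp(opt$par)
  names(s) <- c("sigma2_a", "sigma2_e")
  boundary <- any(opt$par <= lower + 1e-6)

  # observed information in component scale
  f_comp <- function(v) {
    out <- reml_core(yt, Xt, v[1L] * lam + v[2L])
    if (is.null(out)) NA_real_ else out$ll
  }
  H <- fd_hessian(f_comp, s, rel_step = 1e-4)
  info <- -H
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))

  # With one record per queen the only candidate flat direction is the
  # exchange sigma2_a <-> sigma2_e (exactly flat when A = I): probe the
  # likelihood directly along it rather than trusting numerical Hessian
  # eigenvalues.
  ll0 <- -opt$value
  delta <- 0.02 * sum(s)
  probe <- vapply(list(c(delta, -delta), c(-delta, delta)), function(dv) {
    v <- s + dv
    if (any(v <= 0)) return(NA_real_)
    f_comp(v) - ll0
  }, 0)
  identifiable <- any(abs(probe) > 1e-4, na.rm = TRUE)
  if (!identifiable)
    warning("fit_univariate: flat restricted-likelihood direction; ",
            "sigma2_a and sigma2_e are not separately identifiable",
            call. = FALSE)
  dimnames(vcov) <- list(names(s), names(s))

  structure(list(kind = "univariate", trait = trait, varcomp = s,
                 logL = -opt$value, vcov = vcov, converged = converged,
                 boundary = boundary, identifiable = identifiable,
                 n_used = dat$n),
            class = "bee_fit")
}

# central finite-difference Hessian with relative steps
fd_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 1e-8 * max(abs(x), 1))
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Heritability with delta-method standard error
#'
#' h2 = sigma2_a / (sigma2_a + sigma2_e); the SE propagates the fit's
#' observed-information covariance through the variance ratio.
#'
#' @param fit a univariate \code{bee_fit}
#' @return list with \code{h2}, \code{se} and \code{boundary}
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "bee_fit"), fit$kind == "univariate")
  sa <- fit$varcomp[["sigma2_a"]]; se_ <- fit$varcomp[["sigma2_e"]]
  tot <- sa + se_
  if (tot <= 0) stop("model_error: zero total variance", call. = FALSE)
  h2 <- sa / tot
  g <- c(se_, -sa) / tot^2
  se_h2 <- sqrt(max(0, drop(t(g) %*% fit$vcov %*% g)))
  list(h2 = h2, se = se_h2, boundary = fit$boundary)
}

# ---- bivariate -------------------------------------------------------

bi_data <- function(pheno, A, traits, week = "week") {
  stopifnot(length(traits) == 2L)
  d1 <- uni_data(pheno, A, traits[1L], week)
  d2 <- uni_data(pheno, A, traits[2L], week)
  if (d1$n < 10L || d2$n < 10L)
    stop("model_error: fewer than 10 non-missing records", call. = FALSE)
  complete <- identical(d1$ids, d2$ids)
  list(d1 = d1, d2 = d2, complete = complete)
}

# l_R for the bivariate model at given G, R (2x2 each)
bi_loglik <- function(dat, A, G, R) {
  if (dat$complete) {
    bi_loglik_complete(bi_prep_complete(dat, A), G, R)
  } else {
    bi_loglik_general(dat, A, G, R)
  }
}

# spectral transform of the complete-record data, done once per fit
bi_prep_complete <- function(dat, A) {
  As <- phenotyped_submatrix(A, dat$d1$ids)
  e <- eigen(As$A, symmetric = TRUE)
  U <- e$vectors
  list(lam = pmax(e$values, 0),
       y1 = drop(crossprod(U, dat$d1$y)),
       y2 = drop(crossprod(U, dat$d2$y)),
       Xt = crossprod(U, dat$d1$X))
}

bi_loglik_complete <- function(prep, G, R) {
  lam <- prep$lam
  y1 <- prep$y1; y2 <- prep$y2; Xt <- prep$Xt
  n <- length(lam); p <- ncol(Xt)
  m11 <- lam * G[1, 1] + R[1, 1]
  m12 <- lam * G[1, 2] + R[1, 2]
  m22 <- lam * G[2, 2] + R[2, 2]
  det <- m11 * m22 - m12^2
  if (any(det <= 0) || any(m11 <= 0)) return(NA_real_)
  i11 <- m22 / det; i22 <- m11 / det; i12 <- -m12 / det
  B11 <- crossprod(Xt, Xt * i11)
  B12 <- crossprod(Xt, Xt * i12)
  B22 <- crossprod(Xt, Xt * i22)
  M <- rbind(cbind(B11, B12), cbind(B12, B22))
  cM <- tryCatch(chol(M), error = function(er) NULL)
  if (is.null(cM)) return(NA_real_)
  u <- c(crossprod(Xt, i11 * y1 + i12 * y2),
         crossprod(Xt, i12 * y1 + i22 * y2))
  beta <- backsolve(cM, forwardsolve(t(cM), u))
  yVy <- sum(i11 * y1^2 + 2 * i12 * y1 * y2 + i22 * y2^2)
  yPy <- yVy - sum(u * beta)
  -0.5 * ((2 * n - 2 * p) * log(2 * pi) + sum(log(det)) +
          2 * sum(log(diag(cM))) + yPy)
}

bi_loglik_general <- function(dat, A, G, R) {
  ids <- unique(c(dat$d1$ids, dat$d2$ids))
  As <- phenotyped_submatrix(A, ids)$A
  o1 <- match(dat$d1$ids, ids); o2 <- match(dat$d2$ids, ids)
  n1 <- length(o1); n2 <- length(o2)
  V11 <- G[1, 1] * As[o1, o1] + R[1, 1] * diag(n1)
  V22 <- G[2, 2] * As[o2, o2] + R[2, 2] * diag(n2)
  same <- outer(dat$d1$ids, dat$d2$ids, "==")
  V12 <- G[1, 2] * As[o1, o2] + R[1, 2] * same
  V <- rbind(cbind(V11, V12), cbind(t(V12), V22))
  cV <- tryCatch(chol(V), error = function(er) NULL)
  if (is.null(cV)) return(NA_real_)
  X <- rbind(cbind(dat$d1$X, matrix(0, n1, ncol(dat$d2$X))),
             cbind(matrix(0, n2, ncol(dat$d1$X)), dat$d2$X))
  y <- c(dat$d1$y, dat$d2$y)
  Vy <- backsolve(cV, forwardsolve(t(cV), y))
  VX <- backsolve(cV, forwardsolve(t(cV), X))
  M <- crossprod(X, VX)
  cM <- tryCatch(chol(M), error = function(er) NULL)
  if (is.null(cM)) return(NA_real_)
  u <- crossprod(X, Vy)
  beta <- backsolve(cM, forwardsolve(t(cM), u))
  yPy <- sum(y * Vy) - sum(u * beta)
  ntot <- n1 + n2; p <- ncol(X)
  -0.5 * ((ntot - p) * log(2 * pi) + 2 * sum(log(diag(cV))) +
          2 * sum(log(diag(cM))) + yPy)
}

#' Evaluate the bivariate restricted log-likelihood
#'
#' @param pheno phenotype table
#' @param A a \code{\link{bee_amatrix}}
#' @param traits two trait names
#' @param G,R 2x2 genetic and residual covariance matrices
#' @param week week-class column name
#' @return the restricted log-likelihood (constant included)
#' @export
reml_loglik_bivariate <- function(pheno, A, traits, G, R, week = "week") {
  dat <- bi_data(pheno, A, traits, week)
  ll <- bi_loglik(dat, A, as.matrix(G), as.matrix(R))
  if (is.na(ll)) stop("model_error: V not positive definite", call. = FALSE)
  ll
}

theta_to_GR <- function(th) {
  Lg <- matrix(c(exp(th[1L]), th[2L], 0, exp(th[3L])), 2, 2)
  Lr <- matrix(c(exp(th[4L]), th[5L], 0, exp(th[6L])), 2, 2)
  list(G = tcrossprod(Lg), R = tcrossprod(Lr))
}

#' Fit the bivariate animal model by REML
#'
#' Six parameters (2x2 G and R) are estimated through unconstrained
#' Cholesky factors (log-diagonal), which keeps both matrices positive
#' definite during the Nelder-Mead ascent; the ascent is restarted once
#' from its own optimum.  With complete records the likelihood is
#' evaluated in the spectral basis of A (2x2 blocks); with trait-wise
#' missingness, V is assembled over observed (queen, trait) cells only
#' (cell-level deletion, no imputation).  The observed-information
#' covariance over the six components (g11, g12, g22, r11, r12, r22)
#' comes from central finite differences of l_R.
#'
#' @inheritParams reml_loglik_bivariate
#' @return a \code{bee_fit} with \code{G}, \code{R}, \code{logL},
#'   \code{vcov} (6x6), \code{converged}, \code{boundary},
#'   \code{n_used} (per trait), \code{traits}
#' @export
fit_bivariate <- function(pheno, A, traits, week = "week") {
  dat <- bi_data(pheno, A, traits, week)

  # precompute the spectral transform once for the complete-record path
  if (dat$complete) {
    prep <- bi_prep_complete(dat, A)
    ll_at <- function(G, R) bi_loglik_complete(prep, G, R)
  } else {
    ll_at <- function(G, R) bi_loglik_general(dat, A, G, R)
  }

  # start from the week-adjusted sample covariance, split evenly
  r1 <- stats::residuals(stats::lm(dat$d1$y ~ dat$d1$X - 1))
  r2 <- stats::residuals(stats::lm(dat$d2$y ~ dat$d2$X - 1))
  common <- intersect(dat$d1$ids, dat$d2$ids)
  S12 <- stats::cov(r1[match(common, dat$d1$ids)],
                    r2[match(common, dat$d2$ids)])
  S <- matrix(c(stats::var(r1), S12, S12, stats::var(r2)), 2, 2)
  S12max <- 0.9 * sqrt(S[1, 1] * S[2, 2])
  S[1, 2] <- S[2, 1] <- max(min(S[1, 2], S12max), -S12max)
  L0 <- t(chol(S / 2))
  start <- c(log(L0[1, 1]), L0[2, 1], log(L0[2, 2]),
             log(L0[1, 1]), L0[2, 1], log(L0[2, 2]))

  nll <- function(th) {
    gr <- theta_to_GR(th)
    ll <- ll_at(gr$G, gr$R)
    if (is.na(ll)) 1e10 else -ll
  }
  # Nelder-Mead with restarts from its own optimum until the restricted
  # logL stabilizes (fresh simplexes escape premature contraction)
  opt2 <- stats::optim(start, nll, method = "Nelder-Mead",
                       control = list(maxit = 2000L, reltol = 1e-12))
  converged <- FALSE
  for (restart in 1:5) {
    prev <- opt2$value
    opt2 <- stats::optim(opt2$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-12))
    if (opt2$convergence == 0L &&
        abs(prev - opt2$value) < 1e-6 * (abs(opt2$value) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("fit_bivariate: optimizer did not converge for (",
            paste(traits, collapse = ", "), ")", call. = FALSE)
  gr <- theta_to_GR(opt2$par)
  G <- gr$G; R <- gr$R
  dimnames(G) <- dimnames(R) <- list(traits, traits)

  vp <- c(stats::var(dat$d1$y), stats::var(dat$d2$y))
  boundary <- any(diag(G) < 1e-6 * vp) || any(diag(R) < 1e-6 * vp)

  nu <- c(G[1, 1], G[1, 2], G[2, 2], R[1, 1], R[1, 2], R[2, 2])
  names(nu) <- c("g11", "g12", "g22", "r11", "r12", "r22")
  f_comp <- function(v) {
    Gm <- matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
    Rm <- matrix(c(v[4], v[5], v[5], v[6]), 2, 2)
    ll <- ll_at(Gm, Rm)
    if (is.na(ll)) NA_real_ else ll
  }
  H <- fd_hessian(f_comp, nu, rel_step = 1e-4)
  vcov <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 6, 6))
  dimnames(vcov) <- list(names(nu), names(nu))

  structure(list(kind = "bivariate", traits = traits, G = G, R = R,
                 varcomp = nu, logL = -opt2$value, vcov = vcov,
                 converged = converged, boundary = boundary,
                 n_used = c(dat$d1$n, dat$d2$n)),
            class = "bee_fit")
}

#' Genetic and phenotypic correlations with delta-method SEs
#'
#' r_g = g12 / sqrt(g11 g22); r_p = (g12 + r12) / sqrt((g11 + r11)(g22 +
#' r22)).  SEs propagate the bivariate fit's observed-information
#' covariance.  r_g is clamped to [-1, 1] (reported via \code{clamped});
#' if either genetic variance is at the zero boundary, r_g is undefined
#' and returned as NA with a reason.
#'
#' @param fit a bivariate \code{bee_fit}
#' @return list with \code{r_g}, \code{se_g}, \code{r_p}, \code{se_p},
#'   \code{clamped}, \code{reason}
#' @export
correlations <- function(fit) {
  stopifnot(inherits(fit, "bee_fit"), fit$kind == "bivariate")
  v <- fit$varcomp
  g11 <- v[["g11"]]; g12 <- v[["g12"]]; g22 <- v[["g22"]]
  r11 <- v[["r11"]]; r12 <- v[["r12"]]; r22 <- v[["r22"]]
  p11 <- g11 + r11; p22 <- g22 + r22
  out <- list(r_g = NA_real_, se_g = NA_real_, r_p = NA_real_,
              se_p = NA_real_, clamped = FALSE, reason = NA_character_)

  r_p <- (g12 + r12) / sqrt(p11 * p22)
  gp <- c(-r_p / (2 * p11), 1 / sqrt(p11 * p22), -r_p / (2 * p22),
          -r_p / (2 * p11), 1 / sqrt(p11 * p22), -r_p / (2 * p22))
  out$r_p <- r_p
  out$se_p <- sqrt(max(0, drop(t(gp) %*% fit$vcov %*% gp)))

  vp_floor <- 1e-6 * c(p11, p22)
  if (g11 <= vp_floor[1L] || g22 <= vp_floor[2L]) {
    out$reason <- "zero genetic variance in at least one trait"
    return(out)
  }
  r_g <- g12 / sqrt(g11 * g22)
  gg <- c(-r_g / (2 * g11), 1 / sqrt(g11 * g22), -r_g / (2 * g22), 0, 0, 0)
  out$se_g <- sqrt(max(0, drop(t(gg) %*% fit$vcov %*% gg)))
  if (abs(r_g) > 1) {
    out$clamped <- TRUE
    r_g <- sign(r_g)
  }
  out$r_g <- r_g
  out
}

#' @export
print.bee_fit <- function(x, ...) {
  if (x$kind == "univariate") {
    h <- heritability(x)
    cat("bee_fit (univariate)", x$trait, ": sigma2_a =",
        format(x$varcomp[1], digits = 4), ", sigma2_e =",
        format(x$varcomp[2], digits = 4), ", h2 =",
        format(h$h2, digits = 3), "(", format(h$se, digits = 2), ")\n")
  } else {
    co <- correlations(x)
    cat("bee_fit (bivariate)", paste(x$traits, collapse = "/"),
        ": r_g =", format(co$r_g, digits = 3),
        ", r_p =", format(co$r_p, digits = 3), "\n")
  }
  cat("  logL =", format(x$logL, digits = 8), "; converged:", x$converged,
      "; boundary:", x$boundary, "\n")
  invisible(x)
}
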