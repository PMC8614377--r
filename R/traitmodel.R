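#' Trait model for phenotype simulation
#'
#' Holds the generating parameters of the trait model
#' y = mu + week + a + e with breeding values a ~ N(0, G x A) and
#' residuals e ~ N(0, R), plus the spermatheca measurement protocol
#' (three replicate diameter measurements averaged, volume by the sphere
#' formula).
#'
#' @param trait_names simulated trait names (the derived volume trait, if
#'   any, is not simulated directly; see \code{derive_volume})
#' @param means per-trait overall means mu, in trait units
#' @param G genetic covariance matrix (symmetric PSD)
#' @param R residual covariance matrix (symmetric PSD)
#' @param week_effect_sd scalar tau: week effects are drawn once per week
#'   class as N(0, (tau * sigma_p)^2) per trait, sigma_p the generating
#'   phenotypic SD; they are estimated as fixed effects downstream
#' @param derive_volume if TRUE, a volume trait is appended, computed from
#'   the diameter trait by the sphere formula applied to the mean of
#'   \code{measurement_reps} replicate measurements
#' @param diameter_trait,volume_trait trait names for the derivation
#' @param measurement_reps replicate diameter measurements per queen
#' @param measurement_sd SD of replicate measurement noise (mm); the
#'   replicates differ because the organ is not a perfect sphere
#' @param missing_rates named per-trait missingness probabilities
#' @param units optional named units, for reporting
#' @return a \code{trait_model} list
#' @export
trait_model <- function(trait_names, means, G, R,
                        week_effect_sd = 0.3,
                        derive_volume = FALSE,
                        diameter_trait = "sd", volume_trait = "sv",
                        measurement_reps = 3L, measurement_sd = 0,
                        missing_rates = NULL, units = NULL) {
  k <- length(trait_names)
  G <- as.matrix(G); R <- as.matrix(R)
  if (length(means) != k || !all(dim(G) == k) || !all(dim(R) == k))
    stop("trait_model_error: dimension mismatch", call. = FALSE)
  if (!all(is.finite(means)))
    stop("trait_model_error: non-finite means", call. = FALSE)
  for (M in list(G = G, R = R)) {
    if (max(abs(M - t(M))) > 1e-8)
      stop("trait_model_error: covariance matrix not symmetric", call. = FALSE)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("trait_model_error: covariance matrix not PSD", call. = FALSE)
  }
  if (week_effect_sd < 0)
    stop("trait_model_error: week_effect_sd must be >= 0", call. = FALSE)
  if (derive_volume && !(diameter_trait %in% trait_names))
    stop("trait_model_error: diameter trait not simulated", call. = FALSE)
  dimnames(G) <- dimnames(R) <- list(trait_names, trait_names)
  names(means) <- trait_names
  structure(list(trait_names = trait_names, means = means, G = G, R = R,
                 week_effect_sd = week_effect_sd,
                 derive_volume = derive_volume,
                 diameter_trait = diameter_trait,
                 volume_trait = volume_trait,
                 measurement_reps = as.integer(measurement_reps),
                 measurement_sd = measurement_sd,
                 missing_rates = missing_rates, units = units),
            class = "trait_model")
}

#' Single-trait model with a target heritability
#'
#' Convenience constructor for parameter-recovery simulations: one trait
#' with phenotypic variance \code{sigma2_p} split as
#' \code{sigma2_a = h2 * sigma2_p}, \code{sigma2_e = (1 - h2) * sigma2_p}.
#'
#' @param h2 generating heritability in [0, 1]
#' @param mean trait mean
#' @param sigma2_p generating phenotypic variance
#' @param trait trait name
#' @param week_effect_sd tau, as in \code{\link{trait_model}}
#' @return a \code{trait_model}
#' @export
univariate_trait_model <- function(h2, mean = 0, sigma2_p = 1,
                                   trait = "y", week_effect_sd = 0.3) {
  if (h2 < 0 || h2 > 1) stop("trait_model_error: h2 outside [0, 1]",
                             call. = FALSE)
  trait_model(trait, mean, matrix(h2 * sigma2_p),
              matrix((1 - h2) * sigma2_p), week_effect_sd = week_effect_sd)
}

# Published-population calibration tables (marginals and genetic
# parameters of the study population the generator emulates).
study_trait_table <- function() {
  data.frame(
    trait = c("bw", "hw", "tw", "aw", "hwi", "twi", "awi", "wl",
              "sd", "sv", "o", "sp"),
    unit  = c("mg", "mg", "mg", "mg", "mm", "mm", "mm", "mm",
              "mm", "ul", "n", "n_million"),
    mean  = c(195.90, 13.22, 77.93, 104.76, 3.67, 4.67, 4.80, 10.07,
              1.32, 1.27, 141, 3.6),
    sd    = c(19.84, 1.83, 8.17, 15.28, 0.18, 0.26, 0.21, 0.62,
              0.18, 0.53, 25, 2.9),
    h2    = c(0.54, 0.51, 0.50, 0.46, 0.26, 0.42, 0.13, 0.30,
              0.17, 0.88, 0.70, 0.57),
    stringsAsFactors = FALSE)
}

# Genetic (upper triangle) and phenotypic (lower triangle) correlation
# targets among the traits, same order as study_trait_table().
study_correlation_table <- function() {
  tn <- study_trait_table()$trait
  k <- length(tn)
  M <- matrix(NA_real_, k, k, dimnames = list(tn, tn))
  diag(M) <- 1
  # upper triangle: genetic correlations, row by row
  M["bw", c("hw","tw","aw","hwi","twi","awi","wl","sd","sv","o","sp")] <-
    c(0.80, 0.92, 0.84, 0.47, 0.34, -0.22, 0.17, 0.23, 0.40, -0.13, -0.13)
  M["hw", c("tw","aw","hwi","twi","awi","wl","sd","sv","o","sp")] <-
    c(0.99, 0.61, 0.97, 0.34, -0.56, 0.92, -0.44, -0.44, 0.28, 0.23)
  M["tw", c("aw","hwi","twi","awi","wl","sd","sv","o","sp")] <-
    c(0.98, -0.01, 0.83, 0.54, 0.74, 0.78, 0.61, -0.18, 0.15)
  M["aw", c("hwi","twi","awi","wl","sd","sv","o","sp")] <-
    c(0.47, -0.14, -0.60, -0.45, -0.24, 0.06, -0.15, -0.30)
  M["hwi", c("twi","awi","wl","sd","sv","o","sp")] <-
    c(0.21, 0.15, 0.96, 0.89, 0.70, 0.55, 0.63)
  M["twi", c("awi","wl","sd","sv","o","sp")] <-
    c(0.74, 0.98, 0.59, 0.44, 0.02, -0.17)
  M["awi", c("wl","sd","sv","o","sp")] <- c(0.33, -0.22, 0.44, -0.59, 0.26)
  M["wl", c("sd","sv","o","sp")] <- c(0.43, 0.40, 0.79, 0.57)
  M["sd", c("sv","o","sp")] <- c(0.99, -0.42, -0.96)
  M["sv", c("o","sp")] <- c(-0.31, -0.70)
  M["o", "sp"] <- 0.08
  # lower triangle: phenotypic correlations
  M["hw", "bw"] <- 0.39
  M["tw", c("bw","hw")] <- c(0.67, 0.19)
  M["aw", c("bw","hw","tw")] <- c(0.88, 0.31, 0.29)
  M["hwi", c("bw","hw","tw","aw")] <- c(0.36, 0.31, 0.28, 0.27)
  M["twi", c("bw","hw","tw","aw","hwi")] <- c(0.34, 0.30, 0.28, 0.26, 0.32)
  M["awi", c("bw","hw","tw","aw","hwi","twi")] <-
    c(0.39, 0.17, 0.26, 0.33, 0.25, 0.80)
  M["wl", c("bw","hw","tw","aw","hwi","twi","awi")] <-
    c(0.34, 0.16, 0.36, 0.20, 0.26, 0.39, 0.30)
  M["sd", c("bw","hw","tw","aw","hwi","twi","awi","wl")] <-
    c(0.21, 0.04, 0.18, 0.20, 0.08, 0.15, 0.13, 0.10)
  M["sv", c("bw","hw","tw","aw","hwi","twi","awi","wl","sd")] <-
    c(0.22, 0.03, 0.11, 0.18, 0.02, 0.16, 0.16, 0.09, 0.97)
  M["o", c("bw","hw","tw","aw","hwi","twi","awi","wl","sd","sv")] <-
    c(0.01, 0.15, -0.003, -0.02, 0.08, 0.04, 0.03, 0.02, -0.01, -0.05)
  M["sp", c("bw","hw","tw","aw","hwi","twi","awi","wl","sd","sv","o")] <-
    c(0.03, 0.03, 0.09, -0.01, 0.10, 0.04, 0.08, 0.17, -0.07, -0.07, 0.05)
  M
}

#' Default trait model calibrated to the study population
#'
#' Eleven traits are simulated jointly (body weight bw; head/thorax/
#' abdomen weights hw, tw, aw; head/thorax/abdomen widths hwi, twi, awi;
#' wing length wl; spermatheca diameter sd; ovariole count o; sperm count
#' sp) with means, phenotypic SDs and heritabilities set to the study
#' population's estimates; spermatheca volume sv is then derived per
#' queen from three replicate diameter measurements by the sphere
#' formula, as in the laboratory protocol, rather than simulated.
#'
#' Genetic correlations are taken from the published genetic-correlation
#' estimates, residual correlations are backed out from the phenotypic
#' ones (sigma_e12 = r_p sigma_p1 sigma_p2 - sigma_a12); because those
#' estimates carry large sampling error, both correlation targets are
#' projected to the nearest positive-semidefinite correlation matrix
#' (\code{Matrix::nearPD}) before scaling, so realized correlations are
#' close to, not identical with, the published point estimates.
#'
#' @param week_effect_sd tau, see \code{\link{trait_model}}
#' @param measurement_sd replicate diameter measurement SD, mm
#' @param sp_missing_rate missingness probability for sperm count (the
#'   study recorded it on 143 of 147 queens)
#' @return a \code{trait_model} over 11 simulated traits plus derived sv
#' @export
default_trait_model <- function(week_effect_sd = 0.3,
                                measurement_sd = 0.05,
                                sp_missing_rate = 4 / 147) {
  tab <- study_trait_table()
  corr <- study_correlation_table()
  sim <- setdiff(tab$trait, "sv")   # sv is derived, not simulated
  tab <- tab[match(sim, tab$trait), ]
  corr <- corr[sim, sim]

  sig_p <- tab$sd
  sig_a <- sqrt(tab$h2) * sig_p
  sig_e <- sqrt(1 - tab$h2) * sig_p
  k <- length(sim)
  Cg <- corr; Cg[lower.tri(Cg)] <- t(Cg)[lower.tri(Cg)]   # r_g targets
  Cp <- corr; Cp[upper.tri(Cp)] <- t(Cp)[upper.tri(Cp)]   # r_p targets
  # residual correlations implied by the phenotypic and genetic targets
  Ce <- matrix(0, k, k, dimnames = dimnames(corr))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    Ce[i, j] <- (Cp[i, j] * sig_p[i] * sig_p[j] -
                 Cg[i, j] * sig_a[i] * sig_a[j]) / (sig_e[i] * sig_e[j])
  }
  Ce[Ce > 0.98] <- 0.98; Ce[Ce < -0.98] <- -0.98
  diag(Ce) <- 1
  Cg <- as.matrix(Matrix::nearPD(Cg, corr = TRUE)$mat)
  Ce <- as.matrix(Matrix::nearPD(Ce, corr = TRUE)$mat)
  G <- diag(sig_a) %*% Cg %*% diag(sig_a)
  R <- diag(sig_e) %*% Ce %*% diag(sig_e)
  G <- (G + t(G)) / 2; R <- (R + t(R)) / 2

  units <- study_trait_table()$unit
  names(units) <- study_trait_table()$trait
  trait_model(sim, tab$mean, G, R, week_effect_sd = week_effect_sd,
              derive_volume = TRUE, diameter_trait = "sd",
              volume_trait = "sv", measurement_reps = 3L,
              measurement_sd = measurement_sd,
              missing_rates = c(sp = sp_missing_rate), units = units)
}

#' @export
print.trait_model <- function(x, ...) {
  cat("trait_model:", length(x$trait_names), "simulated traits (",
      paste(x$trait_names, collapse = ", "), ")\n")
  if (x$derive_volume)
    cat("  +", x$volume_trait, "derived from", x$diameter_trait,
        "by the sphere formula over", x$measurement_reps,
        "replicate measurements\n")
  invisible(x)
}
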