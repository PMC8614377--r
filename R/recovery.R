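#' Heritability parameter-recovery simulation
#'
#' Simulates replicate breeding populations under a given true
#' heritability and refits the univariate animal model by REML to each,
#' returning the per-replicate estimates.  The default design mirrors a
#' single-season station layout scaled up for power: 500 phenotyped
#' queens in 25 maternal sister lines, 15 weekly harvest classes, and
#' sire groups of 12 drones from 12 drone-producing queens.
#'
#' Each replicate draws its own pedigree, breeding values, week effects
#' and residuals from a replicate-specific seed derived reproducibly
#' from \code{seed}.
#'
#' @param h2 true (generating) heritability
#' @param n_reps number of replicate populations
#' @param seed master integer seed
#' @param design a \code{\link{breeding_design}}; default as above
#' @param sigma2_p generating phenotypic variance
#' @param week_effect_sd tau passed to the trait model
#' @return data.frame with one row per replicate: \code{h2_hat},
#'   \code{se}, \code{converged}, \code{boundary}
#' @export
h2_recovery <- function(h2, n_reps = 100L, seed = 1L,
                        design = breeding_design(
                          years = "y1", lines_per_year = 25L,
                          queens_per_year = 500L, weeks_per_year = 15L,
                          dpq_per_year = 12L, drones_per_mating = 12L),
                        sigma2_p = 100, week_effect_sd = 0.3) {
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  model <- univariate_trait_model(h2, mean = 0, sigma2_p = sigma2_p,
                                  week_effect_sd = week_effect_sd)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ped <- generate_pedigree(design, seed = rep_seeds[r])
    A <- compute_kinship(ped)
    ph <- simulate_phenotypes(ped, A, model, design, seed = rep_seeds[r])
    fit <- suppressWarnings(fit_univariate(ph, A, model$trait_names[1L]))
    h <- heritability(fit)
    out[[r]] <- data.frame(h2_hat = h$h2, se = h$se,
                           converged = fit$converged,
                           boundary = fit$boundary)
  }
  do.call(rbind, out)
}
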