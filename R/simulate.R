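#' Spermatheca volume from replicate diameter measurements
#'
#' The spermatheca is not a perfect sphere, so its diameter is recorded
#' as the average of three measurements; the volume is the volume of a
#' sphere with that mean diameter, (pi/6) d^3.  A diameter in mm gives a
#' volume in mm^3 = microlitres.
#'
#' @param diameters numeric vector of replicate diameters (mm), or a
#'   matrix with one row per queen and one column per replicate
#' @return list with \code{mean_diameter} (mm) and \code{volume} (ul)
#' @export
derive_spermatheca_volume <- function(diameters) {
  d <- if (is.matrix(diameters)) diameters else as.numeric(diameters)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("measurement_error: diameters must be positive and finite",
         call. = FALSE)
  d_bar <- if (is.matrix(d)) rowMeans(d) else mean(d)
  list(mean_diameter = d_bar, volume = pi / 6 * d_bar^3)
}

# lower Cholesky factor with a tiny ridge retry for PSD-but-singular input
safe_chol_lower <- function(M, ridge = 1e-10) {
  ok <- try(chol(M), silent = TRUE)
  if (inherits(ok, "try-error"))
    ok <- chol(M + diag(ridge * mean(diag(M)), nrow(M)))
  t(ok)
}

#' Simulate phenotypes on a pedigree
#'
#' Draws breeding values as a zero-mean Gaussian with covariance G x A
#' (Kronecker, via Cholesky factors), one week effect per week-of-year
#' class with per-trait SD \code{tau * sigma_p}, and residuals with
#' covariance R, then assembles y = mu + week + a + e.  Week classes are
#' assigned to queens within their year, as evenly as possible, in
#' seed-determined random order.  If the model derives a volume trait,
#' replicate diameter measurements with noise SD \code{measurement_sd}
#' are averaged per queen and cubed through the sphere formula; the
#' reported diameter is the replicate mean.
#'
#' @param ped a \code{\link{bee_pedigree}} from
#'   \code{\link{generate_pedigree}} (or any pedigree with a \code{role}
#'   column marking phenotyped queens)
#' @param A a \code{\link{bee_amatrix}} covering the phenotyped queens
#' @param model a \code{\link{trait_model}}
#' @param design the \code{\link{breeding_design}} (for week classes)
#' @param seed integer seed
#' @return a data.frame of class \code{bee_phenotypes}: one row per
#'   queen with \code{queen_id}, \code{year}, \code{week} and one column
#'   per trait (NA = missing).  The generating breeding values are kept
#'   in \code{attr(, "breeding_values")} for simulation diagnostics.
#' @export
simulate_phenotypes <- function(ped, A, model, design, seed = 1L) {
  stopifnot(inherits(ped, "bee_pedigree"), inherits(A, "bee_amatrix"),
            inherits(model, "trait_model"),
            inherits(design, "breeding_design"))
  set.seed(as.integer(seed))
  ids <- phenotyped_ids(ped)
  n <- length(ids)
  if (!all(ids %in% A$ids))
    stop("phenotype_error: relationship matrix does not cover all ",
         "phenotyped queens", call. = FALSE)
  Asub <- phenotyped_submatrix(A, ids)
  yr <- ped$queens$year[match(ids, ped$queens$id)]
  if (all(is.na(yr))) yr <- rep(design$years[1L], n)

  # week classes: balanced within year, order randomized
  week <- character(n)
  for (yi in seq_along(design$years)) {
    sel <- which(yr == design$years[yi])
    if (!length(sel)) next
    wk <- sprintf("%s_w%02d", design$years[yi],
                  seq_len(design$weeks_per_year[yi]))
    week[sel] <- sample(rep_len(wk, length(sel)))
  }

  k <- length(model$trait_names)
  sig_p <- sqrt(diag(model$G) + diag(model$R))

  La <- safe_chol_lower(Asub$A)
  a_vals <- if (all(model$G == 0)) matrix(0, n, k) else {
    Lg <- safe_chol_lower(model$G)
    La %*% matrix(stats::rnorm(n * k), n, k) %*% t(Lg)
  }
  e_vals <- if (all(model$R == 0)) matrix(0, n, k) else {
    Lr <- safe_chol_lower(model$R)
    matrix(stats::rnorm(n * k), n, k) %*% t(Lr)
  }
  wk_levels <- unique(week)
  w_vals <- matrix(stats::rnorm(length(wk_levels) * k), length(wk_levels), k,
                   dimnames = list(wk_levels, NULL))
  w_vals <- sweep(w_vals, 2L, model$week_effect_sd * sig_p, "*")

  Y <- matrix(rep(model$means, each = n), n, k) + a_vals + e_vals +
       w_vals[week, , drop = FALSE]
  colnames(Y) <- model$trait_names
  out <- data.frame(queen_id = ids, year = yr, week = week,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(Y))

  if (model$derive_volume) {
    dtrue <- Y[, model$diameter_trait]
    reps <- matrix(dtrue, n, model$measurement_reps) +
      matrix(stats::rnorm(n * model$measurement_reps,
                          sd = model$measurement_sd),
             n, model$measurement_reps)
    reps[reps <= 0] <- .Machine$double.eps  # degenerate draws guarded
    sphere <- derive_spermatheca_volume(reps)
    out[[model$diameter_trait]] <- sphere$mean_diameter
    out[[model$volume_trait]] <- sphere$volume
    # keep sv next to sd, matching the reporting order
    tr <- colnames(out)[-(1:3)]
    tr <- append(setdiff(tr, model$volume_trait), model$volume_trait,
                 after = match(model$diameter_trait,
                               setdiff(tr, model$volume_trait)))
    out <- out[, c(colnames(out)[1:3], tr)]
  }

  if (!is.null(model$missing_rates)) {
    for (tr in names(model$missing_rates)) {
      r <- model$missing_rates[[tr]]
      if (r < 0 || r > 1)
        stop("phenotype_error: missing rate outside [0, 1]", call. = FALSE)
      if (tr %in% colnames(out) && r > 0)
        out[[tr]][stats::runif(n) < r] <- NA_real_
    }
  }

  rownames(a_vals) <- ids
  colnames(a_vals) <- model$trait_names
  attr(out, "breeding_values") <- a_vals
  attr(out, "week_levels") <- wk_levels
  class(out) <- c("bee_phenotypes", "data.frame")
  out
}

#' Add Bernoulli defect flags to a phenotype table
#'
#' Internal defects observed at dissection (e.g. abnormal intestinal
#' tract, ovary melanosis, enteroliths, ovary atrophy) are modelled as
#' independent per-queen Bernoulli events; no causal link to the
#' quantitative traits is simulated.
#'
#' @param table a \code{bee_phenotypes} data.frame
#' @param rates named vector of per-defect probabilities in [0, 1]
#' @param seed integer seed
#' @return the table with added logical columns \code{defect_<name>}
#' @export
inject_defect_flags <- function(table, rates, seed = 1L) {
  if (any(rates < 0 | rates > 1))
    stop("defect_rate_error: rates must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(table)
  for (nm in names(rates))
    table[[paste0("defect_", nm)]] <- stats::runif(n) < rates[[nm]]
  table
}

#' Default defect rates of the study population
#'
#' Observed prevalences: abnormal intestinal tract 16%, ovary melanosis
#' 9%, enteroliths 8%, ovary atrophy 2.7%, spermatheca anomalies under 1%.
#' @return named numeric vector of probabilities
#' @export
default_defect_rates <- function() {
  c(intestinal = 0.16, melanosis = 0.09, enteroliths = 0.08,
    ovary_atrophy = 0.027, spermatheca = 0.005)
}

#' Write / read a phenotype table as CSV
#' @param pheno a \code{bee_phenotypes} data.frame
#' @param file path
#' @return invisibly, the path
#' @export
write_phenotypes <- function(pheno, file) {
  utils::write.csv(as.data.frame(pheno), file, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "NA")
  out$queen_id <- as.character(out$queen_id)
  out$week <- as.character(out$week)
  class(out) <- c("bee_phenotypes", "data.frame")
  out
}
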