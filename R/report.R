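#' Descriptive statistics per trait
#'
#' Per-trait N, mean, sample SD (n - 1) and coefficient of variation
#' CV% = 100 * SD / mean, missing values excluded per trait.  CV% is
#' additionally reported rounded to 1 decimal (\code{cv_pct_1d}), the
#' precision used in descriptive tables; raw values are kept alongside.
#'
#' @param pheno a phenotype table (data.frame with \code{queen_id} and
#'   numeric trait columns; \code{year}/\code{week}/defect columns are
#'   ignored)
#' @param units optional named character vector of trait units
#' @return data.frame with trait, unit, n, mean, sd, cv_pct, cv_pct_1d
#' @export
summarize_phenotypes <- function(pheno, units = NULL) {
  if (nrow(pheno) == 0L) stop("report_error: empty phenotype table",
                              call. = FALSE)
  skip <- c("queen_id", "year", "week")
  traits <- setdiff(names(pheno), skip)
  traits <- traits[!startsWith(traits, "defect_")]
  traits <- traits[vapply(pheno[traits], is.numeric, TRUE)]
  rows <- lapply(traits, function(tr) {
    x <- pheno[[tr]][!is.na(pheno[[tr]])]
    if (!length(x))
      return(data.frame(trait = tr, unit = NA_character_, n = 0L,
                        mean = NA_real_, sd = NA_real_, cv_pct = NA_real_,
                        cv_pct_1d = NA_real_, stringsAsFactors = FALSE))
    m <- mean(x); s <- stats::sd(x)
    cv <- if (m == 0) NA_real_ else 100 * s / abs(m)
    data.frame(trait = tr,
               unit = if (!is.null(units) && tr %in% names(units))
                 units[[tr]] else NA_character_,
               n = length(x), mean = m, sd = s, cv_pct = cv,
               cv_pct_1d = round(cv, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coefficient of variation from a reported mean and SD
#'
#' CV% = 100 * SD / mean, rounded to 1 decimal as in descriptive tables.
#' @param mean,sd reported mean and standard deviation
#' @return CV in percent, 1-decimal rounding
#' @export
cv_percent <- function(mean, sd) round(100 * sd / mean, 1)

#' Defect prevalence
#'
#' Percentage of flagged queens per defect class (columns named
#' \code{defect_*}), rounded to 1 decimal.
#'
#' @param pheno phenotype table with defect flag columns
#' @return named numeric vector of percentages
#' @export
defect_prevalence <- function(pheno) {
  cols <- grep("^defect_", names(pheno), value = TRUE)
  if (!length(cols))
    stop("report_error: no defect flag columns", call. = FALSE)
  out <- vapply(cols, function(cl) {
    x <- pheno[[cl]]
    round(100 * sum(x, na.rm = TRUE) / sum(!is.na(x)), 1)
  }, 0)
  names(out) <- sub("^defect_", "", cols)
  out
}

#' Assemble the genetic-parameter matrix from fits
#'
#' A k x k triangular summary: heritabilities (with SEs) on the
#' diagonal from the univariate fits, genetic correlations above and
#' phenotypic correlations below the diagonal from the bivariate fits,
#' with per-cell convergence/boundary flags.
#'
#' @param uni_fits named list of univariate \code{bee_fit}s (one per trait)
#' @param bi_fits list of bivariate \code{bee_fit}s (or NULL entries for
#'   failed fits), any order; traits are read from each fit
#' @param traits trait order for the matrix
#' @return a \code{parameter_matrix}: list of matrices \code{estimate},
#'   \code{se}, \code{flag} (character), plus \code{traits}
#' @export
parameter_matrix <- function(uni_fits, bi_fits, traits) {
  k <- length(traits)
  est <- se <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  flag <- matrix("", k, k, dimnames = list(traits, traits))
  for (tr in traits) {
    f <- uni_fits[[tr]]
    if (is.null(f)) { flag[tr, tr] <- "failed"; next }
    h <- heritability(f)
    est[tr, tr] <- h$h2; se[tr, tr] <- h$se
    flag[tr, tr] <- paste0(if (!f$converged) "nonconverged;" else "",
                           if (f$boundary) "boundary;" else "")
  }
  for (f in bi_fits) {
    if (is.null(f)) next
    t1 <- f$traits[1L]; t2 <- f$traits[2L]
    if (!(t1 %in% traits) || !(t2 %in% traits)) next
    co <- correlations(f)
    i <- match(t1, traits); j <- match(t2, traits)
    up <- c(min(i, j), max(i, j)); lo <- rev(up)
    est[up[1L], up[2L]] <- co$r_g; se[up[1L], up[2L]] <- co$se_g
    est[lo[1L], lo[2L]] <- co$r_p; se[lo[1L], lo[2L]] <- co$se_p
    fl <- paste0(if (!f$converged) "nonconverged;" else "",
                 if (f$boundary) "boundary;" else "",
                 if (co$clamped) "clamped;" else "",
                 if (!is.na(co$reason)) "rg_undefined;" else "")
    flag[up[1L], up[2L]] <- fl
    flag[lo[1L], lo[2L]] <- fl
  }
  structure(list(traits = traits, estimate = est, se = se, flag = flag),
            class = "parameter_matrix")
}

#' Write / read a parameter matrix
#'
#' JSON keeps full precision and round-trips exactly; the CSV companion
#' is a human-readable display with 2-decimal estimates and SEs in
#' brackets, diagonal h2, genetic correlations above and phenotypic
#' correlations below the diagonal.
#'
#' @param pm a \code{parameter_matrix}
#' @param json_file,csv_file output paths (either may be NULL)
#' @return invisibly, the JSON path
#' @export
write_parameter_matrix <- function(pm, json_file = NULL, csv_file = NULL) {
  stopifnot(inherits(pm, "parameter_matrix"))
  if (!is.null(json_file)) {
    payload <- list(traits = pm$traits,
                    estimate = pm$estimate, se = pm$se, flag = pm$flag)
    jsonlite::write_json(payload, json_file, digits = NA, na = "null",
                         matrix = "rowmajor", pretty = TRUE)
  }
  if (!is.null(csv_file)) {
    disp <- matrix("", length(pm$traits), length(pm$traits),
                   dimnames = dimnames(pm$estimate))
    for (i in seq_along(pm$traits)) for (j in seq_along(pm$traits)) {
      e <- pm$estimate[i, j]
      disp[i, j] <- if (is.na(e)) "NA" else
        sprintf("%.2f (%.2f)", e, pm$se[i, j])
    }
    utils::write.csv(data.frame(trait = pm$traits, disp,
                                check.names = FALSE),
                     csv_file, row.names = FALSE)
  }
  invisible(json_file)
}

#' @rdname write_parameter_matrix
#' @export
read_parameter_matrix <- function(json_file) {
  p <- jsonlite::read_json(json_file, simplifyVector = TRUE)
  traits <- p$traits
  shape <- function(M, mode = "double") {
    M <- matrix(unlist(ifelse(vapply(as.list(t(M)), is.null, TRUE),
                              NA, as.list(t(M)))),
                length(traits), length(traits), byrow = TRUE)
    storage.mode(M) <- mode
    dimnames(M) <- list(traits, traits)
    M
  }
  est <- p$estimate; se <- p$se; fl <- p$flag
  if (!is.matrix(est)) est <- shape(est)
  if (!is.matrix(se)) se <- shape(se)
  if (!is.matrix(fl)) fl <- shape(fl, "character")
  dimnames(est) <- dimnames(se) <- dimnames(fl) <- list(traits, traits)
  structure(list(traits = traits, estimate = est, se = se, flag = fl),
            class = "parameter_matrix")
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Generates the pedigree and phenotypes, computes the relationship
#' matrix, produces descriptives and defect prevalences, fits one
#' univariate model per trait and one bivariate model per trait pair,
#' and assembles the triangular parameter matrix.  Any fit failure is
#' recorded per cell and the run continues.  Outputs (when
#' \code{out_dir} is given): \code{table1.csv}, \code{table2_matrix.csv},
#' \code{table2_matrix.json}, \code{run_log.csv}.
#'
#' @param design a \code{\link{breeding_design}}
#' @param model a \code{\link{trait_model}}
#' @param seed integer seed for every stochastic step
#' @param traits traits to analyse (default: all trait columns)
#' @param defect_rates named defect probabilities (NULL = none)
#' @param out_dir output directory (NULL = no files written)
#' @return list with \code{pedigree}, \code{A}, \code{phenotypes},
#'   \code{descriptives}, \code{defects}, \code{uni_fits},
#'   \code{bi_fits}, \code{matrix} (a \code{parameter_matrix}),
#'   \code{log} (per-fit status data.frame)
#' @export
run_full_analysis <- function(design = breeding_design(),
                              model = default_trait_model(),
                              seed = 1L, traits = NULL,
                              defect_rates = default_defect_rates(),
                              out_dir = NULL) {
  ped <- generate_pedigree(design, seed = seed)
  A <- compute_kinship(ped)
  pheno <- simulate_phenotypes(ped, A, model, design, seed = seed + 1L)
  if (!is.null(defect_rates))
    pheno <- inject_defect_flags(pheno, defect_rates, seed = seed + 2L)

  if (is.null(traits)) {
    traits <- setdiff(names(pheno), c("queen_id", "year", "week"))
    traits <- traits[!startsWith(traits, "defect_")]
  }
  desc <- summarize_phenotypes(pheno, units = model$units)
  defects <- if (any(startsWith(names(pheno), "defect_")))
    defect_prevalence(pheno) else NULL

  log <- list()
  note <- function(stage, item, status)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, item = item,
                                           status = status,
                                           stringsAsFactors = FALSE)
  uni <- stats::setNames(vector("list", length(traits)), traits)
  for (tr in traits) {
    uni[[tr]] <- tryCatch({
      f <- suppressWarnings(fit_univariate(pheno, A, tr))
      note("univariate", tr,
           if (f$converged) "converged" else "nonconverged")
      f
    }, error = function(e) {
      note("univariate", tr, paste0("error: ", conditionMessage(e)))
      NULL
    })
  }
  pairs <- utils::combn(traits, 2L, simplify = FALSE)
  bi <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    bi[[i]] <- tryCatch({
      f <- suppressWarnings(fit_bivariate(pheno, A, pr))
      note("bivariate", paste(pr, collapse = ":"),
           if (f$converged) "converged" else "nonconverged")
      f
    }, error = function(e) {
      note("bivariate", paste(pr, collapse = ":"),
           paste0("error: ", conditionMessage(e)))
      NULL
    })
  }
  pm <- parameter_matrix(uni, bi, traits)
  log <- do.call(rbind, log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(desc, file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
    write_parameter_matrix(pm,
                           json_file = file.path(out_dir,
                                                 "table2_matrix.json"),
                           csv_file = file.path(out_dir,
                                                "table2_matrix.csv"))
    utils::write.csv(log, file.path(out_dir, "run_log.csv"),
                     row.names = FALSE)
  }
  list(pedigree = ped, A = A, phenotypes = pheno, descriptives = desc,
       defects = defects, uni_fits = uni, bi_fits = bi, matrix = pm,
       log = log)
}
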