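#' Numerator relationship matrix under haplodiploid inheritance
#'
#' Computes kinship coefficients over all queens of a pedigree by a dense
#' tabular recursion adapted to honeybee matings, where the paternal
#' parent is a group of D drones drawn from m drone-producing queens
#' (DPQs), and returns the numerator relationship matrix A = 2 * kinship
#' with diagonal 1 + F.
#'
#' The recursion, with phi the kinship and S the sire group of queen i
#' (dam d, group mothers M_1..M_m, D drones):
#' \itemize{
#'   \item phi(i,i) = (1 + F_i) / 2 with F_i = phi(d, S);
#'   \item phi(S, j) = mean_k phi(M_k, j) for any non-descendant j;
#'   \item phi(i, j) = [phi(d, j) + phi(S, j)] / 2 for a non-descendant j;
#'   \item two queens sharing the same sire group additionally share the
#'     whole paternal genome when their paternal drones coincide
#'     (probability 1/D, a drone being haploid): the paternal co-kinship is
#'     1/D + (1 - 1/D) * phi_pp(S), where phi_pp(S) = mean_{k,l}
#'     psi(M_k, M_l) with psi(M, M) = (1 + F_M)/2 and psi = phi off the
#'     diagonal.  Distinct sire groups never share a drone (a drone mates
#'     once), so across groups only phi_pp applies, which the plain
#'     recursion already yields through the shared DPQ mothers.
#' }
#' Unknown parents are treated as unrelated, non-inbred founders.
#'
#' @param ped a \code{\link{bee_pedigree}}
#' @return An object of class \code{bee_amatrix}: list with \code{ids}
#'   (queen ids, pedigree order), \code{A} (dense symmetric matrix with
#'   dimnames) and \code{f} (named inbreeding coefficients, diag(A) - 1).
#' @export
compute_kinship <- function(ped) {
  stopifnot(inherits(ped, "bee_pedigree"))
  q <- ped$queens
  n <- nrow(q)
  ids <- q$id
  idx <- seq_len(n); names(idx) <- ids
  dam <- ifelse(is.na(q$dam_id), NA_integer_, idx[q$dam_id])
  grp <- q$sire_group_id
  dpq_idx <- lapply(ped$dpq, function(m) unname(idx[m]))
  D <- ped$groups$n_drones; names(D) <- ped$groups$group_id

  phi <- matrix(0, n, n)
  # phi_pp per group: computable once all its DPQ mothers are processed;
  # filled lazily.  phi_pp(S) = mean over ordered mother pairs of
  # psi(M_k, M_l), psi diagonal = (1+F)/2 = phi(M,M).
  phi_pp <- rep(NA_real_, length(dpq_idx)); names(phi_pp) <- names(dpq_idx)

  for (i in seq_len(n)) {
    if (is.na(dam[i])) { # founder: unrelated, non-inbred
      phi[i, i] <- 0.5
      next
    }
    d <- dam[i]
    g <- grp[i]
    mo <- dpq_idx[[g]]
    prev <- seq_len(i - 1L)
    # phi(S, j) over all previously processed j (mothers precede i)
    phi_S <- if (length(mo) == 1L) phi[mo, prev]
             else colMeans(phi[mo, prev, drop = FALSE])
    row <- 0.5 * (phi[d, prev] + phi_S)
    # same-drone correction for older queens sharing this sire group
    same <- prev[!is.na(grp[prev]) & grp[prev] == g]
    if (length(same)) {
      if (is.na(phi_pp[g])) phi_pp[g] <- group_cokinship(phi, mo)
      row[same] <- row[same] + 0.25 * (1 / D[g]) * (1 - phi_pp[g])
    }
    phi[i, prev] <- row
    phi[prev, i] <- row
    f_i <- if (length(mo) == 1L) phi[d, mo] else mean(phi[d, mo])
    phi[i, i] <- 0.5 * (1 + f_i)
  }

  A <- 2 * phi
  dimnames(A) <- list(ids, ids)
  f <- diag(A) - 1
  structure(list(ids = ids, A = A, f = f), class = "bee_amatrix")
}

# mean over ordered DPQ-mother pairs of the paternal-gamete co-kinship;
# the diagonal phi(M,M) = (1+F_M)/2 is exactly the kinship table entry.
group_cokinship <- function(phi, mo) {
  mean(phi[mo, mo])
}

#' @export
print.bee_amatrix <- function(x, ...) {
  cat("bee_amatrix:", length(x$ids), "queens; mean F =",
      format(mean(x$f), digits = 3), "\n")
  invisible(x)
}

#' @export
as.matrix.bee_amatrix <- function(x, ...) x$A

#' Principal submatrix of a relationship matrix
#'
#' @param A a \code{bee_amatrix}
#' @param ids queen ids to keep, in the requested order
#' @return a \code{bee_amatrix} over \code{ids}
#' @export
phenotyped_submatrix <- function(A, ids) {
  stopifnot(inherits(A, "bee_amatrix"))
  ids <- as.character(ids)
  missing <- setdiff(ids, A$ids)
  if (length(missing))
    stop("unknown_id_error: not in relationship matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(ids = ids, A = A$A[ids, ids, drop = FALSE], f = A$f[ids]),
            class = "bee_amatrix")
}

#' Gene-dropping Monte-Carlo estimate of the relationship matrix
#'
#' Simulates Mendelian transmission through the pedigree: each founder
#' queen carries two unique alleles; a queen offspring receives one random
#' allele from her dam and the single allele of one drone sampled
#' uniformly from her sire group; each of a group's D drones carries one
#' random allele of a DPQ mother drawn uniformly from the group's mothers.
#' Drones are instantiated once per replicate and shared by all offspring
#' of the group, so super-sisters (same paternal drone) arise with
#' probability 1/D.  Kinship is estimated as the probability that two
#' alleles, one drawn at random from each queen, are identical by descent.
#'
#' This is the package's independent validation oracle for
#' \code{\link{compute_kinship}}; the two agree within Monte-Carlo error.
#'
#' @param ped a \code{\link{bee_pedigree}}
#' @param n_reps number of Monte-Carlo replicates (>= 1)
#' @param seed integer seed
#' @return a \code{bee_amatrix} with the Monte-Carlo estimate of A
#' @export
gene_dropping <- function(ped, n_reps = 1e5, seed = 1L) {
  stopifnot(inherits(ped, "bee_pedigree"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  n_reps <- as.integer(n_reps)
  set.seed(as.integer(seed))
  q <- ped$queens
  n <- nrow(q)
  idx <- seq_len(n); names(idx) <- q$id
  dam <- ifelse(is.na(q$dam_id), NA_integer_, idx[q$dam_id])
  grp <- q$sire_group_id

  # allele matrices: n_reps x n, maternal and paternal copy per queen
  am <- matrix(0L, n_reps, n)
  ap <- matrix(0L, n_reps, n)
  # per-group drone alleles instantiated on first use: n_reps x D
  drone_alleles <- new.env(parent = emptyenv())
  next_allele <- 1L

  pick <- function(mcol, pcol) { # one random allele per replicate
    u <- stats::runif(n_reps) < 0.5
    ifelse(u, mcol, pcol)
  }

  for (i in seq_len(n)) {
    if (is.na(dam[i])) {
      am[, i] <- next_allele
      ap[, i] <- next_allele + 1L
      next_allele <- next_allele + 2L
      next
    }
    am[, i] <- pick(am[, dam[i]], ap[, dam[i]])
    g <- grp[i]
    if (is.null(drone_alleles[[g]])) {
      mo <- idx[ped$dpq[[g]]]
      D <- ped$groups$n_drones[match(g, ped$groups$group_id)]
      dr <- matrix(0L, n_reps, D)
      for (k in seq_len(D)) {
        mk <- if (length(mo) == 1L) rep(mo, n_reps)
              else mo[sample.int(length(mo), n_reps, replace = TRUE)]
        maternal <- am[cbind(seq_len(n_reps), mk)]
        paternal <- ap[cbind(seq_len(n_reps), mk)]
        dr[, k] <- pick(maternal, paternal)
      }
      drone_alleles[[g]] <- dr
    }
    dr <- drone_alleles[[g]]
    j <- sample.int(ncol(dr), n_reps, replace = TRUE)
    ap[, i] <- dr[cbind(seq_len(n_reps), j)]
  }

  # kinship(i,j) per replicate = mean of the 4 allele IBD indicators
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- (am[, i] == am[, j]) + (am[, i] == ap[, j]) +
           (ap[, i] == am[, j]) + (ap[, i] == ap[, j])
      A[i, j] <- A[j, i] <- 2 * mean(s) / 4
    }
  }
  dimnames(A) <- list(q$id, q$id)
  structure(list(ids = q$id, A = A, f = diag(A) - 1), class = "bee_amatrix")
}

#' Write / read a relationship matrix as CSV
#'
#' Square layout: id header row and column.  \code{long = TRUE} writes the
#' long format (i, j, a_ij) of the upper triangle including the diagonal.
#'
#' @param A a \code{bee_amatrix}
#' @param file output path
#' @param long write long format instead of square
#' @return invisibly, the path
#' @export
write_amatrix <- function(A, file, long = FALSE) {
  stopifnot(inherits(A, "bee_amatrix"))
  if (long) {
    ut <- which(upper.tri(A$A, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(i = A$ids[ut[, 1]], j = A$ids[ut[, 2]],
                     a_ij = A$A[ut])
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(id = A$ids, A$A, check.names = FALSE)
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname write_amatrix
#' @export
read_amatrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$id)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- ids
  storage.mode(A) <- "double"
  structure(list(ids = ids, A = A, f = diag(A) - 1), class = "bee_amatrix")
}
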