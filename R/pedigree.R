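#' Construct a honeybee pedigree with drone-group pseudo-sires
#'
#' A honeybee pedigree links each queen to a dam (another queen) and to a
#' sire group: the set of drones she mated with at the mating station,
#' treated as a single paternal entity.  Drones are haploid; each is a
#' single gamete of a drone-producing queen (DPQ), so paternal
#' relationships flow through the DPQ mothers of the group.
#'
#' Queens with both parents unknown are founders, assumed unrelated and
#' non-inbred.  A queen may not have exactly one known parent: either both
#' dam and sire group are recorded, or neither.
#'
#' @param queens data.frame with columns \code{id}, \code{dam_id},
#'   \code{sire_group_id} (\code{NA} or \code{""} = unknown) and optionally
#'   \code{year}.
#' @param sire_groups data.frame with columns \code{group_id},
#'   \code{dpq_ids} (semicolon-separated queen ids), \code{n_drones}
#'   (positive integer, the number of drones D the queen mated with) and
#'   \code{pool_id} (station-year drone pool label).
#' @return An object of class \code{bee_pedigree}: a list with elements
#'   \code{queens} (topologically sorted data.frame), \code{groups}
#'   (data.frame) and \code{dpq} (named list of DPQ id vectors per group).
#' @export
bee_pedigree <- function(queens, sire_groups = NULL) {
  queens <- as.data.frame(queens, stringsAsFactors = FALSE)
  need <- c("id", "dam_id", "sire_group_id")
  if (!all(need %in% names(queens)))
    stop("pedigree_format_error: queen table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (nm in need) {
    queens[[nm]] <- as.character(queens[[nm]])
    queens[[nm]][!is.na(queens[[nm]]) & queens[[nm]] == ""] <- NA_character_
  }
  if (anyNA(queens$id)) stop("pedigree_format_error: missing queen id", call. = FALSE)
  if (anyDuplicated(queens$id))
    stop("duplicate_id_error: duplicated queen id(s): ",
         paste(unique(queens$id[duplicated(queens$id)]), collapse = ", "),
         call. = FALSE)

  if (is.null(sire_groups) || nrow(as.data.frame(sire_groups)) == 0L) {
    groups <- data.frame(group_id = character(), n_drones = integer(),
                         pool_id = character(), stringsAsFactors = FALSE)
    dpq <- list()
  } else {
    groups <- as.data.frame(sire_groups, stringsAsFactors = FALSE)
    gneed <- c("group_id", "dpq_ids", "n_drones")
    if (!all(gneed %in% names(groups)))
      stop("pedigree_format_error: sire-group table needs columns ",
           paste(gneed, collapse = ", "), call. = FALSE)
    groups$group_id <- as.character(groups$group_id)
    if (anyDuplicated(groups$group_id))
      stop("duplicate_id_error: duplicated sire-group id(s)", call. = FALSE)
    if (is.null(groups$pool_id)) groups$pool_id <- groups$group_id
    groups$pool_id <- as.character(groups$pool_id)
    groups$n_drones <- as.integer(groups$n_drones)
    if (any(is.na(groups$n_drones) | groups$n_drones < 1L))
      stop("pedigree_format_error: n_drones must be a positive integer",
           call. = FALSE)
    dpq <- strsplit(as.character(groups$dpq_ids), ";", fixed = TRUE)
    dpq <- lapply(dpq, function(x) trimws(x[nzchar(trimws(x))]))
    names(dpq) <- groups$group_id
    if (any(lengths(dpq) == 0L))
      stop("pedigree_format_error: sire group with no DPQ mothers", call. = FALSE)
    if (any(vapply(dpq, anyDuplicated, 0L) > 0L))
      stop("pedigree_format_error: duplicated DPQ id within a sire group",
           call. = FALSE)
    groups$dpq_ids <- NULL
  }

  half <- xor(is.na(queens$dam_id), is.na(queens$sire_group_id))
  if (any(half))
    stop("partial_parentage_error: queen(s) with exactly one known parent: ",
         paste(queens$id[half], collapse = ", "), call. = FALSE)
  if (any(!is.na(queens$dam_id) & queens$dam_id == queens$id))
    stop("cycle_error: queen listed as her own dam", call. = FALSE)

  known_dam <- !is.na(queens$dam_id)
  if (!all(queens$dam_id[known_dam] %in% queens$id))
    stop("dangling_reference_error: unknown dam id(s): ",
         paste(setdiff(queens$dam_id[known_dam], queens$id), collapse = ", "),
         call. = FALSE)
  known_grp <- !is.na(queens$sire_group_id)
  if (!all(queens$sire_group_id[known_grp] %in% groups$group_id))
    stop("dangling_reference_error: unknown sire-group id(s): ",
         paste(setdiff(queens$sire_group_id[known_grp], groups$group_id),
               collapse = ", "), call. = FALSE)
  all_dpq <- unique(unlist(dpq, use.names = FALSE))
  if (!all(all_dpq %in% queens$id))
    stop("dangling_reference_error: DPQ id(s) not in queen table: ",
         paste(setdiff(all_dpq, queens$id), collapse = ", "), call. = FALSE)

  # one sire group = one mating: a drone mates once, so all offspring of
  # a group share the same dam.  Reusing a group id across dams would
  # imply drones mating repeatedly, which the kinship recursion (and the
  # biology) excludes.
  by_grp <- split(queens$dam_id[known_grp], queens$sire_group_id[known_grp])
  reused <- names(by_grp)[vapply(by_grp, function(d) length(unique(d)) > 1L,
                                 TRUE)]
  if (length(reused))
    stop("mating_reuse_error: sire group(s) used by more than one dam: ",
         paste(reused, collapse = ", "), call. = FALSE)

  queens <- topo_sort_queens(queens, dpq)
  structure(list(queens = queens, groups = groups, dpq = dpq),
            class = "bee_pedigree")
}

# Kahn topological sort; parents of a queen are her dam and every DPQ
# mother of her sire group.  Raises cycle_error if no valid order exists.
topo_sort_queens <- function(queens, dpq) {
  n <- nrow(queens)
  idx <- seq_len(n)
  names(idx) <- queens$id
  parents <- vector("list", n)
  for (i in idx) {
    if (is.na(queens$dam_id[i])) next
    p <- c(queens$dam_id[i], dpq[[queens$sire_group_id[i]]])
    parents[[i]] <- unname(idx[unique(p)])
  }
  indeg <- lengths(parents)
  children <- vector("list", n)
  for (i in idx) for (p in parents[[i]])
    children[[p]] <- c(children[[p]], i)
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < n)
    stop("cycle_error: pedigree contains a cycle through ",
         paste(queens$id[setdiff(idx, order)], collapse = ", "), call. = FALSE)
  queens[order, , drop = FALSE]
}

#' Load a pedigree from CSV files
#'
#' @param pedigree_file CSV with header \code{id,dam_id,sire_group_id}
#'   (empty field = unknown parent); an optional \code{year} column is kept.
#' @param sire_group_file CSV with header
#'   \code{group_id,dpq_ids,n_drones,pool_id}; \code{dpq_ids} is a
#'   semicolon-separated list of queen ids.
#' @return A validated, topologically sorted \code{\link{bee_pedigree}}.
#' @export
load_pedigree <- function(pedigree_file, sire_group_file = NULL) {
  if (!file.exists(pedigree_file))
    stop("pedigree_format_error: file not found: ", pedigree_file, call. = FALSE)
  queens <- utils::read.csv(pedigree_file, stringsAsFactors = FALSE,
                            colClasses = "character")
  groups <- NULL
  if (!is.null(sire_group_file)) {
    if (!file.exists(sire_group_file))
      stop("pedigree_format_error: file not found: ", sire_group_file,
           call. = FALSE)
    groups <- utils::read.csv(sire_group_file, stringsAsFactors = FALSE,
                              colClasses = "character")
  }
  bee_pedigree(queens, groups)
}

#' Write a pedigree to CSV files
#'
#' @param ped a \code{bee_pedigree}
#' @param pedigree_file,sire_group_file output paths
#' @return invisibly, the two paths
#' @export
write_pedigree <- function(ped, pedigree_file, sire_group_file) {
  stopifnot(inherits(ped, "bee_pedigree"))
  q <- ped$queens
  q$dam_id[is.na(q$dam_id)] <- ""
  q$sire_group_id[is.na(q$sire_group_id)] <- ""
  utils::write.csv(q, pedigree_file, row.names = FALSE, quote = FALSE)
  g <- ped$groups
  g$dpq_ids <- vapply(ped$dpq[g$group_id], paste, "", collapse = ";")
  g <- g[, c("group_id", "dpq_ids", "n_drones", "pool_id")]
  utils::write.csv(g, sire_group_file, row.names = FALSE, quote = FALSE)
  invisible(c(pedigree_file, sire_group_file))
}

#' @export
print.bee_pedigree <- function(x, ...) {
  nf <- sum(is.na(x$queens$dam_id))
  cat("bee_pedigree:", nrow(x$queens), "queens (", nf, "founders ),",
      nrow(x$groups), "sire groups\n")
  invisible(x)
}

#' Queen ids of a pedigree, in topological order
#' @param ped a \code{bee_pedigree}
#' @return character vector of queen ids
#' @export
queen_ids <- function(ped) {
  stopifnot(inherits(ped, "bee_pedigree"))
  ped$queens$id
}
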