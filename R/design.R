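#' Breeding-design parameters for the synthetic queen population
#'
#' Describes a multi-year queen-breeding design: maternal sister lines
#' reared per year, week-of-year harvest classes, and isolated-station
#' matings in which every dam mates with \code{drones_per_mating} drones
#' drawn from that year's drone-producing queens (DPQs).
#'
#' Defaults emulate a two-season commercial breeding population: 147
#' phenotyped queens (70 + 77) from 10 + 7 maternal lines, 6 + 9 weekly
#' harvest classes, 12 DPQ colonies per year and 12 drones per mating,
#' with maternal lines sharing common ancestors one generation back.
#'
#' @param years year labels
#' @param lines_per_year number of maternal lines per year
#' @param queens_per_year phenotyped queens per year (split over lines as
#'   evenly as possible, remainder to the first lines)
#' @param weeks_per_year number of weekly harvest classes per year
#' @param dpq_per_year number of drone-producing queens per year (the
#'   station hosts 12--15 drone-producing colonies)
#' @param drones_per_mating drones per mating, D
#' @param shared_ancestor_depth ancestor generations above the line dams;
#'   0 makes line dams unrelated founders, >= 1 groups lines under shared
#'   grand-dams so that maternal lines are related
#' @return a \code{breeding_design} list
#' @export
breeding_design <- function(years = c("2017", "2018"),
                            lines_per_year = c(10L, 7L),
                            queens_per_year = c(70L, 77L),
                            weeks_per_year = c(6L, 9L),
                            dpq_per_year = 12L,
                            drones_per_mating = 12L,
                            shared_ancestor_depth = 1L) {
  ny <- length(years)
  rl <- function(x) as.integer(rep_len(x, ny))
  d <- list(years = as.character(years),
            lines_per_year = rl(lines_per_year),
            queens_per_year = rl(queens_per_year),
            weeks_per_year = rl(weeks_per_year),
            dpq_per_year = rl(dpq_per_year),
            drones_per_mating = as.integer(drones_per_mating),
            shared_ancestor_depth = as.integer(shared_ancestor_depth))
  if (any(unlist(d[2:5]) < 1L) || d$drones_per_mating < 1L)
    stop("design_error: all counts must be positive", call. = FALSE)
  if (d$shared_ancestor_depth < 0L)
    stop("design_error: shared_ancestor_depth must be >= 0", call. = FALSE)
  class(d) <- "breeding_design"
  d
}

#' Generate a pedigree from a breeding design
#'
#' Builds the relationship substrate the analysis assumes: a founder base
#' (DPQs and, when \code{shared_ancestor_depth >= 1}, shared grand-dams),
#' one dam per maternal line descending from the grand-dams, one sire
#' group per dam mating (D drones from the year's DPQ pool) and the
#' phenotyped daughter queens grouped in sister lines.  Lines are
#' assigned to grand-dams round-robin, so roughly every two lines share a
#' grand-dam and all lines are connected through the base drone pools.
#'
#' @param design a \code{\link{breeding_design}}
#' @param seed integer seed (drives dam/week assignment randomization)
#' @return a \code{\link{bee_pedigree}} whose queens carry \code{role}
#'   (\code{founder}, \code{ancestor}, \code{dam}, \code{phenotyped}) and
#'   \code{year} columns
#' @export
generate_pedigree <- function(design, seed = 1L) {
  stopifnot(inherits(design, "breeding_design"))
  set.seed(as.integer(seed))
  ny <- length(design$years)
  total_lines <- sum(design$lines_per_year)
  if (total_lines < 1L) stop("design_error: no maternal lines", call. = FALSE)

  queens <- list()
  groups <- list()
  add_queen <- function(id, dam = NA, grp = NA, role, year = NA)
    queens[[length(queens) + 1L]] <<- data.frame(
      id = id, dam_id = dam, sire_group_id = grp, role = role,
      year = year, stringsAsFactors = FALSE)
  add_group <- function(gid, dpq, D, pool)
    groups[[length(groups) + 1L]] <<- data.frame(
      group_id = gid, dpq_ids = paste(dpq, collapse = ";"),
      n_drones = D, pool_id = pool, stringsAsFactors = FALSE)

  D <- design$drones_per_mating
  depth <- design$shared_ancestor_depth

  # ancestor lineages: one per pair of lines (round-robin assignment)
  n_lineage <- max(1L, ceiling(total_lines / 2))
  if (depth > 0L) {
    # base drone pool serving the ancestor generations
    base_dpq <- sprintf("DPQ0_%02d", seq_len(design$dpq_per_year[1L]))
    for (id in base_dpq) add_queen(id, role = "founder")
    top <- sprintf("ANC%d_%02d", depth, seq_len(n_lineage))
    for (id in top) add_queen(id, role = "founder")
    gen <- top
    for (lev in rev(seq_len(depth))) {
      nxt <- character(n_lineage)
      for (k in seq_len(n_lineage)) {
        gid <- sprintf("G0_%d_%02d", lev, k)
        add_group(gid, base_dpq, D, "pool_base")
        nxt[k] <- if (lev == 1L) sprintf("DAMROOT_%02d", k)
                  else sprintf("ANC%d_%02d", lev - 1L, k)
        add_queen(nxt[k], dam = gen[k], grp = gid, role = "ancestor")
      }
      gen <- nxt
    }
    lineage_dams <- gen
  } else {
    lineage_dams <- character(0)
  }

  line_no <- 0L
  for (yi in seq_len(ny)) {
    yr <- design$years[yi]
    dpq <- sprintf("DPQ%s_%02d", yr, seq_len(design$dpq_per_year[yi]))
    for (id in dpq) add_queen(id, role = "founder", year = yr)
    nl <- design$lines_per_year[yi]
    nq <- design$queens_per_year[yi]
    per_line <- rep(nq %/% nl, nl)
    if (nq %% nl) per_line[seq_len(nq %% nl)] <- per_line[seq_len(nq %% nl)] + 1L
    for (li in seq_len(nl)) {
      line_no <- line_no + 1L
      dam_id <- sprintf("DAM%s_%02d", yr, li)
      if (depth > 0L) {
        root <- lineage_dams[((line_no - 1L) %% n_lineage) + 1L]
        # line dam is a daughter of her lineage root, mated to base pool
        rg <- sprintf("G0_dam_%03d", line_no)
        add_group(rg, sprintf("DPQ0_%02d", seq_len(design$dpq_per_year[1L])),
                  D, "pool_base")
        add_queen(dam_id, dam = root, grp = rg, role = "dam", year = yr)
      } else {
        add_queen(dam_id, role = "dam", year = yr)
      }
      gid <- sprintf("G%s_%02d", yr, li)
      add_group(gid, dpq, D, paste0("pool_", yr))
      for (qi in seq_len(per_line[li]))
        add_queen(sprintf("Q%s_%02d_%02d", yr, li, qi),
                  dam = dam_id, grp = gid, role = "phenotyped", year = yr)
    }
  }
  bee_pedigree(do.call(rbind, queens), do.call(rbind, groups))
}

#' Ids of the phenotyped queens of a generated pedigree
#' @param ped a \code{bee_pedigree} from \code{\link{generate_pedigree}}
#' @return character vector of queen ids
#' @export
phenotyped_ids <- function(ped) {
  stopifnot(inherits(ped, "bee_pedigree"))
  if (is.null(ped$queens$role)) return(ped$queens$id)
  ped$queens$id[ped$queens$role == "phenotyped"]
}
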