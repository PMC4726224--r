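#' Rectangular grid of anatomical substructures
#'
#' Defines the grid of level-5 substructures onto which the brain is
#' flattened: `n_ap` segments along the anterior-posterior axis times `n_dv`
#' layers along the dorsal-ventral axis (20 x 4 = 80 blocks by default).
#' Coordinates are 1-based and inclusive; `ap = 1` is the anterior (forebrain)
#' end and `dv = 1` the roof (dorsal) layer, `dv = n_dv` the floor (ventral).
#'
#' The flattening of the real anatomy onto a rectangle is exact except at two
#' interfaces (between the alar telencephalic vesicle and the prosomere-3
#' roof plate, and between the rhombomere-1 alar plate and the isthmic roof
#' plate), where grid neighbors are not anatomical neighbors. These
#' discrepancy interfaces are severed from the adjacency by default. Their
#' exact column positions on the grid are not determined by the anatomy
#' alone, so the shipped defaults — roof-row interfaces at ap 2|3 and ap 7|8 —
#' are placeholders and should be overridden when a definitive mapping is
#' available.
#'
#' @param n_ap Number of anterior-posterior segments (default 20).
#' @param n_dv Number of dorsal-ventral layers (default 4).
#' @param discrepancies Data frame with columns `ap1, dv1, ap2, dv2`, one row
#'   per severed interface; each row must name a pair of grid-adjacent cells.
#'   `NULL` for none. The default severs the two interfaces described above.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' spec <- grid_spec()
#' n_cells(spec)
grid_spec <- function(n_ap = 20L, n_dv = 4L,
                      discrepancies = default_discrepancies()) {
  n_ap <- as.integer(n_ap)
  n_dv <- as.integer(n_dv)
  stopifnot(length(n_ap) == 1L, length(n_dv) == 1L, n_ap >= 1L, n_dv >= 1L)
  if (is.null(discrepancies)) {
    discrepancies <- data.frame(ap1 = integer(), dv1 = integer(),
                                ap2 = integer(), dv2 = integer())
  }
  discrepancies <- as.data.frame(discrepancies)
  stopifnot(all(c("ap1", "dv1", "ap2", "dv2") %in% names(discrepancies)))
  spec <- structure(list(n_ap = n_ap, n_dv = n_dv,
                         discrepancies = discrepancies,
                         connectivity = "4-neighbor"),
                    class = "grid_spec")
  # every severed pair must actually be a grid edge
  for (i in seq_len(nrow(discrepancies))) {
    d <- discrepancies[i, ]
    .check_coord(d$ap1, d$dv1, spec)
    .check_coord(d$ap2, d$dv2, spec)
    manhattan <- abs(d$ap1 - d$ap2) + abs(d$dv1 - d$dv2)
    if (manhattan != 1L) {
      stop("discrepancy interface ", i, " is not a grid-adjacent cell pair")
    }
  }
  spec
}

#' @rdname grid_spec
#' @export
default_discrepancies <- function() {
  # placeholder grid positions for the TelA|p3R and r1A|isR interfaces
  data.frame(ap1 = c(2L, 7L), dv1 = c(1L, 1L),
             ap2 = c(3L, 8L), dv2 = c(1L, 1L),
             row.names = c("TelA-p3R", "r1A-isR"))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d AP segments x %d DV layers = %d blocks\n",
              x$n_ap, x$n_dv, x$n_ap * x$n_dv))
  cat(sprintf("  connectivity: %s; severed interfaces: %d\n",
              x$connectivity, nrow(x$discrepancies)))
  invisible(x)
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @export
n_cells <- function(spec) spec$n_ap * spec$n_dv

.check_coord <- function(ap, dv, spec) {
  if (any(ap < 1L | ap > spec$n_ap | dv < 1L | dv > spec$n_dv)) {
    stop(sprintf("cell coordinate (ap=%s, dv=%s) outside the %dx%d grid",
                 paste(ap, collapse = ","), paste(dv, collapse = ","),
                 spec$n_ap, spec$n_dv))
  }
  invisible(TRUE)
}

#' Convert between cell coordinates and linear cell indices
#'
#' Cells are indexed linearly in column-major order over an
#' `n_ap x n_dv` matrix: index = `ap + (dv - 1) * n_ap`. All component and
#' pattern containers store cells as these indices.
#'
#' @param ap,dv Integer coordinate vectors (1-based).
#' @param idx Integer vector of linear cell indices.
#' @param spec A `grid_spec`.
#' @return `cell_index()` returns an integer vector; `cell_coords()` a data
#'   frame with columns `ap` and `dv`.
#' @export
cell_index <- function(ap, dv, spec) {
  .check_coord(ap, dv, spec)
  as.integer(ap + (dv - 1L) * spec$n_ap)
}

#' @rdname cell_index
#' @export
cell_coords <- function(idx, spec) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L & idx <= n_cells(spec)))
  data.frame(ap = ((idx - 1L) %% spec$n_ap) + 1L,
             dv = ((idx - 1L) %/% spec$n_ap) + 1L)
}

#' Build the grid adjacency
#'
#' 4-neighborhood (von Neumann) adjacency over the grid, minus the severed
#' discrepancy interfaces. The result is symmetric and irreflexive; every
#' cell is present, with degree at most 4.
#'
#' @param spec A `grid_spec`.
#' @return A list of length `n_cells(spec)`; element `i` is the integer
#'   vector of neighbors of cell `i`. Class `grid_adjacency`, with the spec
#'   attached as attribute `spec`.
#' @export
#' @examples
#' adj <- build_adjacency(grid_spec())
#' length(adj[[cell_index(10, 2, grid_spec())]])  # interior cell: 4
build_adjacency <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  n_ap <- spec$n_ap
  n_dv <- spec$n_dv
  nc <- n_ap * n_dv
  adj <- vector("list", nc)
  for (dv in seq_len(n_dv)) {
    for (ap in seq_len(n_ap)) {
      i <- ap + (dv - 1L) * n_ap
      nb <- integer(0)
      if (ap > 1L)    nb <- c(nb, i - 1L)
      if (ap < n_ap)  nb <- c(nb, i + 1L)
      if (dv > 1L)    nb <- c(nb, i - n_ap)
      if (dv < n_dv)  nb <- c(nb, i + n_ap)
      adj[[i]] <- nb
    }
  }
  d <- spec$discrepancies
  for (k in seq_len(nrow(d))) {
    a <- cell_index(d$ap1[k], d$dv1[k], spec)
    b <- cell_index(d$ap2[k], d$dv2[k], spec)
    adj[[a]] <- setdiff(adj[[a]], b)
    adj[[b]] <- setdiff(adj[[b]], a)
  }
  structure(adj, class = "grid_adjacency", spec = spec)
}

#' @export
print.grid_adjacency <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("grid_adjacency: %d cells, %d edges\n",
              length(x), sum(lengths(x)) %/% 2L))
  invisible(x)
}

#' Export an adjacency as JSON (debugging aid)
#'
#' @param adjacency A `grid_adjacency`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency_json <- function(adjacency, path) {
  spec <- attr(adjacency, "spec")
  obj <- list(n_ap = spec$n_ap, n_dv = spec$n_dv,
              neighbors = lapply(seq_along(adjacency),
                                 function(i) as.integer(adjacency[[i]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Coarse region groups on the grid
#'
#' Named groups of grid cells used for regional statistics: each group is a
#' rectangle given by AP and/or DV coordinate ranges (an omitted axis spans
#' the whole grid), or a set of pattern indices for pattern-membership mode
#' (see [occurrences_by_time()]). The `control` group always covers the whole
#' grid / all patterns.
#'
#' The default coordinate ranges (forebrain ap 1-6, hindbrain ap 9-20, dorsal
#' dv 1-2, ventral dv 3-4) are documented placeholders: the source atlas does
#' not pin the group boundaries to grid columns, so override them for any
#' serious anatomical claim.
#'
#' @param ... Named group definitions, each a list with optional elements
#'   `ap` (integer vector of AP segments), `dv` (integer vector of DV
#'   layers), and/or `patterns` (integer vector of pattern indices). Omitted
#'   to get the defaults.
#' @return An object of class `region_groups` (named list).
#' @export
#' @examples
#' g <- region_groups()
#' length(cells_in_group(g, "dorsal", grid_spec()))  # 40
region_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 0L) {
    groups <- list(
      forebrain = list(ap = 1:6),
      hindbrain = list(ap = 9:20),
      dorsal    = list(dv = 1:2),
      ventral   = list(dv = 3:4),
      control   = list()
    )
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("all region groups must be named")
  }
  if (!"control" %in% names(groups)) {
    groups$control <- list()
  }
  structure(groups, class = "region_groups")
}

#' Cells belonging to a region group
#'
#' @param groups A `region_groups` object.
#' @param group Group name.
#' @param spec A `grid_spec`.
#' @return Integer vector of linear cell indices (sorted). The `control`
#'   group (or any group with no coordinate constraint) returns all cells.
#' @export
cells_in_group <- function(groups, group, spec) {
  stopifnot(inherits(groups, "region_groups"))
  if (!group %in% names(groups)) {
    stop("unknown region group: ", group)
  }
  def <- groups[[group]]
  ap <- if (is.null(def$ap)) seq_len(spec$n_ap) else as.integer(def$ap)
  dv <- if (is.null(def$dv)) seq_len(spec$n_dv) else as.integer(def$dv)
  ap <- ap[ap >= 1L & ap <= spec$n_ap]
  dv <- dv[dv >= 1L & dv <= spec$n_dv]
  if (length(ap) == 0L || length(dv) == 0L) return(integer(0))
  grid <- expand.grid(ap = ap, dv = dv)
  sort(cell_index(grid$ap, grid$dv, spec))
}

#' Read and write grid / region-group configuration
#'
#' Plain-text YAML configuration holding the grid dimensions, discrepancy
#' interfaces, and region-group definitions, so runs are reproducible from a
#' config file alone.
#'
#' @param path Config file path.
#' @return `read_grid_config()` returns a list with elements `spec`
#'   (a `grid_spec`) and `groups` (a `region_groups`).
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  disc <- if (is.null(cfg$discrepancies)) default_discrepancies()
          else do.call(rbind, lapply(cfg$discrepancies, as.data.frame))
  spec <- grid_spec(n_ap = cfg$n_ap %||% 20L, n_dv = cfg$n_dv %||% 4L,
                    discrepancies = disc)
  groups <- if (is.null(cfg$groups)) region_groups()
            else do.call(region_groups, cfg$groups)
  list(spec = spec, groups = groups)
}

#' @rdname read_grid_config
#' @param spec A `grid_spec`.
#' @param groups A `region_groups`.
#' @export
write_grid_config <- function(spec, groups, path) {
  d <- spec$discrepancies
  cfg <- list(
    n_ap = spec$n_ap, n_dv = spec$n_dv,
    discrepancies = lapply(seq_len(nrow(d)), function(i) as.list(d[i, ])),
    groups = lapply(unclass(groups), function(g) g)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
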