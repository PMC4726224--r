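#' Temporal distribution of expressed-region occurrences for a group
#'
#' Summarizes when (at which developmental time points) the expressed
#' regions of a regional group occur, as a proportion vector over the 7 time
#' points. Two membership modes are supported:
#'
#' * `mode = "pattern"`: the group is a list of pattern indices (element
#'   `patterns` of the group definition); the occurrences are the member
#'   components of those pattern clusters. The `control` group (or any group
#'   without a `patterns` element) uses all clusters.
#' * `mode = "coords"`: patterns are ignored and a component belongs to the
#'   group when at least `min_frac` of its cells lie in the group's cell
#'   rectangle (`strict = TRUE` requires full containment). The `control`
#'   group covers all coordinates.
#'
#' @param x A list of `pattern_cluster` objects (from
#'   [cluster_components()] / [find_patterns()]) or, in coordinate mode, a
#'   `component_pool`.
#' @param groups A `region_groups` object.
#' @param group Group name.
#' @param mode `"pattern"` or `"coords"`.
#' @param spec A `grid_spec` (required in coordinate mode; taken from the
#'   pool attribute when available).
#' @param min_frac Minimum fraction of a component's cells inside the group
#'   rectangle for coordinate-mode membership (default 0.5).
#' @param strict Require full containment in coordinate mode.
#' @return A `temporal_distribution`: list with `proportions` (named over
#'   the 7 time points, summing to 1) and `n` (total occurrences counted).
#' @export
occurrences_by_time <- function(x, groups, group,
                                mode = c("pattern", "coords"),
                                spec = NULL, min_frac = 0.5,
                                strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(groups, "region_groups"))
  if (!group %in% names(groups)) stop("unknown region group: ", group)
  components <- as_component_list(x)
  if (is.null(spec)) spec <- attr(x, "spec")
  if (mode == "pattern") {
    if (!is.list(x) || length(x) == 0L || !inherits(x[[1]], "pattern_cluster")) {
      stop("pattern mode requires a list of pattern_cluster objects")
    }
    idx <- groups[[group]]$patterns
    use <- if (is.null(idx)) x else {
      ids <- vapply(x, `[[`, integer(1), "id")
      if (!all(idx %in% ids)) stop("group names pattern indices not present")
      x[match(idx, ids)]
    }
    members <- unlist(lapply(use, `[[`, "members"), recursive = FALSE)
  } else {
    if (is.null(spec)) stop("coordinate mode requires a grid_spec")
    gcells <- cells_in_group(groups, group, spec)
    members <- Filter(function(co) {
      inside <- mean(co$cells %in% gcells)
      if (strict) inside == 1 else inside >= min_frac
    }, components)
  }
  if (length(members) == 0L) stop("group '", group, "' has no occurrences")
  tp <- factor(vapply(members, `[[`, character(1), "timepoint"),
               levels = .TIMEPOINTS)
  counts <- as.integer(table(tp))
  structure(list(proportions = stats::setNames(counts / sum(counts),
                                               .TIMEPOINTS),
                 n = sum(counts)),
            class = "temporal_distribution")
}

as_component_list <- function(x) {
  if (inherits(x, "component_pool")) return(unclass(x))
  if (is.list(x) && length(x) > 0L && inherits(x[[1]], "pattern_cluster")) {
    return(unlist(lapply(x, `[[`, "members"), recursive = FALSE))
  }
  if (is.list(x)) return(x)
  stop("expected pattern clusters or a component_pool")
}

#' @export
print.temporal_distribution <- function(x, ...) {
  cat(sprintf("temporal_distribution over %d occurrences:\n", x$n))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Temporal distributions for several groups as a table
#'
#' Convenience wrapper around [occurrences_by_time()] for a set of groups,
#' returning one row per group plus the time-point proportions.
#'
#' @inheritParams occurrences_by_time
#' @param group_names Character vector of group names (default: all groups).
#' @return Data frame with columns `group`, `n`, and one proportion column
#'   per time point.
#' @export
coupling_table <- function(x, groups, group_names = names(groups),
                           mode = c("pattern", "coords"), spec = NULL,
                           min_frac = 0.5, strict = FALSE) {
  mode <- match.arg(mode)
  rows <- lapply(group_names, function(g) {
    td <- occurrences_by_time(x, groups, g, mode = mode, spec = spec,
                              min_frac = min_frac, strict = strict)
    cbind(data.frame(group = g, n = td$n), as.data.frame(t(td$proportions)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
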