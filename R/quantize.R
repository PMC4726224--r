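#' Threshold sweep: component structures of a slice
#'
#' Sweeps the binarization threshold over the sorted distinct observed
#' energies of one gene/time-point slice. At a threshold `theta`, a cell is
#' expressed iff its observed energy is `>= theta`; contiguous expressed
#' cells (under the grid adjacency, with missing cells acting as barriers)
#' form components. Each maximal run of consecutive distinct values over
#' which the *number* of components stays constant defines one component
#' structure with a "valid interval"; interval length is counted in distinct
#' data values, not geometric length, which makes the whole procedure
#' invariant under strictly increasing transforms of the energies.
#'
#' Component membership may drift within a run (components shrink as the
#' threshold rises); the reported `components` are taken at the run's lower
#' bound `theta_lo`.
#'
#' @param slice An `n_ap x n_dv` numeric matrix (`NA` = missing), e.g. from
#'   [slice_view()].
#' @param adjacency A `grid_adjacency` from [build_adjacency()].
#' @return List of `component_structure` objects ordered by ascending
#'   `theta_lo`, each a list with elements `n_components`, `components`
#'   (list of integer cell-index vectors, at `theta_lo`), `theta_lo`,
#'   `theta_hi`, `values` (the distinct values in the run) and
#'   `interval_length`. The runs tile all distinct observed values.
#' @export
#' @examples
#' spec <- grid_spec(n_ap = 7, n_dv = 1, discrepancies = NULL)
#' adj <- build_adjacency(spec)
#' s <- matrix(c(0.1, 0.5, 0.6, 0.1, 0.7, 0.8, 0.1), ncol = 1)
#' sapply(sweep_thresholds(s, adj), `[[`, "n_components")  # 1 2 1
sweep_thresholds <- function(slice, adjacency) {
  values <- as.numeric(slice)
  if (length(values) != length(adjacency)) {
    stop("slice size does not match adjacency")
  }
  if (all(is.na(values))) stop("slice has no observed values")
  sw <- sweep_component_counts(values, adjacency)
  runs <- rle(sw$n_components)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- vector("list", length(runs$values))
  for (r in seq_along(runs$values)) {
    theta_lo <- sw$values[starts[r]]
    active <- which(!is.na(values) & values >= theta_lo)
    out[[r]] <- structure(
      list(n_components = runs$values[r],
           components = label_components(active, adjacency),
           theta_lo = theta_lo,
           theta_hi = sw$values[ends[r]],
           values = sw$values[starts[r]:ends[r]],
           interval_length = runs$lengths[r]),
      class = "component_structure")
  }
  out
}

#' @export
print.component_structure <- function(x, ...) {
  cat(sprintf(
    "component_structure: %d component(s), valid over %d distinct value(s) [%g, %g]\n",
    x$n_components, x$interval_length, x$theta_lo, x$theta_hi))
  invisible(x)
}

#' Select the most stable component structure
#'
#' Among the component structures whose valid interval clears the floor
#' `min_lower` (0.2 by default — guards against demarcating at background
#' level), picks the one with the longest valid interval; ties are broken in
#' favor of the smallest `theta_lo`, i.e. the largest expressed areas.
#'
#' Two floor semantics are available. With `clip_floor = TRUE` (the
#' default), a structure whose interval straddles the floor is clipped: only
#' its distinct values at or above `min_lower` count toward the interval
#' length, and its threshold becomes the smallest such value. With
#' `clip_floor = FALSE`, any structure whose lower bound falls below the
#' floor is wholly ineligible. The literal reading is non-clipping, but it
#' degenerates whenever an expression domain dominates the grid: the few
#' background cells then all touch the domain, the stable
#' domain-formation run silently extends down through the background values,
#' and the most meaningful structure is disqualified even though every
#' in-range threshold reproduces it. Clipping keeps such structures
#' comparable on their in-range support.
#'
#' @param structures Output of [sweep_thresholds()].
#' @param min_lower Threshold floor. A structure must have at least one
#'   distinct value at/above the floor (above, when `strict_floor`).
#' @param strict_floor If `TRUE`, the floor comparison is strict (`>`
#'   rather than `>=`).
#' @param clip_floor Clip straddling intervals at the floor (default) or
#'   disqualify them wholesale.
#' @return The selected `component_structure` (with elements
#'   `theta_lo`/`interval_length` reflecting any clipping and the original
#'   bounds kept as `theta_lo_unclipped`), or `NULL` when no structure
#'   qualifies (all observed values below the floor).
#' @export
select_structure <- function(structures, min_lower = 0.2,
                             strict_floor = FALSE, clip_floor = TRUE) {
  in_range <- function(v) if (strict_floor) v > min_lower else v >= min_lower
  cand <- list()
  for (s in structures) {
    if (clip_floor) {
      keep <- in_range(s$values)
      if (!any(keep)) next
      s$theta_lo_unclipped <- s$theta_lo
      s$values <- s$values[keep]
      s$theta_lo <- s$values[1L]
      s$interval_length <- length(s$values)
    } else {
      if (!in_range(s$theta_lo)) next
    }
    cand[[length(cand) + 1L]] <- s
  }
  if (length(cand) == 0L) return(NULL)
  lens <- vapply(cand, `[[`, integer(1), "interval_length")
  los <- vapply(cand, `[[`, numeric(1), "theta_lo")
  best <- which(lens == max(lens))
  cand[[best[which.min(los[best])]]]
}

#' Demarcate the expressed regions of a slice
#'
#' Runs the threshold sweep, selects the most stable component structure,
#' and binarizes the slice at the structure's lower bound (`bound =
#' "lower"`, the largest differentially expressed areas — the default) or
#' upper bound (`bound = "upper"`, only the highest-expression cores; on a
#' profile of two overlapping bumps the lower bound yields the two bumps,
#' the upper bound only the two peaks).
#'
#' @inheritParams sweep_thresholds
#' @inheritParams select_structure
#' @param bound `"lower"` or `"upper"`.
#' @param gene,timepoint Optional labels carried into the result (taken from
#'   the slice attributes when present).
#' @return A `quantized_slice`: list with `gene`, `timepoint`, `theta`
#'   (`NA` when no structure qualifies), `cells` (integer indices of
#'   expressed cells), `components` (list of integer vectors), and `n_valid`
#'   (observed cell count).
#' @export
demarcate <- function(slice, adjacency, min_lower = 0.2,
                      bound = c("lower", "upper"), strict_floor = FALSE,
                      clip_floor = TRUE,
                      gene = attr(slice, "gene"),
                      timepoint = attr(slice, "timepoint")) {
  bound <- match.arg(bound)
  values <- as.numeric(slice)
  n_valid <- sum(!is.na(values))
  structures <- sweep_thresholds(slice, adjacency)
  sel <- select_structure(structures, min_lower = min_lower,
                          strict_floor = strict_floor,
                          clip_floor = clip_floor)
  if (is.null(sel)) {
    q <- list(gene = gene, timepoint = timepoint, theta = NA_real_,
              cells = integer(0), components = list(), n_valid = n_valid)
  } else {
    theta <- if (bound == "lower") sel$theta_lo else sel$theta_hi
    active <- which(!is.na(values) & values >= theta)
    q <- list(gene = gene, timepoint = timepoint, theta = theta,
              cells = active,
              components = label_components(active, adjacency),
              n_valid = n_valid)
  }
  structure(q, class = "quantized_slice")
}

#' @export
print.quantized_slice <- function(x, ...) {
  cat(sprintf(
    "quantized_slice %s @ %s: theta = %s, %d expressed cell(s) in %d component(s), n_valid = %d\n",
    x$gene %||% "?", x$timepoint %||% "?",
    if (is.na(x$theta)) "none" else format(x$theta),
    length(x$cells), length(x$components), x$n_valid))
  invisible(x)
}

#' Demarcate every gene/time-point slice of a field
#'
#' Applies [demarcate()] to all slices. Slices with no observed data are
#' recorded with `n_valid = 0`, no threshold and no expressed cells (they
#' cannot be globally expressed and contribute no components downstream).
#'
#' @param field An `expression_field`.
#' @inheritParams demarcate
#' @param adjacency A `grid_adjacency`; built from `field$spec` when `NULL`.
#' @return A `quantized_field`: list with `slices` (nested list indexed
#'   `[[gene]][[timepoint]]` of `quantized_slice`), `spec`, and the
#'   demarcation parameters.
#' @export
demarcate_field <- function(field, adjacency = NULL, min_lower = 0.2,
                            bound = c("lower", "upper"),
                            strict_floor = FALSE, clip_floor = TRUE) {
  stopifnot(inherits(field, "expression_field"))
  bound <- match.arg(bound)
  if (is.null(adjacency)) adjacency <- build_adjacency(field$spec)
  genes <- field_genes(field)
  slices <- vector("list", length(genes))
  names(slices) <- genes
  for (g in genes) {
    per_tp <- vector("list", length(.TIMEPOINTS))
    names(per_tp) <- .TIMEPOINTS
    for (tp in .TIMEPOINTS) {
      s <- slice_view(field, g, tp)
      if (attr(s, "n_valid") == 0L) {
        per_tp[[tp]] <- structure(
          list(gene = g, timepoint = tp, theta = NA_real_,
               cells = integer(0), components = list(), n_valid = 0L),
          class = "quantized_slice")
      } else {
        per_tp[[tp]] <- demarcate(s, adjacency, min_lower = min_lower,
                                  bound = bound, strict_floor = strict_floor,
                                  clip_floor = clip_floor,
                                  gene = g, timepoint = tp)
      }
    }
    slices[[g]] <- per_tp
  }
  structure(list(slices = slices, spec = field$spec,
                 min_lower = min_lower, bound = bound),
            class = "quantized_field")
}

#' @export
print.quantized_field <- function(x, ...) {
  cat(sprintf(
    "quantized_field: %d genes x %d time points (floor %g, %s bound)\n",
    length(x$slices), length(.TIMEPOINTS), x$min_lower, x$bound))
  invisible(x)
}

#' Write a quantized field as JSON
#'
#' One record per gene/time-point slice: gene, timepoint, theta, n_valid and
#' the expressed cell indices.
#'
#' @param qfield A `quantized_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantized_json <- function(qfield, path) {
  recs <- list()
  for (g in names(qfield$slices)) {
    for (tp in .TIMEPOINTS) {
      q <- qfield$slices[[g]][[tp]]
      recs[[length(recs) + 1L]] <- list(
        gene = g, timepoint = tp,
        theta = if (is.na(q$theta)) NULL else q$theta,
        n_valid = q$n_valid, cells = as.integer(q$cells))
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
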