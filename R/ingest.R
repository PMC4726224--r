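#' Expression fields: energies over gene, time point and grid cell
#'
#' An `expression_field` holds per-gene, per-time-point expression energies
#' on the substructure grid as a 4-dimensional array
#' `[gene, timepoint, ap, dv]` with `NA` marking missing cells. Energies are
#' finite and non-negative where observed; zero is a valid observed energy,
#' distinct from missing. Time points are always the 7 canonical labels in
#' developmental order (see [canonical_timepoints()]).
#'
#' @param values 4-d numeric array `[gene, timepoint, ap, dv]` with dimnames
#'   on the first two dimensions; or `NULL` to create an all-missing field
#'   for `genes`.
#' @param genes Character vector of gene identifiers (used when `values` is
#'   `NULL`).
#' @param spec A `grid_spec`.
#' @return An object of class `expression_field`.
#' @export
expression_field <- function(values = NULL, genes = NULL, spec = grid_spec()) {
  tps <- .TIMEPOINTS
  if (is.null(values)) {
    stopifnot(!is.null(genes))
    genes <- as.character(genes)
    values <- array(NA_real_,
                    dim = c(length(genes), length(tps), spec$n_ap, spec$n_dv),
                    dimnames = list(genes, tps, NULL, NULL))
  }
  stopifnot(length(dim(values)) == 4L,
            dim(values)[3] == spec$n_ap, dim(values)[4] == spec$n_dv,
            identical(dimnames(values)[[2]], tps))
  obs <- values[!is.na(values)]
  if (length(obs) > 0L && (any(!is.finite(obs)) || any(obs < 0))) {
    stop("observed energies must be finite and >= 0")
  }
  structure(list(values = values, spec = spec), class = "expression_field")
}

#' @export
print.expression_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_field: %d genes x %d time points on a %dx%d grid\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  observed entries: %d of %d\n",
              sum(!is.na(x$values)), length(x$values)))
  invisible(x)
}

#' @rdname expression_field
#' @param field An `expression_field`.
#' @export
field_genes <- function(field) dimnames(field$values)[[1]]

#' Extract one gene/time-point slice of an expression field
#'
#' @param field An `expression_field`.
#' @param gene Gene identifier.
#' @param timepoint One of [canonical_timepoints()].
#' @return An `n_ap x n_dv` numeric matrix (`NA` = missing) with attributes
#'   `gene`, `timepoint` and `n_valid` (number of observed cells).
#' @export
slice_view <- function(field, gene, timepoint) {
  stopifnot(inherits(field, "expression_field"))
  if (!gene %in% field_genes(field)) stop("unknown gene: ", gene)
  if (!timepoint %in% .TIMEPOINTS) stop("unknown timepoint: ", timepoint)
  m <- field$values[gene, timepoint, , ]
  dim(m) <- c(field$spec$n_ap, field$spec$n_dv)
  structure(m, gene = gene, timepoint = timepoint, n_valid = sum(!is.na(m)))
}

#' Read an energy table into an expression field
#'
#' The interchange format is a flat TSV with header columns
#' `gene`, `timepoint`, `ap`, `dv`, `energy`. Each row gives the average
#' expression energy of one substructure (grid cell) for one gene at one
#' time point. A blank or `NA` energy marks the cell as missing; triples
#' absent from the table are missing as well. Duplicate
#' (gene, timepoint, cell) triples are an error.
#'
#' @param path TSV file path.
#' @param spec A `grid_spec`.
#' @return An `expression_field`.
#' @export
read_energy_table <- function(path, spec = grid_spec()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c(gene = "character",
                                          timepoint = "character"),
                           na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  required <- c("gene", "timepoint", "ap", "dv", "energy")
  if (!all(required %in% names(tab))) {
    stop("energy table must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("energy table is empty")
  if (any(is.na(tab$gene)) || any(is.na(tab$timepoint)) ||
      any(is.na(tab$ap)) || any(is.na(tab$dv))) {
    stop("malformed row: gene, timepoint, ap, dv must all be present")
  }
  bad_tp <- setdiff(unique(tab$timepoint), .TIMEPOINTS)
  if (length(bad_tp) > 0L) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "))
  }
  tab$ap <- as.integer(tab$ap)
  tab$dv <- as.integer(tab$dv)
  .check_coord(tab$ap, tab$dv, spec)
  key <- paste(tab$gene, tab$timepoint, tab$ap, tab$dv, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, timepoint, ap, dv) triples in energy table")
  }
  genes <- sort(unique(tab$gene))
  field <- expression_field(genes = genes, spec = spec)
  idx <- cbind(match(tab$gene, genes), match(tab$timepoint, .TIMEPOINTS),
               tab$ap, tab$dv)
  field$values[idx] <- tab$energy
  # the constructor's validity checks, re-applied to the filled array
  expression_field(values = field$values, spec = spec)
}

#' Write an expression field as an energy table
#'
#' Writes observed entries only, in canonical row order
#' (gene, timepoint, ap, dv), with enough digits that
#' `read_energy_table()` round-trips the field bit-exactly.
#'
#' @param field An `expression_field`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(field, path) {
  stopifnot(inherits(field, "expression_field"))
  v <- field$values
  obs <- which(!is.na(v), arr.ind = TRUE)
  tab <- data.frame(gene = dimnames(v)[[1]][obs[, 1]],
                    timepoint = .TIMEPOINTS[obs[, 2]],
                    ap = obs[, 3], dv = obs[, 4],
                    energy = v[obs],
                    stringsAsFactors = FALSE)
  ord <- order(tab$gene, match(tab$timepoint, .TIMEPOINTS), tab$ap, tab$dv)
  tab <- tab[ord, ]
  tab$energy <- sprintf("%.17g", tab$energy)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop genes with no observed data
#'
#' Removes genes that have a missing value in every substructure at every
#' time point; genes with at least one observed cell anywhere are kept.
#' Idempotent.
#'
#' @param field An `expression_field`.
#' @return The filtered `expression_field`, with the removed gene names in
#'   attribute `dropped_genes`.
#' @export
filter_genes <- function(field) {
  stopifnot(inherits(field, "expression_field"))
  has_data <- apply(field$values, 1L, function(g) any(!is.na(g)))
  keep <- which(has_data)
  out <- expression_field(
    values = field$values[keep, , , , drop = FALSE],
    spec = field$spec
  )
  attr(out, "dropped_genes") <- field_genes(field)[!has_data]
  out
}
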