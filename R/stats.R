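#' Read a GMT gene-set collection
#'
#' Standard GMT: one tab-separated line per category — name, description,
#' then member gene identifiers.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (category -> gene set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric enrichment of a query gene set against each
#' category of a collection, within a gene universe: with `N` universe
#' genes, `K` of them in the category, and a query of size `n` overlapping
#' the category in `k` genes, the p-value is `P(X >= k)` for
#' hypergeometric `X`. Benjamini-Hochberg q-values are computed across the
#' collection.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]);
#'   categories are intersected with the universe.
#' @param universe Character vector: the gene universe. A natural choice is
#'   all genes surviving [filter_genes()].
#' @return Data frame sorted by p-value with columns `category`, `k`, `K`,
#'   `n`, `N`, `p_value`, `q_value`.
#' @export
#' @examples
#' u <- paste0("g", 1:10)
#' hypergeom_enrich(u[1:4], list(setA = u[1:5]), u)
hypergeom_enrich <- function(query, collection, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  }
  if (length(collection) == 0L || is.null(names(collection))) {
    stop("collection must be a non-empty named list")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(cat) {
    members <- intersect(unique(collection[[cat]]), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  out
}

#' Select co-expression groups relative to a regional reference profile
#'
#' Splits genes into a "similar" group — expressed (after demarcation) in at
#' least one substructure of the reference region at *every* prenatal time
#' point — and a "control" group — expressed in no substructure of the
#' region at *any* prenatal time point. Genes matching neither criterion
#' are excluded. With `rule = "any"`, the similar group instead requires
#' regional expression at at least one prenatal time point.
#'
#' @param qfield A `quantized_field`.
#' @param region_cells Integer vector of grid cell indices defining the
#'   region (e.g. `cells_in_group(region_groups(), "forebrain", spec)`).
#' @param prenatal Character vector of prenatal time points (default the
#'   four embryonic stages).
#' @param rule `"all"` (conjunctive, default) or `"any"` (disjunctive) for
#'   the similar group.
#' @return A `group_selection`: list with `similar_group`, `control_group`
#'   (character vectors, disjoint), `region_cells` and `timepoints`.
#' @export
select_coexpression_groups <- function(qfield, region_cells,
                                       prenatal = canonical_timepoints()[1:4],
                                       rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(qfield, "quantized_field"), length(region_cells) > 0L)
  stopifnot(all(prenatal %in% .TIMEPOINTS))
  genes <- names(qfield$slices)
  in_region <- t(vapply(genes, function(g) {
    vapply(prenatal, function(tp) {
      any(qfield$slices[[g]][[tp]]$cells %in% region_cells)
    }, logical(1))
  }, logical(length(prenatal))))
  similar <- if (rule == "all") apply(in_region, 1L, all)
             else apply(in_region, 1L, any)
  control <- apply(in_region, 1L, function(z) !any(z))
  structure(list(similar_group = genes[similar],
                 control_group = genes[control],
                 region_cells = region_cells,
                 timepoints = prenatal),
            class = "group_selection")
}

#' @export
print.group_selection <- function(x, ...) {
  cat(sprintf(
    "group_selection: %d similar, %d control genes (region of %d cells, %s)\n",
    length(x$similar_group), length(x$control_group),
    length(x$region_cells), paste(x$timepoints, collapse = "/")))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum gap between the two empirical CDFs; the two-sided
#' p-value is asymptotic by default (`exact = TRUE` for the small-sample
#' exact computation). D is rank-based, hence invariant under a common
#' strictly increasing transform of both samples.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact Use the exact p-value computation.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Read a two-column log2-ratio table
#'
#' TSV with header columns `gene` and `log2_ratio` (e.g. mutant/control
#' expression ratios).
#'
#' @param path TSV file path.
#' @return Named numeric vector of finite log2 ratios.
#' @export
read_log2_ratio_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(gene = "character"))
  if (!all(c("gene", "log2_ratio") %in% names(tab))) {
    stop("log2-ratio table must have columns gene, log2_ratio")
  }
  if (any(!is.finite(tab$log2_ratio))) stop("log2 ratios must be finite")
  if (anyDuplicated(tab$gene)) stop("duplicate gene in log2-ratio table")
  stats::setNames(tab$log2_ratio, tab$gene)
}

#' Tail fractions of log2 expression ratios for a gene set
#'
#' For the genes of a set found in a log2-ratio table, reports the fraction
#' responding beyond a fold-change cutoff, the fraction with near-zero
#' response, and the up/down counts by ratio sign. The default `cutoff`
#' `log2(1.1386) = 0.1879` corresponds to a 13.86% up- or down-regulation.
#'
#' @param ratios Named numeric vector of log2 ratios (see
#'   [read_log2_ratio_table()]).
#' @param genes Character vector of genes; members missing from the table
#'   are reported via a message and skipped.
#' @param cutoff Absolute log2-ratio cutoff for the tail fraction.
#' @param small_cutoff Absolute log2-ratio bound for the "near zero"
#'   fraction (default 0.1).
#' @return List with `n` (genes used), `n_missing`, `tail_fraction`
#'   (`|ratio| >= cutoff`), `small_fraction` (`|ratio| < small_cutoff`),
#'   `n_up` and `n_down` (strictly positive / negative ratios).
#' @export
tail_fractions <- function(ratios, genes, cutoff = log2(1.1386),
                           small_cutoff = 0.1) {
  genes <- unique(as.character(genes))
  found <- genes[genes %in% names(ratios)]
  missing <- setdiff(genes, found)
  if (length(found) == 0L) stop("no genes of the set are in the ratio table")
  if (length(missing) > 0L) {
    message(length(missing), " gene(s) not in the ratio table; skipped")
  }
  r <- ratios[found]
  list(n = length(r),
       n_missing = length(missing),
       tail_fraction = mean(abs(r) >= cutoff),
       small_fraction = mean(abs(r) < small_cutoff),
       n_up = sum(r > 0),
       n_down = sum(r < 0))
}
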