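#' Call global expression for one quantized slice
#'
#' A gene is globally expressed at a time point when its largest contiguous
#' expressed component contains more than half (strictly) of the
#' substructures with valid data. The alternative `rule = "count"` calls
#' global expression when the total number of expressed substructures,
#' regardless of contiguity, exceeds half of the valid ones.
#'
#' @param q A `quantized_slice` with `n_valid >= 1`.
#' @param rule `"component"` (largest-component rule, default) or
#'   `"count"` (expressed-cell-count rule).
#' @return Integer bit, `1L` or `0L`.
#' @export
is_global <- function(q, rule = c("component", "count")) {
  rule <- match.arg(rule)
  stopifnot(inherits(q, "quantized_slice"))
  if (q$n_valid == 0L) stop("is_global undefined for a slice with no valid data")
  size <- if (rule == "component") {
    if (length(q$components) == 0L) 0L else max(lengths(q$components))
  } else {
    length(q$cells)
  }
  as.integer(size > q$n_valid / 2)
}

#' Global expression state vector of one gene
#'
#' Collects the per-time-point global calls of a gene into the 7-bit state
#' vector, in canonical developmental order. Time points with no valid data
#' yield bit 0 (a gene cannot be called globally expressed without data).
#'
#' @param slices Named list of `quantized_slice` objects for one gene,
#'   indexed by time point (as in `quantized_field$slices[[gene]]`).
#' @inheritParams is_global
#' @return Named integer vector of 7 bits.
#' @export
state_vector <- function(slices, rule = c("component", "count")) {
  rule <- match.arg(rule)
  bits <- vapply(.TIMEPOINTS, function(tp) {
    q <- slices[[tp]]
    if (is.null(q) || q$n_valid == 0L) 0L else is_global(q, rule = rule)
  }, integer(1))
  bits
}

#' Global expression state table for all genes
#'
#' @param qfield A `quantized_field`.
#' @inheritParams is_global
#' @return Data frame with one row per gene: `gene`, one 0/1 column per time
#'   point, `state` (the 7-character bit string) and `n_expressed_<tp>`
#'   columns with per-time-point expressed-cell counts.
#' @export
global_state_table <- function(qfield, rule = c("component", "count")) {
  rule <- match.arg(rule)
  stopifnot(inherits(qfield, "quantized_field"))
  genes <- names(qfield$slices)
  bits <- t(vapply(genes, function(g) state_vector(qfield$slices[[g]], rule),
                   integer(length(.TIMEPOINTS))))
  counts <- t(vapply(genes, function(g) {
    vapply(.TIMEPOINTS, function(tp) {
      length(qfield$slices[[g]][[tp]]$cells)
    }, integer(1))
  }, integer(length(.TIMEPOINTS))))
  out <- data.frame(gene = genes, bits, stringsAsFactors = FALSE)
  names(out)[2:8] <- .TIMEPOINTS
  out$state <- apply(bits, 1L, paste, collapse = "")
  colnames(counts) <- paste0("n_expressed_", .TIMEPOINTS)
  out <- cbind(out, counts)
  rownames(out) <- NULL
  out
}

#' Rank global expression states by gene count
#'
#' Counts the genes possessing each distinct 7-bit state and sorts the
#' states by decreasing gene count; equal counts are ordered
#' lexicographically by bit string (a deterministic but arbitrary tie rule).
#'
#' @param states Character vector of 7-character bit strings (one per gene),
#'   or a data frame with a `state` column as returned by
#'   [global_state_table()].
#' @return A `state_ranking`: data frame with columns `state` and
#'   `gene_count`, ordered by rank.
#' @export
#' @examples
#' rank_states(c("0000000", "0000000", "1111111"))
rank_states <- function(states) {
  if (is.data.frame(states)) states <- states$state
  stopifnot(is.character(states), all(nchar(states) == 7L),
            length(states) >= 1L)
  tab <- table(states)
  df <- data.frame(state = names(tab), gene_count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$gene_count, df$state), ]
  rownames(df) <- NULL
  class(df) <- c("state_ranking", "data.frame")
  df
}

#' Construct a state ranking from ready-made rows
#'
#' Builds a `state_ranking` from already-ranked (state, gene count) rows,
#' e.g. a published ranking table used as input to window counting. Rows
#' must be in non-increasing gene-count order; duplicate states are allowed
#' (they stay as printed rather than being re-aggregated).
#'
#' @param states Character vector of 7-character bit strings.
#' @param gene_counts Integer vector of gene counts, non-increasing.
#' @return A `state_ranking`.
#' @export
state_ranking <- function(states, gene_counts) {
  stopifnot(is.character(states), all(nchar(states) == 7L),
            all(strsplit(paste(states, collapse = ""), "")[[1]] %in% c("0", "1")),
            length(states) == length(gene_counts))
  gene_counts <- as.integer(gene_counts)
  if (is.unsorted(rev(gene_counts))) {
    stop("gene_counts must be non-increasing (rows must already be ranked)")
  }
  df <- data.frame(state = states, gene_count = gene_counts,
                   stringsAsFactors = FALSE)
  class(df) <- c("state_ranking", "data.frame")
  df
}

#' Reference global-state ranking from the developing mouse brain atlas
#'
#' The published gene counts per top-ranking global expression state for the
#' 1826-gene analysis of the Allen Developing Mouse Brain Atlas energies
#' (29 rows), shipped as a plain-text table and loaded as a
#' [state_ranking()]. Used as input for rank-window bit counting; the rows
#' are kept exactly as printed.
#'
#' @return A `state_ranking` with 29 rows.
#' @export
aba_state_ranking <- function() {
  path <- system.file("extdata", "aba_global_state_ranking.tsv",
                      package = "stexpat", mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = c(state = "character"))
  state_ranking(tab$state, tab$n_genes)
}

#' Count a bit value over a rank window of a state ranking
#'
#' Within rows `rank_from` to `rank_to` (inclusive, 1-based) of a ranking,
#' counts how many states carry the given bit at the given time point.
#'
#' @param ranking A `state_ranking`.
#' @param rank_from,rank_to Window bounds, 1-based inclusive.
#' @param timepoint One of [canonical_timepoints()].
#' @param bit `0L` or `1L`.
#' @return Integer count.
#' @export
#' @examples
#' r <- rank_states(c("0000000", "0000000", "1111111"))
#' count_rank_window(r, 1, 2, "E11.5", 0L)
count_rank_window <- function(ranking, rank_from, rank_to, timepoint, bit) {
  stopifnot(inherits(ranking, "state_ranking"))
  if (rank_from < 1L || rank_to > nrow(ranking) || rank_from > rank_to) {
    stop("rank window [", rank_from, ", ", rank_to,
         "] out of range for a ranking of ", nrow(ranking), " rows")
  }
  pos <- match(timepoint, .TIMEPOINTS)
  if (is.na(pos)) stop("unknown timepoint: ", timepoint)
  stopifnot(bit %in% c(0L, 1L))
  window <- ranking$state[rank_from:rank_to]
  sum(substr(window, pos, pos) == as.character(bit))
}

#' Random-matrix null for the half-grid global rule
#'
#' Simulates binary random matrices on the grid: each cell is expressed
#' independently with probability `p`, and the size of the largest connected
#' component is recorded. The empirical probability that the largest
#' component exceeds half the grid justifies the half-grid global-expression
#' rule: it is very small for moderate `p` and increases monotonically with
#' `p`.
#'
#' @param p Per-cell expression probability in `[0, 1]`.
#' @param adjacency A `grid_adjacency`.
#' @param n_sims Number of simulated matrices (default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @return Object of class `largest_component_null`: list with `sizes`
#'   (integer vector of `n_sims` largest-component sizes), `p`, `n_cells`,
#'   `prob_exceeds_half` (empirical `P(largest > n_cells / 2)`), and moment
#'   summaries `mean` and `var` (descriptive Poisson check: for a thin
#'   random field the two are close).
#' @export
simulate_largest_component_null <- function(p, adjacency, n_sims = 1000L,
                                            seed) {
  stopifnot(p >= 0, p <= 1, n_sims >= 1L)
  if (missing(seed)) stop("an explicit seed is required")
  nc <- length(adjacency)
  sizes <- integer(n_sims)
  with_preserved_rng(seed, {
    for (i in seq_len(n_sims)) {
      active <- which(stats::runif(nc) < p)
      sizes[i] <- largest_component_size(active, adjacency)
    }
  })
  structure(list(sizes = sizes, p = p, n_cells = nc,
                 prob_exceeds_half = mean(sizes > nc / 2),
                 mean = mean(sizes), var = stats::var(sizes)),
            class = "largest_component_null")
}

#' @export
print.largest_component_null <- function(x, ...) {
  cat(sprintf(
    "largest-component null: p = %g on %d cells, %d sims\n  P(largest > %g) = %.4f; size mean %.2f, var %.2f\n",
    x$p, x$n_cells, length(x$sizes), x$n_cells / 2,
    x$prob_exceeds_half, x$mean, x$var))
  invisible(x)
}

#' Mean expressed-substructure count over non-global slices
#'
#' Averages the number of expressed cells over the gene/time-point slices
#' whose global bit is 0 — the quantity separating "locally expressed" from
#' "silent" among the non-global combinations.
#'
#' @param qfield A `quantized_field`.
#' @param state_table Output of [global_state_table()]; computed when
#'   `NULL`.
#' @inheritParams is_global
#' @return List with `mean` (mean expressed-cell count) and `n_slices`
#'   (number of zero-bit slices averaged over).
#' @export
mean_expressed_substructures <- function(qfield, state_table = NULL,
                                         rule = c("component", "count")) {
  rule <- match.arg(rule)
  if (is.null(state_table)) state_table <- global_state_table(qfield, rule)
  counts <- integer(0)
  for (i in seq_len(nrow(state_table))) {
    g <- state_table$gene[i]
    for (tp in .TIMEPOINTS) {
      if (state_table[i, tp] == 0L) {
        counts <- c(counts, length(qfield$slices[[g]][[tp]]$cells))
      }
    }
  }
  if (length(counts) == 0L) stop("no non-global slices to average over")
  list(mean = mean(counts), n_slices = length(counts))
}

#' Write a global-state table as TSV
#'
#' @param state_table Output of [global_state_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(state_table, path) {
  utils::write.table(state_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state after.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
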