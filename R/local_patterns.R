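#' Pool expressed components from non-global slices
#'
#' Collects the contiguous expressed components of every gene/time-point
#' slice whose global expression bit is 0 — the raw material for recurrent
#' local pattern discovery. Each pooled component keeps its (gene,
#' timepoint) tag and the slice's valid-cell count.
#'
#' @param qfield A `quantized_field`.
#' @param state_table Output of [global_state_table()]; computed when
#'   `NULL`.
#' @inheritParams is_global
#' @return A `component_pool`: list of records, each with `gene`,
#'   `timepoint`, `cells` (integer cell indices) and `n_valid`.
#' @export
pool_components <- function(qfield, state_table = NULL,
                            rule = c("component", "count")) {
  rule <- match.arg(rule)
  stopifnot(inherits(qfield, "quantized_field"))
  if (is.null(state_table)) state_table <- global_state_table(qfield, rule)
  pool <- list()
  for (i in seq_len(nrow(state_table))) {
    g <- state_table$gene[i]
    for (tp in .TIMEPOINTS) {
      if (state_table[i, tp] != 0L) next
      q <- qfield$slices[[g]][[tp]]
      for (comp in q$components) {
        pool[[length(pool) + 1L]] <- list(gene = g, timepoint = tp,
                                          cells = comp,
                                          n_valid = q$n_valid)
      }
    }
  }
  structure(pool, class = "component_pool", spec = qfield$spec)
}

#' @export
print.component_pool <- function(x, ...) {
  cat(sprintf("component_pool: %d components from %d gene/time slices\n",
              length(x),
              length(unique(vapply(unclass(x), function(co)
                paste(co$gene, co$timepoint), character(1))))))
  invisible(x)
}

#' Filter pooled components by size
#'
#' Retains components whose cell count lies in
#' `[min_cells, max_fraction_of_valid * n_valid]` for their slice.
#' Single-cell regions are noise-prone and components covering more than
#' half the valid cells belong to the global regime, hence the defaults.
#'
#' @param pool A `component_pool`.
#' @param min_cells Minimum component size (default 2).
#' @param max_fraction_of_valid Maximum component size as a fraction of the
#'   slice's valid cells (default 0.5).
#' @return The filtered `component_pool`.
#' @export
filter_components <- function(pool, min_cells = 2L,
                              max_fraction_of_valid = 0.5) {
  stopifnot(inherits(pool, "component_pool"))
  keep <- vapply(unclass(pool), function(co) {
    n <- length(co$cells)
    n >= min_cells && n <= max_fraction_of_valid * co$n_valid
  }, logical(1))
  structure(unclass(pool)[keep], class = "component_pool",
            spec = attr(pool, "spec"))
}

#' Jaccard overlap between two components
#'
#' @param a,b Components (lists with a `cells` element) or plain integer
#'   cell-index vectors.
#' @return Jaccard index of the two cell sets, in `[0, 1]`.
#' @export
overlap_score <- function(a, b) {
  ca <- if (is.list(a)) a$cells else a
  cb <- if (is.list(b)) b$cells else b
  u <- length(union(ca, cb))
  if (u == 0L) return(0)
  length(intersect(ca, cb)) / u
}

#' Cluster overlapping components into recurrent patterns
#'
#' Builds the overlap graph on the pooled components (an edge joins two
#' components whose Jaccard overlap is at least `jaccard_min`) and takes its
#' connected components as clusters — the simplest deterministic reading of
#' "clusters of overlapped contiguous regions". With `refine = TRUE`, each
#' cluster is additionally required to have average pairwise Jaccard at
#' least `jaccard_min`; clusters failing the check are split greedily by
#' repeatedly removing the member with the lowest average overlap to the
#' rest (a quasi-clique refinement for stricter coherence).
#'
#' The partition is a deterministic function of the pool and parameters:
#' members are processed in pool order and igraph's component labeling is
#' deterministic.
#'
#' @param pool A (filtered) `component_pool`.
#' @param jaccard_min Minimum Jaccard overlap for an edge (default 0.5).
#' @param min_members Minimum number of member components for a cluster to
#'   be reported (default 1, i.e. a full partition of the pool; a typical
#'   reporting choice for prominent recurrent patterns is 5).
#' @param refine Apply the quasi-clique refinement (default `FALSE`).
#' @return List of `pattern_cluster` objects, sorted by [sort_patterns()];
#'   each has `id`, `members` (component records), `occurrence_count`
#'   (member count over gene/time combinations), `gene_count` (distinct
#'   genes), `frequency_map` (`n_ap x n_dv` matrix of per-cell member
#'   coverage fractions) and `time_profile` (member counts per time point).
#' @export
cluster_components <- function(pool, jaccard_min = 0.5, min_members = 1L,
                               refine = FALSE) {
  stopifnot(inherits(pool, "component_pool"))
  spec <- attr(pool, "spec")
  n <- length(pool)
  if (n == 0L) return(list())
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (overlap_score(pool[[i]], pool[[j]]) >= jaccard_min) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  membership <- igraph::components(g)$membership
  groups <- unname(split(seq_len(n), membership))
  if (refine) {
    groups <- unname(unlist(lapply(groups, function(idx)
      refine_group(idx, pool, jaccard_min)), recursive = FALSE))
  }
  clusters <- lapply(groups, function(idx) make_cluster(pool[idx], spec))
  clusters <- clusters[vapply(clusters, function(cl)
    cl$occurrence_count >= min_members, logical(1))]
  sort_patterns(clusters)
}

# Greedy quasi-clique refinement: peel members until the average pairwise
# Jaccard of the group reaches the threshold; peeled members restart as
# their own groups (re-refined recursively).
refine_group <- function(idx, pool, jaccard_min) {
  if (length(idx) <= 2L) return(list(idx))
  jac <- outer(idx, idx, Vectorize(function(i, j)
    overlap_score(pool[[i]], pool[[j]])))
  diag(jac) <- NA_real_
  current <- seq_along(idx)
  peeled <- integer(0)
  while (length(current) > 2L &&
         mean(jac[current, current], na.rm = TRUE) < jaccard_min) {
    avg <- rowMeans(jac[current, current, drop = FALSE], na.rm = TRUE)
    worst <- current[which.min(avg)]
    peeled <- c(peeled, worst)
    current <- setdiff(current, worst)
  }
  out <- list(idx[current])
  for (p in peeled) out <- c(out, list(idx[p]))
  out
}

make_cluster <- function(members, spec) {
  members <- unclass(members)
  nm <- length(members)
  freq <- matrix(0, nrow = spec$n_ap, ncol = spec$n_dv)
  for (co in members) freq[co$cells] <- freq[co$cells] + 1
  tp <- table(factor(vapply(members, `[[`, character(1), "timepoint"),
                     levels = .TIMEPOINTS))
  structure(list(id = NA_integer_,
                 members = members,
                 occurrence_count = nm,
                 gene_count = length(unique(vapply(members, `[[`,
                                                   character(1), "gene"))),
                 frequency_map = freq / nm,
                 time_profile = as.integer(tp)),
            class = "pattern_cluster")
}

#' @export
print.pattern_cluster <- function(x, ...) {
  cat(sprintf(
    "pattern_cluster %s: %d occurrences in %d genes; support cells: %d\n",
    ifelse(is.na(x$id), "?", x$id), x$occurrence_count, x$gene_count,
    sum(x$frequency_map > 0)))
  invisible(x)
}

#' Sort pattern clusters
#'
#' Orders clusters by descending occurrence count, then descending gene
#' count, then (deterministically) by the first member's gene identifier
#' and time point. Assigns consecutive `id`s in the sorted order.
#'
#' @param clusters List of `pattern_cluster` objects.
#' @return The sorted list, with `id` fields set to 1, 2, ...
#' @export
sort_patterns <- function(clusters) {
  if (length(clusters) == 0L) return(clusters)
  key_gene <- vapply(clusters, function(cl) cl$members[[1]]$gene, character(1))
  key_tp <- vapply(clusters, function(cl)
    match(cl$members[[1]]$timepoint, .TIMEPOINTS), integer(1))
  occ <- vapply(clusters, `[[`, integer(1), "occurrence_count")
  gc <- vapply(clusters, `[[`, integer(1), "gene_count")
  ord <- order(-occ, -gc, key_gene, key_tp)
  out <- unname(clusters[ord])
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Per-cell frequency map of a pattern cluster
#'
#' For each grid cell, the fraction of the cluster's member components that
#' cover it (1 means every member covers the cell).
#'
#' @param cluster A non-empty `pattern_cluster`.
#' @return `n_ap x n_dv` numeric matrix with values in `[0, 1]`.
#' @export
frequency_map <- function(cluster) {
  stopifnot(inherits(cluster, "pattern_cluster"))
  if (cluster$occurrence_count == 0L) stop("empty cluster")
  cluster$frequency_map
}

#' Full local-pattern pipeline
#'
#' Pools components from non-global slices, filters them by size, clusters
#' them through the Jaccard overlap graph, and reports the sorted patterns.
#'
#' @param qfield A `quantized_field`.
#' @param state_table Output of [global_state_table()]; computed when
#'   `NULL`.
#' @inheritParams filter_components
#' @inheritParams cluster_components
#' @return Sorted list of `pattern_cluster` objects (see
#'   [cluster_components()]).
#' @export
find_patterns <- function(qfield, state_table = NULL, jaccard_min = 0.5,
                          min_cells = 2L, max_fraction_of_valid = 0.5,
                          min_members = 5L, refine = FALSE) {
  if (is.null(state_table)) state_table <- global_state_table(qfield)
  pool <- pool_components(qfield, state_table)
  pool <- filter_components(pool, min_cells = min_cells,
                            max_fraction_of_valid = max_fraction_of_valid)
  cluster_components(pool, jaccard_min = jaccard_min,
                     min_members = min_members, refine = refine)
}

#' Write pattern clusters as JSON
#'
#' @param clusters List of `pattern_cluster` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patterns_json <- function(clusters, path) {
  recs <- lapply(clusters, function(cl) {
    list(id = cl$id,
         occurrence_count = cl$occurrence_count,
         gene_count = cl$gene_count,
         members = lapply(cl$members, function(co)
           list(gene = co$gene, timepoint = co$timepoint,
                cells = as.integer(co$cells))),
         frequency_map = as.vector(cl$frequency_map),
         time_profile = cl$time_profile)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
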