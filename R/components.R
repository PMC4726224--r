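# Connected-component primitives on the substructure grid.
#
# These are the low-level engine behind the threshold sweep: a flood-fill
# labeler for explicit component membership, and a union-find pass that
# yields component counts at every distinct threshold in one sweep (cells are
# activated in decreasing value order; each activation either opens a new
# component or merges existing ones, which is the persistence-style view of
# the quantization).

# Label connected components among `active` cells (integer indices).
# Returns a list of sorted integer vectors, ordered by smallest member.
label_components <- function(active, adjacency) {
  if (length(active) == 0L) return(list())
  nc <- length(adjacency)
  in_active <- logical(nc)
  in_active[active] <- TRUE
  seen <- logical(nc)
  out <- list()
  k <- 0L
  for (s in sort(as.integer(active))) {
    if (seen[s]) next
    k <- k + 1L
    stack <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      for (nb in adjacency[[v]]) {
        if (in_active[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    out[[k]] <- sort(members)
  }
  out
}

# Size of the largest connected component among `active` cells.
largest_component_size <- function(active, adjacency) {
  comps <- label_components(active, adjacency)
  if (length(comps) == 0L) return(0L)
  max(lengths(comps))
}

# Component counts at every distinct threshold of a slice, by activating
# cells in decreasing value order with union-find. `values` is a numeric
# vector over all cells (NA = missing). Returns list(values = ascending
# distinct observed values, n_components = count when binarizing at >= each
# value).
sweep_component_counts <- function(values, adjacency) {
  obs <- which(!is.na(values))
  if (length(obs) == 0L) stop("slice has no observed values")
  uvals <- sort(unique(values[obs]))
  nu <- length(uvals)
  nc <- length(adjacency)
  parent <- seq_len(nc)
  active <- logical(nc)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  counts_desc <- integer(nu)
  n_comp <- 0L
  # bucket cells by their value rank for descending activation
  rank_of <- match(values[obs], uvals)
  buckets <- split(obs, rank_of)
  for (j in seq.int(nu, 1L)) {
    cells <- buckets[[as.character(j)]]
    if (!is.null(cells)) {
      for (v in cells) {
        active[v] <- TRUE
        n_comp <- n_comp + 1L
        for (nb in adjacency[[v]]) {
          if (active[nb]) {
            ra <- find(v)
            rb <- find(nb)
            if (ra != rb) {
              parent[ra] <- rb
              n_comp <- n_comp - 1L
            }
          }
        }
      }
    }
    counts_desc[j] <- n_comp
  }
  list(values = uvals, n_components = counts_desc)
}
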