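# Independent oracles used across the suite. They deliberately avoid the
# package's own component engine: connected components come from igraph,
# ECDFs from direct scans, hypergeometric probabilities from exhaustive
# subset enumeration.

# Component cell sets among `active` cells, via igraph.
oracle_components <- function(active, adjacency) {
  if (length(active) == 0L) return(list())
  nc <- length(adjacency)
  edges <- integer(0)
  in_active <- logical(nc)
  in_active[active] <- TRUE
  for (v in active) {
    for (nb in adjacency[[v]]) {
      if (in_active[nb] && nb > v) edges <- c(edges, v, nb)
    }
  }
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  comps <- split(active, memb[active])
  unname(lapply(comps, function(x) sort(as.integer(x))))
}

# Brute-force threshold sweep: binarize at every distinct observed value,
# count components with the igraph oracle, and collapse equal-count runs.
oracle_sweep <- function(slice, adjacency) {
  values <- as.numeric(slice)
  obs <- which(!is.na(values))
  uvals <- sort(unique(values[obs]))
  counts <- vapply(uvals, function(th) {
    length(oracle_components(which(!is.na(values) & values >= th), adjacency))
  }, integer(1))
  runs <- rle(counts)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  data.frame(n_components = runs$values,
             theta_lo = uvals[starts], theta_hi = uvals[ends],
             interval_length = runs$lengths)
}

# Two-sample KS D by direct ECDF scan over the pooled support.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws.
oracle_hyper_upper <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  in_cat <- draws <= K  # categories are the first K elements of 1..N
  mean(colSums(in_cat) >= k)
}

# Exact distribution of the largest-component size on a grid with
# independent cell activation, by enumerating all 2^n cell configurations.
oracle_largest_exact <- function(p, adjacency) {
  nc <- length(adjacency)
  sizes <- 0:nc
  prob <- numeric(nc + 1L)
  for (mask in 0:(2^nc - 1L)) {
    active <- which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0L)
    comps <- oracle_components(active, adjacency)
    sz <- if (length(comps) == 0L) 0L else max(lengths(comps))
    prob[sz + 1L] <- prob[sz + 1L] +
      p^length(active) * (1 - p)^(nc - length(active))
  }
  stats::setNames(prob, sizes)
}

# Random test slice on a small grid with a bounded number of distinct
# values and optional missing cells.
random_slice <- function(n_ap, n_dv, n_distinct, missing_rate = 0.15) {
  vals <- sort(stats::runif(n_distinct))
  m <- matrix(sample(vals, n_ap * n_dv, replace = TRUE), n_ap, n_dv)
  m[stats::runif(length(m)) < missing_rate] <- NA_real_
  if (all(is.na(m))) m[1, 1] <- vals[1]
  m
}

# Small deterministic quantized slice for unit tests.
make_qslice <- function(cells, components, n_valid, gene = "g",
                        timepoint = "E11.5", theta = 0.5) {
  structure(list(gene = gene, timepoint = timepoint, theta = theta,
                 cells = as.integer(cells), components = components,
                 n_valid = as.integer(n_valid)),
            class = "quantized_slice")
}
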