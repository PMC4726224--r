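make_pool <- function(comps, spec = grid_spec()) {
  structure(comps, class = "component_pool", spec = spec)
}

comp <- function(cells, gene, tp = "E11.5", n_valid = 80L) {
  list(gene = gene, timepoint = tp, cells = as.integer(cells),
       n_valid = n_valid)
}

test_that("pooling takes components only from non-global slices and keeps tags", {
  field <- expression_field(genes = c("loc", "glob"), spec = grid_spec())
  # local gene: two patches at E11.5 (dv 2 avoids the severed roof edges)
  field$values["loc", "E11.5", 1:3, 2] <- 0.8
  field$values["loc", "E11.5", 10:12, 3] <- 0.7
  field$values["loc", "E11.5", 15:18, 4] <- 0.01
  # globally expressed gene: everything high at E13.5
  field$values["glob", "E13.5", , ] <- 0.6
  qf <- demarcate_field(field)
  st <- global_state_table(qf)
  expect_equal(st$state[st$gene == "glob"], "0100000")
  pool <- pool_components(qf, st)
  expect_length(pool, 2L)
  expect_setequal(vapply(unclass(pool), `[[`, character(1), "gene"),
                  c("loc", "loc"))
  expect_true(all(vapply(unclass(pool), `[[`, character(1), "timepoint") ==
                  "E11.5"))
  # an all-global field pools nothing
  st_all <- st; st_all[, canonical_timepoints()] <- 1L
  expect_length(pool_components(qf, st_all), 0L)
})

test_that("size filtering enforces the [min_cells, fraction * n_valid] window", {
  pool <- make_pool(list(comp(1L, "a"),                 # singleton
                         comp(1:2, "b"),
                         comp(1:41, "c"),               # 41 > 0.5 * 80
                         comp(1:40, "d")))
  kept <- filter_components(pool)
  expect_setequal(vapply(unclass(kept), `[[`, character(1), "gene"),
                  c("b", "d"))
  # identity settings keep everything
  expect_length(filter_components(pool, min_cells = 1,
                                  max_fraction_of_valid = 1), 4L)
  # the fraction applies per slice n_valid
  small <- make_pool(list(comp(1:20, "e", n_valid = 30L)))
  expect_length(filter_components(small), 0L)
})

test_that("overlap score is the Jaccard index of the cell sets", {
  a <- comp(c(1, 2), "a"); b <- comp(c(2, 3), "b")
  expect_equal(overlap_score(a, a), 1)
  expect_equal(overlap_score(comp(1:3, "a"), comp(4:6, "b")), 0)
  expect_equal(overlap_score(a, b), 1/3)
  expect_equal(overlap_score(a, b), overlap_score(b, a))
})

test_that("identical components cluster together; disjoint groups split", {
  pool <- make_pool(list(comp(1:4, "g1"), comp(1:4, "g2"), comp(1:4, "g3"),
                         comp(40:44, "h1", "P4"), comp(40:44, "h2", "P4")))
  cl <- cluster_components(pool)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$occurrence_count, 3L)
  expect_equal(cl[[1]]$gene_count, 3L)
  expect_equal(cl[[2]]$occurrence_count, 2L)
  # min_members filters reported clusters
  expect_length(cluster_components(pool, min_members = 3L), 1L)
})

test_that("clustering partitions the pool deterministically", {
  set.seed(11)
  pool <- make_pool(lapply(1:12, function(i)
    comp(sort(sample(80, sample(3:8, 1))), paste0("g", i %% 5),
         sample(canonical_timepoints(), 1))))
  cl1 <- cluster_components(pool, jaccard_min = 0.3)
  cl2 <- cluster_components(pool, jaccard_min = 0.3)
  expect_identical(cl1, cl2)
  # partition: every pool member appears in exactly one cluster
  keys <- function(cls) sort(unlist(lapply(cls, function(cl)
    vapply(cl$members, function(m)
      paste(m$gene, m$timepoint, paste(m$cells, collapse = ","), sep = "|"),
      character(1)))))
  pool_keys <- sort(vapply(unclass(pool), function(m)
    paste(m$gene, m$timepoint, paste(m$cells, collapse = ","), sep = "|"),
    character(1)))
  expect_identical(keys(cl1), pool_keys)
})

test_that("sorting ranks by occurrences then gene count, deterministically", {
  mk_cluster_pool <- function() {
    make_pool(c(
      lapply(1:10, function(i) comp(1:4, paste0("a", i))),
      lapply(1:7, function(i) comp(20:24, paste0("b", i))),
      lapply(1:7, function(i) comp(60:64, paste0("c", i %% 3), "P14"))))
  }
  cl <- cluster_components(mk_cluster_pool())
  expect_equal(cl[[1]]$occurrence_count, 10L)
  expect_equal(vapply(cl, `[[`, integer(1), "id"), 1:3)
  # equal occurrence counts: larger gene count first
  expect_equal(cl[[2]]$gene_count, 7L)
  expect_equal(cl[[3]]$gene_count, 3L)
})

test_that("frequency maps give per-cell coverage fractions", {
  pool <- make_pool(c(lapply(1:5, function(i) comp(1:3, paste0("g", i))),
                      lapply(1:5, function(i) comp(2:4, paste0("h", i)))))
  cl <- cluster_components(pool, jaccard_min = 0.4)
  expect_length(cl, 1L)
  fm <- frequency_map(cl[[1]])
  expect_equal(fm[2, 1], 1)    # cells 2 and 3 covered by all 10 members
  expect_equal(fm[1, 1], 0.5)  # cell 1 covered by half
  expect_equal(fm[5, 1], 0)
  expect_true(all(fm >= 0 & fm <= 1))
  single <- cluster_components(make_pool(list(comp(c(7, 8), "x"))))
  fms <- frequency_map(single[[1]])
  expect_equal(which(fms == 1), c(7L, 8L))
  expect_equal(sum(fms), 2)
})

test_that("time profiles count members per canonical time point", {
  pool <- make_pool(list(comp(1:3, "a", "E11.5"), comp(1:3, "b", "E11.5"),
                         comp(1:3, "c", "P28")))
  cl <- cluster_components(pool)
  expect_equal(cl[[1]]$time_profile, c(2L, 0L, 0L, 0L, 0L, 0L, 1L))
})

test_that("quasi-clique refinement splits low-coherence chains", {
  # a, b overlap; b, c overlap; a, c disjoint -> chain with low average
  pool <- make_pool(list(comp(1:6, "a"), comp(4:9, "b"), comp(7:12, "c")))
  plain <- cluster_components(pool, jaccard_min = 0.2)
  expect_length(plain, 1L)
  refined <- cluster_components(pool, jaccard_min = 0.45, refine = TRUE)
  expect_gt(length(refined), 1L)
})

test_that("no-noise planted patterns are recovered exactly as clusters", {
  cfg <- synthetic_config(n_patterns = 2L, genes_per_pattern = 10L,
                          pattern_timepoints = 1L, n_global_genes = 0L,
                          n_background_genes = 0L, jitter_sd = 0,
                          flip_rate = 0, missing_rate = 0,
                          missing_block_max = 0L, seed = 301)
  sim <- generate_field(cfg, grid_spec())
  qf <- demarcate_field(sim$field)
  pats <- find_patterns(qf, min_members = 5L)
  expect_length(pats, 2L)
  expect_equal(vapply(pats, `[[`, integer(1), "occurrence_count"),
               c(10L, 10L))
  rec <- evaluate_recovery(sim$truth, global_state_table(qf), pats)
  expect_equal(rec$pattern_jaccard, c(1, 1))
  # recovered cluster support matches the planted cells exactly
  for (p in sim$truth$patterns) {
    fm <- vapply(pats, function(cl) {
      sup <- which(cl$frequency_map == 1)
      identical(sort(sup), p$cells)
    }, logical(1))
    expect_true(any(fm))
  }
})
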