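test_that("global calls use a strict half-grid rule on the largest component", {
  q <- make_qslice(1:80, list(1:80), n_valid = 80)
  expect_equal(is_global(q), 1L)
  expect_equal(is_global(make_qslice(integer(0), list(), 80)), 0L)
  # boundary: largest component exactly half is not global
  q30 <- make_qslice(1:30, list(1:30), n_valid = 60)
  expect_equal(is_global(q30), 0L)
  q31 <- make_qslice(1:31, list(1:31), n_valid = 60)
  expect_equal(is_global(q31), 1L)
  expect_error(is_global(make_qslice(integer(0), list(), 0)), "no valid data")
})

test_that("component and count rules differ on fragmented slices", {
  # 42 expressed cells in many small components
  comps <- split(1:42, rep(1:21, each = 2))
  q <- make_qslice(1:42, unname(comps), n_valid = 80)
  expect_equal(is_global(q, rule = "component"), 0L)
  expect_equal(is_global(q, rule = "count"), 1L)
})

test_that("is_global is monotone in the largest component", {
  base <- make_qslice(1:35, list(1:35), n_valid = 70)
  grown <- make_qslice(1:40, list(1:40), n_valid = 70)
  expect_lte(is_global(base), is_global(grown))
})

test_that("state vectors assemble bits in canonical time order", {
  mk <- function(bit_tp) {
    slices <- lapply(canonical_timepoints(), function(tp) {
      if (tp %in% bit_tp) make_qslice(1:50, list(1:50), 80, timepoint = tp)
      else make_qslice(integer(0), list(), 80, timepoint = tp)
    })
    names(slices) <- canonical_timepoints()
    slices
  }
  expect_equal(unname(state_vector(mk("P14"))), c(0L,0L,0L,0L,0L,1L,0L))
  expect_equal(unname(state_vector(mk(character(0)))), rep(0L, 7))
  expect_equal(unname(state_vector(mk(canonical_timepoints()))), rep(1L, 7))
  # a time point with no data yields bit 0
  slices <- mk("E13.5")
  slices[["P4"]] <- make_qslice(integer(0), list(), 0, timepoint = "P4")
  expect_equal(unname(state_vector(slices)), c(0L,1L,0L,0L,0L,0L,0L))
})

test_that("rank_states sorts by gene count with lexicographic ties and is permutation-invariant", {
  r <- rank_states(c("0000000", "0000000", "1111111"))
  expect_equal(r$state, c("0000000", "1111111"))
  expect_equal(r$gene_count, c(2L, 1L))
  expect_equal(sum(r$gene_count), 3L)
  # ties ordered lexicographically
  r2 <- rank_states(c("0000001", "1000000", "0000010", "1000000"))
  expect_equal(r2$state[1], "1000000")
  expect_equal(r2$state[2:3], c("0000001", "0000010"))
  set.seed(7)
  states <- sample(c("0000000", "0101010", "1111111"), 50, replace = TRUE)
  expect_identical(rank_states(states), rank_states(sample(states)))
  single <- rank_states("0011000")
  expect_equal(single$gene_count, 1L)
})

test_that("ready-made rankings validate ordering and preserve printed rows", {
  expect_error(state_ranking(c("0000000", "1111111"), c(10, 20)),
               "non-increasing")
  r <- state_ranking(c("0000000", "0001111", "0000000"), c(10L, 5L, 2L))
  expect_equal(nrow(r), 3L)  # duplicate states stay as given
  expect_s3_class(r, "state_ranking")
})

test_that("rank-window bit counts work and complement to the window size", {
  r <- state_ranking(c("1111111", "0001111", "0000011", "0000000"),
                     c(40L, 30L, 20L, 10L))
  expect_equal(count_rank_window(r, 2, 4, "E18.5", 1L), 1L)
  expect_equal(count_rank_window(r, 2, 4, "E18.5", 0L), 2L)
  for (tp in canonical_timepoints()) {
    expect_equal(count_rank_window(r, 1, 4, tp, 0L) +
                 count_rank_window(r, 1, 4, tp, 1L), 4L)
  }
  expect_error(count_rank_window(r, 3, 5, "E11.5", 0L), "out of range")
  expect_error(count_rank_window(r, 1, 2, "E12", 0L), "unknown timepoint")
})

test_that("the null simulation handles degenerate probabilities and is seed-reproducible", {
  adj <- build_adjacency(grid_spec())
  n0 <- simulate_largest_component_null(0, adj, n_sims = 50, seed = 1)
  expect_true(all(n0$sizes == 0L))
  n1 <- simulate_largest_component_null(1, adj, n_sims = 20, seed = 1)
  expect_true(all(n1$sizes == 80L))  # the (severed) grid stays connected
  a <- simulate_largest_component_null(0.5, adj, n_sims = 100, seed = 42)
  b <- simulate_largest_component_null(0.5, adj, n_sims = 100, seed = 42)
  expect_identical(a$sizes, b$sizes)
  expect_error(simulate_largest_component_null(0.5, adj, n_sims = 10),
               "seed")
  # caller's RNG state is untouched
  set.seed(99); x1 <- runif(1)
  set.seed(99)
  invisible(simulate_largest_component_null(0.5, adj, n_sims = 5, seed = 3))
  expect_identical(runif(1), x1)
})

test_that("mean expressed-substructure count averages over zero-bit slices", {
  field <- expression_field(genes = c("a", "b"), spec = grid_spec())
  # gene a: 4 expressed cells at E11.5; gene b: 6 at E13.5; others empty
  field$values["a", "E11.5", 1:4, 1] <- 0.8
  field$values["a", "E11.5", 6:9, 1] <- 0.01
  field$values["b", "E13.5", 1:6, 2] <- 0.8
  field$values["b", "E13.5", 8:15, 2] <- 0.01  # n_valid 14, so 6 is not global
  qf <- demarcate_field(field)
  st <- global_state_table(qf)
  expect_true(all(st$state == "0000000"))
  m <- mean_expressed_substructures(qf, st)
  # slices with no data contribute 0; the two expressed slices give 4 and 6
  expect_equal(m$n_slices, 14L)
  expect_equal(m$mean, (4 + 6) / 14)
})
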