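line_grid <- function(n) {
  spec <- grid_spec(n_ap = n, n_dv = 1, discrepancies = NULL)
  list(spec = spec, adj = build_adjacency(spec))
}

test_that("threshold sweep reproduces the worked 1-D component-count runs", {
  g <- line_grid(7)
  s <- matrix(c(0.1, 0.5, 0.6, 0.1, 0.7, 0.8, 0.1), ncol = 1)
  runs <- sweep_thresholds(s, g$adj)
  expect_equal(vapply(runs, `[[`, integer(1), "n_components"), c(1L, 2L, 1L))
  expect_equal(vapply(runs, `[[`, numeric(1), "theta_lo"), c(0.1, 0.5, 0.7))
  expect_equal(vapply(runs, `[[`, numeric(1), "theta_hi"), c(0.1, 0.6, 0.8))
  expect_equal(vapply(runs, `[[`, integer(1), "interval_length"),
               c(1L, 2L, 2L))
  # runs tile all distinct values
  expect_equal(sort(unlist(lapply(runs, `[[`, "values"))),
               sort(unique(as.numeric(s))))
})

test_that("selection keeps the longest eligible run, ties broken toward smaller theta", {
  g <- line_grid(7)
  s <- matrix(c(0.1, 0.5, 0.6, 0.1, 0.7, 0.8, 0.1), ncol = 1)
  sel <- select_structure(sweep_thresholds(s, g$adj))
  expect_equal(sel$theta_lo, 0.5)  # {0.5,0.6} and {0.7,0.8} tie at length 2
  expect_equal(sel$n_components, 2L)
  # all observed values below the floor -> no structure
  low <- matrix(c(0.05, 0.1, 0.15), ncol = 1)
  expect_null(select_structure(sweep_thresholds(low, line_grid(3)$adj)))
  # a single eligible structure is returned as-is
  one <- matrix(c(0.5, 0.5, 0.5), ncol = 1)
  sel1 <- select_structure(sweep_thresholds(one, line_grid(3)$adj))
  expect_equal(sel1$n_components, 1L)
  expect_equal(sel1$theta_lo, 0.5)
})

test_that("floor clipping lets a straddling run compete on its in-range values", {
  g <- line_grid(6)
  # one connected run from 0.05 through 0.6: literal mode disqualifies it
  s <- matrix(c(0.05, 0.1, 0.3, 0.4, 0.5, 0.6), ncol = 1)
  runs <- sweep_thresholds(s, g$adj)
  expect_equal(length(runs), 1L)  # removing end cells never splits the line
  expect_null(select_structure(runs, clip_floor = FALSE))
  sel <- select_structure(runs, clip_floor = TRUE)
  expect_equal(sel$theta_lo, 0.3)          # smallest value >= 0.2
  expect_equal(sel$interval_length, 4L)    # 0.3, 0.4, 0.5, 0.6
  expect_equal(sel$theta_lo_unclipped, 0.05)
})

test_that("constant slices form a single all-cell component at the constant", {
  g <- line_grid(5)
  s <- matrix(rep(0.5, 5), ncol = 1)
  q <- demarcate(s, g$adj)
  expect_equal(q$theta, 0.5)
  expect_equal(q$components, list(1:5))
})

test_that("non-adjacent observed cells split and merge as the threshold crosses them", {
  spec <- grid_spec(n_ap = 3, n_dv = 1, discrepancies = NULL)
  adj <- build_adjacency(spec)
  s <- matrix(c(0.6, NA, 0.9), ncol = 1)
  runs <- sweep_thresholds(s, adj)
  expect_equal(vapply(runs, `[[`, integer(1), "n_components"), c(2L, 1L))
  expect_equal(runs[[1]]$components, list(1L, 3L))
  expect_equal(runs[[2]]$components, list(3L))
})

test_that("two-bump profile: lower bound gives two bumps, upper bound the two peaks", {
  g <- line_grid(9)
  bump <- matrix(c(0.05, 0.5, 0.9, 0.5, 0.4, 0.5, 0.9, 0.5, 0.05), ncol = 1)
  qlo <- demarcate(bump, g$adj, bound = "lower")
  expect_equal(qlo$theta, 0.5)
  expect_equal(qlo$components, list(2:4, 6:8))
  qhi <- demarcate(bump, g$adj, bound = "upper")
  expect_equal(qhi$theta, 0.9)
  expect_equal(qhi$components, list(3L, 7L))
  # upper-bound cells are nested in the lower-bound cells
  expect_true(all(qhi$cells %in% qlo$cells))
})

test_that("all-missing slices error in demarcate but are carried by demarcate_field", {
  g <- line_grid(4)
  s <- matrix(rep(NA_real_, 4), ncol = 1)
  expect_error(sweep_thresholds(s, g$adj), "no observed values")
  expect_error(demarcate(s, g$adj), "no observed values")
})

test_that("sweep matches the brute-force enumeration oracle on random slices", {
  set.seed(401)
  spec <- grid_spec(n_ap = 6, n_dv = 4, discrepancies = NULL)
  adj <- build_adjacency(spec)
  for (i in 1:120) {
    s <- random_slice(6, 4, sample(2:12, 1))
    got <- sweep_thresholds(s, adj)
    want <- oracle_sweep(s, adj)
    expect_equal(vapply(got, `[[`, integer(1), "n_components"),
                 want$n_components)
    expect_equal(vapply(got, `[[`, numeric(1), "theta_lo"), want$theta_lo)
    expect_equal(vapply(got, `[[`, numeric(1), "theta_hi"), want$theta_hi)
    expect_equal(vapply(got, `[[`, integer(1), "interval_length"),
                 want$interval_length)
    # component membership cross-checked against igraph at each theta_lo
    for (r in got) {
      active <- which(!is.na(as.numeric(s)) & as.numeric(s) >= r$theta_lo)
      expect_equal(r$components, oracle_components(active, adj))
    }
  }
})

test_that("demarcation is invariant under strictly increasing transforms", {
  set.seed(402)
  spec <- grid_spec(n_ap = 5, n_dv = 4, discrepancies = NULL)
  adj <- build_adjacency(spec)
  for (i in 1:40) {
    s <- random_slice(5, 4, sample(3:10, 1))
    # keep the floor meaningful: rank invariance holds for transforms that
    # preserve the eligibility split around min_lower, so compare with the
    # floor mapped through the same transform
    f <- function(x) x^1.7 + 0.3 * x
    q1 <- demarcate(s, adj, min_lower = 0.2)
    s2 <- s; s2[] <- f(s)
    q2 <- demarcate(s2, adj, min_lower = f(0.2))
    expect_equal(q1$cells, q2$cells)
    expect_equal(q1$components, q2$components)
  }
})

test_that("expressed sets shrink as the bound moves from lower to upper", {
  set.seed(403)
  spec <- grid_spec(n_ap = 6, n_dv = 3, discrepancies = NULL)
  adj <- build_adjacency(spec)
  for (i in 1:30) {
    s <- random_slice(6, 3, sample(4:12, 1))
    qlo <- demarcate(s, adj, bound = "lower")
    qhi <- demarcate(s, adj, bound = "upper")
    if (is.na(qlo$theta)) {
      expect_true(is.na(qhi$theta))
    } else {
      expect_true(all(qhi$cells %in% qlo$cells))
    }
    # every reported component is connected and within observed cells
    obs <- which(!is.na(as.numeric(s)))
    for (comp in qlo$components) {
      expect_true(all(comp %in% obs))
      expect_length(oracle_components(comp, adj), 1L)
    }
  }
})

test_that("demarcate_field covers every slice and records empty ones", {
  field <- expression_field(genes = c("a", "b"), spec = grid_spec())
  field$values["a", "E11.5", 1:5, 1] <- c(0.5, 0.6, 0.1, 0.7, 0.8)
  qf <- demarcate_field(field)
  expect_equal(qf$slices[["a"]][["E11.5"]]$theta, 0.5)
  expect_equal(qf$slices[["a"]][["P28"]]$n_valid, 0L)
  expect_equal(qf$slices[["b"]][["E11.5"]]$cells, integer(0))
  path <- withr::local_tempfile(fileext = ".json")
  write_quantized_json(qf, path)
  recs <- jsonlite::read_json(path)
  expect_length(recs, 2L * 7L)
})
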