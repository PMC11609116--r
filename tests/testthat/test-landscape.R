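test_that("single-funnel landscape has one minimum owning everything", {
  C <- 5
  # energy = number of +1 spins: unique LM and GM at the all-(-1) state
  E <- rowSums(state_matrix(C) == 1)
  mins <- find_minima(E, C)
  expect_equal(mins$local_minima, 1L)
  expect_equal(mins$global_minimum, 1L)
  basins <- assign_basins(E, C)
  expect_true(all(basins$basin_of == 1L))
  expect_equal(unname(basins$basin_sizes), 2^C)
  expect_error(find_minima(rep(1, 2^C), C), "degenerate")
  expect_error(find_minima(c(NA, rep(1, 2^C - 1)), C), "non-finite")
})

test_that("two symmetric ferromagnetic wells split the cube into equal basins", {
  C <- 5  # odd C: no plateau ties between the wells
  J <- matrix(0.5, C, C); diag(J) <- 0
  m <- pmem_model(rep(0, C), J)
  l <- energy_landscape(m)
  expect_setequal(l$local_minima, c(1L, 2^C))
  expect_equal(unname(l$basin_sizes), c(2^(C - 1), 2^(C - 1)))
})

test_that("minima and basins equal exhaustive brute force on random landscapes", {
  set.seed(5150)
  for (rep_i in 1:30) {
    C <- sample(3:5, 1)
    E <- rnorm(2^C)
    mins <- find_minima(E, C)
    expect_equal(mins$local_minima, brute_minima(E, C))
    expect_equal(mins$global_minimum, which.min(E))
    basins <- assign_basins(E, C)
    expect_equal(basins$basin_of, brute_basins(E, C))
    expect_equal(sum(basins$basin_sizes), 2^C)
  }
})

test_that("random walk is reproducible, flat-landscape walk always moves", {
  C <- 5
  E <- rnorm(2^C)
  w1 <- random_walk(E, C, n_steps = 500, seed = 9)
  w2 <- random_walk(E, C, n_steps = 500, seed = 9)
  expect_identical(w1$trajectory, w2$trajectory)
  # consecutive states identical or Hamming-1
  d <- vapply(seq_len(499), function(t)
    hamming(w1$trajectory[t] - 1, w1$trajectory[t + 1] - 1), numeric(1))
  expect_true(all(d %in% c(0, 1)))
  # flat landscape: acceptance probability exp(0) = 1, every proposal moves
  wf <- random_walk(rep(2, 2^C), C, n_steps = 500, seed = 10)
  df <- vapply(seq_len(499), function(t)
    hamming(wf$trajectory[t] - 1, wf$trajectory[t + 1] - 1), numeric(1))
  expect_true(all(df == 1))
})

test_that("dwell statistics match hand counts on a labelled fixture", {
  # C = 2 cube: both intermediate states neighbour both local minima and
  # descend to the global minimum "11"; basins are {00} and {01,10,11}
  E <- c(-2, -1, 1, -3)
  l <- energy_landscape(E, C = 2)
  expect_setequal(l$local_minima, c(1L, 4L))
  expect_equal(l$global_minimum, 4L)
  expect_equal(unname(l$basin_of), c(1L, 4L, 4L, 4L))
  # hand-built 12-step trajectory; owners B A B B B B B B A A B B
  traj <- c(4, 1, 2, 3, 4, 4, 2, 3, 1, 1, 2, 4)
  walk <- structure(list(trajectory = traj, start = 4, n_steps = 12L,
                         seed = NULL), class = "walk_result")
  fe <- dwell_features(walk, l)
  expect_equal(fe$gm_duration, 9)       # steps owned by the GM
  expect_equal(fe$gm_mean_dwell, 3)     # maximal runs: 1, 6, 2
  expect_equal(fe$n_LM, 2)
  expect_equal(fe$mean_gap, 1)          # E(00) - E(11) = -2 - (-3)
  expect_equal(fe$basin_size_sd, sd(c(1, 3)))
  # trajectory entirely inside the GM basin
  walk2 <- structure(list(trajectory = rep(3, 10), start = 3, n_steps = 10L,
                          seed = NULL), class = "walk_result")
  expect_equal(dwell_features(walk2, l)$gm_duration, 10)
  # alternating basins every step: mean dwell 1
  walk3 <- structure(list(trajectory = rep(c(1, 4), 6), start = 1,
                          n_steps = 12L, seed = NULL), class = "walk_result")
  fe3 <- dwell_features(walk3, l, major_states = 4)
  expect_equal(fe3$major$mean_dwell, 1)
  expect_equal(fe3$major$total, 6)
  expect_equal(fe3$major$visits, 6)
})

test_that("walk occupancy of a deepened GM does not decrease", {
  set.seed(77)
  C <- 4
  E <- rnorm(2^C)
  occ <- function(EE, seeds) {
    l <- energy_landscape(EE, C)
    mean(vapply(seeds, function(s)
      dwell_features(random_walk(l, n_steps = 2000, seed = s), l)$gm_duration,
      numeric(1)))
  }
  gm <- which.min(E)
  E_deep <- E; E_deep[gm] <- E_deep[gm] - 1
  expect_gte(occ(E_deep, 1:20), occ(E, 1:20))
})

test_that("major states are the intersection of LM sets", {
  set.seed(88)
  E1 <- rnorm(32); l1 <- energy_landscape(E1, 5)
  # identical landscapes: majors = the LM set
  mj <- find_major_states(list(l1, l1, l1))
  expect_setequal(mj$major, l1$local_minima)
  # disjoint LM sets: empty, with warning
  E2 <- -E1  # different minima generically
  l2 <- energy_landscape(E2, 5)
  if (length(intersect(l1$local_minima, l2$local_minima)) == 0) {
    expect_warning(mj2 <- find_major_states(list(l1, l2)), "no state")
    expect_length(mj2$major, 0)
  }
  # top list is sorted by selection count
  mj3 <- suppressWarnings(find_major_states(list(l1, l2), top_n = 3))
  expect_true(all(diff(mj3$top$count) <= 0))
})

test_that("planted complementary wells are recovered as major states", {
  # deep-well cohort with neutral knobs: both planted wells are sampled
  # often enough that every fitted landscape keeps them as local minima
  cfg <- cohort_config(n_per_group = 6, seed = 99,
                       group_params = list(j_in = 0.3, j_out = 0.25,
                                           h_bias = 0.1, sigma_J = 0.05,
                                           sigma_h = 0.03, h_base = 0),
                       effect_knobs = list(ruggedness = 1, coupling = 1,
                                           gm_bias = 0))
  coh <- generate_cohort(cfg, continuous = FALSE)
  lands <- lapply(coh$truth, function(p) {
    st <- empirical_stats(p$categories$fear$states)
    energy_landscape(fit_pmem(st, method = "exact"))
  })
  mj <- find_major_states(lands)
  expect_true(all(c("1111000", "0000111") %in% mj$major_labels))
})
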