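test_that("uniform Boltzmann sampling gives near-uniform state frequencies", {
  C <- 7; n <- 2e5
  st <- sample_pmem_states(rep(0, C), NULL, n, seed = 1)
  counts <- empirical_stats(st)$counts
  p <- 1 / 2^C
  # 4 binomial SDs (scaled-down n relative to the 1e6/3SD example)
  tol <- 4 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(counts / n - p) < tol))
})

test_that("strong positive fields drive the all-active state", {
  st <- sample_pmem_states(rep(5, 7), NULL, 100, seed = 2)
  # independence oracle: P(all +1) = prod sigmoid(2*5) = 0.99968^7 > 0.99
  frac <- mean(apply(st$spins, 1, function(s) all(s == 1)))
  expect_gt(frac, 0.99)
})

test_that("sample moments converge to enumerated model moments", {
  set.seed(3)
  C <- 6
  h <- rnorm(C, 0, 0.4); J <- rand_J(C, 0.3)
  st <- sample_pmem_states(h, J, 1e5, seed = 4)
  target <- model_moments(pmem_model(h, J))
  expect_lt(max(abs(empirical_stats(st)$act - target$act)), 5 / sqrt(1e5))
})

test_that("sampling then refitting recovers the generating parameters", {
  set.seed(5)
  C <- 7
  h <- runif(C, -1, 1); J <- rand_J(C, 0.3); J <- pmin(pmax(J, -1), 1)
  st <- sample_pmem_states(h, J, 1e5, seed = 6)
  fit <- fit_pmem(st, method = "exact")
  expect_lt(sqrt(mean((fit$h - h)^2)), 0.1)
  expect_lt(sqrt(mean((fit$J - J)[upper.tri(J)]^2)), 0.1)
})

test_that("spins_to_continuous round-trips and degrades gracefully with noise", {
  set.seed(7)
  spins <- matrix(sample(c(-1, 1), 200 * 3, replace = TRUE), 200, 3)
  # noiseless, unsmoothed: identity
  sig0 <- spins_to_continuous(spins, noise_sd = 0)
  expect_equal(unname(binarize(sig0)$spins), spins)
  # planted alternating spins
  alt <- matrix(rep(c(-1, 1), 50), ncol = 1)
  expect_equal(unname(binarize(spins_to_continuous(alt, noise_sd = 0))$spins),
               alt)
  # constant channel: degenerate downstream (mean threshold undefined)
  cst <- matrix(1, 100, 1)
  expect_error(binarize(spins_to_continuous(cst, noise_sd = 0)),
               "zero-variance")
  # 10% amplitude noise: recovery >= 95% at 1e4 samples
  big <- matrix(sample(c(-1, 1), 1e4 * 2, replace = TRUE), 1e4, 2)
  sig <- spins_to_continuous(big, noise_sd = 0.1, seed = 8)
  expect_gte(mean(binarize(sig)$spins == big), 0.95)
  expect_error(spins_to_continuous(matrix(numeric(0), 0, 3)), "empty")
})

test_that("cohort generation is deterministic and validated", {
  cfg <- cohort_config(n_per_group = 2, seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
  expect_error(cohort_config(n_selected = 30), "n_selected")
  expect_error(cohort_config(sampling_rate_hz = -1), "sampling_rate_hz")
  expect_error(cohort_config(noise_sd = -0.1), "noise_sd")
})

test_that("cohort recordings carry the paradigm and the planted truth", {
  cfg <- cohort_config(n_per_group = 2, seed = 10)
  coh <- generate_cohort(cfg)
  expect_length(coh$recordings, 4)
  rec <- coh$recordings[[1]]
  ann <- rec$annotations
  expect_equal(nrow(ann), 16)                   # 4 blocks x 4 trial types
  expect_equal(as.integer(table(ann$label)), rep(4L, 4))
  expect_equal(ann$duration, rep(18, 16))
  # ground truth: J symmetric with zero diagonal
  for (p in coh$truth) {
    for (cat in names(p$categories)) {
      J <- p$categories[[cat]]$params$J
      expect_equal(J, t(J))
      expect_equal(diag(J), rep(0, 7))
    }
  }
  # planted spins recovered through segment + binarize, up to the
  # documented block-B polarity gauge of the continuous embedding
  seg <- segment(rec, "fear")
  bs <- binarize(seg$signal[, cfg$informative_channels])
  pol <- c(1, 1, 1, 1, -1, -1, -1)
  rec_rate <- mean(sweep(bs$spins, 2, pol, `*`) ==
                     coh$truth[[1]]$categories$fear$states$spins)
  expect_gte(rec_rate, 0.95)
})

test_that("markov persistence keeps the marginal but adds autocorrelation", {
  st <- sample_pmem_states(rep(0, 4), NULL, 2e4, seed = 11,
                           persistence = 0.8)
  expect_lt(max(abs(empirical_stats(st)$act)), 0.05)
  same <- mean(rowSums(st$spins[-1, ] == st$spins[-2e4, ]) == 4)
  expect_gt(same, 0.5)  # sticky chain repeats states
})
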