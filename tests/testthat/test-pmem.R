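test_that("binarize thresholds at the per-channel mean with the strict tie rule", {
  expect_equal(as.vector(binarize(matrix(c(1, 3), ncol = 1))$spins), c(-1, 1))
  # equality with the threshold maps to -1
  expect_equal(as.vector(binarize(matrix(c(0, 0, 3), ncol = 1))$spins),
               c(-1, -1, 1))
  expect_error(binarize(matrix(2, nrow = 5, ncol = 1)), "zero-variance")
  sig <- cbind(a = c(1, 2, 3, 4), b = c(4, 1, 1, 4))
  bs <- binarize(sig)
  expect_equal(unname(bs$spins[, 1]), c(-1, -1, 1, 1))
  expect_equal(unname(bs$spins[, 2]), c(1, -1, -1, 1))
})

test_that("empirical statistics count states and match naive-loop moments", {
  # four samples: s_a twice, s_b, s_c
  s_a <- c(1, -1, 1); s_b <- c(-1, -1, -1); s_c <- c(1, 1, 1)
  spins <- rbind(s_a, s_a, s_b, s_c)
  st <- empirical_stats(spins)
  expect_equal(sum(st$Pe), 1)
  expect_equal(st$Pe[encode_state(s_a) + 1], 0.5)
  expect_equal(st$Pe[encode_state(s_b) + 1], 0.25)
  expect_equal(st$Pe[encode_state(s_c) + 1], 0.25)
  # single repeated state: cooc is the outer product of its spins
  st1 <- empirical_stats(rbind(s_a, s_a))
  expect_equal(unname(st1$cooc), outer(s_a, s_a))
  expect_equal(st1$Pe[encode_state(s_a) + 1], 1)
  # random series against the naive loop oracle
  set.seed(4)
  spins <- matrix(sign(rnorm(50 * 5)), 50, 5)
  st <- empirical_stats(spins)
  nv <- naive_moments(spins)
  expect_equal(unname(st$act), nv$act)
  expect_equal(unname(st$cooc), nv$cooc)
})

test_that("independent MEM closed form reproduces activation rates exactly", {
  C <- 7
  st0 <- moments_from_distribution(rep(1 / 2^C, 2^C), C)
  mem0 <- fit_independent_mem(st0)
  expect_equal(mem0$h, rep(0, C))
  expect_equal(mem0$P, rep(1 / 2^C, 2^C))
  # inverse identity
  st <- st0; st$act <- rep(tanh(0.5), C)
  expect_equal(fit_independent_mem(st)$h, rep(0.5, C))
  # arbitrary valid rates: model moments equal the targets to 1e-10
  set.seed(7)
  st$act <- runif(C, -0.8, 0.8)
  mem <- fit_independent_mem(st)
  expect_lt(max(abs(model_moments(mem)$act - st$act)), 1e-10)
  st$act[1] <- 1
  expect_error(fit_independent_mem(st), "saturated")
})

test_that("Boltzmann probabilities are normalised and gauge-invariant", {
  set.seed(11)
  for (rep_i in 1:5) {
    C <- sample(2:7, 1)
    m <- pmem_model(rnorm(C, 0, 0.5), rand_J(C, 0.4))
    expect_lt(abs(sum(m$P) - 1), 1e-12)
    # adding a constant to all energies leaves P unchanged
    P_shift <- exp(-(m$E + 3.7 - min(m$E + 3.7)))
    expect_equal(P_shift / sum(P_shift), m$P, tolerance = 1e-12)
  }
  expect_error(pmem_model(c(0, 0), matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("exact-gradient fit recovers generating parameters from exact moments", {
  set.seed(21)
  C <- 7
  h <- rnorm(C, 0, 0.3); J <- rand_J(C, 0.3)
  truth <- pmem_model(h, J)
  st <- moments_from_distribution(truth$P, C)
  fit <- fit_pmem(st, method = "exact", tol = 1e-7)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$h - h)), 1e-4)
  expect_lt(max(abs(fit$J - J)), 1e-4)
  # moment consistency at convergence
  mm <- model_moments(fit)
  expect_lt(max(abs(mm$act - st$act)), 1e-5)
  expect_lt(max(abs(mm$cooc - st$cooc)), 1e-5)
  expect_equal(fit$J, t(fit$J))
  expect_equal(diag(fit$J), rep(0, C))
})

test_that("pseudo-likelihood and exact-gradient fits agree on a large sample", {
  set.seed(31)
  C <- 6
  h <- runif(C, -0.5, 0.5); J <- rand_J(C, 0.25)
  states <- sample_pmem_states(h, J, 5e4, seed = 32)
  f_pl <- fit_pmem(states, method = "pl")
  f_ex <- fit_pmem(states, method = "exact")
  expect_lt(max(abs(f_pl$h - f_ex$h)), 0.05)
  expect_lt(max(abs(f_pl$J - f_ex$J)), 0.05)
  # null-model recovery
  states0 <- sample_pmem_states(rep(0, 5), NULL, 5e4, seed = 33)
  f0 <- fit_pmem(states0, method = "pl")
  expect_lt(max(abs(f0$h)), 0.05)
  expect_lt(max(abs(f0$J)), 0.05)
})

test_that("accuracy index matches hand-computed toy cases", {
  # C = 2, Pe = (0.4, 0.1, 0.1, 0.4): activation rates are zero, so the
  # independent fit is uniform and K1 = 0.8 log2(1.6) + 0.2 log2(0.4)
  # = 0.2780719 bits (frozen; cross-checked against the naive KL oracle).
  Pe <- c(0.4, 0.1, 0.1, 0.4)
  st <- moments_from_distribution(Pe, 2)
  mem <- fit_independent_mem(st)
  pm <- fit_pmem(st, method = "exact", tol = 1e-8)
  acc <- accuracy_index(Pe, pm, mem)
  expect_equal(acc$K1, 0.2780719, tolerance = 1e-6)
  expect_equal(acc$K1, naive_kl2(Pe, mem$P), tolerance = 1e-12)
  # C = 2 pairwise family is saturated: fits any distribution exactly
  expect_lt(acc$K2, 1e-4)
  expect_equal(acc$r, 1, tolerance = 1e-3)

  # C = 3 parity distribution (uniform on the four odd-popcount states):
  # all first and second moments vanish, so MEM = pMEM = uniform and
  # K1 = K2 = 1 bit exactly, r = 0.
  Pe3 <- numeric(8); Pe3[c(1, 2, 4, 7) + 1] <- 0.25
  st3 <- moments_from_distribution(Pe3, 3)
  expect_equal(unname(st3$act), rep(0, 3))
  mem3 <- fit_independent_mem(st3)
  pm3 <- fit_pmem(st3, method = "exact")
  acc3 <- accuracy_index(Pe3, pm3, mem3)
  expect_equal(acc3$K1, 1, tolerance = 1e-6)
  expect_equal(acc3$K2, 1, tolerance = 1e-6)
  expect_equal(acc3$r, 0, tolerance = 1e-3)
})

test_that("accuracy index is invariant to channel relabelling", {
  set.seed(41)
  C <- 5
  spins <- sample_pmem_states(rnorm(C, 0, 0.3), rand_J(C, 0.3), 3000,
                              seed = 42)$spins
  r_of <- function(sp) {
    st <- empirical_stats(sp)
    accuracy_index(st$Pe, fit_pmem(st, method = "exact"),
                   fit_independent_mem(st))$r
  }
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(r_of(spins), r_of(spins[, perm]), tolerance = 1e-6)
})

test_that("degenerate and oversized inputs are refused", {
  expect_error(empirical_stats(matrix(1, 2, 13)), "> 12")
  expect_error(fit_pmem(structure(list(), class = "lm")), "must be")
})
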