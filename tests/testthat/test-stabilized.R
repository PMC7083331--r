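# Chain with one stabilized intermediate state

test_that("stabilized occupancy matches oracles and limits", {
  tt <- c(0.1, 0.5, 1, 2, 5, 20)
  # m = 1 (k2 = k1) is the uniform chain
  g1 <- stabilized_occupancy(stabilized_chain(9, 6, 1, 1), tt)
  ge <- erlang_occupancy(1, 9, tt)
  expect_lt(max(abs(g1$probs - ge$probs)), 1e-9)
  # conservation for the (N=9, S=6, m=6) barrier scenario
  ch <- stabilized_from_energy(energy_config(10, 1), 9, 6, 6,
                               "constant_total")
  g <- stabilized_occupancy(ch, c(0.1, 1, 5, 20))
  expect_lt(max(abs(rowSums(g$probs) - 1)), 1e-8)
  # explicit instance vs direct integration (the generator is defective --
  # the repeated rate 2 makes an eigendecomposition oracle singular)
  ch2 <- stabilized_chain(4, 2, 2, 0.5)
  g2 <- stabilized_occupancy(ch2, c(1, 3))
  rates <- rep(2, 5); rates[3L] <- 0.5
  A <- matrix(0, 6, 6)
  for (i in 1:5) { A[i, i] <- -rates[i]; A[i + 1L, i] <- rates[i] }
  expect_lt(max(abs(g2$probs - ode_occupancy_oracle(A, c(1, 3)))), 1e-8)
  # randomized instances vs direct integration, incl. boundary S
  set.seed(41)
  for (i in 1:15) {
    N <- sample(2:8, 1); S <- sample(1:N, 1)
    k1 <- runif(1, 0.5, 5); k2 <- runif(1, 0.05, 0.9) * k1
    tt <- sort(runif(5, 0.05, 12))
    rates <- rep(k1, N + 1L); rates[S + 1L] <- k2
    A <- matrix(0, N + 2L, N + 2L)
    for (j in seq_len(N + 1L)) {
      A[j, j] <- -rates[j]; A[j + 1L, j] <- rates[j]
    }
    g <- stabilized_occupancy(stabilized_chain(N, S, k1, k2), tt)
    expect_lt(max(abs(g$probs - ode_occupancy_oracle(A, tt))), 1e-7)
  }
  expect_error(stabilized_chain(4, 2, 1, 2), "k2")
})

test_that("arrival to the stabilized state has the Erlang mean", {
  expect_equal(mfat_to_stabilized(stabilized_chain(9, 2, 1, 0.5)), 2)
  expect_equal(mfat_to_stabilized(stabilized_chain(9, 1, 4, 0.5)), 0.25)
  # doubling S doubles the mean at fixed k1
  expect_equal(mfat_to_stabilized(stabilized_chain(9, 8, 2, 0.5)),
               2 * mfat_to_stabilized(stabilized_chain(9, 4, 2, 0.5)))
  # the offset convention is exposed as the documented alternative
  expect_equal(mfat_to_stabilized(stabilized_chain(9, 2, 1, 0.5),
                                  convention = "offset"), 3)
  # quadrature of the Erlang(S, k1) arrival density agrees with S/k1
  S <- 6; k1 <- 1.2
  expect_equal(integrate(function(t) t * dgamma(t, S, rate = k1),
                         0, Inf)$value, S / k1, tolerance = 1e-7)
})

test_that("mean dwelling time is exactly 1/k2", {
  expect_equal(mean_dwelling_time(stabilized_chain(9, 6, 1, 1)), 1)
  expect_equal(mean_dwelling_time(stabilized_chain(9, 6, 1, 0.5)), 2)
  expect_equal(mean_dwelling_time(0.2), 5)
  expect_error(mean_dwelling_time(-1), "k2")
})

test_that("stabilized FAT density integrates to its closed-form mean", {
  ch <- stabilized_from_energy(energy_config(10, 1), 9, 6, 6,
                               "constant_total")
  fs <- stabilized_fat(ch)
  expect_equal(fs$mfat, 9 / ch$k1 + 1 / ch$k2, tolerance = 1e-12)
  expect_equal(fs$norm_quad, 1, tolerance = 1e-6)
  expect_equal(fs$mfat_quad / fs$mfat, 1, tolerance = 1e-6)
  # stabilization can only delay relative to the uniform chain at k1
  expect_gt(fs$mfat, (9 + 1) / ch$k1)
})

test_that("macrostate occupancy is invariant to stabilized placement", {
  # stabilized state at index 6 or 8, both inside the 6..10 microstate
  # macrostate: the aggregate trajectory is identical
  tt <- seq(0, 40, by = 0.25)
  en <- energy_config(10, 1)
  g6 <- stabilized_occupancy(stabilized_from_energy(en, 9, 6, 6,
                                                    "constant_total"), tt)
  g8 <- stabilized_occupancy(stabilized_from_energy(en, 9, 8, 6,
                                                    "constant_total"), tt)
  agg6 <- rowSums(g6$probs[, 6:10])
  agg8 <- rowSums(g8$probs[, 6:10])
  expect_lt(max(abs(agg6 - agg8)), 1e-9)
})

test_that("dwelling time and MFAT surfaces behave with m and the barrier", {
  m_grid <- c(1, 2, 4, 6, 8)
  dE_grid <- c(2, 4, 6, 10)
  sw <- stabilized_sweep(9, 6, m_grid, dE_grid, case = "constant_total")
  # m = 1 column equals the uniform chain MFAT for all barriers
  u <- sw[sw$m == 1, ]
  expect_equal(u$mfat_m, 10 / exp(-u$delta_E / 10), tolerance = 1e-12)
  # non-decreasing in m at fixed barrier and vice versa
  for (dd in dE_grid) {
    s <- sw[sw$delta_E == dd, ]
    expect_true(all(diff(s$dwell_time) >= 0))
    expect_true(all(diff(s$mfat_m) >= 0))
  }
  for (mm in m_grid) {
    s <- sw[sw$m == mm, ]
    expect_true(all(diff(s$dwell_time) >= 0))
    expect_true(all(diff(s$mfat_m) >= 0))
  }
  # dwell time strictly increasing in m at dE = 10 (constant-total)
  s10 <- sw[sw$delta_E == 10, ]
  expect_true(all(diff(s10$dwell_time) > 0))
  # varying-total case has the larger dynamic range
  swv <- stabilized_sweep(9, 6, 6, 10, case = "varying_total")
  swc <- stabilized_sweep(9, 6, 6, 10, case = "constant_total")
  expect_gt(swv$mfat_m, swc$mfat_m)
  expect_gt(swv$dwell_time, swc$dwell_time)
})
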