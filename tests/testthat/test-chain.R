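# Linear-chain occupancy, FAT/MFAT, and the MFAT surface

test_that("three-state closed form matches hand values and the ODE oracle", {
  g <- three_state_occupancy(0.6657, 0.4908, c(0, 1, 100))
  expect_equal(unname(g$probs[1L, ]), c(1, 0, 0))
  expect_equal(unname(g$probs[2L, 1L]), exp(-0.6657), tolerance = 1e-12)
  expect_equal(unname(g$probs[3L, ]), c(0, 0, 1), tolerance = 1e-6)
  validate_occupancy(g)
  # against direct integration, including the k1 = k2 confluent limit
  for (ks in list(c(0.6657, 0.4908), c(1.3, 1.3), c(2, 1.999999999))) {
    tt <- c(0.2, 0.7, 1.9, 6)
    A <- matrix(c(-ks[1], ks[1], 0, 0, -ks[2], ks[2], 0, 0, 0), 3, 3)
    orc <- ode_occupancy_oracle(A, tt)
    g <- three_state_occupancy(ks[1], ks[2], tt)
    expect_lt(max(abs(g$probs - orc)), 1e-7)
  }
  expect_error(three_state_occupancy(0, 1, 0:2), "k1")
})

test_that("Erlang chain occupancy conserves probability and stays finite", {
  g <- erlang_occupancy(1, 9, c(0, 2))
  expect_equal(unname(g$probs[2L, 3L]), 2 * exp(-2), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    k <- runif(1, 0.1, 8); N <- sample(0:12, 1)
    tt <- sort(runif(4, 0, 20))
    g <- erlang_occupancy(k, N, tt)
    expect_lt(max(abs(rowSums(g$probs) - 1)), 1e-10)
    expect_true(all(diff(g$probs[, N + 2L]) >= -1e-12))  # p_M monotone
  }
  # kt far beyond the overflow point of direct factorial evaluation
  g <- erlang_occupancy(10, 200, c(100, 500))  # kt up to 5000
  expect_true(all(is.finite(g$probs)))
  expect_lt(max(abs(rowSums(g$probs) - 1)), 1e-8)
})

test_that("reversible solver agrees with eigen and deSolve oracles", {
  tt <- c(0.3, 1, 2.5, 6)
  # 3-state vs eigendecomposition
  g <- reversible_occupancy(1, 0.5, 3, tt)
  A <- matrix(c(-1, 1, 0, 0.5, -1.5, 1, 0, 0, 0), 3, 3)
  expect_lt(max(abs(g$probs - eigen_occupancy_oracle(A, tt))), 1e-8)
  # k_bwd = 0 reduces to the Erlang chain
  g0 <- reversible_occupancy(2, 0, 6, tt)
  ge <- erlang_occupancy(2, 4, tt)
  expect_lt(max(abs(g0$probs - ge$probs)), 1e-7)
  # random instances vs stiff integration of the same generator
  set.seed(21)
  for (i in 1:10) {
    kf <- runif(1, 0.2, 6); kb <- runif(1, 0, 4); n <- sample(3:9, 1)
    g <- reversible_occupancy(kf, kb, n, tt)
    expect_lt(max(abs(rowSums(g$probs) - 1)), 1e-8)
    A <- emtkinetics:::reversible_generator(kf, kb, n)
    expect_lt(max(abs(g$probs - ode_occupancy_oracle(A, tt))), 1e-7)
    # M is absorbing, so p_M is monotone even with backward flow
    gm <- reversible_occupancy(kf, kb, n, seq(0, 10, by = 0.25))
    expect_true(all(diff(gm$probs[, n]) >= -1e-10))
  }
})

test_that("chain FAT density is Erlang with mean (N+1)/k", {
  expect_equal(fat_mfat_chain(1, 0)$mfat, 1)
  fs <- fat_mfat_chain(3.4261, 9)
  expect_equal(fs$mfat, 10 / 3.4261, tolerance = 1e-12)
  expect_equal(fs$mfat_quad, fs$mfat, tolerance = 1e-6)
  for (N in c(0, 3, 10, 20)) for (k in c(0.1, 1, 10)) {
    fs <- fat_mfat_chain(k, N)
    expect_equal(fs$norm_quad, 1, tolerance = 1e-6)
    expect_equal(fs$mfat_quad / fs$mfat, 1, tolerance = 1e-6)
  }
  # f_M equals the time derivative of p_M (central differences)
  k <- 1.7; N <- 5
  tt <- seq(0.05, 12, by = 1e-3)
  pM <- erlang_occupancy(k, N, tt)$probs[, N + 2L]
  dpM <- diff(pM) / diff(tt)
  tm <- (tt[-1L] + tt[-length(tt)]) / 2
  expect_lt(max(abs(dpM - dgamma(tm, N + 1, rate = k))), 1e-5)
})

test_that("MFAT vs N_int has an interior minimum tracking the barrier", {
  # brute-force scan oracle over N_int = 0..100
  for (dE in c(4, 6, 10, 12)) {
    surf <- mfat_surface(dE, 0:100)
    am <- surf$argmin$N_int_min
    expect_gt(am, 0)
    expect_lt(am, 100)
    expect_lte(abs(am + 1 - dE), 1)  # continuous relaxation x* = dE
    # U-shape: endpoints above the minimum
    expect_gt(surf$table$mfat[surf$table$N_int == 0],
              surf$argmin$mfat_min)
  }
  # small barrier: monotone increasing, no interior minimum
  s <- mfat_surface(0.1, 0:30)
  expect_true(all(diff(s$table$mfat[order(s$table$N_int)]) > 0))
  s05 <- mfat_surface(0.5, 0:30)
  expect_true(all(diff(s05$table$mfat[order(s05$table$N_int)]) > 0))
  # calibrated surface value: MFAT(dE=10, N=9) = 10 / 3.4261
  sc <- mfat_surface(10, 9, cal = calibration_spec())
  expect_equal(sc$table$mfat, 10 / 3.4261, tolerance = 1e-12)
})
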