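# Arrhenius rate assignment and topology splitting

test_that("calibrate_k0 inverts the even-split relation", {
  # frozen oracle values: k_fit * exp(dE / (N_fit + 1))
  expect_equal(calibrate_k0(0), 3.4261)
  expect_equal(calibrate_k0(10), 3.4261 * exp(1), tolerance = 1e-12)
  expect_equal(calibrate_k0(5), 5.6486839455457,
               tolerance = 1e-12)  # 3.4261 * exp(0.5), high-precision oracle
  # round trip: chain rate at (dE, N_fit) recovers k_fit to machine precision
  for (dE in c(0.3, 2, 7.5, 15)) {
    k0 <- calibrate_k0(dE)
    k <- step_rates(energy_config(dE, k0),
                    topology_spec("chain", N_int = 9))$step_rates[1L]
    expect_equal(k, 3.4261, tolerance = 1e-12)
  }
  expect_error(calibrate_k0(-1), "delta_E")
})

test_that("step_rates implements the even and stabilized barrier splits", {
  # dE = 0: every rate equals k0
  ra0 <- step_rates(energy_config(0, 1), topology_spec("chain", N_int = 3))
  expect_equal(ra0$step_rates, rep(1, 4))
  # calibrated chain reproduces the fitted step rate
  ra <- step_rates(energy_config(10, calibrate_k0(10)),
                   topology_spec("chain", N_int = 9))
  expect_equal(ra$step_rates, rep(3.4261, 10), tolerance = 1e-12)
  # stabilized, constant-total: k1 = e^{-10/15}, k2 = e^{-4}
  ras <- step_rates(energy_config(10, 1), topology_spec("chain", N_int = 9),
                    stabilized_spec(6, 6, "constant_total"))
  expect_equal(ras$k1, exp(-10 / 15), tolerance = 1e-14)
  expect_equal(ras$k2, exp(-4), tolerance = 1e-14)
  expect_equal(ras$step_rates[7L], ras$k2)  # exit of the 6th intermediate
  # varying-total keeps regular steps at the even split
  rav <- step_rates(energy_config(10, 1), topology_spec("chain", N_int = 9),
                    stabilized_spec(6, 6, "varying_total"))
  expect_equal(rav$k1, exp(-1), tolerance = 1e-14)
  expect_equal(rav$k2, exp(-6), tolerance = 1e-14)
  # parallel and layered aggregates
  rap <- step_rates(energy_config(6, 1),
                    topology_spec("parallel", N_int = 9, N_pth = 2))
  expect_equal(rap$step_rates, exp(-6 / (c(4, 5) + 1)), tolerance = 1e-14)
  expect_equal(rap$k_A, sum(rap$step_rates))
  ral <- step_rates(energy_config(5, 1),
                    topology_spec("layered", N_int = 9, N_ly = 3))
  expect_equal(ral$k, exp(-5 / 4), tolerance = 1e-14)
  expect_equal(ral$k_A, 3 * ral$k)
  expect_error(stabilized_spec(6, 0.5), "m")
})

test_that("per-step barriers add back to the total along every path", {
  k0 <- 2.3
  for (N in c(1, 4, 9)) for (dE in c(0.5, 3, 11)) {
    ra <- step_rates(energy_config(dE, k0), topology_spec("chain", N_int = N))
    expect_equal(sum(-log(ra$step_rates / k0)), dE, tolerance = 1e-12)
    # stabilized constant-total: barriers still sum to dE
    if (N >= 2) {
      ras <- step_rates(energy_config(dE, k0),
                        topology_spec("chain", N_int = N),
                        stabilized_spec(2, 3.5, "constant_total"))
      expect_equal(sum(-log(ras$step_rates / k0)), dE, tolerance = 1e-12)
      # varying-total: total grows by (m-1) dE / (N+1)
      rav <- step_rates(energy_config(dE, k0),
                        topology_spec("chain", N_int = N),
                        stabilized_spec(2, 3.5, "varying_total"))
      expect_equal(sum(-log(rav$step_rates / k0)),
                   dE + (3.5 - 1) * dE / (N + 1), tolerance = 1e-12)
    }
    # parallel: every root-to-absorbing path crosses dE
    if (N >= 3) {
      rap <- step_rates(energy_config(dE, k0),
                        topology_spec("parallel", N_int = N, N_pth = 3))
      for (i in seq_along(rap$path_sizes)) {
        per_step <- -log(rap$step_rates[i] / k0)
        expect_equal(per_step * (rap$path_sizes[i] + 1), dE,
                     tolerance = 1e-12)
      }
    }
  }
  # determinism: identical specs give identical assignments
  a <- step_rates(energy_config(7, 1.1),
                  topology_spec("parallel", N_int = 8, N_pth = 3))
  b <- step_rates(energy_config(7, 1.1),
                  topology_spec("parallel", N_int = 8, N_pth = 3))
  expect_identical(a, b)
})

test_that("path and layer splitting follow the near-equal rules", {
  expect_identical(split_paths(9, 2), c(4L, 5L))
  expect_identical(split_paths(9, 1), 9L)
  expect_identical(split_paths(10, 4), c(2L, 2L, 3L, 3L))
  expect_identical(split_layers(9, 3)$sizes, c(3L, 3L, 3L))
  expect_identical(split_layers(15, 4)$sizes, c(4L, 4L, 4L, 3L))
  expect_identical(split_layers(15, 4)$N_L1, 4L)
  expect_identical(split_layers(9, 9)$sizes, rep(1L, 9))
  # properties over a grid
  for (N in 1:12) for (b in 1:N) {
    sp <- split_paths(N, b)
    expect_equal(sum(sp), N)
    expect_lte(diff(range(sp)), 1L)
    expect_true(all(diff(sp) >= 0))
    sl <- split_layers(N, b)
    expect_equal(sum(sl$sizes), N)
    expect_lte(diff(range(sl$sizes)), 1L)
    expect_identical(sl$N_L1, as.integer(ceiling(N / b)))
  }
  expect_error(split_paths(3, 4), "N_pth")
  expect_error(split_layers(3, 4), "N_ly")
})
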