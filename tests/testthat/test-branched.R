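# Parallel-path and layered kinetics

test_that("single-path and single-state-per-layer cases reduce to the chain", {
  en <- energy_config(4, 1.3)
  ps <- parallel_kinetics(9, en)
  fs <- fat_mfat_chain(1.3 * exp(-4 / 10), 9)
  expect_equal(ps$fat$mfat, fs$mfat, tolerance = 1e-9)
  expect_equal(ps$fat$density, fs$density, tolerance = 1e-9)
  lsol <- layered_kinetics(9, 9, en)  # N_L1 = 1
  fsl <- fat_mfat_chain(1.3 * exp(-4 / 10), 9)
  expect_equal(lsol$fat$mfat, fsl$mfat, tolerance = 1e-9)
})

test_that("parallel occupancy matches direct integration of the wired system", {
  set.seed(31)
  for (i in 1:12) {
    N <- sample(2:6, 1); b <- sample(2:min(3, N), 1)
    dE <- runif(1, 0, 8); k0 <- runif(1, 0.5, 3)
    en <- energy_config(dE, k0)
    tt <- sort(runif(5, 0.05, 15))
    ps <- parallel_kinetics(split_paths(N, b), en, times = tt)
    topo <- topology_spec("parallel", N_int = N, N_pth = b)
    sys <- build_transition_system(topo, step_rates(en, topo))
    orc <- ode_occupancy_oracle(generator_from_system(sys), tt)
    expect_lt(max(abs(ps$occupancy$probs - orc)), 1e-7)
    validate_occupancy(ps$occupancy)
  }
})

test_that("layered occupancy matches layer-aggregated direct integration", {
  set.seed(32)
  for (i in 1:10) {
    N <- sample(3:6, 1); nly <- sample(1:N, 1)
    dE <- runif(1, 0, 8)
    en <- energy_config(dE, 1)
    tt <- sort(runif(5, 0.05, 15))
    lsol <- layered_kinetics(N, nly, en, times = tt)
    topo <- topology_spec("layered", N_int = N, N_ly = nly)
    sys <- build_transition_system(topo, step_rates(en, topo))
    orc <- ode_occupancy_oracle(generator_from_system(sys), tt)
    # aggregate oracle states by layer
    sizes <- split_layers(N, nly)$sizes
    grp <- c(1L, rep(seq_along(sizes) + 1L, sizes), nly + 2L)
    agg <- t(apply(orc, 1L, function(r) tapply(r, grp, sum)))
    expect_lt(max(abs(lsol$occupancy$probs - agg)), 1e-7)
    validate_occupancy(lsol$occupancy)
  }
})

test_that("branched MFAT closed forms agree with quadrature and hand values", {
  # two single-state paths at dE = 0: 1/k_A + 1/k = 1.5 days
  ps <- parallel_kinetics(c(1, 1), energy_config(0, 1))
  expect_equal(ps$fat$mfat, 1.5)
  expect_equal(ps$fat$mfat_quad, 1.5, tolerance = 1e-6)
  # normalization across barriers for the (9, 2) split
  for (dE in c(1, 6, 12)) {
    ps <- parallel_kinetics(split_paths(9, 2), energy_config(dE, 1))
    expect_equal(ps$fat$norm_quad, 1, tolerance = 1e-6)
    expect_equal(ps$fat$mfat_quad / ps$fat$mfat, 1, tolerance = 1e-6)
  }
  # layered (3 layers of 3, k = 1): 3 + 1/3 days
  lsol <- layered_kinetics(9, 3, energy_config(0, 1))
  expect_equal(lsol$fat$mfat, 3 + 1 / 3, tolerance = 1e-12)
  expect_equal(lsol$fat$mfat_quad / lsol$fat$mfat, 1, tolerance = 1e-6)
})

test_that("parallel and layered MFAT curves cross once for comparable topologies", {
  ct <- compare_topologies(15, 4, seq(0.01, 30, by = 0.01))
  expect_equal(nrow(ct$crossings), 1L)
  below <- ct$table$delta_E < ct$crossings$lower
  above <- ct$table$delta_E > ct$crossings$upper
  expect_true(all(ct$table$diff[below] < 0))  # parallel faster at low dE
  expect_true(all(ct$table$diff[above] > 0))  # layered faster at high dE
  # both curves strictly increase with the barrier
  expect_true(all(diff(ct$table$mfat_parallel) > 0))
  expect_true(all(diff(ct$table$mfat_layered) > 0))
  # degenerate two-branch, two-state case: both means equal 1.5 at dE = 0
  ps <- parallel_kinetics(c(1, 1), energy_config(0, 1))
  lsol <- layered_kinetics(2, 1, energy_config(0, 1))  # N_L1 = 2, one layer
  expect_equal(ps$fat$mfat, lsol$fat$mfat)
})

test_that("minimum-over-branches MFAT is non-increasing in N_int", {
  min_mfat <- function(variant, N, dE) {
    min(vapply(seq_len(N), function(nb) {
      if (variant == "parallel") {
        ki <- exp(-dE / (split_paths(N, nb) + 1))
        (1 + N) / sum(ki)
      } else {
        sl <- split_layers(N, nb)
        (nb + 1 / sl$N_L1) / exp(-dE / (nb + 1))
      }
    }, numeric(1L)))
  }
  # non-increasing up to the granularity of the integer branch split:
  # uneven path sizes produce sub-percent upticks at a few N_int (the
  # continuous trend is strictly decreasing)
  for (v in c("parallel", "layered")) {
    dE <- if (v == "parallel") 6 else 5
    curve <- vapply(2:20, min_mfat, numeric(1L), variant = v, dE = dE)
    expect_true(all(diff(curve) <= 5e-3 * curve[-length(curve)]))
    expect_lt(curve[length(curve)], curve[1L])
  }
})
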