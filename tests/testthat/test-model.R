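test_that("plk1 activity is linear in the inhibition fraction", {
  expect_equal(plk1_activity(0, 7.3), 0)
  expect_equal(plk1_activity(1, 4), 4)
  expect_equal(plk1_activity(0.5, 4), 2)
  expect_error(plk1_activity(1.2, 4), "f_plk1")
  expect_error(plk1_activity(-0.1, 4), "f_plk1")
})

test_that("cdc25 equations match hand-expanded values and conserve mass", {
  # no flux when everything sits in the unphosphorylated pool with no kinase
  p0 <- toy_params(k_cdk1_cdc25 = 1, k_plk1_cdc25 = 1, f_plk1 = 0,
                   cyca_cdk2_tot = 0)
  s0 <- network_state(cdc25 = 1, cdc25pp = 0, cycbcdk1 = 0, wee1 = 1,
                      pp2ab55 = 0, subp = 0)
  d0 <- cdc25_rhs(s0, p0)
  expect_equal(unname(d0), c(0, 0))

  # k_PPX = 1, k_B55 = 2, b55 = 0.5, k_Cdk1 = 1, v = 1, k_Plk1 = 1,
  # plk1 = 2, cdc25 = 0.2, cdc25pp = 0.3 (so cdc25p = 0.5):
  # dephos = 1 + 2*0.5 = 2, phos = 1*1 + 1*2 = 3
  # d cdc25 = 2*0.5 - 3*0.2 = 0.4; d cdc25pp = -2*0.3 + 3*0.5 = 0.9
  p <- toy_params()
  s <- network_state(cdc25 = 0.2, cdc25pp = 0.3, cycbcdk1 = 1, wee1 = 0,
                     pp2ab55 = 0.5, subp = 0)
  d <- cdc25_rhs(s, p)
  expect_equal(unname(d), c(0.4, 0.9))

  # the three cdc25 forms are conserved: d/dt of the mono form balances
  for (i in 1:10) {
    set.seed(i)
    x <- stats::runif(2, 0, 0.5)
    si <- network_state(cdc25 = x[1], cdc25pp = x[2],
                        cycbcdk1 = stats::runif(1), wee1 = 0,
                        pp2ab55 = stats::runif(1), subp = 0)
    di <- cdc25_rhs(si, p)
    d_mono <- -sum(di)  # conservation forces the implicit pool derivative
    expect_lt(abs(di[[1]] + di[[2]] + d_mono), 1e-12)
  }

  expect_error(cdc25_rhs(network_state(cdc25 = 0.8, cdc25pp = 0.5,
                                       cycbcdk1 = 0, wee1 = 0,
                                       pp2ab55 = 0, subp = 0), p),
               "conservation")
})

test_that("substrate equation matches hand-expanded values", {
  # saturated substrate with no phosphatase: zero flux
  p <- toy_params(k_b55_sub = 0)
  s <- network_state(cdc25 = 1, cdc25pp = 0, cycbcdk1 = 0.7, wee1 = 0,
                     pp2ab55 = 1, subp = 1)
  expect_equal(substrate_rhs(s, p), 0)

  # k_Cdk1,Sub = 1, v = 2, sub_tot = 1, subp = 0.25, k_B55,Sub = 1,
  # b55 = 1 -> 2 * 0.75 - 0.25 = 1.25
  p2 <- toy_params(cycbcdk1_tot = 2)
  s2 <- network_state(cdc25 = 1, cdc25pp = 0, cycbcdk1 = 2, wee1 = 0,
                      pp2ab55 = 1, subp = 0.25)
  expect_equal(substrate_rhs(s2, p2), 1.25)
})

test_that("reduced mode with zero clamps and no PLK1 gives zero flux", {
  p <- toy_params(f_plk1 = 0, cyca_cdk2_tot = 0)
  s <- network_state(cdc25 = 1, cdc25pp = 0, cycbcdk1 = 0, wee1 = 1,
                     pp2ab55 = 0, subp = 0)
  d <- network_rhs(s, p, reduced = TRUE,
                   clamp = list(v_cdk1 = 0, pp2ab55 = 0))
  expect_equal(unname(d), rep(0, 6))
})

test_that("clamped substrate kinetics reproduce the exponential closed form", {
  # v clamped at 1, no phosphatase: subp(t) = sub_tot (1 - exp(-k v t))
  p <- toy_params(k_b55_sub = 0, k_cdk1_sub = 1, f_plk1 = 0,
                  cyca_cdk2_tot = 0)
  tr <- simulate_cell(p, horizon = 2, output_step = 0.01, reduced = TRUE,
                      clamp = list(v_cdk1 = 1, pp2ab55 = 0))
  expected <- 1 - exp(-tr$times)
  i <- tr$times > 0.05
  expect_lt(max(abs(tr$states[i, "subp"] - expected[i]) / expected[i]), 1e-6)

  # threshold crossing at 30%: t = ln(10/7)
  expect_equal(tr$nebd_time, log(10 / 7), tolerance = 1e-4)
})

test_that("reduced cdc25 subsystem matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  p <- toy_params(k_ppx_y15 = 0.7, k_b55_cdc25 = 1.3, k_cdk1_cdc25 = 2,
                  k_plk1_cdc25 = 0.5, cyca_cdk2_tot = 1.5)
  vclamp <- 0.4
  bclamp <- 0.6
  kin <- p$k_cdk1_cdc25 * vclamp + p$k_plk1_cdc25 * p$f_plk1 * p$cyca_cdk2_tot
  ph <- p$k_ppx_y15 + p$k_b55_cdc25 * bclamp
  # linear system over (cdc25, cdc25p, cdc25pp)
  A <- matrix(c(-kin, ph, 0,
                kin, -(ph + kin), ph,
                0, kin, -ph), 3, 3, byrow = TRUE)
  y0 <- c(1, 0, 0)
  tr <- simulate_cell(p, horizon = 3, output_step = 0.25, reduced = TRUE,
                      clamp = list(v_cdk1 = vclamp, pp2ab55 = bclamp),
                      init = network_state(cdc25 = 1, cdc25pp = 0,
                                           cycbcdk1 = vclamp, wee1 = 0,
                                           pp2ab55 = bclamp, subp = 0))
  for (i in seq_along(tr$times)) {
    yt <- as.numeric(Matrix::expm(A * tr$times[i]) %*% y0)
    expect_equal(unname(tr$states[i, "cdc25"]), yt[1], tolerance = 1e-8)
    expect_equal(unname(tr$states[i, "cdc25pp"]), yt[3], tolerance = 1e-8)
  }
})

test_that("no cdk2-cyclin A input means no NEBD", {
  p <- default_params(f_plk1 = 1, cyca_cdk2_tot = 0)
  tr <- simulate_cell(p, horizon = 5, output_step = 0.05)
  expect_true(tr$censored)
  expect_true(is.na(tr$nebd_time))
})

test_that("substrate fraction equals the threshold at the declared NEBD time", {
  p <- default_params()
  tr <- simulate_cell(p, horizon = 10)
  expect_false(tr$censored)
  frac_at <- stats::approx(tr$times, tr$states[, "sub_frac"],
                           xout = tr$nebd_time)$y
  expect_equal(frac_at, 0.30, tolerance = 1e-6)
})

test_that("NEBD detection interpolates linearly and handles censoring", {
  traj <- list(times = c(2, 3),
               states = cbind(sub_frac = c(0.28, 0.32)))
  expect_equal(detect_nebd(traj, 0.30), 2.5)
  low <- list(times = 0:5, states = cbind(sub_frac = rep(0.1, 6)))
  expect_true(is.na(detect_nebd(low, 0.30)))
  bad <- list(times = c(1, 1, 2), states = cbind(sub_frac = c(0, 1, 1)))
  expect_error(detect_nebd(bad, 0.3), "increasing")
  expect_error(detect_nebd(list(times = 1, states = cbind(sub_frac = 1)),
                           0.3), "2 samples")
})

test_that("trajectories conserve cdc25 pools and stay in bounds", {
  for (f in c(0, 1)) {
    p <- default_params(f_plk1 = f)
    tr <- simulate_cell(p, horizon = 6, output_step = 0.05)
    total <- tr$states[, "cdc25"] + tr$states[, "cdc25pp"]
    mono <- p$cdc25_tot - total
    expect_true(all(mono >= -1e-7))
    expect_true(all(total <= p$cdc25_tot + 1e-7))
    expect_true(all(tr$states[, "subp"] >= -1e-7 &
                      tr$states[, "subp"] <= p$sub_tot + 1e-7))
    expect_true(all(tr$states[, "cycbcdk1"] >= -1e-7 &
                      tr$states[, "cycbcdk1"] <= p$cycbcdk1_tot + 1e-7))
    expect_true(all(tr$states[, "pp2ab55"] >= -1e-7))
  }
})

test_that("more plk1 activity never delays NEBD (dose monotonicity)", {
  doses <- c(0, 0.25, 0.5, 0.75, 1)
  nebd <- vapply(doses, function(f) {
    simulate_cell(default_params(f_plk1 = f), horizon = 24,
                  output_step = 0.02, stop_at_nebd = TRUE)$nebd_time
  }, 0)
  expect_false(anyNA(nebd))
  expect_true(all(diff(nebd) <= 1e-6))
})

test_that("parameter validation rejects invalid values", {
  expect_error(default_params(f_plk1 = 2), "f_plk1")
  expect_error(toy_params(k_ppx_y15 = -1), "non-negative")
  expect_error(kinetic_params(1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                              nebd_threshold = 1.2), "nebd_threshold")
})

test_that("parameter sets round-trip through JSON", {
  p <- default_params(f_plk1 = 0.5, cyca_cdk2_tot = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(list(main = p), path)
  back <- read_params(path)$main
  expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
})
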