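test_that("time course relaxes to the closed-form steady state", {
  m <- pathway_model(v_in = 0.35, vmax = 0.7, k_half = 1, mu = 0.1)
  tc <- simulate_timecourse(m, t_end = 500, n_points = 51L)
  # half-saturating influx forces S* = k_half; P* = flux / mu
  expect_equal(tc$S[51L], 1.0, tolerance = 1e-6)
  expect_equal(tc$P[51L], 3.5, tolerance = 1e-6)
  expect_true(all(tc$S >= 0 & tc$P >= 0))

  tc0 <- simulate_timecourse(pathway_model(0, 0.7, 1, 0.1), t_end = 10)
  expect_true(all(tc0$S == 0 & tc0$P == 0))
})

test_that("influx above enzyme capacity diverges at rate v_in - vmax", {
  m <- pathway_model(v_in = 0.4, vmax = 0.02, k_half = 1, mu = 0.1)
  tc <- simulate_timecourse(m, t_end = 2000, n_points = 21L)
  slope <- diff(tc$S[20:21]) / diff(tc$time[20:21])
  expect_equal(slope, 0.38, tolerance = 1e-3)
  ss <- steady_state(m)
  expect_false(ss$feasible)
  expect_equal(ss$flux, 0.02)  # vmax asymptote reported
})

test_that("closed-form steady state matches its textbook values", {
  ss <- steady_state(pathway_model(0.35, 0.7, 1, 0.1))
  expect_equal(ss$s_star, 1.0)
  expect_equal(ss$flux, 0.35)
  expect_equal(ss$p_star, 3.5)
  # near-capacity influx: S* = K * v / (Vmax - v) blows up
  expect_equal(steady_state(pathway_model(0.39, 0.4, 1, 0.1))$s_star, 39.0)
  # mu = 0 with positive flux: product pool has no steady state
  ss0 <- steady_state(pathway_model(0.1, 0.5, 2, 0))
  expect_true(ss0$feasible)
  expect_false(ss0$p_defined)
  expect_true(is.na(ss0$p_star))
})

test_that("closed form and long ODE integration agree over random parameters", {
  set.seed(42)
  for (i in 1:25) {
    vmax <- 10^runif(1, -3, 3)
    k <- 10^runif(1, -3, 3)
    mu <- 10^runif(1, -3, 3)
    v_in <- runif(1, 0.05, 0.95) * vmax
    m <- pathway_model(v_in, vmax, k, mu)
    cf <- steady_state(m)
    ode <- ode_steady_state(m)
    expect_equal(ode$s_star, cf$s_star, tolerance = 1e-6)
    expect_equal(ode$flux, cf$flux, tolerance = 1e-6)
    expect_equal(ode$p_star, cf$p_star, tolerance = 1e-6)
  }
})

test_that("steady-state mass balance: influx = conversion = dilution", {
  set.seed(7)
  for (i in 1:20) {
    m <- pathway_model(v_in = runif(1, 0.01, 0.9), vmax = 1,
                       k_half = 10^runif(1, -2, 2), mu = 10^runif(1, -2, 1))
    ss <- steady_state(m)
    conv <- mm_rate(ss$s_star, m$vmax, m$k_half)
    expect_equal(conv, m$v_in, tolerance = 1e-9)
    expect_equal(ss$p_star * m$mu, ss$flux, tolerance = 1e-9)
  }
})

test_that("substrate dilution mode solves the quadratic balance", {
  m <- pathway_model(0.35, 0.7, 1, 0.1, dilute_intermediate = TRUE)
  ss <- steady_state(m)
  # balance: v_in = MM(S*) + mu * S*
  expect_equal(mm_rate(ss$s_star, m$vmax, m$k_half) + m$mu * ss$s_star,
               m$v_in, tolerance = 1e-9)
  expect_lt(ss$s_star, 1.0)  # extra drain lowers S* below the undiluted case
  ode <- ode_steady_state(m)
  expect_equal(ode$s_star, ss$s_star, tolerance = 1e-6)
  # with dilution, influx above vmax is still feasible
  m2 <- pathway_model(1.2, 0.7, 1, 0.1, dilute_intermediate = TRUE)
  ss2 <- steady_state(m2)
  expect_true(ss2$feasible)
  expect_equal(mm_rate(ss2$s_star, 0.7, 1) + 0.1 * ss2$s_star, 1.2,
               tolerance = 1e-9)
})

test_that("design scan tabulates feasible and infeasible regions", {
  base <- pathway_model(0.1, 1, 1, 0.4)
  scan <- design_scan(base, c(0.02, 0.4, 0.7), seq(0.01, 0.4, by = 0.01))
  expect_equal(nrow(scan), 3L * 40L)

  row <- scan[scan$vmax == 0.7 & abs(scan$v_in - 0.35) < 1e-12, ]
  expect_equal(row$s_star, 1.0)
  expect_equal(row$saturation_fraction, 0.5)

  low <- scan[scan$vmax == 0.02, ]
  expect_identical(low$feasible, low$v_in < 0.02)

  feas <- scan[scan$feasible, ]
  expect_true(all(feas$saturation_fraction >= 0 & feas$saturation_fraction <= 1))
  expect_true(all(feas$flux < feas$vmax))
  for (vm in unique(feas$vmax)) {
    sub <- feas[feas$vmax == vm, ]
    sub <- sub[order(sub$v_in), ]
    expect_true(all(diff(sub$s_star) > 0))   # strictly increasing in v_in
    expect_true(all(diff(sub$flux) > 0))
  }
})

test_that("model construction rejects invalid parameters", {
  expect_error(pathway_model(-0.1, 1, 1, 0.4), class = "invivokin_config_error")
  expect_error(pathway_model(0.1, 0, 1, 0.4), class = "invivokin_config_error")
  expect_error(pathway_model(0.1, 1, -1, 0.4), class = "invivokin_config_error")
  expect_error(design_scan(pathway_model(0.1, 1, 1, 0.4), numeric(0), 0.1),
               class = "invivokin_config_error")
})
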