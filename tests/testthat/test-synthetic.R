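test_that("a noiseless panel lies exactly on the Michaelis-Menten curve", {
  cfg <- panel_config(influx_levels = c(5, 20, 80, 200, 400),
                      true_vmax = 849, true_k_half = 19,
                      mu_sd = 0, noise_cv_conc = 0)
  ds <- build_dataset(generate_strain_panel(cfg, seed = 1))
  expect_equal(ds$rate, mm_rate(ds$substrate, 849, 19), tolerance = 1e-12)
  # growth-rate variability alone does not perturb the curve either:
  # the dilution flux recovers the influx exactly, whatever mu was drawn
  cfg2 <- panel_config(influx_levels = c(5, 20, 80), true_vmax = 849,
                       true_k_half = 19, mu_sd = 0.03, noise_cv_conc = 0)
  ds2 <- build_dataset(generate_strain_panel(cfg2, seed = 2))
  expect_equal(ds2$rate, mm_rate(ds2$substrate, 849, 19), tolerance = 1e-9)
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- panel_preset("crtB_medium")
  a <- generate_strain_panel(cfg, seed = 77)
  b <- generate_strain_panel(cfg, seed = 77)
  expect_identical(a, b)
  expect_false(identical(a$substrate,
                         generate_strain_panel(cfg, seed = 78)$substrate))
})

test_that("below-LOQ flags are set iff the noisy value is below the limit", {
  cfg <- panel_config(influx_levels = mm_rate(c(0.05, 0.2, 1, 5, 20), 849, 19),
                      true_vmax = 849, true_k_half = 19,
                      loq_substrate = 0.15, loq_product = 5)
  panel <- generate_strain_panel(cfg, seed = 13)
  expect_identical(panel$substrate_below_loq, panel$substrate < 0.15)
  expect_identical(panel$product_below_loq, panel$product < 5)
  expect_true(any(panel$substrate_below_loq))  # lowest strain is censored
})

test_that("lognormal noise is mean-corrected", {
  cfg <- panel_config(influx_levels = mm_rate(5, 849, 19), true_vmax = 849,
                      true_k_half = 19, mu_sd = 0, n_replicates = 10000L)
  panel <- generate_strain_panel(cfg, seed = 99)
  s_true <- 5
  se <- s_true * 0.10 / sqrt(10000)
  expect_lt(abs(mean(panel$substrate) - s_true), 3 * se)
})

test_that("the phytoene-synthase preset spans the designed 167-fold range", {
  cfg <- panel_preset("crtB_medium")
  design <- attr(generate_strain_panel(cfg, seed = 1), "truth")$design
  expect_equal(max(design$s_star) / min(design$s_star), 20.78 / 0.12,
               tolerance = 1e-9)
  # realised (noisy, strain-mean) span stays within 20% of the design
  panel <- generate_strain_panel(cfg, seed = 8)
  realized <- fold_range(build_dataset(panel), by_strain = TRUE)
  expect_lt(abs(realized / (20.78 / 0.12) - 1), 0.20)
})

test_that("the substrate-producer titration preset spans a 38-fold range", {
  design <- attr(generate_strain_panel(panel_preset("ggpp_panel"), seed = 1),
                 "truth")$design
  expect_equal(max(design$s_star) / min(design$s_star), 38, tolerance = 1e-9)
})

test_that("the design-scan preset reproduces the published simulation grid", {
  p <- panel_preset("design_scan_fig4b")
  expect_equal(p$vmax_levels, c(0.02, 0.4, 0.7))
  expect_equal(p$k_half, 1)
  expect_equal(range(p$v_in_grid), c(0.01, 0.4))
})

test_that("infeasible influx levels are rejected unless censoring is allowed", {
  expect_error(panel_config(influx_levels = c(0.1, 1.2), true_vmax = 1,
                            true_k_half = 1),
               class = "invivokin_config_error")
  cfg <- panel_config(influx_levels = c(0.1, 1.2), true_vmax = 1,
                      true_k_half = 1, allow_infeasible = TRUE)
  panel <- generate_strain_panel(cfg, seed = 1)
  expect_equal(nrow(panel), 6L)  # censored strain still emitted
  expect_false(attr(panel, "truth")$design$feasible[2L])
})

test_that("fitted CIs bracket the truth for most saturating-preset panels", {
  hits <- vapply(1:30, function(i) {
    p <- generate_strain_panel(panel_preset("crtI_fungal"), seed = i)
    f <- mm_fit(build_dataset(p), n_mc = 300, seed = 700 + i)
    s <- f$mc$summary
    s["vmax", "ci95_low"] <= 168 && 168 <= s["vmax", "ci95_high"] &&
      s["k_half", "ci95_low"] <= 380 && 380 <= s["k_half", "ci95_high"]
  }, logical(1L))
  expect_gte(sum(hits), 16L)  # majority; see methods vignette on calibration
})
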