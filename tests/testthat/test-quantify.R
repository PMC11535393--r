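test_that("biomass-specific amounts convert to intracellular molarity", {
  # hand unit analysis: 1 umol/gDCW over 6.59e10 cells * 66 fL = 229.9 uM
  expect_equal(amount_to_concentration(0), 0)
  expect_equal(amount_to_concentration(1), 1 / (6.59e10 * 66e-15),
               tolerance = 1e-12)
  expect_equal(amount_to_concentration(1), 229.9, tolerance = 1e-4)
  expect_equal(amount_to_concentration(0.01), 2.299, tolerance = 1e-3)
  # linearity
  q <- c(0.2, 1.7, 31)
  expect_equal(amount_to_concentration(q), q * amount_to_concentration(1))
  expect_error(amount_to_concentration(-1), class = "invivokin_schema_error")
})

test_that("protein-specific abundances convert to nM", {
  # 1 fmol/ug = 1 nmol/g protein; x 0.63 g/gDCW / 4.3494e-3 L/gDCW = 144.8 nM
  expect_equal(protein_to_concentration(0), 0)
  expect_equal(protein_to_concentration(1), 0.63 / (6.59e10 * 66e-15),
               tolerance = 1e-12)
  expect_equal(protein_to_concentration(1), 144.8, tolerance = 1e-3)
  expect_equal(protein_to_concentration(0.29), 42.0, tolerance = 1e-3)
  expect_error(protein_to_concentration(-0.1), class = "invivokin_schema_error")
})

test_that("conversions are invertible to 1e-12 relative", {
  set.seed(1)
  const <- conversion_constants()
  q <- 10^runif(20, -4, 2)
  expect_equal(concentration_to_amount(amount_to_concentration(q, const), const),
               q, tolerance = 1e-12)
  expect_equal(protein_to_concentration(concentration_to_protein(q, const), const),
               q, tolerance = 1e-12)
  # custom constants round-trip too
  c2 <- conversion_constants(3e10, 40, 0.5)
  expect_equal(concentration_to_amount(amount_to_concentration(q, c2), c2), q,
               tolerance = 1e-12)
})

test_that("dilution flux is concentration times growth rate", {
  expect_equal(dilution_flux(100, 0.40), 40)
  expect_equal(dilution_flux(0, 0.3), 0)
  expect_equal(dilution_flux(1641, 0.40), 656.4)
  conc <- c(3.2, 88, 1641)
  expect_equal(dilution_flux(conc, 0.37) / 0.37, conc, tolerance = 1e-12)
  expect_error(dilution_flux(10, 0), class = "invivokin_schema_error")
  expect_error(dilution_flux(-1, 0.4), class = "invivokin_schema_error")
})

test_that("turnover number converts maximal rate per enzyme to 1/s", {
  kcat <- turnover_number(849, 0.042)
  expect_equal(kcat, 849 / (0.042 * 3600), tolerance = 1e-12)
  expect_equal(round(kcat), 6)
  # unit identity: vmax = 3600 * E gives exactly 1/s
  for (e in c(0.01, 0.042, 5)) expect_equal(turnover_number(3600 * e, e), 1)
  expect_equal(turnover_number(309, 0.042), 2.04, tolerance = 3e-3)
  expect_error(turnover_number(849, 0), class = "invivokin_schema_error")
})

test_that("build_dataset converts, computes fluxes and preserves counts", {
  cfg <- panel_config(influx_levels = mm_rate(exp(seq(log(0.12), log(20.78),
                                                      length.out = 8)), 849, 19),
                      true_vmax = 849, true_k_half = 19)
  panel <- generate_strain_panel(cfg, seed = 5)
  ds <- build_dataset(panel)
  expect_s3_class(ds, "kinetic_dataset")
  expect_equal(nrow(ds), 24L)  # 8 strains x 3 replicates, none censored
  expect_equal(nrow(ds) + nrow(attr(ds, "dropped")), nrow(panel))
  expect_equal(ds$rate,
               panel$product * panel$growth_rate_per_h, tolerance = 1e-12)
  # enzyme concentration carried through (nM)
  expect_equal(attr(ds, "enzyme_nm"), mean(panel$enzyme), tolerance = 1e-12)
})

test_that("umol/gDCW records equal the conversion-then-flux composition", {
  panel <- synthetic_reference_panel(849, 19, 0.12, 20.78)
  ds <- build_dataset(panel)
  const <- conversion_constants()
  expect_equal(ds$substrate, amount_to_concentration(panel$substrate, const),
               tolerance = 1e-12)
  expect_equal(ds$rate,
               dilution_flux(amount_to_concentration(panel$product, const),
                             panel$growth_rate_per_h),
               tolerance = 1e-12)
  # and the pairs lie exactly on the generating MM curve (noiseless panel)
  expect_equal(ds$rate, mm_rate(ds$substrate, 849, 19), tolerance = 1e-9)
})

test_that("below-LOQ policies drop or substitute flagged records", {
  panel <- generate_strain_panel(panel_preset("crtB_medium"), seed = 2)
  panel$product_below_loq[c(2, 5, 9)] <- TRUE
  ds <- build_dataset(panel, loq_policy = "drop")
  expect_equal(nrow(ds), nrow(panel) - 3L)
  expect_equal(nrow(attr(ds, "dropped")), 3L)

  ds2 <- build_dataset(panel, loq_policy = "substitute",
                       loq_substrate = 0.05, loq_product = 0.1)
  expect_equal(nrow(ds2), nrow(panel))
  subbed <- ds2$rate[c(2, 5, 9)]
  expect_equal(subbed, 0.05 * panel$growth_rate_per_h[c(2, 5, 9)],
               tolerance = 1e-12)  # LOQ/2 times mu
  expect_error(build_dataset(panel, loq_policy = "substitute"),
               class = "invivokin_config_error")
})

test_that("schema violations are rejected with offending rows named", {
  panel <- generate_strain_panel(panel_preset("crtB_medium"), seed = 3)
  mixed <- panel
  mixed$substrate_unit[4] <- "umol_per_gDCW"
  expect_error(build_dataset(mixed), class = "invivokin_schema_error")
  expect_error(build_dataset(mixed), "4")

  bad_unit <- panel
  bad_unit$product_unit[1] <- "mg_per_L"
  expect_error(build_dataset(bad_unit), class = "invivokin_schema_error")

  expect_error(validate_records(panel[, setdiff(names(panel), "growth_rate_per_h")]),
               class = "invivokin_schema_error")
  neg <- panel; neg$substrate[2] <- -1
  expect_error(validate_records(neg), class = "invivokin_schema_error")
})

test_that("panel files round-trip through read_panel and write_dataset", {
  panel <- generate_strain_panel(panel_preset("crtB_medium"), seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  expect_true(file.exists(paste0(f, ".truth.json")))
  back <- read_panel(f)
  expect_equal(back$substrate, panel$substrate, tolerance = 1e-12)

  ds <- build_dataset(back)
  out <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, out)
  prov <- jsonlite::read_json(paste0(out, ".provenance.json"))
  expect_equal(prov$constants$cells_per_gdcw, 6.59e10)
  expect_equal(prov$n_pairs, nrow(ds))
  expect_match(prov$assumptions, "steady state")

  expect_error(read_panel("no/such/file.csv"), class = "invivokin_schema_error")
})

test_that("fold_range reports the substrate span", {
  d <- data.frame(substrate = c(1, 2, 10, 38), rate = 1:4,
                  strain_id = c("a", "a", "b", "c"))
  expect_equal(fold_range(d, by_strain = FALSE), 38)
  expect_equal(fold_range(d, by_strain = TRUE), 38 / 1.5)
})
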