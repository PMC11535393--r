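#' Run the full in vivo enzymology pipeline on a measurement file
#'
#' Reads a strain-panel measurement table, converts it to absolute
#' concentrations and dilution fluxes ([build_dataset()]), fits the
#' irreversible Michaelis-Menten model with Monte-Carlo uncertainty and
#' identifiability triage ([mm_fit()]), and assembles a self-describing
#' report. When the panel carries enzyme concentrations, the in vivo turnover
#' number `kcat_cell = Vmax_cell / [E]` is computed, with a Monte-Carlo 95%
#' interval propagated from the `Vmax` distribution.
#'
#' The report is deterministic given the file contents and the seed:
#' rerunning with the recorded configuration reproduces it byte-for-byte.
#'
#' @param data_file path to the measurement table (see [read_panel()]).
#' @param config_file optional YAML or JSON configuration; keys mirror
#'   [conversion_constants()] (`cells_per_gdcw`, `cell_volume_fl`,
#'   `protein_fraction`) and the fitting controls `n_mc`, `seed`,
#'   `rsd_threshold`, `noise_floor`, `loq_policy`, `loq_substrate`,
#'   `loq_product`.
#' @param overrides named list overriding config values programmatically.
#' @return object of class `pipeline_report` (a named list; see
#'   [write_report()] for the serialised form).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_panel(generate_strain_panel(panel_preset("crtB_medium"), seed = 7), f)
#' rep <- run_pipeline(f, overrides = list(n_mc = 100))
#' rep$fit$vmax
#' @export
run_pipeline <- function(data_file, config_file = NULL, overrides = list()) {
  cfg <- list(cells_per_gdcw = 6.59e10, cell_volume_fl = 66,
              protein_fraction = 0.63,
              n_mc = 1000L, seed = 42L, rsd_threshold = 0.5,
              noise_floor = NULL, loq_policy = "drop",
              loq_substrate = NA_real_, loq_product = NA_real_)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      .schema_error(sprintf("config file not found: %s", config_file))
    file_cfg <- if (grepl("\\.json$", config_file, ignore.case = TRUE))
      jsonlite::read_json(config_file, simplifyVector = TRUE)
    else yaml::read_yaml(config_file)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      .schema_error(paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
    cfg <- modifyList(cfg, file_cfg)
  }
  cfg <- modifyList(cfg, overrides)

  records <- read_panel(data_file)
  const <- conversion_constants(cfg$cells_per_gdcw, cfg$cell_volume_fl,
                                cfg$protein_fraction)
  dataset <- build_dataset(records, const, loq_policy = cfg$loq_policy,
                           loq_substrate = cfg$loq_substrate,
                           loq_product = cfg$loq_product)
  fit <- mm_fit(dataset, n_mc = cfg$n_mc, seed = cfg$seed,
                rsd_threshold = cfg$rsd_threshold,
                noise_floor = cfg$noise_floor)

  enzyme_nm <- attr(dataset, "enzyme_nm")
  kcat <- NULL
  if (is.finite(enzyme_nm)) {
    e_um <- enzyme_nm / 1000
    kcat <- list(
      value_per_s = turnover_number(fit$coefficients[["vmax"]], e_um),
      enzyme_nm = enzyme_nm,
      ci95_low = turnover_number(fit$mc$summary["vmax", "ci95_low"], e_um),
      ci95_high = turnover_number(fit$mc$summary["vmax", "ci95_high"], e_um))
  }

  mc_summ <- fit$mc$summary
  id <- fit$identifiability
  report <- list(
    package = "invivokin",
    version = as.character(packageVersion("invivokin")),
    seed = as.integer(cfg$seed),
    input = list(data_file = data_file,
                 config_file = if (is.null(config_file)) NA else config_file,
                 n_records = nrow(records),
                 n_strains = length(unique(records$strain_id))),
    config = cfg[c("cells_per_gdcw", "cell_volume_fl", "protein_fraction",
                   "n_mc", "seed", "rsd_threshold", "loq_policy")],
    dataset = list(
      n_pairs = nrow(dataset),
      n_dropped = nrow(attr(dataset, "dropped")),
      substrate_min_um = min(dataset$substrate),
      substrate_max_um = max(dataset$substrate),
      fold_range = fold_range(dataset, by_strain = FALSE),
      fold_range_strain_means = fold_range(dataset, by_strain = TRUE),
      assumptions = attr(dataset, "assumptions")),
    fit = list(
      vmax = fit$coefficients[["vmax"]],
      k_half = fit$coefficients[["k_half"]],
      residual_sd = fit$residual_sd,
      efficiency = fit$efficiency,
      condition_number = fit$cond,
      convergence = fit$convergence),
    monte_carlo = list(
      n = fit$mc$n, seed = fit$mc$seed, noise_sd = fit$mc$noise_sd,
      n_failed = fit$mc$n_failed,
      vmax = as.list(mc_summ["vmax", -1L]),
      k_half = as.list(mc_summ["k_half", -1L])),
    identifiability = list(
      vmax = list(identifiable = unname(id$identifiable["vmax"]),
                  lower_limit = unname(id$lower_limits["vmax"]),
                  reason = unname(id$reasons["vmax"])),
      k_half = list(identifiable = unname(id$identifiable["k_half"]),
                    lower_limit = unname(id$lower_limits["k_half"]),
                    reason = unname(id$reasons["k_half"]))),
    kcat_cell = kcat)
  structure(report, class = "pipeline_report", fit = fit)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== in vivo enzymology pipeline report ==\n")
  cat(sprintf("input: %s (%d records, %d strains; %d pairs retained, %d dropped)\n",
              x$input$data_file, x$input$n_records, x$input$n_strains,
              x$dataset$n_pairs, x$dataset$n_dropped))
  cat(sprintf("substrate span: %.4g - %.4g uM (fold range %.3g; strain means %.3g)\n",
              x$dataset$substrate_min_um, x$dataset$substrate_max_um,
              x$dataset$fold_range, x$dataset$fold_range_strain_means))
  mc <- x$monte_carlo
  cat(sprintf("Vmax_cell = %.4g uM/h  (MC mean %.4g, sd %.3g, rsd %.1f%%, 95%% CI [%.4g, %.4g])\n",
              x$fit$vmax, mc$vmax$mean, mc$vmax$sd, 100 * mc$vmax$rsd,
              mc$vmax$ci95_low, mc$vmax$ci95_high))
  cat(sprintf("K1/2_cell = %.4g uM    (MC mean %.4g, sd %.3g, rsd %.1f%%, 95%% CI [%.4g, %.4g])\n",
              x$fit$k_half, mc$k_half$mean, mc$k_half$sd,
              100 * mc$k_half$rsd, mc$k_half$ci95_low, mc$k_half$ci95_high))
  for (p in c("vmax", "k_half")) {
    idp <- x$identifiability[[p]]
    if (!idp$identifiable)
      cat(sprintf("NOTE: %s not identifiable (%s); lower limit %.4g\n",
                  p, idp$reason, idp$lower_limit))
  }
  if (!is.null(x$kcat_cell))
    cat(sprintf("kcat_cell = %.3g 1/s at [E] = %.3g nM (95%% CI [%.3g, %.3g])\n",
                x$kcat_cell$value_per_s, x$kcat_cell$enzyme_nm,
                x$kcat_cell$ci95_low, x$kcat_cell$ci95_high))
  cat(sprintf("Monte-Carlo: n = %d, seed = %d, %d refit failure(s)\n",
              mc$n, mc$seed, mc$n_failed))
  invisible(x)
}

# round every numeric leaf to 6 significant digits, preserving structure
.signif_rec <- function(x, digits = 6L) {
  if (is.list(x)) lapply(x, .signif_rec, digits = digits)
  else if (is.double(x)) signif(x, digits)
  else x
}

#' Serialise a pipeline report to JSON
#'
#' Machine-readable JSON with fixed key order and floats rounded to 6
#' significant digits, so identical inputs produce byte-identical files.
#'
#' @param report a `pipeline_report` (from [run_pipeline()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- .signif_rec(unclass(report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
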