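#' Configuration of a synthetic strain panel
#'
#' Describes an engineered-strain collection in which the expression of the
#' substrate-producing enzyme is titrated (via promoter strength and gene
#' copy number) to span a wide range of intracellular substrate
#' concentrations, while the enzyme under study is expressed at a constant
#' level. Defaults mirror the measured behaviour of such panels in budding
#' yeast: growth rate 0.40 ± 0.03 1/h across strains, ~42 nM of the studied
#' enzyme, 3 biological replicates, and ~10% CV measurement noise on
#' concentrations.
#'
#' @param influx_levels substrate-producing fluxes, one per strain: either a
#'   numeric vector of `v_in` (µM/h) or a data.frame with columns `promoter`,
#'   `copies`, `per_copy_influx` (µM/h per gene copy; `v_in = copies *
#'   per_copy_influx`, i.e. linear per copy with promoter-specific strength).
#' @param true_vmax,true_k_half kinetic parameters of the studied enzyme
#'   (µM/h, µM) used to compute the noiseless steady states.
#' @param mu_mean,mu_sd mean and SD of the specific growth rate (1/h); draws
#'   are truncated at 0.
#' @param enzyme_conc_nm intracellular concentration of the studied enzyme
#'   (nM); `NA` omits the enzyme columns.
#' @param n_replicates biological replicates per strain.
#' @param noise_cv_conc coefficient of variation of the multiplicative
#'   lognormal measurement noise applied to substrate, product and enzyme
#'   concentrations (mean-corrected so the expected value equals the
#'   noiseless steady state).
#' @param loq_substrate,loq_product limits of quantification (µM); noisy
#'   values below them are flagged `*_below_loq`.
#' @param seed default RNG seed for [generate_strain_panel()].
#' @param allow_infeasible if `FALSE` (default), influx levels at or above
#'   `true_vmax` (no steady state) raise a configuration error; if `TRUE`
#'   they are permitted and emitted as censored (flagged) records.
#' @param name optional label.
#' @return object of class `panel_config`.
#' @seealso [generate_strain_panel()], [panel_preset()]
#' @export
panel_config <- function(influx_levels, true_vmax, true_k_half,
                         mu_mean = 0.40, mu_sd = 0.03,
                         enzyme_conc_nm = 42, n_replicates = 3L,
                         noise_cv_conc = 0.10,
                         loq_substrate = 0.05, loq_product = 0.1,
                         seed = 1L, allow_infeasible = FALSE, name = NULL) {
  if (is.data.frame(influx_levels)) {
    need <- c("promoter", "copies", "per_copy_influx")
    if (!all(need %in% names(influx_levels)))
      .config_error("influx_levels data.frame needs columns promoter, copies, per_copy_influx")
    v_in <- influx_levels$copies * influx_levels$per_copy_influx
    promoter <- as.character(influx_levels$promoter)
    copies <- influx_levels$copies
  } else {
    v_in <- as.numeric(influx_levels)
    promoter <- paste0("crtE_L", seq_along(v_in))
    copies <- rep(1L, length(v_in))
  }
  if (length(v_in) == 0L) .config_error("influx_levels must be non-empty")
  if (any(!is.finite(v_in)) || any(v_in <= 0))
    .config_error("all influx levels must be finite and > 0")
  .stopifnot_scalar(true_vmax, "true_vmax", positive = TRUE)
  .stopifnot_scalar(true_k_half, "true_k_half", positive = TRUE)
  .stopifnot_scalar(mu_mean, "mu_mean", positive = TRUE)
  .stopifnot_scalar(mu_sd, "mu_sd", nonneg = TRUE)
  .stopifnot_scalar(noise_cv_conc, "noise_cv_conc", nonneg = TRUE)
  .stopifnot_scalar(loq_substrate, "loq_substrate", nonneg = TRUE)
  .stopifnot_scalar(loq_product, "loq_product", nonneg = TRUE)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) .config_error("n_replicates must be >= 1")
  if (!allow_infeasible && any(v_in >= true_vmax))
    .config_error(paste("influx level(s) at or above true_vmax have no",
                        "steady state; lower them or set allow_infeasible",
                        "= TRUE to emit them as censored records"))
  structure(list(v_in = v_in, promoter = promoter, copies = copies,
                 true_vmax = true_vmax, true_k_half = true_k_half,
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 enzyme_conc_nm = enzyme_conc_nm,
                 n_replicates = n_replicates,
                 noise_cv_conc = noise_cv_conc,
                 loq_substrate = loq_substrate, loq_product = loq_product,
                 seed = as.integer(seed),
                 allow_infeasible = allow_infeasible,
                 name = name),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("Strain-panel config%s: %d strains x %d replicates\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$v_in), x$n_replicates))
  cat(sprintf("  truth: vmax = %g uM/h, k_half = %g uM\n",
              x$true_vmax, x$true_k_half))
  cat(sprintf("  influx: %.3g - %.3g uM/h; mu ~ N(%g, %g) /h; noise CV %g\n",
              min(x$v_in), max(x$v_in), x$mu_mean, x$mu_sd, x$noise_cv_conc))
  invisible(x)
}

# mean-corrected multiplicative lognormal noise factors, E[factor] = 1
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a seeded synthetic strain panel
#'
#' For each strain × replicate: the growth rate is drawn from a truncated
#' normal; the noiseless steady state (substrate `s_star`, product
#' `flux / mu`) is computed from the pathway model at the strain's influx
#' level; mean-corrected multiplicative lognormal noise (CV
#' `noise_cv_conc`) is applied to the substrate, product and enzyme
#' concentrations; below-LOQ flags are set on the noisy values. The true
#' parameters and per-strain design are attached as a `truth` attribute
#' (written as a separate sidecar file by the CLI, so that fitting code can
#' never read it by accident).
#'
#' @param cfg a [panel_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return data.frame of measurement records in the [read_panel()] schema,
#'   with attribute `truth` (list: `true_vmax`, `true_k_half`, `mu_mean`,
#'   `enzyme_conc_nm`, per-strain `design` with `v_in`, `s_star`, `flux`).
#' @examples
#' panel <- generate_strain_panel(panel_preset("crtB_medium"), seed = 1)
#' head(panel)
#' @export
generate_strain_panel <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "panel_config"))
  set.seed(as.integer(seed))

  n_strain <- length(cfg$v_in)
  design <- do.call(rbind, lapply(seq_len(n_strain), function(i) {
    feasible <- cfg$v_in[i] < cfg$true_vmax
    ss <- if (feasible)
      steady_state(pathway_model(cfg$v_in[i], cfg$true_vmax, cfg$true_k_half,
                                 cfg$mu_mean))
    else list(s_star = Inf, flux = cfg$true_vmax, feasible = FALSE)
    data.frame(strain_id = sprintf("S%02d", i), promoter = cfg$promoter[i],
               crt_e_copies = cfg$copies[i], v_in = cfg$v_in[i],
               s_star = ss$s_star, flux = ss$flux, feasible = ss$feasible)
  }))

  rows <- vector("list", n_strain * cfg$n_replicates)
  k <- 0L
  for (i in seq_len(n_strain)) {
    for (r in seq_len(cfg$n_replicates)) {
      mu <- rnorm(1L, cfg$mu_mean, cfg$mu_sd)
      while (mu <= 0) mu <- rnorm(1L, cfg$mu_mean, cfg$mu_sd)
      if (design$feasible[i]) {
        s_true <- design$s_star[i]
        p_true <- design$flux[i] / mu
      } else {
        # censored: substrate accumulates beyond the quantifiable range;
        # emitted with the saturated flux and flagged below/above-LOQ aside
        s_true <- cfg$true_k_half * 1e3
        p_true <- cfg$true_vmax / mu
      }
      s_obs <- s_true * .lognoise(1L, cfg$noise_cv_conc)
      p_obs <- p_true * .lognoise(1L, cfg$noise_cv_conc)
      e_obs <- if (is.finite(cfg$enzyme_conc_nm))
        cfg$enzyme_conc_nm * .lognoise(1L, cfg$noise_cv_conc) else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(
        strain_id = design$strain_id[i], promoter = design$promoter[i],
        crt_e_copies = design$crt_e_copies[i], replicate = r,
        growth_rate_per_h = mu,
        substrate = s_obs, substrate_unit = "uM",
        product = p_obs, product_unit = "uM",
        enzyme = e_obs, enzyme_unit = if (is.finite(e_obs)) "nM" else NA_character_,
        substrate_below_loq = s_obs < cfg$loq_substrate,
        product_below_loq = p_obs < cfg$loq_product,
        enzyme_below_loq = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    true_vmax = cfg$true_vmax, true_k_half = cfg$true_k_half,
    mu_mean = cfg$mu_mean, mu_sd = cfg$mu_sd,
    enzyme_conc_nm = cfg$enzyme_conc_nm,
    noise_cv_conc = cfg$noise_cv_conc, seed = as.integer(seed),
    name = cfg$name, design = design)
  out
}

#' Named panel presets mirroring published in vivo saturation experiments
#'
#' Four presets covering the qualitatively different regimes of the method:
#' \describe{
#'   \item{`crtB_medium`}{phytoene-synthase-like, partially saturating: truth
#'     (Vmax = 849 µM/h, K1/2 = 19 µM), 8 strains spanning steady-state
#'     substrate 0.12–20.78 µM (167-fold).}
#'   \item{`crtI_fungal`}{fungal-desaturase-like, saturating: truth (168
#'     µM/h, 380 µM), substrate span 4–1641 µM (430-fold).}
#'   \item{`crtI_bacterial`}{bacterial-desaturase-like, non-identifiable:
#'     truth shaped on the reported lower limits (13 µM/h, 560 µM) with the
#'     substrate grid truncated below saturation (4–56 µM, i.e. up to
#'     K1/2/10, so the half-saturation constant far exceeds the substrate
#'     span and only lower limits are recoverable).}
#'   \item{`ggpp_panel`}{substrate-producer titration panel: 8 strains
#'     spanning a 38-fold range of steady-state substrate concentration.}
#' }
#' `design_scan_fig4b` is also accepted and returns the design-scan
#' configuration (enzyme levels `vmax` {0.02, 0.4, 0.7} µM/h, `k_half` 1 µM,
#' influx 0.01–0.4 µM/h) rather than a panel config.
#'
#' @param name preset name.
#' @return a [panel_config()], or for `design_scan_fig4b` a list with
#'   `vmax_levels`, `k_half`, `mu`, `v_in_grid`.
#' @export
panel_preset <- function(name = c("crtB_medium", "crtI_fungal",
                                  "crtI_bacterial", "ggpp_panel",
                                  "design_scan_fig4b")) {
  name <- match.arg(name)
  span_cfg <- function(s_min, s_max, vmax, k, ...) {
    s_targets <- exp(seq(log(s_min), log(s_max), length.out = 8L))
    panel_config(influx_levels = mm_rate(s_targets, vmax, k),
                 true_vmax = vmax, true_k_half = k, name = name, ...)
  }
  switch(name,
    crtB_medium = span_cfg(0.12, 20.78, 849, 19),
    crtI_fungal = span_cfg(4, 1641, 168, 380),
    crtI_bacterial = span_cfg(4, 56, 13, 560),
    ggpp_panel = span_cfg(0.54, 0.54 * 38, 849, 19),
    design_scan_fig4b = list(vmax_levels = c(0.02, 0.4, 0.7), k_half = 1,
                             mu = 0.4, v_in_grid = seq(0.01, 0.4, by = 0.01)))
}

#' @rdname panel_preset
#' @export
panel_presets <- function() {
  c("crtB_medium", "crtI_fungal", "crtI_bacterial", "ggpp_panel",
    "design_scan_fig4b")
}

#' Write a generated panel with its truth sidecar
#'
#' The measurement table goes to `path` (CSV, [read_panel()] schema); the
#' generating truth goes to a separate `<path>.truth.json` sidecar so that
#' downstream fitting can never read it by accident.
#'
#' @param records output of [generate_strain_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(records, path) {
  truth <- attr(records, "truth")
  write.csv(records, path, row.names = FALSE)
  if (!is.null(truth)) {
    truth$design <- truth$design
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(path)
}
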