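# shared fixtures, all generated in code

# log-spaced noiseless Michaelis-Menten pairs
mm_pairs <- function(vmax, k, s_min, s_max, n = 8L, reps = 1L) {
  s <- rep(exp(seq(log(s_min), log(s_max), length.out = n)), each = reps)
  data.frame(substrate = s, rate = mm_rate(s, vmax, k))
}

# independent ODE route to the steady state: integrate, doubling the horizon,
# until the remaining deviation implied by the local relaxation rate
# (|dX/dt| / lambda) is below 1e-8 relative. A raw |dX/dt| threshold is not
# enough: when lambda is small the state can still be far away.
ode_steady_state <- function(model, t_start = 1e4, t_max = 1e13) {
  t_end <- t_start
  repeat {
    tc <- simulate_timecourse(model, t_end = t_end, n_points = 5L)
    S <- tc$S[5L]; P <- tc$P[5L]
    conv <- mm_rate(S, model$vmax, model$k_half)
    dS <- model$v_in - conv -
      if (model$dilute_intermediate) model$mu * S else 0
    dP <- conv - model$mu * P
    lam_s <- model$vmax * model$k_half / (model$k_half + S)^2 +
      if (model$dilute_intermediate) model$mu else 0
    lam_p <- model$mu
    ok_s <- abs(dS) / lam_s < 1e-8 * max(abs(S), 1e-12)
    ok_p <- lam_p == 0 || abs(dP) / lam_p < 1e-8 * max(abs(P), 1e-12)
    if (ok_s && ok_p) return(list(s_star = S, p_star = P, flux = conv))
    t_end <- t_end * 4
    if (t_end > t_max) stop("ODE route did not reach steady state")
  }
}

# noiseless reconstruction of a published-style saturation panel: strain
# means at the design steady states, emitted in umol/gDCW so the full unit
# conversion path is exercised (synthetic stand-in, not measured data)
synthetic_reference_panel <- function(vmax, k, s_min, s_max,
                                      n_strain = 8L, reps = 3L, mu = 0.40) {
  cfg <- panel_config(
    influx_levels = mm_rate(exp(seq(log(s_min), log(s_max),
                                    length.out = n_strain)), vmax, k),
    true_vmax = vmax, true_k_half = k,
    mu_mean = mu, mu_sd = 0, noise_cv_conc = 0, n_replicates = reps)
  panel <- generate_strain_panel(cfg, seed = 1L)
  const <- conversion_constants()
  panel$substrate <- concentration_to_amount(panel$substrate, const)
  panel$substrate_unit <- "umol_per_gDCW"
  panel$product <- concentration_to_amount(panel$product, const)
  panel$product_unit <- "umol_per_gDCW"
  panel
}

# majority identifiability verdict of a panel preset over replicate panels
preset_identifiable <- function(preset, n_panels = 5L, seed0 = 1L,
                                n_mc = 500L) {
  fits <- lapply(seq_len(n_panels), function(i) {
    p <- generate_strain_panel(panel_preset(preset), seed = seed0 + i)
    mm_fit(build_dataset(p), n_mc = n_mc, seed = seed0 + 100L + i)
  })
  votes <- vapply(fits, function(f) all(f$identifiability$identifiable),
                  logical(1L))
  list(identifiable = mean(votes) > 0.5, fits = fits, votes = votes)
}
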