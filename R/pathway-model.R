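#' Kinetic model of a constant-influx / MM-conversion / growth-dilution pathway
#'
#' A minimal model of a linear two-metabolite pathway: the substrate S is
#' produced at a constant flux `v_in` (the substrate-producing enzyme, e.g. a
#' GGPP synthase), converted into the product P by the enzyme under study with
#' an irreversible Michaelis-Menten rate `vmax * S / (k_half + S)`, and P is
#' diluted by growth at rate `mu * P` (first-order mass action). Optionally the
#' substrate pool is also diluted by growth.
#'
#' All concentrations are in µM, fluxes in µM/h, rates in 1/h; unit conversion
#' from raw omics measurements is the job of [build_dataset()] and friends.
#'
#' @param v_in constant substrate-producing flux (µM/h), >= 0.
#' @param vmax maximal rate of the converting enzyme (µM/h), > 0.
#' @param k_half half-saturation constant (µM), > 0.
#' @param mu specific growth rate diluting the product pool (1/h), >= 0.
#' @param dilute_intermediate logical; if `TRUE` the substrate pool is also
#'   diluted by growth (`- mu * S` term). Default `FALSE`: the design model
#'   treats the intermediate as drained only by the enzymatic conversion.
#' @return an object of class `pathway_model`.
#' @examples
#' m <- pathway_model(v_in = 0.35, vmax = 0.7, k_half = 1, mu = 0.1)
#' steady_state(m)
#' @seealso [steady_state()], [simulate_timecourse()], [design_scan()]
#' @export
pathway_model <- function(v_in, vmax, k_half, mu,
                          dilute_intermediate = FALSE) {
  .stopifnot_scalar(v_in, "v_in", nonneg = TRUE)
  .stopifnot_scalar(vmax, "vmax", positive = TRUE)
  .stopifnot_scalar(k_half, "k_half", positive = TRUE)
  .stopifnot_scalar(mu, "mu", nonneg = TRUE)
  stopifnot(is.logical(dilute_intermediate), length(dilute_intermediate) == 1L)
  structure(
    list(v_in = v_in, vmax = vmax, k_half = k_half, mu = mu,
         dilute_intermediate = dilute_intermediate),
    class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("Pathway model: constant influx -> MM conversion -> growth dilution\n")
  cat(sprintf("  v_in   = %g uM/h\n  vmax   = %g uM/h\n  k_half = %g uM\n  mu     = %g /h\n",
              x$v_in, x$vmax, x$k_half, x$mu))
  cat(sprintf("  substrate diluted by growth: %s\n", x$dilute_intermediate))
  invisible(x)
}

#' Michaelis-Menten rate law
#'
#' @param s substrate concentration(s), µM.
#' @param vmax maximal rate (µM/h).
#' @param k_half half-saturation constant (µM).
#' @return rate(s) in µM/h.
#' @export
mm_rate <- function(s, vmax, k_half) vmax * s / (k_half + s)

#' Steady state of the pathway model
#'
#' Without substrate dilution the steady state is closed-form: the conversion
#' flux must equal the influx, so `s_star = k_half * v_in / (vmax - v_in)`
#' whenever `v_in < vmax`; if `v_in >= vmax` the conversion cannot balance the
#' influx and the substrate grows without bound (`feasible = FALSE`; the flux
#' saturates at the `vmax` asymptote). With substrate dilution the balance
#' `v_in = vmax*S/(k_half+S) + mu*S` is a quadratic in S, solved for its
#' positive root; every influx is then feasible (for `mu > 0`).
#'
#' The product pool obeys `p_star = flux / mu`; with `mu = 0` and a positive
#' flux the product has no steady state and `p_star` is reported as `NA`.
#'
#' @param model a [pathway_model()].
#' @return an object of class `steady_state`: list with `s_star`, `p_star`,
#'   `flux` (all µM or µM/h), `feasible`, and `p_defined`.
#' @examples
#' steady_state(pathway_model(0.35, 0.7, 1, 0.1))  # s_star = k_half
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  v <- model$v_in; vmax <- model$vmax; k <- model$k_half; mu <- model$mu

  if (model$dilute_intermediate && mu > 0) {
    # mu*S^2 + (mu*k + vmax - v)*S - v*k = 0, positive root
    b <- mu * k + vmax - v
    c0 <- -v * k
    disc <- b * b - 4 * mu * c0
    s_star <- if (v == 0) 0 else (-b + sqrt(disc)) / (2 * mu)
    flux <- mm_rate(s_star, vmax, k)
    feasible <- TRUE
  } else {
    if (v >= vmax) {
      out <- structure(list(s_star = Inf, p_star = NA_real_, flux = vmax,
                            feasible = FALSE, p_defined = FALSE),
                       class = "steady_state")
      return(out)
    }
    s_star <- k * v / (vmax - v)
    flux <- v
    feasible <- TRUE
  }

  if (mu > 0) {
    p_star <- flux / mu
    p_defined <- TRUE
  } else if (flux == 0) {
    p_star <- 0
    p_defined <- TRUE
  } else {
    p_star <- NA_real_
    p_defined <- FALSE
  }
  structure(list(s_star = s_star, p_star = p_star, flux = flux,
                 feasible = feasible, p_defined = p_defined),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  if (!x$feasible) {
    cat("Infeasible steady state: influx exceeds enzyme capacity",
        sprintf("(flux saturates at the vmax asymptote %g uM/h)\n", x$flux))
  } else {
    cat(sprintf("Steady state: S* = %g uM, flux = %g uM/h, P* = %s uM\n",
                x$s_star, x$flux,
                if (x$p_defined) format(x$p_star) else "undefined (mu = 0)"))
  }
  invisible(x)
}

#' Simulate the pathway time course by ODE integration
#'
#' Integrates `dS/dt = v_in - vmax*S/(k_half+S) [- mu*S]`,
#' `dP/dt = vmax*S/(k_half+S) - mu*P` with a stiff-capable solver
#' (`deSolve::lsoda`, rtol 1e-8, atol 1e-10).
#'
#' @param model a [pathway_model()].
#' @param s0,p0 initial concentrations (µM), >= 0.
#' @param t_end end time (h), > 0.
#' @param n_points number of output time points (including t = 0).
#' @return data.frame with columns `time`, `S`, `P`.
#' @examples
#' tc <- simulate_timecourse(pathway_model(0.35, 0.7, 1, 0.1), t_end = 200)
#' tail(tc, 1)  # S -> 1, P -> 3.5
#' @export
simulate_timecourse <- function(model, s0 = 0, p0 = 0, t_end, n_points = 200L) {
  stopifnot(inherits(model, "pathway_model"))
  .stopifnot_scalar(s0, "s0", nonneg = TRUE)
  .stopifnot_scalar(p0, "p0", nonneg = TRUE)
  .stopifnot_scalar(t_end, "t_end", positive = TRUE)
  n_points <- max(2L, as.integer(n_points))

  deriv <- function(t, y, p) {
    conv <- mm_rate(y[1L], p$vmax, p$k_half)
    dS <- p$v_in - conv - if (p$dilute_intermediate) p$mu * y[1L] else 0
    dP <- conv - p$mu * y[2L]
    list(c(dS, dP))
  }
  times <- seq(0, t_end, length.out = n_points)
  out <- deSolve::ode(y = c(S = s0, P = p0), times = times, func = deriv,
                      parms = model, rtol = 1e-8, atol = 1e-10)
  out <- as.data.frame(out)
  if (anyNA(out) || any(!is.finite(as.matrix(out)))) {
    bad <- which(!stats::complete.cases(out) |
                   !is.finite(out$S) | !is.finite(out$P))[1L]
    t_reached <- if (bad > 1L) out$time[bad - 1L] else 0
    .fit_error(sprintf(
      "integration failure: non-finite state; last valid time reached t = %g h",
      t_reached))
  }
  # solver can undershoot zero by ~atol; clamp
  out$S <- pmax(out$S, 0)
  out$P <- pmax(out$P, 0)
  `names<-`(out, c("time", "S", "P"))
}

#' Design scan over enzyme levels and influx
#'
#' Tabulates the steady-state substrate concentration and flux for every
#' combination of enzyme activity (`vmax_levels`) and substrate-producing flux
#' (`v_in_grid`), as used to decide which expression levels of the enzyme under
#' study yield informative saturation data. Infeasible combinations
#' (`v_in >= vmax`) are flagged, not dropped.
#'
#' @param base a [pathway_model()] supplying `k_half`, `mu` and the dilution
#'   mode; its `v_in` and `vmax` are overridden by the grids.
#' @param vmax_levels numeric vector of enzyme activities (µM/h).
#' @param v_in_grid numeric vector of influxes (µM/h).
#' @return data.frame with one row per (vmax, v_in) pair and columns `vmax`,
#'   `v_in`, `s_star`, `p_star`, `flux`, `saturation_fraction`, `feasible`.
#' @examples
#' base <- pathway_model(0.1, 1, 1, 0.4)
#' scan <- design_scan(base, c(0.02, 0.4, 0.7), seq(0.01, 0.4, by = 0.01))
#' @export
design_scan <- function(base, vmax_levels, v_in_grid) {
  stopifnot(inherits(base, "pathway_model"))
  if (length(vmax_levels) == 0L || length(v_in_grid) == 0L)
    .config_error("vmax_levels and v_in_grid must be non-empty")
  grid <- expand.grid(v_in = v_in_grid, vmax = vmax_levels,
                      KEEP.OUT.ATTRS = FALSE)[, c("vmax", "v_in")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- pathway_model(grid$v_in[i], grid$vmax[i], base$k_half, base$mu,
                       base$dilute_intermediate)
    ss <- steady_state(m)
    data.frame(vmax = m$vmax, v_in = m$v_in,
               s_star = if (ss$feasible) ss$s_star else NA_real_,
               p_star = ss$p_star, flux = ss$flux,
               saturation_fraction = ss$flux / m$vmax,
               feasible = ss$feasible)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
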