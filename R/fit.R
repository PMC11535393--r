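#' Fit an irreversible Michaelis-Menten rate law
#'
#' Estimates the in vivo maximal rate (`vmax`, a.k.a. Vmax_cell) and
#' half-saturation constant (`k_half`, K1/2_cell) by unweighted nonlinear
#' least squares on the model `rate = vmax * S / (k_half + S)`.
#'
#' Numerically the fit uses variable projection: for any fixed `k_half` the
#' conditionally optimal `vmax` is the closed-form linear least-squares
#' solution, so the problem reduces to a 1-D minimisation over `log(k_half)`.
#' The profile objective is evaluated on a coarse log-spaced grid spanning
#' `[min(S)/1e4, max(S)*1e4]` and the bracketed minimum is then refined with
#' `stats::optimize`. This keeps `k_half` positive by construction and is
#' robust to poor starting values; it is also fast enough to refit thousands
#' of Monte-Carlo datasets. Supplying `init` narrows the initial bracket
#' around the given `k_half` guess.
#'
#' With `n_mc > 0` the Monte-Carlo uncertainty analysis
#' ([mm_monte_carlo()]) and identifiability triage ([mm_identifiability()])
#' are chained onto the fit.
#'
#' @param data a `kinetic_dataset` (from [build_dataset()]) or any data.frame
#'   with numeric columns `substrate` (µM, > 0) and `rate` (µM/h). At least 3
#'   pairs are required.
#' @param init optional numeric vector `c(vmax0, k0)`; only `k0` is used (to
#'   centre the search bracket), since `vmax` is profiled out.
#' @param bounds optional length-2 vector: search bounds for `k_half` (µM).
#' @param n_mc number of Monte-Carlo datasets (0 = point fit only;
#'   default 1000).
#' @param seed RNG seed for the Monte-Carlo stage (always recorded).
#' @param rsd_threshold relative-standard-deviation threshold for the
#'   identifiability verdict, see [mm_identifiability()].
#' @param noise_floor optional noise standard deviation (µM/h) to use in the
#'   Monte-Carlo stage when the residual SD is degenerate (e.g. noiseless
#'   input).
#' @return an object of class `mm_fit`; see Details. Components include
#'   `coefficients` (vmax, k_half), `residual_sd`, `cov` (2×2 covariance from
#'   the Jacobian), `cond` (condition number of the normal matrix),
#'   `efficiency` (vmax/k_half, the catalytic-efficiency analogue), `mc`
#'   (Monte-Carlo summary, if run) and `identifiability`.
#' @examples
#' d <- data.frame(substrate = c(0.5, 1, 2, 5, 10, 20),
#'                 rate = mm_rate(c(0.5, 1, 2, 5, 10, 20), 100, 4))
#' fit <- mm_fit(d, n_mc = 0)
#' coef(fit)
#' @seealso [mm_monte_carlo()], [mm_identifiability()], [plot.mm_fit()]
#' @export
mm_fit <- function(data, init = NULL, bounds = NULL, n_mc = 1000L,
                   seed = 42L, rsd_threshold = 0.5, noise_floor = NULL) {
  d <- .as_pairs(data)
  S <- d$substrate; v <- d$rate
  if (length(S) < 3L)
    .schema_error(sprintf("at least 3 (substrate, rate) pairs are required to fit (got %d)",
                          length(S)))

  if (is.null(bounds)) bounds <- c(min(S) / 1e4, max(S) * 1e4)
  if (!is.null(init)) {
    k0 <- init[length(init)]  # accept c(vmax0, k0) or just k0
    .stopifnot_scalar(k0, "init k0", positive = TRUE)
    bounds <- c(max(bounds[1L], k0 / 1e3), min(bounds[2L], k0 * 1e3))
  }

  sol <- .mm_solve(S, v, bounds)
  if (!sol$converged)
    .fit_error(paste("Michaelis-Menten fit did not converge:",
                     sol$diagnostics))

  n <- length(S)
  fitted_v <- mm_rate(S, sol$vmax, sol$k)
  res <- v - fitted_v
  residual_sd <- sqrt(sum(res^2) / max(n - 2L, 1L))

  jac <- .mm_jacobian(S, sol$vmax, sol$k)
  jtj <- crossprod(jac)
  cond <- .cond2x2(jtj)
  cov <- tryCatch(residual_sd^2 * solve(jtj),
                  error = function(e) matrix(NA_real_, 2, 2))
  dimnames(cov) <- list(c("vmax", "k_half"), c("vmax", "k_half"))

  fit <- structure(list(
    coefficients = c(vmax = sol$vmax, k_half = sol$k),
    residual_sd = residual_sd,
    cov = cov,
    cond = cond,
    efficiency = sol$vmax / sol$k,
    fitted.values = fitted_v,
    residuals = res,
    data = d,
    n = n,
    bounds = bounds,
    at_bound = sol$at_bound,
    convergence = "converged",
    mc = NULL,
    identifiability = NULL,
    call = match.call()), class = "mm_fit")

  if (n_mc > 0L) {
    fit <- mm_monte_carlo(fit, n = n_mc, seed = seed,
                          noise_sd = noise_floor)
    fit <- mm_identifiability(fit, rsd_threshold = rsd_threshold)
  }
  fit
}

.as_pairs <- function(data) {
  if (!is.data.frame(data))
    .schema_error("data must be a data.frame or kinetic_dataset")
  if (is.null(data$substrate) || is.null(data$rate))
    .schema_error("data needs numeric columns 'substrate' and 'rate'")
  S <- as.numeric(data$substrate); v <- as.numeric(data$rate)
  if (any(!is.finite(S)) || any(S <= 0))
    .schema_error("substrate concentrations must be finite and > 0")
  if (any(!is.finite(v)))
    .schema_error("rates must be finite")
  data.frame(substrate = S, rate = v)
}

# profile SSR over k (vmax solved in closed form); returns list(ssr, vmax)
.mm_profile <- function(logk, S, v) {
  k <- exp(logk)
  x <- S / (k + S)
  vmax <- sum(v * x) / sum(x * x)
  if (!is.finite(vmax) || vmax <= 0) vmax <- .Machine$double.xmin
  r <- v - vmax * x
  list(ssr = sum(r * r), vmax = vmax)
}

# grid + bracketed 1-D optimisation over log(k_half)
.mm_solve <- function(S, v, bounds, n_grid = 41L) {
  lb <- log(bounds[1L]); ub <- log(bounds[2L])
  grid <- seq(lb, ub, length.out = n_grid)
  ssr <- vapply(grid, function(lk) .mm_profile(lk, S, v)$ssr, 0)
  if (all(!is.finite(ssr)))
    return(list(converged = FALSE,
                diagnostics = "profile objective non-finite over the whole grid"))
  i <- which.min(ssr)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, n_grid)]
  opt <- optimize(function(lk) .mm_profile(lk, S, v)$ssr,
                  interval = c(lo, hi), tol = 1e-10)
  k <- exp(opt$minimum)
  prof <- .mm_profile(opt$minimum, S, v)
  at_bound <- i == 1L || i == n_grid
  list(converged = is.finite(prof$ssr) && is.finite(prof$vmax),
       vmax = prof$vmax, k = k, ssr = prof$ssr, at_bound = at_bound,
       diagnostics = "")
}

.mm_jacobian <- function(S, vmax, k) {
  cbind(vmax = S / (k + S), k_half = -vmax * S / (k + S)^2)
}

# exact 2-norm condition number of a symmetric 2x2 matrix
.cond2x2 <- function(m) {
  tr <- m[1, 1] + m[2, 2]
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 0) Inf else l1 / l2
}

# --- S3 methods --------------------------------------------------------------

#' @export
coef.mm_fit <- function(object, ...) object$coefficients

#' @export
vcov.mm_fit <- function(object, ...) object$cov

#' @export
fitted.mm_fit <- function(object, ...) object$fitted.values

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$substrate else newdata$substrate
  mm_rate(s, object$coefficients[["vmax"]], object$coefficients[["k_half"]])
}

#' Simulate noisy rate datasets from a fitted Michaelis-Menten model
#'
#' Draws `nsim` replicate datasets by adding independent homoscedastic
#' Gaussian noise to the fitted rates. The noise standard deviation defaults
#' to the residual SD of the fit — this is the parametric bootstrap behind
#' [mm_monte_carlo()].
#'
#' @param object an `mm_fit`.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param noise_sd noise SD (µM/h); defaults to `object$residual_sd`.
#' @param ... unused.
#' @return data.frame of simulated rate columns `sim_1 ... sim_nsim`; the
#'   substrate grid of the fit applies row-wise.
#' @export
simulate.mm_fit <- function(object, nsim = 1, seed = NULL,
                            noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdv <- if (is.null(noise_sd)) object$residual_sd else noise_sd
  n <- object$n
  sims <- matrix(rnorm(n * nsim, mean = object$fitted.values, sd = sdv),
                 nrow = n, ncol = nsim)
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat("Irreversible Michaelis-Menten fit (in vivo)\n")
  cat(sprintf("  Vmax_cell  = %s uM/h\n  K1/2_cell  = %s uM\n",
              format(x$coefficients[["vmax"]], digits = digits),
              format(x$coefficients[["k_half"]], digits = digits)))
  cat(sprintf("  residual SD = %s uM/h on %d pairs\n",
              format(x$residual_sd, digits = digits), x$n))
  if (!is.null(x$identifiability)) {
    id <- x$identifiability$identifiable
    cat(sprintf("  identifiable: vmax %s, k_half %s\n",
                id[["vmax"]], id[["k_half"]]))
  }
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  catalytic efficiency vmax/k_half = %s 1/h\n",
              format(f$efficiency, digits = digits)))
  cat(sprintf("  Jacobian normal-matrix condition number = %s\n",
              format(f$cond, digits = 3)))
  if (!is.null(f$mc)) {
    cat(sprintf("\nMonte-Carlo uncertainty (n = %d, seed = %d, noise SD = %s, %d refit failure(s)):\n",
                f$mc$n, f$mc$seed, format(f$mc$noise_sd, digits = digits),
                f$mc$n_failed))
    print(format(f$mc$summary, digits = digits))
  }
  if (!is.null(f$identifiability)) {
    id <- f$identifiability
    for (p in names(id$identifiable)) {
      if (id$identifiable[[p]]) {
        cat(sprintf("  %s: identifiable\n", p))
      } else {
        cat(sprintf("  %s: NOT identifiable (%s); lower limit %s\n",
                    p, id$reasons[[p]],
                    format(id$lower_limits[[p]], digits = digits)))
      }
    }
  }
  invisible(x)
}

#' Saturation-curve plot of a Michaelis-Menten fit
#'
#' Data points, fitted curve, and (when a Monte-Carlo analysis is attached)
#' a pointwise 95% confidence band of the fitted curve.
#'
#' @param x an `mm_fit`.
#' @param n_curve points on the curve.
#' @param log_x logarithmic substrate axis.
#' @param ... passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.mm_fit <- function(x, n_curve = 200L, log_x = FALSE, ...) {
  S <- x$data$substrate
  grid <- if (log_x) exp(seq(log(min(S)), log(max(S)), length.out = n_curve))
          else seq(min(S), max(S), length.out = n_curve)
  pred <- mm_rate(grid, x$coefficients[["vmax"]], x$coefficients[["k_half"]])
  band <- NULL
  if (!is.null(x$mc) && nrow(x$mc$samples) > 1L) {
    curves <- apply(x$mc$samples, 1L,
                    function(th) mm_rate(grid, th[1L], th[2L]))
    band <- apply(curves, 1L, quantile, probs = c(0.025, 0.975))
  }
  ylim <- range(x$data$rate, pred, band, finite = TRUE)
  plot(S, x$data$rate, xlab = "substrate (uM)", ylab = "rate (uM/h)",
       log = if (log_x) "x" else "", ylim = ylim,
       pch = 19, col = "grey30", ...)
  if (!is.null(band))
    graphics::polygon(c(grid, rev(grid)), c(band[1L, ], rev(band[2L, ])),
                      col = grDevices::adjustcolor("red", 0.15), border = NA)
  graphics::lines(grid, pred, col = "red", lwd = 2)
  invisible(x)
}
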