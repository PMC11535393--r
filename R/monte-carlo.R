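#' Monte-Carlo uncertainty of Michaelis-Menten parameter estimates
#'
#' Parametric bootstrap: `n` simulated noisy datasets are generated by adding
#' independent Gaussian noise to the fitted rates, where the noise standard
#' deviation is the residual SD of the original fit; each dataset is refitted
#' (restarting from the point estimate) and the distribution of the refitted
#' parameters is summarised by its mean, SD, relative SD and percentile 95%
#' confidence interval. Refit failures are counted, reported and excluded
#' from the summaries.
#'
#' Only the rates are resampled; substrate measurement error is not part of
#' the noise model (the residual SD already absorbs its projection onto the
#' rate axis).
#'
#' @param fit an [mm_fit()] result (point fit).
#' @param n number of simulated datasets (default 1000).
#' @param seed RNG seed; recorded in the result.
#' @param noise_sd optional noise SD override (µM/h). Required when the fit
#'   is noiseless (`residual_sd == 0`), otherwise a degenerate-noise error is
#'   raised advising a user-supplied noise floor.
#' @return the `mm_fit` with its `mc` component filled: `n`, `seed`,
#'   `noise_sd`, `n_failed`, `samples` (matrix of refitted `vmax`, `k_half`)
#'   and `summary` (data.frame with `mean`, `sd`, `rsd`, `ci95_low`,
#'   `ci95_high` per parameter).
#' @export
mm_monte_carlo <- function(fit, n = 1000L, seed = 42L, noise_sd = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  n <- as.integer(n)
  if (n < 2L) .config_error("n must be >= 2 Monte-Carlo datasets")
  sdv <- if (is.null(noise_sd)) fit$residual_sd else noise_sd
  # residual SDs at rounding-error scale are noiseless in all but name
  degenerate <- !is.finite(sdv) ||
    sdv <= 1e-10 * max(abs(fit$data$rate), 1e-300)
  if (degenerate)
    .noise_error(paste("degenerate noise: the fit has residual SD 0",
                       "(noiseless input); supply a noise floor",
                       "(noise_sd / --noise-floor) to run the Monte-Carlo",
                       "analysis"))

  set.seed(as.integer(seed))
  S <- fit$data$substrate
  mu <- fit$fitted.values
  k_hat <- fit$coefficients[["k_half"]]
  # refits restart from the point estimate: search bracketed around k_hat,
  # falling back to the full original bounds if the narrow bracket binds
  narrow <- c(max(fit$bounds[1L], k_hat / 1e3),
              min(fit$bounds[2L], k_hat * 1e3))

  noise <- matrix(rnorm(fit$n * n, sd = sdv), nrow = fit$n, ncol = n)
  samples <- matrix(NA_real_, nrow = n, ncol = 2L,
                    dimnames = list(NULL, c("vmax", "k_half")))
  n_failed <- 0L
  for (j in seq_len(n)) {
    vj <- mu + noise[, j]
    sol <- .mm_solve(S, vj, narrow, n_grid = 15L)
    if (sol$converged && sol$at_bound)
      sol <- .mm_solve(S, vj, fit$bounds, n_grid = 41L)
    if (!sol$converged || !is.finite(sol$vmax) || !is.finite(sol$k)) {
      n_failed <- n_failed + 1L
    } else {
      samples[j, ] <- c(sol$vmax, sol$k)
    }
  }
  ok <- samples[stats::complete.cases(samples), , drop = FALSE]
  if (nrow(ok) < 2L)
    .fit_error(sprintf("Monte-Carlo refits failed (%d/%d); cannot summarise",
                       n_failed, n))

  summ <- do.call(rbind, lapply(c("vmax", "k_half"), function(p) {
    xs <- ok[, p]
    ci <- quantile(xs, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(xs), sd = sd(xs),
               rsd = sd(xs) / mean(xs), ci95_low = ci[1L], ci95_high = ci[2L])
  }))
  rownames(summ) <- summ$parameter

  fit$mc <- list(n = n, seed = as.integer(seed), noise_sd = sdv,
                 n_failed = n_failed, samples = ok, summary = summ)
  fit
}

#' Identifiability triage for a fitted Michaelis-Menten model
#'
#' A parameter is declared non-identifiable when the data do not constrain
#' it, judged from three signals: (i) the relative SD of its Monte-Carlo
#' distribution exceeds `rsd_threshold`; (ii) the Monte-Carlo distribution
#' piles up against a search bound (more than `bound_frac` of the refits land
#' within 5% of a bound on the log scale); (iii) the normal matrix of the
#' Jacobian is near-singular (condition number above `cond_threshold`), which
#' flags both parameters. For each non-identifiable parameter the 2.5th
#' percentile of its Monte-Carlo distribution is reported as a finite lower
#' limit — the data still exclude smaller values even when no upper bound
#' exists.
#'
#' @param fit an `mm_fit` with the Monte-Carlo stage run
#'   ([mm_monte_carlo()]).
#' @param rsd_threshold relative-SD threshold (default 0.5).
#' @param cond_threshold condition-number threshold (default 1e8).
#' @param bound_frac fraction of refits at a bound that triggers the flag
#'   (default 0.05).
#' @return the `mm_fit` with its `identifiability` component filled:
#'   `identifiable` (named logical), `lower_limits` (named numeric; NA for
#'   identifiable parameters), `reasons` (named character), and the
#'   thresholds used.
#' @export
mm_identifiability <- function(fit, rsd_threshold = 0.5,
                               cond_threshold = 1e8, bound_frac = 0.05) {
  stopifnot(inherits(fit, "mm_fit"))
  if (is.null(fit$mc))
    .config_error("run mm_monte_carlo() before assessing identifiability")
  summ <- fit$mc$summary
  samples <- fit$mc$samples

  # pile-up against the k_half search bounds, on the log scale
  lb <- log(fit$bounds[1L]); ub <- log(fit$bounds[2L])
  width <- ub - lb
  lk <- log(samples[, "k_half"])
  pile_k <- mean(lk < lb + 0.05 * width | lk > ub - 0.05 * width)

  near_singular <- !is.finite(fit$cond) || fit$cond > cond_threshold

  verdict <- function(p, piled) {
    reasons <- character(0)
    if (summ[p, "rsd"] > rsd_threshold)
      reasons <- c(reasons, sprintf("MC rsd %.2f > %.2f", summ[p, "rsd"],
                                    rsd_threshold))
    if (piled)
      reasons <- c(reasons, "MC distribution piles onto a search bound")
    if (near_singular)
      reasons <- c(reasons, sprintf("near-singular covariance (cond %.3g)",
                                    fit$cond))
    list(ok = length(reasons) == 0L,
         reason = paste(reasons, collapse = "; "))
  }
  v_vmax <- verdict("vmax", FALSE)
  v_k <- verdict("k_half", pile_k > bound_frac)

  identifiable <- c(vmax = v_vmax$ok, k_half = v_k$ok)
  lower_limits <- c(
    vmax = if (v_vmax$ok) NA_real_
           else quantile(samples[, "vmax"], 0.025, names = FALSE),
    k_half = if (v_k$ok) NA_real_
             else quantile(samples[, "k_half"], 0.025, names = FALSE))

  fit$identifiability <- list(
    identifiable = identifiable,
    lower_limits = lower_limits,
    reasons = c(vmax = v_vmax$reason, k_half = v_k$reason),
    rsd_threshold = rsd_threshold,
    cond_threshold = cond_threshold,
    bound_frac = bound_frac)
  fit
}
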