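#' Three-phase piecewise linear (Buchanan) growth model
#'
#' The Buchanan primary model describes a batch growth curve on the log10
#' scale as three line segments: a lag plateau at `P0` until `t_lag`, a
#' linear rise at the maximum specific growth rate `mu` (log10 cfu/mL per
#' hour) until the carrying capacity `Pmax` is reached at `t_max`, and a
#' stationary plateau thereafter.  `t_max` is not a free parameter: it is
#' fixed by continuity: `t_max = t_lag + (Pmax - P0) * ln(10) / mu`.  As in
#' the usual predictive-microbiology fitters, `mu` is the maximum specific
#' growth rate on the natural-log scale (so the slope on the log10 axis is
#' `mu / ln(10)`), while densities are stored as log10 cfu/mL.
#'
#' @param fit a `buchanan_fit` object, or a list/vector with elements
#'   `P0`, `Pmax`, `t_lag`, `mu`.
#' @param t numeric vector of times (h), non-negative.
#' @return predicted log10 population density at `t`.
#' @examples
#' f <- buchanan_params(P0 = 4.62, Pmax = 8.97, t_lag = 6.31, mu = 0.80)
#' buchanan_predict(f, c(2, 10, 25))
#' @export
buchanan_predict <- function(fit, t) {
  fit <- buchanan_params(fit$P0, fit$Pmax, fit$t_lag, fit$mu)
  if (any(t < 0)) stop("times must be non-negative")
  elapsed <- pmin(pmax(t - fit$t_lag, 0), fit$t_max - fit$t_lag)
  fit$P0 + fit$mu * elapsed / log(10)
}

#' Construct a Buchanan parameter set
#'
#' Validates the four free parameters and derives the log-to-stationary
#' transition time `t_max`.
#'
#' @param P0 log10 initial density (log10 cfu/mL).
#' @param Pmax log10 maximum density (carrying capacity, log10 cfu/mL).
#' @param t_lag lag-phase duration (h).
#' @param mu maximum specific growth rate (natural-log scale, h^-1 as
#'   printed in kinetic-parameter tables), must be > 0.
#' @param sse optional residual sum of squares of a fit.
#' @param converged optional convergence flag of a fit.
#' @return an object of class `buchanan_fit`.
#' @export
buchanan_params <- function(P0, Pmax, t_lag, mu, sse = NA_real_,
                            converged = NA) {
  stopifnot(is.finite(P0), is.finite(Pmax), is.finite(t_lag), is.finite(mu))
  if (mu <= 0) stop("mu must be positive")
  if (Pmax < P0) stop("Pmax must be >= P0")
  if (t_lag < 0) stop("t_lag must be >= 0")
  structure(
    list(P0 = P0, Pmax = Pmax, t_lag = t_lag, mu = mu,
         t_max = t_lag + (Pmax - P0) * log(10) / mu,
         sse = sse, converged = converged),
    class = "buchanan_fit")
}

#' @export
print.buchanan_fit <- function(x, ...) {
  cat("Buchanan three-phase fit\n")
  cat(sprintf("  P0    = %.4f log10 cfu/mL\n", x$P0))
  cat(sprintf("  Pmax  = %.4f log10 cfu/mL\n", x$Pmax))
  cat(sprintf("  t_lag = %.4f h\n", x$t_lag))
  cat(sprintf("  mu    = %.4f h^-1 (ln scale)\n", x$mu))
  cat(sprintf("  t_max = %.4f h (derived)\n", x$t_max))
  if (is.finite(x$sse)) cat(sprintf("  SSE   = %.6g\n", x$sse))
  invisible(x)
}

#' Log-to-stationary transition time of a Buchanan fit
#'
#' The time at which the linear log phase meets the stationary plateau:
#' `t_max = t_lag + (Pmax - P0) * ln(10) / mu`, with `mu` the maximum
#' specific growth rate on the natural-log scale.
#'
#' @inheritParams buchanan_predict
#' @return transition time in hours.
#' @examples
#' transition_time(list(P0 = 4.62, Pmax = 8.97, t_lag = 6.31, mu = 0.80))
#' @export
transition_time <- function(fit) {
  if (!is.finite(fit$mu) || fit$mu <= 0) stop("mu must be positive")
  fit$t_lag + (fit$Pmax - fit$P0) * log(10) / fit$mu
}

#' Assign a growth phase to sampling times
#'
#' Boundary convention: a time exactly at a breakpoint belongs to the
#' earlier phase (`t <= t_lag` is lag, `t_lag < t <= t_max` is log,
#' `t > t_max` is stationary).
#'
#' @inheritParams buchanan_predict
#' @return factor with levels lag, log, stationary.
#' @export
assign_phase <- function(fit, t) {
  tmax <- if (!is.null(fit$t_max)) fit$t_max else transition_time(fit)
  ph <- ifelse(t <= fit$t_lag, "lag", ifelse(t <= tmax, "log", "stationary"))
  factor(ph, levels = c("lag", "log", "stationary"))
}

# Conditionally linear least squares: with the two breakpoints fixed the
# model is linear in (P0, mu); Pmax follows from continuity.
.buchanan_profile_sse <- function(times, values, t_lag, t_max) {
  if (t_max < t_lag) return(list(sse = Inf))
  g <- pmin(pmax(times - t_lag, 0), t_max - t_lag)
  X <- cbind(1, g)
  cf <- tryCatch(qr.coef(qr(X), values), error = function(e) c(NA, NA))
  if (any(!is.finite(cf))) {
    # degenerate design (e.g. all times in one phase): intercept-only
    cf <- c(mean(values), 0)
  }
  res <- values - (cf[1] + cf[2] * g)
  # cf[2] is the log10-scale slope; mu is reported on the ln scale
  list(sse = sum(res^2), P0 = unname(cf[1]), mu = unname(cf[2]) * log(10),
       Pmax = unname(cf[1] + cf[2] * (t_max - t_lag)))
}

#' Fit the Buchanan model to a growth curve
#'
#' Least-squares fit of the three-phase piecewise linear model.  The two
#' breakpoints are profiled on a grid built from the observed sampling
#' times (with midpoint refinement); at each candidate pair the remaining
#' parameters are the exact conditional linear least-squares solution.  The
#' best grid point is then polished with a Nelder-Mead search on the
#' breakpoints.  This avoids the flat/kinked regions of the objective that
#' defeat naive gradient starts on piecewise-linear models.
#'
#' @param curve a data frame with columns `time_h` and `value`, or an
#'   object from [synth_growth_curve()].  If `scale` is "linear" the values
#'   are log10-transformed first.
#' @param scale either "log10" (default; values already log10 cfu/mL) or
#'   "linear" (raw counts/densities, transformed internally).
#' @return a `buchanan_fit` with `sse` and `converged` set.  Degenerate
#'   curves (flat or decreasing, fitted `mu <= 0`) are reported with
#'   `converged = FALSE` and an error is raised, never silently defaulted.
#' @export
fit_buchanan <- function(curve, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  times <- curve$time_h
  values <- curve$value
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 6)
    stop("insufficient data: need at least 6 points to fit three phases")
  if (is.unsorted(times, strictly = TRUE)) {
    o <- order(times)
    times <- times[o]; values <- values[o]
    if (anyDuplicated(times)) stop("times must be strictly increasing")
  }
  if (any(times < 0)) stop("times must be non-negative")
  if (scale == "linear") {
    if (any(values <= 0)) stop("linear-scale values must be positive")
    values <- log10(values)
  }

  # breakpoint candidate grid: observed times plus midpoints
  cand <- sort(unique(c(times, (times[-1] + times[-length(times)]) / 2)))
  best <- list(sse = Inf)
  for (tl in cand) {
    for (tm in cand[cand >= tl]) {
      f <- .buchanan_profile_sse(times, values, tl, tm)
      if (f$sse < best$sse) {
        best <- f; best$t_lag <- tl; best$t_max <- tm
      }
    }
  }

  # polish breakpoints; clamp inside the observation window
  obj <- function(p) {
    tl <- min(max(p[1], 0), max(times))
    tm <- min(max(p[2], tl), max(times))
    .buchanan_profile_sse(times, values, tl, tm)$sse
  }
  op <- stats::optim(c(best$t_lag, best$t_max), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
  tl <- min(max(op$par[1], 0), max(times))
  tm <- min(max(op$par[2], tl), max(times))
  f <- .buchanan_profile_sse(times, values, tl, tm)
  if (f$sse > best$sse) {  # keep grid optimum if polish drifted
    tl <- best$t_lag; tm <- best$t_max
    f <- best
  }

  if (!is.finite(f$mu) || f$mu <= 1e-12 || f$Pmax < f$P0)
    stop("fit did not converge: curve has no identifiable growth phase ",
         "(fitted mu <= 0)")
  buchanan_params(P0 = f$P0, Pmax = f$Pmax, t_lag = tl, mu = f$mu,
                  sse = f$sse, converged = TRUE)
}

#' Simulate a noisy growth curve from known Buchanan parameters
#'
#' Used for parameter-recovery studies: model values plus iid Gaussian
#' noise on the log10 scale.
#'
#' @inheritParams buchanan_predict
#' @param times sampling times (h).
#' @param noise_sd Gaussian noise standard deviation (log10 units), >= 0.
#' @param seed optional integer seed for reproducibility.
#' @param condition,replicate optional labels carried in the output.
#' @return data frame with columns `time_h`, `value`, `condition`,
#'   `replicate` (class `growth_curve`).
#' @export
synth_growth_curve <- function(fit, times, noise_sd = 0, seed = NULL,
                               condition = NA_character_,
                               replicate = NA_integer_) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu_t <- buchanan_predict(fit, times)
  val <- mu_t + if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd)
                else 0
  structure(data.frame(time_h = times, value = val,
                       condition = condition, replicate = replicate),
            class = c("growth_curve", "data.frame"))
}
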