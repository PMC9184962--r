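# Numerical integration front-end and limit-cycle / arrest characterisation.

#' Default all-low initial state for a model
#'
#' Every species starts at zero; limit-cycle statistics are independent of
#' the initial condition once the transient is discarded, so figure-level
#' scenarios start here unless stated otherwise.
#'
#' @param model A \code{"cc_model"}.
#' @return Named numeric state vector of zeros.
#' @export
initial_state <- function(model) {
  stats::setNames(numeric(length(model$states)), model$states)
}

#' Integrate a cell-cycle model
#'
#' Adaptive stiff-capable integration (\code{deSolve::lsoda}) with dense
#' output on the requested grid.  The relaxation oscillations of the
#' bistable models have near-discontinuous jumps, hence the tight default
#' tolerances.
#'
#' @param model A \code{"cc_model"}.
#' @param x0 Initial state (default: [initial_state()]); checked against
#'   the model's invariants.
#' @param times Output time grid (min), strictly increasing, or a length-2
#'   span from which a grid with step \code{dt} is built.
#' @param params Optional parameter override (default \code{model$params}).
#' @param dt Output step when \code{times} is a span (min).
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param method \code{deSolve} method name.
#' @return Object of class \code{"cc_trajectory"}: list with \code{times},
#'   \code{states} (matrix, one row per time), \code{derived} (closure
#'   series: free B55, ENSA-P:B55 complex, ubiquitinated fraction f, active
#'   Wee1/Cdc25 where defined), \code{events} (division times, empty here)
#'   and run metadata.
#' @export
#' @examples
#' tr <- cc_integrate(cc_model("model1"), times = c(0, 200))
#' range(tr$states[, "MPF"])
cc_integrate <- function(model, x0 = NULL, times = c(0, 1000), params = NULL,
                         dt = 0.1, rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  if (is.null(params)) params <- model$params
  if (is.null(x0)) x0 <- initial_state(model)
  .check_state(model, x0)
  if (length(times) == 2L) times <- seq(times[1], times[2], by = dt)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = model$rhs,
                      parms = params, method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failure for ", model$id, " near t = ",
         signif(max(sol[, 1]), 6), "; last state: ",
         paste(signif(sol[nrow(sol), -1], 4), collapse = ", "))
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- model$states
  derived <- t(apply(states, 1L, model$closures, p = params))
  if (length(derived) == 0L) derived <- matrix(numeric(0), nrow = nrow(states))
  structure(list(times = sol[, 1], states = states, derived = derived,
                 events = numeric(0), model_id = model$id, params = params,
                 rtol = rtol, atol = atol),
            class = "cc_trajectory")
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat("<cc_trajectory>", x$model_id, ":", length(x$times), "points over [",
      min(x$times), ",", max(x$times), "] min\n")
  cat("  states:", paste(colnames(x$states), collapse = ", "), "\n")
  if (length(x$events)) cat("  divisions:", length(x$events), "\n")
  invisible(x)
}

#' @export
summary.cc_trajectory <- function(object, ...) {
  rng <- apply(object$states, 2L, range)
  rownames(rng) <- c("min", "max")
  rng
}

#' @export
plot.cc_trajectory <- function(x, vars = NULL, ...) {
  if (is.null(vars)) vars <- colnames(x$states)
  graphics::matplot(x$times, x$states[, vars, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (min)", ylab = "concentration (a.u.)", ...)
  graphics::legend("topright", legend = vars, col = seq_along(vars), lty = 1, bty = "n")
  invisible(x)
}

# Locate local maxima of a series, refined by quadratic interpolation of the
# three samples around each discrete peak (needed for sub-grid period accuracy).
.find_peaks <- function(t, y, min_prominence = 1e-4) {
  n <- length(y)
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[i > 1 & i < n]
  if (!length(i)) return(numeric(0))
  keep <- (y[i] - min(y)) > min_prominence * max(diff(range(y)), .Machine$double.eps)
  i <- i[keep]
  vapply(i, function(k) {
    y0 <- y[k - 1]; y1 <- y[k]; y2 <- y[k + 1]
    denom <- y0 - 2 * y1 + y2
    off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / denom
    t[k] + off * (t[k + 1] - t[k])
  }, numeric(1))
}

#' Find and characterise a limit cycle
#'
#' Integrates the model, discards a transient (by default three putative
#' periods or 500 min, whichever is larger), and measures the period as the
#' mean spacing of successive MPF maxima.  The cycle is flagged converged
#' when at least five maxima are found and the coefficient of variation of
#' their spacings is below \code{cv_tol}.  Non-oscillation is a reported
#' outcome, not an error.
#'
#' @inheritParams cc_integrate
#' @param var Observable on which peaks are measured (default \code{"MPF"},
#'   the reference variable of every model here).
#' @param transient Time to discard (min); \code{NULL} for the default rule.
#' @param max_time Total integration horizon (min).
#' @param dt Output resolution (min); peak times are interpolated below it.
#' @param cv_tol Convergence threshold on the coefficient of variation of
#'   peak spacings.
#' @return Object of class \code{"cc_limit_cycle"}: \code{oscillating},
#'   \code{period} (min), \code{converged}, per-variable \code{max}/
#'   \code{min} over the final cycle, and \code{orbit}, one sampled period.
#' @export
#' @examples
#' lc <- find_limit_cycle(cc_model("model1"))
#' lc$period    # about 46 min
find_limit_cycle <- function(model, x0 = NULL, params = NULL, var = "MPF",
                             transient = NULL, max_time = 4000, dt = 0.1,
                             rtol = 1e-8, atol = 1e-10, cv_tol = 1e-3) {
  if (is.null(params)) params <- model$params
  tr <- cc_integrate(model, x0 = x0, times = c(0, max_time), params = params,
                     dt = dt, rtol = rtol, atol = atol)
  y <- tr$states[, var]
  pk_all <- .find_peaks(tr$times, y)
  no_cycle <- structure(list(oscillating = FALSE, period = NA_real_,
                             converged = FALSE, max = NULL, min = NULL,
                             orbit = NULL, model_id = model$id),
                        class = "cc_limit_cycle")
  if (length(pk_all) < 3L) return(no_cycle)
  est_period <- stats::median(diff(pk_all))
  if (is.null(transient)) transient <- max(3 * est_period, 500)
  pk <- pk_all[pk_all > transient]
  if (length(pk) < 5L) {
    # transient rule left too few peaks; keep the last five if available
    if (length(pk_all) >= 5L) pk <- utils::tail(pk_all, 5L) else return(no_cycle)
  }
  sp <- diff(pk)
  # amplitude must be non-degenerate (a decaying focus has shrinking peaks)
  sel <- tr$times > utils::tail(pk, 1) - 2 * mean(sp)
  amp <- diff(range(y[sel]))
  if (amp < 1e-5) return(no_cycle)
  period <- mean(sp)
  cv <- stats::sd(sp) / period
  keep <- tr$times >= utils::tail(pk, 2)[1] & tr$times <= utils::tail(pk, 1)
  orbit <- cbind(time = tr$times[keep], tr$states[keep, , drop = FALSE])
  structure(list(oscillating = TRUE, period = period, converged = cv < cv_tol,
                 cv = cv, n_peaks = length(pk),
                 max = apply(tr$states[sel, , drop = FALSE], 2L, max),
                 min = apply(tr$states[sel, , drop = FALSE], 2L, min),
                 orbit = orbit, model_id = model$id),
            class = "cc_limit_cycle")
}

#' @export
print.cc_limit_cycle <- function(x, ...) {
  if (!x$oscillating) {
    cat("<cc_limit_cycle>", x$model_id, ": no sustained oscillation detected\n")
  } else {
    cat("<cc_limit_cycle>", x$model_id, sprintf(": period %.3f min (cv %.2g, %s)\n",
        x$period, x$cv, if (x$converged) "converged" else "not converged"))
    amp <- rbind(max = x$max, min = x$min)
    print(signif(amp, 4))
  }
  invisible(x)
}

#' Classify long-time behaviour: arrested steady state or oscillation
#'
#' Integrates over \code{horizon} and inspects a trailing window: if the
#' maximum derivative magnitude stays below \code{rhs_tol} and the state
#' drifts by less than \code{drift_tol}, the system is declared at a steady
#' state (a checkpoint arrest when that replaces a limit cycle); otherwise
#' the decision is deferred to [find_limit_cycle()].
#'
#' @inheritParams find_limit_cycle
#' @param horizon Integration horizon (min).
#' @param window Fraction of the horizon used as trailing window.
#' @param rhs_tol,drift_tol Steady-state thresholds.
#' @return List with \code{classification} (\code{"steady-state"},
#'   \code{"oscillation"} or \code{"inconclusive"}), \code{terminal_state},
#'   and the \code{cycle} object when oscillating.
#' @export
#' @examples
#' g2 <- apply_checkpoint(cc_model("model4"), "G2")
#' detect_arrest(g2)$classification   # "steady-state"
detect_arrest <- function(model, x0 = NULL, params = NULL, horizon = 6000,
                          window = 0.1, rhs_tol = 1e-8, drift_tol = 1e-6,
                          rtol = 1e-10, atol = 1e-12) {
  if (is.null(params)) params <- model$params
  tr <- cc_integrate(model, x0 = x0, times = c(0, horizon), params = params,
                     dt = 1, rtol = rtol, atol = atol)
  n <- length(tr$times)
  tail_idx <- seq.int(max(1L, floor((1 - window) * n)), n)
  rhs_max <- max(vapply(tail_idx, function(i)
    max(abs(model$rhs(tr$times[i], tr$states[i, ], params)[[1]])), numeric(1)))
  drift <- max(abs(tr$states[utils::tail(tail_idx, 1), ] -
                   tr$states[tail_idx[1], ]))
  terminal <- stats::setNames(tr$states[n, ], colnames(tr$states))
  if (rhs_max < rhs_tol && drift < drift_tol)
    return(list(classification = "steady-state", terminal_state = terminal,
                rhs_max = rhs_max, drift = drift))
  lc <- find_limit_cycle(model, x0 = x0, params = params, max_time = horizon)
  if (lc$oscillating)
    return(list(classification = "oscillation", terminal_state = terminal,
                cycle = lc))
  list(classification = "inconclusive", terminal_state = terminal,
       rhs_max = rhs_max, drift = drift)
}
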