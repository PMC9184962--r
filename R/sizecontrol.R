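# Hybrid simulation of size-controlled division in fission yeast: the
# dual-switch network (model4) with total Cdc25 tied to cell size V,
# dV/dt = mu*V, and V -> V/2 at division.  Division fires on the downward
# crossing of MPF through `exit_threshold`, armed only after MPF has
# exceeded `entry_threshold` (mitotic entry) since the last division.
# Protein concentrations are intensive and stay continuous across division;
# only V is halved.

#' Simulate size-controlled cell division cycles
#'
#' Runs the dual-switch cell-cycle network with \code{Cdc25_tot = V(t)},
#' exponential growth \code{dV/dt = mu V}, and a factor-of-two reduction of
#' V at each division.  Crossings are located by the integrator's
#' root-finding (\code{deSolve::lsodar}), so division times are accurate to
#' the root tolerance, far below the output step.
#'
#' @param params Model-4 parameter list (default: reference set).
#' @param mu Specific growth rate (per min).
#' @param v0 Initial cell size (a.u.).
#' @param entry_threshold MPF level defining mitotic entry (arms division).
#' @param exit_threshold MPF level whose downward crossing triggers
#'   division; must be below \code{entry_threshold}.
#' @param n_cycles Number of divisions to record.
#' @param x0 Initial protein state (default: all-low).
#' @param max_time Safety horizon (min); exceeded means the cell never
#'   divides under these conditions, which is reported as an error with the
#'   final state.
#' @param dt Output resolution (min).
#' @param rtol,atol Integration tolerances.
#' @return Object of class \code{"cc_lineage"}: \code{divisions} (one row
#'   per division: time, size at division and at birth, cycle duration,
#'   MPF peak of the cycle), plus the full \code{trajectory} including V.
#' @export
#' @examples
#' \donttest{
#' lin <- simulate_size_control(n_cycles = 6)
#' interdivision_stats(lin)
#' }
simulate_size_control <- function(params = NULL, mu = 0.005, v0 = 0.6,
                                  entry_threshold = 0.5, exit_threshold = 0.2,
                                  n_cycles = 10, x0 = NULL, max_time = 20000,
                                  dt = 0.5, rtol = 1e-9, atol = 1e-11) {
  if (mu <= 0) stop("'mu' must be positive")
  if (exit_threshold >= entry_threshold)
    stop("require exit_threshold < entry_threshold")
  base <- cc_model("model4", params = params)
  p <- base$params
  nst <- length(base$states)           # 6 protein states, V appended as 7th
  mpf_i <- match("MPF", base$states)
  rhs <- function(t, x, q) {
    q$Cdc25_tot <- x[nst + 1L]
    dx <- base$rhs(t, x[seq_len(nst)], q)[[1]]
    list(c(dx, mu * x[nst + 1L]))
  }
  root <- function(t, x, q) c(x[mpf_i] - entry_threshold,
                              x[mpf_i] - exit_threshold)
  if (is.null(x0)) x0 <- initial_state(base)
  .check_state(base, x0)
  state <- c(as.numeric(x0), v0)
  t0 <- 0
  armed <- FALSE
  v_birth <- v0
  t_birth <- 0
  mpf_peak <- 0
  divisions <- NULL
  times_all <- NULL
  states_all <- NULL
  while (is.null(divisions) || nrow(divisions) < n_cycles) {
    if (t0 > max_time)
      stop("no division within allotted time; last state: ",
           paste(signif(state, 4), collapse = ", "))
    grid <- seq(t0, min(t0 + 2000, max_time + 2000), by = dt)
    sol <- deSolve::lsodar(y = state, times = grid, func = rhs, parms = p,
                           rootfunc = root, rtol = rtol, atol = atol)
    seg_t <- sol[, 1]
    seg_x <- sol[, -1, drop = FALSE]
    mpf_peak <- max(mpf_peak, max(seg_x[, mpf_i]))
    # mitotic entry is a level condition: MPF exceeded the entry threshold
    # at some point since the last division
    if (max(seg_x[, mpf_i]) >= entry_threshold) armed <- TRUE
    keep <- if (is.null(times_all)) TRUE else seg_t > utils::tail(times_all, 1)
    times_all <- c(times_all, seg_t[keep])
    states_all <- rbind(states_all, seg_x[keep, , drop = FALSE])
    t_end <- utils::tail(seg_t, 1)
    x_end <- seg_x[nrow(seg_x), ]
    troot <- attr(sol, "troot")
    if (!is.null(troot) && length(troot)) {
      # did the stopping root fall through the exit threshold while armed?
      d_end <- rhs(t_end, x_end, p)[[1]][mpf_i]
      near_exit <- abs(x_end[mpf_i] - exit_threshold) <
        abs(x_end[mpf_i] - entry_threshold)
      if (near_exit && armed && d_end < 0) {
        v_div <- x_end[nst + 1L]
        divisions <- rbind(divisions, data.frame(
          time = t_end, V_division = v_div, V_birth = v_div / 2,
          cycle_duration = t_end - t_birth, MPF_peak = mpf_peak))
        x_end[nst + 1L] <- v_div / 2
        armed <- FALSE
        t_birth <- t_end
        mpf_peak <- 0
      }
    }
    # hop a short root-free stretch so a root sitting exactly at the restart
    # point cannot re-fire and stall the sweep; relaxation jumps take minutes,
    # so a 0.05-min hop cannot step over a crossing undetected
    hop_dt <- 0.05
    hop <- deSolve::ode(y = x_end, times = c(t_end, t_end + hop_dt),
                        func = rhs, parms = p, rtol = rtol, atol = atol)
    x_hop <- hop[nrow(hop), -1]
    if (x_hop[mpf_i] >= entry_threshold) armed <- TRUE
    state <- x_hop
    times_all <- c(times_all, t_end + hop_dt)
    states_all <- rbind(states_all, matrix(x_hop, nrow = 1))
    mpf_peak <- max(mpf_peak, x_hop[mpf_i])
    t0 <- t_end + hop_dt
  }
  states <- states_all
  colnames(states) <- c(base$states, "V")
  structure(list(divisions = divisions,
                 trajectory = structure(list(times = times_all, states = states,
                                             derived = NULL,
                                             events = divisions$time,
                                             model_id = "model4_size",
                                             params = p, rtol = rtol, atol = atol),
                                        class = "cc_trajectory"),
                 mu = mu, v0 = v0, entry_threshold = entry_threshold,
                 exit_threshold = exit_threshold),
            class = "cc_lineage")
}

#' @export
print.cc_lineage <- function(x, ...) {
  cat("<cc_lineage>", nrow(x$divisions), "divisions, mu =", x$mu, "per min\n")
  print(utils::head(x$divisions, 10))
  invisible(x)
}

#' @export
plot.cc_lineage <- function(x, ...) {
  tr <- x$trajectory
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(tr$times, tr$states[, "V"], type = "l", xlab = "time (min)",
                 ylab = "cell size V (a.u.)", ...)
  graphics::abline(v = x$divisions$time, col = "grey80", lty = 3)
  graphics::plot(tr$times, tr$states[, "MPF"], type = "l", xlab = "time (min)",
                 ylab = "[MPF] (a.u.)")
  graphics::abline(h = x$exit_threshold, col = "red", lty = 2)
  invisible(x)
}

#' Interdivision statistics of a lineage
#'
#' Summary of cycle durations and sizes over the retained cycles, after
#' discarding the first \code{discard} cycles as transient (newborn cells
#' inherit an arbitrary initial protein state; size homeostasis draws the
#' birth size to its fixed point within a couple of cycles).
#'
#' @param trace A \code{"cc_lineage"} from [simulate_size_control()].
#' @param discard Number of leading cycles to drop.
#' @return List: \code{n_cycles}, \code{mean_cycle}, \code{cv_cycle},
#'   \code{mean_V_birth}, \code{mean_V_division}.
#' @export
interdivision_stats <- function(trace, discard = 2L) {
  d <- if (inherits(trace, "cc_lineage")) trace$divisions else trace
  if (nrow(d) < discard + 3L)
    stop("need at least ", discard + 3L, " completed cycles, have ", nrow(d))
  d <- d[-seq_len(discard), , drop = FALSE]
  list(n_cycles = nrow(d),
       mean_cycle = mean(d$cycle_duration),
       cv_cycle = stats::sd(d$cycle_duration) / mean(d$cycle_duration),
       mean_V_birth = mean(d$V_birth),
       mean_V_division = mean(d$V_division))
}
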