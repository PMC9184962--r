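# Pseudo-arclength continuation of steady-state branches with fold and
# Hopf detection, SNIC classification by period divergence, pseudo-nullcline
# computation and limit-cycle envelopes.  The corrector is a Newton
# iteration on the residual augmented with the arclength constraint; the
# predictor is the secant through the last two accepted points.

# Residual of the extended system y = (x, q), q the free parameter.
.make_F <- function(model, params, free_param) {
  n <- length(model$states)
  function(y) {
    params[[free_param]] <- y[n + 1L]
    model$rhs(0, y[seq_len(n)], params)[[1]]
  }
}

# Rectangular Jacobian dF/dy (n x n+1) by central differences.
.fd_jacobian_rect <- function(f, y, rel_step = 1e-6) {
  m <- length(f(y))
  J <- matrix(0, m, length(y))
  for (i in seq_along(y)) {
    h <- rel_step * max(abs(y[i]), 0.01)
    yp <- y; ym <- y
    yp[i] <- y[i] + h
    ym[i] <- y[i] - h
    J[, i] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

# One pseudo-arclength corrector solve: find y with F(y)=0 and
# t.(y - yB) = ds, Newton from the predictor.
.arc_correct <- function(Ffun, y, tv, yB, ds, tol = 1e-11, maxit = 40L) {
  for (k in seq_len(maxit)) {
    rr <- c(Ffun(y), sum((y - yB) * tv) - ds)
    if (max(abs(rr)) < tol) return(list(y = y, ok = TRUE))
    J <- rbind(.fd_jacobian_rect(Ffun, y), tv)
    dy <- tryCatch(solve(J, -rr), error = function(e) NULL)
    if (is.null(dy)) return(list(ok = FALSE))
    y <- y + dy
  }
  list(ok = FALSE)
}

# Natural continuation solve at fixed parameter value (used by the Hopf
# bisection, where the branch is locally not folded).
.solve_at_param <- function(model, params, free_param, q, x_guess, tol = 1e-12) {
  params[[free_param]] <- q
  f <- function(x) model$rhs(0, x, params)[[1]]
  .newton(f, x_guess, tol = tol)
}

# Largest real part among the complex-conjugate eigenvalues (the Hopf test
# function); -Inf when the spectrum is entirely real.
.complex_max_re <- function(ev, eps = 1e-9) {
  cp <- abs(Im(ev)) > eps
  if (!any(cp)) return(-Inf)
  max(Re(ev[cp]))
}

# Refine a fold bracketed by three consecutive branch points: swap roles so
# the state component changing fastest across the bracket becomes the
# continuation variable, express the parameter as a smooth function q(x_k),
# and locate its interior extremum with Brent's method.
.refine_fold <- function(model, params, free_param, yA, yB, yC) {
  n <- length(model$states)
  d <- abs(yC[seq_len(n)] - yA[seq_len(n)])
  k <- which.max(d)
  if (d[k] < 1e-12) return(list(param = yB[n + 1L],
                                state = yB[seq_len(n)], ok = FALSE))
  q_of <- function(xk) {
    g <- function(z) {   # z = (x[-k], q)
      x <- numeric(n)
      x[-k] <- z[seq_len(n - 1L)]
      x[k] <- xk
      params[[free_param]] <- z[n]
      model$rhs(0, x, params)[[1]]
    }
    z0 <- c(yB[seq_len(n)][-k], yB[n + 1L])
    r <- .newton(g, z0, tol = 1e-12)
    if (!r$ok) return(NA_real_)
    r$x[n]
  }
  lo <- min(yA[k], yC[k]); hi <- max(yA[k], yC[k])
  qm <- q_of(yB[k]); qe <- q_of(lo)
  if (is.na(qm) || is.na(qe)) return(list(param = yB[n + 1L],
                                          state = yB[seq_len(n)], ok = FALSE))
  maximum <- qm > qe
  opt <- stats::optimize(function(v) { q <- q_of(v); if (is.na(q)) yB[n + 1L] else q },
                         lower = lo, upper = hi, maximum = maximum,
                         tol = 1e-10)
  qstar <- if (maximum) opt$objective else opt$objective
  xkstar <- if (maximum) opt$maximum else opt$minimum
  # recover the full state at the fold
  g <- function(z) {
    x <- numeric(n)
    x[-k] <- z[seq_len(n - 1L)]
    x[k] <- xkstar
    params[[free_param]] <- z[n]
    model$rhs(0, x, params)[[1]]
  }
  r <- .newton(g, c(yB[seq_len(n)][-k], yB[n + 1L]), tol = 1e-12)
  xs <- numeric(n)
  if (r$ok) { xs[-k] <- r$x[seq_len(n - 1L)]; xs[k] <- xkstar }
  else xs <- yB[seq_len(n)]
  list(param = qstar, state = stats::setNames(xs, model$states), ok = r$ok)
}

# Refine a Hopf point bracketed by two branch points via bisection on the
# free parameter, tracking the complex-pair real part.
.refine_hopf <- function(model, params, free_param, yL, yR, tol = 1e-8) {
  n <- length(model$states)
  eval_at <- function(q, guess) {
    r <- .solve_at_param(model, params, free_param, q, guess)
    if (!r$ok) return(NULL)
    params[[free_param]] <- q
    J <- .fd_jacobian(function(x) model$rhs(0, x, params)[[1]], r$x)
    ev <- eigen(J, only.values = TRUE)$values
    list(x = r$x, re = .complex_max_re(ev), ev = ev)
  }
  qL <- yL[n + 1L]; qR <- yR[n + 1L]
  gL <- eval_at(qL, yL[seq_len(n)])
  gR <- eval_at(qR, yR[seq_len(n)])
  if (is.null(gL) || is.null(gR) || !is.finite(gL$re) || !is.finite(gR$re) ||
      sign(gL$re) == sign(gR$re))
    return(list(param = (qL + qR) / 2, state = yL[seq_len(n)], ok = FALSE,
                omega = NA_real_))
  for (i in 1:60) {
    qm <- (qL + qR) / 2
    gm <- eval_at(qm, (gL$x + gR$x) / 2)
    if (is.null(gm)) break
    if (sign(gm$re) == sign(gL$re)) { qL <- qm; gL <- gm } else { qR <- qm; gR <- gm }
    if (abs(qR - qL) < tol * max(1, abs(qm))) break
  }
  cp <- gL$ev[abs(Im(gL$ev)) > 1e-9]
  omega <- if (length(cp)) max(abs(Im(cp))) else NA_real_
  list(param = (qL + qR) / 2, state = stats::setNames(gL$x, model$states),
       ok = TRUE, omega = omega)
}

#' Continue a steady-state branch in one parameter
#'
#' Pseudo-arclength continuation (secant predictor, Newton corrector) of
#' the steady states of a model as one parameter varies.  Folds are flagged
#' where the branch's parameter direction reverses and refined by a local
#' role-swap and Brent search; Hopf points are flagged where a
#' complex-conjugate eigenvalue pair of the Jacobian crosses the imaginary
#' axis and refined by bisection on the parameter.
#'
#' @param model A \code{"cc_model"} (full or clamped).
#' @param free_param Name of the parameter to vary (any entry of the
#'   parameter list, including a clamped state's name).
#' @param range Length-2 parameter interval to cover.
#' @param params Optional parameter override.
#' @param x0 Starting steady state at \code{range[1]} (or \code{range[2]}
#'   when \code{direction = -1}); located automatically when \code{NULL}.
#' @param direction +1 to start at \code{range[1]}, -1 at \code{range[2]}.
#' @param ds Initial arclength step.
#' @param ds_max Maximum arclength step.
#' @param max_points Cap on accepted branch points.
#' @param stop_at_first_fold Stop (after refining) once the first fold is
#'   passed: used for directed hysteresis sweeps.
#' @return Object of class \code{"cc_branch"}: \code{points} (data frame of
#'   parameter value, state columns, leading eigenvalue real part, number
#'   of unstable eigenvalues, stability class), \code{folds} and
#'   \code{hopfs} (lists of refined bifurcation points).
#' @export
continue_branch <- function(model, free_param, range, params = NULL, x0 = NULL,
                            direction = 1, ds = 0.004, ds_max = 0.01,
                            max_points = 4000L, stop_at_first_fold = FALSE) {
  if (is.null(params)) params <- model$params
  n <- length(model$states)
  q0 <- if (direction > 0) range[1] else range[2]
  if (is.null(x0)) {
    # cheap route first: relax from the all-low state and polish by Newton;
    # fall back to the multi-start grid search if that lands nowhere
    params0 <- params
    params0[[free_param]] <- q0
    tr <- cc_integrate(model, times = c(0, 20000), params = params0, dt = 20,
                       rtol = 1e-10, atol = 1e-12)
    guess <- tr$states[nrow(tr$states), ]
    pol <- .solve_at_param(model, params, free_param, q0, as.numeric(guess))
    if (pol$ok && .is_admissible(model, params0, pol$x)) {
      x0 <- pol$x
    } else {
      ss <- find_steady_states(model, params = params0)
      if (!length(ss)) stop("no steady state found at ", free_param, " = ", q0)
      stable <- which(vapply(ss, function(s) startsWith(s$class, "stable"), logical(1)))
      x0 <- if (length(stable)) ss[[stable[1]]]$state else ss[[1]]$state
    }
  }
  Ffun <- .make_F(model, params, free_param)
  # correct the start and take one natural step to seed the secant
  r0 <- .solve_at_param(model, params, free_param, q0, as.numeric(x0))
  if (!r0$ok) stop("could not converge the starting steady state")
  h0 <- direction * max(1e-3 * abs(diff(range)), 1e-5)
  r1 <- .solve_at_param(model, params, free_param, q0 + h0, r0$x)
  if (!r1$ok) stop("could not take the initial continuation step")
  y_prev <- c(r0$x, q0)
  y_curr <- c(r1$x, q0 + h0)
  eig_at <- function(y) {
    params[[free_param]] <- y[n + 1L]
    J <- .fd_jacobian(function(x) model$rhs(0, x, params)[[1]], y[seq_len(n)])
    eigen(J, only.values = TRUE)$values
  }
  rows <- vector("list", 0L)
  record <- function(y) {
    ev <- eig_at(y)
    rows[[length(rows) + 1L]] <<- c(y[n + 1L], y[seq_len(n)], max(Re(ev)),
                                    .complex_max_re(ev), sum(Re(ev) > 1e-8))
  }
  record(y_prev); record(y_curr)
  folds <- list(); hopfs <- list()
  y_trail <- list(y_prev, y_curr)
  dq_prev <- y_curr[n + 1L] - y_prev[n + 1L]
  step <- ds
  while (length(rows) < max_points) {
    yA <- y_trail[[length(y_trail) - 1L]]
    yB <- y_trail[[length(y_trail)]]
    tv <- yB - yA
    tv <- tv / sqrt(sum(tv^2))
    res <- .arc_correct(Ffun, yB + step * tv, tv, yB, step)
    ok <- isTRUE(res$ok) && sqrt(sum((res$y - yB)^2)) < 3 * step
    if (!ok) {
      step <- step / 2
      if (step < 1e-8) break
      next
    }
    y <- res$y
    record(y)
    dq <- y[n + 1L] - yB[n + 1L]
    if (dq * dq_prev < 0) {
      fr <- .refine_fold(model, params, free_param, yA, yB, y)
      # stability adjacency: is any flanking branch point attracting?  (At
      # the fold itself the critical eigenvalue sits at zero, so the point
      # one step back is the reliable witness of the stable side.)
      flank <- rows[seq.int(max(1L, length(rows) - 2L), length(rows))]
      fr$adjacent_stable <- any(vapply(flank, `[[`, numeric(1), n + 4L) == 0)
      fr$index <- length(rows) - 1L
      folds[[length(folds) + 1L]] <- fr
      if (stop_at_first_fold) {
        y_trail[[length(y_trail) + 1L]] <- y
        break
      }
    }
    # Hopf test between consecutive points
    prev_row <- rows[[length(rows) - 1L]]
    curr_row <- rows[[length(rows)]]
    reL <- prev_row[n + 3L]; reR <- curr_row[n + 3L]
    if (is.finite(reL) && is.finite(reR) && sign(reL) != sign(reR) &&
        reL != 0 && dq * dq_prev > 0) {
      hr <- .refine_hopf(model, params, free_param, yB, y)
      if (hr$ok) hopfs[[length(hopfs) + 1L]] <- hr
    }
    dq_prev <- dq
    y_trail[[length(y_trail) + 1L]] <- y
    if (length(y_trail) > 3L) y_trail <- y_trail[-1L]
    step <- min(step * 1.2, ds_max)
    if (y[n + 1L] > max(range) + 1e-9 || y[n + 1L] < min(range) - 1e-9) break
  }
  pts <- do.call(rbind, rows)
  colnames(pts) <- c(free_param, model$states, "max_re", "complex_max_re",
                     "n_unstable")
  pts <- as.data.frame(pts)
  pts$class <- ifelse(pts$n_unstable == 0L, "stable",
                      ifelse(pts$max_re > 1e-8 &
                             pts$n_unstable < length(model$states), "saddle/unstable",
                             "unstable"))
  structure(list(points = pts, folds = folds, hopfs = hopfs,
                 free_param = free_param, model_id = model$id, range = range),
            class = "cc_branch")
}

#' @export
print.cc_branch <- function(x, ...) {
  cat("<cc_branch>", x$model_id, "over", x$free_param, "in [",
      paste(signif(x$range, 4), collapse = ", "), "]:",
      nrow(x$points), "points\n")
  if (length(x$folds))
    cat("  folds at", x$free_param, "=",
        paste(signif(vapply(x$folds, `[[`, numeric(1), "param"), 5), collapse = ", "), "\n")
  if (length(x$hopfs))
    cat("  Hopf at", x$free_param, "=",
        paste(signif(vapply(x$hopfs, `[[`, numeric(1), "param"), 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cc_branch <- function(x, var = NULL, ...) {
  if (is.null(var)) var <- setdiff(colnames(x$points), x$free_param)[1]
  stable <- x$points$n_unstable == 0
  graphics::plot(x$points[[x$free_param]], x$points[[var]], type = "n",
                 xlab = x$free_param, ylab = var, ...)
  graphics::lines(x$points[[x$free_param]], x$points[[var]], col = "grey70", lty = 2)
  graphics::points(x$points[[x$free_param]][stable], x$points[[var]][stable],
                   pch = 16, cex = 0.4, col = "red")
  for (f in x$folds)
    graphics::abline(v = f$param, col = "blue", lty = 3)
  for (h in x$hopfs)
    graphics::abline(v = h$param, col = "darkgreen", lty = 3)
  invisible(x)
}

#' Classify a fold as SNIC or plain saddle-node by period divergence
#'
#' A saddle-node on an invariant circle (SNIC) gives birth to a
#' large-amplitude oscillation whose period diverges as the parameter
#' approaches the fold.  The test probes the oscillatory side of the fold
#' at a decreasing sequence of offsets: the fold is declared a SNIC when
#' stable oscillations exist at every probe, their measured period
#' increases monotonically towards the fold, and the period closest to the
#' fold exceeds \code{factor} times the far-field period.
#'
#' @param model,params,free_param As in [continue_branch()].
#' @param fold_param Parameter value of the fold.
#' @param side +1 when oscillations live above the fold value, -1 below.
#' @param offsets Decreasing probe distances from the fold.
#' @param factor Period-divergence factor required (operational criterion).
#' @param x0 Initial state for the oscillation probes.
#' @param max_time Integration horizon per probe (min).
#' @return List with \code{classification} (\code{"SNIC"}, \code{"fold"} or
#'   \code{"inconclusive"}), probe \code{offsets} and \code{periods}.
#' @export
classify_snic <- function(model, free_param, fold_param, params = NULL,
                          side = 1, offsets = c(0.15, 0.05, 0.01, 1e-4),
                          factor = 5, x0 = NULL, max_time = 8000) {
  if (is.null(params)) params <- model$params
  offsets <- sort(offsets, decreasing = TRUE)
  periods <- rep(NA_real_, length(offsets))
  for (i in seq_along(offsets)) {
    p <- params
    p[[free_param]] <- fold_param + side * offsets[i]
    lc <- tryCatch(
      suppressWarnings(
        find_limit_cycle(model, x0 = x0, params = p, max_time = max_time,
                         dt = 0.2)),
      error = function(e) list(oscillating = FALSE))
    if (!lc$oscillating)
      return(list(classification = "fold", offsets = offsets, periods = periods))
    if (!lc$converged && lc$n_peaks < 5L)
      return(list(classification = "inconclusive", offsets = offsets,
                  periods = periods))
    periods[i] <- lc$period
  }
  monotone <- all(diff(periods) > 0)
  diverged <- periods[length(periods)] > factor * periods[1]
  list(classification = if (monotone && diverged) "SNIC" else "fold",
       offsets = offsets, periods = periods)
}

#' Pseudo-nullcline of a model
#'
#' Removes one state variable's ODE, treats that variable as a parameter,
#' and continues the steady states of the reduced system over a range of
#' the clamped value: the high-dimensional generalisation of a nullcline
#' used to project these models onto informative phase planes.  Two
#' directed sweeps, one from each end of the range starting on the stable
#' branch, locate the hysteresis folds (the activation/inactivation
#' thresholds); reduced systems of dimension four and above can carry
#' additional folds on unstable interior segments, which are retained in
#' the curve data but do not enter the shape classification.
#'
#' @param model A full \code{"cc_model"}.
#' @param clamp_var State variable to clamp (e.g. \code{"MPF"},
#'   \code{"CycBT"}).
#' @param clamp_range Range of the clamped value.
#' @param response_var Variable reported as the response (default: the
#'   model's first remaining state).
#' @param params Optional parameter override.
#' @param ds,ds_max Continuation step controls.
#' @return Object of class \code{"cc_nullcline"}: \code{curve} (full branch
#'   points), \code{folds} (the hysteresis folds, length 0 or 2),
#'   \code{shape} (\code{"monotone"}, \code{"S-shaped"}, \code{"Z-shaped"}
#'   or \code{"complex"}), and the sweep branches.
#' @export
#' @examples
#' \donttest{
#' nc <- pseudo_nullcline(cc_model("model4"), "CycBT", c(0.2, 2))
#' nc$shape; vapply(nc$folds, `[[`, numeric(1), "param")
#' }
pseudo_nullcline <- function(model, clamp_var, clamp_range,
                             response_var = NULL, params = NULL,
                             ds = 0.004, ds_max = 0.01) {
  if (is.null(params)) params <- model$params
  model$params <- params
  red <- clamp_state(model, clamp_var, value = clamp_range[1])
  if (is.null(response_var)) response_var <- red$states[1]
  full <- continue_branch(red, clamp_var, clamp_range, direction = 1,
                          ds = ds, ds_max = ds_max)
  # Hysteresis thresholds: the extreme folds that terminate *stable*
  # segments of the curve.  Reduced systems of dimension >= 4 can fold
  # several more times on interior (unstable or sub-segmented) stretches;
  # those do not bound the bistable window.
  sa <- Filter(function(f) isTRUE(f$adjacent_stable), full$folds)
  folds <- list()
  if (length(sa)) {
    qs <- vapply(sa, `[[`, numeric(1), "param")
    if (length(sa) >= 2L && diff(range(qs)) > 1e-8) {
      folds <- list(activation = sa[[which.max(qs)]],
                    inactivation = sa[[which.min(qs)]])
    } else folds <- list(fold = sa[[1L]])
  }
  shape <- if (length(full$folds) == 0L) "monotone"
           else if (length(folds) == 2L) {
             st <- full$points[full$points$n_unstable == 0, ]
             slope <- if (nrow(st) > 2)
               stats::coef(stats::lm(st[[response_var]] ~ st[[clamp_var]]))[2]
             else 1
             if (is.finite(slope) && slope < 0) "Z-shaped" else "S-shaped"
           } else "complex"
  structure(list(curve = full$points, folds = folds, shape = shape,
                 clamp_var = clamp_var, response_var = response_var,
                 branch = full, model_id = model$id),
            class = "cc_nullcline")
}

#' @export
print.cc_nullcline <- function(x, ...) {
  cat("<cc_nullcline>", x$model_id, ": clamp", x$clamp_var, "->",
      x$response_var, "(", x$shape, ")\n")
  for (nm in names(x$folds))
    cat("  ", nm, "fold at", x$clamp_var, "=",
        signif(x$folds[[nm]]$param, 5), "\n")
  invisible(x)
}

#' Limit-cycle envelope over a parameter sweep
#'
#' Brute-force characterisation used for one-parameter bifurcation
#' diagrams: at each parameter value the model is integrated from a fixed
#' initial state, oscillation is detected, and the extrema and period of
#' the observable are recorded (the terminal value when at steady state).
#'
#' @inheritParams continue_branch
#' @param values Parameter values to probe.
#' @param var Observable (default \code{"MPF"}).
#' @param max_time Integration horizon per value (min).
#' @return Data frame (class \code{"cc_envelope"}): parameter, oscillating
#'   flag, max, min, period.
#' @export
cycle_envelope <- function(model, free_param, values, params = NULL,
                           var = "MPF", x0 = NULL, max_time = 4000) {
  if (is.null(params)) params <- model$params
  rows <- lapply(values, function(v) {
    p <- params
    p[[free_param]] <- v
    lc <- find_limit_cycle(model, x0 = x0, params = p, var = var,
                           max_time = max_time, dt = 0.2)
    if (lc$oscillating)
      data.frame(param = v, oscillating = TRUE, max = lc$max[[var]],
                 min = lc$min[[var]], period = lc$period)
    else {
      tr <- cc_integrate(model, x0 = x0, times = c(0, max_time), params = p,
                         dt = 1)
      terminal <- tr$states[nrow(tr$states), var]
      data.frame(param = v, oscillating = FALSE, max = terminal,
                 min = terminal, period = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- free_param
  class(out) <- c("cc_envelope", class(out))
  out
}
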