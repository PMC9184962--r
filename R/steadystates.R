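# Steady-state location by damped Newton iteration from a deterministic
# grid of starting points, with stability classification from the
# finite-difference Jacobian.

#' Finite-difference Jacobian of a model right-hand side
#'
#' Central differences with per-component step
#' \code{h_i = rel_step * max(|x_i|, 0.01)}.  A symmetric-step consistency
#' check (halving the step must not move any entry by more than
#' \code{check_tol} relative) can be requested for diagnostic use.
#'
#' @param model A \code{"cc_model"}.
#' @param state State at which to differentiate.
#' @param params Optional parameter override.
#' @param rel_step Relative step (default 1e-6).
#' @param check Logical; run the step-halving consistency check.
#' @param check_tol Relative tolerance for the check.
#' @return Jacobian matrix (d rhs_i / d x_j).
#' @export
cc_jacobian <- function(model, state, params = NULL, rel_step = 1e-6,
                        check = FALSE, check_tol = 1e-4) {
  if (is.null(params)) params <- model$params
  if (any(state < -1e-6))
    stop("cc_jacobian: state violates non-negativity")
  f <- function(x) model$rhs(0, x, params)[[1]]
  J <- .fd_jacobian(f, as.numeric(state), rel_step)
  if (check) {
    J2 <- .fd_jacobian(f, as.numeric(state), rel_step / 2)
    scale <- max(abs(J), 1)
    if (max(abs(J - J2)) / scale > check_tol)
      warning("Jacobian step-halving check failed; rhs may be non-smooth here")
  }
  J
}

.fd_jacobian <- function(f, x, rel_step = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- rel_step * max(abs(x[i]), 0.01)
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Damped Newton with simple backtracking line search on the residual norm.
.newton <- function(f, x, tol = 1e-12, maxit = 80L) {
  for (k in seq_len(maxit)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) return(list(x = x, ok = TRUE, res = max(abs(fx))))
    J <- .fd_jacobian(f, x)
    dx <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, ok = FALSE, res = max(abs(fx))))
    lam <- 1
    repeat {
      xn <- x - lam * dx
      if (max(abs(f(xn))) < max(abs(fx)) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn
  }
  list(x = x, ok = max(abs(f(x))) < tol, res = max(abs(f(x))))
}

#' Classify a steady state from its eigenvalues
#'
#' @param ev Complex eigenvalue vector.
#' @param eps Margin around zero for the real parts.
#' @return One of \code{"stable node"}, \code{"stable focus"},
#'   \code{"saddle"}, \code{"unstable node"}, \code{"unstable focus"},
#'   \code{"marginal"}.
#' @export
stability_class <- function(ev, eps = 1e-8) {
  re <- Re(ev)
  cplx <- any(abs(Im(ev)) > eps)
  if (all(re < -eps)) return(if (cplx) "stable focus" else "stable node")
  if (all(re > eps)) return(if (cplx) "unstable focus" else "unstable node")
  if (any(re > eps) && any(re < -eps)) return("saddle")
  "marginal"
}

# Admissible box for Newton starting points: state bounds implied by the
# conservation laws plus the synthesis/degradation ceiling for cyclin.
.state_box <- function(model, params) {
  p <- params
  cyc_cap <- if (!is.null(p$kde1_cycb) && p$kde1_cycb > 0)
    1.25 * p$ksy_cycb / p$kde1_cycb else 5
  ub <- vapply(model$states, function(s) switch(s,
    MPF = cyc_cap, CycBT = cyc_cap,
    KinP = p$Kin_tot, GwlP = p$Gwl_tot, ENSAP = p$ENSA_tot,
    APCP = p$APC_tot, APCPC20 = min(p$APC_tot, p$Cdc20_tot), 1), numeric(1))
  rbind(lower = 0 * ub, upper = ub)
}

# Invariant filter for candidate steady states (rejects, e.g., the spurious
# roots of the APC_P:Cdc20 binding equation with complex > total).
.is_admissible <- function(model, params, x, tol = 1e-6) {
  if (!isTRUE(model$nonneg)) return(all(is.finite(x)))
  if (any(x < -tol)) return(FALSE)
  s <- stats::setNames(x, model$states)
  p <- params
  ok <- TRUE
  has <- function(v) v %in% names(s)
  if (has("APCPC20")) {
    apcp <- if (has("APCP")) s[["APCP"]] else p$APC_tot
    ok <- ok && s[["APCPC20"]] <= min(apcp, p$Cdc20_tot) + tol
  }
  if (has("MPF") && has("CycBT"))
    ok <- ok && s[["MPF"]] <= s[["CycBT"]] + tol
  caps <- c(GwlP = "Gwl_tot", ENSAP = "ENSA_tot", APCP = "APC_tot", KinP = "Kin_tot")
  for (nm in names(caps))
    if (has(nm) && !is.null(p[[caps[[nm]]]]))
      ok <- ok && s[[nm]] <= p[[caps[[nm]]]] + tol
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate all steady states of a model
#'
#' Damped Newton iteration from a deterministic factorial grid of starting
#' points spanning the admissible state box; converged roots are filtered
#' against the model's physical invariants, de-duplicated, and classified
#' by the eigenvalues of the finite-difference Jacobian.
#'
#' @param model A \code{"cc_model"} (possibly clamped, see [clamp_state()]).
#' @param params Optional parameter override.
#' @param levels Grid levels per dimension, as fractions of the box.
#' @param extra_starts Optional matrix of additional starting states.
#' @param res_tol Residual tolerance for an accepted root.
#' @param dedup_tol Distance below which two roots are considered one.
#' @return List of \code{"cc_steady_state"} objects, each with
#'   \code{state}, \code{eigenvalues}, \code{class}, \code{residual}.
#'   An empty list is a legal outcome.
#' @export
#' @examples
#' g2 <- apply_checkpoint(cc_model("model4"), "G2")
#' length(find_steady_states(g2))   # coexisting node and saddle(s)
find_steady_states <- function(model, params = NULL,
                               levels = c(0.02, 0.5, 0.95),
                               extra_starts = NULL,
                               res_tol = 1e-10, dedup_tol = 1e-6) {
  if (is.null(params)) params <- model$params
  f <- function(x) model$rhs(0, x, params)[[1]]
  box <- .state_box(model, params)
  n <- length(model$states)
  fracs <- if (n <= 5L) levels else c(0.05, 0.9)
  grid <- as.matrix(expand.grid(rep(list(fracs), n)))
  starts <- sweep(grid, 2L, box["upper", ], `*`)
  if (n > 5L) {   # keep the factorial grid moderate but add face centres
    centre <- 0.5 * box["upper", ]
    starts <- rbind(starts, centre,
                    t(vapply(seq_len(n), function(i) {
                      v <- centre; v[i] <- 0.05 * box["upper", i]; v
                    }, numeric(n))))
  }
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  # clip MPF <= CycBT on the grid itself so starts are admissible
  ic <- match("CycBT", model$states)
  im <- match("MPF", model$states)
  if (!is.na(ic) && !is.na(im)) starts[, im] <- pmin(starts[, im], starts[, ic])
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    r <- .newton(f, as.numeric(starts[i, ]), tol = res_tol)
    if (!r$ok) next
    if (!.is_admissible(model, params, r$x)) next
    dup <- any(vapply(sols, function(s) max(abs(s$state - r$x)) < dedup_tol,
                      logical(1)))
    if (dup) next
    J <- .fd_jacobian(f, r$x)
    ev <- eigen(J, only.values = TRUE)$values
    sols[[length(sols) + 1L]] <- structure(
      list(state = stats::setNames(r$x, model$states), eigenvalues = ev,
           class = stability_class(ev), residual = r$res),
      class = "cc_steady_state")
  }
  sols
}

#' @export
print.cc_steady_state <- function(x, ...) {
  cat("<cc_steady_state>", x$class, " residual", signif(x$residual, 2), "\n")
  print(signif(x$state, 5))
  invisible(x)
}
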