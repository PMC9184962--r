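# Model library: right-hand sides, algebraic closures and conservation
# relations for the four nested cell-cycle control models.
#
# State conventions (all concentrations dimensionless a.u., time in min):
#   model1: MPF, KinP, APCP            (delayed negative feedback, frog-egg oscillator)
#   model2: MPF, GwlP, ENSAP, APCP, APCPC20
#   model3: as model2, Gwl additionally dephosphorylated by free B55
#   model4: CycBT, MPF, GwlP, ENSAP, APCP, APCPC20 (tyrosine-phosphorylation
#           switch on Cdk1; MPF <= CycBT always)
# Conservation closures: Kin/Gwl/APC/ENSA totals fixed; B55_free =
# B55_tot - [ENSA-P:B55] with the complex from the tQSSA.

.rhs_model1 <- function(t, x, p) {
  MPF <- x[1]; KinP <- x[2]; APCP <- x[3]
  Kin <- p$Kin_tot - KinP
  APC <- p$APC_tot - APCP
  list(c(
    p$ksy_cycb - (p$kde1_cycb + p$kde2_cycb * APCP) * MPF,
    p$kph_gwl * MPF * Kin / (p$Jph_kin + Kin) -
      p$kdp1_gwl * p$PP * KinP / (p$Jdp_kin + KinP),
    p$kph_apc * KinP * APC / (p$Jph_apc + APC) -
      p$kdp_apc * p$PP * APCP / (p$Jdp_apc + APCP)
  ))
}

# Shared core of models 2/3: `b55_gwl` switches the B55 feedback on Gwl.
# Closure arguments are clamped at zero so the rhs stays evaluable at the
# slightly negative probe points of root solvers and finite differences;
# the mass-action terms themselves are polynomials and need no guard.
.rhs_beg <- function(t, x, p, b55_gwl) {
  MPF <- x[1]; GwlP <- x[2]; ENSAP <- x[3]; APCP <- x[4]; C20 <- x[5]
  EB <- tqssa_complex(max(ENSAP, 0), p$B55_tot, p$Km_tqssa)
  B55 <- p$B55_tot - EB
  f <- ub_fraction(max(C20, 0) / p$deUb)
  gwl_dp <- if (b55_gwl) (p$kdp1_gwl * p$PP + p$kdp2_gwl * B55) else p$kdp1_gwl * p$PP
  list(c(
    p$ksy_cycb - (p$kde1_cycb + f * p$kde2_cycb) * MPF,
    p$kph_gwl * MPF * (p$Gwl_tot - GwlP) - gwl_dp * GwlP,
    p$kph_ensa * GwlP * (p$ENSA_tot - ENSAP) - p$kcat * EB,
    p$kph_apc * MPF * (p$APC_tot - APCP) - p$kdp_apc * B55 * APCP,
    p$kas1 * (APCP - C20) * (p$Cdc20_tot - C20) - p$kdi1 * C20
  ))
}

.rhs_model2 <- function(t, x, p) .rhs_beg(t, x, p, b55_gwl = FALSE)
.rhs_model3 <- function(t, x, p) .rhs_beg(t, x, p, b55_gwl = TRUE)

.rhs_model4 <- function(t, x, p) {
  CycBT <- x[1]; MPF <- x[2]; GwlP <- x[3]; ENSAP <- x[4]; APCP <- x[5]; C20 <- x[6]
  EB <- tqssa_complex(max(ENSAP, 0), p$B55_tot, p$Km_tqssa)
  B55 <- p$B55_tot - EB
  f <- ub_fraction(max(C20, 0) / p$deUb)
  s <- max(MPF, 0) / p$CAP
  Wee1 <- p$Wee1_tot * wee1_active_fraction(s)
  Wee1P <- p$Wee1_tot - Wee1
  Cdc25P <- p$Cdc25_tot * cdc25_active_fraction(s)
  Cdc25 <- p$Cdc25_tot - Cdc25P
  kde3 <- if (is.null(p$kde3_cycb)) 0 else p$kde3_cycb
  deg <- p$kde1_cycb + f * p$kde2_cycb + kde3 * (p$APC_tot - APCP)
  list(c(
    p$ksy_cycb - deg * CycBT,
    p$ksy_cycb - deg * MPF -
      (p$kph1_cdk * Wee1P + p$kph2_cdk * Wee1) * MPF +
      (p$kdp1_cdk * Cdc25 + p$kdp2_cdk * Cdc25P) * (CycBT - MPF),
    p$kph_gwl * MPF * (p$Gwl_tot - GwlP) -
      (p$kdp1_gwl * p$PP + p$kdp2_gwl * B55) * GwlP,
    p$kph_ensa * GwlP * (p$ENSA_tot - ENSAP) - p$kcat * EB,
    p$kph_apc * MPF * (p$APC_tot - APCP) - p$kdp_apc * B55 * APCP,
    p$kas1 * (APCP - C20) * (p$Cdc20_tot - C20) - p$kdi1 * C20
  ))
}

.closures_beg <- function(x, p) {
  EB <- tqssa_complex(x[["ENSAP"]], p$B55_tot, p$Km_tqssa)
  c(ENSAPB55 = unname(EB), B55_free = unname(p$B55_tot - EB),
    f = unname(ub_fraction(x[["APCPC20"]] / p$deUb)))
}

.closures_model4 <- function(x, p) {
  base <- .closures_beg(x, p)
  s <- x[["MPF"]] / p$CAP
  c(base,
    Wee1_active = unname(p$Wee1_tot * wee1_active_fraction(s)),
    Cdc25P_active = unname(p$Cdc25_tot * cdc25_active_fraction(s)))
}

.model_registry <- list(
  model1 = list(states = c("MPF", "KinP", "APCP"), rhs = .rhs_model1,
                closures = function(x, p) numeric(0)),
  model2 = list(states = c("MPF", "GwlP", "ENSAP", "APCP", "APCPC20"),
                rhs = .rhs_model2, closures = .closures_beg),
  model3 = list(states = c("MPF", "GwlP", "ENSAP", "APCP", "APCPC20"),
                rhs = .rhs_model3, closures = .closures_beg),
  model4 = list(states = c("CycBT", "MPF", "GwlP", "ENSAP", "APCP", "APCPC20"),
                rhs = .rhs_model4, closures = .closures_model4)
)

#' Construct a cell-cycle model definition
#'
#' A model definition bundles the ordered state-variable names, the ODE
#' right-hand side, the algebraic closures (tQSSA complex, free B55,
#' ubiquitination fraction, active Wee1/Cdc25) and a default reference
#' parameter set.  All analysis functions in the package
#' ([cc_integrate()], [find_steady_states()], [continue_branch()], ...)
#' accept these objects.
#'
#' @param id \code{"model1"}, \code{"model2"}, \code{"model3"} or
#'   \code{"model4"} (integers 1-4 accepted).
#' @param params Optional parameter list; defaults to
#'   \code{table1_parameters(id)}.
#' @return Object of class \code{"cc_model"}: a list with elements
#'   \code{id}, \code{states}, \code{rhs(t, x, p)}, \code{closures(x, p)}
#'   and \code{params}.
#' @export
#' @examples
#' m <- cc_model("model1")
#' m$rhs(0, c(0, 0, 0), m$params)
cc_model <- function(id, params = NULL) {
  cid <- .canon_model_id(id)
  reg <- .model_registry[[cid]]
  if (is.null(params)) params <- table1_parameters(cid)
  else validate_parameters(params, cid)
  structure(list(id = cid, states = reg$states, rhs = reg$rhs,
                 closures = reg$closures, params = params,
                 scenario = "none", nonneg = TRUE),
            class = "cc_model")
}

#' @export
print.cc_model <- function(x, ...) {
  cat("<cc_model>", x$id,
      if (!identical(x$scenario, "none")) paste0("[", x$scenario, "]"), "\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

.check_state <- function(model, state, tol = 1e-6) {
  if (length(state) != length(model$states))
    stop("state vector for ", model$id, " must have ",
         length(model$states), " entries (", paste(model$states, collapse = ", "), ")")
  if (!isTRUE(model$nonneg)) return(invisible(state))
  if (any(state < -tol))
    stop("invariant violation: negative concentration in state")
  p <- model$params
  nm <- model$states
  s <- stats::setNames(as.numeric(state), nm)
  if ("APCPC20" %in% nm && s[["APCPC20"]] > s[["APCP"]] + tol)
    stop("invariant violation: APCPC20 > APCP")
  if ("CycBT" %in% nm && s[["MPF"]] > s[["CycBT"]] + tol)
    stop("invariant violation: MPF > CycBT (unreachable region)")
  if ("GwlP" %in% nm && s[["GwlP"]] > p$Gwl_tot + tol)
    stop("invariant violation: GwlP > Gwl_tot")
  if ("ENSAP" %in% nm && s[["ENSAP"]] > p$ENSA_tot + tol)
    stop("invariant violation: ENSAP > ENSA_tot")
  if ("APCP" %in% nm && s[["APCP"]] > p$APC_tot + tol)
    stop("invariant violation: APCP > APC_tot")
  invisible(s)
}

.rhs_checked <- function(id, state, params) {
  m <- cc_model(id, params = params)
  .check_state(m, state)
  m$rhs(0, as.numeric(state), m$params)[[1]]
}

#' Evaluate a model right-hand side at one state
#'
#' User-facing, validating wrappers around the model derivatives: the state
#' is checked against the model's invariants (non-negativity, conservation
#' bounds, \code{MPF <= CycBT}) before evaluation.
#'
#' @param state Numeric state vector in the model's state order (see
#'   [cc_model()]).
#' @param params Optional parameter list (default: reference set).
#' @return Named derivative vector (per minute).
#' @export
model1_rhs <- function(state, params = NULL) {
  d <- .rhs_checked("model1", state, params)
  stats::setNames(d, c("MPF", "KinP", "APCP"))
}

#' @rdname model1_rhs
#' @export
model2_rhs <- function(state, params = NULL) {
  d <- .rhs_checked("model2", state, params)
  stats::setNames(d, c("MPF", "GwlP", "ENSAP", "APCP", "APCPC20"))
}

#' @rdname model1_rhs
#' @export
model3_rhs <- function(state, params = NULL) {
  d <- .rhs_checked("model3", state, params)
  stats::setNames(d, c("MPF", "GwlP", "ENSAP", "APCP", "APCPC20"))
}

#' @rdname model1_rhs
#' @export
model4_rhs <- function(state, params = NULL) {
  d <- .rhs_checked("model4", state, params)
  stats::setNames(d, c("CycBT", "MPF", "GwlP", "ENSAP", "APCP", "APCPC20"))
}

#' Checkpoint scenario descriptor
#'
#' Checkpoints are modelled as parameter changes to the dual-switch network
#' (model4) that convert its limit cycle into a stable arrested steady
#' state: the G2 checkpoint sequesters cytoplasmic Cdc25 (lower
#' \code{Cdc25_tot}), the spindle assembly checkpoint sequesters Cdc20 in
#' mitotic checkpoint complexes (lower \code{Cdc20_tot}), and the G1
#' checkpoint stabilises APC/C:Cdh1, adding a degradation pathway for
#' cyclin B proportional to unphosphorylated APC/C
#' (\code{kde3_cycb * (APC_tot - APCP)}).
#'
#' @param kind \code{"G1"}, \code{"G2"}, \code{"SAC"} or \code{"none"}.
#' @param value Override value for the scenario's parameter; defaults are
#'   \code{Cdc25_tot = 0.4} (G2), \code{Cdc20_tot = 0.1} (SAC) and
#'   \code{kde3_cycb = 0.2} (G1).
#' @return Object of class \code{"cc_checkpoint"}.
#' @export
checkpoint_scenario <- function(kind = c("none", "G1", "G2", "SAC"), value = NULL) {
  kind <- match.arg(kind)
  default <- switch(kind, none = NULL, G2 = 0.4, SAC = 0.1, G1 = 0.2)
  if (is.null(value)) value <- default
  structure(list(kind = kind, value = value), class = "cc_checkpoint")
}

#' Apply a checkpoint scenario to the dual-switch model
#'
#' Returns a copy of the model with the scenario's single parameter
#' override applied.  Only the parameter named for that checkpoint is
#' touched, so applying \code{kind = "none"} (or re-applying the original
#' value) restores the original definition exactly.
#'
#' @param model A \code{"cc_model"} with \code{id == "model4"}.
#' @param scenario A [checkpoint_scenario()], or one of the kind strings.
#' @return Modified \code{"cc_model"}.
#' @export
#' @examples
#' m <- apply_checkpoint(cc_model("model4"), "G2")
#' m$params$Cdc25_tot   # 0.4
apply_checkpoint <- function(model, scenario) {
  if (!inherits(model, "cc_model") || model$id != "model4")
    stop("checkpoints are defined for model4 only")
  if (is.character(scenario)) scenario <- checkpoint_scenario(scenario)
  if (!inherits(scenario, "cc_checkpoint"))
    stop("'scenario' must be a cc_checkpoint or kind string")
  if (scenario$kind == "none") {
    model$scenario <- "none"
    return(model)
  }
  pname <- switch(scenario$kind, G2 = "Cdc25_tot", SAC = "Cdc20_tot", G1 = "kde3_cycb")
  model$params[[pname]] <- scenario$value
  model$scenario <- scenario$kind
  model
}

#' Clamp one state variable of a model
#'
#' Removes a state variable's ODE and treats its value as a parameter: the
#' construction behind pseudo-nullclines and behind the reduced systems
#' whose steady-state branches are continued in [pseudo_nullcline()] and
#' the size-control bifurcation diagram.  The clamped value is read from
#' the parameter list under the variable's own name.
#'
#' @param model A \code{"cc_model"}.
#' @param var Name of the state variable to clamp.
#' @param value Initial clamped value (stored in \code{params[[var]]}).
#' @return A \code{"cc_model"} with one fewer state.
#' @export
clamp_state <- function(model, var, value = 0) {
  idx <- match(var, model$states)
  if (is.na(idx)) stop("'", var, "' is not a state of ", model$id)
  orig_rhs <- model$rhs
  n <- length(model$states)
  model$params[[var]] <- value
  model$states <- model$states[-idx]
  model$rhs <- function(t, x, p) {
    full <- numeric(n)
    full[-idx] <- x
    full[idx] <- p[[var]]
    list(orig_rhs(t, full, p)[[1]][-idx])
  }
  model$id <- paste0(model$id, "_clamped_", var)
  model$clamped <- var
  model
}
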