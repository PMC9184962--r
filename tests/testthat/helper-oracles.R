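# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package implementation: explicit
# linear-algebra steady states for the modification chains, polynomial
# root-finding for the tQSSA quadratic, and plain re-transcriptions of the
# model equations in rational (unguarded) form.

# Steady-state top-state occupancy of an N-state ordered-distributive
# modification chain with forward rate r and backward rate 1, computed by
# solving the master-equation null space with dense linear algebra.
chain_top_occupancy <- function(r, n_states = 5L) {
  A <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states - 1L)) {
    A[i, i] <- A[i, i] - r       # forward out of state i
    A[i + 1L, i] <- A[i + 1L, i] + r
    A[i, i + 1L] <- A[i, i + 1L] + 1  # backward out of state i+1
    A[i + 1L, i + 1L] <- A[i + 1L, i + 1L] - 1
  }
  A[n_states, ] <- 1            # replace last row by normalisation
  b <- c(rep(0, n_states - 1L), 1)
  pi <- solve(A, b)
  pi[n_states]
}

# Occupancy share of selected states of the 9-state phosphorylation chain.
geometric_share <- function(s, idx0) {
  w <- s^(0:8)
  sum(w[idx0 + 1L]) / sum(w)
}

# Smaller root of C^2 - B C + E*T = 0 via polyroot().
tqssa_root_oracle <- function(ensaP, b55_tot, km) {
  B <- ensaP + b55_tot + km
  rts <- polyroot(c(ensaP * b55_tot, -B, 1))
  min(Re(rts))
}

# --- independent transcriptions of the model equations -------------------
# Written in the plain rational forms, evaluated away from singular points.

oracle_rhs_model1 <- function(x, p) {
  MPF <- x[1]; KinP <- x[2]; APCP <- x[3]
  Kin <- p$Kin_tot - KinP; APC <- p$APC_tot - APCP
  c(p$ksy_cycb - (p$kde1_cycb + p$kde2_cycb * APCP) * MPF,
    p$kph_gwl * MPF * Kin / (p$Jph_kin + Kin) -
      p$kdp1_gwl * p$PP * KinP / (p$Jdp_kin + KinP),
    p$kph_apc * KinP * APC / (p$Jph_apc + APC) -
      p$kdp_apc * p$PP * APCP / (p$Jdp_apc + APCP))
}

oracle_f <- function(r) {
  if (r == 0) return(0)
  if (abs(r - 1) < 1e-12) return(0.2)
  r^4 * (1 - r) / (1 - r^5)
}

oracle_complex <- function(ensaP, b55, km) {
  B <- ensaP + b55 + km
  (B - sqrt(B^2 - 4 * ensaP * b55)) / 2
}

oracle_rhs_model23 <- function(x, p, with_b55_on_gwl) {
  MPF <- x[1]; GwlP <- x[2]; ENSAP <- x[3]; APCP <- x[4]; C20 <- x[5]
  EB <- oracle_complex(ENSAP, p$B55_tot, p$Km_tqssa)
  B55 <- p$B55_tot - EB
  f <- oracle_f(C20 / p$deUb)
  dgw <- if (with_b55_on_gwl) p$kdp1_gwl * p$PP + p$kdp2_gwl * B55
         else p$kdp1_gwl * p$PP
  c(p$ksy_cycb - (p$kde1_cycb + f * p$kde2_cycb) * MPF,
    p$kph_gwl * MPF * (p$Gwl_tot - GwlP) - dgw * GwlP,
    p$kph_ensa * GwlP * (p$ENSA_tot - ENSAP) - p$kcat * EB,
    p$kph_apc * MPF * (p$APC_tot - APCP) - p$kdp_apc * B55 * APCP,
    p$kas1 * (APCP - C20) * (p$Cdc20_tot - C20) - p$kdi1 * C20)
}

oracle_rhs_model4 <- function(x, p) {
  CycBT <- x[1]
  core <- oracle_rhs_model23(x[-1], p, with_b55_on_gwl = TRUE)
  MPF <- x[2]
  s <- MPF / p$CAP
  wee_frac <- if (abs(s - 1) < 1e-12) 5 / 9 else (1 - s^5) / (1 - s^9)
  cdc_frac <- if (abs(s - 1) < 1e-12) 4 / 9 else s^5 * (1 - s^4) / (1 - s^9)
  Wee1 <- p$Wee1_tot * wee_frac
  Cdc25P <- p$Cdc25_tot * cdc_frac
  kde3 <- if (is.null(p$kde3_cycb)) 0 else p$kde3_cycb
  deg <- p$kde1_cycb + oracle_f(x[6] / p$deUb) * p$kde2_cycb +
    kde3 * (p$APC_tot - x[5])
  dCycBT <- p$ksy_cycb - deg * CycBT
  dMPF <- p$ksy_cycb - deg * MPF -
    (p$kph1_cdk * (p$Wee1_tot - Wee1) + p$kph2_cdk * Wee1) * MPF +
    (p$kdp1_cdk * (p$Cdc25_tot - Cdc25P) + p$kdp2_cdk * Cdc25P) * (CycBT - MPF)
  # core[1] lacks the kde3 extension and uses deg without it; rebuild MPF row
  c(dCycBT, dMPF, core[2:5])
}

# Random valid state generator for a model (fixed-seed callers).
random_state <- function(model, p = model$params) {
  nm <- model$states
  x <- stats::setNames(numeric(length(nm)), nm)
  for (v in nm) {
    x[v] <- switch(v,
      MPF = stats::runif(1, 0, 1.8),
      CycBT = NA,
      KinP = stats::runif(1, 0, p$Kin_tot),
      GwlP = stats::runif(1, 0, p$Gwl_tot),
      ENSAP = stats::runif(1, 0, p$ENSA_tot),
      APCP = stats::runif(1, 0, p$APC_tot),
      APCPC20 = NA,
      stats::runif(1))
  }
  if ("APCPC20" %in% nm)
    x["APCPC20"] <- stats::runif(1, 0, min(x["APCP"], p$Cdc20_tot))
  if ("CycBT" %in% nm) {
    x["CycBT"] <- stats::runif(1, x["MPF"], 2.2)
  }
  x
}
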