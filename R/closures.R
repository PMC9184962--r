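#' Polyubiquitinated fraction of the cyclin B pool
#'
#' Fraction of cyclin B carrying the full ubiquitin chain (four ubiquitins)
#' under an ordered-distributive ubiquitination mechanism: APC/C:Cdc20 adds
#' ubiquitins one at a time, dissociating between steps, while a
#' deubiquitinase removes them, so the five chain states Ub0..Ub4 reach a
#' geometric steady-state occupancy with common ratio \code{r}.  The fully
#' modified (degradation-competent) top state then carries
#' \deqn{f(r) = \frac{r^4 (1 - r)}{1 - r^5} = \frac{r^4}{1 + r + r^2 + r^3 + r^4},}
#' where \code{r} is the ratio of ubiquitination to deubiquitination
#' activity.  The right-hand form is singularity-free and is the one
#' evaluated (the rational form has a removable singularity at \code{r = 1},
#' where \code{f = 1/5}).
#'
#' @param r Non-negative activity ratio, typically
#'   \code{[APC_P:C20] / [deUb]} (dimensionless).
#' @return Fraction in \code{[0, 1]}, same length as \code{r}; monotonically
#'   non-decreasing, \code{f(0) = 0}, \code{f -> 1} as \code{r -> Inf}.
#' @seealso [wee1_active_fraction()] for the analogous multisite
#'   phosphorylation chain.
#' @export
#' @examples
#' ub_fraction(c(0, 1, 2))   # 0, 0.2, 16/31
ub_fraction <- function(r) {
  if (any(!is.finite(r) & !is.infinite(r)) || any(r < 0))
    stop("ub_fraction: 'r' must be non-negative")
  ifelse(is.infinite(r), 1, {
    # divide top and bottom by r^4 when r > 1 so large ratios cannot overflow
    small <- pmin(r, 1 / pmax(r, .Machine$double.xmin))
    num <- ifelse(r <= 1, r^4, 1)
    num / (small^4 + small^3 + small^2 + small + 1)
  })
}

#' ENSA-P : PP2A:B55 complex by the total quasi-steady-state approximation
#'
#' Concentration of the inhibitory complex between phosphorylated ENSA and
#' the PP2A:B55 phosphatase, computed by the total quasi-steady-state
#' approximation (tQSSA): the physically meaningful (smaller) root of
#' \deqn{C^2 - B C + E_T B_T = 0, \quad B = E_T + B_T + K_m,}
#' with \code{E_T} total phospho-ENSA (free plus complexed), \code{B_T} total
#' B55 and \code{K_m} the Michaelis-type constant
#' \code{(k_di2 + k_cat)/k_as2}.  Evaluated in the numerically stable form
#' \code{2 E_T B_T / (B + sqrt(B^2 - 4 E_T B_T))}, which avoids catastrophic
#' cancellation when binding is tight (\code{K_m} small).
#'
#' @param ensaP Total phosphorylated ENSA concentration (a.u., >= 0).
#' @param b55_tot Total B55 concentration (a.u., > 0).
#' @param km Michaelis-type constant (a.u., > 0).
#' @return Complex concentration, bounded by \code{min(ensaP, b55_tot)}.
#' @export
#' @examples
#' tqssa_complex(4, 1, 0.0026)  # near-stoichiometric sequestration
tqssa_complex <- function(ensaP, b55_tot, km) {
  if (any(ensaP < 0) || any(b55_tot <= 0) || any(km <= 0))
    stop("tqssa_complex: require ensaP >= 0, b55_tot > 0, km > 0")
  B <- ensaP + b55_tot + km
  2 * ensaP * b55_tot / (B + sqrt(B^2 - 4 * ensaP * b55_tot))
}

# Shared kernel for the nine-state ordered-distributive phosphorylation chain
# acting on Wee1 and Cdc25 (eight MPF sites + unmodified state).  State
# occupancies are geometric with ratio s = [MPF]/[CAP]; `lo` selects which
# phospho-states count as "active".  Evaluated with the chain normalised by
# its largest term so s >> 1 cannot overflow.
.phospho_chain_share <- function(s, lo, hi) {
  if (any(s < 0) || any(is.na(s)))
    stop("multisite fraction: 's' must be non-negative")
  vapply(s, function(si) {
    if (is.infinite(si)) return(if (hi == 8L) 1 else 0)
    w <- if (si <= 1) si^(0:8) else (1 / si)^(8:0)
    sum(w[(lo + 1L):(hi + 1L)]) / sum(w)
  }, numeric(1))
}

#' Active fraction of Wee1 under multisite phosphorylation by MPF
#'
#' Wee1 is phosphorylated on eight sites by MPF in an ordered-distributive
#' fashion, opposed by a counter-acting phosphatase (CAP); the nine
#' phospho-states P0..P8 take geometric occupancies with ratio
#' \code{s = [MPF]/[CAP]}.  States P0..P4 retain kinase activity towards
#' Cdk1, so the active fraction is
#' \deqn{(1 - s^5) / (1 - s^9) = \sum_{i=0}^{4} s^i / \sum_{i=0}^{8} s^i,}
#' a decreasing sigmoid from 1 at \code{s = 0} to 0 as \code{s -> Inf}
#' (value 5/9 at the removable singularity \code{s = 1}).
#'
#' @param s Non-negative ratio \code{[MPF]/[CAP]}.
#' @return Active Wee1 fraction in \code{[0, 1]}, same length as \code{s}.
#' @export
wee1_active_fraction <- function(s) .phospho_chain_share(s, 0L, 4L)

#' Active fraction of Cdc25 under multisite phosphorylation by MPF
#'
#' Complement of [wee1_active_fraction()]: Cdc25 phospho-states P5..P8 are
#' the more active ones, so the active fraction is
#' \deqn{s^5 (1 - s^4) / (1 - s^9) = \sum_{i=5}^{8} s^i / \sum_{i=0}^{8} s^i,}
#' increasing from 0 to 1 (value 4/9 at \code{s = 1}).  For every
#' \code{s >= 0}, \code{wee1_active_fraction(s) + cdc25_active_fraction(s)}
#' is identically 1.
#'
#' @inheritParams wee1_active_fraction
#' @return Active Cdc25 fraction in \code{[0, 1]}.
#' @export
cdc25_active_fraction <- function(s) .phospho_chain_share(s, 5L, 8L)
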