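#' Hill activation function
#'
#' Fractional activation of a target by an activator, `x^h / (k^h + x^h)`.
#' Used for all Ste11n-dependent transcriptional upregulation steps (PheS,
#' Mat1-Pm, Mei2, Ste11 autoregulation), eliminating intermediate activation
#' steps.
#'
#' @param x Activator level (dimensionless concentration), `x >= 0`.
#' @param k Half-saturation constant, `k > 0`. At `x = k` the function is 0.5.
#' @param h Hill coefficient, `h >= 1`; larger values sharpen the response.
#' @return Fraction in `[0, 1]`, strictly increasing in `x`.
#' @examples
#' hill_activation(0.3, k = 0.3, h = 2) # 0.5 at half-saturation
#' @export
hill_activation <- function(x, k, h) {
  if (any(k <= 0)) stop("hill_activation: half-saturation `k` must be > 0")
  if (any(h < 1)) stop("hill_activation: Hill coefficient `h` must be >= 1")
  if (any(x < 0)) stop("hill_activation: activator `x` must be >= 0")
  xh <- (x / k)^h
  xh / (1 + xh)
}

#' Michaelis-Menten flux
#'
#' Enzyme-limited conversion flux `kcat * E * S / (Km + S)` (units 1/min on
#' the dimensionless concentration scale). Used for the multi-site
#' phosphorylation and dephosphorylation of Mei2 by Pat1 and its opposing
#' phosphatase; small `Km` relative to substrate gives the zero-order
#' ultrasensitivity that makes Mei2 activation switch-like.
#'
#' @param substrate Substrate concentration, `>= 0`.
#' @param enzyme_activity Enzyme activity level, `>= 0`.
#' @param kcat Catalytic rate constant (1/min), `>= 0`.
#' @param Km Michaelis constant, `> 0`.
#' @return Flux; monotone in `substrate`, saturating at `kcat * enzyme_activity`.
#' @export
mm_flux <- function(substrate, enzyme_activity, kcat, Km) {
  if (any(Km <= 0)) stop("mm_flux: Michaelis constant `Km` must be > 0")
  if (any(substrate < 0) || any(enzyme_activity < 0) || any(kcat < 0)) {
    stop("mm_flux: substrate, enzyme_activity and kcat must be >= 0")
  }
  kcat * enzyme_activity * substrate / (Km + substrate)
}

#' Goldbeter-Koshland function
#'
#' Steady-state fraction of a substrate in its modified form when opposing
#' converter enzymes (activation rate `va`, inactivation rate `vi`) both work
#' near saturation (Michaelis constants `Ja`, `Ji` scaled by total substrate).
#' Used in the cell-cycle module for Wee1, Cdc25 and the transcription factor
#' of the starter kinase.
#'
#' @param va,vi Activating and inactivating rates (>= 0).
#' @param Ja,Ji Scaled Michaelis constants (> 0).
#' @return Fraction in `[0, 1]`.
#' @keywords internal
goldbeter_koshland <- function(va, vi, Ja, Ji) {
  b <- vi - va + Ja * vi + Ji * va
  2 * va * Ji / (b + sqrt(pmax(b^2 - 4 * (vi - va) * va * Ji, 0)))
}

#' Partition total Pat1 into free-active and inhibited pools
#'
#' Mei3 inhibits Pat1 by stoichiometric complex formation; the pheromone
#' signalling activity PheS lowers the specific activity of the remaining
#' free kinase without sequestering it. Given the current complex level this
#' returns the algebraic partition used by the right-hand side and by the
#' derived observables.
#'
#' @param pat1_total Total Pat1 (`Pat1_T`), `>= 0`.
#' @param mei3_complex Current Pat1:Mei3 complex concentration, in
#'   `[0, pat1_total]`.
#' @param phes PheS activity level, `>= 0`.
#' @param params Parameter set (needs `j_iphe`, the PheS level halving Pat1
#'   activity).
#' @return Named list with `free` (free Pat1), `complexed` (Pat1:Mei3) and
#'   `activity` (free Pat1 scaled down by PheS inhibition). `free + complexed`
#'   equals `pat1_total` exactly.
#' @export
pat1_partition <- function(pat1_total, mei3_complex, phes, params) {
  if (any(c(pat1_total, mei3_complex, phes) < 0)) {
    stop("pat1_partition: all inputs must be >= 0")
  }
  cpx <- pmin(mei3_complex, pat1_total)
  free <- pat1_total - cpx
  list(
    free = free,
    complexed = cpx,
    activity = free / (1 + phes / params[["j_iphe"]])
  )
}

# central finite-difference Jacobian with per-component adaptive step
fd_jacobian <- function(f, x, eps = NULL) {
  n <- length(x)
  f0 <- f(x)
  m <- length(f0)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    h <- if (is.null(eps)) (.Machine$double.eps)^(1 / 3) * max(abs(x[j]), 1e-4) else eps
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
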