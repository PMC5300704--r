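#' Viscous drag coefficient of a monomer in the channel
#'
#' Einstein-Smoluchowski relation in thermal units: `zeta = kT / D`, so
#' with energies measured in kT the drag is simply `1 / D` (kT s / nm^2).
#'
#' @param D Apparent diffusion coefficient, nm^2/s (> 0).
#' @return Drag coefficient in kT s / nm^2.
#' @examples
#' drag_coefficient(5000)  # 2e-4 kT s/nm^2
#' @export
drag_coefficient <- function(D) {
  if (any(D <= 0)) stop("'D' must be positive")
  1 / D
}

#' Work to drive monomers through the channel during an insertion
#'
#' When a new monomer is injected while `n` residents sit close-packed at
#' the base, the apparatus must push all of them a distance `s` at velocity
#' `v` against viscous drag, costing `W = n * zeta * v * s = n * kT * v * s
#' / D`.  For the fitted channel (D = 5000 nm^2/s) with n = 12 residents
#' pushed s = 56 nm: a 0.1-s insertion (v = 560 nm/s) costs 75.3 kT, while
#' spreading it over the full 0.6-s secretion cycle (v = 56/0.6 nm/s) costs
#' 12.5 kT.
#'
#' @param n Number of pushed resident monomers (>= 0).
#' @param v Push velocity, nm/s (> 0); alternatively give `push_time_s`.
#' @param s Push distance, nm (> 0); default one monomer length, 56 nm.
#' @param D Diffusion coefficient, nm^2/s (> 0).
#' @param push_time_s If supplied, `v` is computed as `s / push_time_s`.
#' @param kT_per_ATP Thermal-to-chemical conversion for the ATP-equivalent
#'   figure (default 20 kT per ATP hydrolysis).
#' @return A list with `W_kT` and `W_ATP`.
#' @examples
#' injection_work(n = 12, v = 560, s = 56, D = 5000)$W_kT  # 75.3
#' @export
injection_work <- function(n, v = NULL, s = 56, D = 5000,
                           push_time_s = NULL, kT_per_ATP = 20) {
  if (n < 0 || n != round(n)) stop("'n' must be a non-negative integer")
  if (!is.null(push_time_s)) {
    if (push_time_s <= 0) stop("'push_time_s' must be positive")
    v <- s / push_time_s
  }
  if (is.null(v) || v <= 0) stop("'v' must be positive")
  if (s <= 0 || D <= 0 || kT_per_ATP <= 0)
    stop("'s', 'D' and 'kT_per_ATP' must be positive")
  W <- n * v * s / D
  list(W_kT = W, W_ATP = W / kT_per_ATP)
}
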