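#' On-site base-pair potential (Morse + Gaussian solvent barrier)
#'
#' `V(y) = D_c (exp(-a_c y) - 1)^2 + G_bar exp(-(y - b_pos)^2 / (2 b_w^2))`,
#' where the Morse depth and width depend on the pair class `c` (A-T or G-C).
#' The Gaussian bump models the entropic cost of exposing bases to the
#' solvent; it stabilizes open states and sharpens thermal denaturation.
#'
#' @param y Opening(s) in Angstrom (vectorized).
#' @param pair_class "AT" or "GC" (scalar, or one per element of `y`).
#' @param params A [model_params()] object.
#' @return Potential energy in eV, same length as `y`.
#' @export
onsite_potential <- function(y, pair_class, params) {
  stopifnot(inherits(params, "breath_params"))
  pair_class <- match.arg(pair_class, c("AT", "GC"), several.ok = TRUE)
  pair_class <- rep_len(pair_class, length(y))
  D <- ifelse(pair_class == "AT", params$D_AT, params$D_GC)
  a <- ifelse(pair_class == "AT", params$a_AT, params$a_GC)
  if (length(unique(D)) == 1L && length(unique(a)) == 1L) {
    .onsite_cpp(as.numeric(y), D[1], a[1], unclass(params))
  } else {
    vapply(seq_along(y), function(i)
      .onsite_cpp(y[i], D[i], a[i], unclass(params)), 0)
  }
}

#' Anharmonic stacking potential between neighboring base pairs
#'
#' `W(y_n, y_prev) = k/2 (1 + rho exp(-alpha (y_n + y_prev))) (y_n - y_prev)^2`.
#' The effective elastic constant is `k (1 + rho)` when both pairs are closed
#' and drops to `k` when either opens, which is the source of the model's
#' cooperativity (bubbles, sharp melting).
#'
#' @param y_n,y_prev Openings of the two neighbors (A; vectorized).
#' @param params A [model_params()] object.
#' @return Stacking energy in eV.
#' @export
stacking_potential <- function(y_n, y_prev, params) {
  stopifnot(inherits(params, "breath_params"))
  d <- y_n - y_prev
  0.5 * params$k_stack *
    (1 + params$rho * exp(-params$alpha * (y_n + y_prev))) * d^2
}

#' Particle-chain interaction potential
#'
#' The sliding particle sees a field of Gaussian wells centered on each base
#' pair whose depth grows with the local opening:
#' `V_p(x, y) = -A_p * sum_n f(y_n) exp(-(x - n)^2 / (2 sigma_p^2))`,
#' with the saturating amplitude `f(y) = tanh(max(y, 0) / y_sat)` (linear for
#' small openings, bounded at 1 to avoid self-trapping, zero for compressed
#' pairs). The sum is truncated at `|x - n| <= 6 sigma_p`; wells are not
#' wrapped across the periodic particle boundary.
#'
#' @param x Particle coordinate in base-pair index units, `[0, N)`. The well
#'   of the first chain site sits at `x = 0` (R site index 1).
#' @param y Vector of all N openings (A).
#' @param params A [model_params()] object.
#' @return Interaction energy in eV (non-positive).
#' @export
particle_potential <- function(x, y, params) {
  stopifnot(inherits(params, "breath_params"))
  N <- length(y)
  .energy_cpp(as.numeric(y), x, rep(params$D_AT, N), rep(params$a_AT, N),
              unclass(params), TRUE)$particle
}

#' Total potential energy of a chain state
#'
#' Sum of on-site, stacking and particle-coupling terms. The kinetic term is
#' handled by the dynamics module ([langevin_run()] records it per frame).
#'
#' @param y Vector of openings, one per simulated site (A).
#' @param x Particle coordinate in `[0, N)`; ignored when `with_particle` is
#'   FALSE.
#' @param chain An [encode_chain()] object.
#' @param params A [model_params()] object.
#' @param with_particle Include the particle coupling term? Defaults to
#'   `params$A_p > 0`.
#' @return A list with components `onsite`, `stacking`, `particle`, `total`
#'   (eV).
#' @export
total_energy <- function(y, x, chain, params,
                         with_particle = params$A_p > 0) {
  stopifnot(inherits(chain, "encoded_chain"), inherits(params, "breath_params"))
  if (length(y) != chain$N)
    stop("length(y) = ", length(y), " does not match chain length ", chain$N)
  sm <- site_morse(chain, params)
  .energy_cpp(as.numeric(y), x, sm$D, sm$a, unclass(params), with_particle)
}

#' Forces (exact negative gradients) on the chain and particle
#'
#' Analytic derivatives of [total_energy()] with respect to every opening
#' `y_n` and the particle coordinate `x`, including the back-reaction of the
#' particle on the chain (open pairs under the particle are pulled further
#' open).
#'
#' @inheritParams total_energy
#' @return A list with `fy` (length-N force vector, eV/A) and `fx` (force on
#'   the particle along the chain axis, eV per bp unit).
#' @export
chain_forces <- function(y, x, chain, params,
                         with_particle = params$A_p > 0) {
  stopifnot(inherits(chain, "encoded_chain"), inherits(params, "breath_params"))
  if (length(y) != chain$N)
    stop("length(y) = ", length(y), " does not match chain length ", chain$N)
  sm <- site_morse(chain, params)
  .forces_cpp(as.numeric(y), x, sm$D, sm$a, unclass(params), with_particle)
}
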