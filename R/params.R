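#' Model parameters for the DNA-chain / sliding-particle Hamiltonian
#'
#' Collects every constant of the mesoscopic Hamiltonian: the Morse on-site
#' potential (sequence-dependent, two classes A-T and G-C), the Gaussian
#' solvent barrier that stabilizes open states, the anharmonic stacking
#' interaction, the Gaussian-well coupling between the sliding particle and
#' open base pairs, and the thermal/friction constants of the Langevin bath.
#'
#' Units: energies in eV, lengths in Angstrom, mass in amu, temperature in
#' Kelvin. The derived simulation time unit is `A*sqrt(amu/eV)` (about 10 fs).
#' `sigma_p` is dimensionless (base-pair index units) because the particle
#' slides along the discrete chain axis.
#'
#' Defaults follow the standard parameterization of the solvent-barrier
#' Peyrard-Bishop-Dauxois literature; the particle-coupling defaults are
#' chosen so that particle-stabilized bubbles span about 10 bp and openings
#' saturate at a few Angstrom (see the package vignette). Every value can be
#' overridden.
#'
#' @param D_AT,D_GC Morse depths (eV); G-C pairs bind more strongly.
#' @param a_AT,a_GC Morse inverse widths (1/A).
#' @param G_bar,b_pos,b_w Gaussian solvent barrier height (eV), center (A)
#'   and width (A). `G_bar = 0` disables the barrier.
#' @param k_stack Stacking elastic constant (eV/A^2).
#' @param rho Anharmonicity amplitude (dimensionless); the effective stacking
#'   constant is `k_stack*(1+rho)` for closed pairs, dropping to `k_stack`
#'   when either pair opens.
#' @param alpha Stacking decay constant (1/A).
#' @param A_p Particle-chain coupling amplitude (eV).
#' @param sigma_p Width of the Gaussian wells the particle sees (bp units).
#' @param y_sat Opening scale (A) at which the coupling saturates.
#' @param mass Reduced mass per base pair (amu).
#' @param mass_p Effective inertia of the sliding particle (amu). Together
#'   with `gamma` it sets the particle's one-dimensional sliding diffusivity
#'   `D_p = kB*T/(mass_p*gamma)` (bp^2 per time unit); the default makes the
#'   particle explore a few hundred bp within one production run, matching
#'   the millisecond-scale sliding of DNA-binding proteins relative to the
#'   breathing timescale.
#' @param gamma Friction coefficient (1/time unit).
#' @param temperature Bath temperature (K).
#' @param kB Boltzmann constant (eV/K).
#' @return An object of class `breath_params` (a validated named list).
#' @examples
#' p <- model_params()
#' kBT(p)                      # thermal energy in eV at 290 K
#' model_params(A_p = 0)       # chain-only model, no particle coupling
#' @export
model_params <- function(D_AT = 0.05, D_GC = 0.075,
                         a_AT = 4.2, a_GC = 6.9,
                         G_bar = 0.03, b_pos = 2.0, b_w = 0.5,
                         k_stack = 0.025, rho = 2.0, alpha = 0.35,
                         A_p = 0.03, sigma_p = 5.0, y_sat = 1.5,
                         mass = 300, mass_p = 1, gamma = 0.05,
                         temperature = 290, kB = 8.617333262e-5) {
  p <- list(D_AT = D_AT, D_GC = D_GC, a_AT = a_AT, a_GC = a_GC,
            G_bar = G_bar, b_pos = b_pos, b_w = b_w,
            k_stack = k_stack, rho = rho, alpha = alpha,
            A_p = A_p, sigma_p = sigma_p, y_sat = y_sat,
            mass = mass, mass_p = mass_p, gamma = gamma,
            temperature = temperature, kB = kB)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (!(p$D_GC > p$D_AT && p$D_AT > 0))
    stop("Morse depths must satisfy D_GC > D_AT > 0 (G-C pairs bind stronger)")
  if (p$a_AT <= 0 || p$a_GC <= 0) stop("Morse widths must be positive")
  if (p$G_bar < 0) stop("barrier height G_bar must be >= 0")
  if (p$b_w <= 0) stop("barrier width b_w must be positive")
  pos <- c("k_stack", "rho", "alpha", "sigma_p", "y_sat", "mass", "mass_p",
           "gamma", "temperature", "kB")
  for (nm in pos) if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0")
  if (p$A_p < 0) stop("coupling amplitude A_p must be >= 0")
  structure(p, class = "breath_params")
}

#' Thermal energy kB*T of a parameter set
#'
#' @param params A [model_params()] object.
#' @param temperature Optional temperature override (K).
#' @return kB*T in eV.
#' @export
kBT <- function(params, temperature = NULL) {
  stopifnot(inherits(params, "breath_params"))
  Tval <- if (is.null(temperature)) params$temperature else temperature
  params$kB * Tval
}

#' @export
print.breath_params <- function(x, ...) {
  cat("Mesoscopic DNA-particle model parameters\n")
  cat(sprintf("  Morse:    D_AT=%.4g D_GC=%.4g eV, a_AT=%.3g a_GC=%.3g 1/A\n",
              x$D_AT, x$D_GC, x$a_AT, x$a_GC))
  cat(sprintf("  Barrier:  G=%.4g eV at %.3g A (width %.3g A)\n",
              x$G_bar, x$b_pos, x$b_w))
  cat(sprintf("  Stacking: k=%.4g eV/A^2, rho=%.3g, alpha=%.3g 1/A\n",
              x$k_stack, x$rho, x$alpha))
  cat(sprintf("  Particle: A_p=%.4g eV, sigma_p=%.3g bp, y_sat=%.3g A\n",
              x$A_p, x$sigma_p, x$y_sat))
  cat(sprintf("  Bath:     T=%.4g K (kBT=%.5g eV), gamma=%.3g, mass=%.4g amu\n",
              x$temperature, kBT(x), x$gamma, x$mass))
  invisible(x)
}

#' Read or write a parameter profile as flat JSON
#'
#' Parameter sets are serialized as a flat key-value JSON object so that
#' external parameter tables can be dropped in verbatim.
#'
#' @param path File path.
#' @param params A [model_params()] object (for writing).
#' @return For `read_params_json`, a `breath_params` object.
#' @export
read_params_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, as.list(vals))
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "breath_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulation configuration for the Langevin dynamics
#'
#' Default production scales follow the study design of the analysis pipeline:
#' five independent realizations of 1e6 time units each (dt = 0.5, so 2e6
#' integration steps), with 1e4 time units of preheating discarded, sampled
#' every `sample_stride` steps. Tests and examples use much shorter, scaled
#' down configurations.
#'
#' @param dt Integration time step (model time units).
#' @param n_steps Production steps per realization.
#' @param preheat_steps Equilibration steps discarded before production.
#' @param n_realizations Number of independent realizations.
#' @param sample_stride Steps between stored frames (the effective lag time
#'   of the downstream Markov network).
#' @param seed Master seed; per-realization streams are derived
#'   deterministically from `(seed, realization_id)`.
#' @param temperature Optional bath temperature override (K).
#' @param y_wall Optional reflecting wall on the openings (A); `Inf` (the
#'   default) means no wall. Used for finite-box sampling checks of
#'   unbounded single-pair openings.
#' @return An object of class `breath_simconfig`.
#' @export
sim_config <- function(dt = 0.5, n_steps = 2e6, preheat_steps = 2e4,
                       n_realizations = 5, sample_stride = 100,
                       seed = 1L, temperature = NULL, y_wall = Inf) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (n_steps < 1 || n_realizations < 1)
    stop("n_steps and n_realizations must be >= 1")
  if (sample_stride < 1) stop("sample_stride must be >= 1")
  if (preheat_steps < 0) stop("preheat_steps must be >= 0")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 preheat_steps = as.integer(preheat_steps),
                 n_realizations = as.integer(n_realizations),
                 sample_stride = as.integer(sample_stride),
                 seed = as.integer(seed), temperature = temperature,
                 y_wall = y_wall),
            class = "breath_simconfig")
}
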