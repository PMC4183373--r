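# Langevin dynamics of the coupled chain + particle system.
#
# The integrator composes a classical 4th-order Runge-Kutta step on the
# conservative dynamics with an exact Ornstein-Uhlenbeck update of the
# velocities (damping exp(-gamma*dt), noise variance kBT/m*(1-exp(-2 gamma
# dt)) ~ 2 gamma kBT dt / m). In the deterministic limit (gamma = 0 or
# T = 0 with gamma = 0) the scheme is exactly RK4, so the energy drift of a
# frictionless run scales as O(dt^4).

# deterministic per-realization seed stream below 2^31
realization_seed <- function(master_seed, realization_id) {
  as.integer((as.numeric(master_seed) * 48271 + 77777 * realization_id) %%
               2147483647)
}

#' Low-level Langevin integration of a chain state
#'
#' Integrates `n_steps` Langevin steps from an explicit initial state and
#' returns sampled frames. Clamped sites are held at `y = 0` (fixed chain
#' boundaries); the particle coordinate is wrapped periodically into
#' `[0, N)`. This is the building block used by [run_realization()]; it is
#' exported for convergence and sampling diagnostics.
#'
#' @param chain An [encode_chain()] object.
#' @param params A [model_params()] object.
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param sample_stride Steps between stored frames.
#' @param y0,v0 Initial openings and velocities (default: closed chain,
#'   Maxwell-Boltzmann velocities at the bath temperature).
#' @param x0,u0 Initial particle position/velocity.
#' @param temperature Bath temperature override (K); `0` disables noise.
#' @param gamma Friction override (default `params$gamma`; `0` disables
#'   friction and noise, giving a purely conservative RK4 run).
#' @param with_particle Couple the particle? Defaults to `params$A_p > 0`.
#' @param y_wall Optional reflecting wall on openings (A); `Inf` = none.
#' @param record_energy Record total mechanical energy per frame.
#' @param method `"srk4"` (production integrator) or `"euler"` (first-order
#'   Euler-Maruyama reference, used as a cross-check oracle).
#' @return A list with matrix `Y` (frames x N), vectors `x`, `kinetic`,
#'   optionally `energy`, and the final phase-space state.
#' @export
langevin_run <- function(chain, params, dt, n_steps, sample_stride = 1L,
                         y0 = NULL, v0 = NULL, x0 = 0, u0 = 0,
                         temperature = NULL, gamma = NULL,
                         with_particle = params$A_p > 0,
                         y_wall = Inf, record_energy = FALSE,
                         method = c("srk4", "euler")) {
  stopifnot(inherits(chain, "encoded_chain"), inherits(params, "breath_params"))
  method <- match.arg(method)
  N <- chain$N
  kT <- kBT(params, temperature)
  if (is.null(gamma)) gamma <- params$gamma
  if (is.null(y0)) y0 <- numeric(N)
  if (is.null(v0)) {
    v0 <- if (kT > 0) stats::rnorm(N, sd = sqrt(kT / params$mass))
          else numeric(N)
  }
  sm <- site_morse(chain, params)
  if (method == "srk4") {
    .simulate_cpp(y0, v0, x0, u0, sm$D, sm$a, chain$is_clamp,
                  unclass(params), gamma, kT, dt, as.integer(n_steps),
                  as.integer(sample_stride), with_particle, y_wall,
                  record_energy)
  } else {
    .simulate_em_cpp(y0, v0, x0, u0, sm$D, sm$a, chain$is_clamp,
                     unclass(params), gamma, kT, dt, as.integer(n_steps),
                     as.integer(sample_stride), with_particle, y_wall)
  }
}

#' Run one Langevin realization of a promoter chain
#'
#' Performs a preheating run (discarded) followed by production sampling.
#' The random stream is derived deterministically from
#' `(config$seed, realization_id)`, so a realization is bit-reproducible
#' regardless of how many others are run.
#'
#' @param chain An [encode_chain()] object.
#' @param params A [model_params()] object.
#' @param config A [sim_config()] object.
#' @param realization_id Integer id (1-based).
#' @return An object of class `breath_trajectory`: list with `Y` (frames x N
#'   opening matrix), `x` (particle coordinate per frame), `times`,
#'   `kinetic`, `realization_id`, `seed_used`, `dt`, `stride`.
#' @export
run_realization <- function(chain, params, config, realization_id = 1L) {
  stopifnot(inherits(config, "breath_simconfig"))
  seed_r <- realization_seed(config$seed, realization_id)
  wp <- params$A_p > 0
  res <- withr::with_seed(seed_r, {
    N <- chain$N
    kT <- kBT(params, config$temperature)
    x0 <- if (wp) stats::runif(1, 0, N) else 0
    y0 <- numeric(N)
    v0 <- if (kT > 0) stats::rnorm(N, sd = sqrt(kT / params$mass))
          else numeric(N)
    u0 <- 0
    if (config$preheat_steps > 0L) {
      pre <- langevin_run(chain, params, dt = config$dt,
                          n_steps = config$preheat_steps,
                          sample_stride = config$preheat_steps,
                          y0 = y0, v0 = v0, x0 = x0, u0 = u0,
                          temperature = config$temperature,
                          with_particle = wp, y_wall = config$y_wall)
      y0 <- pre$y_final; v0 <- pre$v_final
      x0 <- pre$x_final; u0 <- pre$u_final
    }
    langevin_run(chain, params, dt = config$dt, n_steps = config$n_steps,
                 sample_stride = config$sample_stride,
                 y0 = y0, v0 = v0, x0 = x0, u0 = u0,
                 temperature = config$temperature,
                 with_particle = wp, y_wall = config$y_wall)
  })
  nframes <- nrow(res$Y)
  structure(list(Y = res$Y, x = res$x, kinetic = res$kinetic,
                 times = config$dt * config$sample_stride * seq_len(nframes),
                 realization_id = as.integer(realization_id),
                 seed_used = seed_r, dt = config$dt,
                 stride = config$sample_stride),
            class = "breath_trajectory")
}

#' @export
print.breath_trajectory <- function(x, ...) {
  cat(sprintf(
    "breath_trajectory: %d frames x %d sites (realization %d, stride %d)\n",
    nrow(x$Y), ncol(x$Y), x$realization_id, x$stride))
  invisible(x)
}

#' Simulate an ensemble of realizations and average observables
#'
#' @inheritParams run_realization
#' @return A list with `trajectories` (list of `breath_trajectory`) and
#'   `profile` (an [opening_profile()] object).
#' @export
run_ensemble <- function(chain, params, config) {
  stopifnot(inherits(config, "breath_simconfig"))
  if (config$n_realizations < 1L) stop("need at least one realization")
  trajs <- lapply(seq_len(config$n_realizations), function(r)
    run_realization(chain, params, config, realization_id = r))
  list(trajectories = trajs, profile = opening_profile(trajs, chain))
}

#' Mean opening profile and particle visit histogram
#'
#' Averages `<y_n>` over all frames of all realizations and tabulates the
#' fraction of frames the particle spends at each site (nearest integer with
#' periodic wrap). Both observables are reported on non-clamp sites only;
#' the histogram is renormalized over those sites.
#'
#' @param trajectories List of `breath_trajectory` objects.
#' @param chain The [encode_chain()] they were simulated on.
#' @return An object of class `breath_profile`: data.frame with one row per
#'   non-clamp site (`site`, `seq_position`, `label`, `pair_class`,
#'   `mean_opening`, `particle_fraction`).
#' @export
opening_profile <- function(trajectories, chain) {
  stopifnot(length(trajectories) >= 1L)
  N <- chain$N
  ysum <- numeric(N)
  counts <- numeric(N)
  nframes <- 0L
  for (tr in trajectories) {
    ysum <- ysum + colSums(tr$Y)
    site <- particle_site(tr$x, N)
    tb <- tabulate(site, nbins = N)
    counts <- counts + tb
    nframes <- nframes + nrow(tr$Y)
  }
  mean_y <- ysum / nframes
  keep <- which(chain$mask)
  frac <- counts[keep]
  frac <- if (sum(frac) > 0) frac / sum(frac) else frac
  out <- data.frame(site = keep,
                    seq_position = chain$seq_position[keep],
                    label = chain$position_labels[keep],
                    pair_class = chain$pair_class[keep],
                    mean_opening = mean_y[keep],
                    particle_fraction = frac)
  class(out) <- c("breath_profile", "data.frame")
  out
}

# nearest-site assignment of the continuous particle coordinate, 1-based,
# with periodic wrap (x = 0 corresponds to site 1)
particle_site <- function(x, N) {
  (as.integer(round(x)) %% N) + 1L
}

#' Time-averaged kinetic temperature of a trajectory
#'
#' Diagnostic for equipartition: returns the time average of
#' `2 * KE / (n_dof * kB)` in Kelvin, where `n_dof` counts non-clamp sites
#' plus the particle (when coupled).
#'
#' @param traj A `breath_trajectory`.
#' @param chain Its [encode_chain()].
#' @param params The [model_params()] used.
#' @param with_particle Whether the particle degree of freedom was active.
#' @return Temperature estimate in K.
#' @export
kinetic_temperature <- function(traj, chain, params,
                                with_particle = params$A_p > 0) {
  ndof <- sum(chain$mask) + as.integer(with_particle)
  mean(traj$kinetic) * 2 / (ndof * params$kB)
}
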