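#' Langevin dynamics parameters
#'
#' Defaults follow the package's standard sampling protocol: 298 K, a
#' friction constant of 15 ps^-1 and a 1 fs integration step.
#'
#' @param temperature K (default 298).
#' @param gamma friction, ps^-1 (default 15; 0 gives microcanonical
#'   velocity-Verlet dynamics).
#' @param dt time step, ps (default 0.001).
#' @param n_steps number of integration steps.
#' @param seed RNG seed; fixed seed reproduces the trajectory exactly.
#' @param sample_stride record every this many steps (default 10).
#' @export
sim_params <- function(temperature = 298, gamma = 15, dt = 0.001,
                       n_steps = 1000L, seed = 1L, sample_stride = 10L) {
  stopifnot(temperature > 0, gamma >= 0, dt > 0, n_steps >= 1)
  base::structure(list(temperature = temperature, gamma = gamma, dt = dt,
                       n_steps = as.integer(n_steps), seed = seed,
                       sample_stride = as.integer(sample_stride)),
                  class = "drs_sim_params")
}

#' Define a system for the Langevin sampler
#'
#' @param potential function of the flat coordinate vector returning
#'   `list(energy =, force =)` with the force the negative gradient
#'   (kJ mol^-1 nm^-1).
#' @param masses numeric: one mass per degree of freedom, or one per
#'   particle (recycled over x, y, z), or a scalar. amu.
#' @param x0 initial coordinates, flat numeric vector (or N x 3 matrix,
#'   flattened row-wise).
#' @param v0 optional initial velocities (defaults to a Maxwell-Boltzmann
#'   draw at the run temperature).
#' @export
langevin_system <- function(potential, masses, x0, v0 = NULL) {
  if (is.matrix(x0)) x0 <- as.numeric(t(x0))
  nd <- length(x0)
  if (length(masses) == 1L) masses <- rep(masses, nd)
  if (length(masses) == nd / 3) masses <- rep(masses, each = 3L)
  if (length(masses) != nd) {
    stop("masses must map to degrees of freedom (scalar, per-particle, ",
         "or per-dof)")
  }
  stopifnot(all(masses > 0), is.function(potential))
  if (!is.null(v0) && length(v0) != nd) stop("v0 length mismatch")
  base::structure(list(potential = potential, masses = masses, x0 = x0,
                       v0 = v0),
                  class = "drs_system")
}

#' Run Langevin dynamics (BAOAB discretization)
#'
#' Integrates the system with the BAOAB splitting of the Langevin
#' equation: half kick, half drift, Ornstein-Uhlenbeck velocity
#' randomization, half drift, half kick. With `gamma = 0` (and therefore
#' no noise) the scheme reduces to velocity Verlet. The run is
#' reproducible for a fixed seed and aborts with the step index if the
#' energy turns non-finite.
#'
#' @param system a [langevin_system()].
#' @param params a [sim_params()].
#' @param record optional observable hook `function(x)` evaluated at every
#'   sampled step (e.g. a dU/dlambda evaluator); its values are returned
#'   as the `observable` series.
#' @param save_trajectory keep the sampled coordinates (default TRUE).
#' @return list with `times` (ps), `observable` (numeric series or NULL),
#'   `xyz` (matrix samples x dof, or NULL), `kinetic_temperature`
#'   (mean over samples, K), `final_x`, `final_v`.
#' @export
langevin_run <- function(system, params = sim_params(), record = NULL,
                         save_trajectory = TRUE) {
  stopifnot(inherits(system, "drs_system"),
            inherits(params, "drs_sim_params"))
  kT <- kbt(params$temperature)
  m <- system$masses
  nd <- length(system$x0)
  dt <- params$dt
  c1 <- exp(-params$gamma * dt)
  c2 <- sqrt((1 - c1^2) * kT / m)

  with_seed(params$seed, {
    x <- system$x0
    v <- if (is.null(system$v0)) rnorm(nd) * sqrt(kT / m) else system$v0
    p <- system$potential(x)
    if (!is.finite(p$energy)) stop("non-finite initial energy")
    f <- p$force

    n_samp <- params$n_steps %/% params$sample_stride
    obs <- if (!is.null(record)) numeric(n_samp) else NULL
    traj <- if (save_trajectory) matrix(NA_real_, n_samp, nd) else NULL
    times <- numeric(n_samp)
    ktemp <- numeric(n_samp)
    k <- 0L

    for (step in seq_len(params$n_steps)) {
      v <- v + 0.5 * dt * f / m
      x <- x + 0.5 * dt * v
      if (params$gamma > 0) v <- c1 * v + c2 * rnorm(nd)
      x <- x + 0.5 * dt * v
      p <- system$potential(x)
      if (!is.finite(p$energy)) {
        stop("divergence error: non-finite energy at step ", step)
      }
      f <- p$force
      v <- v + 0.5 * dt * f / m
      if (step %% params$sample_stride == 0L) {
        k <- k + 1L
        times[k] <- step * dt
        ktemp[k] <- sum(m * v^2) / (nd * KB)
        if (!is.null(record)) obs[k] <- record(x)
        if (save_trajectory) traj[k, ] <- x
      }
    }
    list(times = times, observable = obs, xyz = traj,
         kinetic_temperature = mean(ktemp), final_x = x, final_v = v)
  })
}

#' Total energy (potential + kinetic) helper for conservation checks
#'
#' @param system a [langevin_system()].
#' @param x,v coordinate and velocity vectors.
#' @return kJ/mol.
#' @export
total_energy <- function(system, x, v) {
  system$potential(x)$energy + 0.5 * sum(system$masses * v^2)
}

#' Write a dU/dlambda (or any observable) series as two-column text
#'
#' @param times numeric, ps.
#' @param values numeric, kJ/mol.
#' @param path file path.
#' @export
write_series <- function(times, values, path) {
  write.table(data.frame(time = times, value = values), path,
              row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  read.table(path, header = TRUE, col.names = c("time", "value"))
}

#' Dump sampled coordinates as a plain XYZ trajectory
#'
#' @param result a [langevin_run()] result with `xyz` kept.
#' @param path file path.
#' @param labels optional per-particle element labels.
#' @export
write_xyz <- function(result, path, labels = NULL) {
  if (is.null(result$xyz)) stop("run was made without save_trajectory")
  n <- ncol(result$xyz) / 3
  if (is.null(labels)) labels <- rep("C", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in seq_len(nrow(result$xyz))) {
    writeLines(c(as.character(n), sprintf("t = %.4f ps", result$times[fr])),
               con)
    xyz <- matrix(result$xyz[fr, ], n, 3, byrow = TRUE)
    writeLines(sprintf("%s %12.6f %12.6f %12.6f", labels,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
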