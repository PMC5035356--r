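#' Build a harmonic-tether toy system
#'
#' Every atom is tethered to its reference position by an isotropic spring of
#' stiffness `k`.  At temperature T each atom then fluctuates independently
#' with \eqn{\langle u^2 \rangle = k_B T / k} per axis, giving the closed
#' form \eqn{B = 8\pi^2 k_B T / k} used as an analytic oracle.
#'
#' @param ref_coords n x 3 matrix of reference positions, A.
#' @param k spring constant, kcal/mol/A^2.
#' @param masses atomic masses in amu (scalar recycled, or length n).
#' @return Object of class `toy_system`.
#' @export
harmonic_tether_system <- function(ref_coords, k = 1, masses = 12) {
  ref_coords <- as.matrix(ref_coords)
  stopifnot(ncol(ref_coords) == 3L, k > 0)
  n <- nrow(ref_coords)
  masses <- rep_len(masses, n)
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(n_atoms = n, masses = masses,
                 potential = list(type = "harmonic_tether", k = k,
                                  ref = ref_coords)),
            class = "toy_system")
}

#' Build an elastic-network toy system
#'
#' Nodes within `cutoff` of each other in the reference conformation are
#' connected by springs of stiffness `k` at their reference separations.
#' The default 8 A cutoff mirrors typical nonbonded cutoffs.  The contact
#' graph must be connected for the analytic fluctuation oracle to apply.
#'
#' @inheritParams harmonic_tether_system
#' @param cutoff contact cutoff, A.
#' @return Object of class `toy_system` whose potential carries the contact
#'   `pairs` (1-based index matrix) and equilibrium lengths `r0`.
#' @export
elastic_network_system <- function(ref_coords, k = 1, cutoff = 8, masses = 12) {
  ref_coords <- as.matrix(ref_coords)
  stopifnot(ncol(ref_coords) == 3L, k > 0, cutoff > 0)
  n <- nrow(ref_coords)
  masses <- rep_len(masses, n)
  if (any(masses <= 0)) stop("masses must be positive")
  d <- as.matrix(stats::dist(ref_coords))
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop("no contacts within cutoff")
  r0 <- d[pairs]
  structure(list(n_atoms = n, masses = masses,
                 potential = list(type = "elastic_network", k = k,
                                  ref = ref_coords, cutoff = cutoff,
                                  pairs = pairs, r0 = r0)),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  p <- x$potential
  cat(sprintf("toy_system: %d atoms, %s (k = %g kcal/mol/A^2%s)\n",
              x$n_atoms, p$type, p$k,
              if (p$type == "elastic_network")
                sprintf(", cutoff %g A, %d contacts", p$cutoff, nrow(p$pairs))
              else ""))
  invisible(x)
}

#' Configure a toy MD run
#'
#' @param timestep integrator timestep in fs (nominal clock).
#' @param n_steps total number of integration steps.
#' @param save_interval_steps frame saving cadence in steps.
#' @param ensemble one of `nve()`, `berendsen(T0, tau)`, `langevin(T0, gamma)`.
#' @param heat_ramp optional `list(rate = K/ps, target = K)`: the thermostat
#'   target rises from 0 K at `rate` until `target`.
#' @param seed integer seed used for velocity initialisation and the
#'   Langevin noise stream.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(timestep = 1.0, n_steps, save_interval_steps = 1000L,
                       ensemble = nve(), heat_ramp = NULL, seed = 1L) {
  stopifnot(timestep > 0, n_steps >= save_interval_steps,
            save_interval_steps >= 1L)
  if (ensemble$kind == "berendsen" && ensemble$tau <= timestep) {
    stop("Berendsen coupling time tau must exceed the timestep")
  }
  if (!is.null(heat_ramp)) {
    stopifnot(is.list(heat_ramp), heat_ramp$rate > 0, heat_ramp$target >= 0)
  }
  structure(list(timestep = timestep, n_steps = as.integer(n_steps),
                 save_interval_steps = as.integer(save_interval_steps),
                 ensemble = ensemble, heat_ramp = heat_ramp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
nve <- function() list(kind = "nve", T0 = 0)

#' @rdname sim_config
#' @param T0 thermostat target temperature, K.
#' @param tau Berendsen coupling time, fs.
#' @export
berendsen <- function(T0, tau = 100) {
  stopifnot(T0 >= 0, tau > 0)
  list(kind = "berendsen", T0 = T0, tau = tau)
}

#' @rdname sim_config
#' @param gamma Langevin friction, 1/fs.
#' @export
langevin <- function(T0, gamma = 0.01) {
  stopifnot(T0 >= 0, gamma > 0)
  list(kind = "langevin", T0 = T0, gamma = gamma)
}

#' Draw Maxwell-Boltzmann initial velocities
#'
#' Per-axis velocity variance is \eqn{k_B T c_E / m} (A/fs)^2; the
#' centre-of-mass momentum of the draw is removed.  With a `seed` the draw
#' is fully deterministic.
#'
#' @param masses amu vector.
#' @param T temperature in K (T = 0 gives all-zero velocities).
#' @param seed optional integer seed.
#' @return n x 3 velocity matrix, A/fs.
#' @export
init_velocities <- function(masses, T, seed = NULL) {
  if (T < 0) stop("temperature must be non-negative")
  n <- length(masses)
  if (!is.null(seed)) set.seed(seed)
  if (T == 0) return(matrix(0, n, 3))
  sd_v <- sqrt(md_units$kB * T * md_units$energy_to_internal / masses)
  v <- matrix(rnorm(3 * n), n, 3) * sd_v
  # remove centre-of-mass momentum
  p_com <- colSums(v * masses) / sum(masses)
  sweep(v, 2, p_com, "-")
}

ensemble_code <- function(ensemble) {
  switch(ensemble$kind, nve = 0L, berendsen = 1L, langevin = 2L,
         stop("unknown ensemble kind"))
}

#' Integrate one trajectory of a toy system
#'
#' Velocity-Verlet integration (BAOAB splitting under the Langevin
#' thermostat), saving frames and an energy log at the configured cadence.
#'
#' @param system a `toy_system`.
#' @param config a [sim_config()].
#' @param coords starting coordinates (defaults to the reference).
#' @param velocities starting velocities; by default drawn with
#'   [init_velocities()] at the thermostat target under `config$seed`.
#' @return List with `frames` (n_saved x atoms x 3), `log` (data frame:
#'   step, time_fs, kinetic_T, potential, total), `final_coords`,
#'   `final_vels`.
#' @export
integrate_system <- function(system, config, coords = NULL,
                             velocities = NULL) {
  stopifnot(inherits(system, "toy_system"), inherits(config, "sim_config"))
  p <- system$potential
  if (is.null(coords)) coords <- p$ref
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == system$n_atoms)
  if (is.null(velocities)) {
    velocities <- init_velocities(system$masses, config$ensemble$T0,
                                  seed = config$seed)
  } else {
    set.seed(config$seed)  # still pin the Langevin noise stream
  }
  pot_type <- if (p$type == "harmonic_tether") 0L else 1L
  pairs0 <- if (pot_type == 1L) p$pairs - 1L else matrix(0L, 0L, 2L)
  r0 <- if (pot_type == 1L) p$r0 else numeric(0)
  ens <- config$ensemble
  hr <- config$heat_ramp
  res <- integrate_cpp(coords, velocities, system$masses, pot_type, p$k,
                       p$ref, pairs0, r0, config$timestep, config$n_steps,
                       config$save_interval_steps, ensemble_code(ens),
                       ens$T0, if (is.null(ens$tau)) 0 else ens$tau,
                       if (is.null(ens$gamma)) 0 else ens$gamma,
                       !is.null(hr),
                       if (is.null(hr)) 0 else hr$rate / 1000,  # K/ps -> K/fs
                       if (is.null(hr)) 0 else hr$target)
  log <- as.data.frame(res$log)
  names(log) <- c("step", "time_fs", "kinetic_T", "potential", "total")
  list(frames = res$frames, log = log, final_coords = res$final_coords,
       final_vels = res$final_vels)
}

#' Run an ensemble of independent replicate simulations
#'
#' All replicates share the system, schedule and starting coordinates and
#' differ only in their seed (initial velocities and, under Langevin, the
#' noise stream).
#'
#' @param system a `toy_system`.
#' @param config a [sim_config()]; its own seed is ignored.
#' @param seeds integer vector, one seed per replicate.
#' @param initial_coords optional list of per-replicate starting coordinate
#'   matrices (multi-start mode) or a single matrix shared by all.
#' @return A [trajectory_ensemble()] whose atom table is a generic carbon
#'   atom per node.
#' @export
run_ensemble <- function(system, config, seeds, initial_coords = NULL) {
  stopifnot(length(seeds) >= 1L)
  starts <- if (is.null(initial_coords)) {
    rep(list(system$potential$ref), length(seeds))
  } else if (is.matrix(initial_coords)) {
    rep(list(initial_coords), length(seeds))
  } else {
    stopifnot(length(initial_coords) == length(seeds))
    for (k in seq_along(initial_coords)) {
      if (!identical(dim(as.matrix(initial_coords[[k]])),
                     c(system$n_atoms, 3L))) {
        stop(sprintf("initial conformation %d does not match the atom table", k))
      }
    }
    initial_coords
  }
  trajs <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seeds[i])
    trajs[[i]] <- integrate_system(system, cfg_i, coords = starts[[i]])$frames
  }
  trajectory_ensemble(trajs, toy_atom_table(system), seeds,
                      save_interval_steps = config$save_interval_steps,
                      nominal_timestep = config$timestep)
}

#' Atom table for a toy system (generic carbon nodes, CA-named)
#' @param system a `toy_system`.
#' @return An `md_structure`.
#' @export
toy_atom_table <- function(system) {
  n <- system$n_atoms
  ref <- system$potential$ref
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", resname = "GLY", chain = "A",
    resid = seq_len(n), x = ref[, 1], y = ref[, 2], z = ref[, 3],
    occupancy = 1, bfactor = 0, element = "C", het = FALSE,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source_id = "toy_system"),
            class = "md_structure")
}

#' Analytic equilibrium B-factors of a toy system
#'
#' Equilibrium positional covariance of a harmonic system at temperature T
#' is \eqn{k_B T} times the pseudo-inverse of the (mass-unweighted) Hessian.
#' For an elastic network the six rigid-body zero modes are projected out;
#' tether potentials have none.  Per atom,
#' \eqn{B_i = (8\pi^2/3)\,\mathrm{tr}\,C_{ii}} with \eqn{C_{ii}} the atom's
#' 3 x 3 covariance block.
#'
#' @param system a `toy_system`.
#' @param T temperature, K (> 0).
#' @return Per-atom B-factor vector, A^2.
#' @export
enm_analytic_bfactors <- function(system, T) {
  stopifnot(inherits(system, "toy_system"), T > 0)
  p <- system$potential
  n <- system$n_atoms
  if (p$type == "harmonic_tether") {
    return(rep(8 * pi^2 * md_units$kB * T / p$k, n))
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (q in seq_len(nrow(p$pairs))) {
    i <- p$pairs[q, 1]; j <- p$pairs[q, 2]
    e <- (p$ref[j, ] - p$ref[i, ]) / p$r0[q]
    K <- p$k * tcrossprod(e)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + K
    H[jj, jj] <- H[jj, jj] + K
    H[ii, jj] <- H[ii, jj] - K
    H[jj, ii] <- H[jj, ii] - K
  }
  eig <- eigen(H, symmetric = TRUE)
  tol <- 1e-8 * max(eig$values)
  zero <- sum(eig$values < tol)
  if (zero > 6L) {
    stop(sprintf("elastic network is disconnected: %d near-zero modes", zero))
  }
  keep <- which(eig$values >= tol)
  # per-coordinate variance summed into per-atom traces
  V2 <- eig$vectors[, keep, drop = FALSE]^2
  var_per_coord <- md_units$kB * T *
    as.vector(V2 %*% (1 / eig$values[keep]))
  msf3d <- colSums(matrix(var_per_coord, nrow = 3))
  (8 * pi^2 / 3) * msf3d
}

#' Measure the oscillation period of a single tethered atom
#'
#' Integrates a one-atom tether displaced along x in NVE and estimates the
#' period from interpolated upward zero crossings of the displacement.  The
#' closed form is \eqn{2\pi\sqrt{m/(k\,c_E)}} with \eqn{c_E} the kcal/mol
#' energy conversion.
#'
#' @param k spring constant, kcal/mol/A^2.
#' @param mass amu.
#' @param timestep fs.
#' @param n_periods how many periods to integrate over.
#' @param amplitude initial displacement, A.
#' @return Measured period in fs.
#' @export
oscillator_period <- function(k = 1, mass = 12, timestep = 0.5,
                              n_periods = 10, amplitude = 0.5) {
  theory <- 2 * pi * sqrt(mass / (k * md_units$energy_to_internal))
  n_steps <- ceiling(n_periods * theory / timestep)
  sys <- harmonic_tether_system(matrix(0, 1, 3), k = k, masses = mass)
  cfg <- sim_config(timestep = timestep, n_steps = n_steps,
                    save_interval_steps = 1L, ensemble = nve(), seed = 1L)
  res <- integrate_system(sys, cfg,
                          coords = matrix(c(amplitude, 0, 0), 1, 3),
                          velocities = matrix(0, 1, 3))
  xs <- res$frames[, 1, 1]
  ts <- res$log$time_fs
  up <- which(xs[-length(xs)] < 0 & xs[-1] >= 0)
  if (length(up) < 2L) stop("too few oscillations to measure a period")
  # linear interpolation of each crossing time
  tc <- ts[up] + (ts[up + 1] - ts[up]) * (-xs[up]) / (xs[up + 1] - xs[up])
  mean(diff(tc))
}
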