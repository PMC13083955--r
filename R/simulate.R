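#' Simulation configuration
#'
#' Holds the thermodynamic state and run-length bookkeeping of a Langevin
#' simulation.  Defaults are the single-chain protocol this package
#' reproduces: 298.15 K, pH 6.8, ionic strength 0.22 M, 70 ns production
#' with the first 3.5 ns discarded as equilibration, drag coefficient
#' 0.01 ps^-1, 10 fs timestep, frames saved every 0.5 ps (the save interval
#' that reconciles 70 ns, a 3.5 ns discard, and 133,000 production frames),
#' 10 replicas.
#'
#' @slot temperature K.
#' @slot pH dimensionless.
#' @slot ionicStrength M.
#' @slot duration production length, ns.
#' @slot equilibration discarded initial span, ns.
#' @slot friction Langevin drag coefficient, ps^-1.
#' @slot timestep integration step, fs.
#' @slot saveInterval frame save interval, ps.
#' @slot replicas integer replica count.
#' @slot seeds integer seeds, one per replica.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(temperature = "numeric", pH = "numeric",
                 ionicStrength = "numeric", duration = "numeric",
                 equilibration = "numeric", friction = "numeric",
                 timestep = "numeric", saveInterval = "numeric",
                 replicas = "integer", seeds = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@equilibration >= object@duration)
    msg <- c(msg, "equilibration cut must be smaller than the duration")
  if (object@timestep <= 0) msg <- c(msg, "timestep must be positive")
  if (object@saveInterval <= 0) msg <- c(msg, "save interval must be positive")
  if (object@replicas < 1) msg <- c(msg, "replica count must be >= 1")
  if (length(object@seeds) != object@replicas)
    msg <- c(msg, "one seed per replica required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %.4g K, pH %.3g, I %.3g M\n",
    "%.4g ns production (%.4g ns equilibration), dt %.3g fs, save %.3g ps\n",
    "friction %.3g ps^-1, %d replica(s)\n"),
    object@temperature, object@pH, object@ionicStrength, object@duration,
    object@equilibration, object@timestep, object@saveInterval,
    object@friction, object@replicas))
})

#' Create a simulation configuration
#'
#' @param temperature temperature (K); default 298.15.
#' @param pH solution pH; default 6.8.
#' @param ionicStrength ionic strength (M); default 0.22.
#' @param duration production length (ns); default 70.
#' @param equilibration span discarded as equilibration (ns); default 3.5.
#' @param friction Langevin drag coefficient (ps^-1); default 0.01.
#' @param timestep integration timestep (fs); default 10.
#' @param saveInterval frame save interval (ps); default 0.5.
#' @param replicas number of independent replicas; default 10.
#' @param seedBase replica i uses seed \code{seedBase + i}.
#' @return a \code{\link{SimulationConfig}}.
#' @export
simulationConfig <- function(temperature = 298.15, pH = 6.8,
                             ionicStrength = 0.22, duration = 70,
                             equilibration = 3.5, friction = 0.01,
                             timestep = 10, saveInterval = 0.5,
                             replicas = 10, seedBase = 1000) {
  new("SimulationConfig", temperature = temperature, pH = pH,
      ionicStrength = ionicStrength, duration = duration,
      equilibration = equilibration, friction = friction,
      timestep = timestep, saveInterval = saveInterval,
      replicas = as.integer(replicas),
      seeds = seedBase + seq_len(replicas))
}

#' Closed-form production frame count
#'
#' Number of frames remaining after the equilibration cut:
#' \code{floor((duration - equilibration) * 1000 / saveInterval)} with
#' durations in ns and the save interval in ps.  For the default protocol
#' (70 ns, 3.5 ns cut, 0.5 ps) this is 133,000.
#'
#' @param duration production length (ns).
#' @param equilibration equilibration cut (ns).
#' @param saveInterval save interval (ps).
#' @return integer frame count.
#' @export
productionFrameCount <- function(duration, equilibration, saveInterval) {
  if (equilibration >= duration)
    stop("equilibration cut must be smaller than the duration")
  ## small guard against binary-fraction artifacts (0.6 - 0.05, etc.)
  as.integer(floor((duration - equilibration) * 1000 / saveInterval + 1e-9))
}

#' Initial conformation for a replica
#'
#' Starts from the topology's reference coordinates and perturbs the
#' geometry of linker (non-domain) beads with Gaussian jitter under the
#' replica seed, so replicas start from distinct disordered-region
#' conformations while folded domains keep their reference pose.
#'
#' @param topology a \code{\link{ChainTopology}}.
#' @param seed integer seed.
#' @param jitter Gaussian SD of the perturbation (nm); default 0.03.
#' @return numeric matrix (beads x 3), nm.
#' @export
initialConformation <- function(topology, seed, jitter = 0.03) {
  coords <- referenceCoords(topology)
  group <- .restraintGroups(domainTable(topology), nBeads(topology))
  idr <- which(is.na(group))
  if (length(idr) && jitter > 0) {
    withSeed(seed, {
      coords[idr, ] <- coords[idr, ] +
        matrix(stats::rnorm(3 * length(idr), 0, jitter), ncol = 3)
    })
  }
  coords
}

#' Run Langevin dynamics on a chain topology
#'
#' Integrates the chain with a BAOAB-type Langevin scheme at the configured
#' temperature and friction, starting from Maxwell-Boltzmann velocities
#' drawn under the seed.  A short soft-core warmup (non-bonded pair forces
#' clipped; not part of the saved trajectory) relaxes residual clashes and
#' strain in the starting conformation.  Frames are saved every \code{saveInterval}; the run is
#' deterministic for a fixed (topology, config, seed) on a fixed platform.
#'
#' @param topology a \code{\link{ChainTopology}}.
#' @param config a \code{\link{SimulationConfig}}.
#' @param seed integer seed for velocities, warmup noise and thermostat.
#' @param initialCoords optional starting coordinates (beads x 3, nm);
#'   default \code{\link{initialConformation}} under the same seed.
#' @param saveVelocities retain velocities at save points (for thermostat
#'   diagnostics); default FALSE.
#' @param warmupSteps soft-core warmup steps before t = 0; default 5000.
#' @param forceCap warmup cap on each non-bonded pair force (kJ/mol/nm);
#'   default 500.
#' @param epsilon short-range energy scale (kJ/mol); default 0.8368.
#' @param ahCutoff short-range cutoff (nm); default 2.0.
#' @param dhCutoff electrostatic cutoff (nm); default 4.0.
#' @param replica replica id recorded in the trajectory; default 1.
#' @return a \code{\link{Trajectory}} (untrimmed; apply
#'   \code{\link{trimEquilibration}} for production frames).
#' @export
runLangevin <- function(topology, config, seed, initialCoords = NULL,
                        saveVelocities = FALSE, warmupSteps = 5000,
                        forceCap = 500, epsilon = 0.8368,
                        ahCutoff = 2.0, dhCutoff = 4.0, replica = 1L) {
  stopifnot(is(topology, "ChainTopology"), is(config, "SimulationConfig"))
  dt <- config@timestep / 1000                      # fs -> ps
  nSteps <- round(config@duration * 1000 / dt)
  saveEvery <- max(1L, round(config@saveInterval / dt))
  if (is.null(initialCoords))
    initialCoords <- initialConformation(topology, seed)
  initialCoords <- as.matrix(initialCoords)
  if (!all(is.finite(initialCoords)))
    stop("initial coordinates contain non-finite values")

  n <- nBeads(topology)
  if (nSteps == 0) {
    coords <- array(initialCoords, dim = c(n, 3, 1))
    return(.newTrajectory(coords, times = 0, dt = config@saveInterval,
                          replica = replica))
  }

  epsr <- waterDielectric(config@temperature)
  kappa <- debyeKappa(config@ionicStrength, config@temperature,
                      dielectric = epsr)
  kT <- .kB * config@temperature

  res <- withSeed(seed, .cgLangevin(
    initialCoords, topology@masses, topology@charges, topology@lambdas,
    topology@sigmas, topology@bonds, topology@bondR0, topology@bondK,
    topology@restraints, topology@restraintR0, topology@restraintK,
    epsilon, ahCutoff, dhCutoff, kappa, .coulomb / epsr,
    kT, config@friction, dt, as.integer(nSteps), as.integer(saveEvery),
    as.integer(warmupSteps), forceCap, saveVelocities))

  nSave <- res$nSaved
  coords <- array(res$coords[seq_len(n * 3 * nSave)], dim = c(n, 3, nSave))
  vel <- NULL
  if (saveVelocities)
    vel <- array(res$velocities[seq_len(n * 3 * nSave)],
                 dim = c(n, 3, nSave))
  .newTrajectory(coords, times = res$times[seq_len(nSave)],
                 dt = saveEvery * dt, replica = replica, velocities = vel)
}

#' Discard equilibration frames from a trajectory
#'
#' Removes every frame with time at or below the cut; frame spacing is
#' preserved.  A zero cut is the identity.
#'
#' @param trajectory a \code{\link{Trajectory}}.
#' @param cut equilibration span to discard (ns).
#' @return the trimmed \code{\link{Trajectory}}.
#' @export
trimEquilibration <- function(trajectory, cut) {
  stopifnot(is(trajectory, "Trajectory"))
  if (cut == 0) return(trajectory)
  cutPs <- cut * 1000
  duration <- max(frameTimes(trajectory))
  if (cutPs >= duration)
    stop("equilibration cut (", cut, " ns) must be smaller than the ",
         "trajectory duration (", duration / 1000, " ns)")
  keep <- which(frameTimes(trajectory) > cutPs)
  coords <- trajectory@coords[, , keep, drop = FALSE]
  vel <- trajectory@velocities
  if (!is.null(vel)) vel <- vel[, , keep, drop = FALSE]
  .newTrajectory(coords, times = trajectory@times[keep],
                 dt = trajectory@dt, replica = trajectory@replica,
                 velocities = vel)
}

#' Equipartition estimate of the kinetic temperature
#'
#' Computes per-frame temperatures \eqn{T_f = \sum_i m_i |v_i|^2 / (3 N
#' k_B)} from saved velocities and returns their mean with a standard
#' error over frames.
#'
#' @param x a \code{\link{Trajectory}} run with \code{saveVelocities =
#'   TRUE}, or a velocities array (beads x 3 x frames, nm/ps).
#' @param masses bead masses (Da).
#' @return list with \code{temperature} (K), \code{se} (K) and
#'   \code{nFrames}.
#' @export
kineticTemperature <- function(x, masses) {
  vel <- if (is(x, "Trajectory")) x@velocities else x
  if (is.null(vel)) stop("trajectory was run without saveVelocities")
  d <- dim(vel)
  if (length(d) != 3 || d[2] != 3) stop("velocities must be beads x 3 x frames")
  if (length(masses) != d[1]) stop("one mass per bead required")
  if (prod(d) < 100) stop("too few velocity samples (need >= 100)")
  perFrame <- apply(vel, 3, function(v) sum(masses * rowSums(v^2)))
  temps <- perFrame / (3 * d[1] * .kB)
  ## blocked standard error: successive frames are correlated
  nb <- min(10, length(temps))
  blocks <- split(temps, cut(seq_along(temps), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- if (nb > 1) stats::sd(bm) / sqrt(nb) else 0
  list(temperature = mean(temps), se = se, nFrames = d[3])
}
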