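#' Assemble a study configuration
#'
#' Bundles everything \code{\link{runStudy}} needs: sequence, domain and
#' transient-helix annotations, reference geometry, simulation protocol,
#' variants to run, groove definition and effective-concentration settings.
#' Defaults describe the reproduced protocol (298.15 K, pH 6.8, 0.22 M,
#' 70 ns x 10 replicas with a 3.5 ns discard and 0.5 ps saves; the
#' excluded-volume baseline runs 10x longer) on the synthetic multidomain
#' chain.  Pass a smaller \code{simulation} for desk-scale runs.
#'
#' @param sequence one-letter chain sequence.
#' @param domains domain table (name, start, end, group).
#' @param regions transient-helix region table (name, start, end).
#' @param simulation a \code{\link{SimulationConfig}}.
#' @param variants subset of \code{c("unbound", "bound", "ev")}.
#' @param evDurationFactor multiplier on the production length of the
#'   excluded-volume baseline; default 10.
#' @param referenceCoords,boundCoords,groove optional explicit geometry;
#'   defaults come from \code{\link{syntheticReferenceCoords}}.
#' @param grooveDomain name of the groove-bearing domain used when the
#'   default synthetic geometry is generated; default "STI1".
#' @param candidates candidate residues for occupancy; default all
#'   residues outside the annotated domains.
#' @param contactDistance effective-concentration shell center (nm);
#'   default the first/last-domain center-of-mass separation in the bound
#'   pose.
#' @param shellWidth shell width (nm); default 0.2.
#' @param seedBase integer; replica r of variant v uses seed
#'   \code{seedBase + 100 * v + r}.
#' @param outDir optional output directory for TSV/JSON reports and the
#'   trajectory cache.
#' @return a list of class \code{studyConfig}.
#' @export
studyConfig <- function(sequence = syntheticMultidomainSequence(),
                        domains = syntheticDomainTable(),
                        regions = syntheticHelixRegions(),
                        simulation = simulationConfig(),
                        variants = c("unbound", "bound", "ev"),
                        evDurationFactor = 10,
                        referenceCoords = NULL, boundCoords = NULL,
                        groove = NULL, grooveDomain = "STI1",
                        candidates = NULL,
                        contactDistance = NULL, shellWidth = 0.2,
                        seedBase = 1000, outDir = NULL) {
  seq <- .splitSequence(sequence)
  n <- length(seq)
  if (is.null(referenceCoords) || is.null(groove) || is.null(boundCoords)) {
    ref <- syntheticReferenceCoords(domains = domains, n = n,
                                    grooveDomain = grooveDomain)
    if (is.null(referenceCoords)) referenceCoords <- ref$coords
    if (is.null(boundCoords)) boundCoords <- ref$boundCoords
    if (is.null(groove)) groove <- ref$groove
  }
  if (is.null(candidates)) {
    inDomain <- unlist(mapply(seq, domains$start, domains$end,
                              SIMPLIFY = FALSE))
    candidates <- setdiff(seq_len(n), inDomain)
  }
  validObject(simulation)
  structure(list(sequence = seq, domains = domains, regions = regions,
                 simulation = simulation, variants = variants,
                 evDurationFactor = evDurationFactor,
                 referenceCoords = referenceCoords,
                 boundCoords = boundCoords, groove = groove,
                 candidates = as.integer(candidates),
                 contactDistance = contactDistance,
                 shellWidth = shellWidth, seedBase = seedBase,
                 outDir = outDir),
            class = "studyConfig")
}

#' Run the full study pipeline
#'
#' For each requested topology variant (unbound chain, bound first/last
#' domain complex, excluded-volume baseline) this builds the topology,
#' runs the replica Langevin simulations, trims equilibration, and
#' computes per-residue groove-occupancy profiles, radius-of-gyration
#' summaries, the effective concentration of the first/last domain pair,
#' excess-occupancy profiles against the excluded-volume baseline, and
#' per-region enrichments.  Deterministic for a fixed config (seeds are
#' derived from \code{seedBase}); when \code{outDir} is set, trajectories
#' are cached there and reused on re-runs with the same seeds, and TSV and
#' JSON reports are written.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param verbose print per-stage progress; default FALSE.
#' @return a list bundle with elements \code{topologies},
#'   \code{trajectories}, \code{occupancy}, \code{rg}, \code{excess},
#'   \code{enrichment}, \code{effectiveConcentration}, \code{manifest}.
#' @export
runStudy <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "studyConfig"))
  sim <- config$simulation
  if (sim@equilibration >= sim@duration)
    stop("equilibration cut must be smaller than the duration")
  params <- loadParameterTable()
  say <- function(...) if (verbose) message(sprintf(...))

  base <- buildTopology(config$sequence, params, config$referenceCoords,
                        domains = config$domains, pH = sim@pH)
  topologies <- list()
  for (v in config$variants) {
    topologies[[v]] <- switch(v,
      unbound = base,
      bound = boundComplexVariant(
        base, c(config$domains$group[1],
                config$domains$group[nrow(config$domains)]),
        config$boundCoords),
      ev = excludedVolumeVariant(base),
      stop("unknown variant: ", v))
  }

  cacheDir <- NULL
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    cacheDir <- file.path(config$outDir, "cache")
    dir.create(cacheDir, showWarnings = FALSE)
  }

  variantConfig <- function(v) {
    if (v != "ev") return(sim)
    simulationConfig(temperature = sim@temperature, pH = sim@pH,
                     ionicStrength = sim@ionicStrength,
                     duration = sim@duration * config$evDurationFactor,
                     equilibration = sim@equilibration,
                     friction = sim@friction, timestep = sim@timestep,
                     saveInterval = sim@saveInterval,
                     replicas = sim@replicas, seedBase = 0)
  }

  trajectories <- list()
  for (vi in seq_along(config$variants)) {
    v <- config$variants[vi]
    vc <- variantConfig(v)
    reps <- vector("list", vc@replicas)
    for (r in seq_len(vc@replicas)) {
      seed <- config$seedBase + 100 * vi + r
      cacheFile <- if (!is.null(cacheDir))
        file.path(cacheDir, sprintf("%s_rep%02d_seed%d.rds", v, r, seed))
      if (!is.null(cacheFile) && file.exists(cacheFile)) {
        say("reusing cached %s replica %d", v, r)
        reps[[r]] <- readRDS(cacheFile)
      } else {
        say("simulating %s replica %d (seed %d, %.3g ns)", v, r, seed,
            vc@duration)
        tr <- runLangevin(topologies[[v]], vc, seed = seed, replica = r)
        reps[[r]] <- tr
        if (!is.null(cacheFile)) saveRDS(tr, cacheFile)
      }
    }
    trajectories[[v]] <- lapply(reps, trimEquilibration,
                                cut = vc@equilibration)
  }

  masses <- beadMasses(base)
  occupancy <- lapply(trajectories, function(reps) {
    say("classifying groove occupancy")
    occupancyProfile(reps, config$groove, config$candidates)
  })
  rg <- lapply(trajectories, rgSummary, masses = masses)

  excess <- list(); enrichment <- list()
  if ("ev" %in% names(occupancy)) {
    for (v in setdiff(names(occupancy), "ev")) {
      excess[[v]] <- excessOccupancy(occupancy[[v]], occupancy[["ev"]])
      enrichment[[v]] <- regionEnrichment(excess[[v]], config$regions)
    }
  }

  ceff <- NULL
  if ("unbound" %in% names(trajectories) && nrow(config$domains) >= 2) {
    d <- config$domains
    groupA <- d$start[1]:d$end[1]
    groupB <- d$start[nrow(d)]:d$end[nrow(d)]
    contact <- config$contactDistance
    if (is.null(contact)) {
      a <- .centerOfMass(config$boundCoords[groupA, , drop = FALSE],
                         masses[groupA])
      b <- .centerOfMass(config$boundCoords[groupB, , drop = FALSE],
                         masses[groupB])
      contact <- sqrt(sum((a - b)^2))
    }
    ceff <- effectiveConcentration(trajectories[["unbound"]], masses,
                                   groupA, groupB, contact,
                                   config$shellWidth)
    ceff$contactDistance <- contact
  }

  manifest <- list(
    package = as.character(utils::packageVersion("GrooveSim")),
    nResidues = length(config$sequence),
    variants = config$variants,
    temperature = sim@temperature, pH = sim@pH,
    ionicStrength = sim@ionicStrength,
    duration = sim@duration, equilibration = sim@equilibration,
    timestep = sim@timestep, saveInterval = sim@saveInterval,
    friction = sim@friction, replicas = sim@replicas,
    evDurationFactor = config$evDurationFactor,
    seedBase = config$seedBase,
    grooveInterior = grooveInterior(config$groove),
    grooveExterior = grooveExterior(config$groove),
    grooveThreshold = config$groove@threshold,
    shellWidth = config$shellWidth)

  bundle <- list(topologies = topologies, trajectories = trajectories,
                 occupancy = occupancy, rg = rg, excess = excess,
                 enrichment = enrichment, effectiveConcentration = ceff,
                 manifest = manifest)
  if (!is.null(config$outDir)) .writeStudyReports(bundle, config)
  bundle
}

.writeStudyReports <- function(bundle, config) {
  out <- config$outDir
  for (v in names(bundle$occupancy)) {
    utils::write.table(occupancyTable(bundle$occupancy[[v]]),
                       file.path(out, paste0("occupancy_", v, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (v in names(bundle$excess)) {
    utils::write.table(enrichmentTable(bundle$excess[[v]]),
                       file.path(out, paste0("excess_", v, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summaryJSON <- list(
    manifest = bundle$manifest,
    rg = lapply(bundle$rg, function(s) as.list(rgMean(s))),
    enrichment = bundle$enrichment,
    effectiveConcentration =
      if (is.null(bundle$effectiveConcentration)) NULL
      else bundle$effectiveConcentration[c("concentration", "sem",
                                           "fractionInShell",
                                           "contactDistance")])
  jsonlite::write_json(summaryJSON, file.path(out, "study_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Compare a simulated Rg ensemble with an experimental scattering profile
#'
#' Reports the simulated mean Rg with its replica SEM, the Guinier Rg of
#' the experimental profile with its fit error, and their difference and
#' ratio.  A Guinier failure (non-decaying profile) is propagated as a
#' flagged comparison rather than an error.
#'
#' @param rg an \code{\link{RgSummary}}.
#' @param profile a \code{\link{ScatteringProfile}}.
#' @param qRgMax Guinier window limit; default 1.3.
#' @return list with \code{simulatedRg}, \code{simulatedSEM},
#'   \code{guinierRg}, \code{guinierSE}, \code{difference} (simulated -
#'   experimental, Angstrom), \code{ratio}, \code{flagged} and
#'   \code{message}.
#' @export
compareToExperiment <- function(rg, profile, qRgMax = 1.3) {
  stopifnot(is(rg, "RgSummary"), is(profile, "ScatteringProfile"))
  sim <- rgMean(rg)
  fit <- tryCatch(guinierFit(profile, qRgMax = qRgMax),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(simulatedRg = sim[["mean"]], simulatedSEM = sim[["sem"]],
                guinierRg = NA_real_, guinierSE = NA_real_,
                difference = NA_real_, ratio = NA_real_, flagged = TRUE,
                message = conditionMessage(fit)))
  }
  list(simulatedRg = sim[["mean"]], simulatedSEM = sim[["sem"]],
       guinierRg = fit$rg, guinierSE = fit$rgSE,
       difference = sim[["mean"]] - fit$rg,
       ratio = sim[["mean"]] / fit$rg, flagged = FALSE, message = "ok")
}
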