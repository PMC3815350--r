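## Canonical simulation experiments: bivalent-domain formation (localized /
## delocalized seeds), decay under crosstalk demethylation, nucleation-site
## localization, and the cell-cycle-length sweep.  These double as the
## package's fixture generators: every initial lattice is built
## programmatically.

#' Build an initial lattice
#'
#' \describe{
#'   \item{localized}{\code{n0} consecutive bivalent (AR) nucleosomes
#'     centered on the lattice (left-biased for even remainders: the block
#'     starts at \code{floor((N - n0) / 2) + 1}), all other sites UU.}
#'   \item{delocalized}{\code{n0} AR nucleosomes at equally spaced sites
#'     spanning the whole lattice: site 1 plus \code{round(k N / (n0 - 1))}
#'     for \code{k = 1 .. n0 - 1}.  For \code{N = 80, n0 = 5} this places
#'     seeds at sites 1, 20, 40, 60, 80.}
#'   \item{all_AR / all_UU}{every site AR / UU.}
#'   \item{custom}{states given explicitly via \code{states}.}
#' }
#'
#' @param kind one of \code{"localized"}, \code{"delocalized"},
#'   \code{"all_AR"}, \code{"all_UU"}, \code{"custom"}.
#' @param N lattice size.
#' @param n0 number of initially bivalent nucleosomes (ignored for
#'   \code{all_*} and \code{custom}).
#' @param states state labels or codes for \code{kind = "custom"}.
#' @return A \linkS4class{Lattice}.
#' @export
#' @examples
#' which(decodeStates(buildInitialCondition("delocalized", 80, 5)@states) == "AR")
#' # 1 20 40 60 80
#' which(decodeStates(buildInitialCondition("localized", 80, 5)@states) == "AR")
#' # 38:42
buildInitialCondition <- function(kind = c("localized", "delocalized",
                                           "all_AR", "all_UU", "custom"),
                                  N, n0 = 5L, states = NULL) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  if (kind == "custom") {
    if (is.null(states)) stop("kind 'custom' requires 'states'")
    lat <- lattice(states)
    if (nSites(lat) != N) stop("custom states must have length N")
    return(lat)
  }
  s <- rep(.STATE_UU, N)
  if (kind == "all_AR") return(lattice(rep(.STATE_AR, N)))
  if (kind == "all_UU") return(lattice(s))
  n0 <- as.integer(n0)
  if (n0 < 1L || n0 > N) stop("n0 must be in 1..N (n0=", n0, ", N=", N, ")")
  if (kind == "localized") {
    off <- (N - n0) %/% 2L
    s[(off + 1L):(off + n0)] <- .STATE_AR
  } else {                               # delocalized
    sites <- if (n0 == 1L) round((N + 1) / 2)
             else c(1L, as.integer(round(seq_len(n0 - 1L) * N / (n0 - 1L))))
    sites <- pmin(pmax(sites, 1L), N)
    if (anyDuplicated(sites))
      stop("cannot place ", n0, " distinct equally spaced seeds on ", N,
           " sites")
    s[sites] <- .STATE_AR
  }
  lattice(s)
}

#' Seed sites of an initial condition
#'
#' @param lat a \linkS4class{Lattice}.
#' @return Integer indices of sites initially in the AR state.
#' @export
seedSites <- function(lat) which(lat@states == .STATE_AR)

#' Construct a ScenarioConfig
#'
#' Builds one of the canonical experiments with its documented defaults.
#' Ensemble sizes default to the full published sizes (2000 runs for the
#' formation and nucleation scenarios, 1000 for decay); tests and routine
#' use pass smaller \code{nRuns}.
#'
#' \describe{
#'   \item{formation_localized / formation_delocalized}{5 AR seeds on an
#'     80-site lattice, spreading \code{kMeA = 0.046} (A rates twice R
#'     rates), turnover \code{(0.003, 0.0015)}, crosstalk demethylation and
#'     nucleation off, 10 cycles of 360 steps.}
#'   \item{decay}{all-AR initial lattice; crosstalk demethylation on
#'     (\code{kDmA = 0.016} by default, \code{kDmR = kDmA / 2}); other rates
#'     as in formation.}
#'   \item{nucleation}{5 central AR seeds; elevated spontaneous placement
#'     (\code{nucleationMagnitude}, default 0.01/step for the active mark
#'     and half for the repressive) at \code{nucleationSites} (default the
#'     central site), zero elsewhere; mild crosstalk demethylation
#'     (\code{kDmA = 0.008}); 5 cycles (plotted at step 1800).}
#'   \item{cellcycle_sweep}{all-AR initial lattice with formation rates; the
#'     sweep axis is the cell-cycle length in hours (default 6 to 24 h).}
#'   \item{custom}{caller supplies everything.}
#' }
#'
#' @param name scenario name.
#' @param N lattice size (default 80).
#' @param n0 initial AR count (default 5).
#' @param nRuns ensemble size (scenario-specific default).
#' @param nCycles number of cell cycles (scenario-specific default).
#' @param params a \linkS4class{RateParams}; scenario-specific default.
#' @param sweep list with \code{axis} and \code{values}; scenario-specific
#'   default (empty for non-sweep scenarios).  Supported axes: \code{"n0"},
#'   \code{"kDmA"}, \code{"kExMinusA"}, \code{"cycleHours"},
#'   \code{"nucleationMagnitude"}; the paired repressive-mark rate keeps the
#'   2:1 active:repressive ratio.
#' @param seed base seed (default 1).
#' @param nucleationSites,nucleationMagnitude nucleation-scenario knobs.
#' @param initialKind override the scenario's initial-condition kind.
#' @param initialStates state labels/codes for \code{initialKind="custom"}.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
#' @examples
#' scenarioConfig("formation_localized", nRuns = 200)
scenarioConfig <- function(name = c("formation_localized",
                                    "formation_delocalized", "decay",
                                    "nucleation", "cellcycle_sweep",
                                    "custom"),
                           N = 80L, n0 = 5L, nRuns = NULL, nCycles = NULL,
                           params = NULL, sweep = NULL, seed = 1L,
                           nucleationSites = NULL,
                           nucleationMagnitude = 0.01,
                           initialKind = NULL, initialStates = NULL) {
  name <- match.arg(name)
  N <- as.integer(N)
  defKind <- switch(name,
    formation_localized = "localized",
    formation_delocalized = "delocalized",
    decay = "all_AR",
    nucleation = "localized",
    cellcycle_sweep = "all_AR",
    custom = "custom")
  if (is.null(initialKind)) initialKind <- defKind
  if (is.null(nCycles))
    nCycles <- switch(name, nucleation = 5L, 10L)
  if (is.null(nRuns))
    nRuns <- switch(name, decay = 1000L, 2000L)
  if (is.null(params)) {
    params <- switch(name,
      decay = rateParams(kDmA = 0.016),
      nucleation = {
        if (is.null(nucleationSites))
          nucleationSites <- as.integer(round((N + 1) / 2))
        kpA <- rep(0, N); kpA[nucleationSites] <- nucleationMagnitude
        kpR <- rep(0, N); kpR[nucleationSites] <- nucleationMagnitude / 2
        rateParams(kDmA = 0.008, kExPlusA = kpA, kExPlusR = kpR)
      },
      rateParams())
  }
  if (is.null(sweep))
    sweep <- switch(name,
      cellcycle_sweep = list(axis = "cycleHours",
                             values = c(6, 9, 12, 15, 18, 21, 24)),
      list())
  new("ScenarioConfig", name = name, N = N, n0 = as.integer(n0),
      initialKind = initialKind,
      initialStates = if (is.null(initialStates)) integer(0)
                      else lattice(initialStates)@states,
      nRuns = as.integer(nRuns), nCycles = as.integer(nCycles),
      params = params, sweep = sweep, seed = as.integer(seed))
}

# initial lattice of a scenario configuration
.initialLattice <- function(config) {
  if (config@initialKind == "custom")
    buildInitialCondition("custom", config@N, states = config@initialStates)
  else
    buildInitialCondition(config@initialKind, config@N, config@n0)
}

# apply one sweep value, returning list(initial, params); repressive-mark
# partners keep the 2:1 A:R ratio
.applySweepValue <- function(config, axis, value) {
  p <- config@params
  initial <- NULL
  switch(axis,
    n0 = {
      initial <- buildInitialCondition(config@initialKind, config@N,
                                       as.integer(value))
    },
    kDmA = {
      p@kDmA <- value; p@kDmR <- value / 2
    },
    kExMinusA = {
      p@kExMinusA <- value; p@kExMinusR <- value / 2
    },
    cycleHours = {
      p@stepsPerCycle <- as.integer(round(value * 60 / p@dtMinutes))
    },
    nucleationMagnitude = {
      sites <- which(.expandSiteRate(p@kExPlusA, config@N, "kExPlusA") > 0)
      kpA <- rep(0, config@N); kpA[sites] <- value
      kpR <- rep(0, config@N); kpR[sites] <- value / 2
      p@kExPlusA <- kpA; p@kExPlusR <- kpR
    },
    stop("unknown sweep axis '", axis, "'"))
  validObject(p)
  if (is.null(initial)) initial <- .initialLattice(config)
  list(initial = initial, params = p)
}

#' Run an ensemble of independent simulations
#'
#' Runs \code{nRuns} trajectories from the same initial lattice with
#' deterministic per-run seeds (\code{\link{runSeeds}}), accumulating the
#' ensemble occupancy incrementally so that memory stays bounded.
#'
#' @param initial a \linkS4class{Lattice}.
#' @param params a \linkS4class{RateParams}.
#' @param nCycles cycles per run.
#' @param nRuns ensemble size.
#' @param baseSeed base seed.
#' @param replication apply replication dilution (default TRUE).
#' @param engine simulation engine, \code{"cpp"} or \code{"R"}.
#' @param keepTrajectories number of leading runs to retain as full
#'   \linkS4class{Trajectory} objects (default 0).
#' @return A list with \code{occupancy} (an
#'   \linkS4class{EnsembleOccupancy}), \code{finalStates} (integer
#'   \code{nRuns x N} matrix of final lattices), \code{hasStateFraction}
#'   (4 x (nSteps + 1) matrix: fraction of runs containing at least one site
#'   in each state, by time), \code{trajectories} (list, possibly empty) and
#'   \code{seeds}.
#' @export
runEnsemble <- function(initial, params, nCycles, nRuns, baseSeed = 1L,
                        replication = TRUE, engine = c("cpp", "R"),
                        keepTrajectories = 0L) {
  stopifnot(is(initial, "Lattice"), is(params, "RateParams"), nRuns >= 1L)
  engine <- match.arg(engine)
  N <- nSites(initial)
  nTot <- as.integer(nCycles) * params@stepsPerCycle
  nT <- nTot + 1L
  counts <- numeric(4L * N * nT)
  hasState <- matrix(0, nrow = 4L, ncol = nT)
  finalStates <- matrix(0L, nrow = nRuns, ncol = N)
  seeds <- runSeeds(baseSeed, nRuns)
  kept <- vector("list", min(keepTrajectories, nRuns))
  timeIdx <- rep(seq_len(nT), N)              # row (time) index of vec(M)
  siteIdx <- rep(seq_len(N), each = nT)
  base <- 4L * ((siteIdx - 1L) + N * (timeIdx - 1L))
  for (k in seq_len(nRuns)) {
    tr <- runSimulation(initial, params, nCycles, seed = seeds[k],
                        replication = replication, engine = engine)
    M <- tr@states
    counts <- counts + tabulate(as.vector(M) + base, nbins = 4L * N * nT)
    for (s in 1:4)
      hasState[s, ] <- hasState[s, ] + (rowSums(M == s) > 0L)
    finalStates[k, ] <- M[nT, ]
    if (k <= length(kept)) kept[[k]] <- tr
  }
  occ <- array(counts / nRuns, dim = c(4L, N, nT),
               dimnames = list(state = stateLabels(), NULL, NULL))
  repl <- if (replication)
    seq.int(params@stepsPerCycle, nTot, by = params@stepsPerCycle)
  else integer(0)
  list(occupancy = new("EnsembleOccupancy", occupancy = occ,
                       nRuns = as.integer(nRuns),
                       replicationTimes = as.integer(repl)),
       finalStates = finalStates,
       hasStateFraction = hasState / nRuns,
       trajectories = kept, seeds = seeds)
}

#' Run a scenario
#'
#' Executes the configured experiment.  For plain scenarios this is a single
#' ensemble; for sweep scenarios one ensemble per sweep value, with the same
#' per-run seeds reused across sweep points (paired seeds) so that
#' comparisons along the axis are not confounded by sampling noise.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param engine simulation engine.
#' @param keepTrajectories trajectories to retain per ensemble.
#' @return A list with \code{config}, \code{summary} (a data.frame with one
#'   row per ensemble: sweep value, mean final AR fraction over runs and
#'   lattice, its standard error over runs, and the fraction of runs with at
#'   least one final AR nucleosome) and \code{results} (one
#'   \code{\link{runEnsemble}} result per row).
#' @export
#' @examples
#' \donttest{
#' cfg <- scenarioConfig("formation_localized", nRuns = 20, nCycles = 2)
#' res <- runScenario(cfg)
#' res$summary
#' }
runScenario <- function(config, engine = c("cpp", "R"),
                        keepTrajectories = 0L) {
  stopifnot(is(config, "ScenarioConfig"))
  engine <- match.arg(engine)
  if (length(config@sweep)) {
    axis <- config@sweep$axis
    values <- config@sweep$values
  } else {
    axis <- NA_character_
    values <- NA_real_
  }
  results <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    if (is.na(axis)) {
      initial <- .initialLattice(config)
      params <- config@params
    } else {
      sw <- .applySweepValue(config, axis, values[i])
      initial <- sw$initial
      params <- sw$params
    }
    res <- runEnsemble(initial, params, config@nCycles, config@nRuns,
                       baseSeed = config@seed, engine = engine,
                       keepTrajectories = keepTrajectories)
    perRunAR <- rowMeans(res$finalStates == .STATE_AR)
    rows[[i]] <- data.frame(
      axis = axis, value = values[i],
      finalARFraction = mean(perRunAR),
      finalARSE = stats::sd(perRunAR) / sqrt(length(perRunAR)),
      fracRunsWithAR = mean(rowSums(res$finalStates == .STATE_AR) > 0L),
      stringsAsFactors = FALSE)
    results[[i]] <- res
  }
  list(config = config, summary = do.call(rbind, rows), results = results)
}
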