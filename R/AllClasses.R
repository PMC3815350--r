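#' @import methods
#' @importFrom stats runif lm coef setNames
#' @importFrom utils write.table packageVersion modifyList
NULL

#' Ordered state alphabet of the reduced four-state model
#'
#' The reduced model allows four nucleosome states: \code{AU} (one H3 carries
#' an active mark), \code{UR} (one H3 carries a repressive mark), \code{AR}
#' (bivalent: one H3 active, the other repressive) and \code{UU} (fully
#' unmodified).  The order returned here is the canonical sampling order used
#' by the inverse-CDF draw in the simulation engine and by all occupancy
#' arrays; it must not be changed without invalidating stored seeds.
#'
#' @return Character vector \code{c("AU", "UR", "AR", "UU")}.
#' @export
#' @examples
#' stateLabels()
stateLabels <- function() c("AU", "UR", "AR", "UU")

# integer codes used throughout: AU=1, UR=2, AR=3, UU=4
.STATE_AU <- 1L
.STATE_UR <- 2L
.STATE_AR <- 3L
.STATE_UU <- 4L

#' Encode state labels as integer codes
#'
#' @param labels character vector of labels among \code{stateLabels()}.
#' @return integer vector (AU=1, UR=2, AR=3, UU=4).
#' @export
encodeStates <- function(labels) {
  codes <- match(labels, stateLabels())
  if (anyNA(codes))
    stop("unknown state label(s): ",
         paste(unique(labels[is.na(codes)]), collapse = ", "))
  codes
}

#' Decode integer state codes to labels
#'
#' @param codes integer vector with values in 1..4.
#' @return character vector of state labels.
#' @export
decodeStates <- function(codes) {
  if (any(codes < 1L | codes > 4L))
    stop("state codes must be in 1..4")
  stateLabels()[codes]
}

#' RateParams: transition coefficients of the reduced model
#'
#' Container for all per-step transition coefficients of the four-state
#' nucleosome model.  Recruitment channels scale with the local mark density
#' within a window of \code{2r + 1} sites; exchange channels are
#' neighbour-independent.  All coefficients are dimensionless per-step
#' probability factors in \eqn{[0, 1]}.
#'
#' @slot kMeA,kMeR recruitment-addition (methylation spreading) coefficients
#'   for the active / repressive mark.
#' @slot kDmA,kDmR recruitment-removal (crosstalk demethylation) coefficients;
#'   removal of a mark is recruited by the \emph{opposite} mark density.
#' @slot kExPlusA,kExPlusR exchange-addition (nucleation) probabilities,
#'   either a scalar applied to every site or a per-site vector.
#' @slot kExMinusA,kExMinusR exchange-removal (histone turnover)
#'   probabilities.
#' @slot r integer recruitment half-range; the window spans \code{2r + 1}
#'   nucleosomes.
#' @slot dtMinutes real minutes per time step (default 2).
#' @slot stepsPerCycle integer steps between replication events (default 360,
#'   a 12-hour cycle at 2 minutes per step).
#' @slot multiplicityUU multiplicity factor applied to additions out of UU,
#'   where either of the two unmodified histones can receive the first mark
#'   (default 2; set to 1 for sensitivity checks).
#' @slot exchangeMultiplicity logical; whether the UU multiplicity factor also
#'   applies to the exchange-addition (nucleation) channel (default TRUE).
#' @slot includeSelf logical; whether the recruitment window includes the
#'   focal site itself (default TRUE).
#' @export
setClass("RateParams", representation(
  kMeA = "numeric", kMeR = "numeric",
  kDmA = "numeric", kDmR = "numeric",
  kExPlusA = "numeric", kExPlusR = "numeric",
  kExMinusA = "numeric", kExMinusR = "numeric",
  r = "integer", dtMinutes = "numeric", stepsPerCycle = "integer",
  multiplicityUU = "numeric", exchangeMultiplicity = "logical",
  includeSelf = "logical"))

setValidity("RateParams", function(object) {
  msgs <- character()
  sc <- c(kMeA = object@kMeA, kMeR = object@kMeR,
          kDmA = object@kDmA, kDmR = object@kDmR,
          kExMinusA = object@kExMinusA, kExMinusR = object@kExMinusR)
  if (any(lengths(list(object@kMeA, object@kMeR, object@kDmA, object@kDmR,
                       object@kExMinusA, object@kExMinusR)) != 1L))
    msgs <- c(msgs, "recruitment and turnover coefficients must be scalars")
  allco <- c(sc, object@kExPlusA, object@kExPlusR)
  if (anyNA(allco) || any(allco < 0) || any(allco > 1))
    msgs <- c(msgs, "all rate coefficients must lie in [0, 1]")
  if (length(object@r) != 1L || is.na(object@r) || object@r < 0L)
    msgs <- c(msgs, "r must be a single nonnegative integer")
  if (length(object@stepsPerCycle) != 1L || object@stepsPerCycle < 1L)
    msgs <- c(msgs, "stepsPerCycle must be >= 1")
  if (!object@multiplicityUU %in% c(1, 2))
    msgs <- c(msgs, "multiplicityUU must be 1 or 2")
  if (object@dtMinutes <= 0)
    msgs <- c(msgs, "dtMinutes must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RateParams object
#'
#' Defaults follow the formation parameter set: active-mark rates are twice
#' the repressive-mark rates (active-mark kinetics are faster), spreading
#' coefficient \code{kMeA = 0.046}, turnover \code{(0.003, 0.0015)},
#' crosstalk demethylation and nucleation switched off, recruitment
#' half-range \code{r = 2} and a 12-hour cell cycle of 360 two-minute steps.
#'
#' @param kMeA,kMeR recruitment-addition coefficients (defaults 0.046 and
#'   \code{kMeA / 2}).
#' @param kDmA,kDmR recruitment-removal coefficients (defaults 0 and
#'   \code{kDmA / 2}).
#' @param kExPlusA,kExPlusR nucleation probabilities, scalar or per-site
#'   (defaults 0).
#' @param kExMinusA,kExMinusR turnover probabilities (defaults 0.003 and
#'   \code{kExMinusA / 2}).
#' @param r recruitment half-range in nucleosomes (default 2).
#' @param dtMinutes minutes per step (default 2).
#' @param stepsPerCycle steps per cell cycle (default 360).
#' @param multiplicityUU multiplicity factor for additions out of UU
#'   (default 2).
#' @param exchangeMultiplicity apply the multiplicity factor to nucleation
#'   out of UU as well (default TRUE).
#' @param includeSelf include the focal site in the recruitment window
#'   (default TRUE).
#' @return A \linkS4class{RateParams} object.
#' @export
#' @examples
#' rateParams()                      # formation defaults
#' rateParams(kDmA = 0.016)          # decay-like: crosstalk demethylation on
rateParams <- function(kMeA = 0.046, kMeR = kMeA / 2,
                       kDmA = 0, kDmR = kDmA / 2,
                       kExPlusA = 0, kExPlusR = kExPlusA / 2,
                       kExMinusA = 0.003, kExMinusR = kExMinusA / 2,
                       r = 2L, dtMinutes = 2, stepsPerCycle = 360L,
                       multiplicityUU = 2, exchangeMultiplicity = TRUE,
                       includeSelf = TRUE) {
  new("RateParams",
      kMeA = as.numeric(kMeA), kMeR = as.numeric(kMeR),
      kDmA = as.numeric(kDmA), kDmR = as.numeric(kDmR),
      kExPlusA = as.numeric(kExPlusA), kExPlusR = as.numeric(kExPlusR),
      kExMinusA = as.numeric(kExMinusA), kExMinusR = as.numeric(kExMinusR),
      r = as.integer(r), dtMinutes = as.numeric(dtMinutes),
      stepsPerCycle = as.integer(stepsPerCycle),
      multiplicityUU = as.numeric(multiplicityUU),
      exchangeMultiplicity = isTRUE(exchangeMultiplicity),
      includeSelf = isTRUE(includeSelf))
}

#' Lattice: a vector of nucleosome states
#'
#' An ordered 1-based vector of nucleosome states in the reduced four-state
#' model, stored as integer codes in the canonical order
#' \code{stateLabels()}.
#'
#' @slot states integer vector of state codes (AU=1, UR=2, AR=3, UU=4).
#' @export
setClass("Lattice", representation(states = "integer"))

setValidity("Lattice", function(object) {
  s <- object@states
  if (length(s) < 1L) return("lattice must have at least one site")
  if (anyNA(s) || any(s < 1L | s > 4L))
    return("lattice states must be integer codes in 1..4")
  TRUE
})

#' Construct a Lattice
#'
#' @param states character vector of labels among \code{stateLabels()}, or
#'   integer codes in 1..4.
#' @return A \linkS4class{Lattice}.
#' @export
#' @examples
#' lattice(c("UU", "AR", "UU"))
lattice <- function(states) {
  if (is.character(states)) states <- encodeStates(states)
  new("Lattice", states = as.integer(states))
}

#' Trajectory: a single run of the lattice simulation
#'
#' Rows index time (\code{0..nSteps}); columns index sites \code{1..N}.
#' At replication times the stored lattice is the post-replication one.
#'
#' @slot states integer matrix, \code{(nSteps + 1) x N}.
#' @slot replicationTimes integer step indices at which replication occurred.
#' @slot seed integer seed the run was generated from (NA for constructed
#'   trajectories).
#' @export
setClass("Trajectory", representation(
  states = "matrix", replicationTimes = "integer", seed = "integer"))

setValidity("Trajectory", function(object) {
  s <- object@states
  if (!is.numeric(s) || anyNA(s) || any(s < 1L | s > 4L))
    return("trajectory states must be integer codes in 1..4")
  if (nrow(s) < 1L || ncol(s) < 1L)
    return("trajectory must contain at least one snapshot of one site")
  if (any(object@replicationTimes < 1L | object@replicationTimes > nrow(s) - 1L))
    return("replication times must be step indices within the trajectory")
  TRUE
})

#' @describeIn Trajectory-class number of sites
#' @param object,x a Trajectory
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname Trajectory-class
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

setMethod("nSites", "Lattice", function(x) length(x@states))
setMethod("nSites", "Trajectory", function(x) ncol(x@states))
setMethod("nSteps", "Trajectory", function(x) nrow(x@states) - 1L)

#' Lattice snapshot at a given time step
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param t time step in \code{0..nSteps(traj)}.
#' @return A \linkS4class{Lattice}.
#' @export
latticeAt <- function(traj, t) {
  stopifnot(is(traj, "Trajectory"))
  if (t < 0L || t > nSteps(traj)) stop("t out of range 0..", nSteps(traj))
  lattice(traj@states[t + 1L, ])
}

#' @rdname Trajectory-class
#' @export
replicationTimes <- function(x) x@replicationTimes

#' EnsembleOccupancy: per-(state, site, time) run fractions
#'
#' The occupancy ("level") of a state at a site and time is the fraction of
#' ensemble runs whose nucleosome at that site is in that state.  Stored as a
#' 3D array \code{[state, site, time]} with states in canonical order and the
#' third dimension indexing times \code{0..nSteps}.
#'
#' @slot occupancy numeric array \code{4 x N x (nSteps + 1)}.
#' @slot nRuns number of runs averaged.
#' @slot replicationTimes integer replication step indices shared by the runs.
#' @export
setClass("EnsembleOccupancy", representation(
  occupancy = "array", nRuns = "integer", replicationTimes = "integer"))

setValidity("EnsembleOccupancy", function(object) {
  occ <- object@occupancy
  if (length(dim(occ)) != 3L || dim(occ)[1] != 4L)
    return("occupancy must be a 4 x N x T array")
  if (anyNA(occ) || any(occ < -1e-12) || any(occ > 1 + 1e-12))
    return("occupancies must lie in [0, 1]")
  tot <- apply(occ, c(2, 3), sum)
  if (any(abs(tot - 1) > 1e-9))
    return("occupancies must sum to 1 over states at every (site, time)")
  TRUE
})

setMethod("nSites", "EnsembleOccupancy", function(x) dim(x@occupancy)[2])
setMethod("nSteps", "EnsembleOccupancy", function(x) dim(x@occupancy)[3] - 1L)

#' Occupancy matrix of one state
#'
#' @param occ an \linkS4class{EnsembleOccupancy}.
#' @param state a state label among \code{stateLabels()}.
#' @return numeric matrix, sites x times (columns = \code{0..nSteps}).
#' @export
stateOccupancy <- function(occ, state) {
  stopifnot(is(occ, "EnsembleOccupancy"))
  m <- occ@occupancy[encodeStates(state), , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = nSites(occ))
  dimnames(m) <- list(site = NULL, time = NULL)
  m
}

#' @rdname EnsembleOccupancy-class
#' @param x an EnsembleOccupancy
#' @export
nRuns <- function(x) x@nRuns

#' ChainDistribution: exact distribution over lattice configurations
#'
#' Probability vector over all \code{4^N} lattice configurations of a small
#' lattice.  Configuration index 1 corresponds to all sites in state AU;
#' site 1 is the least-significant base-4 digit (see
#' \code{\link{configurationIndex}}).
#'
#' @slot probs numeric vector of length \code{4^N}, summing to 1.
#' @slot N lattice size.
#' @slot time step index the distribution refers to.
#' @export
setClass("ChainDistribution", representation(
  probs = "numeric", N = "integer", time = "integer"))

setValidity("ChainDistribution", function(object) {
  p <- object@probs
  if (length(p) != 4L^object@N)
    return("probs must have length 4^N")
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9)
    return("probs must be nonnegative and sum to 1")
  TRUE
})

#' FrontTrack: domain edges through time
#'
#' Left/right outermost sites of the connected above-threshold occupancy
#' block containing the seeded region, for each recorded time, plus the
#' fitted expansion speed of the domain width in nucleosomes per cell cycle.
#'
#' @slot leftEdge,rightEdge numeric vectors (NA where no site reaches the
#'   threshold).
#' @slot speed fitted least-squares growth rate of the domain width,
#'   nucleosomes per cell cycle.
#' @slot threshold occupancy threshold defining the domain.
#' @slot stepsPerCycle steps per cell cycle used for the speed conversion.
#' @export
setClass("FrontTrack", representation(
  leftEdge = "numeric", rightEdge = "numeric", speed = "numeric",
  threshold = "numeric", stepsPerCycle = "integer"))

setValidity("FrontTrack", function(object) {
  if (length(object@leftEdge) != length(object@rightEdge))
    return("leftEdge and rightEdge must have equal length")
  ok <- !is.na(object@leftEdge) & !is.na(object@rightEdge)
  if (any(object@rightEdge[ok] < object@leftEdge[ok]))
    return("rightEdge must be >= leftEdge wherever defined")
  TRUE
})

#' ScenarioConfig: a named simulation experiment
#'
#' Bundles the lattice size, initial condition, ensemble size, run length,
#' rate parameters and (for sweeps) the swept axis of one of the canonical
#' scenarios: localized/delocalized domain formation, decay under crosstalk
#' demethylation, nucleation-site localization, and the cell-cycle-length
#' sweep.
#'
#' @slot name scenario name.
#' @slot N lattice size.
#' @slot n0 number of initially bivalent (AR) nucleosomes.
#' @slot initialKind one of "localized", "delocalized", "all_AR", "all_UU",
#'   "custom".
#' @slot initialStates integer codes used when \code{initialKind == "custom"}.
#' @slot nRuns ensemble size.
#' @slot nCycles number of cell cycles simulated.
#' @slot params a \linkS4class{RateParams}.
#' @slot sweep named list with elements \code{axis} (character) and
#'   \code{values} (numeric vector); empty list for non-sweep scenarios.
#' @slot seed base seed.
#' @export
setClass("ScenarioConfig", representation(
  name = "character", N = "integer", n0 = "integer",
  initialKind = "character", initialStates = "integer",
  nRuns = "integer", nCycles = "integer",
  params = "RateParams", sweep = "list", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msgs <- character()
  if (object@n0 > object@N)
    msgs <- c(msgs, "n0 must not exceed N")
  if (object@nRuns < 1L || object@nCycles < 1L)
    msgs <- c(msgs, "nRuns and nCycles must be >= 1")
  if (length(object@sweep) &&
      (!all(c("axis", "values") %in% names(object@sweep)) ||
       !length(object@sweep$values)))
    msgs <- c(msgs, "sweep must contain a nonempty 'values' vector and an 'axis'")
  if (length(msgs)) msgs else TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "RateParams", function(object) {
  cat("RateParams (reduced 4-state model)\n")
  cat(sprintf("  recruitment add    kMeA=%.4g kMeR=%.4g\n",
              object@kMeA, object@kMeR))
  cat(sprintf("  recruitment remove kDmA=%.4g kDmR=%.4g\n",
              object@kDmA, object@kDmR))
  fmt <- function(v) if (length(v) == 1L) sprintf("%.4g", v)
    else sprintf("per-site [%.4g..%.4g]", min(v), max(v))
  cat(sprintf("  exchange add       kExPlusA=%s kExPlusR=%s\n",
              fmt(object@kExPlusA), fmt(object@kExPlusR)))
  cat(sprintf("  exchange remove    kExMinusA=%.4g kExMinusR=%.4g\n",
              object@kExMinusA, object@kExMinusR))
  cat(sprintf("  window r=%d (span %d), dt=%g min, %d steps/cycle\n",
              object@r, 2L * object@r + 1L, object@dtMinutes,
              object@stepsPerCycle))
})

setMethod("show", "Lattice", function(object) {
  n <- nSites(object)
  cat(sprintf("Lattice of %d nucleosomes\n", n))
  lab <- decodeStates(object@states)
  if (n <= 40L) cat(" ", paste(lab, collapse = " "), "\n")
  else cat(" ", paste(lab[1:20], collapse = " "), "...\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d sites, %d steps (+ t=0), %d replications\n",
              nSites(object), nSteps(object),
              length(object@replicationTimes)))
})

setMethod("show", "EnsembleOccupancy", function(object) {
  cat(sprintf("EnsembleOccupancy: %d sites, %d steps, averaged over %d runs\n",
              nSites(object), nSteps(object), object@nRuns))
})

setMethod("show", "ChainDistribution", function(object) {
  cat(sprintf("ChainDistribution: N=%d (%d configurations), time=%d\n",
              object@N, length(object@probs), object@time))
})

setMethod("show", "FrontTrack", function(object) {
  cat(sprintf(
    "FrontTrack: %d time points, threshold %.2f, speed %.2f nucleosomes/cycle\n",
    length(object@leftEdge), object@threshold, object@speed))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig '%s': N=%d, n0=%d, %d runs x %d cycles, seed %d\n",
              object@name, object@N, object@n0, object@nRuns,
              object@nCycles, object@seed))
  if (length(object@sweep))
    cat(sprintf("  sweep over %s: %s\n", object@sweep$axis,
                paste(signif(object@sweep$values, 4), collapse = ", ")))
})
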