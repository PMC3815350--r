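## Ensemble statistics and derived observables: occupancy levels, front
## tracking and expansion speed, merge and equilibration times, persistence
## of the bivalent state across runs, and domain profile geometry.

#' Ensemble occupancy from stored trajectories
#'
#' Per-(state, site, time) fraction of runs in each state.  Equivalent to
#' the incremental accumulation performed by \code{\link{runEnsemble}}.
#'
#' @param runs nonempty list of \linkS4class{Trajectory} objects with equal
#'   dimensions.
#' @return An \linkS4class{EnsembleOccupancy}.
#' @export
ensembleOccupancy <- function(runs) {
  if (!length(runs)) stop("empty run list")
  if (!all(vapply(runs, is, logical(1), "Trajectory")))
    stop("runs must be Trajectory objects")
  dims <- vapply(runs, function(r) dim(r@states), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must have the same number of sites and steps")
  nT <- dims[1, 1]; N <- dims[2, 1]
  counts <- numeric(4L * N * nT)
  timeIdx <- rep(seq_len(nT), N)
  siteIdx <- rep(seq_len(N), each = nT)
  base <- 4L * ((siteIdx - 1L) + N * (timeIdx - 1L))
  for (r in runs)
    counts <- counts + tabulate(as.vector(r@states) + base,
                                nbins = 4L * N * nT)
  occ <- array(counts / length(runs), dim = c(4L, N, nT),
               dimnames = list(state = stateLabels(), NULL, NULL))
  new("EnsembleOccupancy", occupancy = occ, nRuns = length(runs),
      replicationTimes = runs[[1]]@replicationTimes)
}

# connected above-threshold block containing `site`; c(left, right) or NULL
.blockAround <- function(above, site) {
  if (!above[site]) return(NULL)
  l <- site
  while (l > 1L && above[l - 1L]) l <- l - 1L
  r <- site
  while (r < length(above) && above[r + 1L]) r <- r + 1L
  c(l, r)
}

#' Track domain fronts through time
#'
#' For each time, finds the left and right outermost sites of the connected
#' block of sites whose occupancy of \code{state} is at least
#' \code{threshold} and which contains the seed site; times where the seed
#' site itself falls below the threshold (e.g. immediately after a
#' replication dip) yield \code{NA} edges.  The expansion speed is the
#' least-squares growth rate of the occupied domain width
#' (\code{right - left + 1}) over the fitted time range, converted to
#' nucleosomes per cell cycle.
#'
#' @param occ an \linkS4class{EnsembleOccupancy}.
#' @param state state label tracked (default \code{"AR"}).
#' @param threshold occupancy threshold in (0, 1) defining the domain
#'   (default 0.5, the midpoint of the color transition in ensemble
#'   space-time plots).
#' @param seedSite site whose block is tracked; default the lattice center.
#' @param fitSteps integer time steps (0-based) used for the speed fit;
#'   default all steps with defined edges.
#' @param stepsPerCycle steps per cell cycle for the speed conversion;
#'   default inferred from the occupancy's replication times.
#' @return A \linkS4class{FrontTrack}; if no time ever reaches the
#'   threshold, all edges are \code{NA} and the speed is \code{NA} (flagged,
#'   not an error).
#' @export
frontTrack <- function(occ, state = "AR", threshold = 0.5, seedSite = NULL,
                       fitSteps = NULL, stepsPerCycle = NULL) {
  stopifnot(is(occ, "EnsembleOccupancy"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  N <- nSites(occ)
  if (is.null(seedSite)) seedSite <- as.integer(round((N + 1) / 2))
  if (is.null(stepsPerCycle)) {
    if (!length(occ@replicationTimes))
      stop("stepsPerCycle must be given when the ensemble has no ",
           "replication events")
    stepsPerCycle <- occ@replicationTimes[1]
  }
  m <- stateOccupancy(occ, state)       # sites x times
  nT <- ncol(m)
  left <- right <- rep(NA_real_, nT)
  for (t in seq_len(nT)) {
    blk <- .blockAround(m[, t] >= threshold, seedSite)
    if (!is.null(blk)) { left[t] <- blk[1]; right[t] <- blk[2] }
  }
  times <- seq_len(nT) - 1L
  if (is.null(fitSteps)) fitSteps <- times
  sel <- times %in% fitSteps & !is.na(left)
  speed <- NA_real_
  if (sum(sel) >= 2L && length(unique(times[sel])) >= 2L) {
    width <- right[sel] - left[sel] + 1
    fit <- lm(width ~ t, data = data.frame(width = width, t = times[sel]))
    speed <- unname(coef(fit)[2]) * stepsPerCycle
  }
  new("FrontTrack", leftEdge = left, rightEdge = right, speed = speed,
      threshold = threshold, stepsPerCycle = as.integer(stepsPerCycle))
}

#' Time at which fronts from multiple seeds merge
#'
#' The fronts are considered merged at the first time at which every site
#' between the outermost seeds carries a mark with ensemble probability at
#' least \code{threshold}; "carries a mark" means the site is not in the UU
#' state (occupancy of AU, UR and AR combined), so the merged region is a
#' single connected above-threshold block spanning all seeds.
#'
#' @param occ an \linkS4class{EnsembleOccupancy}.
#' @param seeds integer vector of at least two seed sites.
#' @param threshold occupancy threshold (default 0.5).
#' @return The 0-based merge step, or \code{NA} if the fronts never merge
#'   within the trajectory.
#' @export
mergeTime <- function(occ, seeds, threshold = 0.5) {
  stopifnot(is(occ, "EnsembleOccupancy"))
  if (length(seeds) < 2L) stop("at least two seed sites are required")
  N <- nSites(occ)
  if (any(seeds < 1L | seeds > N)) stop("seed sites out of range 1..", N)
  span <- min(seeds):max(seeds)
  nonUU <- 1 - stateOccupancy(occ, "UU")   # sites x times
  merged <- colSums(nonUU[span, , drop = FALSE] >= threshold) == length(span)
  if (!any(merged)) return(NA_integer_)
  as.integer(which(merged)[1] - 1L)
}

#' Equilibration time of the ensemble occupancy
#'
#' Replication imprints a deterministic sawtooth of period one cell cycle on
#' every occupancy curve, so convergence is judged at matching cycle phases:
#' each time \code{t'} is compared with the last recorded time sharing its
#' phase (\code{t' + stepsPerCycle * floor((T - t') / stepsPerCycle)}).  The
#' equilibration time is the first \code{t} such that this phase-matched
#' deviation, maximised over sites and states, stays below \code{tol} for
#' every \code{t'} in \code{[t, t + window]}.  The trajectory should extend
#' at least one cycle plus one window beyond the expected equilibration time,
#' since comparisons inside the final cycle are self-referential.
#'
#' @param occ an \linkS4class{EnsembleOccupancy}.
#' @param window number of steps over which the deviation must stay below
#'   \code{tol} (default one cell cycle).
#' @param tol occupancy tolerance (default 0.05).
#' @param stepsPerCycle steps per cycle; default inferred from replication
#'   times.
#' @return The 0-based equilibration step, or \code{NA} if never satisfied.
#' @export
equilibrationTime <- function(occ, window = NULL, tol = 0.05,
                              stepsPerCycle = NULL) {
  stopifnot(is(occ, "EnsembleOccupancy"))
  if (is.null(stepsPerCycle)) {
    if (!length(occ@replicationTimes))
      stop("stepsPerCycle must be given when the ensemble has no ",
           "replication events")
    stepsPerCycle <- occ@replicationTimes[1]
  }
  if (is.null(window)) window <- stepsPerCycle
  if (window < 1L) stop("window must be >= 1")
  a <- occ@occupancy
  Tend <- dim(a)[3] - 1L                  # last 0-based time
  times <- 0:Tend
  ref <- times + stepsPerCycle * ((Tend - times) %/% stepsPerCycle)
  dev <- vapply(seq_along(times), function(i) {
    max(abs(a[, , i] - a[, , ref[i] + 1L]))
  }, numeric(1))
  ok <- dev < tol
  lastStart <- Tend - window
  if (lastStart < 0L) return(NA_integer_)
  for (t in 0:lastStart) {
    if (all(ok[(t + 1L):(t + window + 1L)])) return(as.integer(t))
  }
  NA_integer_
}

#' Fraction of runs containing a state
#'
#' The fraction of runs whose lattice at the given time contains at least
#' one site in the given state; for the bivalent AR state this measures
#' domain persistence (a run keeps its domain "alive" while any bivalent
#' nucleosome survives), which decays more slowly than the mean occupancy.
#'
#' @param runs list of \linkS4class{Trajectory} objects.
#' @param state state label.
#' @param time 0-based step, or vector of steps; default the full curve
#'   \code{0..nSteps}.
#' @return Numeric vector of fractions, one per requested time.
#' @export
fractionRunsWithState <- function(runs, state = "AR", time = NULL) {
  if (!length(runs)) stop("empty run list")
  code <- encodeStates(state)
  nT <- nrow(runs[[1]]@states)
  if (is.null(time)) time <- 0:(nT - 1L)
  if (any(time < 0L | time > nT - 1L)) stop("time out of range")
  hits <- vapply(runs, function(r)
    rowSums(r@states[time + 1L, , drop = FALSE] == code) > 0L,
    logical(length(time)))
  if (length(time) == 1L) mean(hits) else rowMeans(matrix(hits, nrow = length(time)))
}

#' Width, amplitude and center of a final occupancy profile
#'
#' Amplitude is the maximum occupancy over sites; width is the number of
#' sites at or above half the amplitude (full width at half maximum, in
#' sites); center is the occupancy-weighted mean site.
#'
#' @param profile per-site numeric occupancy profile, or an
#'   \linkS4class{EnsembleOccupancy} (in which case \code{state} and
#'   \code{time} select the profile; \code{time} defaults to the final
#'   step).
#' @param state,time used when \code{profile} is an ensemble occupancy.
#' @return A list with \code{amplitude}, \code{width} and \code{center}
#'   (\code{NA} center for an all-zero profile).
#' @export
#' @examples
#' p <- numeric(80); p[30:50] <- 0.8
#' domainProfileStats(p)  # amplitude 0.8, width 21, center 40
domainProfileStats <- function(profile, state = "AR", time = NULL) {
  if (is(profile, "EnsembleOccupancy")) {
    if (is.null(time)) time <- nSteps(profile)
    profile <- stateOccupancy(profile, state)[, time + 1L]
  }
  if (!is.numeric(profile) || any(profile < 0))
    stop("profile must be a nonnegative numeric vector")
  amp <- max(profile)
  if (amp == 0)
    return(list(amplitude = 0, width = 0L, center = NA_real_))
  width <- sum(profile >= amp / 2)
  center <- sum(seq_along(profile) * profile) / sum(profile)
  list(amplitude = amp, width = as.integer(width), center = center)
}
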