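## Synchronous stochastic dynamics of the reduced 4-state model.
##
## Per step, every site's one-step distribution is computed from the
## time-t lattice (recruitment channels read the local mark densities),
## then all sites are sampled independently with one uniform draw each,
## inverse-CDF over the fixed order AU, UR, AR, UU.  Replication mixes
## each site with UU at weight 1/2 at cell-cycle boundaries.

# expand a scalar-or-per-site nucleation rate to length N
.expandSiteRate <- function(v, N, what) {
  if (length(v) == 1L) return(rep(v, N))
  if (length(v) != N)
    stop(what, " must be a scalar or have one value per site (N=", N, ")")
  v
}

# windowed mark counts with phantom (out-of-lattice) sites counted as UU;
# returns integer counts of carrier sites in [i-r, i+r] for each i
.windowCounts <- function(carrier, r) {
  N <- length(carrier)
  if (r == 0L) return(as.integer(carrier))
  cs <- c(0L, cumsum(as.integer(carrier)))
  hi <- pmin(seq_len(N) + r, N)
  lo <- pmax(seq_len(N) - r, 1L)
  cs[hi + 1L] - cs[lo]
}

# local mark fractions for every site; list(thetaA, thetaR)
.localFractions <- function(states, r, includeSelf) {
  carriesA <- states == .STATE_AU | states == .STATE_AR
  carriesR <- states == .STATE_UR | states == .STATE_AR
  cntA <- .windowCounts(carriesA, r)
  cntR <- .windowCounts(carriesR, r)
  if (includeSelf) {
    denom <- 2 * r + 1
  } else {
    cntA <- cntA - as.integer(carriesA)
    cntR <- cntR - as.integer(carriesR)
    denom <- 2 * r
    if (denom == 0L) return(list(thetaA = numeric(length(states)),
                                 thetaR = numeric(length(states))))
  }
  list(thetaA = cntA / denom, thetaR = cntR / denom)
}

#' Local mark fraction around a site
#'
#' Fraction of nucleosomes in the recruitment window \code{[site - r, site +
#' r]} whose state carries the given mark.  Indices outside \code{1..N} are
#' phantom sites counted as fully unmodified (UU); the bivalent AR state
#' counts toward both marks.  The denominator is always the full window span
#' \code{2r + 1} (or \code{2r} when the focal site is excluded).
#'
#' @param lat a \linkS4class{Lattice}.
#' @param site site index in \code{1..N}.
#' @param mark \code{"A"} or \code{"R"}.
#' @param r recruitment half-range (nonnegative integer).
#' @param includeSelf whether the focal site contributes to its own window
#'   (default TRUE).
#' @return A fraction in \eqn{[0, 1]}.
#' @export
#' @examples
#' lat <- lattice(rep("AR", 5))
#' localMarkFraction(lat, 3, "A", r = 2)  # 1.0
#' localMarkFraction(lat, 1, "A", r = 2)  # 3/5: two phantom sites count UU
localMarkFraction <- function(lat, site, mark = c("A", "R"), r,
                              includeSelf = TRUE) {
  stopifnot(is(lat, "Lattice"))
  mark <- match.arg(mark)
  N <- nSites(lat)
  if (length(site) != 1L || site < 1L || site > N)
    stop("site must be a single index in 1..", N)
  if (length(r) != 1L || is.na(r) || r < 0)
    stop("r must be a single nonnegative integer")
  th <- .localFractions(lat@states, as.integer(r), isTRUE(includeSelf))
  if (mark == "A") th$thetaA[site] else th$thetaR[site]
}

# full N x 4 matrix of one-step destination probabilities (columns in
# canonical order AU, UR, AR, UU), computed from the whole lattice state.
# Shared by the R sampler, transitionProbabilities() and the exact oracle.
.siteDistributions <- function(states, params) {
  N <- length(states)
  th <- .localFractions(states, params@r, params@includeSelf)
  thetaA <- th$thetaA; thetaR <- th$thetaR
  kexpA <- .expandSiteRate(params@kExPlusA, N, "kExPlusA")
  kexpR <- .expandSiteRate(params@kExPlusR, N, "kExPlusR")
  m <- params@multiplicityUU

  addA <- params@kMeA * thetaA + kexpA          # gain A on a singly-eligible histone
  addR <- params@kMeR * thetaR + kexpR
  remA <- params@kDmA * thetaR + params@kExMinusA
  remR <- params@kDmR * thetaA + params@kExMinusR
  if (params@exchangeMultiplicity) {
    uuToAU <- m * addA                          # both histones eligible out of UU
    uuToUR <- m * addR
  } else {
    uuToAU <- m * (params@kMeA * thetaA) + kexpA
    uuToUR <- m * (params@kMeR * thetaR) + kexpR
  }

  isAU <- states == .STATE_AU
  isUR <- states == .STATE_UR
  isAR <- states == .STATE_AR
  isUU <- states == .STATE_UU

  exitSum <- numeric(N)
  exitSum[isUU] <- uuToAU[isUU] + uuToUR[isUU]
  exitSum[isAU] <- addR[isAU] + remA[isAU]
  exitSum[isUR] <- addA[isUR] + remR[isUR]
  exitSum[isAR] <- remA[isAR] + remR[isAR]
  if (any(bad <- exitSum > 1 + 1e-12)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("one-step exit probability %.4f > 1 at site %d ",
                        "(state %s): parameters violate the small-time-step ",
                        "assumption"),
                 exitSum[i], i, decodeStates(states[i])))
  }

  p <- matrix(0, nrow = N, ncol = 4L,
              dimnames = list(NULL, stateLabels()))
  # UU rows
  p[isUU, 1L] <- uuToAU[isUU]
  p[isUU, 2L] <- uuToUR[isUU]
  p[isUU, 4L] <- 1 - exitSum[isUU]
  # AU rows
  p[isAU, 1L] <- 1 - exitSum[isAU]
  p[isAU, 3L] <- addR[isAU]
  p[isAU, 4L] <- remA[isAU]
  # UR rows
  p[isUR, 2L] <- 1 - exitSum[isUR]
  p[isUR, 3L] <- addA[isUR]
  p[isUR, 4L] <- remR[isUR]
  # AR rows
  p[isAR, 1L] <- remR[isAR]
  p[isAR, 2L] <- remA[isAR]
  p[isAR, 3L] <- 1 - exitSum[isAR]
  p
}

#' One-step transition distribution of a site
#'
#' The full one-step probability distribution over the four states for a
#' given site, conditioned on the whole lattice at the current time.
#' Forbidden one-step moves (UU to AR, AU to UR and reverses, which would
#' change two modification sites) carry probability zero; the self-transition
#' takes the remaining mass.
#'
#' @param lat a \linkS4class{Lattice}.
#' @param site site index in \code{1..N}.
#' @param params a \linkS4class{RateParams}.
#' @return Named numeric vector over \code{stateLabels()}, summing to 1.
#' @export
#' @examples
#' p <- transitionProbabilities(lattice(rep("UU", 5)), 3, rateParams())
#' sum(p)  # 1
transitionProbabilities <- function(lat, site, params) {
  stopifnot(is(lat, "Lattice"), is(params, "RateParams"))
  N <- nSites(lat)
  if (length(site) != 1L || site < 1L || site > N)
    stop("site must be a single index in 1..", N)
  .siteDistributions(lat@states, params)[site, ]
}

# one synchronous update of a raw integer state vector (R engine); consumes
# exactly N uniforms in site order, matching the C++ engine bit-for-bit
.stepStates <- function(states, params) {
  p <- .siteDistributions(states, params)
  u <- runif(length(states))
  cum1 <- p[, 1L]
  cum2 <- cum1 + p[, 2L]
  cum3 <- cum2 + p[, 3L]
  1L + (u >= cum1) + (u >= cum2) + (u >= cum3)
}

#' Advance the lattice one time step
#'
#' Synchronous update: all per-site distributions are computed from the
#' current lattice, then every site is sampled independently with one
#' uniform draw, inverse-CDF over the fixed order \code{stateLabels()}.
#' Uses R's global RNG stream.
#'
#' @param lat a \linkS4class{Lattice}.
#' @param params a \linkS4class{RateParams}.
#' @return The updated \linkS4class{Lattice}.
#' @export
stepLattice <- function(lat, params) {
  stopifnot(is(lat, "Lattice"), is(params, "RateParams"))
  lattice(.stepStates(lat@states, params))
}

#' Replication dilution
#'
#' Models DNA replication following one daughter strand: each nucleosome is
#' independently replaced by an unmodified (UU) nucleosome with probability
#' 1/2, else retains its parental state.  Consumes one uniform draw per site
#' from R's global RNG stream.
#'
#' @param lat a \linkS4class{Lattice}.
#' @return The diluted \linkS4class{Lattice}.
#' @export
replicateLattice <- function(lat) {
  stopifnot(is(lat, "Lattice"))
  s <- lat@states
  s[runif(length(s)) < 0.5] <- .STATE_UU
  lattice(s)
}

#' Run a single simulation
#'
#' Iterates the synchronous update for \code{nCycles} cell cycles of
#' \code{stepsPerCycle(params)} steps each, applying replication dilution
#' after the last step of every cycle (the snapshot recorded at a cycle
#' boundary is the post-replication lattice; t = 0 is not a replication
#' event).  The compiled engine and the reference R engine consume the RNG
#' stream identically and produce bit-identical trajectories under the same
#' seed.
#'
#' @param initial a \linkS4class{Lattice}.
#' @param params a \linkS4class{RateParams}.
#' @param nCycles number of cell cycles (>= 1).
#' @param seed optional integer seed; when given, \code{set.seed(seed)} is
#'   called before the run and recorded in the trajectory.
#' @param replication apply replication dilution at cycle boundaries
#'   (default TRUE).
#' @param engine \code{"cpp"} (compiled, default) or \code{"R"} (reference).
#' @return A \linkS4class{Trajectory} holding all \code{nCycles *
#'   stepsPerCycle + 1} snapshots.
#' @export
#' @examples
#' tr <- runSimulation(lattice(rep("AR", 10)), rateParams(), nCycles = 1,
#'                     seed = 1)
#' nSteps(tr)  # 360
runSimulation <- function(initial, params, nCycles, seed = NULL,
                          replication = TRUE, engine = c("cpp", "R")) {
  stopifnot(is(initial, "Lattice"), is(params, "RateParams"))
  engine <- match.arg(engine)
  if (nCycles < 1L) stop("nCycles must be >= 1")
  N <- nSites(initial)
  spc <- params@stepsPerCycle
  nTot <- as.integer(nCycles) * spc
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    set.seed(seed)
  } else seed <- NA_integer_
  # validate parameters once on the initial configuration
  invisible(.siteDistributions(initial@states, params))

  if (engine == "cpp") {
    states <- run_sim_cpp(initial@states, nTot, spc, isTRUE(replication),
                          params@kMeA, params@kMeR, params@kDmA, params@kDmR,
                          .expandSiteRate(params@kExPlusA, N, "kExPlusA"),
                          .expandSiteRate(params@kExPlusR, N, "kExPlusR"),
                          params@kExMinusA, params@kExMinusR,
                          params@r, params@includeSelf,
                          params@multiplicityUU, params@exchangeMultiplicity)
  } else {
    states <- matrix(0L, nrow = nTot + 1L, ncol = N)
    cur <- initial@states
    states[1L, ] <- cur
    for (t in seq_len(nTot)) {
      cur <- .stepStates(cur, params)
      if (replication && t %% spc == 0L)
        cur[runif(N) < 0.5] <- .STATE_UU
      states[t + 1L, ] <- cur
    }
  }
  repl <- if (replication) seq.int(spc, nTot, by = spc) else integer(0)
  new("Trajectory", states = states, replicationTimes = as.integer(repl),
      seed = seed)
}

#' Deterministic per-run seeds for an ensemble
#'
#' @param baseSeed integer base seed.
#' @param nRuns number of runs.
#' @return Integer vector of \code{nRuns} distinct seeds (kept below 2^31).
#' @export
runSeeds <- function(baseSeed, nRuns) {
  s <- (as.double(baseSeed) + seq_len(nRuns) - 1) %% 2147483647
  as.integer(s)
}
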