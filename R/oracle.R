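## Exact Markov-chain oracle for tiny lattices.
##
## For N <= 4 the full lattice chain over 4^N configurations is tractable as
## a dense stochastic matrix, which gives exact transient distributions to
## validate the Monte-Carlo engine against.  Correctness, not scale, is the
## point: N is capped rather than optimized.

.MAX_ORACLE_N <- 4L

#' Configuration index of a lattice
#'
#' Bijection between lattices of size N and \code{1..4^N}: site 1 is the
#' least-significant base-4 digit, using the canonical state codes
#' (AU=1, UR=2, AR=3, UU=4).
#'
#' @param lat a \linkS4class{Lattice} (or integer state codes).
#' @return Integer configuration index.
#' @export
#' @examples
#' configurationIndex(lattice(c("AU", "AU")))  # 1
#' configurationIndex(lattice(c("UU", "UU")))  # 16
configurationIndex <- function(lat) {
  s <- if (is(lat, "Lattice")) lat@states else as.integer(lat)
  as.integer(1 + sum((s - 1) * 4^(seq_along(s) - 1)))
}

#' Decode a configuration index
#'
#' @param idx configuration index in \code{1..4^N}.
#' @param N lattice size.
#' @return A \linkS4class{Lattice}.
#' @export
indexToConfiguration <- function(idx, N) {
  if (idx < 1L || idx > 4^N) stop("idx out of range 1..4^", N)
  rem <- idx - 1
  s <- integer(N)
  for (i in seq_len(N)) {
    s[i] <- rem %% 4
    rem <- rem %/% 4
  }
  lattice(s + 1L)
}

#' Exact one-step transition matrix of the lattice chain
#'
#' Entry \code{(c, c')} is the probability of moving from configuration
#' \code{c} to \code{c'} in one synchronous step: the product over sites of
#' the per-site one-step probabilities, with each site's distribution
#' evaluated on configuration \code{c} (phantom-boundary rule included).
#' Every row sums to 1.
#'
#' @param params a \linkS4class{RateParams}.
#' @param N lattice size (at most 4).
#' @return A dense \code{4^N x 4^N} stochastic matrix.
#' @export
buildTransitionMatrix <- function(params, N) {
  stopifnot(is(params, "RateParams"))
  N <- as.integer(N)
  if (N < 1L || N > .MAX_ORACLE_N)
    stop("exact oracle supports N in 1..", .MAX_ORACLE_N,
         " (4^N configurations must stay tractable)")
  M <- 4L^N
  P <- matrix(0, nrow = M, ncol = M)
  for (c0 in seq_len(M)) {
    states <- indexToConfiguration(c0, N)@states
    p <- .siteDistributions(states, params)    # N x 4
    v <- p[1L, ]
    if (N > 1L)
      for (i in 2:N) v <- as.vector(outer(v, p[i, ]))
    P[c0, ] <- v
  }
  P
}

#' Exact replication-dilution operator
#'
#' Each site is independently replaced by UU with probability 1/2, else kept;
#' the full-lattice operator is the N-fold Kronecker product of the per-site
#' mixing matrix.
#'
#' @param N lattice size (at most 4).
#' @return A dense \code{4^N x 4^N} stochastic matrix.
#' @export
replicationOperator <- function(N) {
  N <- as.integer(N)
  if (N < 1L || N > .MAX_ORACLE_N)
    stop("exact oracle supports N in 1..", .MAX_ORACLE_N)
  m <- 0.5 * diag(4)
  m[, .STATE_UU] <- m[, .STATE_UU] + 0.5
  m[.STATE_UU, .STATE_UU] <- 1
  Reduce(kronecker, rep(list(m), N))
}

#' Exact transient distribution of the lattice chain
#'
#' Propagates the delta distribution on the initial configuration through
#' \code{tSteps} applications of the exact transition matrix, inserting the
#' exact replication operator after the last step of each cell cycle when
#' \code{replication = TRUE} (mirroring the simulation engine's bookkeeping:
#' the distribution reported at a cycle boundary is post-replication).
#'
#' @param initial a \linkS4class{Lattice} with at most 4 sites.
#' @param params a \linkS4class{RateParams}.
#' @param tSteps number of steps (>= 0).
#' @param replication insert replication at cycle boundaries (default FALSE).
#' @return A \linkS4class{ChainDistribution} at time \code{tSteps}.
#' @export
#' @examples
#' d <- exactTransientDistribution(lattice(c("UU", "UU")), rateParams(), 10)
#' sum(d@probs)  # 1
exactTransientDistribution <- function(initial, params, tSteps,
                                       replication = FALSE) {
  stopifnot(is(initial, "Lattice"), is(params, "RateParams"))
  N <- nSites(initial)
  if (N > .MAX_ORACLE_N)
    stop("exact oracle supports N in 1..", .MAX_ORACLE_N)
  if (tSteps < 0L) stop("tSteps must be >= 0")
  v <- numeric(4L^N)
  v[configurationIndex(initial)] <- 1
  if (tSteps > 0L) {
    P <- buildTransitionMatrix(params, N)
    K <- if (replication) replicationOperator(N) else NULL
    spc <- params@stepsPerCycle
    for (t in seq_len(tSteps)) {
      v <- as.vector(v %*% P)
      if (replication && t %% spc == 0L)
        v <- as.vector(v %*% K)
    }
  }
  new("ChainDistribution", probs = v, N = N, time = as.integer(tSteps))
}

#' Compare Monte-Carlo configuration frequencies with the exact oracle
#'
#' Runs \code{nRuns} independent simulations of a small lattice, tabulates
#' the configuration frequencies at time \code{tSteps}, and compares them
#' with the exact transient distribution.  Used by the \code{oracle-check}
#' command and the validation tests.
#'
#' @param initial a \linkS4class{Lattice} with at most 4 sites.
#' @param params a \linkS4class{RateParams}.
#' @param tSteps comparison time step.
#' @param nRuns Monte-Carlo ensemble size.
#' @param seed base seed for the ensemble.
#' @param replication apply replication at cycle boundaries (default FALSE).
#' @return A list with \code{empirical} and \code{exact} probability
#'   vectors, \code{maxAbsDeviation}, \code{maxSigma} (largest deviation in
#'   units of the binomial standard error, taken over configurations with
#'   nonzero exact mass), \code{nViolations} (configurations whose observed
#'   count falls outside the central 99.73\% binomial interval, the
#'   discreteness-safe equivalent of a 3-sigma band), and \code{nRuns}.
#' @importFrom stats qbinom
#' @export
oracleCheck <- function(initial, params, tSteps, nRuns = 20000L, seed = 1L,
                        replication = FALSE) {
  stopifnot(is(initial, "Lattice"))
  N <- nSites(initial)
  exact <- exactTransientDistribution(initial, params, tSteps,
                                      replication = replication)@probs
  counts <- integer(4L^N)
  seeds <- runSeeds(seed, nRuns)
  # simulate tSteps in "one cycle" chunks so replication timing matches
  spc <- params@stepsPerCycle
  for (k in seq_len(nRuns)) {
    set.seed(seeds[k])
    st <- run_sim_cpp(initial@states, as.integer(tSteps), spc,
                      isTRUE(replication),
                      params@kMeA, params@kMeR, params@kDmA, params@kDmR,
                      .expandSiteRate(params@kExPlusA, N, "kExPlusA"),
                      .expandSiteRate(params@kExPlusR, N, "kExPlusR"),
                      params@kExMinusA, params@kExMinusR,
                      params@r, params@includeSelf,
                      params@multiplicityUU, params@exchangeMultiplicity)
    idx <- configurationIndex(st[tSteps + 1L, ])
    counts[idx] <- counts[idx] + 1L
  }
  emp <- counts / nRuns
  dev <- abs(emp - exact)
  se <- sqrt(pmax(exact * (1 - exact), 0) / nRuns)
  pos <- se > 0
  maxSigma <- if (any(pos)) max(dev[pos] / se[pos]) else 0
  lo <- qbinom(0.00135, nRuns, exact)
  hi <- qbinom(0.99865, nRuns, exact)
  nViolations <- sum(counts < lo | counts > hi)
  list(empirical = emp, exact = exact,
       maxAbsDeviation = max(dev), maxSigma = maxSigma,
       nViolations = nViolations, nRuns = nRuns)
}
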