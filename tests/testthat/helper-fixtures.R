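# shared fixture builders; everything is generated in code

# parameters with every channel switched off (identity dynamics);
# individual channels can be re-enabled through ...
zeroRates <- function(...) {
  base <- list(kMeA = 0, kMeR = 0, kDmA = 0, kDmR = 0,
               kExPlusA = 0, kExPlusR = 0, kExMinusA = 0, kExMinusR = 0)
  do.call(rateParams, utils::modifyList(base, list(...)))
}

# formation-like / decay-like parameter sets used for oracle comparisons
formationLikeParams <- function(...) rateParams(...)
decayLikeParams <- function(...) {
  do.call(rateParams, utils::modifyList(list(kDmA = 0.016), list(...)))
}

# an EnsembleOccupancy with a prescribed occupancy matrix for one state and
# the remaining mass assigned to UU (other states zero)
syntheticOccupancy <- function(m, state = "AR", nRuns = 100L,
                               replicationTimes = integer(0)) {
  N <- nrow(m); nT <- ncol(m)
  occ <- array(0, dim = c(4L, N, nT),
               dimnames = list(state = stateLabels(), NULL, NULL))
  occ[encodeStates(state), , ] <- m
  occ[encodeStates("UU"), , ] <- 1 - m
  new("EnsembleOccupancy", occupancy = occ, nRuns = as.integer(nRuns),
      replicationTimes = as.integer(replicationTimes))
}

# constant-state trajectory (no dynamics), for ensemble statistics tests
constantTrajectory <- function(label, N = 4L, nT = 5L) {
  new("Trajectory",
      states = matrix(encodeStates(label), nrow = nT + 1L, ncol = N),
      replicationTimes = integer(0), seed = NA_integer_)
}
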