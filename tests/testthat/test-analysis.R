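# ensemble statistics, front tracking, merge/equilibration detectors,
# persistence curves and profile geometry

test_that("ensemble occupancy averages runs and partitions unity", {
  runs <- list(constantTrajectory("AR"), constantTrajectory("AR"))
  occ <- ensembleOccupancy(runs)
  expect_true(all(stateOccupancy(occ, "AR") == 1))

  occ2 <- ensembleOccupancy(list(constantTrajectory("AR"),
                                 constantTrajectory("UU")))
  expect_true(all(stateOccupancy(occ2, "AR") == 0.5))
  expect_true(all(stateOccupancy(occ2, "UU") == 0.5))
  tot <- apply(occ2@occupancy, c(2, 3), sum)
  expect_true(all(abs(tot - 1) < 1e-12))

  expect_error(ensembleOccupancy(list()), "empty")
  expect_error(ensembleOccupancy(list(constantTrajectory("AR", N = 3),
                                      constantTrajectory("AR", N = 4))),
               "same number")
})

test_that("ensemble occupancy is invariant under run relabeling", {
  set.seed(12)
  runs <- lapply(1:6, function(i)
    runSimulation(buildInitialCondition("localized", 8, 3),
                  rateParams(stepsPerCycle = 15L), 1, seed = i))
  a <- ensembleOccupancy(runs)
  b <- ensembleOccupancy(runs[sample(6)])
  expect_equal(a@occupancy, b@occupancy)
})

test_that("front tracking recovers edges and expansion speed", {
  # block growing by exactly one site per side every 36 steps
  N <- 60L; nT <- 721L
  m <- matrix(0, N, nT)
  width <- integer(nT)
  for (t in 0:720) {
    g <- t %/% 36L
    lo <- 28L - g; hi <- 32L + g
    m[lo:hi, t + 1L] <- 0.9
    width[t + 1L] <- hi - lo + 1L
  }
  occ <- syntheticOccupancy(m)
  ft <- frontTrack(occ, "AR", threshold = 0.5, seedSite = 30L,
                   stepsPerCycle = 360L)
  expect_equal(ft@rightEdge - ft@leftEdge + 1, as.numeric(width))
  # independent fit of the constructed width series
  slope <- unname(coef(lm(width ~ t, data.frame(width = width, t = 0:720)))[2])
  expect_equal(ft@speed, slope * 360, tolerance = 1e-10)
  expect_equal(ft@speed, 20, tolerance = 0.1 * 20)

  # constant occupancy: zero speed
  flat <- syntheticOccupancy(matrix(rep(c(0, 0.8, 0), c(10, 5, 10)), 25, 50))
  ftFlat <- frontTrack(flat, "AR", seedSite = 12L, stepsPerCycle = 360L)
  expect_equal(ftFlat@speed, 0)

  # never above threshold: flagged empty track, not an error
  ftNone <- frontTrack(syntheticOccupancy(matrix(0.1, 10, 10)), "AR",
                       seedSite = 5L, stepsPerCycle = 360L)
  expect_true(all(is.na(ftNone@leftEdge)))
  expect_true(is.na(ftNone@speed))
})

test_that("front tracking mirrors under spatial reflection", {
  set.seed(4)
  N <- 30L
  m <- matrix(0, N, 40)
  for (t in 1:40) m[10:(10 + min(t %/% 4, 8)), t] <- 1
  occ <- syntheticOccupancy(m)
  occR <- syntheticOccupancy(m[N:1, ])
  ft <- frontTrack(occ, "AR", seedSite = 10L, stepsPerCycle = 100L)
  ftR <- frontTrack(occR, "AR", seedSite = N + 1L - 10L, stepsPerCycle = 100L)
  expect_equal(ftR@leftEdge, N + 1 - ft@rightEdge)
  expect_equal(ftR@rightEdge, N + 1 - ft@leftEdge)
})

test_that("merge detector finds when fronts span the seeds", {
  # already connected at t = 0
  m0 <- matrix(0.9, 20, 5)
  expect_equal(mergeTime(syntheticOccupancy(m0), c(3, 17)), 0L)

  # two fronts expanding one site per step from seeds 10 and 21 (gap 10)
  N <- 30L; nT <- 10L
  m <- matrix(0, N, nT)
  for (t in 0:(nT - 1L)) {
    k <- t
    m[max(1, 10 - k):min(N, 10 + k), t + 1L] <- 0.9
    m[max(1, 21 - k):min(N, 21 + k), t + 1L] <- 0.9
  }
  expect_equal(mergeTime(syntheticOccupancy(m), c(10, 21)), 5L)

  # merging is judged on total non-UU occupancy, not a single state
  mm <- syntheticOccupancy(m, state = "AU")
  expect_equal(mergeTime(mm, c(10, 21)), 5L)

  # never merges
  mNever <- matrix(0, 20, 6); mNever[c(3, 17), ] <- 0.9
  expect_true(is.na(mergeTime(syntheticOccupancy(mNever), c(3, 17))))
  expect_error(mergeTime(syntheticOccupancy(mNever), 3), "two seed")
})

test_that("equilibration detector matches the analytic relaxation time", {
  # constant occupancy equilibrates immediately
  occFlat <- syntheticOccupancy(matrix(0.4, 10, 200))
  expect_equal(equilibrationTime(occFlat, window = 20, tol = 0.05,
                                 stepsPerCycle = 1L), 0L)

  # exponential relaxation with known rate: occupancy
  # p(t) = 0.6 - 0.5 exp(-t / 40), compared against the final time
  nT <- 301L; tau <- 40; tol <- 0.02
  p <- 0.6 - 0.5 * exp(-(0:300) / tau)
  occ <- syntheticOccupancy(matrix(rep(p, each = 5), 5, nT))
  # analytic first time with |p(t) - p(Tend)| < tol, Tend = 300
  dev <- abs(p - p[nT])
  expected <- which(dev < tol)[1] - 1L
  got <- equilibrationTime(occ, window = 30, tol = tol, stepsPerCycle = 1L)
  expect_equal(got, expected)
  # closed form: t* = -tau * log(tol / 0.5 + exp(-300 / tau))
  expect_equal(expected, ceiling(-tau * log(tol / 0.5 + exp(-300 / tau))))

  # never settles within tolerance
  drift <- syntheticOccupancy(matrix(seq(0, 0.9, length.out = 100),
                                     3, 100, byrow = TRUE))
  expect_true(is.na(equilibrationTime(drift, window = 50, tol = 0.001,
                                      stepsPerCycle = 1L)))
})

test_that("persistence dominates mean occupancy and tracks extinction", {
  expect_equal(fractionRunsWithState(list(constantTrajectory("AR")), "AR", 2),
               1)
  expect_equal(fractionRunsWithState(list(constantTrajectory("UU")), "AR", 2),
               0)
  # decay-like ensemble: P(at least one AR) >= mean AR occupancy everywhere
  set.seed(31)
  runs <- lapply(1:40, function(i)
    runSimulation(buildInitialCondition("all_AR", 12),
                  decayLikeParams(kDmA = 0.03, stepsPerCycle = 60L), 2,
                  seed = 300 + i))
  occ <- ensembleOccupancy(runs)
  meanAR <- colMeans(stateOccupancy(occ, "AR"))
  persist <- fractionRunsWithState(runs, "AR")
  expect_true(all(persist >= meanAR - 1e-12))
})

test_that("profile geometry: amplitude, FWHM width, weighted center", {
  p <- numeric(80); p[30:50] <- 0.8
  st <- domainProfileStats(p)
  expect_equal(st$amplitude, 0.8)
  expect_equal(st$width, 21L)
  expect_equal(st$center, 40)

  z <- domainProfileStats(numeric(15))
  expect_equal(z$amplitude, 0)
  expect_equal(z$width, 0L)
  expect_true(is.na(z$center))

  # triangular profile: FWHM counts sites at or above half max
  tri <- c(0.1, 0.2, 0.4, 0.8, 0.4, 0.2, 0.1)
  expect_equal(domainProfileStats(tri)$width, 3L)
})
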