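# local recruitment densities, one-step distributions, synchronous updates,
# replication dilution and trajectory bookkeeping

test_that("local mark fraction respects window, marks and phantom sites", {
  allUU <- lattice(rep("UU", 7))
  expect_equal(localMarkFraction(allUU, 4, "A", r = 2), 0)
  expect_equal(localMarkFraction(allUU, 1, "R", r = 3), 0)

  allAR <- lattice(rep("AR", 5))
  expect_equal(localMarkFraction(allAR, 3, "A", r = 2), 1)
  expect_equal(localMarkFraction(allAR, 3, "R", r = 2), 1)
  # boundary window covers two phantom sites counted as UU
  expect_equal(localMarkFraction(allAR, 1, "A", r = 2), 3 / 5)

  mixed <- lattice(c("AU", "UR", "UU", "AR", "UU"))
  expect_equal(localMarkFraction(mixed, 2, "A", r = 1), 1 / 3)  # AU only
  expect_equal(localMarkFraction(mixed, 4, "R", r = 1), 1 / 3)  # AR only
  # excluding the focal site: window {2, 4}, only AR carries A
  expect_equal(localMarkFraction(mixed, 3, "A", r = 1, includeSelf = FALSE),
               1 / 2)

  expect_error(localMarkFraction(mixed, 0, "A", r = 1), "site")
  expect_error(localMarkFraction(mixed, 6, "A", r = 1), "site")
  expect_error(localMarkFraction(mixed, 2, "A", r = -1), "r must")
})

test_that("one-step distributions implement the reduced-model channels", {
  # no removal channel: a bivalent nucleosome cannot leave AR
  p <- transitionProbabilities(lattice(rep("AR", 3)), 2,
                               zeroRates(kMeA = 0.1, kMeR = 0.05))
  expect_equal(unname(p["AR"]), 1)
  expect_equal(sum(p), 1)

  # recruitment onto UU with theta_A = 1/2 and multiplicity 2:
  # P(UU -> AU) = 2 * 0.046 * 0.5 = 0.046 (hand evaluation)
  lat <- lattice(c("AR", "UU", "UU"))
  p <- transitionProbabilities(lat, 2, zeroRates(kMeA = 0.046, r = 1L,
                                                 includeSelf = FALSE))
  expect_equal(unname(p["AU"]), 0.046)
  expect_equal(unname(p["UR"]), 0)
  expect_equal(unname(p["AR"]), 0)   # two-site move is forbidden
  expect_equal(unname(p["UU"]), 1 - 0.046)

  # multiplicity switch: m = 1 halves the UU addition channel
  p1 <- transitionProbabilities(lat, 2, zeroRates(kMeA = 0.046, r = 1L,
                                                  includeSelf = FALSE,
                                                  multiplicityUU = 1))
  expect_equal(unname(p1["AU"]), 0.023)

  # removal is recruited by the opposite mark: AU with repressive neighbors
  lat2 <- lattice(c("UR", "AU", "UR"))
  p2 <- transitionProbabilities(lat2, 2, zeroRates(kDmA = 0.3, r = 1L))
  expect_equal(unname(p2["UU"]), 0.3 * (2 / 3))
  expect_equal(unname(p2["UR"]), 0)  # AU -> UR is a two-site move
  expect_equal(sum(p2), 1)

  # exchange channels are neighbour-independent
  p3 <- transitionProbabilities(lattice(rep("AR", 3)), 1,
                                zeroRates(kExMinusA = 0.3, kExMinusR = 0.1))
  expect_equal(unname(p3["UR"]), 0.3)  # losing the active mark
  expect_equal(unname(p3["AU"]), 0.1)  # losing the repressive mark
  expect_equal(unname(p3["UU"]), 0)
})

test_that("distributions normalize over random configurations", {
  set.seed(71)
  params <- rateParams(kDmA = 0.01, kExPlusA = 0.02)
  for (i in 1:20) {
    lat <- lattice(sample(1:4, 15, replace = TRUE))
    site <- sample(15, 1)
    p <- transitionProbabilities(lat, site, params)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("parameterizations violating the small-step bound are rejected", {
  lat <- lattice(rep("UU", 4))
  bad <- zeroRates(kExPlusA = 0.9, kExPlusR = 0.9)  # exit mass 3.6 from UU
  expect_error(transitionProbabilities(lat, 1, bad),
               "exit probability.*site 1")
  expect_error(runSimulation(lat, bad, 1, seed = 1), "exit probability")
})

test_that("empirical step frequencies match the analytic distribution", {
  # one-site lattice held in UU: repeated single steps are iid draws
  params <- zeroRates(kExPlusA = 0.2, kExPlusR = 0.1)
  lat <- lattice("UU")
  p <- transitionProbabilities(lat, 1, params)
  n <- 20000L
  set.seed(405)
  draws <- vapply(seq_len(n), function(i) stepLattice(lat, params)@states,
                  integer(1))
  freq <- tabulate(draws, nbins = 4) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 3 * se + 1 / n))
})

test_that("step is deterministic under a fixed seed and identity at zero rates", {
  lat <- lattice(sample(1:4, 30, replace = TRUE))
  params <- rateParams(kDmA = 0.01)
  set.seed(9); a <- stepLattice(lat, params)
  set.seed(9); b <- stepLattice(lat, params)
  expect_identical(a@states, b@states)
  set.seed(9)
  expect_identical(stepLattice(lat, zeroRates())@states, lat@states)
})

test_that("replication resets each site independently with probability 1/2", {
  allUU <- lattice(rep("UU", 20))
  set.seed(2)
  expect_identical(replicateLattice(allUU)@states, allUU@states)
  allAR <- lattice(rep("AR", 80))
  set.seed(33)
  fracs <- replicate(500, mean(replicateLattice(allAR)@states == 4L))
  se <- sqrt(0.25 / (500 * 80))
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)
  # kept sites keep their state
  set.seed(5)
  out <- replicateLattice(allAR)@states
  expect_true(all(out %in% c(3L, 4L)))
})

test_that("trajectory bookkeeping: snapshots, replication times, cycles", {
  init <- buildInitialCondition("localized", 10, 4)
  params <- rateParams(stepsPerCycle = 30L)
  tr <- runSimulation(init, params, 2, seed = 3)
  expect_equal(nSteps(tr), 60L)
  expect_equal(nrow(tr@states), 61L)
  expect_equal(replicationTimes(tr), c(30L, 60L))
  expect_identical(latticeAt(tr, 0)@states, init@states)

  # zero-rate dynamics change the lattice only at replication steps
  tr0 <- runSimulation(lattice(rep("AR", 12)), zeroRates(stepsPerCycle = 20L),
                       2, seed = 8)
  for (t in 1:40) {
    if (t %in% tr0@replicationTimes) next
    expect_identical(tr0@states[t + 1L, ], tr0@states[t, ])
  }
  # replication only ever converts sites to UU
  for (t in tr0@replicationTimes)
    expect_true(all(tr0@states[t + 1L, ] %in%
                    c(tr0@states[t, ], 4L)))
})

test_that("compiled and reference engines are bit-identical", {
  init <- buildInitialCondition("localized", 25, 5)
  paramSets <- list(
    rateParams(stepsPerCycle = 40L),
    rateParams(kDmA = 0.02, stepsPerCycle = 40L, includeSelf = FALSE),
    rateParams(kExPlusA = c(rep(0, 12), 0.01, rep(0, 12)),
               kExPlusR = c(rep(0, 12), 0.005, rep(0, 12)),
               stepsPerCycle = 40L, multiplicityUU = 1,
               exchangeMultiplicity = FALSE))
  for (p in paramSets) {
    a <- runSimulation(init, p, 2, seed = 17, engine = "cpp")
    b <- runSimulation(init, p, 2, seed = 17, engine = "R")
    expect_identical(a@states, b@states)
    expect_identical(a@replicationTimes, b@replicationTimes)
  }
})

test_that("lost marks cannot recover without nucleation", {
  # strong turnover drives extinction; once no site carries A, none may
  # reappear (checked on every run, every step)
  params <- zeroRates(kMeA = 0.03, kMeR = 0.015,
                      kExMinusA = 0.05, kExMinusR = 0.025,
                      stepsPerCycle = 60L)
  extinctionSeen <- FALSE
  for (s in 1:30) {
    tr <- runSimulation(buildInitialCondition("localized", 10, 3), params,
                        2, seed = 100 + s)
    hasA <- rowSums(tr@states == 1L | tr@states == 3L) > 0L
    firstLost <- which(!hasA)[1]
    if (!is.na(firstLost)) {
      extinctionSeen <- TRUE
      expect_false(any(hasA[firstLost:length(hasA)]))
    }
  }
  expect_true(extinctionSeen)
})
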