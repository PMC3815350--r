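# initial conditions, scenario configurations, ensemble bookkeeping

test_that("initial conditions place bivalent seeds as specified", {
  deloc <- buildInitialCondition("delocalized", 80, 5)
  expect_equal(seedSites(deloc), c(1L, 20L, 40L, 60L, 80L))

  loc <- buildInitialCondition("localized", 80, 5)
  expect_equal(seedSites(loc), 38:42)
  expect_true(all(loc@states[-(38:42)] == encodeStates("UU")))

  # center placement is left-biased for even remainders
  expect_equal(seedSites(buildInitialCondition("localized", 10, 4)), 4:7)

  expect_identical(decodeStates(buildInitialCondition("all_AR", 3)@states),
                   rep("AR", 3))
  expect_identical(decodeStates(buildInitialCondition("all_UU", 3)@states),
                   rep("UU", 3))

  cust <- buildInitialCondition("custom", 4, states = c("AU", "UU", "UR", "AR"))
  expect_equal(decodeStates(cust@states), c("AU", "UU", "UR", "AR"))

  expect_error(buildInitialCondition("localized", 10, 11), "n0 must be")
  expect_error(buildInitialCondition("delocalized", 10, 11), "n0 must be")
  expect_error(buildInitialCondition("custom", 5, states = c("AU", "UU")),
               "length N")
})

test_that("scenario defaults encode the canonical experiments", {
  f <- scenarioConfig("formation_localized")
  expect_equal(f@params@kMeA, 0.046)
  expect_equal(f@params@kMeR, 0.023)
  expect_equal(f@params@kDmA, 0)
  expect_equal(f@params@kExMinusA, 0.003)
  expect_equal(f@params@kExMinusR, 0.0015)
  expect_equal(f@params@stepsPerCycle, 360L)
  expect_equal(f@params@r, 2L)
  expect_equal(f@N, 80L)
  expect_equal(f@nCycles, 10L)

  d <- scenarioConfig("decay")
  expect_equal(d@initialKind, "all_AR")
  expect_equal(d@params@kDmA, 0.016)
  expect_equal(d@params@kDmR, 0.008)

  n <- scenarioConfig("nucleation")
  expect_equal(n@nCycles, 5L)
  kpA <- n@params@kExPlusA
  expect_equal(sum(kpA > 0), 1L)
  expect_equal(kpA[40], 0.01)
  expect_equal(n@params@kExPlusR[40], 0.005)

  cc <- scenarioConfig("cellcycle_sweep")
  expect_equal(cc@sweep$axis, "cycleHours")
  expect_equal(range(cc@sweep$values), c(6, 24))

  expect_error(scenarioConfig("formation_localized", N = 10, n0 = 20),
               "n0 must not exceed N")
})

test_that("sweep application adjusts the right knob and keeps 2:1 ratios", {
  cfg <- scenarioConfig("cellcycle_sweep", nRuns = 2, nCycles = 1)
  sw <- bivalentSim:::.applySweepValue(cfg, "cycleHours", 6)
  expect_equal(sw$params@stepsPerCycle, 180L)
  sw24 <- bivalentSim:::.applySweepValue(cfg, "cycleHours", 24)
  expect_equal(sw24$params@stepsPerCycle, 720L)

  dcfg <- scenarioConfig("decay", nRuns = 2, nCycles = 1)
  swd <- bivalentSim:::.applySweepValue(dcfg, "kDmA", 0.034)
  expect_equal(swd$params@kDmA, 0.034)
  expect_equal(swd$params@kDmR, 0.017)

  fcfg <- scenarioConfig("formation_localized", nRuns = 2, nCycles = 1)
  swn <- bivalentSim:::.applySweepValue(fcfg, "n0", 9)
  expect_equal(seedSites(swn$initial), 36:44)
})

test_that("incremental ensemble statistics match stored trajectories", {
  init <- buildInitialCondition("localized", 12, 4)
  params <- rateParams(kDmA = 0.01, stepsPerCycle = 25L)
  ens <- runEnsemble(init, params, nCycles = 2, nRuns = 15, baseSeed = 7,
                     keepTrajectories = 15)
  byHand <- ensembleOccupancy(ens$trajectories)
  expect_equal(ens$occupancy@occupancy, byHand@occupancy)
  expect_equal(ens$occupancy@replicationTimes, c(25L, 50L))
  # persistence curves agree with the trajectory-based operation
  for (s in stateLabels())
    expect_equal(ens$hasStateFraction[encodeStates(s), ],
                 fractionRunsWithState(ens$trajectories, s))
  # final lattices agree
  finals <- t(vapply(ens$trajectories, function(tr) tr@states[51L, ],
                     integer(12)))
  expect_equal(ens$finalStates, finals)
  # per-run seeds are deterministic and distinct
  expect_equal(ens$seeds, runSeeds(7, 15))
  expect_false(anyDuplicated(ens$seeds) > 0)
})

test_that("formation ensembles spread bivalent occupancy outward", {
  cfg <- scenarioConfig("formation_localized", N = 40, n0 = 5, nRuns = 60,
                        nCycles = 1, seed = 5)
  cfg@params@stepsPerCycle <- 120L
  res <- runScenario(cfg)
  occ <- res$results[[1]]$occupancy
  ar <- stateOccupancy(occ, "AR")
  seeds <- seedSites(.initLat <- bivalentSim:::.initialLattice(cfg))
  flank <- c(min(seeds) - (2:1), max(seeds) + (1:2))
  # flanking sites start empty and gain bivalent occupancy
  expect_true(all(ar[flank, 1] == 0))
  expect_gt(mean(ar[flank, 120]), 0.1)
  # summary bookkeeping
  expect_equal(nrow(res$summary), 1L)
  expect_true(res$summary$finalARFraction >= 0 &&
              res$summary$finalARFraction <= 1)
})

test_that("sweeps reuse paired seeds across points", {
  cfg <- scenarioConfig("decay", N = 10, nRuns = 5, nCycles = 1, seed = 9,
                        sweep = list(axis = "kDmA", values = c(0.01, 0.03)))
  cfg@params@stepsPerCycle <- 20L
  res <- runScenario(cfg)
  expect_equal(nrow(res$summary), 2L)
  expect_equal(res$results[[1]]$seeds, res$results[[2]]$seeds)
})
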