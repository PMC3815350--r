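## Configuration files and run manifests.  Configs are nested YAML merged
## over documented defaults; every parameter the model exposes (including
## the ones the published analyses leave implicit: r, the A:R rate ratios,
## nucleation magnitude, detector thresholds) is a top-level key so that
## analyses can pin them explicitly.

.paramsToList <- function(p) {
  list(kMeA = p@kMeA, kMeR = p@kMeR, kDmA = p@kDmA, kDmR = p@kDmR,
       kExPlusA = as.numeric(p@kExPlusA), kExPlusR = as.numeric(p@kExPlusR),
       kExMinusA = p@kExMinusA, kExMinusR = p@kExMinusR,
       r = p@r, dtMinutes = p@dtMinutes, stepsPerCycle = p@stepsPerCycle,
       multiplicityUU = p@multiplicityUU,
       exchangeMultiplicity = p@exchangeMultiplicity,
       includeSelf = p@includeSelf)
}

.configDefaults <- function() {
  list(scenario = list(name = "formation_localized", latticeSize = 80L,
                       n0 = 5L, nRuns = NULL, nCycles = NULL, seed = 1L),
       params = .paramsToList(rateParams()),
       sweep = NULL,
       nucleation = list(sites = NULL, magnitude = 0.01))
}

.checkKnownKeys <- function(given, known, where) {
  unknown <- setdiff(names(given), known)
  if (length(unknown))
    stop("unknown config key(s) in '", where, "': ",
         paste(unknown, collapse = ", "))
}

#' Load a scenario configuration from YAML
#'
#' Merges the file's keys over the documented defaults (an empty file yields
#' the full default formation scenario: N = 80, 360 steps per cycle, r = 2,
#' kMeA = 0.046).  Unknown keys are errors; range violations are reported
#' with the offending key.  Sections: \code{scenario} (name, latticeSize, n0, nRuns,
#' nCycles, seed), \code{params} (all \code{\link{rateParams}} fields;
#' \code{kExPlusA}/\code{kExPlusR} may be per-site vectors), \code{sweep}
#' (axis, values) and \code{nucleation} (sites, magnitude; applied when the
#' scenario name is \code{"nucleation"}).
#'
#' @param path YAML file path.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  given <- yaml::read_yaml(path)
  if (is.null(given)) given <- list()
  if (!is.list(given)) stop("config must be a YAML mapping")
  def <- .configDefaults()
  .checkKnownKeys(given, names(def), "top level")
  for (sec in c("scenario", "params", "nucleation"))
    if (!is.null(given[[sec]]))
      .checkKnownKeys(given[[sec]], names(def[[sec]]), sec)
  if (!is.null(given$sweep))
    .checkKnownKeys(given$sweep, c("axis", "values"), "sweep")
  merged <- def
  for (sec in names(given)) {
    if (sec == "sweep") merged$sweep <- given$sweep
    else merged[[sec]] <- modifyList(merged[[sec]], given[[sec]])
  }

  pl <- merged$params
  badRange <- names(pl)[vapply(pl, function(v)
    is.numeric(v) && (anyNA(v)), logical(1))]
  if (length(badRange))
    stop("config key(s) with missing values in 'params': ",
         paste(badRange, collapse = ", "))
  params <- tryCatch(
    do.call(rateParams, pl),
    error = function(e) stop("invalid 'params' section: ",
                             conditionMessage(e), call. = FALSE))
  sc <- merged$scenario
  sweep <- if (is.null(merged$sweep)) NULL
           else list(axis = merged$sweep$axis,
                     values = as.numeric(merged$sweep$values))
  cfg <- scenarioConfig(
    name = sc$name, N = sc$latticeSize, n0 = sc$n0,
    nRuns = sc$nRuns, nCycles = sc$nCycles,
    params = if (is.null(given$params) && sc$name %in%
                 c("decay", "nucleation")) NULL else params,
    sweep = sweep, seed = sc$seed,
    nucleationSites = merged$nucleation$sites,
    nucleationMagnitude = merged$nucleation$magnitude)
  validObject(cfg)
  cfg
}

#' Save a scenario configuration as normalized YAML
#'
#' Writes the fully resolved configuration; \code{loadConfig(saveConfig(x))}
#' reproduces \code{x}.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param path output YAML path.
#' @return Invisibly, \code{path}.
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "ScenarioConfig"))
  out <- list(
    scenario = list(name = config@name, latticeSize = config@N,
                    n0 = config@n0, nRuns = config@nRuns,
                    nCycles = config@nCycles, seed = config@seed),
    params = .paramsToList(config@params))
  if (length(config@sweep))
    out$sweep <- list(axis = config@sweep$axis,
                      values = as.numeric(config@sweep$values))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed for exact replay of an output directory: the
#' resolved configuration, base and per-run seeds, package version, wall
#' time, and an inventory of output files with MD5 checksums.
#'
#' @param dir output directory.
#' @param config the \linkS4class{ScenarioConfig} that was run.
#' @param files character vector of produced file paths.
#' @param wallTime elapsed seconds.
#' @param file manifest path (default \code{<dir>/manifest.yaml}).
#' @return Invisibly, the manifest path.
#' @export
writeRunManifest <- function(dir, config, files, wallTime = NA_real_,
                             file = file.path(dir, "manifest.yaml")) {
  stopifnot(is(config, "ScenarioConfig"))
  inv <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  man <- list(
    package = "bivalentSim",
    version = as.character(packageVersion("bivalentSim")),
    wallTimeSeconds = wallTime,
    baseSeed = config@seed,
    runSeeds = runSeeds(config@seed, config@nRuns),
    scenario = list(name = config@name, latticeSize = config@N,
                    n0 = config@n0, nRuns = config@nRuns,
                    nCycles = config@nCycles),
    params = .paramsToList(config@params),
    sweep = if (length(config@sweep))
      list(axis = config@sweep$axis,
           values = as.numeric(config@sweep$values)) else NULL,
    files = inv)
  yaml::write_yaml(man, file)
  invisible(file)
}
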