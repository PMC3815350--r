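## Plain-text serialization: trajectory and occupancy TSV matrices with
## key-value metadata sidecars, sweep summary tables, and an optional
## bedGraph export mapping lattice sites to synthetic genomic intervals.

.writeMatrixTSV <- function(m, file, valueFormat = identity) {
  df <- data.frame(time = seq_len(nrow(m)) - 1L, valueFormat(m),
                   check.names = FALSE)
  colnames(df) <- c("time", paste0("site_", seq_len(ncol(m))))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a trajectory to TSV
#'
#' Rows are time steps (column \code{time}, 0-based), columns are sites,
#' values are state labels.  A key-value YAML sidecar records the seed, the
#' replication times and (when given) the rate parameters.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param file output TSV path.
#' @param params optional \linkS4class{RateParams} recorded in the sidecar.
#' @param metaFile sidecar path (default \code{<file>.meta.yaml}).
#' @return Invisibly, the paths written.
#' @export
writeTrajectory <- function(traj, file, params = NULL,
                            metaFile = paste0(file, ".meta.yaml")) {
  stopifnot(is(traj, "Trajectory"))
  lab <- matrix(decodeStates(traj@states), nrow = nrow(traj@states))
  .writeMatrixTSV(lab, file)
  meta <- list(seed = traj@seed,
               nSites = nSites(traj), nSteps = nSteps(traj),
               replicationTimes = as.integer(traj@replicationTimes))
  if (!is.null(params)) meta$params <- .paramsToList(params)
  yaml::write_yaml(meta, metaFile)
  invisible(c(file, metaFile))
}

#' Read a trajectory written by \code{writeTrajectory}
#'
#' @param file TSV path.
#' @param metaFile sidecar path (default \code{<file>.meta.yaml}).
#' @return A \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(file, metaFile = paste0(file, ".meta.yaml")) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  states <- matrix(encodeStates(as.vector(m)), nrow = nrow(m))
  meta <- if (file.exists(metaFile)) yaml::read_yaml(metaFile) else list()
  repl <- as.integer(meta$replicationTimes %||% integer(0))
  seed <- as.integer(meta$seed %||% NA_integer_)
  new("Trajectory", states = states, replicationTimes = repl, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ensemble occupancy matrices to TSV
#'
#' One TSV per state (\code{<prefix>_<state>.tsv}; rows = time steps,
#' columns = sites) plus a metadata sidecar \code{<prefix>_meta.yaml} with
#' the ensemble size and replication times.
#'
#' @param occ an \linkS4class{EnsembleOccupancy}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"occupancy"}).
#' @return Invisibly, the paths written.
#' @export
writeOccupancy <- function(occ, dir, prefix = "occupancy") {
  stopifnot(is(occ, "EnsembleOccupancy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in stateLabels()) {
    f <- file.path(dir, paste0(prefix, "_", s, ".tsv"))
    .writeMatrixTSV(t(stateOccupancy(occ, s)), f)
    paths <- c(paths, f)
  }
  metaFile <- file.path(dir, paste0(prefix, "_meta.yaml"))
  yaml::write_yaml(list(nRuns = occ@nRuns,
                        replicationTimes = as.integer(occ@replicationTimes)),
                   metaFile)
  invisible(c(paths, metaFile))
}

#' Read ensemble occupancy matrices written by \code{writeOccupancy}
#'
#' @param dir directory containing the TSVs.
#' @param prefix file-name prefix.
#' @return An \linkS4class{EnsembleOccupancy}.
#' @export
readOccupancy <- function(dir, prefix = "occupancy") {
  mats <- lapply(stateLabels(), function(s) {
    f <- file.path(dir, paste0(prefix, "_", s, ".tsv"))
    if (!file.exists(f)) stop("missing occupancy file: ", f)
    df <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
    t(as.matrix(df[, -1, drop = FALSE]))      # sites x times
  })
  N <- nrow(mats[[1]]); nT <- ncol(mats[[1]])
  occ <- array(0, dim = c(4L, N, nT),
               dimnames = list(state = stateLabels(), NULL, NULL))
  for (i in 1:4) occ[i, , ] <- mats[[i]]
  meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yaml")))
  new("EnsembleOccupancy", occupancy = occ,
      nRuns = as.integer(meta$nRuns %||% 1L),
      replicationTimes = as.integer(meta$replicationTimes %||% integer(0)))
}

#' Export a per-site profile as bedGraph
#'
#' Maps lattice site \code{i} to the synthetic genomic interval
#' \code{[(i - 1) * siteWidth, i * siteWidth)} on a synthetic contig, for
#' browser-style inspection of e.g. the final bivalent occupancy profile.
#'
#' @param profile numeric per-site values, or an
#'   \linkS4class{EnsembleOccupancy} (with \code{state}, \code{time} as in
#'   \code{\link{domainProfileStats}}).
#' @param file output bedGraph path.
#' @param siteWidth bases per nucleosome site (default 200).
#' @param seqname synthetic contig name (default \code{"sim_lattice"}).
#' @param state,time profile selection when \code{profile} is an ensemble
#'   occupancy.
#' @return Invisibly, the \code{GRanges} exported.
#' @export
exportBedGraph <- function(profile, file, siteWidth = 200L,
                           seqname = "sim_lattice", state = "AR",
                           time = NULL) {
  if (is(profile, "EnsembleOccupancy")) {
    if (is.null(time)) time <- nSteps(profile)
    profile <- stateOccupancy(profile, state)[, time + 1L]
  }
  n <- length(profile)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = (seq_len(n) - 1L) * siteWidth + 1L,
                              width = siteWidth),
    score = as.numeric(profile))
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(gr)
}

#' Write a sweep summary table
#'
#' @param summary the summary data.frame from \code{\link{runScenario}}.
#' @param file output TSV path.
#' @export
writeSweepSummary <- function(summary, file) {
  write.table(summary, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
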