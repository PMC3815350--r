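## State-space algebra for the nucleosome model.
##
## A nucleosome state is an unordered pair of H3 histone descriptors; each
## histone has an active slot (u/a) and a repressive slot (u/r).  The
## constrained models forbid a==active together with r==repressive on the
## same histone; the reduced model further drops the doubly-marked AA and RR
## states.

# descriptor of one histone: "A" (active mark), "R" (repressive mark),
# "U" (unmodified), "X" (forbidden a+r combination)
.histoneLabel <- function(active, repressive) {
  ifelse(active & repressive, "X",
         ifelse(active, "A", ifelse(repressive, "R", "U")))
}

# canonical pair label; histones ordered A < U < R so {A,U}->"AU",
# {U,R}->"UR", {A,R}->"AR"
.pairLabel <- function(h1, h2) {
  rank <- c(A = 1L, U = 2L, R = 3L, X = 4L)
  swap <- rank[h1] > rank[h2]
  paste0(ifelse(swap, h2, h1), ifelse(swap, h1, h2))
}

.rawStateTable <- function() {
  g <- expand.grid(h1Active = c(FALSE, TRUE), h1Repressive = c(FALSE, TRUE),
                   h2Active = c(FALSE, TRUE), h2Repressive = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE)
  h1 <- .histoneLabel(g$h1Active, g$h1Repressive)
  h2 <- .histoneLabel(g$h2Active, g$h2Repressive)
  g$label <- ifelse(h1 == "X" | h2 == "X", NA_character_, .pairLabel(h1, h2))
  g
}

#' Enumerate nucleosome states
#'
#' Enumerates the nucleosome state space of the model variants.
#' \code{"raw_ordered"} lists every ordered assignment of the four binary
#' modification sites (two slots on each of the two H3 copies).
#' \code{"six_state"} applies the same-histone exclusion (a histone cannot
#' carry an active and a repressive mark simultaneously) and identifies
#' states that differ only by interchanging the two histones.
#' \code{"four_state"} additionally removes the doubly-marked AA and RR
#' states, leaving the reduced model alphabet \{UU, AU, UR, AR\}.
#'
#' The six- and four-state sets are computed by filtering and deduplicating
#' the raw enumeration, not hard-coded, so the state counts are genuine
#' consequences of the constraints.
#'
#' @param model one of \code{"raw_ordered"}, \code{"six_state"},
#'   \code{"four_state"}.
#' @return A data.frame with logical columns \code{h1Active, h1Repressive,
#'   h2Active, h2Repressive} (a representative ordered assignment) and a
#'   \code{label} column (\code{NA} in the raw enumeration where a histone
#'   violates the exclusion constraint).
#' @export
#' @examples
#' nrow(enumerateStates("raw_ordered"))  # 16
#' enumerateStates("six_state")$label    # UU AU UR AR AA RR (some order)
#' enumerateStates("four_state")$label
enumerateStates <- function(model = c("six_state", "four_state", "raw_ordered")) {
  if (length(model) != 1L || !model %in% c("six_state", "four_state", "raw_ordered"))
    stop("unknown model '", paste(model, collapse = ","),
         "'; expected one of raw_ordered, six_state, four_state")
  raw <- .rawStateTable()
  if (model == "raw_ordered") return(raw)
  valid <- raw[!is.na(raw$label), ]
  dedup <- valid[!duplicated(valid$label), ]
  rownames(dedup) <- NULL
  if (model == "four_state")
    dedup <- dedup[!dedup$label %in% c("AA", "RR"), ]
  rownames(dedup) <- NULL
  dedup
}

# the four modification-site bits of both histone orderings of a state row
.siteBits <- function(row) {
  rbind(c(row$h1Active, row$h1Repressive, row$h2Active, row$h2Repressive),
        c(row$h2Active, row$h2Repressive, row$h1Active, row$h1Repressive))
}

# minimal number of differing modification sites between two unordered states
.siteDistance <- function(rowA, rowB) {
  a <- .siteBits(rowA)[1, ]
  b <- .siteBits(rowB)
  min(sum(a != b[1, ]), sum(a != b[2, ]))
}

#' Enumerate single-site transitions
#'
#' Lists every ordered pair of distinct states that differ in exactly one of
#' the four modification sites (the small-time-step assumption: at most one
#' site changes per step), with histone interchange taken into account.
#'
#' @param states a state table from \code{\link{enumerateStates}}
#'   (\code{six_state} or \code{four_state}); rows with \code{NA} labels are
#'   ignored.
#' @return A data.frame with columns \code{from}, \code{to},
#'   \code{changedSites} (always 1); zero rows when no pair qualifies.
#' @export
#' @examples
#' nrow(enumerateTransitions(enumerateStates("six_state")))   # 12
#' nrow(enumerateTransitions(enumerateStates("four_state")))  # 8
enumerateTransitions <- function(states) {
  states <- states[!is.na(states$label), , drop = FALSE]
  n <- nrow(states)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (.siteDistance(states[i, ], states[j, ]) == 1L)
        out[[length(out) + 1L]] <- data.frame(
          from = states$label[i], to = states$label[j], changedSites = 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(from = character(), to = character(),
                      changedSites = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Does a state carry a given mark?
#'
#' A state carries the active mark iff at least one histone has its active
#' slot modified (AU, AR, AA); repressive analogously (UR, AR, RR).  The
#' bivalent AR state carries both.
#'
#' @param labels character vector of state labels.
#' @param mark \code{"A"} or \code{"R"}.
#' @return logical vector.
#' @export
#' @examples
#' carriesMark(c("AR", "UU", "AU"), "A")  # TRUE FALSE TRUE
carriesMark <- function(labels, mark = c("A", "R")) {
  mark <- match.arg(mark)
  six <- enumerateStates("six_state")
  col <- if (mark == "A") six$h1Active | six$h2Active
         else six$h1Repressive | six$h2Repressive
  idx <- match(labels, six$label)
  if (anyNA(idx)) stop("unknown state label(s): ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  col[idx]
}

#' Mirror state labels under the active/repressive relabeling
#'
#' Exchanging the roles of active and repressive marks maps AU to UR, AA to
#' RR and vice versa, and fixes AR and UU.  The model's transition structure
#' is invariant under this relabeling.
#'
#' @param labels character vector of state labels.
#' @return character vector of mirrored labels.
#' @export
mirrorStateLabels <- function(labels) {
  map <- c(AU = "UR", UR = "AU", AR = "AR", UU = "UU", AA = "RR", RR = "AA")
  out <- map[labels]
  if (anyNA(out)) stop("unknown state label(s)")
  unname(out)
}
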