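#' @include AllClasses.R
NULL

# position convention: rot taken modulo 360 into [0, 360), then
# round(rot/60) mod 6.  NA rot -> NA position.
.positionFromRot <- function(rot_deg) {
  r <- rot_deg %% 360
  as.integer(round(r / 60) %% 6)
}

#' Construct a ProtomerTable from a record data.frame
#'
#' Convenience constructor used by the simulator and tests.  Unsupplied
#' optional columns are filled with NA/UNASSIGNED.
#'
#' @param records data.frame with at least \code{particle_id} and
#'   \code{class_id}.
#' @param symmetryGroup "C1", "C6" or "D6".
#' @param provenance free text.
#' @return a [ProtomerTable]
#' @export
ProtomerTable <- function(records, symmetryGroup = "C1", provenance = "") {
  n <- nrow(records)
  records$particle_id <- as.character(records$particle_id)
  records$class_id <- as.integer(records$class_id)
  if (is.null(records$state)) records$state <- rep("UNASSIGNED", n)
  if (is.null(records$rot_deg)) records$rot_deg <- rep(NA_real_, n)
  if (is.null(records$tilt_flipped)) records$tilt_flipped <- rep(NA, n)
  if (is.null(records$hemichannel_index))
    records$hemichannel_index <- ifelse(is.na(records$tilt_flipped),
                                        NA_integer_,
                                        as.integer(records$tilt_flipped))
  if (is.null(records$position_index))
    records$position_index <- .positionFromRot(records$rot_deg)
  new("ProtomerTable", records = records, symmetryGroup = symmetryGroup,
      provenance = provenance)
}

#' Construct a class-to-state map
#'
#' @param PLN,FN,OTHER integer vectors of 3D-class ids assigned to each
#'   conformational state.  The default is the eight-class protomer-focused
#'   classification of the wild-type nanodisc dataset: classes 1-4 and 7 show
#'   the pore-lining N-terminal helix (PLN), classes 5, 6 and 8 the flexible
#'   one (FN).
#' @return a [ClassStateMap]
#' @examples
#' ClassStateMap()                          # the default 8-class map
#' ClassStateMap(PLN = 1:2, FN = 3, OTHER = 4)
#' @export
ClassStateMap <- function(PLN = c(1L, 2L, 3L, 4L, 7L),
                          FN = c(5L, 6L, 8L), OTHER = integer()) {
  ids <- c(PLN, FN, OTHER)
  if (anyDuplicated(ids)) stop("a class id may map to only one state")
  mapping <- setNames(
    c(rep("PLN", length(PLN)), rep("FN", length(FN)),
      rep("OTHER", length(OTHER))),
    as.character(ids))
  new("ClassStateMap", mapping = mapping)
}

#' Symmetry-expand an unexpanded particle table
#'
#' Replicates every particle record under each rotation of the point group,
#' as done before per-protomer focused classification.  D6 produces 12 copies
#' per particle (in-plane rotations 0, 60, ..., 300 degrees for each of the
#' two hemichannels); C6 produces 6 copies, all in hemichannel 0.  The
#' position and hemichannel indices are set from the rotation offset and the
#' flip flag.
#'
#' @param table an unexpanded [ProtomerTable] (one record per particle id).
#' @param group \code{"C6"} or \code{"D6"}.
#' @return the expanded [ProtomerTable]
#' @examples
#' tab <- ProtomerTable(data.frame(particle_id = "p1", class_id = 1L))
#' expandSymmetry(tab, "D6")     # 12 records
#' @export
expandSymmetry <- function(table, group = c("D6", "C6")) {
  stopifnot(is(table, "ProtomerTable"))
  group <- match.arg(group)
  rec <- records(table)
  if (!nrow(rec)) stop("cannot expand an empty table")
  if (anyDuplicated(rec$particle_id))
    stop("input already expanded: duplicate particle_id present; ",
         "expandSymmetry requires one record per particle")
  base_rot <- ifelse(is.na(rec$rot_deg), 0, rec$rot_deg)
  offsets <- seq(0, 300, by = 60)
  flips <- if (group == "D6") c(FALSE, TRUE) else FALSE
  grid <- expand.grid(offset = offsets, flip = flips)
  idx <- rep(seq_len(nrow(rec)), each = nrow(grid))
  out <- rec[idx, , drop = FALSE]
  out$rot_deg <- (base_rot[idx] + rep(grid$offset, nrow(rec))) %% 360
  out$tilt_flipped <- rep(grid$flip, nrow(rec))
  out$hemichannel_index <- as.integer(out$tilt_flipped)
  out$position_index <- .positionFromRot(out$rot_deg)
  rownames(out) <- NULL
  new("ProtomerTable", records = out,
      symmetryGroup = group,
      provenance = paste0(table@provenance, " + expandSymmetry(", group, ")"))
}

#' Assign conformational states from 3D-class labels
#'
#' Every record's class id is looked up in the map; classes absent from the
#' map are labelled \code{UNASSIGNED}.  Per-state record counts are reported
#' as a message and attached as an attribute.
#'
#' @param table a [ProtomerTable] with class ids.
#' @param map a [ClassStateMap].
#' @param verbose report per-state counts (default TRUE).
#' @return the table with the \code{state} column set; attribute
#'   \code{stateCounts} holds the per-state tally.
#' @export
assignStates <- function(table, map, verbose = TRUE) {
  stopifnot(is(table, "ProtomerTable"), is(map, "ClassStateMap"))
  if (!length(map@mapping)) stop("empty class-state map")
  rec <- records(table)
  st <- unname(map@mapping[as.character(rec$class_id)])
  st[is.na(st)] <- "UNASSIGNED"
  rec$state <- st
  out <- new("ProtomerTable", records = rec,
             symmetryGroup = table@symmetryGroup,
             provenance = table@provenance)
  counts <- table(factor(st, levels = .STATE_LEVELS))
  if (verbose)
    message("assignStates: ",
            paste(names(counts), counts, sep = "=", collapse = " "))
  attr(out, "stateCounts") <- counts
  out
}

.STATE_CHAR <- c(PLN = "P", FN = "F", OTHER = "O", UNASSIGNED = "U")

#' Collapse protomer records into per-particle compositions
#'
#' Traces symmetry-expanded records back to their parent particles.
#' Redundant records (same particle id, hemichannel and ring position) are
#' removed first and the removal count reported.  Each complete particle
#' yields state counts and one ring string per hemichannel, ordered by ring
#' position.  Particles whose record multiplicity does not equal the
#' symmetry-group order after deduplication are excluded and listed.
#'
#' @param table an expanded [ProtomerTable] with states assigned and
#'   position/hemichannel indices set.
#' @param verbose report dedup/exclusion counts (default TRUE).
#' @param foldOtherIntoFN relabel OTHER protomers as FN before counting, so
#'   third states enter the binary FN:PLN statistics on the FN side
#'   (default FALSE: OTHER is carried as its own label and the binary
#'   summaries refuse it).
#' @return a [CompositionSet]
#' @export
groupByParticle <- function(table, verbose = TRUE, foldOtherIntoFN = FALSE) {
  stopifnot(is(table, "ProtomerTable"))
  sym <- symmetryGroup(table)
  order_needed <- .SYMMETRY_ORDER[[sym]]
  if (order_needed < 6L)
    stop("groupByParticle needs an expanded (C6 or D6) table; ",
         "run expandSymmetry first")
  rec <- records(table)
  if (anyNA(rec$position_index) || anyNA(rec$hemichannel_index))
    stop("position/hemichannel indices unset; run expandSymmetry ",
         "or read a table with rotation angles")
  if (foldOtherIntoFN) rec$state[rec$state == "OTHER"] <- "FN"

  key <- paste(rec$particle_id, rec$hemichannel_index, rec$position_index,
               sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]

  ids <- unique(rec$particle_id)
  mult <- table(rec$particle_id)[ids]
  incomplete <- ids[mult != order_needed]
  keep <- !(rec$particle_id %in% incomplete)
  rec <- rec[keep, , drop = FALSE]
  ids <- setdiff(ids, incomplete)

  if (verbose) {
    if (n_dup) message("groupByParticle: removed ", n_dup,
                       " redundant record(s)")
    if (length(incomplete))
      message("groupByParticle: excluded ", length(incomplete),
              " particle(s) with record multiplicity != ", order_needed)
  }

  if (!nrow(rec)) {
    comp <- data.frame(particle_id = character(), n_PLN = integer(),
                       n_FN = integer(), n_OTHER = integer(),
                       n_UNASSIGNED = integer(), k_PLN = integer(),
                       ring1 = character(), ring2 = character(),
                       stringsAsFactors = FALSE)
    return(new("CompositionSet", compositions = comp, symmetryGroup = sym,
               nDuplicatesRemoved = as.integer(n_dup),
               incompleteParticles = as.character(incomplete)))
  }

  # order records so each particle's copies line up as
  # hemichannel 0 positions 0..5, then hemichannel 1 positions 0..5
  o <- order(rec$particle_id, rec$hemichannel_index, rec$position_index)
  rec <- rec[o, , drop = FALSE]
  st_char <- .STATE_CHAR[rec$state]
  m <- matrix(st_char, ncol = order_needed, byrow = TRUE)
  pid <- rec$particle_id[seq(1, nrow(rec), by = order_needed)]

  ring1 <- apply(m[, 1:6, drop = FALSE], 1, paste, collapse = "")
  ring2 <- if (order_needed == 12L)
    apply(m[, 7:12, drop = FALSE], 1, paste, collapse = "")
  else rep(NA_character_, length(pid))

  count_state <- function(ch) as.integer(rowSums(m == ch))
  comp <- data.frame(
    particle_id = pid,
    n_PLN = count_state("P"),
    n_FN = count_state("F"),
    n_OTHER = count_state("O"),
    n_UNASSIGNED = count_state("U"),
    ring1 = ring1, ring2 = ring2,
    stringsAsFactors = FALSE)
  comp$k_PLN <- comp$n_PLN
  new("CompositionSet", compositions = comp, symmetryGroup = sym,
      nDuplicatesRemoved = as.integer(n_dup),
      incompleteParticles = as.character(incomplete))
}

#' Select conformationally hetero-junctional particles
#'
#' A hemichannel belongs to the PLN group when at least \code{threshold} of
#' its six protomers are in the PLN state, and to the FN group when at least
#' \code{threshold} are FN.  A particle is hetero-junctional when its two
#' hemichannels fall in the two different groups; the selection is symmetric
#' under swapping the hemichannels.  The default threshold of 6 requires
#' conformationally pure rings.
#'
#' @param compSet a [CompositionSet] from a D6-expanded table.
#' @param threshold minimum protomers (out of 6) defining a hemichannel
#'   group; integer in 4..6 (a majority below 4 would let a ring qualify for
#'   both groups).
#' @return character vector of selected particle ids
#' @export
selectHeteroJunctional <- function(compSet, threshold = 6L) {
  stopifnot(is(compSet, "CompositionSet"))
  threshold <- as.integer(threshold)
  if (threshold < 4L || threshold > 6L)
    stop("threshold must be in 4..6")
  comp <- compositions(compSet)
  if (symmetryGroup(compSet) != "D6" || all(is.na(comp$ring2)))
    stop("hetero-junctional selection needs both hemichannel rings (D6)")
  grp <- function(ring) {
    nP <- nchar(gsub("[^P]", "", ring))
    nF <- nchar(gsub("[^F]", "", ring))
    ifelse(nP >= threshold, "PLN", ifelse(nF >= threshold, "FN", NA))
  }
  g1 <- grp(comp$ring1)
  g2 <- grp(comp$ring2)
  sel <- !is.na(g1) & !is.na(g2) & g1 != g2
  comp$particle_id[sel]
}
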