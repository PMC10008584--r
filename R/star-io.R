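#' @include AllClasses.R
NULL

# ---- low-level STAR parsing (RELION-3.1 dialect) -------------------------

.star_tokenize <- function(line) {
  strsplit(trimws(line), "[ \t]+")[[1]]
}

# Parse a STAR file into a named list of data.frames (one per data_ block).
# Columns that look numeric are converted; loop-free key-value blocks become
# one-row data.frames.  Errors carry the offending line number.
.parseStar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  current_block <- NULL

  next_content <- function(i) {
    while (i <= n) {
      lt <- trimws(lines[i])
      if (nzchar(lt) && !startsWith(lt, "#")) return(i)
      i <- i + 1L
    }
    i
  }

  while ((i <- next_content(i)) <= n) {
    lt <- trimws(lines[i])
    if (!startsWith(lt, "data_"))
      stop("STAR parse error at line ", i,
           ": expected a data_ block header, got '", lt, "'")
    block_name <- sub("^data_", "", lt)
    i <- i + 1L
    i <- next_content(i)
    cols <- character()
    rows <- list()
    kv <- list()
    if (i <= n && trimws(lines[i]) == "loop_") {
      i <- i + 1L
      while ((i <- next_content(i)) <= n && startsWith(trimws(lines[i]), "_")) {
        cols <- c(cols, sub("^_([^ \t#]+).*$", "\\1", trimws(lines[i])))
        i <- i + 1L
      }
      if (!length(cols))
        stop("STAR parse error at line ", i, ": loop_ without column labels")
      while (i <= n) {
        lt <- trimws(lines[i])
        if (!nzchar(lt) || startsWith(lt, "data_")) break
        if (startsWith(lt, "#")) { i <- i + 1L; next }
        fields <- .star_tokenize(lt)
        if (length(fields) != length(cols))
          stop("STAR parse error at line ", i, ": expected ",
               length(cols), " fields, found ", length(fields))
        rows[[length(rows) + 1L]] <- fields
        i <- i + 1L
      }
      if (length(rows)) {
        mat <- do.call(rbind, rows)
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- cols
      } else {
        df <- as.data.frame(setNames(rep(list(character()), length(cols)),
                                     cols))
      }
    } else {
      # key-value block
      while (i <= n) {
        lt <- trimws(lines[i])
        if (!nzchar(lt) || startsWith(lt, "data_")) break
        if (startsWith(lt, "#")) { i <- i + 1L; next }
        if (!startsWith(lt, "_"))
          stop("STAR parse error at line ", i,
               ": expected '_key value' pair in block data_", block_name)
        fields <- .star_tokenize(lt)
        kv[[sub("^_", "", fields[1])]] <- paste(fields[-1], collapse = " ")
        i <- i + 1L
      }
      df <- as.data.frame(kv, stringsAsFactors = FALSE)
    }
    # type conversion: all-numeric columns become numeric
    for (cn in names(df)) {
      v <- df[[cn]]
      if (length(v) && !anyNA(suppressWarnings(as.numeric(v))))
        df[[cn]] <- as.numeric(v)
    }
    blocks[[block_name]] <- df
  }
  blocks
}

.format_star_value <- function(v) {
  if (is.numeric(v)) {
    out <- vapply(v, function(x) {
      if (is.na(x)) return("NA")
      if (x == round(x) && abs(x) < 1e15) sprintf("%d", as.integer(x))
      else format(x, digits = 12, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  } else as.character(v)
}

.writeStarBlock <- function(con, name, df) {
  writeLines(c("# version 30001", "", paste0("data_", name), "", "loop_"),
             con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  if (nrow(df)) {
    cols <- lapply(df, .format_star_value)
    cols <- lapply(cols, formatC, flag = "-")
    writeLines(do.call(paste, c(cols, sep = " ")), con)
  }
  writeLines("", con)
}

.default_optics <- function() {
  data.frame(
    rlnOpticsGroup = 1,
    rlnOpticsGroupName = "opticsGroup1",
    rlnVoltage = 300,
    rlnSphericalAberration = 2.7,
    rlnAmplitudeContrast = 0.1,
    rlnImagePixelSize = 1.0,
    rlnImageSize = 360,
    rlnImageDimensionality = 2,
    stringsAsFactors = FALSE
  )
}

# ---- user-facing readers/writers -----------------------------------------

.RLN_MAP <- c(particle_id = "rlnImageName", class_id = "rlnClassNumber",
              rot_deg = "rlnAngleRot", state = "connexonState")

#' Read a RELION-3.1 STAR particle table
#'
#' Reads a STAR file with \code{data_optics}/\code{data_particles} blocks
#' into a [ProtomerTable].  Particle identity is the \code{rlnImageName}
#' string, the 3D class is \code{rlnClassNumber}, and the in-plane expansion
#' rotation (when present) is \code{rlnAngleRot}.  The hemichannel flip of a
#' D6-expanded record is encoded in \code{rlnAngleTilt}: tilt > 90 degrees
#' marks the copy expanded into the opposite hemichannel.  All other columns
#' are preserved for round-tripping.
#'
#' The symmetry group of the table is inferred from the particle-id
#' multiplicity (12 per id = D6, 6 = C6, otherwise C1/unexpanded).
#'
#' @param path STAR file path.
#' @param blockName name of the particles block (default
#'   \code{"particles"}; the first block containing \code{rlnImageName} is
#'   used as fallback).
#' @return a [ProtomerTable]
#' @examples
#' tab <- simulateMetadata(nParticles = 5, pPLN = 0.5, seed = 1)$table
#' f <- tempfile(fileext = ".star")
#' writeStar(tab, f)
#' readStar(f)
#' @export
readStar <- function(path, blockName = "particles") {
  if (!file.exists(path)) stop("file not found: ", path)
  blocks <- .parseStar(path)
  if (!length(blocks)) stop("STAR format error: no data blocks in ", path)
  part <- blocks[[blockName]]
  if (is.null(part)) {
    hit <- which(vapply(blocks, function(b) "rlnImageName" %in% names(b),
                        logical(1)))
    if (!length(hit))
      stop("STAR format error: missing mandatory column rlnImageName ",
           "in every block of ", path)
    part <- blocks[[hit[1]]]
  }
  for (col in c("rlnImageName", "rlnClassNumber"))
    if (!col %in% names(part))
      stop("STAR format error: missing mandatory column ", col)

  rec <- data.frame(particle_id = as.character(part$rlnImageName),
                    class_id = as.integer(part$rlnClassNumber),
                    stringsAsFactors = FALSE)
  rec$state <- if ("connexonState" %in% names(part))
    as.character(part$connexonState) else rep("UNASSIGNED", nrow(part))
  rec$rot_deg <- if ("rlnAngleRot" %in% names(part))
    as.numeric(part$rlnAngleRot) else rep(NA_real_, nrow(part))
  tilt <- if ("rlnAngleTilt" %in% names(part))
    as.numeric(part$rlnAngleTilt) else rep(NA_real_, nrow(part))
  rec$tilt_flipped <- !is.na(tilt) & tilt > 90
  rec$hemichannel_index <- ifelse(is.na(tilt), NA_integer_,
                                  as.integer(rec$tilt_flipped))
  rec$position_index <- .positionFromRot(rec$rot_deg)

  extra <- setdiff(names(part),
                   c(.RLN_MAP, "rlnAngleTilt"))
  for (cn in extra) rec[[cn]] <- part[[cn]]

  mult <- table(rec$particle_id)
  sym <- if (length(mult) && all(mult == 12L)) "D6"
         else if (length(mult) && all(mult == 6L)) "C6" else "C1"
  new("ProtomerTable", records = rec, symmetryGroup = sym,
      provenance = paste0("readStar(", path, ")"))
}

#' Write a ProtomerTable as a RELION-3.1 STAR file
#'
#' Emits \code{data_optics} and \code{data_particles} blocks.  Core fields
#' map to \code{rlnImageName}, \code{rlnClassNumber}, \code{rlnAngleRot} and
#' \code{rlnAngleTilt} (0/180 encoding the hemichannel flip); assigned states
#' travel in a \code{connexonState} column; preserved extra columns are
#' written back verbatim.
#'
#' @param table a non-empty [ProtomerTable]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeStar <- function(table, path) {
  stopifnot(is(table, "ProtomerTable"))
  rec <- records(table)
  if (!nrow(rec)) stop("refusing to write an empty ProtomerTable")
  part <- data.frame(rlnImageName = rec$particle_id,
                     rlnClassNumber = as.integer(rec$class_id),
                     stringsAsFactors = FALSE)
  if (!is.null(rec$rot_deg) && !all(is.na(rec$rot_deg)))
    part$rlnAngleRot <- rec$rot_deg
  if (!is.null(rec$tilt_flipped) && !all(is.na(rec$hemichannel_index)))
    part$rlnAngleTilt <- ifelse(rec$tilt_flipped, 180, 0)
  if (!is.null(rec$state) && any(rec$state != "UNASSIGNED"))
    part$connexonState <- rec$state
  extra <- setdiff(names(rec),
                   c("particle_id", "class_id", "state", "rot_deg",
                     "tilt_flipped", "hemichannel_index", "position_index"))
  for (cn in extra) part[[cn]] <- rec[[cn]]
  if (!"rlnOpticsGroup" %in% names(part)) part$rlnOpticsGroup <- 1

  con <- file(path, open = "wt")
  on.exit(close(con))
  .writeStarBlock(con, "optics", .default_optics())
  .writeStarBlock(con, "particles", part)
  invisible(path)
}
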