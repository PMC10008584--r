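#' @include AllClasses.R
NULL

# Bondi-style van der Waals radii (Angstrom); unknown elements fall back to
# the carbon radius with a warning
.VDW_TABLE <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90, FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31,
                "NA" = 2.27, K = 2.75)
.VDW_DEFAULT <- 1.70

.assignVdw <- function(element, table = .VDW_TABLE) {
  el <- toupper(element)
  r <- unname(table[el])
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using default radius ", .VDW_DEFAULT, " A")
    r[is.na(r)] <- .VDW_DEFAULT
  }
  r
}

.WATER_RESID <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")

#' Load an atomic structure for pore profiling
#'
#' Reads a PDB or mmCIF file (via the bio3d parsers), keeps heavy atoms, and
#' assigns van der Waals radii from a Bondi-style table (unknown elements get
#' the carbon radius of 1.7 A with a warning).  Waters and HETATM ligands are
#' excluded by default.
#'
#' @param path PDB (\code{.pdb}) or mmCIF (\code{.cif}) file.
#' @param includeWaters keep water molecules (default FALSE).
#' @param includeHetero keep non-water HETATM records (default FALSE).
#' @param keepHydrogens keep hydrogen atoms (default FALSE).
#' @param radiusTable named vector of per-element radii overriding the
#'   default table.
#' @return an [AtomSet]
#' @export
loadStructure <- function(path, includeWaters = FALSE,
                          includeHetero = FALSE, keepHydrogens = FALSE,
                          radiusTable = .VDW_TABLE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- substr(trimws(at$elety), 1, 1)
  el <- toupper(trimws(el))
  keep <- rep(TRUE, nrow(at))
  if (!keepHydrogens) keep <- keep & el != "H" & el != "D"
  is_water <- toupper(at$resid) %in% .WATER_RESID
  if (!includeWaters) keep <- keep & !is_water
  if (!includeHetero) keep <- keep & (at$type == "ATOM" | is_water)
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  new("AtomSet",
      coords = cbind(at$x, at$y, at$z),
      radius = .assignVdw(el, radiusTable),
      element = el,
      chain = as.character(at$chain),
      resid = as.character(at$resid),
      resno = as.integer(at$resno))
}

#' Construct an AtomSet from coordinates
#'
#' @param coords n-by-3 matrix, Angstrom.
#' @param radius per-atom vdW radii (recycled if scalar).
#' @param element,chain,resid,resno optional bookkeeping.
#' @return an [AtomSet]
#' @export
AtomSet <- function(coords, radius, element = "C", chain = "A",
                    resid = "UNK", resno = seq_len(nrow(coords))) {
  n <- nrow(coords)
  new("AtomSet", coords = as.matrix(coords),
      radius = rep_len(radius, n), element = rep_len(element, n),
      chain = rep_len(chain, n), resid = rep_len(resid, n),
      resno = as.integer(rep_len(resno, n)))
}

#' Write an AtomSet as a PDB file
#'
#' @param atoms an [AtomSet].
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeAtomsPDB <- function(atoms, path) {
  stopifnot(is(atoms, "AtomSet"))
  n <- nrow(atoms@coords)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(atoms@coords)),
                   resno = atoms@resno,
                   resid = atoms@resid,
                   chain = atoms@chain,
                   elety = atoms@element,
                   elesy = atoms@element)
  invisible(path)
}

# clearance of a sphere centred at (cx, cy, z): distance to the nearest vdW
# surface; +Inf when no atoms are given
.clearance <- function(cx, cy, z, coords, radius) {
  if (!nrow(coords)) return(Inf)
  d <- sqrt((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2 +
              (coords[, 3] - z)^2) - radius
  min(d)
}

#' Inscribed-sphere pore-radius profile along the z axis
#'
#' HOLE-style profiler restricted to a straight axis: at each z sample the
#' in-plane centre (cx, cy) is optimised to maximise the radius of the
#' largest sphere centred at (cx, cy, z) that overlaps no atom's van der
#' Waals sphere.  Optimisation is multi-start Nelder-Mead seeded on the axis
#' and on a coarse in-plane grid; atoms further than \code{cutoff} from the
#' sample plane are ignored.  Where no atom lies within the cutoff the
#' radius is capped at \code{rMax} and flagged unconstrained.
#'
#' @param atoms an [AtomSet].
#' @param zRange length-2 numeric, axial range to sample (default: the
#'   structure's z extent).
#' @param step axial sampling step, Angstrom (default 1).
#' @param axisXY in-plane position of the nominal pore axis (default the
#'   coordinate centroid).
#' @param rMax radius cap, Angstrom (default 20).
#' @param cutoff axial atom-culling cutoff, Angstrom (default 15).
#' @param nStarts number of coarse-grid starts besides the axis (default 4).
#' @return a [PoreProfile]
#' @export
poreProfile <- function(atoms, zRange = NULL, step = 1, axisXY = NULL,
                        rMax = 20, cutoff = 15, nStarts = 4L) {
  stopifnot(is(atoms, "AtomSet"))
  if (step <= 0) stop("step must be positive")
  co <- atoms@coords
  if (!nrow(co)) stop("empty AtomSet")
  if (is.null(zRange)) zRange <- range(co[, 3])
  if (is.null(axisXY)) axisXY <- colMeans(co[, 1:2, drop = FALSE])
  zs <- seq(zRange[1], zRange[2], by = step)

  starts <- rbind(c(0, 0),
                  cbind(2 * cos(2 * pi * seq_len(nStarts) / nStarts),
                        2 * sin(2 * pi * seq_len(nStarts) / nStarts)))
  starts <- sweep(starts, 2, axisXY, "+")

  n <- length(zs)
  rad <- cx <- cy <- numeric(n)
  unflag <- logical(n)
  for (i in seq_len(n)) {
    z <- zs[i]
    sel <- abs(co[, 3] - z) <= cutoff
    sub <- co[sel, , drop = FALSE]
    vr <- atoms@radius[sel]
    if (!nrow(sub)) {
      rad[i] <- rMax; cx[i] <- axisXY[1]; cy[i] <- axisXY[2]
      unflag[i] <- TRUE
      next
    }
    best <- c(-Inf, axisXY)
    for (s in seq_len(nrow(starts))) {
      fit <- optim(starts[s, ], function(par)
        -.clearance(par[1], par[2], z, sub, vr),
        method = "Nelder-Mead",
        control = list(reltol = 1e-10, maxit = 500))
      if (-fit$value > best[1]) best <- c(-fit$value, fit$par)
    }
    rad[i] <- min(max(best[1], 0), rMax)
    cx[i] <- best[2]; cy[i] <- best[3]
  }
  new("PoreProfile", z = zs, radius = rad, cx = cx, cy = cy,
      rMax = rMax, unconstrained = unflag)
}

#' Minimum constriction diameter of a pore profile
#'
#' Twice the smallest pore radius over the requested axial window.
#'
#' @param profile a [PoreProfile].
#' @param zWindow length-2 numeric window; default the whole sampled range.
#' @return diameter in Angstrom
#' @export
minConstrictionDiameter <- function(profile, zWindow = NULL) {
  stopifnot(is(profile, "PoreProfile"))
  if (is.null(zWindow)) zWindow <- range(profile@z)
  sel <- profile@z >= zWindow[1] & profile@z <= zWindow[2]
  if (!any(sel)) stop("empty z window: no profile samples inside")
  2 * min(profile@radius[sel])
}

#' Pore profile as a data.frame
#'
#' @param profile a [PoreProfile].
#' @return data.frame with columns z, radius, cx, cy, unconstrained
#' @export
profileTable <- function(profile) {
  stopifnot(is(profile, "PoreProfile"))
  data.frame(z = profile@z, radius = profile@radius, cx = profile@cx,
             cy = profile@cy, unconstrained = profile@unconstrained)
}
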