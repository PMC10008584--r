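#' @include AllClasses.R
NULL

#' Construct an IonTrajectory
#'
#' @param x,y,z frames-by-ions coordinate matrices, Angstrom.
#' @param species per-ion species labels.
#' @param charge per-ion signed charges, elementary units.
#' @param dt ps between stored frames.
#' @param box box edge lengths (x, y, z), Angstrom; z is periodic.
#' @param voltage applied voltage along z, mV.
#' @param temperature K.
#' @return an [IonTrajectory]
#' @export
IonTrajectory <- function(x, y, z, species, charge, dt, box,
                          voltage = 0, temperature = 300) {
  new("IonTrajectory", x = as.matrix(x), y = as.matrix(y),
      z = as.matrix(z), species = as.character(species),
      charge = as.numeric(charge), dt = as.numeric(dt),
      box = as.numeric(box), voltage = as.numeric(voltage),
      temperature = as.numeric(temperature))
}

#' @describeIn IonTrajectory trajectory duration in ns
#' @param traj an IonTrajectory
#' @export
trajectoryDuration <- function(traj) {
  stopifnot(is(traj, "IonTrajectory"))
  (nrow(traj@z) - 1L) * traj@dt / 1000
}

#' Read an ion trajectory from columnar text
#'
#' The columnar contract is a whitespace-separated text file with a header
#' line \code{frame ion_id species x y z} and one row per ion per frame;
#' electrical metadata travel in \code{#key value} comment lines
#' (\code{dt_ps}, \code{box_x}, \code{box_y}, \code{box_z}, \code{voltage_mV},
#' \code{temperature_K}, and \code{charge_<species>} entries).
#'
#' @param path file path.
#' @return an [IonTrajectory]
#' @seealso [writeTrajectory()]
#' @export
readTrajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    tok <- strsplit(sub("^#\\s*", "", ml), "[ \t]+")[[1]]
    if (length(tok) >= 2) meta[[tok[1]]] <- tok[2]
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, stringsAsFactors = FALSE,
                          na.strings = character(0))  # "NA" is sodium
  need <- c("frame", "ion_id", "species", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns: ", paste(need, collapse = " "))
  ions <- unique(df[, c("ion_id", "species")])
  ions <- ions[order(ions$ion_id), ]
  frames <- sort(unique(df$frame))
  fidx <- match(df$frame, frames)
  iidx <- match(df$ion_id, ions$ion_id)
  shape <- c(length(frames), nrow(ions))
  grab <- function(col) {
    m <- matrix(NA_real_, shape[1], shape[2])
    m[cbind(fidx, iidx)] <- df[[col]]
    if (anyNA(m)) stop("trajectory has missing (frame, ion) combinations")
    m
  }
  charge <- vapply(ions$species, function(sp) {
    key <- paste0("charge_", sp)
    if (!is.null(meta[[key]])) as.numeric(meta[[key]])
    else if (toupper(sp) %in% c("NA", "K", "NA+", "K+")) 1
    else if (toupper(sp) %in% c("CL", "CL-")) -1
    else stop("unknown charge for species ", sp,
              "; add a '#charge_", sp, " <q>' header line")
  }, numeric(1))
  num <- function(key, default) {
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  }
  IonTrajectory(grab("x"), grab("y"), grab("z"),
                species = ions$species, charge = charge,
                dt = num("dt_ps", 1),
                box = c(num("box_x", NA), num("box_y", NA),
                        num("box_z", NA)),
                voltage = num("voltage_mV", 0),
                temperature = num("temperature_K", 300))
}

#' Write an ion trajectory as columnar text
#'
#' @param traj an [IonTrajectory].
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "IonTrajectory"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("#dt_ps %g", traj@dt),
    sprintf("#box_x %g", traj@box[1]),
    sprintf("#box_y %g", traj@box[2]),
    sprintf("#box_z %g", traj@box[3]),
    sprintf("#voltage_mV %g", traj@voltage),
    sprintf("#temperature_K %g", traj@temperature)), con)
  for (sp in unique(traj@species))
    writeLines(sprintf("#charge_%s %g", sp,
                       traj@charge[match(sp, traj@species)]), con)
  nf <- nrow(traj@z); ni <- ncol(traj@z)
  df <- data.frame(frame = rep(seq_len(nf) - 1L, ni),
                   ion_id = rep(seq_len(ni) - 1L, each = nf),
                   species = rep(traj@species, each = nf),
                   x = as.vector(traj@x), y = as.vector(traj@y),
                   z = as.vector(traj@z))
  writeLines(paste("frame", "ion_id", "species", "x", "y", "z"), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# unwrap periodic jumps along z: any per-frame step larger than half the box
# is a wrap, corrected to the minimal-image displacement
.unwrapZ <- function(z, Lz) {
  if (nrow(z) < 2L) return(z)
  dz <- diff(z)
  dz <- dz - round(dz / Lz) * Lz
  rbind(z[1L, , drop = FALSE],
        sweep(apply(dz, 2, cumsum), 2, z[1L, ], "+"))
}

.selectIons <- function(traj, species) {
  if (is.null(species)) seq_along(traj@species)
  else which(traj@species %in% species)
}

#' Count gate crossings with two-plane hysteresis
#'
#' A complete upward passage is recorded when an ion that was last below the
#' lower gate plane \code{zLo} first moves above the upper plane \code{zHi}
#' (and mirror-image for downward passages).  Excursions that enter the gate
#' region and retreat are not counted, which suppresses diffusive recrossing
#' noise.  Periodic-wrap jumps along z (|dz| > box_z/2) are unwrapped before
#' detection, so a passage through the periodic boundary is never mistaken
#' for a gate crossing.
#'
#' @param traj an [IonTrajectory].
#' @param zLo,zHi gate planes, Angstrom (default -5, +5 around the junction
#'   midplane).
#' @param species species to count (default: all ions if a single species is
#'   present, otherwise must be given).
#' @return a [CrossingCount]
#' @export
countCrossings <- function(traj, zLo = -5, zHi = 5, species = NULL) {
  stopifnot(is(traj, "IonTrajectory"))
  if (zLo >= zHi) stop("gate must satisfy zLo < zHi")
  Lz <- traj@box[3]
  if (zHi - zLo >= Lz) stop("gate wider than the periodic box")
  if (is.null(species)) {
    sp <- unique(traj@species)
    species_label <- if (length(sp) == 1L) sp else "ALL"
    ions <- seq_along(traj@species)
  } else {
    species_label <- paste(species, collapse = "+")
    ions <- .selectIons(traj, species)
  }
  if (!length(ions))
    return(new("CrossingCount", species = species_label, nUp = 0L,
               nDown = 0L, gate = c(zLo, zHi)))
  zu <- .unwrapZ(traj@z[, ions, drop = FALSE], Lz)
  zc <- (zLo + zHi) / 2
  base <- zc - Lz / 2
  n_up <- 0L; n_down <- 0L
  for (j in seq_len(ncol(zu))) {
    zuj <- zu[, j]
    k <- floor((zuj - base) / Lz)
    zl <- zuj - k * Lz               # local coordinate in [base, base+Lz)
    region <- ifelse(zl < zLo, -1L, ifelse(zl > zHi, 1L, 0L))
    keep <- region != 0L
    if (sum(keep) < 2L) next
    # s enumerates alternating gate/boundary planes along the unwrapped
    # axis; each odd value of s corresponds to one gate passage
    s <- 2 * k[keep] + (region[keep] == 1L)
    fs <- floor((s + 1) / 2)         # odd-plane count up to s
    d <- diff(fs)
    n_up <- n_up + sum(pmax(d, 0))
    n_down <- n_down + sum(pmax(-d, 0))
  }
  new("CrossingCount", species = species_label,
      nUp = as.integer(n_up), nDown = as.integer(n_down),
      gate = c(zLo, zHi))
}

#' Ionic current from net crossing count
#'
#' I = q e net / T: the net number of charge carriers per unit time through
#' the gate, in nA.  The sign follows charge times net crossings (positive
#' charge moving up the axis gives positive current).
#'
#' @param crossings a [CrossingCount] (or an integer net count).
#' @param duration ns over which the crossings were collected.
#' @param charge carrier charge in elementary units.
#' @return current in nA
#' @examples
#' ionicCurrent(7L, duration = 160, charge = 1)   # ~0.007 nA
#' @export
ionicCurrent <- function(crossings, duration, charge = 1) {
  if (is(crossings, "CrossingCount"))
    net <- crossings@nUp - crossings@nDown
  else net <- as.numeric(crossings)
  if (duration <= 0) stop("duration must be positive (ns)")
  # e[C] * net / (T[s]) in nA: e * 1e18 / duration_ns
  charge * net * (.ELEMENTARY_CHARGE * 1e18) / duration
}

#' Single-channel conductance with viscosity correction
#'
#' g[pS] = 1e6 * I[nA] / V[mV] (equivalently g = I/V with I in nA and V in V
#' gives nS).  The standard three-site simulation water model has roughly
#' 30 percent of the experimental viscosity, inflating diffusion
#' coefficients and currents about threefold; \code{gCorrected} divides by
#' \code{correctionFactor} (default 3) to compensate.
#'
#' @param I total ionic current, nA.
#' @param V applied voltage, mV (non-zero).
#' @param correctionFactor dimensionless divisor, default 3.
#' @return a [CurrentEstimate]
#' @examples
#' conductance(0.007, 200)           # 35 pS, corrected ~11.7 pS
#' conductance(0.023 + 0.001, 200)   # 120 pS
#' @export
conductance <- function(I, V, correctionFactor = 3) {
  if (V == 0) stop("V must be non-zero")
  if (correctionFactor <= 0) stop("correctionFactor must be positive")
  g <- 1e6 * I / V
  new("CurrentEstimate", I = I, g = g, gCorrected = g / correctionFactor,
      correctionFactor = correctionFactor, V = V)
}

#' Cation/anion selectivity ratio
#'
#' @param iCation,iAnion currents (nA) measured from the same trajectory and
#'   voltage.
#' @return |iCation| / |iAnion|; when the anion current is zero the value is
#'   \code{Inf} with attribute \code{flag = "unbounded"}; when both are zero
#'   it is \code{NaN} with \code{flag = "undefined"}.
#' @export
selectivityRatio <- function(iCation, iAnion) {
  if (iCation == 0 && iAnion == 0)
    return(structure(NaN, flag = "undefined"))
  if (iAnion == 0)
    return(structure(Inf, flag = "unbounded"))
  structure(abs(iCation) / abs(iAnion), flag = "finite")
}

#' Measure a species current with block-averaged uncertainty
#'
#' Counts gate crossings over the whole run and over \code{nBlocks}
#' contiguous time blocks; the standard error is the between-block standard
#' deviation of the block currents divided by sqrt(nBlocks).
#'
#' @param traj an [IonTrajectory].
#' @param zLo,zHi gate planes, Angstrom.
#' @param species species selector (see [countCrossings()]).
#' @param nBlocks number of blocks (default 20).
#' @return list with \code{I} (nA), \code{se}, \code{crossings}
#'   (a [CrossingCount]), \code{blockCurrents}
#' @export
measureCurrent <- function(traj, zLo = -5, zHi = 5, species = NULL,
                           nBlocks = 20L) {
  stopifnot(is(traj, "IonTrajectory"))
  ions <- if (is.null(species)) seq_along(traj@species)
          else .selectIons(traj, species)
  q <- if (length(ions)) traj@charge[ions[1]] else 1
  cr <- countCrossings(traj, zLo, zHi, species)
  dur <- trajectoryDuration(traj)
  I <- ionicCurrent(cr, dur, q)
  nf <- nrow(traj@z)
  bounds <- floor(seq(1, nf, length.out = nBlocks + 1L))
  bI <- vapply(seq_len(nBlocks), function(b) {
    rows <- bounds[b]:bounds[b + 1L]
    sub <- IonTrajectory(traj@x[rows, , drop = FALSE],
                         traj@y[rows, , drop = FALSE],
                         traj@z[rows, , drop = FALSE],
                         traj@species, traj@charge, traj@dt, traj@box,
                         traj@voltage, traj@temperature)
    ionicCurrent(countCrossings(sub, zLo, zHi, species),
                 trajectoryDuration(sub), q)
  }, numeric(1))
  list(I = I, se = stats::sd(bI) / sqrt(nBlocks), crossings = cr,
       blockCurrents = bI)
}

#' Axial concentration profile inside a cylinder
#'
#' Mean ion occupancy per z bin, restricted to the cylinder x^2 + y^2 <= r^2
#' about the pore axis, converted to molarity: M = occupancy / (N_A V) with
#' the bin volume V = pi r^2 dz in litres (1 A^3 = 1e-27 L).
#'
#' @param traj an [IonTrajectory].
#' @param radius cylinder radius, Angstrom (positive).
#' @param zEdges bin edges along z, Angstrom (strictly increasing).
#' @return a [ConcentrationProfile]
#' @export
concentrationProfile <- function(traj, radius, zEdges) {
  stopifnot(is(traj, "IonTrajectory"))
  if (radius <= 0) stop("cylinder radius must be positive")
  if (length(zEdges) < 2L || any(diff(zEdges) <= 0))
    stop("zEdges must be strictly increasing with at least two edges")
  Lz <- traj@box[3]
  zw <- ((traj@z + Lz / 2) %% Lz) - Lz / 2
  inside <- (traj@x^2 + traj@y^2) <= radius^2
  nb <- length(zEdges) - 1L
  species <- sort(unique(traj@species))
  nf <- nrow(zw)
  vol_L <- pi * radius^2 * diff(zEdges) * 1e-27
  mol <- matrix(0, nb, length(species),
                dimnames = list(NULL, species))
  for (si in seq_along(species)) {
    cols <- traj@species == species[si]
    zz <- zw[, cols, drop = FALSE]
    ok <- inside[, cols, drop = FALSE] & zz >= zEdges[1] &
      zz <= zEdges[nb + 1L]
    bin <- findInterval(zz[ok], zEdges, rightmost.closed = TRUE)
    occ <- tabulate(bin, nbins = nb) / nf
    mol[, si] <- occ / (.AVOGADRO * vol_L)
  }
  new("ConcentrationProfile", zEdges = zEdges, molarity = mol,
      radius = radius, species = species)
}

#' 3D density and flux map of an ion trajectory
#'
#' Bins time-averaged ion number density on a cubic grid spanning the box,
#' and assigns each frame-to-frame displacement (periodic-unwrapped along z,
#' divided by dt) to the voxel containing the displacement midpoint.  The
#' flux slot holds the occupancy-weighted mean displacement rate per voxel.
#'
#' @param traj an [IonTrajectory].
#' @param spacing voxel edge, Angstrom (positive, not larger than the box).
#' @param species species selector; default all ions.
#' @return a [DensityFluxMap]
#' @export
densityFluxMap <- function(traj, spacing, species = NULL) {
  stopifnot(is(traj, "IonTrajectory"))
  if (spacing <= 0) stop("spacing must be positive")
  if (spacing > min(traj@box)) stop("spacing larger than the box")
  ions <- .selectIons(traj, species)
  dims <- as.integer(ceiling(traj@box / spacing))
  origin <- -traj@box / 2
  Lz <- traj@box[3]

  wrap <- function(v, L) ((v + L / 2) %% L) - L / 2
  vox <- function(xx, yy, zz) {
    ix <- pmin(pmax(floor((xx - origin[1]) / spacing), 0), dims[1] - 1L)
    iy <- pmin(pmax(floor((yy - origin[2]) / spacing), 0), dims[2] - 1L)
    iz <- pmin(pmax(floor((zz - origin[3]) / spacing), 0), dims[3] - 1L)
    1L + ix + dims[1] * (iy + dims[2] * iz)
  }
  x <- traj@x[, ions, drop = FALSE]
  y <- traj@y[, ions, drop = FALSE]
  z <- traj@z[, ions, drop = FALSE]
  nf <- nrow(z)
  nvox <- prod(dims)

  occ <- tabulate(vox(wrap(x, traj@box[1]), wrap(y, traj@box[2]),
                      wrap(z, Lz)), nbins = nvox)
  density <- array(occ / nf / spacing^3, dim = dims)

  flux <- array(0, dim = c(dims, 3L))
  if (nf >= 2L) {
    zu <- .unwrapZ(z, Lz)
    dx <- diff(x); dy <- diff(y); dz <- diff(zu)
    midx <- wrap((x[-nf, , drop = FALSE] + dx / 2), traj@box[1])
    midy <- wrap((y[-nf, , drop = FALSE] + dy / 2), traj@box[2])
    midz <- wrap((zu[-nf, , drop = FALSE] + dz / 2), Lz)
    vi <- as.vector(vox(midx, midy, midz))
    cnt <- tabulate(vi, nbins = nvox)
    sums <- vapply(list(dx, dy, dz), function(d) {
      s <- numeric(nvox)
      agg <- rowsum(as.vector(d), vi)
      s[as.integer(rownames(agg))] <- agg[, 1]
      s
    }, numeric(nvox))
    vel <- sums / (pmax(cnt, 1L) * traj@dt)
    flux <- array(vel, dim = c(dims, 3L))
  }
  new("DensityFluxMap", origin = origin, spacing = spacing, dims = dims,
      density = density, flux = flux)
}
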