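#' @include connexon-package.R
NULL

.STATE_LEVELS <- c("PLN", "FN", "OTHER", "UNASSIGNED")
.SYMMETRY_ORDER <- c(C1 = 1L, C6 = 6L, D6 = 12L)

.REQUIRED_RECORD_COLS <- c("particle_id", "class_id")

#' ProtomerTable: symmetry-expanded particle classification metadata
#'
#' A table of protomer records, one per symmetry-expanded copy of a particle.
#' Each record carries the parent particle identifier, the 3D-class label, the
#' conformational state (once assigned), the in-plane expansion rotation, and
#' the hemichannel/ring-position indices derived from it.  Extra columns read
#' from a STAR file are kept alongside and written back on round-trip.
#'
#' Under D6 expansion every particle identifier appears exactly 12 times
#' (6 ring positions times 2 hemichannels); under C6, 6 times.
#'
#' @slot records data.frame with at least columns \code{particle_id}
#'   (character) and \code{class_id} (integer); optionally \code{state},
#'   \code{rot_deg}, \code{tilt_flipped}, \code{hemichannel_index},
#'   \code{position_index}, plus any preserved STAR columns.
#' @slot symmetryGroup one of \code{"C1"}, \code{"C6"}, \code{"D6"};
#'   \code{"C1"} denotes an unexpanded table.
#' @slot provenance free-text origin of the table.
#'
#' @seealso [readStar()], [expandSymmetry()], [assignStates()],
#'   [groupByParticle()]
#' @export
setClass("ProtomerTable",
  representation(
    records = "data.frame",
    symmetryGroup = "character",
    provenance = "character"
  ),
  prototype(
    records = data.frame(particle_id = character(), class_id = integer()),
    symmetryGroup = "C1",
    provenance = ""
  )
)

setValidity("ProtomerTable", function(object) {
  rec <- object@records
  msg <- character()
  missing_cols <- setdiff(.REQUIRED_RECORD_COLS, names(rec))
  if (length(missing_cols))
    msg <- c(msg, paste0("records lack column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (length(object@symmetryGroup) != 1L ||
      !object@symmetryGroup %in% names(.SYMMETRY_ORDER))
    msg <- c(msg, "symmetryGroup must be one of C1, C6, D6")
  if ("state" %in% names(rec) && nrow(rec) &&
      !all(rec$state %in% .STATE_LEVELS))
    msg <- c(msg, paste0("state values must be in {",
                         paste(.STATE_LEVELS, collapse = ", "), "}"))
  if ("position_index" %in% names(rec) && nrow(rec)) {
    pos <- rec$position_index[!is.na(rec$position_index)]
    if (length(pos) && (any(pos < 0L) || any(pos > 5L)))
      msg <- c(msg, "position_index must lie in 0..5")
  }
  if ("hemichannel_index" %in% names(rec) && nrow(rec)) {
    hemi <- rec$hemichannel_index[!is.na(rec$hemichannel_index)]
    if (length(hemi) && !all(hemi %in% c(0L, 1L)))
      msg <- c(msg, "hemichannel_index must be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' ClassStateMap: map 3D-class labels to conformational states
#'
#' @slot mapping named character vector; names are class ids (as strings),
#'   values are state labels (\code{"PLN"}, \code{"FN"}, \code{"OTHER"}).
#'
#' @seealso [assignStates()]
#' @export
setClass("ClassStateMap", representation(mapping = "character"))

setValidity("ClassStateMap", function(object) {
  m <- object@mapping
  if (length(m) < 1L)
    return("mapping must contain at least one class")
  if (is.null(names(m)) || any(!nzchar(names(m))))
    return("mapping must be named by class id")
  if (!all(m %in% setdiff(.STATE_LEVELS, "UNASSIGNED")))
    return("mapped states must be PLN, FN or OTHER")
  if (anyNA(suppressWarnings(as.integer(names(m)))))
    return("mapping names must be integer class ids")
  TRUE
})

#' CompositionSet: per-particle conformational-state compositions
#'
#' One row per complete particle: state counts over all protomer copies and
#' one length-6 ring string per hemichannel, ordered by ring position
#' (characters \code{P}, \code{F}, \code{O}, \code{U}).  Particles whose
#' record multiplicity does not match the symmetry-group order after
#' deduplication are excluded and reported.
#'
#' @slot compositions data.frame with columns \code{particle_id},
#'   \code{n_PLN}, \code{n_FN}, \code{n_OTHER}, \code{n_UNASSIGNED},
#'   \code{k_PLN}, \code{ring1}, \code{ring2} (\code{ring2} is \code{NA}
#'   for C6 tables).
#' @slot symmetryGroup symmetry group of the source table.
#' @slot nDuplicatesRemoved number of redundant records dropped before
#'   counting.
#' @slot incompleteParticles ids excluded for wrong record multiplicity.
#'
#' @seealso [groupByParticle()], [compositionDistribution()]
#' @export
setClass("CompositionSet",
  representation(
    compositions = "data.frame",
    symmetryGroup = "character",
    nDuplicatesRemoved = "integer",
    incompleteParticles = "character"
  )
)

#' CompositionDistribution: histogram of per-channel PLN counts
#'
#' Thirteen bins for the FN:PLN ratios 0:12 through 12:0 of a dodecameric
#' channel, indexed by the number of PLN protomers k = 0..12.
#'
#' @slot counts integer vector of length 13 (names "0".."12").
#' @slot nParticles total number of particles counted.
#'
#' @export
setClass("CompositionDistribution",
  representation(counts = "integer", nParticles = "integer"))

setValidity("CompositionDistribution", function(object) {
  if (length(object@counts) != 13L)
    return("counts must have exactly 13 bins (k = 0..12)")
  if (sum(object@counts) != object@nParticles)
    return("counts must sum to nParticles")
  TRUE
})

#' StateFractionEstimate: estimated fraction of PLN protomers
#'
#' @slot pHat point estimate, the fraction of classified protomers in the
#'   PLN state.
#' @slot n number of classified (PLN or FN) protomer records.
#' @slot ciLow,ciHigh Wilson 95\% confidence bounds.
#'
#' @export
setClass("StateFractionEstimate",
  representation(pHat = "numeric", n = "integer",
                 ciLow = "numeric", ciHigh = "numeric"))

setValidity("StateFractionEstimate", function(object) {
  if (object@ciLow > object@pHat + 1e-12 ||
      object@ciHigh < object@pHat - 1e-12)
    return("confidence interval must bracket pHat")
  TRUE
})

#' IndependenceTestResult: goodness-of-fit of ring arrangements to a
#' random-placement null
#'
#' @slot statistic test statistic (Pearson X^2 for both methods).
#' @slot df degrees of freedom (NA for the Monte-Carlo method).
#' @slot p.value p-value.
#' @slot method \code{"pearson_chi2"} or \code{"exact_multinomial_mc"}.
#' @slot pooledBins description of any pooling of sparse bins.
#'
#' @export
setClass("IndependenceTestResult",
  representation(statistic = "numeric", df = "numeric", p.value = "numeric",
                 method = "character", pooledBins = "character"))

setValidity("IndependenceTestResult", function(object) {
  if (object@statistic < 0) return("statistic must be non-negative")
  if (object@p.value < 0 || object@p.value > 1)
    return("p.value must lie in [0, 1]")
  TRUE
})

#' IonTrajectory: per-frame ion coordinates with electrical metadata
#'
#' Coordinates are stored as frames-by-ions matrices (one per axis) in
#' Angstrom; the pore axis is z with the junction midplane at z = 0.  The
#' simulation box is periodic along z.
#'
#' @slot x,y,z numeric matrices, \code{n_frames} rows by \code{n_ions}
#'   columns, Angstrom.
#' @slot species character, one label per ion (e.g. \code{"NA"},
#'   \code{"CL"}).
#' @slot charge numeric, signed charge per ion in elementary charges.
#' @slot dt time between stored frames, ps.
#' @slot box box edge lengths (x, y, z), Angstrom.
#' @slot voltage applied transjunctional voltage along z, mV.
#' @slot temperature K.
#'
#' @seealso [simulateIonTrajectory()], [countCrossings()], [ionicCurrent()]
#' @export
setClass("IonTrajectory",
  representation(
    x = "matrix", y = "matrix", z = "matrix",
    species = "character", charge = "numeric",
    dt = "numeric", box = "numeric",
    voltage = "numeric", temperature = "numeric"
  )
)

setValidity("IonTrajectory", function(object) {
  n_ions <- ncol(object@z)
  n_frames <- nrow(object@z)
  msg <- character()
  if (!all(dim(object@x) == dim(object@z)) ||
      !all(dim(object@y) == dim(object@z)))
    msg <- c(msg, "x, y, z must have identical dimensions")
  if (length(object@species) != n_ions || length(object@charge) != n_ions)
    msg <- c(msg, "species and charge must have one entry per ion")
  if (any(!is.finite(object@x)) || any(!is.finite(object@y)) ||
      any(!is.finite(object@z)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(object@box) != 3L || any(object@box <= 0))
    msg <- c(msg, "box must be three positive edge lengths")
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be a positive scalar (ps)")
  if (n_frames > 0 && n_ions > 0 && any(object@charge == 0))
    msg <- c(msg, "charge must be non-zero for every ion")
  if (length(msg)) msg else TRUE
})

#' CrossingCount: hysteresis gate-crossing events for one species
#'
#' @slot species ion species label.
#' @slot nUp,nDown numbers of complete upward/downward gate passages.
#' @slot gate the two gate planes (z_lo, z_hi), Angstrom.
#'
#' @seealso [countCrossings()]
#' @export
setClass("CrossingCount",
  representation(species = "character", nUp = "integer", nDown = "integer",
                 gate = "numeric"))

setValidity("CrossingCount", function(object) {
  if (object@nUp < 0L || object@nDown < 0L)
    return("crossing counts must be non-negative")
  if (length(object@gate) != 2L || object@gate[1] >= object@gate[2])
    return("gate must be (z_lo, z_hi) with z_lo < z_hi")
  TRUE
})

#' CurrentEstimate: ionic current and single-channel conductance
#'
#' Unit chain: g[pS] = 1e6 * I[nA] / V[mV] (i.e. g = I/V with I in nA and V
#' in V gives nS; times 1000 gives pS).  The corrected conductance divides
#' by the water-model viscosity correction factor.
#'
#' @slot I current, nA (signed).
#' @slot g conductance, pS.
#' @slot gCorrected viscosity-corrected conductance, pS.
#' @slot correctionFactor dimensionless divisor (default 3).
#' @slot V applied voltage, mV.
#'
#' @seealso [conductance()]
#' @export
setClass("CurrentEstimate",
  representation(I = "numeric", g = "numeric", gCorrected = "numeric",
                 correctionFactor = "numeric", V = "numeric"))

#' ConcentrationProfile: axial molarity profile inside a cylinder
#'
#' @slot zEdges bin edges along z, Angstrom.
#' @slot molarity matrix, bins by species, mol/L.
#' @slot radius cylinder radius, Angstrom.
#' @slot species column species labels.
#'
#' @seealso [concentrationProfile()]
#' @export
setClass("ConcentrationProfile",
  representation(zEdges = "numeric", molarity = "matrix",
                 radius = "numeric", species = "character"))

setValidity("ConcentrationProfile", function(object) {
  if (any(object@molarity < 0)) return("molarity must be non-negative")
  if (nrow(object@molarity) != length(object@zEdges) - 1L)
    return("molarity must have one row per z bin")
  TRUE
})

#' DensityFluxMap: voxelised number density and mean velocity field
#'
#' @slot origin grid origin (corner), Angstrom.
#' @slot spacing voxel edge length, Angstrom.
#' @slot dims grid dimensions (nx, ny, nz).
#' @slot density array dims, time-averaged ions per cubic Angstrom.
#' @slot flux array c(dims, 3), occupancy-weighted mean displacement rate
#'   (Angstrom/ps) assigned to displacement-midpoint voxels.
#'
#' @seealso [densityFluxMap()]
#' @export
setClass("DensityFluxMap",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 density = "array", flux = "array"))

#' AtomSet: heavy atoms with van der Waals radii
#'
#' @slot coords n-by-3 matrix, Angstrom.
#' @slot radius van der Waals radius per atom, Angstrom.
#' @slot element element symbols.
#' @slot chain,resid,resno residue bookkeeping.
#'
#' @seealso [loadStructure()], [poreProfile()]
#' @export
setClass("AtomSet",
  representation(coords = "matrix", radius = "numeric", element = "character",
                 chain = "character", resid = "character", resno = "integer"))

setValidity("AtomSet", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (length(object@radius) != n) return("one radius per atom required")
  if (n && any(object@radius <= 0)) return("radii must be positive")
  if (n && any(!is.finite(object@coords)))
    return("coordinates must be finite")
  TRUE
})

#' PoreProfile: inscribed-sphere pore radius along the z axis
#'
#' At each z sample the profile holds the radius of the largest sphere whose
#' centre lies in that plane and that overlaps no atom, together with the
#' optimal in-plane centre.  Radii are capped at \code{rMax} where no atoms
#' constrain the sphere.
#'
#' @slot z axial sample positions, Angstrom.
#' @slot radius pore radius at each z, Angstrom.
#' @slot cx,cy in-plane centre of the inscribed sphere.
#' @slot rMax cap applied where the pore is unconstrained.
#' @slot unconstrained logical flag per sample (no atom within cutoff).
#'
#' @seealso [poreProfile()], [minConstrictionDiameter()]
#' @export
setClass("PoreProfile",
  representation(z = "numeric", radius = "numeric", cx = "numeric",
                 cy = "numeric", rMax = "numeric",
                 unconstrained = "logical"))

setValidity("PoreProfile", function(object) {
  if (any(object@radius < 0)) return("pore radius must be non-negative")
  if (length(object@radius) != length(object@z))
    return("one radius per z sample required")
  TRUE
})
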