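#' @include AllClasses.R conformation.R
NULL

# ---- exact ring model -----------------------------------------------------

# Boltzmann weights of the 6-site cyclic Ising model over all 64 ring
# states: weight = exp(h * sum(sigma) + J * sum(sigma_i sigma_{i+1})),
# spins +/-1, bit 1 = PLN
.ringWeights <- function(h, J) {
  codes <- 0:63
  bits <- t(vapply(codes, function(cd)
    as.integer(bitwAnd(bitwShiftR(cd, 0:5), 1L)), integer(6)))
  sig <- 2 * bits - 1
  nb <- sig[, c(2:6, 1)]
  exp(h * rowSums(sig) + J * rowSums(sig * nb))
}

.ringMarginal <- function(h, J) {
  w <- .ringWeights(h, J)
  bits1 <- as.integer(bitwAnd(0:63, 1L))
  sum(w * bits1) / sum(w)
}

# field giving marginal PLN probability p on the 6-cycle at coupling J;
# bisection to 1e-6 on the exact marginal
.isingFieldForMarginal <- function(p, J, tol = 1e-6) {
  if (p <= 0 || p >= 1)
    stop("marginal p = ", p, " is unattainable with finite field; ",
         "use the independent (J = 0) path for degenerate fractions")
  lo <- -60; hi <- 60
  if (.ringMarginal(lo, J) > p || .ringMarginal(hi, J) < p)
    stop("marginal p = ", p, " unattainable at coupling J = ", J)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.ringMarginal(mid, J) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Exact distribution over the 64 hexameric ring states
#'
#' Ring states follow a 6-site cyclic Ising model: independent protomers at
#' coupling J = 0, positively coupled neighbours at J > 0.  The field is
#' solved (bisection, tolerance 1e-6) so the per-protomer PLN marginal
#' equals \code{p}; probabilities are computed by exact enumeration of all
#' 64 states with Boltzmann weights.
#'
#' @param p per-protomer PLN probability (0 < p < 1 when J != 0).
#' @param J nearest-neighbour log-odds coupling (0 = independence).
#' @return named numeric vector of 64 probabilities (names are P/F strings,
#'   position 1 in the lowest bit), summing to 1
#' @export
exactRingDistribution <- function(p, J = 0) {
  stopifnot(is.finite(p), is.finite(J))
  codes <- 0:63
  nm <- vapply(codes, .codeToString, character(1))
  if (J == 0) {
    k <- vapply(codes, function(cd)
      sum(as.integer(bitwAnd(bitwShiftR(cd, 0:5), 1L))), numeric(1))
    return(setNames(p^k * (1 - p)^(6 - k), nm))
  }
  h <- .isingFieldForMarginal(p, J)
  w <- .ringWeights(h, J)
  setNames(w / sum(w), nm)
}

# ---- classification-metadata generator ------------------------------------

#' Simulate symmetry-expanded classification metadata
#'
#' Generates the metadata table a per-protomer focused classification of N
#' dodecameric (D6) or hexameric (C6) particles would produce, with known
#' ground truth.  At \code{couplingJ = 0} each protomer is independently PLN
#' with probability \code{pPLN}; at \code{couplingJ != 0} each hemichannel
#' ring is drawn from the 6-cycle Ising model via a Gibbs sampler (500
#' burn-in sweeps by default) whose field is solved so the marginal equals
#' \code{pPLN}.  Class labels are drawn uniformly from the classes mapped to
#' each true state; rotation angles, flip flags and position indices are
#' written exactly as [expandSymmetry()] writes them.
#'
#' @param nParticles number of particles (the wild-type nanodisc dataset
#'   had 85,080).
#' @param pPLN per-protomer PLN probability (default 0.57, the observed
#'   protomer split).
#' @param couplingJ ring nearest-neighbour coupling (default 0).
#' @param symmetry \code{"D6"} (default) or \code{"C6"}.
#' @param classMap a [ClassStateMap] supplying class ids per state.
#' @param seed RNG seed (required for reproducibility).
#' @param burnin Gibbs burn-in sweeps when \code{couplingJ != 0}.
#' @return list with \code{table} (an expanded [ProtomerTable], states
#'   unassigned, class ids set) and \code{groundTruth} (list: \code{pPLN},
#'   \code{couplingJ}, \code{field}, \code{states} matrix of "PLN"/"FN" with
#'   one row per ring, \code{seed})
#' @export
simulateMetadata <- function(nParticles, pPLN = 0.57, couplingJ = 0,
                             symmetry = c("D6", "C6"),
                             classMap = ClassStateMap(), seed,
                             burnin = 500L) {
  symmetry <- match.arg(symmetry)
  stopifnot(nParticles >= 1)
  if (pPLN < 0 || pPLN > 1) stop("pPLN must be in [0, 1]")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  nHemi <- if (symmetry == "D6") 2L else 1L
  nRings <- nParticles * nHemi

  if (couplingJ == 0) {
    states <- matrix(rbinom(nRings * 6L, 1L, pPLN), nrow = nRings)
    field <- NA_real_
  } else {
    field <- .isingFieldForMarginal(pPLN, couplingJ)
    states <- .gibbsRings(nRings, field, couplingJ, as.integer(burnin))
  }

  pln_classes <- as.integer(names(classMap@mapping)[
    classMap@mapping == "PLN"])
  fn_classes <- as.integer(names(classMap@mapping)[
    classMap@mapping == "FN"])
  if (!length(pln_classes) || !length(fn_classes))
    stop("classMap must provide at least one PLN and one FN class")

  st_vec <- as.vector(t(states))      # ring-major, positions 0..5
  n_rec <- length(st_vec)
  class_id <- integer(n_rec)
  class_id[st_vec == 1L] <- sample(pln_classes, sum(st_vec == 1L),
                                   replace = TRUE)
  class_id[st_vec == 0L] <- sample(fn_classes, sum(st_vec == 0L),
                                   replace = TRUE)

  pid <- sprintf("gjc_%06d", seq_len(nParticles))
  rec <- data.frame(
    particle_id = rep(pid, each = 6L * nHemi),
    class_id = class_id,
    state = "UNASSIGNED",
    rot_deg = rep(seq(0, 300, by = 60), nParticles * nHemi),
    tilt_flipped = rep(rep(c(FALSE, TRUE)[seq_len(nHemi)],
                           each = 6L), nParticles),
    stringsAsFactors = FALSE)
  rec$hemichannel_index <- as.integer(rec$tilt_flipped)
  rec$position_index <- .positionFromRot(rec$rot_deg)

  table <- new("ProtomerTable", records = rec, symmetryGroup = symmetry,
               provenance = sprintf(
                 "simulateMetadata(N=%d, p=%g, J=%g, %s, seed=%d)",
                 nParticles, pPLN, couplingJ, symmetry, seed))
  truth <- list(pPLN = pPLN, couplingJ = couplingJ, field = field,
                states = matrix(ifelse(states == 1L, "PLN", "FN"),
                                nrow = nRings),
                symmetry = symmetry, seed = seed)
  list(table = table, groundTruth = truth)
}

# ---- drift-diffusion trajectory generator ---------------------------------

#' Simulate a drift-diffusion ion trajectory
#'
#' Overdamped Langevin dynamics of non-interacting ions in a reflective
#' cylinder of radius \code{poreRadius}, periodic along z over \code{boxZ}.
#' Each step: dz = (D q E / kT) dt + sqrt(2 D dt) xi, with the constant
#' field E = V / poreLength applied only where |z| <= poreLength/2 (when
#' \code{boxZ > poreLength}, the remaining z range is a field-free
#' reservoir).  Optional Gaussian potential wells (depth in kT) emulate
#' attractive bands along the pore.
#'
#' When \code{concentration} is supplied, the implied ion count
#' (c N_A V) is compared with \code{nIons} and a warning issued if they
#' disagree by more than 10 percent.
#'
#' @param nIons ions per species (vector parallel to \code{species}).
#' @param species species labels (default \code{"NA"}).
#' @param charge per-species charges, elementary units (default +1).
#' @param D per-species diffusion coefficients, A^2/ps (default 0.1).
#' @param poreRadius cylinder radius, A.
#' @param poreLength pore (field) segment length along z, A.
#' @param boxZ periodic box length along z, A; default \code{poreLength}
#'   (uniform system, the regime of [closedFormCurrent()]).
#' @param voltage applied voltage, mV.
#' @param temperature K (default 300).
#' @param concentration nominal reservoir concentration, mol/L (optional,
#'   consistency check only).
#' @param wells optional data.frame with columns \code{z}, \code{depth_kT},
#'   \code{width} describing Gaussian wells.
#' @param dt integration step, ps.
#' @param nSteps number of integration steps.
#' @param stride store every \code{stride}-th frame (default 10).
#' @param seed RNG seed (required).
#' @return an [IonTrajectory]
#' @export
simulateIonTrajectory <- function(nIons, species = "NA", charge = 1,
                                  D = 0.1, poreRadius = 10,
                                  poreLength = 60, boxZ = poreLength,
                                  voltage = 0, temperature = 300,
                                  concentration = NULL, wells = NULL,
                                  dt = 1, nSteps = 1000L, stride = 10L,
                                  seed) {
  if (missing(seed)) stop("seed is required")
  ns <- length(species)
  stopifnot(length(nIons) == ns)
  charge <- rep_len(charge, ns)
  D <- rep_len(D, ns)
  if (boxZ < poreLength) stop("boxZ must be >= poreLength")
  kT_eV <- .BOLTZMANN_EV * temperature
  E_V_per_A <- voltage * 1e-3 / poreLength

  # stability: deterministic displacement per step must stay below 0.5 A
  max_drift <- max(abs(D * charge * E_V_per_A / kT_eV)) * dt
  if (!is.null(wells) && nrow(wells)) {
    # max Gaussian-well force at u = width: depth/width * exp(-1/2)
    max_drift <- max_drift +
      max(D) * dt * max(abs(wells$depth_kT) / wells$width) * exp(-0.5)
  }
  if (max_drift >= 0.5)
    stop("unstable configuration: drift per step ", signif(max_drift, 3),
         " A >= 0.5 A; reduce dt or the field")

  if (!is.null(concentration)) {
    vol_L <- pi * poreRadius^2 * boxZ * 1e-27
    expected <- concentration * .AVOGADRO * vol_L
    if (abs(sum(nIons) - expected) > 0.1 * max(expected, 1))
      warning("ion count ", sum(nIons), " differs >10% from c*N_A*V = ",
              signif(expected, 4))
  }

  set.seed(seed)
  wd <- if (is.null(wells) || !nrow(wells)) numeric() else wells$depth_kT
  wz <- if (is.null(wells) || !nrow(wells)) numeric() else wells$z
  ww <- if (is.null(wells) || !nrow(wells)) numeric() else wells$width

  xs <- ys <- zs <- NULL
  for (si in seq_len(ns)) {
    n <- nIons[si]
    r0 <- poreRadius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    run <- .langevinRun(D[si], charge[si] * E_V_per_A / kT_eV, dt,
                        as.integer(nSteps), as.integer(stride),
                        poreRadius, poreLength / 2, boxZ,
                        wd, wz, ww,
                        r0 * cos(th), r0 * sin(th),
                        runif(n, -boxZ / 2, boxZ / 2))
    xs <- cbind(xs, run$x); ys <- cbind(ys, run$y); zs <- cbind(zs, run$z)
  }
  IonTrajectory(xs, ys, zs,
                species = rep(species, nIons),
                charge = rep(charge, nIons),
                dt = dt * stride,
                box = c(2 * poreRadius, 2 * poreRadius, boxZ),
                voltage = voltage, temperature = temperature)
}

#' Closed-form Nernst-Planck current for the uniform generator
#'
#' For a uniform cylindrical system (field over the whole periodic length,
#' no wells) the steady-state ion density is uniform and the drift current
#' is exactly I = q c A v with v = D q E / kT: the constant-field
#' Nernst-Planck result, which the Langevin generator must reproduce.
#'
#' @param nIons ions of the species in the system.
#' @param charge elementary charges.
#' @param D diffusion coefficient, A^2/ps.
#' @param poreRadius,poreLength cylinder radius and length, A.
#' @param boxZ periodic box length; must equal \code{poreLength}
#'   (otherwise the field-free reservoirs invalidate the formula and the
#'   oracle refuses).
#' @param voltage mV.
#' @param temperature K.
#' @param wells must be NULL/empty; the oracle refuses wells.
#' @return current in nA
#' @export
closedFormCurrent <- function(nIons, charge = 1, D = 0.1, poreRadius = 10,
                              poreLength = 60, boxZ = poreLength,
                              voltage = 200, temperature = 300,
                              wells = NULL) {
  if (!is.null(wells) && nrow(wells) > 0)
    stop("closed-form oracle invalid with potential wells")
  if (boxZ != poreLength)
    stop("closed-form oracle requires a uniform system ",
         "(boxZ == poreLength, no reservoirs)")
  kT_eV <- .BOLTZMANN_EV * temperature
  E_V_per_A <- voltage * 1e-3 / poreLength
  v <- D * charge * E_V_per_A / kT_eV          # A/ps
  A <- pi * poreRadius^2                       # A^2
  conc <- nIons / (A * boxZ)                   # ions/A^3
  charge * conc * A * v * (.ELEMENTARY_CHARGE * 1e21)
}

# ---- toy pore structures --------------------------------------------------

#' Build a toy pore structure from stacked atom rings
#'
#' Places \code{nAtoms} atoms equally spaced on a circle of the given radius
#' at each z, giving a synthetic pore with analytically known constriction:
#' the inscribed-sphere radius at a ring's plane is (ring radius - vdW
#' radius).
#'
#' @param rings data.frame with columns \code{z}, \code{radius},
#'   \code{nAtoms} (each at least 8).
#' @param atomVdw van der Waals radius assigned to every atom, A.
#' @param element element symbol (default "C").
#' @return an [AtomSet]
#' @export
simulateToyPore <- function(rings, atomVdw = 1.7, element = "C") {
  stopifnot(is.data.frame(rings),
            all(c("z", "radius", "nAtoms") %in% names(rings)))
  if (any(rings$radius < 0)) stop("ring radius must be non-negative")
  if (any(rings$nAtoms < 8)) stop("need at least 8 atoms per ring")
  coords <- do.call(rbind, lapply(seq_len(nrow(rings)), function(i) {
    n <- rings$nAtoms[i]
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(rings$radius[i] * cos(th), rings$radius[i] * sin(th),
          rings$z[i])
  }))
  AtomSet(coords, radius = atomVdw, element = element)
}
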