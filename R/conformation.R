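#' @include AllClasses.R
NULL

#' Composition distribution over the 13 FN:PLN ratios
#'
#' Counts particles at each of the 13 possible FN:PLN compositions of a
#' dodecameric channel (0:12 through 12:0), indexed by the number of PLN
#' protomers k.  Particles containing OTHER or UNASSIGNED protomers are not
#' binary and are rejected; exclude or fold them upstream.
#'
#' @param compSet a [CompositionSet] from a D6-expanded table.
#' @return a [CompositionDistribution]
#' @export
compositionDistribution <- function(compSet) {
  stopifnot(is(compSet, "CompositionSet"))
  comp <- compositions(compSet)
  if (!nrow(comp)) stop("no complete particles to count")
  if (any(comp$n_OTHER > 0L | comp$n_UNASSIGNED > 0L))
    stop("non-binary states present; composition counting requires ",
         "records classified as PLN or FN only")
  counts <- setNames(as.integer(tabulate(comp$k_PLN + 1L, nbins = 13L)),
                     as.character(0:12))
  new("CompositionDistribution", counts = counts,
      nParticles = nrow(comp))
}

#' Expected composition counts under random placement
#'
#' If each protomer independently adopts the PLN state with probability p,
#' the number k of PLN protomers among n is Binomial(n, p); the expected
#' count in bin k for N particles is N * C(n,k) * p^k * (1-p)^(n-k).
#'
#' @param p PLN probability per protomer, in [0, 1].
#' @param n protomers per particle (12 for a dodecamer, 6 for one ring).
#' @param N number of particles.
#' @return named numeric vector of expected counts over k = 0..n
#' @export
binomialExpectation <- function(p, n = 12L, N = 1L) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  stopifnot(n >= 1L, N >= 0)
  setNames(N * dbinom(0:n, n, p), as.character(0:n))
}

#' Estimate the PLN state fraction with a Wilson interval
#'
#' The point estimate is the fraction of classified protomer records (PLN or
#' FN; OTHER and UNASSIGNED are ignored) in the PLN state, with a Wilson
#' 95\% score interval.
#'
#' @param table a [ProtomerTable] with states assigned.
#' @param conf confidence level (default 0.95).
#' @return a [StateFractionEstimate]
#' @export
estimateStateFraction <- function(table, conf = 0.95) {
  stopifnot(is(table, "ProtomerTable"))
  st <- records(table)$state
  nP <- sum(st == "PLN")
  nF <- sum(st == "FN")
  n <- nP + nF
  if (n == 0L) stop("no records classified as PLN or FN")
  ci <- .wilson(nP, n, conf)
  new("StateFractionEstimate", pHat = nP / n, n = as.integer(n),
      ciLow = ci[1], ciHigh = ci[2])
}

.wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

# ---- necklace machinery ---------------------------------------------------

.ring_chars <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) != 6L) stop("ring string must have length 6, got '", s, "'")
  if (!all(ch %in% c("P", "F")))
    stop("ring string must be over the alphabet {P, F}, got '", s, "'")
  ch
}

#' Canonical necklace representative of a 6-ring state string
#'
#' Hexameric ring arrangements are compared under rotation only (the C6
#' cyclic group): the two faces of a docked hemichannel are distinguishable,
#' so reflections are not identified.  The canonical form is the
#' lexicographically smallest of the six cyclic rotations; the orbit size is
#' the number of distinct rotations (a divisor of 6).
#'
#' @param states length-6 string over \code{P}/\code{F}
#'   (e.g. \code{"PFPFPF"}).
#' @param dihedral also identify mirror images (bracelet equivalence);
#'   intended for sensitivity analysis only, since the docked ring faces
#'   are physically distinguishable.  Collapses the 14 rotation classes to
#'   13.
#' @return list with \code{canonical} (string) and \code{orbitSize}
#'   (integer)
#' @examples
#' canonicalNecklace("PFPFPF")  # "FPFPFP", orbit 2
#' @export
canonicalNecklace <- function(states, dihedral = FALSE) {
  ch <- .ring_chars(states)
  variants <- if (dihedral) list(ch, rev(ch)) else list(ch)
  all_s <- unlist(lapply(variants, function(v)
    vapply(0:5, function(r)
      paste(v[((seq_len(6) - 1 + r) %% 6) + 1], collapse = ""),
      character(1))))
  list(canonical = min(all_s), orbitSize = length(unique(all_s)))
}

# canonical class and orbit size for every 6-bit code (bit i = position i
# is PLN) under rotation (cyclic) or rotation+reflection (dihedral)
# equivalence; computed once per group, fixture-free
.necklaceTable <- local({
  cache <- list()
  function(dihedral = FALSE) {
    key <- if (dihedral) "dihedral" else "cyclic"
    if (is.null(cache[[key]])) {
      codes <- 0:63
      bits <- t(vapply(codes, function(cd) as.integer(bitwAnd(
        bitwShiftR(cd, 0:5), 1L)), integer(6)))
      canon <- integer(64)
      orbit <- integer(64)
      for (cd in codes) {
        b <- bits[cd + 1, ]
        variants <- if (dihedral) list(b, rev(b)) else list(b)
        var_bits <- unlist(lapply(variants, function(v)
          lapply(0:5, function(r) v[((0:5 + r) %% 6) + 1])),
          recursive = FALSE)
        # lexicographic string order: the first ring position is the most
        # significant character (F < P)
        lex <- vapply(var_bits, function(rb) sum(rb * 2L^(5:0)),
                      numeric(1))
        canon[cd + 1] <- sum(var_bits[[which.min(lex)]] * 2L^(0:5))
        orbit[cd + 1] <- length(unique(lex))
      }
      cache[[key]] <<- data.frame(code = codes, canonical = canon,
                                  orbit = orbit, k = rowSums(bits))
    }
    cache[[key]]
  }
})

.codeToString <- function(code) {
  bits <- as.integer(bitwAnd(bitwShiftR(code, 0:5), 1L))
  paste(ifelse(bits == 1L, "P", "F"), collapse = "")
}

.ringToCode <- function(rings) {
  # rings: character vector of length-6 P/F strings -> integer codes
  m <- matrix(unlist(strsplit(rings, "", fixed = TRUE), use.names = FALSE),
              ncol = 6, byrow = TRUE)
  as.integer((m == "P") %*% 2L^(0:5))
}

#' Observed vs expected ring-arrangement (necklace) distribution
#'
#' Tallies hemichannel rings by canonical necklace class (both rings of each
#' particle for D6 tables) and attaches the expected count under independent
#' placement: for a class of orbit size s containing k PLN protomers,
#' E = N_rings * s * p^k * (1-p)^(6-k).  All 14 classes are returned, also
#' when unobserved.
#'
#' @param compSet a [CompositionSet] with ring strings (positions known).
#' @param p PLN probability; default \code{NULL} uses the plug-in estimate
#'   from the same rings.
#' @param dihedral use bracelet (rotation + reflection) equivalence for
#'   sensitivity analysis (default FALSE: rotations only).
#' @return data.frame with columns \code{canonical}, \code{k_PLN},
#'   \code{orbit_size}, \code{observed}, \code{expected}; attributes
#'   \code{nRings} and \code{p}.
#' @export
arrangementDistribution <- function(compSet, p = NULL, dihedral = FALSE) {
  stopifnot(is(compSet, "CompositionSet"))
  comp <- compositions(compSet)
  rings <- c(comp$ring1, comp$ring2)
  rings <- rings[!is.na(rings)]
  if (!length(rings)) stop("no rings available")
  if (any(grepl("[^PF]", rings)))
    stop("rings contain non-binary states; exclude OTHER/UNASSIGNED upstream")
  codes <- .ringToCode(rings)
  tab <- .necklaceTable(dihedral)
  if (is.null(p)) {
    p <- sum(tab$k[codes + 1]) / (6 * length(codes))
    p_plugin <- TRUE
  } else p_plugin <- FALSE
  canon_codes <- sort(unique(tab$canonical))
  obs <- tabulate(match(tab$canonical[codes + 1], canon_codes),
                  nbins = length(canon_codes))
  cls <- tab[tab$code %in% canon_codes, ]
  cls <- cls[match(canon_codes, cls$code), ]
  out <- data.frame(
    canonical = vapply(canon_codes, .codeToString, character(1)),
    k_PLN = cls$k,
    orbit_size = cls$orbit,
    observed = obs,
    expected = length(rings) * cls$orbit * p^cls$k * (1 - p)^(6 - cls$k),
    stringsAsFactors = FALSE)
  attr(out, "nRings") <- length(rings)
  attr(out, "p") <- p
  attr(out, "pPlugin") <- p_plugin
  out
}

#' Goodness-of-fit test of observed against expected class counts
#'
#' \code{pearson_chi2}: Pearson X^2 after pooling all classes with expected
#' count below 5 into a single bin; df = bins - 1, minus one more when the
#' placement probability was estimated from the same data
#' (\code{pEstimated}).  \code{exact_multinomial_mc}: Monte-Carlo multinomial
#' test using the same X^2 statistic, p = (1 + #(X2* >= X2)) / (B + 1).
#'
#' @param observed,expected count vectors over the same classes.
#' @param method \code{"pearson_chi2"} (default) or
#'   \code{"exact_multinomial_mc"}.
#' @param pEstimated was the placement probability estimated from the data
#'   being tested?  Reduces df by 1 (default TRUE, matching the plug-in
#'   default of [arrangementDistribution()]).
#' @param nRep Monte-Carlo replicates (default 10000).
#' @param seed RNG seed for the Monte-Carlo method.
#' @return an [IndependenceTestResult]
#' @export
independenceTest <- function(observed, expected,
                             method = c("pearson_chi2",
                                        "exact_multinomial_mc"),
                             pEstimated = TRUE, nRep = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (is.data.frame(observed)) {
    df <- observed
    observed <- df$observed
    if (missing(expected)) expected <- df$expected
  }
  stopifnot(length(observed) == length(expected))
  if (all(expected == 0)) stop("all expected counts are zero")
  N <- sum(observed)
  if (N < 1) stop("need at least one observation")

  # pool sparse classes (expected < 5) into one bin
  sparse <- expected < 5
  pooled_desc <- ""
  if (any(sparse) && sum(!sparse) >= 1L) {
    observed <- c(observed[!sparse], sum(observed[sparse]))
    expected <- c(expected[!sparse], sum(expected[sparse]))
    pooled_desc <- paste0(sum(sparse), " classes with expected < 5 pooled")
  }
  # rescale expected to the observed total so the multinomial is proper
  expected <- expected * N / sum(expected)
  stat <- sum((observed - expected)^2 / expected)

  if (method == "pearson_chi2") {
    df_ <- length(observed) - 1L - as.integer(pEstimated)
    if (df_ < 1L) stop("not enough bins for a chi-square test")
    p <- pchisq(stat, df = df_, lower.tail = FALSE)
    new("IndependenceTestResult", statistic = stat, df = as.numeric(df_),
        p.value = p, method = method, pooledBins = pooled_desc)
  } else {
    if (!is.null(seed)) set.seed(seed)
    probs <- expected / N
    sims <- rmultinom(nRep, size = N, prob = probs)
    stat_sim <- colSums((sims - expected)^2 / expected)
    p <- (1 + sum(stat_sim >= stat - 1e-12)) / (nRep + 1)
    new("IndependenceTestResult", statistic = stat, df = NA_real_,
        p.value = p, method = method, pooledBins = pooled_desc)
  }
}

#' Nearest-neighbour coupling statistic for hexameric rings
#'
#' The statistic is the mean, over rings, of the number of cyclically
#' adjacent equal-state pairs (0-6 per ring).  The null distribution is
#' generated by independently permuting the states across the six positions
#' within each ring (preserving every ring's composition), which destroys
#' spatial structure but keeps the composition mix fixed.  The p-value is
#' two-sided Monte-Carlo: 2 * min(P(T* >= T), P(T* <= T)), capped at 1.
#'
#' @param compSet a [CompositionSet] with ring strings.
#' @param nPerm number of permutation replicates (default 1000; below 100 a
#'   warning is issued but the statistic is still computed).
#' @param seed RNG seed.
#' @return list with \code{statistic}, \code{p.value}, \code{nullMean},
#'   \code{nPerm}
#' @export
adjacencyCouplingStat <- function(compSet, nPerm = 1000L, seed = NULL) {
  stopifnot(is(compSet, "CompositionSet"))
  comp <- compositions(compSet)
  rings <- c(comp$ring1, comp$ring2)
  rings <- rings[!is.na(rings)]
  if (!length(rings)) stop("no rings available")
  if (nPerm < 100L)
    warning("nPerm < 100: permutation p-value will be coarse")
  m <- matrix(unlist(strsplit(rings, "", fixed = TRUE), use.names = FALSE),
              ncol = 6, byrow = TRUE)
  adj_mean <- function(mm) {
    nb <- mm[, c(2:6, 1), drop = FALSE]
    mean(rowSums(mm == nb))
  }
  stat <- adj_mean(m)
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(m)
  v <- as.vector(t(m))                 # row-major: ring after ring
  g <- rep(seq_len(nr), each = 6L)
  null_stats <- vapply(seq_len(nPerm), function(i) {
    o <- order(g, runif(6L * nr))      # random within-ring order
    adj_mean(matrix(v[o], nrow = nr, byrow = TRUE))
  }, numeric(1))
  p_hi <- (1 + sum(null_stats >= stat - 1e-12)) / (nPerm + 1)
  p_lo <- (1 + sum(null_stats <= stat + 1e-12)) / (nPerm + 1)
  list(statistic = stat, p.value = min(1, 2 * min(p_hi, p_lo)),
       nullMean = mean(null_stats), nPerm = nPerm)
}
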