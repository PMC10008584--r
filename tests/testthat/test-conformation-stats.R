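test_that("composition histograms have 13 bins filled as constructed", {
  cs <- groupByParticle(table_from_rings(rep("PPPPPP", 10),
                                         rep("PPPPPP", 10)),
                        verbose = FALSE)
  cd <- compositionDistribution(cs)
  expect_length(cd@counts, 13L)
  expect_equal(unname(cd@counts[13]), 10L)
  expect_equal(sum(cd@counts), 10L)

  mixed <- groupByParticle(
    table_from_rings(c("FFFFFF", "PPPFFF", "FFFPPP", "PPPPPP"),
                     c("FFFFFF", "PPPFFF", "PPPFFF", "PPPPPP")),
    verbose = FALSE)
  cd2 <- compositionDistribution(mixed)
  expect_equal(unname(cd2@counts[c(1, 7, 13)]), c(1L, 2L, 1L))
})

test_that("binomial expectation matches brute-force enumeration", {
  # all 4096 outcomes of 12 protomers at p = 0.5
  outcomes <- expand.grid(rep(list(0:1), 12))
  k6 <- mean(rowSums(outcomes) == 6)
  expect_equal(k6, 924 / 4096)
  be <- binomialExpectation(0.5, 12, 1)
  expect_equal(unname(be["6"]), k6, tolerance = 1e-12)
  # full-PLN probability at the observed protomer split
  expect_equal(unname(binomialExpectation(0.57, 12, 1)["12"]), 0.57^12,
               tolerance = 1e-12)
  expect_equal(unname(binomialExpectation(0.57, 12, 1)["12"]), 1.18e-3,
               tolerance = 5e-3)
  # degenerate p
  expect_equal(unname(binomialExpectation(0, 12, 5)["0"]), 5)
  expect_equal(sum(binomialExpectation(0.3, 12, 1000)), 1000,
               tolerance = 1e-9)
  expect_error(binomialExpectation(1.2, 12, 1), "probability")
})

test_that("state-fraction estimates count PLN over classified records", {
  rec <- data.frame(particle_id = sprintf("p%d", 1:100), class_id = 1L,
                    state = c(rep("PLN", 57), rep("FN", 43)))
  est <- estimateStateFraction(ProtomerTable(rec))
  expect_equal(est@pHat, 0.57)
  expect_lt(est@ciLow, 0.57)
  expect_gt(est@ciHigh, 0.57)

  rec0 <- transform(rec, state = "FN")
  est0 <- estimateStateFraction(ProtomerTable(rec0))
  expect_equal(est0@pHat, 0)
  expect_equal(est0@ciLow, 0)

  recU <- transform(rec, state = "UNASSIGNED")
  expect_error(estimateStateFraction(ProtomerTable(recU)), "no records")
})

test_that("canonical necklaces agree with brute-force rotation orbits", {
  expect_equal(canonicalNecklace("PFPFPF"),
               list(canonical = "FPFPFP", orbitSize = 2L))
  expect_equal(canonicalNecklace("PPPPPP"),
               list(canonical = "PPPPPP", orbitSize = 1L))
  expect_error(canonicalNecklace("PPP"), "length 6")
  expect_error(canonicalNecklace("PPPPPX"), "alphabet")

  classes <- brute_necklace_classes()
  expect_length(classes, 14L)
  # class multiplicities by PLN count k = 0..6
  k_of <- vapply(names(classes), function(s)
    sum(strsplit(s, "")[[1]] == "P"), numeric(1))
  expect_equal(unname(table(k_of)), c(1L, 1L, 3L, 4L, 3L, 1L, 1L),
               ignore_attr = TRUE)
  # Burnside cross-check: strings fixed by rotation r number 2^gcd(r,6)
  expect_equal((2^6 + 2^1 + 2^2 + 2^3 + 2^2 + 2^1) / 6, 14)
  # orbit sizes from the package match the brute-force partition
  for (s in names(classes)) {
    cn <- canonicalNecklace(s)
    expect_equal(cn$canonical, s)
    expect_equal(cn$orbitSize, length(classes[[s]]))
  }
})

test_that("canonical form is rotation invariant", {
  set.seed(4)
  for (i in 1:50) {
    s <- paste(sample(c("P", "F"), 6, replace = TRUE), collapse = "")
    base <- canonicalNecklace(s)$canonical
    ch <- strsplit(s, "")[[1]]
    for (r in 1:5)
      expect_equal(
        canonicalNecklace(paste(rotate_chars(ch, r), collapse = ""))$canonical,
        base)
  }
})

test_that("arrangement expectations are normalised and split k=2 correctly", {
  rings <- random_rings(500, 0.57)
  cs <- comp_set_from_rings(rings)
  for (p in c(0, 0.25, 0.5, 0.57, 1)) {
    ad <- arrangementDistribution(cs, p = p)
    expect_equal(sum(ad$expected), 500, tolerance = 1e-9)
    expect_equal(sum(ad$observed), 500)
  }
  ad <- arrangementDistribution(cs, p = 0.5)
  expect_equal(nrow(ad), 14L)
  # the three distinct arrangements of two PLN protomers on the ring
  k2 <- sort(ad$canonical[ad$k_PLN == 2])
  expect_equal(k2, sort(c("FFFFPP", "FFFPFP", "FFPFFP")))
  expect_equal(sum(ad$orbit_size[ad$k_PLN == 2]), choose(6, 2))
})

test_that("pure rings at p = 1 give expected equal to observed", {
  cs <- comp_set_from_rings(rep("PPPPPP", 50))
  ad <- arrangementDistribution(cs, p = 1)
  expect_equal(ad$expected, ad$observed, ignore_attr = TRUE)
})

test_that("goodness-of-fit statistic is zero when observed equals expected", {
  obs <- c(40, 30, 20, 10)
  r <- independenceTest(obs, obs, pEstimated = FALSE)
  expect_equal(r@statistic, 0)
  expect_equal(r@p.value, 1)
  rmc <- independenceTest(obs, obs, method = "exact_multinomial_mc",
                          nRep = 500, seed = 1)
  expect_gt(rmc@p.value, 0.9)
  expect_error(independenceTest(obs, rep(0, 4)), "expected")
})

test_that("sparse classes are pooled before the chi-square", {
  obs <- c(100, 50, 2, 1)
  exp_ <- c(95, 52, 3, 3)
  r <- independenceTest(obs, exp_, pEstimated = FALSE)
  expect_match(r@pooledBins, "2 classes")
  expect_equal(r@df, 3 - 1)  # two kept bins + one pooled bin, minus 1
})

test_that("adjacent same-state pairs are counted on the cyclic ring", {
  r1 <- adjacencyCouplingStat(comp_set_from_rings("PFPFPF"), nPerm = 100,
                              seed = 1)
  expect_equal(r1$statistic, 0)
  r2 <- adjacencyCouplingStat(comp_set_from_rings("PPPFFF"), nPerm = 100,
                              seed = 1)
  expect_equal(r2$statistic, 4)
  expect_warning(
    adjacencyCouplingStat(comp_set_from_rings("PPPFFF"), nPerm = 50,
                          seed = 1),
    "coarse")
})

test_that("composition of independent simulations is binomial", {
  sim <- simulateMetadata(nParticles = 50000, pPLN = 0.5, seed = 17)
  tab <- assignStates(sim$table, ClassStateMap(), verbose = FALSE)
  cd <- compositionDistribution(groupByParticle(tab, verbose = FALSE))
  expected <- binomialExpectation(0.5, 12, cd@nParticles)
  r <- independenceTest(as.numeric(cd@counts), unname(expected),
                        pEstimated = FALSE)
  expect_gt(r@p.value, 0.01)
})

test_that("dihedral equivalence collapses the 14 rotation classes to 13", {
  # bracelet count for binary length-6 strings is 13: the chiral pair of
  # k = 3 arrangements (PPFPFF / PPFFPF) merges under reflection
  all_strings <- apply(expand.grid(rep(list(c("F", "P")), 6)), 1, paste,
                       collapse = "")
  canon_d <- vapply(all_strings, function(s)
    canonicalNecklace(s, dihedral = TRUE)$canonical, character(1))
  expect_length(unique(canon_d), 13L)
  rings <- random_rings(200, 0.5)
  ad <- arrangementDistribution(comp_set_from_rings(rings), p = 0.5,
                                dihedral = TRUE)
  expect_equal(nrow(ad), 13L)
  expect_equal(sum(ad$expected), 200, tolerance = 1e-9)
  expect_equal(sum(ad$observed), 200)
})

test_that("OTHER protomers can be folded into FN for binary statistics", {
  tab <- table_from_rings("PPPPPP", "PPPPPP")
  rec <- records(tab)
  rec$state[1] <- "OTHER"
  tab2 <- ProtomerTable(rec, symmetryGroup = "D6")
  expect_error(
    compositionDistribution(groupByParticle(tab2, verbose = FALSE)),
    "non-binary")
  cs <- groupByParticle(tab2, verbose = FALSE, foldOtherIntoFN = TRUE)
  cd <- compositionDistribution(cs)
  expect_equal(unname(cd@counts[["11"]]), 1L)
})
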