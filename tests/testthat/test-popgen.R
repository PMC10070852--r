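test_that("allele frequencies from counts and from proportions", {
  expect_equal(alleleFrequencies(GenotypeCounts(10, 6, 8))[["p"]],
               26 / 48)
  expect_equal(alleleFrequencies(GenotypeCounts(5, 0, 0))[["p"]], 1)
  expect_equal(alleleFrequencies(GenotypeCounts(1, 2, 1))[["p"]], 0.5)
  expect_error(alleleFrequencies(GenotypeCounts(0, 0, 0)), "n = 0")
  # p = f_hom + f_het/2 on the published proportion rows
  expect_equal(alleleFreqFromGenotypeFreqs(0.46, 0.26), 0.59)
  expect_equal(alleleFreqFromGenotypeFreqs(0.31, 0.54), 0.58)
  expect_equal(alleleFreqFromGenotypeFreqs(0.25, 0.50), 0.5)
  expect_error(alleleFreqFromGenotypeFreqs(-0.1, 0.5), "non-negative")
  # proportion-to-count reconstruction (round half away from zero)
  ct <- countsFromProportions(c(0.42, 0.25, 0.33), 24)
  expect_identical(c(ct@nHomRef, ct@nHet, ct@nHomAlt), c(10L, 6L, 8L))
})

test_that("Hardy-Weinberg expected counts and chi-square", {
  expd <- unname(hweExpected(GenotypeCounts(10, 6, 8)))
  expect_equal(expd, c(7.0417, 11.9167, 5.0417), tolerance = 1e-4)
  expect_equal(sum(expd), 24)
  expect_equal(unname(hweExpected(GenotypeCounts(25, 50, 25))),
               c(25, 50, 25))

  hw <- hweChisq(GenotypeCounts(10, 6, 8))
  expect_equal(hw@chi2, 5.916, tolerance = 1e-3)
  expect_equal(hw@pValue, 0.015, tolerance = 1e-2)
  expect_equal(hw@df, 1)
  expect_equal(hweChisq(GenotypeCounts(25, 50, 25))@chi2, 0)
  expect_equal(hweChisq(GenotypeCounts(30, 10, 10))@chi2, 13.72,
               tolerance = 1e-2)
  # heterozygote deficit gives positive inbreeding estimate
  expect_gt(hw@fHat, 0)
  expect_error(hweChisq(GenotypeCounts(10, 0, 0)), "monomorphic")
})

test_that("chi-square equals the textbook sum over random count triples", {
  set.seed(31)
  for (rep in 1:300) {
    cts <- c(sample(0:40, 1), sample(1:40, 1), sample(0:40, 1))
    n <- sum(cts)
    p <- (2 * cts[1] + cts[2]) / (2 * n)
    if (p %in% c(0, 1)) next
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    ref <- sum((cts - expd)^2 / expd)  # independent direct evaluation
    hw <- hweChisq(GenotypeCounts(cts[1], cts[2], cts[3]))
    expect_equal(hw@chi2, ref, tolerance = 1e-9)
    expect_equal(hw@pValue, pchisq(ref, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("MAF computation and strict-threshold filtering", {
  expect_equal(siteMaf(c(0, 0, 0, 1)), 0.25)
  expect_equal(siteMaf(c(0, 1, 0, 1)), 0.5)
  expect_equal(siteMaf(c(0, 0, 0, 0)), 0)
  expect_equal(siteMaf(c(0, NA, 1, 1)), 1 / 3)
  expect_error(siteMaf(c(NA, NA)), "non-missing")

  # 20 haplotypes: singleton site (maf 0.05) must be dropped at 0.05
  a <- cbind(c(1L, rep(0L, 19)),            # maf 0.05 -> dropped
             c(rep(1L, 2), rep(0L, 18)),    # maf 0.10 -> kept
             rep(0L, 20))                   # monomorphic -> dropped
  h <- HaplotypeMatrix(a, sites = c(3L, 7L, 9L))
  f <- filterByMaf(h, threshold = 0.05)
  expect_identical(sitePositions(f), 7L)
  # threshold 0 keeps exactly the polymorphic sites
  f0 <- filterByMaf(h, threshold = 0)
  expect_identical(sitePositions(f0), c(3L, 7L))
  # high-missingness sites dropped first
  am <- cbind(c(rep(NA, 6), rep(0L, 7), rep(1L, 7)), a[, 2])
  expect_message(fm <- filterByMaf(HaplotypeMatrix(am), maxMissing = 0.2),
                 "missingness")
  expect_identical(nSites(fm), 1L)
})

test_that("Tajima constants reproduce their defining formulas", {
  expect_equal(tajimaConstants(2)[["a1"]], 1)
  expect_equal(tajimaConstants(20)[["a1"]], sum(1 / (1:19)))
  expect_equal(tajimaConstants(24)[["b1"]], 25 / 69)
  expect_error(tajimaConstants(1), "n >= 2")
  for (n in c(4, 10, 24, 50, 200)) {
    k <- tajimaConstants(n)
    i <- seq_len(n - 1)
    expect_equal(k[["a1"]], sum(1 / i), tolerance = 1e-12)
    expect_equal(k[["a2"]], sum(1 / i^2), tolerance = 1e-12)
    expect_equal(k[["c1"]], k[["b1"]] - 1 / k[["a1"]], tolerance = 1e-12)
    expect_equal(k[["c2"]],
                 k[["b2"]] - (n + 2) / (k[["a1"]] * n) +
                   k[["a2"]] / k[["a1"]]^2, tolerance = 1e-12)
    expect_equal(k[["e1"]], k[["c1"]] / k[["a1"]], tolerance = 1e-12)
    expect_equal(k[["e2"]], k[["c2"]] / (k[["a1"]]^2 + k[["a2"]]),
                 tolerance = 1e-12)
    expect_gt(k[["e1"]], 0)
    expect_gt(k[["e2"]], 0)
  }
})

test_that("pairwise pi equals the brute-force all-pairs oracle", {
  # fixed examples
  expect_equal(pairwisePi(HaplotypeMatrix(rbind(c(0L, 0L), c(0L, 1L)))),
               1)
  split1010 <- HaplotypeMatrix(matrix(rep(c(0L, 1L), each = 10), 20, 1))
  expect_equal(pairwisePi(split1010), 100 / 190)
  expect_equal(pairwisePi(HaplotypeMatrix(matrix(0L, 5, 3))), 0)
  # random matrices up to n = 30, S = 50: closed form vs brute force
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    S <- sample(1:50, 1)
    a <- randomHapMatrix(n, S)
    expect_equal(pairwisePi(HaplotypeMatrix(a)), bruteForcePi(a),
                 tolerance = 1e-9)
  }
  # missing data: pairwise deletion agrees with the loop oracle
  a <- randomHapMatrix(8, 10)
  a[sample(length(a), 12)] <- NA
  expect_equal(pairwisePi(HaplotypeMatrix(a)), bruteForcePi(a),
               tolerance = 1e-9)
})

test_that("Tajima's D matches the independent oracle and sign logic", {
  # 20 haplotypes, 20 sites split 10/10: strongly positive D
  a <- matrix(rep(rep(c(0L, 1L), each = 10), 20), 20, 20)
  d <- tajimasD(HaplotypeMatrix(a))
  expect_equal(tajimaD(d), oracleTajimaD(a), tolerance = 1e-9)
  expect_equal(tajimaD(d), 3.30, tolerance = 0.01)
  # 20 singleton sites: excess rare variants depress D
  s <- matrix(0L, 20, 20); for (j in 1:20) s[j, j] <- 1L
  ds <- tajimasD(HaplotypeMatrix(s))
  expect_lt(tajimaD(ds), 0)
  expect_equal(tajimaD(ds), oracleTajimaD(s), tolerance = 1e-9)
  # component identity D = (pi - S/a1)/sqrt(e1 S + e2 S(S-1))
  expect_equal(tajimaD(d),
               (d@pi - d@S / d@a1) /
                 sqrt(d@e1 * d@S + d@e2 * d@S * (d@S - 1)),
               tolerance = 1e-12)
  expect_equal(d@thetaW, d@S / d@a1, tolerance = 1e-12)
  # S = 0 is undefined (NaN with warning), not zero and not an error
  empty <- HaplotypeMatrix(matrix(0L, 6, 2))
  expect_warning(d0 <- tajimasD(empty), "undefined")
  expect_true(is.nan(tajimaD(d0)))
  expect_error(tajimasD(HaplotypeMatrix(matrix(0L, 1, 2))), "at least 2")
  expect_warning(tajimasD(HaplotypeMatrix(rbind(c(0L, 1L), c(1L, 0L)))),
                 "n < 4")
})

test_that("D moves with the site frequency spectrum as theory predicts", {
  set.seed(33)
  base <- randomHapMatrix(12, 8)
  d0 <- tajimaD(tajimasD(HaplotypeMatrix(base)))
  # adding an intermediate-frequency (6/6) site never decreases D
  mid <- cbind(base, rep(c(0L, 1L), each = 6))
  expect_gte(tajimaD(tajimasD(HaplotypeMatrix(mid))), d0)
  expect_equal(tajimaD(tajimasD(HaplotypeMatrix(mid))),
               oracleTajimaD(mid), tolerance = 1e-9)
  # adding a singleton never increases D
  sing <- cbind(base, c(1L, rep(0L, 11)))
  expect_lte(tajimaD(tajimasD(HaplotypeMatrix(sing))), d0)
  expect_equal(tajimaD(tajimasD(HaplotypeMatrix(sing))),
               oracleTajimaD(sing), tolerance = 1e-9)
})

test_that("unphased diploid pi matches its formula and the phased path", {
  # 2 samples both heterozygous at one site: 2 p q * 2N/(2N-1)
  vt <- new("VariantTable", chrom = "locus", pos = 1L, ref = "A",
            alt = list("G"),
            genotypes = matrix(c("0/1", "0/1"), 1, 2,
                               dimnames = list(NULL, c("s1", "s2"))),
            sampleIds = c("s1", "s2"))
  expect_equal(genotypePi(vt), 2 * 0.25 * 4 / 3, tolerance = 1e-12)
  vt0 <- vt; vt0@genotypes[] <- "0/0"
  expect_equal(genotypePi(vt0), 0)
  # equivalence with pairwisePi on phased data expanded to haplotypes
  gm <- matrix(c("0/0", "1/1", "0/1", "0/0", "1/1", "1/1"), 3, 2,
               dimnames = list(NULL, c("s1", "s2")))
  vt2 <- new("VariantTable", chrom = "locus", pos = 1:3,
             ref = rep("A", 3), alt = list("G", "G", "G"),
             genotypes = gm, sampleIds = c("s1", "s2"))
  attr(vt2, "phased") <- TRUE
  h <- haplotypesFromVariants(vt2, phased = TRUE)
  expect_equal(genotypePi(vt2), pairwisePi(h), tolerance = 1e-12)
})
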