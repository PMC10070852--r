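# Population-genetic operations: allele/genotype frequencies,
# Hardy-Weinberg chi-square, MAF filtering and Tajima's D with its full
# constant chain.

#' Allele frequencies from genotype counts
#'
#' p = (2 * n_hom_ref + n_het) / (2n) for the reference (A) allele,
#' q = 1 - p for the alternate (G) allele.
#'
#' @param counts a [GenotypeCounts-class] object.
#' @return named numeric vector `c(p = ..., q = ...)`.
#' @examples
#' alleleFrequencies(GenotypeCounts(10, 6, 8))  # p = 26/48
#' @export
alleleFrequencies <- function(counts) {
  stopifnot(is(counts, "GenotypeCounts"))
  n <- sampleSize(counts)
  if (n < 1L)
    stop("allele frequencies undefined for an empty sample (n = 0)")
  p <- (2 * counts@nHomRef + counts@nHet) / (2 * n)
  c(p = p, q = 1 - p)
}

#' Allele frequency from genotype frequencies
#'
#' p = f_hom_ref + f_het / 2, for use with published genotype-proportion
#' tables where raw counts are unavailable.
#'
#' @param fHomRef frequency of the reference homozygote.
#' @param fHet frequency of the heterozygote.
#' @return the reference-allele frequency.
#' @examples
#' alleleFreqFromGenotypeFreqs(0.46, 0.26)  # 0.59
#' @export
alleleFreqFromGenotypeFreqs <- function(fHomRef, fHet) {
  if (any(fHomRef < 0) || any(fHet < 0))
    stop("genotype frequencies must be non-negative")
  if (any(fHomRef + fHet > 1 + 1e-9))
    stop("genotype frequencies exceed 1")
  fHomRef + fHet / 2
}

#' Reconstruct integer genotype counts from printed proportions
#'
#' Multiplies each proportion by n and rounds half away from zero, the
#' reconstruction rule for recovering count data from a table printed to
#' two decimals.
#'
#' @param freqs numeric length-3 genotype proportions (hom ref, het,
#'   hom alt).
#' @param n total sample size.
#' @param population label for the resulting object.
#' @return a [GenotypeCounts-class] object.
#' @examples
#' countsFromProportions(c(0.42, 0.25, 0.33), 24)  # 10, 6, 8
#' @export
countsFromProportions <- function(freqs, n, population = "pop") {
  stopifnot(length(freqs) == 3L)
  roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)
  cts <- roundHalfAway(freqs * n)
  GenotypeCounts(cts[1], cts[2], cts[3], population = population)
}

#' Expected genotype counts under Hardy-Weinberg equilibrium
#'
#' (n p^2, 2 n p q, n q^2) with p estimated from the observed counts;
#' the three always sum to n.
#'
#' @param counts a [GenotypeCounts-class] object.
#' @return numeric length-3 expected counts.
#' @examples
#' hweExpected(GenotypeCounts(10, 6, 8))
#' @export
hweExpected <- function(counts) {
  n <- sampleSize(counts)
  if (n < 1L) stop("n = 0: no expected counts")
  f <- alleleFrequencies(counts)
  n * c(f["p"]^2, 2 * f["p"] * f["q"], f["q"]^2)
}

#' Hardy-Weinberg chi-square test
#'
#' Goodness-of-fit chi-square over the three genotype classes,
#' sum((obs - exp)^2 / exp), with df = 1 (three classes, one estimated
#' allele frequency) and no continuity correction. Also returns the
#' inbreeding coefficient estimate F = 1 - observed het / expected het
#' (positive F means a heterozygote deficit).
#'
#' @param counts a [GenotypeCounts-class] object with both alleles present.
#' @return an [HWEResult-class] object.
#' @examples
#' hweChisq(GenotypeCounts(10, 6, 8))  # chi2 = 5.916, p ~ 0.015
#' @export
hweChisq <- function(counts) {
  n <- sampleSize(counts)
  if (n < 1L) stop("n = 0: test undefined")
  f <- alleleFrequencies(counts)
  if (f["p"] == 0 || f["p"] == 1)
    stop("monomorphic sample: Hardy-Weinberg test undefined")
  expd <- unname(hweExpected(counts))
  obs <- c(counts@nHomRef, counts@nHet, counts@nHomAlt)
  if (any(expd == 0 & obs > 0)) {
    warning("expected count of zero with nonzero observations; ",
            "statistic reported as infinite")
    chi2 <- Inf
  } else {
    ok <- expd > 0
    chi2 <- sum((obs[ok] - expd[ok])^2 / expd[ok])
  }
  fHat <- 1 - obs[2] / expd[2]
  new("HWEResult",
      chi2 = chi2, df = 1,
      pValue = pchisq(chi2, df = 1, lower.tail = FALSE),
      expected = expd, fHat = fHat)
}

#' Minor allele frequency of one site
#'
#' min(freq(0), freq(1)) among non-missing allele codes.
#'
#' @param column vector of allele codes in \{0, 1, NA\}.
#' @return the minor allele frequency.
#' @examples
#' siteMaf(c(0, 0, 0, 1))  # 0.25
#' @export
siteMaf <- function(column) {
  v <- column[!is.na(column)]
  if (length(v) < 2L)
    stop("need at least 2 non-missing alleles to compute a MAF")
  f1 <- mean(v == 1)
  min(f1, 1 - f1)
}

#' Filter haplotype-matrix sites by minor allele frequency
#'
#' Retains sites with MAF strictly greater than `threshold` (strict
#' inequality: a site at exactly the threshold is dropped). Column order
#' is preserved; sites with more than `maxMissing` missingness are dropped
#' first with a message.
#'
#' @param hap a [HaplotypeMatrix-class] object.
#' @param threshold MAF cut, default 0.05.
#' @param maxMissing maximum tolerated per-site missing fraction
#'   (default 0.2).
#' @return a filtered [HaplotypeMatrix-class] (possibly zero sites).
#' @export
filterByMaf <- function(hap, threshold = 0.05, maxMissing = 0.2) {
  stopifnot(is(hap, "HaplotypeMatrix"))
  a <- hap@alleles
  if (ncol(a) == 0L) return(hap)
  missFrac <- colMeans(is.na(a))
  tooMissing <- missFrac > maxMissing
  if (any(tooMissing))
    message(sum(tooMissing), " site(s) dropped for >",
            round(100 * maxMissing), "% missingness")
  keepMiss <- !tooMissing
  mafs <- rep(0, ncol(a))
  for (j in which(keepMiss)) {
    v <- a[!is.na(a[, j]), j]
    mafs[j] <- if (length(v) >= 2L) min(mean(v == 1), mean(v == 0)) else 0
  }
  keep <- keepMiss & mafs > threshold
  HaplotypeMatrix(a[, keep, drop = FALSE], sites = hap@sites[keep])
}

#' Tajima (1989) constants
#'
#' The full constant chain for a sample of n haplotypes:
#' a1 = sum 1/i, a2 = sum 1/i^2 (i = 1..n-1), b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#'
#' @param n haplotype count, at least 2.
#' @return named numeric vector with a1, a2, b1, b2, c1, c2, e1, e2.
#' @examples
#' tajimaConstants(24)["b1"]  # 25/69
#' @export
tajimaConstants <- function(n) {
  if (n < 2L) stop("Tajima constants need n >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
    e1 = e1, e2 = e2)
}

#' Mean pairwise differences (nucleotide diversity pi)
#'
#' Average over all C(n, 2) haplotype pairs of the number of sites at
#' which the pair differs; sites missing in either member of a pair are
#' excluded for that pair (pairwise deletion). On complete data this
#' equals sum_j 2 p_j (1 - p_j) n/(n - 1).
#'
#' @param hap a [HaplotypeMatrix-class] object with n >= 2.
#' @return pi, in units of sites.
#' @export
pairwisePi <- function(hap) {
  stopifnot(is(hap, "HaplotypeMatrix"))
  a <- hap@alleles
  n <- nrow(a)
  if (n < 2L) stop("pi needs at least 2 haplotypes")
  if (ncol(a) == 0L) return(0)
  if (!anyNA(a)) {
    # per-site closed form, vectorized
    p <- colMeans(a)
    return(sum(2 * p * (1 - p)) * n / (n - 1))
  }
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- a[i, ] != a[j, ]
      total <- total + sum(d, na.rm = TRUE)
    }
  }
  total / choose(n, 2)
}

#' Tajima's D with full component decomposition
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1)). Positive D indicates an
#' excess of intermediate-frequency variants (the balancing-selection
#' signature); negative D an excess of rare variants. With S = 0 the
#' statistic is undefined and D is returned as NaN with a warning, never
#' as 0.
#'
#' @param hap a [HaplotypeMatrix-class] object; n >= 4 recommended (a
#'   warning is issued below that).
#' @param mafThreshold optional MAF filter applied first via
#'   [filterByMaf()] (NULL = no filtering).
#' @return a [TajimaComponents-class] object.
#' @examples
#' h <- HaplotypeMatrix(matrix(rep(c(0, 1), each = 10), ncol = 1))
#' tajimasD(h)
#' @export
tajimasD <- function(hap, mafThreshold = NULL) {
  stopifnot(is(hap, "HaplotypeMatrix"))
  n <- nHaplotypes(hap)
  if (n < 2L) stop("Tajima's D needs at least 2 haplotypes")
  if (n < 4L) warning("n < 4: Tajima's D is unreliable at this size")
  if (!is.null(mafThreshold))
    hap <- filterByMaf(hap, threshold = mafThreshold)
  a <- hap@alleles
  seg <- logical(ncol(a))
  for (j in seq_len(ncol(a))) {
    v <- a[!is.na(a[, j]), j]
    seg[j] <- length(v) >= 2L && any(v == 0) && any(v == 1)
  }
  S <- sum(seg)
  k <- tajimaConstants(n)
  if (S == 0L) {
    warning("no segregating sites: Tajima's D undefined (NaN)")
    return(new("TajimaComponents", n = as.integer(n), S = 0L,
               pi = 0, thetaW = 0,
               a1 = k[["a1"]], a2 = k[["a2"]], b1 = k[["b1"]],
               b2 = k[["b2"]], c1 = k[["c1"]], c2 = k[["c2"]],
               e1 = k[["e1"]], e2 = k[["e2"]], D = NaN))
  }
  segHap <- HaplotypeMatrix(a[, seg, drop = FALSE],
                            sites = hap@sites[seg])
  pi <- pairwisePi(segHap)
  thetaW <- S / k[["a1"]]
  D <- (pi - thetaW) / sqrt(k[["e1"]] * S + k[["e2"]] * S * (S - 1))
  new("TajimaComponents", n = as.integer(n), S = as.integer(S),
      pi = pi, thetaW = thetaW,
      a1 = k[["a1"]], a2 = k[["a2"]], b1 = k[["b1"]], b2 = k[["b2"]],
      c1 = k[["c1"]], c2 = k[["c2"]], e1 = k[["e1"]], e2 = k[["e2"]],
      D = D)
}

#' Per-site diversity from unphased diploid genotypes
#'
#' "Unphased mode" used when haplotype phase is unavailable: the 2N allele
#' copies at each site are treated as the sample, so
#' pi_site = 2 p (1 - p) * 2N / (2N - 1), summed over sites. On phased
#' data expanded to haplotypes this agrees with [pairwisePi()] by
#' construction.
#'
#' @param variants a [VariantTable-class] object with diploid genotypes,
#'   at least 2 samples.
#' @return summed per-site diversity (units: sites).
#' @export
genotypePi <- function(variants) {
  stopifnot(is(variants, "VariantTable"))
  gts <- variants@genotypes
  if (ncol(gts) < 2L) stop("unphased pi needs at least 2 diploid samples")
  total <- 0
  for (i in seq_len(nrow(gts))) {
    alleles <- unlist(strsplit(gts[i, ], "/", fixed = TRUE))
    alleles <- alleles[alleles != "."]
    m <- length(alleles)
    if (m < 2L) next
    p <- mean(alleles == "1")
    total <- total + 2 * p * (1 - p) * m / (m - 1)
  }
  total
}
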