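#' @import methods
#' @importFrom stats dnorm pchisq quantile rbinom rexp rmultinom rnorm rpois
#'   runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

#' One-dimensional Gaussian mixture fit of M-values
#'
#' Holds the maximum-likelihood parameters of a univariate Gaussian mixture
#' fitted to M-values at a SNP-overlapping methylation probe. Components are
#' always stored sorted by ascending mean, so for the canonical three-class
#' fit component 1 is the hypomethylated class, component 2 the
#' hemimethylated class and component 3 the hypermethylated class.
#'
#' @slot k integer, number of components (1--3).
#' @slot weights numeric, mixing proportions summing to 1.
#' @slot means numeric, component means on the M-value scale, strictly
#'   increasing.
#' @slot sds numeric, positive component standard deviations (M-value scale).
#' @slot logLik numeric, maximized log-likelihood.
#' @slot bic numeric, Bayesian information criterion of the fit.
#' @slot converged logical, whether EM met the log-likelihood tolerance.
#' @slot nIter integer, EM iterations used.
#'
#' @seealso [fitMethylationMixture()], [callGenotypes()]
#' @export
setClass("MixtureFit",
  representation(
    k = "integer",
    weights = "numeric",
    means = "numeric",
    sds = "numeric",
    logLik = "numeric",
    bic = "numeric",
    converged = "logical",
    nIter = "integer"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character(0)
  k <- object@k
  if (length(k) != 1L || k < 1L)
    msg <- c(msg, "'k' must be a single positive integer")
  if (length(object@weights) != k || length(object@means) != k ||
      length(object@sds) != k)
    msg <- c(msg, "'weights', 'means' and 'sds' must each have length k")
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "'weights' must sum to 1 (tolerance 1e-9)")
  if (k > 1L && any(diff(object@means) <= 0))
    msg <- c(msg, "'means' must be strictly increasing")
  if (any(object@sds <= 0))
    msg <- c(msg, "'sds' must all be positive")
  if (length(msg)) msg else TRUE
})

#' Genotype counts for one population
#'
#' Counts of the three diploid genotype classes at a biallelic site, the
#' unit on which allele-frequency estimation and the Hardy-Weinberg
#' chi-square test operate. By convention the "ref" homozygote carries the
#' low-methylation (CpG-abolishing) allele, A at the motivating locus.
#'
#' @slot population character, population label.
#' @slot nHomRef integer, homozygous-reference count (e.g. A/A).
#' @slot nHet integer, heterozygote count (e.g. A/G).
#' @slot nHomAlt integer, homozygous-alternate count (e.g. G/G).
#'
#' @seealso [alleleFrequencies()], [hweChisq()]
#' @export
setClass("GenotypeCounts",
  representation(
    population = "character",
    nHomRef = "integer",
    nHet = "integer",
    nHomAlt = "integer"
  )
)

setValidity("GenotypeCounts", function(object) {
  cts <- c(object@nHomRef, object@nHet, object@nHomAlt)
  if (length(cts) != 3L || anyNA(cts) || any(cts < 0L))
    return("counts must be three non-negative integers")
  TRUE
})

#' Hardy-Weinberg chi-square test result
#'
#' @slot chi2 numeric, chi-square statistic (no continuity correction).
#' @slot df numeric, degrees of freedom (1 for a biallelic site).
#' @slot pValue numeric, upper-tail p-value.
#' @slot expected numeric, the three expected genotype counts under HWE.
#' @slot fHat numeric, inbreeding coefficient estimate
#'   1 - observed het / expected het.
#'
#' @seealso [hweChisq()]
#' @export
setClass("HWEResult",
  representation(
    chi2 = "numeric",
    df = "numeric",
    pValue = "numeric",
    expected = "numeric",
    fHat = "numeric"
  )
)

setValidity("HWEResult", function(object) {
  msg <- character(0)
  if (is.finite(object@chi2) && object@chi2 < 0)
    msg <- c(msg, "'chi2' must be non-negative")
  if (length(object@expected) != 3L)
    msg <- c(msg, "'expected' must have length 3")
  if (is.finite(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "'pValue' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Matrix of biallelic haplotypes
#'
#' n haplotypes by S biallelic sites, coded 0 (ancestral/ref), 1
#' (derived/alt) or NA (missing). Site positions are 1-based and strictly
#' increasing. This is the unit on which the diversity statistics
#' ([pairwisePi()], [tajimasD()]) operate.
#'
#' @slot alleles integer matrix, n x S with entries in \{0, 1, NA\}.
#' @slot sites integer, 1-based positions of the S sites, strictly
#'   increasing.
#'
#' @seealso [HaplotypeMatrix()], [filterByMaf()], [tajimasD()]
#' @export
setClass("HaplotypeMatrix",
  representation(
    alleles = "matrix",
    sites = "integer"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- character(0)
  a <- object@alleles
  if (!is.numeric(a) && !is.integer(a))
    msg <- c(msg, "'alleles' must be a numeric matrix")
  if (length(object@sites) != ncol(a))
    msg <- c(msg, "'sites' length must equal the number of columns")
  if (length(object@sites) > 1L && any(diff(object@sites) <= 0))
    msg <- c(msg, "'sites' must be strictly increasing")
  vals <- a[!is.na(a)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    msg <- c(msg, "allele codes must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Full decomposition of a Tajima's D computation
#'
#' All intermediate quantities of the statistic: the sample size, the
#' segregating-site count, the two diversity estimators and the constant
#' chain a1, a2, b1, b2, c1, c2, e1, e2 (Tajima 1989), together with D
#' itself. D is NaN when S = 0 (the statistic is undefined without
#' polymorphism).
#'
#' @slot n integer, haplotype count.
#' @slot S integer, segregating-site count.
#' @slot pi numeric, mean pairwise differences (units: sites).
#' @slot thetaW numeric, Watterson's estimator S/a1 (units: sites).
#' @slot a1,a2,b1,b2,c1,c2,e1,e2 numeric, the constant chain.
#' @slot D numeric, the statistic (dimensionless).
#'
#' @seealso [tajimasD()], [tajimaConstants()]
#' @export
setClass("TajimaComponents",
  representation(
    n = "integer",
    S = "integer",
    pi = "numeric",
    thetaW = "numeric",
    a1 = "numeric", a2 = "numeric",
    b1 = "numeric", b2 = "numeric",
    c1 = "numeric", c2 = "numeric",
    e1 = "numeric", e2 = "numeric",
    D = "numeric"
  )
)

setValidity("TajimaComponents", function(object) {
  msg <- character(0)
  if (object@n < 2L) msg <- c(msg, "'n' must be at least 2")
  if (object@S < 0L) msg <- c(msg, "'S' must be non-negative")
  if (object@S >= 2L && is.finite(object@D)) {
    check <- (object@pi - object@S / object@a1) /
      sqrt(object@e1 * object@S + object@e2 * object@S * (object@S - 1))
    if (abs(check - object@D) > 1e-9)
      msg <- c(msg, "'D' does not reproduce its defining formula")
  }
  if (length(msg)) msg else TRUE
})

#' Variant sites extracted from an alignment
#'
#' One record per polymorphic alignment column, VCF-serializable.
#' Positions are 1-based alignment columns. Genotype strings are haploid
#' ("0", "1", ".") or unphased diploid ("0/0", "0/1", "1/1", "./.");
#' phased "|" input is normalized to "/" on read.
#'
#' @slot chrom character, contig/locus label (recycled over records).
#' @slot pos integer, 1-based positions, strictly increasing.
#' @slot ref character, reference allele per record (majority allele,
#'   alphabetical tie-break).
#' @slot alt list of character, alternate allele(s) per record.
#' @slot genotypes character matrix, records x samples.
#' @slot sampleIds character, column names of `genotypes`.
#'
#' @seealso [variantsFromAlignment()], [writeVariantVcf()],
#'   [haplotypesFromVariants()]
#' @export
setClass("VariantTable",
  representation(
    chrom = "character",
    pos = "integer",
    ref = "character",
    alt = "list",
    genotypes = "matrix",
    sampleIds = "character"
  )
)

setValidity("VariantTable", function(object) {
  msg <- character(0)
  nr <- length(object@pos)
  if (length(object@ref) != nr || length(object@alt) != nr)
    msg <- c(msg, "'ref' and 'alt' must have one entry per position")
  if (nr > 1L && any(diff(object@pos) <= 0))
    msg <- c(msg, "'pos' must be strictly increasing")
  if (nrow(object@genotypes) != nr)
    msg <- c(msg, "'genotypes' must have one row per position")
  if (ncol(object@genotypes) != length(object@sampleIds))
    msg <- c(msg, "'genotypes' must have one column per sample id")
  for (i in seq_len(nr)) {
    if (object@ref[i] %in% object@alt[[i]])
      msg <- c(msg, sprintf("record %d: ref allele appears in alt", i))
  }
  if (length(msg)) msg else TRUE
})
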