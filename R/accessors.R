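# Constructors, accessors and show methods for the core classes.

#' Construct a HaplotypeMatrix
#'
#' @param alleles numeric/integer matrix, n haplotypes x S sites, entries in
#'   \{0, 1, NA\}.
#' @param sites integer vector of 1-based site positions (default
#'   `seq_len(ncol(alleles))`), strictly increasing.
#' @return A [HaplotypeMatrix-class] object.
#' @examples
#' h <- HaplotypeMatrix(rbind(c(0, 0), c(0, 1), c(1, 1)))
#' nHaplotypes(h)
#' @export
HaplotypeMatrix <- function(alleles, sites = seq_len(ncol(alleles))) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  new("HaplotypeMatrix", alleles = alleles, sites = as.integer(sites))
}

#' Construct a GenotypeCounts object
#'
#' @param nHomRef,nHet,nHomAlt non-negative integer counts of the three
#'   genotype classes.
#' @param population population label.
#' @return A [GenotypeCounts-class] object.
#' @examples
#' GenotypeCounts(10, 6, 8, population = "HA")
#' @export
GenotypeCounts <- function(nHomRef, nHet, nHomAlt, population = "pop") {
  new("GenotypeCounts",
      population = as.character(population),
      nHomRef = as.integer(nHomRef),
      nHet = as.integer(nHet),
      nHomAlt = as.integer(nHomAlt))
}

#' @describeIn HaplotypeMatrix-class number of haplotypes (rows).
#' @param x a `HaplotypeMatrix`.
#' @export
nHaplotypes <- function(x) nrow(x@alleles)

#' @describeIn HaplotypeMatrix-class number of sites (columns).
#' @export
nSites <- function(x) ncol(x@alleles)

#' @describeIn HaplotypeMatrix-class integer allele matrix.
#' @export
alleleMatrix <- function(x) x@alleles

#' @describeIn HaplotypeMatrix-class 1-based site positions.
#' @export
sitePositions <- function(x) x@sites

#' Total sample size of a GenotypeCounts object
#' @param x a [GenotypeCounts-class] object.
#' @return integer, sum of the three genotype counts.
#' @export
sampleSize <- function(x) {
  stopifnot(is(x, "GenotypeCounts"))
  x@nHomRef + x@nHet + x@nHomAlt
}

#' @describeIn MixtureFit-class component means, ascending.
#' @param object a `MixtureFit`.
#' @export
mixtureMeans <- function(object) object@means

#' @describeIn MixtureFit-class component standard deviations.
#' @export
mixtureSds <- function(object) object@sds

#' @describeIn MixtureFit-class mixing proportions.
#' @export
mixtureWeights <- function(object) object@weights

#' @describeIn TajimaComponents-class the D statistic.
#' @param x a `TajimaComponents`.
#' @export
tajimaD <- function(x) x@D

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: k = %d, %s, logLik = %.3f, BIC = %.3f\n",
              object@k,
              if (object@converged) "converged" else "NOT converged",
              object@logLik, object@bic))
  print(data.frame(weight = round(object@weights, 4),
                   mean = round(object@means, 4),
                   sd = round(object@sds, 4)))
  invisible(NULL)
})

setMethod("show", "GenotypeCounts", function(object) {
  cat(sprintf("GenotypeCounts [%s]: hom_ref = %d, het = %d, hom_alt = %d (n = %d)\n",
              object@population, object@nHomRef, object@nHet,
              object@nHomAlt, sampleSize(object)))
  invisible(NULL)
})

setMethod("show", "HWEResult", function(object) {
  cat(sprintf("HWE chi-square test: chi2 = %.4f, df = %d, p = %.4g, F = %.4f\n",
              object@chi2, as.integer(object@df), object@pValue,
              object@fHat))
  invisible(NULL)
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes x %d sites\n",
              nHaplotypes(object), nSites(object)))
  invisible(NULL)
})

setMethod("show", "TajimaComponents", function(object) {
  cat(sprintf("Tajima's D = %.4f  (n = %d, S = %d, pi = %.4f, theta_W = %.4f)\n",
              object@D, object@n, object@S, object@pi, object@thetaW))
  invisible(NULL)
})

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d record(s), %d sample(s) on '%s'\n",
              length(object@pos), length(object@sampleIds),
              object@chrom[1]))
  if (length(object@pos)) {
    alt <- vapply(object@alt, paste, "", collapse = ",")
    print(utils::head(data.frame(pos = object@pos, ref = object@ref,
                                 alt = alt), 10))
  }
  invisible(NULL)
})
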