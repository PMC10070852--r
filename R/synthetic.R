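# Synthetic-data generators: Gaussian methylation classes, genotype counts
# under inbreeding, and neutral / two-class balanced coalescent haplotype
# samples. Every generator is deterministic given (seed, config); pass
# seed = NULL to draw from the current RNG stream (used when a caller
# threads one seed across many replicates).

.seedIf <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

#' Simulate methylation samples from the three genotype classes
#'
#' Draws M-values from one Gaussian per genotype class (hypomethylated
#' homozygote, hemimethylated heterozygote, hypermethylated homozygote)
#' and derives beta-values via [mToBeta()]. Defaults are the 96-sample
#' cohort class parameters; the `"test"` preset in
#' [methylationClassPreset()] gives tight, well-separated classes for
#' accuracy checks.
#'
#' @param nPerGenotype integer length-3, samples per class (A/A, A/G,
#'   G/G).
#' @param classMeans,classSds numeric length-3 class parameters on the M
#'   scale (means ascending), defaults the 96-sample cohort values
#'   (-4.21, -0.51, 1.41) and (1.96, 2.06, 0.97).
#' @param seed integer seed (NULL = use current RNG state).
#' @param lowAllele,highAllele allele letters used in the true-genotype
#'   labels.
#' @return data.frame with `sample_id`, `beta`, `m_value`,
#'   `true_genotype`.
#' @examples
#' head(simulateMethylation(c(5, 5, 5), seed = 1))
#' @export
simulateMethylation <- function(nPerGenotype,
                                classMeans = c(-4.21, -0.51, 1.41),
                                classSds = c(1.96, 2.06, 0.97),
                                seed = NULL,
                                lowAllele = "A", highAllele = "G") {
  stopifnot(length(nPerGenotype) == 3L, length(classMeans) == 3L,
            length(classSds) == 3L)
  if (any(classSds <= 0)) stop("class sds must be positive")
  ord <- order(classMeans)
  classMeans <- classMeans[ord]
  classSds <- classSds[ord]
  .seedIf(seed)
  labels <- c(paste(lowAllele, lowAllele, sep = "/"),
              paste(lowAllele, highAllele, sep = "/"),
              paste(highAllele, highAllele, sep = "/"))
  m <- numeric(0)
  gt <- character(0)
  for (cls in 1:3) {
    nc <- nPerGenotype[cls]
    if (nc > 0) {
      m <- c(m, rnorm(nc, classMeans[cls], classSds[cls]))
      gt <- c(gt, rep(labels[cls], nc))
    }
  }
  data.frame(sample_id = sprintf("s%03d", seq_along(m)),
             beta = mToBeta(m),
             m_value = m,
             true_genotype = gt,
             stringsAsFactors = FALSE)
}

#' Simulate genotype counts under inbreeding
#'
#' Multinomial draw of n diploid genotypes from
#' (p^2 + f p q, 2 p q (1 - f), q^2 + f p q): f = 0 is Hardy-Weinberg
#' equilibrium, f > 0 a heterozygote deficit, f = 1 no heterozygotes.
#'
#' @param n sample size.
#' @param p reference-allele frequency in [0, 1].
#' @param f inbreeding coefficient in [-min(p/q, q/p), 1].
#' @param seed integer seed (NULL = current RNG state).
#' @param population label.
#' @return a [GenotypeCounts-class] object.
#' @examples
#' simulateGenotypeCounts(24, p = 0.54, f = 0.5, seed = 1)
#' @export
simulateGenotypeCounts <- function(n, p, f = 0, seed = NULL,
                                   population = "sim") {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  q <- 1 - p
  probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12))
    stop("genotype probabilities outside [0, 1]; f = ", f,
         " is infeasible for p = ", p)
  probs <- pmin(pmax(probs, 0), 1)
  .seedIf(seed)
  cts <- as.vector(rmultinom(1, n, probs))
  GenotypeCounts(cts[1], cts[2], cts[3], population = population)
}

# Kingman coalescent for n leaves: returns the branch segments
# (descendant leaf set + length) and the TMRCA. Time is in units of 2N
# generations.
.coalescentSegments <- function(n) {
  lineages <- lapply(seq_len(n), identity)
  segLeaves <- list()
  segLen <- numeric(0)
  tmrca <- 0
  k <- n
  while (k > 1L) {
    t <- rexp(1, rate = k * (k - 1) / 2)
    tmrca <- tmrca + t
    segLeaves <- c(segLeaves, lineages)
    segLen <- c(segLen, rep(t, k))
    pair <- sample.int(k, 2L)
    merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages <- c(lineages[-pair], list(merged))
    k <- k - 1L
  }
  list(leaves = segLeaves, len = segLen, tmrca = tmrca)
}

#' Simulate haplotypes under the neutral coalescent
#'
#' Standard n-sample Kingman coalescent (exponential coalescence times
#' with rate choose(k, 2), time in units of 2N generations) with
#' infinite-sites mutation: mutation count Poisson with mean
#' theta/2 times the total branch length, each mutation a unique site
#' whose carriers are the leaves below its branch. theta is the per-locus
#' scaled mutation rate (4 N mu per locus, not per site). The expected
#' segregating-site count is theta * a1(n).
#'
#' @param n haplotype count, at least 2.
#' @param theta per-locus scaled mutation rate, non-negative.
#' @param seed integer seed (NULL = current RNG state).
#' @return a [HaplotypeMatrix-class] with the TMRCA attached as attribute
#'   `"tmrca"` (coalescent units).
#' @examples
#' h <- simulateNeutralHaplotypes(10, theta = 5, seed = 1)
#' nSites(h)
#' @export
simulateNeutralHaplotypes <- function(n, theta, seed = NULL) {
  if (n < 2L) stop("coalescent sample needs n >= 2")
  if (theta < 0) stop("theta must be non-negative")
  .seedIf(seed)
  tree <- .coalescentSegments(n)
  totalLen <- sum(tree$len)
  nMut <- rpois(1, theta / 2 * totalLen)
  if (nMut == 0L) {
    h <- HaplotypeMatrix(matrix(integer(0), n, 0), sites = integer(0))
    attr(h, "tmrca") <- tree$tmrca
    return(h)
  }
  segIdx <- sample.int(length(tree$len), nMut, replace = TRUE,
                       prob = tree$len)
  a <- matrix(0L, n, nMut)
  for (m in seq_len(nMut))
    a[tree$leaves[[segIdx[m]]], m] <- 1L
  h <- HaplotypeMatrix(a, sites = seq_len(nMut))
  attr(h, "tmrca") <- tree$tmrca
  h
}

#' Simulate a two-class balanced polymorphism
#'
#' Structural surrogate for an ancient balanced polymorphism: each
#' allelic class is an independent neutral coalescent sample with
#' within-class mutation rate `thetaWithin`, and `kFixed` additional
#' sites are fixed differences between the classes (class 2 carries the
#' derived allele). Concatenating the classes yields a sample whose
#' intermediate-frequency fixed differences inflate pi relative to
#' Watterson's theta — the positive-Tajima's-D signature of balancing
#' selection — without modelling selection coefficients.
#'
#' @param nPerClass integer length-2, haplotypes per allelic class (both
#'   positive).
#' @param thetaWithin per-locus scaled mutation rate within each class.
#' @param kFixed number of fixed inter-class differences.
#' @param seed integer seed (NULL = current RNG state).
#' @return a [HaplotypeMatrix-class] of `sum(nPerClass)` haplotypes; the
#'   class of each haplotype is attached as attribute `"alleleClass"`.
#' @examples
#' h <- simulateBalancedHaplotypes(c(10, 10), thetaWithin = 0,
#'                                 kFixed = 5, seed = 1)
#' tajimaD(tajimasD(h))
#' @export
simulateBalancedHaplotypes <- function(nPerClass, thetaWithin = 1,
                                       kFixed = 0, seed = NULL) {
  stopifnot(length(nPerClass) == 2L)
  if (any(nPerClass < 1L)) stop("both allelic classes must be non-empty")
  if (kFixed < 0) stop("kFixed must be non-negative")
  if (kFixed == 0 && thetaWithin == 0)
    warning("kFixed = 0 and thetaWithin = 0: no variation will be ",
            "generated")
  .seedIf(seed)
  n1 <- nPerClass[1]; n2 <- nPerClass[2]
  h1 <- simulateNeutralHaplotypes(n1, thetaWithin, seed = NULL)
  h2 <- simulateNeutralHaplotypes(n2, thetaWithin, seed = NULL)
  s1 <- nSites(h1); s2 <- nSites(h2)
  S <- s1 + s2 + kFixed
  a <- matrix(0L, n1 + n2, S)
  if (s1 > 0) a[seq_len(n1), seq_len(s1)] <- alleleMatrix(h1)
  if (s2 > 0) a[n1 + seq_len(n2), s1 + seq_len(s2)] <- alleleMatrix(h2)
  if (kFixed > 0) a[n1 + seq_len(n2), s1 + s2 + seq_len(kFixed)] <- 1L
  h <- HaplotypeMatrix(a, sites = seq_len(S))
  attr(h, "alleleClass") <- rep(1:2, c(n1, n2))
  h
}

#' Write simulated haplotypes as an aligned FASTA
#'
#' Renders a haplotype matrix as sequences over a monomorphic background,
#' mapping allele 0 to `refBase` ("A") and allele 1 to `altBase` ("G") at
#' the variant columns. With `diploid = TRUE` consecutive haplotype pairs
#' are collapsed into diploid consensus sequences using IUPAC ambiguity
#' codes at heterozygous positions (R for A/G), emulating Sanger-style
#' consensus sequences.
#'
#' @param hap a [HaplotypeMatrix-class] object.
#' @param path output FASTA path.
#' @param length total alignment length (default: enough to hold the
#'   sites, at least 60); sites are placed at their recorded positions.
#' @param refBase,altBase bases for alleles 0 and 1.
#' @param background base filling the monomorphic columns (default "C").
#' @param diploid collapse haplotype pairs into IUPAC consensus diploids.
#' @return the path, invisibly.
#' @export
writeHaplotypeFasta <- function(hap, path,
                                length = max(60L, max(c(0L, hap@sites))),
                                refBase = "A", altBase = "G",
                                background = "C", diploid = FALSE) {
  stopifnot(is(hap, "HaplotypeMatrix"))
  a <- alleleMatrix(hap)
  n <- nrow(a)
  iupac <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  seqFor <- function(alleles) {
    s <- rep(background, length)
    s[hap@sites] <- ifelse(is.na(alleles), "N",
                           ifelse(alleles == 0, refBase, altBase))
    paste(s, collapse = "")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!diploid) {
    ids <- rownames(a)
    if (is.null(ids)) ids <- paste0("hap", seq_len(n))
    for (i in seq_len(n)) {
      writeLines(paste0(">", ids[i]), con)
      writeLines(seqFor(a[i, ]), con)
    }
  } else {
    if (n %% 2L != 0L)
      stop("diploid output needs an even number of haplotypes")
    for (s in seq_len(n / 2L)) {
      b1 <- a[2L * s - 1L, ]; b2 <- a[2L * s, ]
      chars <- rep(background, length)
      for (jj in seq_along(hap@sites)) {
        x <- b1[jj]; y <- b2[jj]
        ch <- if (is.na(x) || is.na(y)) "N"
        else if (x == y) {
          if (x == 0) refBase else altBase
        } else {
          key <- paste(sort(c(refBase, altBase)), collapse = "")
          iupac[[key]]
        }
        chars[hap@sites[jj]] <- ch
      }
      writeLines(paste0(">ind", s), con)
      writeLines(paste(chars, collapse = ""), con)
    }
  }
  invisible(path)
}
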