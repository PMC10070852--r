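# End-to-end orchestration: methylation -> genotype calls ->
# frequencies/HWE per population -> alignment variants -> MAF filter ->
# Tajima's D -> report. All module-level math is called directly; the
# pipeline adds no arithmetic of its own.

.log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Read a genotype CSV into per-population counts
#'
#' Expects columns `sample_id`, `genotype` and optionally `population`
#' (default "all"). Genotypes are two allele letters joined by "/" or
#' plain concatenation ("A/G" or "AG").
#'
#' @param path CSV path.
#' @param lowAllele,highAllele the two allele letters (reference first).
#' @return named list of [GenotypeCounts-class], one per population.
#' @export
readGenotypeCsv <- function(path, lowAllele = "A", highAllele = "G") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "genotype") %in% names(df)))
    stop("genotype CSV needs 'sample_id' and 'genotype' columns")
  if (!"population" %in% names(df)) df$population <- "all"
  g <- gsub("/", "", df$genotype, fixed = TRUE)
  homRef <- paste0(lowAllele, lowAllele)
  hets <- c(paste0(lowAllele, highAllele), paste0(highAllele, lowAllele))
  homAlt <- paste0(highAllele, highAllele)
  bad <- !(g %in% c(homRef, hets, homAlt))
  if (any(bad))
    stop("unrecognized genotype(s): ",
         paste(unique(df$genotype[bad]), collapse = ", "))
  out <- lapply(split(g, df$population), function(v)
    GenotypeCounts(sum(v == homRef), sum(v %in% hets), sum(v == homAlt)))
  for (p in names(out)) out[[p]]@population <- p
  out
}

.tajimaFromSummary <- function(n, S, pi) {
  k <- tajimaConstants(n)
  thetaW <- S / k[["a1"]]
  D <- if (S == 0) NaN else
    (pi - thetaW) / sqrt(k[["e1"]] * S + k[["e2"]] * S * (S - 1))
  new("TajimaComponents", n = as.integer(n), S = as.integer(S),
      pi = pi, thetaW = thetaW,
      a1 = k[["a1"]], a2 = k[["a2"]], b1 = k[["b1"]], b2 = k[["b2"]],
      c1 = k[["c1"]], c2 = k[["c2"]], e1 = k[["e1"]], e2 = k[["e2"]],
      D = D)
}

#' Run the full population scan
#'
#' Orchestrates the analysis chain. If a methylation CSV is supplied and
#' a genotype CSV is not, genotypes are inferred first (three-class
#' mixture + posterior calls) and written to `<outDir>/genotype_calls.csv`.
#' Allele frequencies and the Hardy-Weinberg chi-square test are computed
#' per population; if an aligned FASTA is supplied, variant sites are
#' extracted, MAF-filtered and summarized with Tajima's D, and a
#' balancing-selection flag (`D > balancingThreshold`) is set. The report
#' is returned and, when `outDir` is given, written as
#' `population_report.csv` and `report.json` (plus `variants.vcf` when a
#' FASTA was analyzed). Reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param methylationCsv CSV with `sample_id`, `beta` (or `m_value`),
#'   optional `population`, optional `true_genotype`.
#' @param genotypeCsv CSV with `sample_id`, `population`, `genotype`.
#' @param fastaPath aligned FASTA of the locus.
#' @param referenceCsv optional reference allele-frequency CSV (see
#'   [compareToReference()]).
#' @param mafThreshold minor-allele-frequency filter for Tajima's D
#'   (strict inequality; default 0.05).
#' @param piMode "haplotype" (exact pairwise pi on expanded haplotypes)
#'   or "unphased" (2N-allele-copy estimator via [genotypePi()]).
#' @param balancingThreshold D value above which the balancing-selection
#'   flag is set (default 1.80).
#' @param diploidIupac treat FASTA sequences as diploid IUPAC consensus
#'   (default TRUE).
#' @param lowAllele,highAllele allele orientation (low methylation =
#'   homozygote for `lowAllele`).
#' @param minHweN populations smaller than this skip the HWE test with a
#'   warning (default 5).
#' @param seed integer seed threaded through every stochastic step.
#' @param outDir output directory (NULL = return only).
#' @return a list of class `"PopulationReport"`: `schema_version`,
#'   `populations` (data.frame), `tajima` (data.frame or NULL),
#'   `genotype_calls`, `class_summary`, `reference_comparison`,
#'   `provenance`.
#' @export
runPopulationScan <- function(methylationCsv = NULL, genotypeCsv = NULL,
                              fastaPath = NULL, referenceCsv = NULL,
                              mafThreshold = 0.05,
                              piMode = c("haplotype", "unphased"),
                              balancingThreshold = 1.80,
                              diploidIupac = TRUE,
                              lowAllele = "A", highAllele = "G",
                              minHweN = 5L, seed = 1L, outDir = NULL) {
  piMode <- match.arg(piMode)
  if (is.null(methylationCsv) && is.null(genotypeCsv) &&
      is.null(fastaPath))
    stop("at least one input (methylation CSV, genotype CSV or FASTA) ",
         "is required")
  calls <- NULL
  classSummary <- NULL
  countsList <- NULL
  methDf <- NULL
  if (!is.null(methylationCsv)) {
    methDf <- read.csv(methylationCsv, stringsAsFactors = FALSE)
    if (!"m_value" %in% names(methDf))
      methDf$m_value <- betaToM(methDf$beta,
                                sampleIds = methDf$sample_id)
  }
  if (!is.null(genotypeCsv)) {
    gdf <- read.csv(genotypeCsv, stringsAsFactors = FALSE)
    if (!is.null(methDf)) {
      orphans <- c(setdiff(methDf$sample_id, gdf$sample_id),
                   setdiff(gdf$sample_id, methDf$sample_id))
      if (length(orphans))
        stop("sample ids do not reconcile between methylation and ",
             "genotype inputs; orphans: ",
             paste(orphans, collapse = ", "))
    }
    countsList <- readGenotypeCsv(genotypeCsv, lowAllele, highAllele)
  } else if (!is.null(methDf)) {
    # genotypes absent: infer them from the methylation mixture first
    fit <- fitMethylationMixture(methDf$m_value, k = 3L, seed = seed)
    .log("INFO", "mixture fit: means ",
         paste(round(fit@means, 3), collapse = ", "))
    calls <- callGenotypes(methDf, fit, lowAllele = lowAllele,
                           highAllele = highAllele)
    classSummary <- summarizeClasses(calls, methDf)
    pop <- if (!is.null(methDf$population)) methDf$population else "all"
    gt <- calls$genotype
    sp <- split(gt, pop)
    countsList <- lapply(names(sp), function(p) {
      v <- gsub("/", "", sp[[p]], fixed = TRUE)
      GenotypeCounts(sum(v == paste0(lowAllele, lowAllele)),
                     sum(v == paste0(lowAllele, highAllele)),
                     sum(v == paste0(highAllele, highAllele)),
                     population = p)
    })
    names(countsList) <- names(sp)
  }
  popRows <- NULL
  if (!is.null(countsList)) {
    popRows <- do.call(rbind, lapply(countsList, function(ct) {
      n <- sampleSize(ct)
      fr <- alleleFrequencies(ct)
      row <- data.frame(population = ct@population, n = n,
                        freq_low = unname(fr["p"]),
                        freq_high = unname(fr["q"]),
                        f_hom_low = ct@nHomRef / n,
                        f_het = ct@nHet / n,
                        f_hom_high = ct@nHomAlt / n,
                        chi2 = NA_real_, p_value = NA_real_,
                        f_hat = NA_real_)
      if (n < minHweN) {
        warning("population '", ct@population, "' has n = ", n,
                " < ", minHweN, ": HWE test skipped")
      } else if (fr["p"] %in% c(0, 1)) {
        .log("WARN", "population '", ct@population,
             "' is monomorphic: HWE test skipped")
      } else {
        hw <- hweChisq(ct)
        row$chi2 <- hw@chi2
        row$p_value <- hw@pValue
        row$f_hat <- hw@fHat
      }
      row
    }))
    rownames(popRows) <- NULL
    names(popRows)[names(popRows) == "freq_low"] <-
      paste0("freq_", lowAllele)
    names(popRows)[names(popRows) == "freq_high"] <-
      paste0("freq_", highAllele)
  }
  tajRow <- NULL
  variants <- NULL
  if (!is.null(fastaPath)) {
    aln <- readFastaAlignment(fastaPath)
    variants <- variantsFromAlignment(aln, diploidIupac = diploidIupac)
    biallelic <- lengths(variants@alt) == 1L
    hapAll <- if (piMode == "haplotype")
      haplotypesFromVariants(
        new("VariantTable", chrom = variants@chrom,
            pos = variants@pos[biallelic],
            ref = variants@ref[biallelic],
            alt = variants@alt[biallelic],
            genotypes = variants@genotypes[biallelic, , drop = FALSE],
            sampleIds = variants@sampleIds),
        phased = TRUE)
    else NULL
    if (piMode == "haplotype") {
      hapF <- filterByMaf(hapAll, threshold = mafThreshold)
      .log("INFO", "MAF filter (> ", mafThreshold, "): ",
           nSites(hapAll), " site(s) before, ", nSites(hapF), " after")
      taj <- tajimasD(hapF)
    } else {
      # unphased mode: 2N allele copies per site are the sample
      gts <- variants@genotypes[biallelic, , drop = FALSE]
      mafs <- apply(gts, 1, function(g) {
        al <- unlist(strsplit(g, "/", fixed = TRUE))
        al <- al[al != "."]
        f1 <- mean(al == "1")
        min(f1, 1 - f1)
      })
      keep <- mafs > mafThreshold
      .log("INFO", "MAF filter (> ", mafThreshold, "): ",
           sum(biallelic), " site(s) before, ", sum(keep), " after")
      vkeep <- new("VariantTable", chrom = variants@chrom,
                   pos = variants@pos[biallelic][keep],
                   ref = variants@ref[biallelic][keep],
                   alt = variants@alt[biallelic][keep],
                   genotypes = gts[keep, , drop = FALSE],
                   sampleIds = variants@sampleIds)
      nCopies <- 2L * length(variants@sampleIds)
      taj <- .tajimaFromSummary(nCopies, sum(keep), genotypePi(vkeep))
    }
    tajRow <- data.frame(grouping = "all", n = taj@n, S = taj@S,
                         pi = taj@pi, theta_w = taj@thetaW, D = taj@D,
                         balancing_selection =
                           is.finite(taj@D) & taj@D > balancingThreshold,
                         pi_mode = piMode)
  }
  report <- list(
    schema_version = 1L,
    populations = popRows,
    tajima = tajRow,
    genotype_calls = calls,
    class_summary = classSummary,
    reference_comparison = NULL,
    provenance = list(seed = seed, maf_threshold = mafThreshold,
                      pi_mode = piMode,
                      balancing_threshold = balancingThreshold,
                      alleles = c(lowAllele, highAllele),
                      package_version =
                        as.character(utils::packageVersion("episelect")))
  )
  class(report) <- "PopulationReport"
  if (!is.null(referenceCsv))
    report <- compareToReference(report, referenceCsv,
                                 lowAllele = lowAllele,
                                 highAllele = highAllele)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(calls))
      write.csv(calls, file.path(outDir, "genotype_calls.csv"),
                row.names = FALSE)
    if (!is.null(popRows)) {
      out <- popRows
      out$p_value <- round(out$p_value, 3)
      write.csv(out, file.path(outDir, "population_report.csv"),
                row.names = FALSE)
    }
    if (!is.null(variants) && length(variants@pos))
      writeVariantVcf(variants, file.path(outDir, "variants.vcf"))
    jsonlite::write_json(
      lapply(unclass(report), function(x)
        if (is.data.frame(x)) x else x),
      file.path(outDir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  report
}

#' @export
print.PopulationReport <- function(x, ...) {
  cat("PopulationReport (schema_version ", x$schema_version, ")\n",
      sep = "")
  if (!is.null(x$populations)) {
    cat("Populations:\n")
    print(x$populations)
  }
  if (!is.null(x$tajima)) {
    cat("Tajima's D:\n")
    print(x$tajima)
  }
  invisible(x)
}

#' Merge a reference allele-frequency table into a report
#'
#' Places user-supplied reference population frequencies (e.g. public
#' panel populations) beside the report's sample populations, sorted by
#' ascending low-allele frequency. No statistical test is attached. The
#' reference CSV needs columns `population`, `allele`, `frequency`; only
#' rows for the two analyzed alleles are used. If the reference's allele
#' labels are oriented the other way round, `flip = TRUE` swaps them
#' consistently.
#'
#' @param report a `"PopulationReport"` from [runPopulationScan()].
#' @param referenceCsv path to the reference CSV.
#' @param flip swap the reference's allele orientation.
#' @param lowAllele,highAllele the analyzed allele letters.
#' @return the report with a `reference_comparison` data.frame added.
#' @export
compareToReference <- function(report, referenceCsv, flip = FALSE,
                               lowAllele = "A", highAllele = "G") {
  ref <- read.csv(referenceCsv, stringsAsFactors = FALSE)
  if (nrow(ref) == 0L) {
    warning("empty reference table: report unchanged")
    return(report)
  }
  if (!all(c("population", "allele", "frequency") %in% names(ref)))
    stop("reference CSV needs columns population, allele, frequency")
  if (flip) {
    ref$allele <- ifelse(ref$allele == lowAllele, highAllele,
                         ifelse(ref$allele == highAllele, lowAllele,
                                ref$allele))
  }
  known <- ref$allele %in% c(lowAllele, highAllele)
  if (!any(known))
    stop("no reference rows use alleles ", lowAllele, "/", highAllele,
         "; if the table is oriented the other way, set flip = TRUE")
  ref <- ref[known, ]
  freqLow <- vapply(split(ref, ref$population), function(d) {
    lo <- d$frequency[d$allele == lowAllele]
    if (length(lo)) lo[1] else 1 - d$frequency[d$allele == highAllele][1]
  }, 0)
  refRows <- data.frame(population = names(freqLow),
                        freq_low = unname(freqLow),
                        freq_high = 1 - unname(freqLow),
                        source = "reference",
                        stringsAsFactors = FALSE)
  sampRows <- NULL
  if (!is.null(report$populations)) {
    sampRows <- data.frame(
      population = report$populations$population,
      freq_low = report$populations[[paste0("freq_", lowAllele)]],
      freq_high = report$populations[[paste0("freq_", highAllele)]],
      source = "sample", stringsAsFactors = FALSE)
  }
  merged <- rbind(sampRows, refRows)
  merged <- merged[order(merged$freq_low), ]
  rownames(merged) <- NULL
  names(merged)[2:3] <- paste0("freq_", c(lowAllele, highAllele))
  report$reference_comparison <- merged
  report
}
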