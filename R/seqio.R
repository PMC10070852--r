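# Sequence I/O: aligned FASTA in, variant sites out (SNP-sites-equivalent
# column scan), minimal GT-only VCF v4.2 read/write, and expansion of
# variant records into a HaplotypeMatrix.
#
# Coordinates are 1-based throughout: VCF POS and alignment columns alike.

# two-base IUPAC ambiguity codes, the heterozygote encodings a Sanger
# consensus caller can emit for a diploid
.IUPAC2 <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

#' Read an aligned FASTA file
#'
#' Parses a multiple sequence alignment, uppercases it and enforces that
#' all records have equal length and unique identifiers. IUPAC ambiguity
#' codes, N and gaps ("-") are accepted.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] of equal-width sequences.
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aln <- Biostrings::readDNAStringSet(path)
  if (length(aln) == 0L)
    stop("format error: ", path, " contains no FASTA records")
  w <- Biostrings::width(aln)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1])
    stop("format error: unequal sequence lengths; offending record(s): ",
         paste(names(aln)[bad], collapse = ", "))
  }
  if (anyDuplicated(names(aln)))
    stop("format error: duplicate sequence ids")
  aln
}

#' Extract variant sites from an alignment
#'
#' Scans every alignment column and emits one record per polymorphic
#' column, the in-package equivalent of running a SNP caller on a
#' consensus alignment. With `diploidIupac = TRUE` (the default, since
#' Sanger consensus sequences commonly encode heterozygotes as ambiguity
#' codes) each sequence is a diploid individual: two-base IUPAC codes
#' (R, Y, S, W, K, M) become heterozygous genotypes and plain bases
#' homozygotes. Gaps, N and three/four-base ambiguity codes are missing
#' data (the latter with a warning). The reference allele is the majority
#' allele over allele copies, ties broken alphabetically; columns with
#' more than two alleles are emitted multi-allelic with a warning;
#' all-missing columns are skipped with a message.
#'
#' @param aln a [Biostrings::DNAStringSet] from [readFastaAlignment()].
#' @param diploidIupac treat sequences as diploid consensus with IUPAC
#'   heterozygotes (default TRUE); FALSE treats them as haploid and turns
#'   ambiguity codes into missing calls.
#' @param chrom contig label for the records (default "locus").
#' @return a [VariantTable-class] object (positions are 1-based alignment
#'   columns).
#' @export
variantsFromAlignment <- function(aln, diploidIupac = TRUE,
                                  chrom = "locus") {
  mat <- as.matrix(aln)  # sequences x columns, single characters
  nSamp <- nrow(mat)
  pos <- integer(0)
  refs <- character(0)
  alts <- list()
  gts <- list()
  warned34 <- FALSE
  nSkipped <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- toupper(mat[, j])
    # per-sequence allele copies; NA = missing
    copies <- vector("list", nSamp)
    for (i in seq_len(nSamp)) {
      ch <- col[i]
      if (ch %in% c("A", "C", "G", "T")) {
        copies[[i]] <- if (diploidIupac) c(ch, ch) else ch
      } else if (diploidIupac && ch %in% names(.IUPAC2)) {
        copies[[i]] <- .IUPAC2[[ch]]
      } else {
        if (ch %in% c("B", "D", "H", "V") && !warned34) {
          warning("three/four-base ambiguity codes treated as missing")
          warned34 <- TRUE
        }
        copies[[i]] <- NA_character_
      }
    }
    pool <- unlist(copies)
    pool <- pool[!is.na(pool)]
    if (length(pool) == 0L) {
      nSkipped <- nSkipped + 1L
      next
    }
    alleles <- sort(unique(pool))
    if (length(alleles) < 2L) next  # monomorphic
    tab <- table(factor(pool, levels = alleles))
    # majority allele; table() order is alphabetical, so which.max's
    # first-hit rule is the alphabetical tie-break
    ref <- names(tab)[which.max(tab)]
    alt <- setdiff(alleles, ref)
    if (length(alt) > 1L)
      warning("column ", j, " has >2 alleles; emitted multi-allelic")
    code <- setNames(as.character(seq_along(alt)), alt)
    code[ref] <- "0"
    gt <- vapply(copies, function(cp) {
      if (anyNA(cp)) {
        if (diploidIupac) "./." else "."
      } else {
        paste(sort(code[cp]), collapse = if (diploidIupac) "/" else "")
      }
    }, "")
    pos <- c(pos, j)
    refs <- c(refs, ref)
    alts <- c(alts, list(alt))
    gts <- c(gts, list(gt))
  }
  if (nSkipped > 0L)
    message(nSkipped, " all-missing column(s) skipped")
  gmat <- if (length(gts)) do.call(rbind, gts) else
    matrix(character(0), 0, nSamp)
  ids <- names(aln)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nSamp))
  colnames(gmat) <- ids
  vt <- new("VariantTable", chrom = chrom, pos = pos, ref = refs,
            alt = alts, genotypes = gmat, sampleIds = ids)
  # IUPAC-derived heterozygotes carry no phase
  attr(vt, "phased") <- !diploidIupac
  vt
}

#' Write a minimal VCF v4.2 file
#'
#' Header plus GT-only records: columns CHROM, POS, ID, REF, ALT, QUAL,
#' FILTER, INFO, FORMAT, then one column per sample. Positions are
#' 1-based.
#'
#' @param variants a [VariantTable-class] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVariantVcf <- function(variants, path) {
  stopifnot(is(variants, "VariantTable"))
  if (anyDuplicated(variants@pos))
    stop("duplicate positions in variant table")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", variants@sampleIds),
                   collapse = "\t"), con)
  chrom <- rep_len(variants@chrom, length(variants@pos))
  for (i in seq_along(variants@pos)) {
    line <- paste(c(chrom[i], variants@pos[i], ".", variants@ref[i],
                    paste(variants@alt[[i]], collapse = ","), ".", ".",
                    ".", "GT", variants@genotypes[i, ]),
                  collapse = "\t")
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a GT-only VCF file
#'
#' Parses biallelic SNP records; indel and multi-allelic records are
#' skipped and counted. A phased genotype separator "|" is accepted and
#' normalized to "/".
#'
#' @param path path to a VCF file.
#' @return a [VariantTable-class]; the number of skipped records is
#'   attached as attribute `"nSkipped"` and whether all heterozygous
#'   genotypes were phased as attribute `"phased"`.
#' @export
readVariantVcf <- function(path) {
  lines <- readLines(path)
  hdrIdx <- grep("^#CHROM\t", lines)
  if (length(hdrIdx) != 1L)
    stop("format error: no #CHROM header line in ", path)
  hdr <- strsplit(lines[hdrIdx], "\t", fixed = TRUE)[[1]]
  ids <- hdr[-(1:9)]
  body <- lines[-seq_len(hdrIdx)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  pos <- integer(0); refs <- character(0); alts <- list()
  gts <- list(); chrom <- character(0)
  nSkipped <- 0L
  sawPipe <- FALSE
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    ref <- f[4]
    alt <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    snp <- nchar(ref) == 1L && length(alt) == 1L && all(nchar(alt) == 1L)
    if (!snp) {
      nSkipped <- nSkipped + 1L
      next
    }
    g <- f[-(1:9)]
    g <- sub("^([^:]*).*$", "\\1", g)  # GT is the first FORMAT field
    if (any(grepl("|", g, fixed = TRUE))) sawPipe <- TRUE
    g <- gsub("|", "/", g, fixed = TRUE)
    chrom <- c(chrom, f[1])
    pos <- c(pos, as.integer(f[2]))
    refs <- c(refs, ref)
    alts <- c(alts, list(alt))
    gts <- c(gts, list(g))
  }
  if (nSkipped > 0L)
    message(nSkipped, " non-biallelic-SNP record(s) skipped")
  gmat <- if (length(gts)) do.call(rbind, gts) else
    matrix(character(0), 0, length(ids))
  colnames(gmat) <- ids
  vt <- new("VariantTable",
            chrom = if (length(chrom)) unique(chrom) else "locus",
            pos = pos, ref = refs, alt = alts, genotypes = gmat,
            sampleIds = ids)
  attr(vt, "nSkipped") <- nSkipped
  attr(vt, "phased") <- sawPipe ||
    !any(vapply(seq_along(pos), function(i) any(gmat[i, ] == "0/1"), TRUE))
  vt
}

#' Expand variant records into a haplotype matrix
#'
#' Phased mode splits each diploid genotype into its two haplotypes
#' column-consistently (first allele to haplotype a, second to haplotype
#' b); haploid records pass through one haplotype per sample. Unphased
#' diploid data with heterozygous sites cannot be expanded — diversity on
#' such data goes through [genotypePi()] instead — so `phased = TRUE` on
#' unphased input containing heterozygotes is a contract error, as is
#' `phased = FALSE` itself.
#'
#' @param variants a [VariantTable-class] object with biallelic records.
#' @param phased assert that diploid genotypes are phased (default taken
#'   from the table's `"phased"` attribute, itself TRUE when no unphased
#'   heterozygote was seen).
#' @return a [HaplotypeMatrix-class] object.
#' @export
haplotypesFromVariants <- function(variants,
                                   phased = isTRUE(attr(variants,
                                                        "phased"))) {
  stopifnot(is(variants, "VariantTable"))
  if (any(lengths(variants@alt) > 1L))
    stop("haplotype expansion needs biallelic records")
  gts <- variants@genotypes
  nrec <- nrow(gts)
  diploid <- any(grepl("/", gts, fixed = TRUE))
  if (diploid && !phased)
    stop("unphased diploid genotypes cannot be expanded to haplotypes; ",
         "use genotypePi() for diversity on unphased data")
  anyHet <- nrec > 0L && any(gts == "0/1" | gts == "1/0")
  if (diploid && anyHet && !isTRUE(attr(variants, "phased")))
    stop("contract error: heterozygous genotypes present but the table ",
         "is not phased; use genotypePi()")
  code1 <- function(ch) switch(ch, "0" = 0L, "1" = 1L, NA_integer_)
  if (!diploid) {
    a <- matrix(NA_integer_, ncol(gts), nrec)
    for (i in seq_len(nrec))
      a[, i] <- vapply(gts[i, ], code1, 0L, USE.NAMES = FALSE)
    rownames(a) <- variants@sampleIds
    return(HaplotypeMatrix(a, sites = variants@pos))
  }
  nSamp <- ncol(gts)
  a <- matrix(NA_integer_, 2L * nSamp, nrec)
  for (i in seq_len(nrec)) {
    parts <- strsplit(gts[i, ], "/", fixed = TRUE)
    for (s in seq_len(nSamp)) {
      p <- parts[[s]]
      if (length(p) == 2L) {
        a[2L * s - 1L, i] <- code1(p[1])
        a[2L * s, i] <- code1(p[2])
      }
    }
  }
  rownames(a) <- paste0(rep(variants@sampleIds, each = 2L),
                        c("_a", "_b"))
  HaplotypeMatrix(a, sites = variants@pos)
}
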