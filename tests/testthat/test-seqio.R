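test_that("aligned FASTA parsing enforces the alignment contract", {
  fa <- writeTempFasta(c(">s1", "acgtacgtac", ">s2", "ACGTACGTAC"))
  aln <- readFastaAlignment(fa)
  expect_length(aln, 2)
  expect_identical(unique(Biostrings::width(aln)), 10L)
  # lowercase input is uppercased by the DNA alphabet
  expect_identical(as.character(aln[[1]]), as.character(aln[[2]]))

  bad <- writeTempFasta(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTA"))
  expect_error(readFastaAlignment(bad), "s2")
  empty <- writeTempFasta(character(0))
  expect_error(readFastaAlignment(empty), "no FASTA records")
  expect_error(readFastaAlignment(tempfile()), "no such file")
})

test_that("variant extraction finds polymorphic columns with 1-based positions", {
  # haploid: column 3 is A/A/G/G, tie broken alphabetically to ref A
  fa <- writeTempFasta(c(">h1", "CCACC", ">h2", "CCACC",
                         ">h3", "CCGCC", ">h4", "CCGCC"))
  v <- variantsFromAlignment(readFastaAlignment(fa),
                             diploidIupac = FALSE)
  expect_identical(v@pos, 3L)
  expect_identical(v@ref, "A")
  expect_identical(v@alt[[1]], "G")
  expect_identical(unname(v@genotypes[1, ]), c("0", "0", "1", "1"))

  # identical sequences: no records
  same <- writeTempFasta(c(">a", "ACGT", ">b", "ACGT"))
  v0 <- variantsFromAlignment(readFastaAlignment(same),
                              diploidIupac = FALSE)
  expect_length(v0@pos, 0)

  # diploid IUPAC: column A/R/G expands to 0/0, 0/1, 1/1
  dip <- writeTempFasta(c(">i1", "CAC", ">i2", "CRC", ">i3", "CGC"))
  vd <- variantsFromAlignment(readFastaAlignment(dip))
  expect_identical(vd@pos, 2L)
  expect_identical(unname(vd@genotypes[1, ]), c("0/0", "0/1", "1/1"))
  # IUPAC heterozygotes carry no phase
  expect_false(attr(vd, "phased"))

  # gaps/N are missing; an all-gap column is skipped with a message
  gap <- writeTempFasta(c(">g1", "-AC", ">g2", "-GC", ">g3", "-NC"))
  expect_message(vg <- variantsFromAlignment(readFastaAlignment(gap),
                                             diploidIupac = FALSE),
                 "skipped")
  expect_identical(vg@pos, 2L)
  expect_identical(unname(vg@genotypes[1, ]), c("0", "1", "."))

  # >2 alleles: multi-allelic record with a warning
  tri <- writeTempFasta(c(">t1", "AC", ">t2", "CC", ">t3", "TC",
                          ">t4", "AC"))
  expect_warning(vt <- variantsFromAlignment(readFastaAlignment(tri),
                                             diploidIupac = FALSE),
                 "multi-allelic")
  expect_identical(vt@ref, "A")
  expect_identical(sort(vt@alt[[1]]), c("C", "T"))
})

test_that("positions agree with a brute-force column scanner on random alignments", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:15) {
    n <- sample(3:8, 1); L <- sample(10:40, 1)
    mat <- matrix(sample(bases, n * L, replace = TRUE,
                         prob = c(0.7, 0.1, 0.1, 0.1)), n, L)
    seqs <- apply(mat, 1, paste, collapse = "")
    fa <- writeTempFasta(as.vector(rbind(paste0(">r", 1:n), seqs)))
    v <- suppressWarnings(
      variantsFromAlignment(readFastaAlignment(fa),
                            diploidIupac = FALSE))
    polymorphic <- which(apply(mat, 2, function(cl)
      length(unique(cl)) > 1))  # independent scanner
    expect_identical(v@pos, as.integer(polymorphic))
    expect_true(all(diff(v@pos) > 0))
  }
})

test_that("VCF write/read round trip preserves records", {
  fa <- writeTempFasta(c(">h1", "CCACC", ">h2", "CCACC",
                         ">h3", "CCGCG", ">h4", "CCGCC"))
  v <- variantsFromAlignment(readFastaAlignment(fa),
                             diploidIupac = FALSE)
  vcf <- tempfile(fileext = ".vcf")
  writeVariantVcf(v, vcf)
  lines <- readLines(vcf)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  expect_match(lines[3], "^#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\th1")
  # one body line per record, 10+ tab-separated columns
  body <- lines[-(1:3)]
  expect_length(body, length(v@pos))
  expect_true(all(lengths(strsplit(body, "\t")) == 13L))

  v2 <- readVariantVcf(vcf)
  expect_identical(v2@pos, v@pos)
  expect_identical(v2@ref, v@ref)
  expect_identical(v2@genotypes, v@genotypes)

  # empty record list: header-only file round trips
  v0 <- new("VariantTable", chrom = "locus", pos = integer(0),
            ref = character(0), alt = list(),
            genotypes = matrix(character(0), 0, 2,
                               dimnames = list(NULL, c("a", "b"))),
            sampleIds = c("a", "b"))
  writeVariantVcf(v0, vcf)
  expect_length(readLines(vcf), 3)
  expect_length(readVariantVcf(vcf)@pos, 0)
})

test_that("VCF reader skips non-SNPs, accepts phase and rejects bad headers", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "locus\t2\t.\tA\tG\t.\t.\t.\tGT\t0|1\t1|1",
    "locus\t5\t.\tA\tAT\t.\t.\t.\tGT\t0/0\t0/1"), vcf)
  expect_message(v <- readVariantVcf(vcf), "1 non-biallelic-SNP")
  expect_identical(attr(v, "nSkipped"), 1L)
  expect_identical(v@pos, 2L)
  # phased separator accepted and normalized to "/"
  expect_identical(unname(v@genotypes[1, ]), c("0/1", "1/1"))
  expect_true(attr(v, "phased"))

  noHdr <- tempfile(fileext = ".vcf")
  writeLines("locus\t2\t.\tA\tG\t.\t.\t.\tGT\t0/1", noHdr)
  expect_error(readVariantVcf(noHdr), "#CHROM")
})

test_that("VCF output is parseable by an independent VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  fa <- writeTempFasta(c(">h1", "CCACC", ">h2", "CCACC",
                         ">h3", "CCGCG", ">h4", "CCGCC"))
  v <- variantsFromAlignment(readFastaAlignment(fa),
                             diploidIupac = FALSE)
  vcf <- tempfile(fileext = ".vcf")
  writeVariantVcf(v, vcf)
  ref <- suppressWarnings(VariantAnnotation::readVcf(vcf,
                                                     genome = "locus"))
  expect_identical(unname(BiocGenerics::start(
    SummarizedExperiment::rowRanges(ref))), as.integer(v@pos))
  gt <- VariantAnnotation::geno(ref)$GT
  expect_identical(unname(gt[1, ]), unname(v@genotypes[1, ]))
})

test_that("haplotype expansion honors phase and ploidy", {
  # diploid 0/0 and 1/1: four haplotypes (0,0,1,1)
  gm <- matrix(c("0/0", "1/1"), 1, 2,
               dimnames = list(NULL, c("s1", "s2")))
  vt <- new("VariantTable", chrom = "locus", pos = 1L, ref = "A",
            alt = list("G"), genotypes = gm,
            sampleIds = c("s1", "s2"))
  attr(vt, "phased") <- TRUE
  h <- haplotypesFromVariants(vt, phased = TRUE)
  expect_identical(nHaplotypes(h), 4L)
  expect_identical(as.vector(alleleMatrix(h)), c(0L, 0L, 1L, 1L))

  # haploid records pass through unchanged
  gh <- matrix(c("0", "1", "."), 1, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  vh <- new("VariantTable", chrom = "locus", pos = 1L, ref = "A",
            alt = list("G"), genotypes = gh,
            sampleIds = c("a", "b", "c"))
  hh <- haplotypesFromVariants(vh, phased = FALSE)
  expect_identical(nHaplotypes(hh), 3L)
  expect_identical(as.vector(alleleMatrix(hh)), c(0L, 1L, NA))

  # heterozygote without phase is a contract error
  gu <- matrix(c("0/1", "0/0"), 1, 2,
               dimnames = list(NULL, c("s1", "s2")))
  vu <- new("VariantTable", chrom = "locus", pos = 1L, ref = "A",
            alt = list("G"), genotypes = gu,
            sampleIds = c("s1", "s2"))
  attr(vu, "phased") <- FALSE
  expect_error(haplotypesFromVariants(vu, phased = TRUE), "phased")
  expect_error(haplotypesFromVariants(vu, phased = FALSE), "unphased")
})

test_that("FASTA -> variants -> VCF -> haplotypes reproduces the truth", {
  # hand-written truth: haplotypes over a 12-column locus
  truth <- rbind(c(0L, 0L, 1L), c(0L, 1L, 0L),
                 c(1L, 0L, 0L), c(0L, 0L, 0L), c(0L, 1L, 1L),
                 c(1L, 1L, 0L))
  hTrue <- HaplotypeMatrix(truth, sites = c(2L, 5L, 9L))
  fa <- tempfile(fileext = ".fa")
  writeHaplotypeFasta(hTrue, fa, length = 12)
  v <- variantsFromAlignment(readFastaAlignment(fa),
                             diploidIupac = FALSE)
  expect_identical(v@pos, c(2L, 5L, 9L))
  vcf <- tempfile(fileext = ".vcf")
  writeVariantVcf(v, vcf)
  h <- haplotypesFromVariants(readVariantVcf(vcf))
  expect_identical(unname(alleleMatrix(h)), truth)
  expect_identical(sitePositions(h), c(2L, 5L, 9L))
})
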