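tab <- function(...) paste(..., sep = "\t")

test_that("plain pileup lines decode bases, strands and qualities", {
  col <- parsePileupLine(tab("chr1", "100", "A", "3", "..,", "III", "]]]"))
  expect_identical(col$chrom, "chr1")
  expect_identical(col$pos, 100L)
  expect_identical(col$base, rep(1L, 3))        # all reference A
  expect_identical(col$strand, c("+", "+", "-"))
  expect_identical(col$qual, rep(40L, 3))
  expect_identical(col$mapq, rep(60L, 3))
  # mismatches, case encodes strand
  col2 <- parsePileupLine(tab("chr1", "7", "C", "4", ".Tg,", "IIII", "]]]]"))
  expect_identical(col2$base, c(2L, 4L, 3L, 2L))
  expect_identical(col2$strand, c("+", "+", "-", "-"))
})

test_that("read starts, ends, indels and skip markers are handled", {
  # ^X consumes the next char without an observation; $ consumes nothing
  col <- parsePileupLine(tab("chr1", "5", "G", "3", "^I..$,", "III", "]]]"))
  expect_identical(col$base, rep(3L, 3))
  # insertion attaches to the preceding read with that read's quality
  col2 <- parsePileupLine(tab("chr1", "101", "C", "2", ".+2AG,", "II", "]]"))
  expect_identical(col2$base, c(2L, 2L))
  expect_identical(col2$indels$kind, "ins")
  expect_identical(col2$indels$seq, "AG")
  expect_identical(col2$indels$qual, 40L)
  # deletion record on the reverse strand
  col3 <- parsePileupLine(tab("chr1", "8", "T", "2", ",-3acg.", "5I", "]]"))
  expect_identical(col3$indels$kind, "del")
  expect_identical(col3$indels$seq, "ACG")
  expect_identical(col3$indels$strand, "-")
  # N and * consume a quality slot but produce no observation
  col4 <- parsePileupLine(tab("chr1", "9", "A", "4", ".N*,", "IJKL", "]]]]"))
  expect_identical(col4$base, c(1L, 1L))
  expect_identical(col4$skipped, 2L)
  expect_identical(col4$qual, c(40L, 43L))      # I and L retained
})

test_that("malformed pileup lines fail with informative errors", {
  expect_error(parsePileupLine(tab("chr1", "100", "A", "3", "..,,", "III", "]]]")),
               "depth")
  expect_error(parsePileupLine(tab("chr1", "100", "A", "3", "..,", "II", "]]]")),
               "quality string length")
  expect_error(parsePileupLine(tab("chr1", "100", "A", "3", "..,", "III")),
               "7 tab-separated columns")
  expect_error(parsePileupLine(tab("chr1", "100", "A", "2", ".+A,", "II", "]]")),
               "indel")
  expect_error(readPileup(text = tab("chr1", "1", "A", "1", ".", "5", "]"),
                          qualityOffset = 64L), "offset")
})

test_that("parser never misaligns observations and qualities", {
  lines <- c(tab("chr1", "1", "A", "3", "..,", "ABC", "]]@"),
             tab("chr1", "2", "C", "5", ".N,*^I.", "ABCDE", "IJKLM"),
             tab("chr1", "3", "G", "2", ".+3TTT,", "AB", "]]"))
  pu <- readPileup(text = lines)
  expect_identical(length(pu), 3L)
  expect_identical(lengths(pu@obsBase), lengths(pu@obsQual))
  expect_identical(lengths(pu@obsBase), lengths(pu@obsMapq))
  expect_identical(unname(depth(pu)), c(3L, 5L, 2L))
  expect_identical(pu@obsQual[[2]], c(utf8ToInt("A"), utf8ToInt("C"),
                                      utf8ToInt("E")) - 33L)
})

test_that("simulated pileups round-trip through the parser exactly", {
  cfg <- simConfig(genomeLength = 3000L, meanDepth = 8, seed = 21,
                   ploidy = "diploid", snpRate = 0.002,
                   damageMax = 0.3, damageLambda = 0.3)
  g <- simulateGenome(cfg)
  rd <- simulateReads(g, cfg)
  pu <- readPileup(text = simulatePileup(g, rd, cfg))
  want <- simBaseCounts(g, rd, cfg)
  got <- t(vapply(pu@obsBase, function(b) tabulate(b, 4L), integer(4)))
  expect_identical(pu@pos, want$pos)
  expect_identical(unname(got), unname(as.matrix(want[, c("A", "C", "G", "T")])))
  # declared depth accounted for by retained observations + skipped
  expect_identical(unname(depth(pu)), as.integer(rowSums(got)) + pu@skipped)
})

test_that("VCF records encode genotypes against REF/ALT correctly", {
  calls <- makeCalls(pos = c(10, 20, 30), ref = c("A", "A", "G"),
                     genotype = c("AA", "AC", "TT"),
                     phred = c(50, 45, 80), ploidy = "diploid")
  lines <- writeVcf(calls)
  recs <- strsplit(grep("^#", lines, value = TRUE, invert = TRUE), "\t")
  expect_length(recs, 3)
  expect_true(all(lengths(recs) == 10L))
  # hom-ref: ALT "." and GT 0/0
  expect_identical(recs[[1]][5], ".")
  expect_match(recs[[1]][10], "^0/0:")
  # het: ALT C, GT 0/1
  expect_identical(recs[[2]][5], "C")
  expect_match(recs[[2]][10], "^0/1:")
  # hom-alt: ALT T, GT 1/1
  expect_identical(recs[[3]][5], "T")
  expect_match(recs[[3]][10], "^1/1:")
  # haploid call: single GT index
  hap <- makeCalls(pos = 5, ref = "C", genotype = "T", phred = 60,
                   ploidy = "haploid")
  hrec <- strsplit(grep("^#", writeVcf(hap), value = TRUE, invert = TRUE),
                   "\t")[[1]]
  expect_identical(hrec[5], "T")
  expect_match(hrec[10], "^1:")
  # variants-only mode drops the hom-ref record
  expect_length(grep("^#", writeVcf(calls, variantsOnly = TRUE),
                     value = TRUE, invert = TRUE), 2)
  expect_error(writeVcf(calls[c(2, 1)]), "sorted")
})

test_that("written VCF is structurally valid and machine-readable", {
  calls <- makeCalls(pos = c(10, 20), ref = c("A", "C"),
                     genotype = c("AG", "CT"), phred = c(40, 35))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcf(calls, f)
  cs <- readCallSet(f, "x")
  expect_identical(length(cs), 2L)
  expect_identical(variants(cs)$pos, c(10L, 20L))
  expect_identical(variants(cs)$zygosity, c("het", "het"))
  # GT indices always reference an allele in REF+ALT
  for (l in grep("^#", readLines(f), value = TRUE, invert = TRUE)) {
    fl <- strsplit(l, "\t")[[1]]
    nAllele <- 1L + length(strsplit(fl[5], ",")[[1]])
    gt <- as.integer(strsplit(sub(":.*", "", fl[10]), "/")[[1]])
    expect_true(all(gt >= 0 & gt < nAllele))
  }
  # gzip output round-trips
  fgz <- withr::local_tempfile(fileext = ".vcf.gz")
  writeVcf(calls, fgz)
  expect_identical(readLines(gzfile(fgz)), readLines(f))
})
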