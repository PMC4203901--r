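## Seeded read/pileup simulator: plants SNPs in a random reference,
## samples single-end reads with a linear quality-decay profile and
## end-clustered deamination damage, and emits FASTQ, truth VCF and
## mpileup -s text directly (reads are perfectly placed, bypassing
## mapping so the genotyper is testable in isolation).

#' Simulation configuration
#'
#' Collects and validates all simulator settings. Defaults emulate a
#' short-read ancient-DNA style design: 36 bp single-end reads, a Phred
#' quality profile decaying linearly along the read (signal-to-noise
#' degrades towards the 3' end), and optional deamination damage whose
#' per-base probability is \code{damageMax * exp(-damageLambda * j)} at
#' distance j from the 5' end for C-to-T (mirrored from the 3' end for
#' G-to-A, strand-aware).
#'
#' @param genomeLength reference length in bp.
#' @param gcContent GC fraction of the simulated reference.
#' @param ploidy "haploid" or "diploid".
#' @param snpRate per-position probability of planting a variant.
#' @param hetFraction fraction of planted diploid SNPs that are
#'   heterozygous (default 5/9, giving a planted hom:het ratio of 0.8).
#' @param readLength read length in bp.
#' @param meanDepth target mean fold-coverage.
#' @param qualityProfile length-2 numeric (q at read start, q at read
#'   end), linearly interpolated.
#' @param damageMax terminal per-base deamination probability (0 = no
#'   damage).
#' @param damageLambda exponential decay rate of damage per position.
#' @param mapQuality constant mapping quality written into the pileup.
#' @param chrom chromosome name used in all outputs.
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return a validated list of class "SimConfig".
#' @export
simConfig <- function(genomeLength = 100000L, gcContent = 0.5,
                      ploidy = c("haploid", "diploid"), snpRate = 0.001,
                      hetFraction = 5 / 9, readLength = 36L,
                      meanDepth = 27, qualityProfile = c(40, 30),
                      damageMax = 0, damageLambda = 0.3,
                      mapQuality = 60L, chrom = "sim1", seed = 1L) {
  ploidy <- match.arg(ploidy)
  stopifnot(genomeLength >= readLength, gcContent >= 0, gcContent <= 1,
            snpRate >= 0, snpRate < 1, hetFraction >= 0, hetFraction <= 1,
            readLength >= 1, meanDepth > 0, length(qualityProfile) == 2L,
            all(qualityProfile >= 0), damageMax >= 0, damageMax <= 1,
            damageLambda >= 0, mapQuality >= 0)
  structure(list(genomeLength = as.integer(genomeLength),
                 gcContent = gcContent, ploidy = ploidy, snpRate = snpRate,
                 hetFraction = hetFraction, readLength = as.integer(readLength),
                 meanDepth = meanDepth, qualityProfile = qualityProfile,
                 damageMax = damageMax, damageLambda = damageLambda,
                 mapQuality = as.integer(mapQuality), chrom = chrom,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:\n")
  for (k in names(x))
    cat(sprintf("  %s = %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

#' Simulate a reference genome and individual haplotypes
#'
#' Draws a random reference with the configured GC content, plants SNPs
#' at \code{snpRate} (alternative allele uniform over the other three
#' bases; diploid SNPs heterozygous with probability \code{hetFraction},
#' homozygous-alternative otherwise), and records the ground truth.
#'
#' @param config a [simConfig()] list.
#' @return list with \code{ref} (integer base codes), \code{haplotypes}
#'   (list of 1 or 2 integer code vectors), \code{truth} (data.frame:
#'   pos, ref, genotype, zygosity), \code{chrom}.
#' @export
simulateGenome <- function(config) {
  set.seed(config$seed)
  L <- config$genomeLength
  gc <- config$gcContent
  ref <- sample.int(4L, L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  vpos <- which(runif(L) < config$snpRate)
  nv <- length(vpos)
  alt <- integer(nv)
  if (nv > 0)
    alt <- vapply(ref[vpos], function(r)
      sample(setdiff(1:4, r), 1L), integer(1))
  if (config$ploidy == "haploid") {
    hap <- ref
    hap[vpos] <- alt
    truth <- data.frame(pos = vpos, ref = BASES[ref[vpos]],
                        genotype = BASES[alt],
                        zygosity = rep("hom", nv),
                        stringsAsFactors = FALSE)
    return(list(ref = ref, haplotypes = list(hap), truth = truth,
                chrom = config$chrom))
  }
  het <- runif(nv) < config$hetFraction
  hap1 <- ref; hap2 <- ref
  ## heterozygous: alternative allele on a random one of the two haplotypes
  onFirst <- runif(nv) < 0.5
  hap1[vpos[!het | onFirst]] <- alt[!het | onFirst]
  hap2[vpos[!het | !onFirst]] <- alt[!het | !onFirst]
  gt <- vapply(seq_len(nv), function(k) {
    a <- if (het[k]) sort(c(ref[vpos[k]], alt[k])) else c(alt[k], alt[k])
    paste(BASES[a], collapse = "")
  }, character(1))
  truth <- data.frame(pos = vpos, ref = BASES[ref[vpos]], genotype = gt,
                      zygosity = ifelse(het, "het", "hom"),
                      stringsAsFactors = FALSE)
  list(ref = ref, haplotypes = list(hap1, hap2), truth = truth,
       chrom = config$chrom)
}

#' Simulate sequencing reads
#'
#' Read starts and strands are uniform; the source haplotype is chosen
#' uniformly per read (sampling both alleles at heterozygous sites).
#' Damage is applied first, in read space — C-to-T with probability
#' \code{damageMax * exp(-damageLambda * j)} at 0-based distance j from
#' the 5' end, G-to-A mirrored from the 3' end — because deamination is a
#' template property; sequencing errors then hit each base with
#' probability 10^(-q/10) (substituting uniformly among the other three
#' bases). The FASTQ qualities encode the profile q, not the realised
#' errors: damage is invisible to the sequencer.
#'
#' @param genome output of [simulateGenome()].
#' @param config the same [simConfig()].
#' @return list of class "SimReads": \code{start}, \code{strand},
#'   \code{hap}, \code{codes} (reads x readLength integer matrix, read
#'   orientation), \code{qual} (per-cycle Phred vector), \code{chrom},
#'   \code{nReads}.
#' @export
simulateReads <- function(genome, config) {
  set.seed(config$seed + 1L)
  L <- config$genomeLength
  rl <- config$readLength
  n <- as.integer(round(config$meanDepth * L / rl))
  start <- sample.int(L - rl + 1L, n, replace = TRUE)
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  nHap <- length(genome$haplotypes)
  hap <- if (nHap == 1L) rep(1L, n) else sample.int(nHap, n, replace = TRUE)
  hapFlat <- unlist(genome$haplotypes)
  idx <- rep(start, times = rl) + rep(0:(rl - 1L), each = n) +
    (hap - 1L) * L
  M <- matrix(hapFlat[idx], n, rl)        # genome orientation fragments
  isRev <- strand == "-"
  M[isRev, ] <- 5L - M[isRev, rl:1, drop = FALSE]  # reverse-complement
  ## deamination damage, read space, 5' C->T and 3' G->A
  if (config$damageMax > 0) {
    p5 <- config$damageMax * exp(-config$damageLambda * (0:(rl - 1L)))
    P5 <- matrix(p5, n, rl, byrow = TRUE)
    P3 <- matrix(rev(p5), n, rl, byrow = TRUE)
    U <- matrix(runif(n * rl), n, rl)
    M[M == 2L & U < P5] <- 4L             # C -> T
    M[M == 3L & U < P3] <- 1L             # G -> A
  }
  ## sequencing error at the profile rate
  q <- as.integer(round(seq(config$qualityProfile[1],
                            config$qualityProfile[2], length.out = rl)))
  E <- matrix(runif(n * rl), n, rl) <
    matrix(10^(-q / 10), n, rl, byrow = TRUE)
  if (any(E)) {
    shift <- sample.int(3L, sum(E), replace = TRUE)
    M[E] <- ((M[E] - 1L + shift) %% 4L) + 1L
  }
  structure(list(start = start, strand = strand, hap = hap, codes = M,
                 qual = q, chrom = genome$chrom, nReads = n),
            class = "SimReads")
}

#' Write simulated reads as FASTQ
#'
#' @param reads a "SimReads" object from [simulateReads()].
#' @param file output FASTQ path.
#' @return invisibly, \code{file}.
#' @export
writeSimFastq <- function(reads, file) {
  n <- reads$nReads
  chm <- matrix(BASES[reads$codes], n, ncol(reads$codes))
  seqs <- do.call(paste0, as.data.frame(chm, stringsAsFactors = FALSE))
  qstr <- intToUtf8(reads$qual + 33L)
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("read_%d %s:%d:%s", seq_len(n), reads$chrom,
                        reads$start, reads$strand)
  qs <- Biostrings::PhredQuality(rep(qstr, n))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, qs)
  Biostrings::writeQualityScaledXStringSet(qdna, file)
  invisible(file)
}

#' Write the simulated reference as FASTA
#'
#' @param genome output of [simulateGenome()].
#' @param file output FASTA path.
#' @return invisibly, \code{file}.
#' @export
writeSimFasta <- function(genome, file) {
  dna <- Biostrings::DNAStringSet(paste(BASES[genome$ref], collapse = ""))
  names(dna) <- genome$chrom
  Biostrings::writeXStringSet(dna, file)
  invisible(file)
}

#' Write simulator ground truth as a VCF
#'
#' @param genome output of [simulateGenome()].
#' @param file output VCF path.
#' @return invisibly, \code{file}.
#' @export
writeTruthVcf <- function(genome, file) {
  tr <- genome$truth
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pileupCall-simulator-truth",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO", "FORMAT", "TRUTH"),
                             collapse = "\t")))
  recs <- vapply(seq_len(nrow(tr)), function(k) {
    enc <- .vcfAlleles(tr$genotype[k], tr$ref[k])
    paste(genome$chrom, tr$pos[k], ".", tr$ref[k], enc$alt, ".", "PASS",
          ".", "GT", enc$gt, sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), file)
  invisible(file)
}

#' Simulate a pileup directly
#'
#' Emits mpileup -s text for the simulated reads with perfect placement
#' and a constant mapping quality, parseable by [readPileup()]. Within a
#' column, reads appear in read-index order; positions with zero coverage
#' produce no line.
#'
#' @param genome output of [simulateGenome()].
#' @param reads output of [simulateReads()].
#' @param config the same [simConfig()].
#' @param file optional path; when given, lines are also written there.
#' @return character vector of pileup lines (invisibly when \code{file}
#'   is given).
#' @export
simulatePileup <- function(genome, reads, config, file = NULL) {
  n <- reads$nReads
  rl <- config$readLength
  ## reference-orientation observations: genome offset j in 1..rl
  O <- reads$codes
  Q <- matrix(reads$qual, n, rl, byrow = TRUE)
  isRev <- reads$strand == "-"
  O[isRev, ] <- 5L - O[isRev, rl:1, drop = FALSE]
  Q[isRev, ] <- Q[isRev, rl:1, drop = FALSE]
  pos <- rep(reads$start, times = rl) + rep(0:(rl - 1L), each = n)
  obs <- as.vector(O)
  qual <- as.vector(Q)
  isRevLong <- rep(isRev, times = rl)
  refAt <- genome$ref[pos]
  ## pileup display character
  chr <- ifelse(obs == refAt,
                ifelse(isRevLong, ",", "."),
                ifelse(isRevLong, tolower(BASES[obs]), BASES[obs]))
  qlut <- intToUtf8(33:126, multiple = TRUE)
  qchr <- qlut[qual + 1L]
  mqchr <- intToUtf8(config$mapQuality + 33L)
  readId <- rep(seq_len(n), times = rl)
  dt <- data.table::data.table(pos = pos, readId = readId, chr = chr,
                               qchr = qchr)
  data.table::setorder(dt, pos, readId)
  agg <- dt[, list(depth = .N, bases = paste(chr, collapse = ""),
                   bq = paste(qchr, collapse = "")), by = "pos"]
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%s\t%s", genome$chrom, agg$pos,
                   BASES[genome$ref[agg$pos]], agg$depth, agg$bases,
                   agg$bq, strrep(mqchr, agg$depth))
  if (!is.null(file)) {
    con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
    writeLines(lines, con)
    close(con)
    return(invisible(lines))
  }
  lines
}

#' Per-position base tallies of the simulated reads
#'
#' Reference-orientation base counts per covered position, for round-trip
#' checks against a parsed pileup.
#'
#' @param genome,reads,config as in [simulatePileup()].
#' @return data.frame: pos, A, C, G, T counts.
#' @export
simBaseCounts <- function(genome, reads, config) {
  n <- reads$nReads
  rl <- config$readLength
  O <- reads$codes
  isRev <- reads$strand == "-"
  O[isRev, ] <- 5L - O[isRev, rl:1, drop = FALSE]
  pos <- rep(reads$start, times = rl) + rep(0:(rl - 1L), each = n)
  obs <- as.vector(O)
  dt <- data.table::data.table(pos = pos, obs = obs)
  agg <- dt[, list(A = sum(obs == 1L), C = sum(obs == 2L),
                   G = sum(obs == 3L), T = sum(obs == 4L)), by = "pos"]
  data.table::setorder(agg, pos)
  as.data.frame(agg)
}
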