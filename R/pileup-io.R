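## Parsing of samtools "mpileup -s" text (7 columns: chrom, pos, ref,
## depth, bases, base qualities, mapping qualities) and VCF 4.2 output.

.openText <- function(file) {
  if (grepl("\\.gz$", file)) gzfile(file, "rt") else file
}

## decode one bases-string with special tokens; returns list(base codes,
## strand, keptIdx into the quality strings, skipped count, indels df).
## Quality strings have one character per read in the column (including
## N/* reads), so we track the read index separately from retained obs.
.tokenizeBases <- function(s, lineno) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L; readIdx <- 0L
  base <- integer(0); strand <- character(0); kept <- integer(0)
  skipped <- 0L
  ikind <- character(0); iseq <- character(0); istrand <- character(0)
  iread <- integer(0)
  lastStrand <- "+"
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {           # read start; next char encodes mapq, skip both
      i <- i + 2L
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
      if (j == i + 1L)
        stop(sprintf("malformed indel at line %d", lineno))
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n)
        stop(sprintf("indel length overruns line %d", lineno))
      seq <- paste(ch[j:(j + len - 1L)], collapse = "")
      ikind <- c(ikind, if (c0 == "+") "ins" else "del")
      iseq <- c(iseq, toupper(seq))
      istrand <- c(istrand, if (seq == toupper(seq)) "+" else "-")
      iread <- c(iread, readIdx)
      i <- j + len
    } else {
      readIdx <- readIdx + 1L
      if (c0 == "." ) { base <- c(base, 0L); strand <- c(strand, "+")
        kept <- c(kept, readIdx); lastStrand <- "+"
      } else if (c0 == ",") { base <- c(base, 0L); strand <- c(strand, "-")
        kept <- c(kept, readIdx); lastStrand <- "-"
      } else if (c0 %in% c("A", "C", "G", "T")) {
        base <- c(base, match(c0, BASES)); strand <- c(strand, "+")
        kept <- c(kept, readIdx); lastStrand <- "+"
      } else if (c0 %in% c("a", "c", "g", "t")) {
        base <- c(base, match(toupper(c0), BASES)); strand <- c(strand, "-")
        kept <- c(kept, readIdx); lastStrand <- "-"
      } else if (c0 %in% c("N", "n", "*", ">", "<")) {
        skipped <- skipped + 1L
      } else {
        stop(sprintf("unexpected pileup character '%s' at line %d", c0, lineno))
      }
      i <- i + 1L
    }
  }
  list(base = base, strand = strand, kept = kept, nReads = readIdx,
       skipped = skipped,
       indels = data.frame(kind = ikind, seq = iseq, strand = istrand,
                           read = iread, stringsAsFactors = FALSE))
}

#' Parse a single mpileup -s line
#'
#' Decodes one 7-column pileup line into its observations: '.'/',' are
#' reference matches on the forward/reverse strand, letters are
#' mismatches (case = strand), '^X' read-start markers (X encodes a
#' mapping quality) and '$' read-end markers are consumed without
#' producing observations, '+N&lt;seq&gt;'/'-N&lt;seq&gt;' become indel records
#' attached to the column, and 'N'/'*'/ref-skips are dropped but counted.
#' Base- and mapping-quality strings are index-aligned with the retained
#' observations.
#'
#' @param line one tab-separated pileup line.
#' @param qualityOffset ASCII offset for both quality strings (33 =
#'   Sanger/Illumina 1.8+, the samtools convention; 64 selectable).
#' @param lineno line number used in error messages.
#' @return list with fields chrom, pos, ref, depth, base (integer codes
#'   into [BASES]), strand, qual, mapq, skipped, indels (data.frame with
#'   kind, seq, strand, qual).
#' @export
parsePileupLine <- function(line, qualityOffset = 33L, lineno = 1L) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 7L)
    stop(sprintf("expected 7 tab-separated columns at line %d, got %d",
                 lineno, length(f)))
  depth <- as.integer(f[4])
  ref <- toupper(f[3])
  tk <- .tokenizeBases(f[5], lineno)
  bq <- utf8ToInt(f[6]) - qualityOffset
  mq <- utf8ToInt(f[7]) - qualityOffset
  if (tk$nReads != depth)
    stop(sprintf("declared depth %d but %d read observations at line %d",
                 depth, tk$nReads, lineno))
  if (length(bq) != depth || length(mq) != depth)
    stop(sprintf("quality string length mismatch at line %d", lineno))
  if (any(bq < 0) || any(mq < 0))
    stop(sprintf("negative quality at line %d: wrong ASCII offset?", lineno))
  b <- tk$base
  refCode <- match(ref, BASES)
  isRef <- b == 0L
  if (any(isRef) && is.na(refCode))
    stop(sprintf("reference match to unknown reference base at line %d", lineno))
  b[isRef] <- refCode
  qual <- bq[tk$kept]; mapq <- mq[tk$kept]
  indels <- tk$indels
  indels$qual <- ifelse(indels$read >= 1L & indels$read <= depth,
                        effectiveQuality(bq, mq)[indels$read], 0L)
  ## index of the carrying read among the retained observations (NA when
  ## attached to a dropped read)
  indels$obs <- match(indels$read, tk$kept)
  indels$read <- NULL
  list(chrom = f[1], pos = as.integer(f[2]), ref = ref, depth = depth,
       base = b, strand = tk$strand, qual = qual, mapq = mapq,
       skipped = tk$skipped, indels = indels)
}

.EMPTY_INDELS <- data.frame(kind = character(0), seq = character(0),
                            strand = character(0), qual = integer(0),
                            obs = integer(0), stringsAsFactors = FALSE)

#' Read a samtools mpileup -s file
#'
#' Parses the 7-column "mpileup -s" dialect into a [Pileup-class] object.
#' Lines whose bases column contains only plain observation characters
#' (the common case) go through a vectorised fast path; lines with
#' read-start/end markers, indels or skip characters fall back to the
#' full tokenizer of [parsePileupLine()]. Plain or gzip-compressed input.
#'
#' @param file path to a pileup file, or (via \code{text=}) a character
#'   vector of pileup lines.
#' @param qualityOffset ASCII quality offset (default 33).
#' @param text optional character vector of lines, used instead of
#'   \code{file}.
#' @return a [Pileup-class] object.
#' @export
readPileup <- function(file, qualityOffset = 33L, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(.openText(file))
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n == 0L)
    return(new("Pileup", chrom = character(0), pos = integer(0),
               ref = character(0), obsBase = list(), obsQual = list(),
               obsMapq = list(), obsStrand = list(), indels = list(),
               skipped = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 7L))
    stop(sprintf("expected 7 tab-separated columns at line %d, got %d",
                 which(nf != 7L)[1], nf[nf != 7L][1]))
  fm <- matrix(unlist(f), ncol = 7L, byrow = TRUE)
  chrom <- fm[, 1]; pos <- as.integer(fm[, 2]); ref <- toupper(fm[, 3])
  depth <- as.integer(fm[, 4])
  bases <- fm[, 5]; bq <- fm[, 6]; mq <- fm[, 7]

  simple <- !grepl("[^.,ACGTacgt]", bases)
  obsBase <- vector("list", n); obsQual <- vector("list", n)
  obsMapq <- vector("list", n); obsStrand <- vector("list", n)
  indels <- rep(list(.EMPTY_INDELS), n)
  skipped <- integer(n)

  lut <- integer(128)                      # char code -> base code
  lut[utf8ToInt("ACGTacgt") ] <- 0L        # placeholder; filled below
  codes <- utf8ToInt("ACGTacgt")
  lut[codes] <- rep(1:4, 2)
  fwdChars <- utf8ToInt(".ACGT")

  for (i in which(simple)) {
    cc <- utf8ToInt(bases[i])
    if (length(cc) != depth[i])
      stop(sprintf("declared depth %d but %d read observations at line %d",
                   depth[i], length(cc), i))
    b <- lut[cc]
    isRef <- b == 0L
    if (any(isRef)) {
      rc <- match(ref[i], BASES)
      if (is.na(rc))
        stop(sprintf("reference match to unknown reference base at line %d", i))
      b[isRef] <- rc
    }
    q <- utf8ToInt(bq[i]) - qualityOffset
    m <- utf8ToInt(mq[i]) - qualityOffset
    if (length(q) != depth[i] || length(m) != depth[i])
      stop(sprintf("quality string length mismatch at line %d", i))
    if (any(q < 0) || any(m < 0))
      stop(sprintf("negative quality at line %d: wrong ASCII offset?", i))
    obsBase[[i]] <- b
    obsStrand[[i]] <- ifelse(cc %in% fwdChars, "+", "-")
    obsQual[[i]] <- q
    obsMapq[[i]] <- m
  }
  for (i in which(!simple)) {
    col <- parsePileupLine(lines[i], qualityOffset, lineno = i)
    obsBase[[i]] <- col$base; obsQual[[i]] <- col$qual
    obsMapq[[i]] <- col$mapq; obsStrand[[i]] <- col$strand
    indels[[i]] <- col$indels; skipped[i] <- col$skipped
  }
  new("Pileup", chrom = chrom, pos = pos, ref = ref, obsBase = obsBase,
      obsQual = obsQual, obsMapq = obsMapq, obsStrand = obsStrand,
      indels = indels, skipped = skipped)
}

## ---- VCF output -----------------------------------------------------

.gtAlleles <- function(genotype) {
  if (nchar(genotype) == 1L) genotype else
    c(substr(genotype, 1, 1), substr(genotype, 2, 2))
}

## REF/ALT/GT encoding for one call against its reference base
.vcfAlleles <- function(genotype, ref) {
  al <- .gtAlleles(genotype)
  uniq <- unique(al)
  alts <- setdiff(uniq, ref)
  allAlleles <- c(ref, alts)
  idx <- match(al, allAlleles) - 1L
  gt <- paste(sort(idx), collapse = "/")
  list(alt = if (length(alts)) paste(alts, collapse = ",") else ".",
       gt = gt, alts = alts)
}

#' Write genotype calls as VCF 4.2
#'
#' One record per covered position (all-sites mode, the default) or only
#' non-reference calls (\code{variantsOnly}). QUAL and GQ carry the
#' Phred-scaled posterior (GQ rounded to integer), INFO carries DP (depth
#' used after capping) and MQ (mean mapping quality), and the sample
#' column carries GT:DP:GQ:AD where AD lists the read support for the
#' reference and each ALT allele. Run parameters are echoed into the
#' header.
#'
#' @param calls a [GenotypeCalls-class] object sorted by (chrom, pos).
#' @param file output path ("" returns the lines invisibly without
#'   writing); ".gz" suffix writes gzip-compressed text.
#' @param sampleName sample column name.
#' @param variantsOnly emit only variant records.
#' @return invisibly, the VCF lines.
#' @export
writeVcf <- function(calls, file = "", sampleName = "SAMPLE",
                     variantsOnly = FALSE) {
  stopifnot(is(calls, "GenotypeCalls"))
  o <- order(calls@chrom, calls@pos)
  if (any(o != seq_along(o)))
    stop("calls must be sorted by (chrom, pos)")
  p <- calls@params
  paramStr <- paste(sprintf("%s=%s", names(p),
                            vapply(p, function(v) paste(format(v), collapse = ","),
                                   character(1))), collapse = " ")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pileupCall",
           sprintf("##pileupCallParams=\"%s\"", paramStr),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth used after capping\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality of reads used\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth used\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read support per allele (ref, alts)\">",
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO", "FORMAT", sampleName),
                             collapse = "\t")))
  n <- length(calls)
  recs <- character(n)
  keepRec <- logical(n)
  for (i in seq_len(n)) {
    ref <- calls@ref[i]
    enc <- .vcfAlleles(calls@genotype[i], ref)
    isVar <- enc$alt != "."
    keepRec[i] <- !variantsOnly || isVar
    if (!keepRec[i]) next
    ad <- .alleleDepths(calls, i, c(ref, enc$alts))
    recs[i] <- paste(calls@chrom[i], calls@pos[i], ".", ref, enc$alt,
                     sprintf("%.2f", calls@phred[i]), "PASS",
                     sprintf("DP=%d;MQ=%.1f", calls@depthUsed[i],
                             calls@meanMapq[i]),
                     "GT:DP:GQ:AD",
                     sprintf("%s:%d:%d:%s", enc$gt, calls@depthUsed[i],
                             as.integer(round(calls@phred[i])),
                             paste(ad, collapse = ",")),
                     sep = "\t")
  }
  lines <- c(hdr, recs[keepRec])
  if (nzchar(file)) {
    con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
    writeLines(lines, con)
    close(con)
  }
  invisible(lines)
}

## per-allele read support from the stored base tallies
.alleleDepths <- function(calls, i, alleles) {
  if (length(calls@baseTally) < i) return(rep(0L, length(alleles)))
  counts <- calls@baseTally[[i]]
  vapply(alleles, function(a) {
    k <- match(a, BASES)
    if (is.na(k)) 0L else as.integer(counts[k])
  }, integer(1))
}
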