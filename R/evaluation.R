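## Call-set metrics: SNP rate, hom:het ratio, Venn-style overlaps and
## exclusive fractions, and truth-based precision/recall/concordance for
## simulated data.

#' Construct a CallSet
#'
#' @param label name of the set.
#' @param chrom,pos,alt,zygosity per-variant vectors (recycled where
#'   scalar). Duplicate positions are collapsed (first occurrence wins).
#' @return a [CallSet-class].
#' @export
callSet <- function(label, chrom, pos, alt = NA_character_,
                    zygosity = NA_character_) {
  n <- length(pos)
  v <- data.frame(chrom = rep_len(as.character(chrom), n),
                  pos = as.integer(pos),
                  alt = rep_len(as.character(alt), n),
                  zygosity = rep_len(as.character(zygosity), n),
                  stringsAsFactors = FALSE)
  v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  new("CallSet", label = label, variants = v)
}

#' CallSet from genotype calls
#'
#' Collects the variant calls (see [isVariant()]) of a
#' [GenotypeCalls-class] into a [CallSet-class]; zygosity "hom" means
#' homozygous-alternative.
#'
#' @param calls a [GenotypeCalls-class].
#' @param label set label.
#' @return a [CallSet-class].
#' @export
callSetFromCalls <- function(calls, label = "calls") {
  i <- which(isVariant(calls))
  alt <- vapply(i, function(k)
    paste(setdiff(unique(.gtAlleles(calls@genotype[k])), calls@ref[k]),
          collapse = ","), character(1))
  callSet(label, calls@chrom[i], calls@pos[i], alt, zygosity(calls)[i])
}

#' CallSet from a VCF file
#'
#' Reads a VCF (via the vcfR package) and keeps variant records
#' (ALT != "."). Zygosity is derived from the first sample's GT field
#' when present.
#'
#' @param file VCF path.
#' @param label set label (default: the file name).
#' @return a [CallSet-class].
#' @export
readCallSet <- function(file, label = basename(file)) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- !is.na(fix[, "ALT"]) & fix[, "ALT"] != "."
  zyg <- rep(NA_character_, nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, element = "GT")
    g1 <- gt[, 1]
    zyg <- ifelse(is.na(g1), NA_character_,
                  ifelse(grepl("[/|]", g1) &
                           vapply(strsplit(g1, "[/|]"),
                                  function(x) x[1] != x[2], logical(1)),
                         "het", "hom"))
  }
  callSet(label, fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
          fix[keep, "ALT"], zyg[keep])
}

#' Truth records from a simulated genome
#'
#' @param genome output of [simulateGenome()].
#' @return the truth data.frame with a chrom column prepended.
#' @export
truthRecords <- function(genome) {
  cbind(data.frame(chrom = rep(genome$chrom, nrow(genome$truth)),
                   stringsAsFactors = FALSE), genome$truth)
}

#' Predicted SNP rate
#'
#' Number of predicted SNPs divided by the number of positions
#' considered.
#'
#' @param calls a [CallSet-class].
#' @param nPositions positions analysed (> 0).
#' @return fraction in [0, 1].
#' @export
snpRateOf <- function(calls, nPositions) {
  stopifnot(is(calls, "CallSet"), nPositions > 0)
  nrow(calls@variants) / nPositions
}

#' Homozygous:heterozygous ratio
#'
#' Count of homozygous-alternative calls divided by heterozygous calls;
#' around 0.8 is the expectation for human data. NaN (with a warning)
#' when the set has no heterozygotes.
#'
#' @param calls a [CallSet-class] with diploid zygosity annotations.
#' @return numeric ratio, or NaN.
#' @export
homHetRatio <- function(calls) {
  stopifnot(is(calls, "CallSet"))
  z <- calls@variants$zygosity
  nHet <- sum(z == "het", na.rm = TRUE)
  nHom <- sum(z == "hom", na.rm = TRUE)
  if (nHet == 0) {
    warning("no heterozygous calls: hom:het ratio undefined")
    return(NaN)
  }
  nHom / nHet
}

.setKeys <- function(cs, byAllele = FALSE) {
  v <- cs@variants
  if (byAllele) paste(v$chrom, v$pos, v$alt) else paste(v$chrom, v$pos)
}

#' Overlaps between call sets
#'
#' Computes every Venn cell (counts of positions with each non-empty
#' membership pattern across the sets), the pairwise overlap fractions
#' (entry [i, j] = fraction of set i's variants also found in set j), and
#' each set's exclusive fraction (variants found by no other set). By
#' default positions are compared by coordinate only;
#' \code{byAllele = TRUE} also requires the ALT allele to match.
#'
#' @param sets list of two or more [CallSet-class] objects.
#' @param byAllele compare (position, allele) instead of position.
#' @return list with \code{cells} (named integer vector; names are
#'   membership patterns like "110" in input order), \code{pairwise}
#'   (numeric matrix), \code{exclusive} (named numeric vector).
#' @export
overlapMatrix <- function(sets, byAllele = FALSE) {
  stopifnot(length(sets) >= 2)
  labels <- vapply(sets, label, character(1))
  keys <- lapply(sets, .setKeys, byAllele = byAllele)
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  cells <- table(pattern)
  cells <- setNames(as.integer(cells), names(cells))
  nSet <- length(sets)
  pairwise <- matrix(NA_real_, nSet, nSet, dimnames = list(labels, labels))
  for (i in seq_len(nSet)) for (j in seq_len(nSet))
    pairwise[i, j] <- if (length(keys[[i]]) == 0) NaN else
      mean(keys[[i]] %in% keys[[j]])
  exclusive <- vapply(seq_len(nSet), function(i) {
    others <- unique(unlist(keys[-i]))
    if (length(keys[[i]]) == 0) NaN else mean(!(keys[[i]] %in% others))
  }, numeric(1))
  list(cells = cells, pairwise = pairwise,
       exclusive = setNames(exclusive, labels))
}

#' Evaluate calls against simulator ground truth
#'
#' Site-level precision (fraction of called variant positions that are
#' truth positions) and recall (fraction of truth positions called as
#' variant), plus genotype concordance: the fraction of truth sites at
#' which the called genotype matches the planted genotype exactly
#' (alleles and zygosity). Sites absent from \code{calls} count against
#' recall and concordance.
#'
#' @param calls a [CallSet-class] (for precision/recall) — concordance
#'   additionally needs \code{genotypeCalls}.
#' @param truth truth data.frame from [truthRecords()].
#' @param genotypeCalls optional [GenotypeCalls-class] used for the
#'   genotype-level concordance; when omitted concordance is NA.
#' @return list(precision, recall, concordance, nTruth, nCalled).
#' @export
truthEval <- function(calls, truth, genotypeCalls = NULL) {
  stopifnot(is(calls, "CallSet"))
  keyCalls <- .setKeys(calls)
  keyTruth <- paste(truth$chrom, truth$pos)
  nCalled <- length(keyCalls)
  nTruth <- length(keyTruth)
  tp <- sum(keyCalls %in% keyTruth)
  precision <- if (nCalled == 0) {
    warning("empty call set: precision undefined")
    NaN
  } else tp / nCalled
  recall <- if (nTruth == 0) NaN else
    sum(keyTruth %in% keyCalls) / nTruth
  concordance <- NA_real_
  if (!is.null(genotypeCalls)) {
    keyGc <- paste(genotypeCalls@chrom, genotypeCalls@pos)
    idx <- match(keyTruth, keyGc)
    called <- ifelse(is.na(idx), NA_character_, genotypeCalls@genotype[idx])
    concordance <- mean(!is.na(called) & called == truth$genotype)
  }
  list(precision = precision, recall = recall, concordance = concordance,
       nTruth = nTruth, nCalled = nCalled)
}

#' Write an evaluation report
#'
#' Emits the metrics of [truthEval()]/[overlapMatrix()] as a TSV, and
#' optionally the Venn cells as JSON.
#'
#' @param metrics named list of scalar metrics.
#' @param file TSV output path.
#' @param venn optional result of [overlapMatrix()]; written to
#'   \code{jsonFile}.
#' @param jsonFile JSON output path for the Venn cells.
#' @return invisibly, \code{file}.
#' @export
writeMetrics <- function(metrics, file, venn = NULL, jsonFile = NULL) {
  df <- data.frame(metric = names(metrics),
                   value = vapply(metrics, function(v)
                     format(v, digits = 10), character(1)))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(venn) && !is.null(jsonFile))
    jsonlite::write_json(list(cells = as.list(venn$cells),
                              exclusive = as.list(venn$exclusive)),
                         jsonFile, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
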