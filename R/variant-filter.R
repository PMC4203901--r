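## Post-hoc high-quality (QC) filtering and the simple two-allele indel
## caller.

#' Quality-control filter for variant calls
#'
#' Reproduces the post-hoc filtering used to build a high-quality (QC)
#' call set: keep only variant calls whose Phred-scaled posterior is
#' strictly greater than \code{minPhred} (default 30) and that are
#' supported by at least \code{minSupport} reads carrying a non-reference
#' allele of the called genotype (default 10; 5 is a common relaxed
#' setting, and 1 reduces the filter to quality-only). Homozygous-
#' reference calls are never variants. Idempotent; the output is always a
#' subset of the input.
#'
#' @param calls a [GenotypeCalls-class] object.
#' @param minPhred strict lower bound on the call quality.
#' @param minSupport minimum number of reads supporting the variant
#'   allele(s).
#' @return the filtered [GenotypeCalls-class].
#' @export
qcFilter <- function(calls, minPhred = 30, minSupport = 10L) {
  stopifnot(is(calls, "GenotypeCalls"))
  if (minPhred < 0 || minSupport < 1)
    stop("minPhred must be >= 0 and minSupport >= 1")
  keep <- isVariant(calls) & calls@phred > minPhred &
    calls@altSupport >= minSupport
  calls[which(keep)]
}

#' Quality-control filter on a VCF file
#'
#' File-level counterpart of [qcFilter()]: reads a VCF written by
#' [writeVcf()], keeps variant records (ALT != ".") with QUAL strictly
#' above \code{minPhred} and total ALT-allele read support (from the AD
#' sample field) of at least \code{minSupport}, and writes the surviving
#' records (header preserved). Malformed records are skipped with a
#' warning.
#'
#' @param infile input VCF path.
#' @param outfile output VCF path ("" to skip writing).
#' @inheritParams qcFilter
#' @return invisibly, the retained VCF lines.
#' @export
qcFilterVcf <- function(infile, outfile = "", minPhred = 30,
                        minSupport = 10L) {
  lines <- readLines(.openText(infile))
  hdr <- grepl("^#", lines)
  recs <- lines[!hdr]
  keep <- vapply(recs, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) {
      warning("skipping malformed VCF record: ", substr(l, 1, 60))
      return(FALSE)
    }
    if (f[5] == ".") return(FALSE)
    qual <- suppressWarnings(as.numeric(f[6]))
    if (is.na(qual) || qual <= minPhred) return(FALSE)
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    adIdx <- match("AD", fmt)
    if (is.na(adIdx) || adIdx > length(smp)) {
      warning("skipping record without AD field at ", f[1], ":", f[2])
      return(FALSE)
    }
    ad <- suppressWarnings(as.integer(strsplit(smp[adIdx], ",", fixed = TRUE)[[1]]))
    sum(ad[-1], na.rm = TRUE) >= minSupport
  }, logical(1), USE.NAMES = FALSE)
  out <- c(lines[hdr], recs[keep])
  if (nzchar(outfile)) {
    con <- if (grepl("\\.gz$", outfile)) gzfile(outfile, "wt") else
      file(outfile, "wt")
    writeLines(out, con)
    close(con)
  }
  invisible(out)
}

#' Two-allele indel caller
#'
#' The generative model has no indel channel; this caller reuses its
#' diploid machinery on the reduced two-allele space \{reference allele,
#' most frequent indel allele\} at each column that carries indel
#' records. Per read, the probability of an erroneous observation comes
#' from the effective quality (indel-supporting reads use the quality of
#' the read the indel is attached to); the genotype prior over \{RR, RV,
#' VV\} reuses the SNP-rate machinery (1 - mu, p(1-p), p^2, renormalised).
#' Calls are then subjected to the same QC policy as SNPs.
#'
#' @param pileup a [Pileup-class] with indel records.
#' @param snpRate prior SNP rate feeding the two-allele prior.
#' @param minPhred,minSupport QC policy (as [qcFilter()]).
#' @param cap error-probability cap.
#' @return data.frame with one row per QC-passing indel: chrom, pos, ref
#'   kind ("ins"/"del"), seq, genotype ("RV" heterozygous or "VV"
#'   homozygous), phred, support, depth.
#' @export
callIndels <- function(pileup, snpRate = 0.001, minPhred = 30,
                       minSupport = 10L, cap = 0.75) {
  stopifnot(is(pileup, "Pileup"))
  p <- solveAltAlleleProb(snpRate)
  pri <- c(RR = 1 - snpRate, RV = p * (1 - p), VV = p^2)
  pri <- pri / sum(pri)
  out <- list()
  for (i in seq_len(length(pileup))) {
    ind <- pileup@indels[[i]]
    if (nrow(ind) == 0L) next
    key <- paste(ind$kind, ind$seq)
    top <- names(sort(table(key), decreasing = TRUE))[1]
    sup <- ind[key == top, , drop = FALSE]
    nSup <- nrow(sup)
    nTot <- length(pileup@obsBase[[i]])
    if (nTot < nSup) nTot <- nSup
    eSup <- phredToErrorProb(pmin(sup$qual, .MAXQ), cap = cap)
    qOther <- effectiveQuality(pileup@obsQual[[i]], pileup@obsMapq[[i]])
    othIdx <- setdiff(seq_along(qOther), sup$obs[!is.na(sup$obs)])
    eOth <- phredToErrorProb(pmin(qOther[othIdx], .MAXQ), cap = cap)
    ## per-read two-allele likelihoods: P(obs | S = R or V)
    ## supporting read: obs = V; non-supporting: obs = R
    logLik <- function(pV) {               # pV = P(S = V | G)
      sum(log(pV * (1 - eSup) + (1 - pV) * eSup)) +
        sum(log(pV * eOth + (1 - pV) * (1 - eOth)))
    }
    lp <- log(pri) + c(logLik(0), logLik(0.5), logLik(1))
    lp <- lp - max(lp)
    post <- exp(lp) / sum(exp(lp))
    k <- which.max(post)
    if (k == 1L) next                      # homozygous reference
    phred <- phredFromPosterior(post[k])
    if (phred <= minPhred || nSup < minSupport) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = pileup@chrom[i], pos = pileup@pos[i], ref = pileup@ref[i],
      kind = sup$kind[1], seq = sup$seq[1],
      genotype = names(pri)[k], phred = phred, support = nSup,
      depth = nTot, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), kind = character(0),
                      seq = character(0), genotype = character(0),
                      phred = numeric(0), support = integer(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
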