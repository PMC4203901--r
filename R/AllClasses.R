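#' @import methods
#' @importFrom stats runif rbinom setNames
#' @importFrom utils head
#' @importFrom data.table data.table setorder
NULL

.datatable.aware <- TRUE

## Canonical base and genotype orderings used throughout the package.
## Diploid genotypes are the 10 unordered pairs in lexicographic order;
## ties in the MAP genotype are broken towards the smaller index, i.e.
## the lexicographically smallest genotype string.

#' Nucleotide alphabet
#'
#' The fixed base ordering \code{A, C, G, T} used for every probability
#' vector and matrix in the package.
#' @export
BASES <- c("A", "C", "G", "T")

#' Diploid genotype alphabet
#'
#' The ten unordered diploid genotypes in lexicographic order.
#' @export
DIPLOID_GENOTYPES <- c("AA", "AC", "AG", "AT", "CC",
                       "CG", "CT", "GG", "GT", "TT")

## allele indices (into BASES) for each diploid genotype
.GT_ALLELES <- matrix(c(1L,1L, 1L,2L, 1L,3L, 1L,4L, 2L,2L,
                        2L,3L, 2L,4L, 3L,3L, 3L,4L, 4L,4L),
                      ncol = 2L, byrow = TRUE,
                      dimnames = list(DIPLOID_GENOTYPES, c("a1", "a2")))

#' SubstitutionMatrix: the read-error model P(R | S)
#'
#' A 4x4 row-stochastic matrix over \code{A,C,G,T}: rows index the sampled
#' (true) base S, columns the observed read base R. Holds the sequencing
#' error rate \code{tau} and, for the ancient-DNA damage model, the
#' deamination rate \code{delta} (excess C-to-T and, on the opposite strand,
#' G-to-A mismatch probability).
#'
#' @slot probs 4x4 numeric matrix, rows summing to 1.
#' @slot tau numeric, error rate in [0, 1).
#' @slot delta numeric, damage rate in [0, 1).
#' @seealso [errorMatrix()], [damageMatrix()]
#' @export
setClass("SubstitutionMatrix",
         representation(probs = "matrix", tau = "numeric", delta = "numeric"))

setValidity("SubstitutionMatrix", function(object) {
  p <- object@probs
  if (!is.numeric(p) || !identical(dim(p), c(4L, 4L)))
    return("'probs' must be a numeric 4x4 matrix")
  if (any(p < 0 | p > 1))
    return("all entries must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-12))
    return("every row must sum to 1 (within 1e-12)")
  TRUE
})

#' ReferencePrior: the distribution P(H) over the reference base
#'
#' In \code{"flat"} mode all four bases are equally likely a priori; in
#' \code{"observed"} mode the reference base at each position is treated as
#' known (a point mass, applied per position); \code{"custom"} carries a
#' user-supplied length-4 distribution.
#'
#' @slot mode one of "flat", "observed", "custom".
#' @slot probs length-4 probability vector over A,C,G,T (unused in
#'   observed mode, where the per-position reference base is the prior).
#' @export
setClass("ReferencePrior",
         representation(mode = "character", probs = "numeric"))

setValidity("ReferencePrior", function(object) {
  if (!object@mode %in% c("flat", "observed", "custom"))
    return("mode must be one of 'flat', 'observed', 'custom'")
  if (object@mode != "observed") {
    if (length(object@probs) != 4L || any(object@probs < 0))
      return("probs must be a non-negative length-4 vector")
    if (abs(sum(object@probs) - 1) > 1e-12)
      return("probs must sum to 1")
  }
  TRUE
})

#' GenotypePrior: the distribution P(G | H)
#'
#' Row-stochastic matrix with one row per reference base H and one column
#' per genotype: 4x4 for haploid genomes (genotypes A,C,G,T) or 4x10 for
#' diploid genomes (the ten unordered pairs). Built from an expected SNP
#' rate; in the diploid case the per-allele alternative probability p is
#' the positive root of the Hardy-Weinberg equation 3p(1-p) + 6p^2 = mu.
#'
#' @slot ploidy "haploid" or "diploid".
#' @slot snpRate numeric, expected SNP rate mu.
#' @slot altAlleleProb numeric, p (diploid; 0 for haploid).
#' @slot probs the prior matrix, rows A,C,G,T.
#' @seealso [genotypePrior()], [solveAltAlleleProb()]
#' @export
setClass("GenotypePrior",
         representation(ploidy = "character", snpRate = "numeric",
                        altAlleleProb = "numeric", probs = "matrix"))

setValidity("GenotypePrior", function(object) {
  if (!object@ploidy %in% c("haploid", "diploid"))
    return("ploidy must be 'haploid' or 'diploid'")
  nG <- if (object@ploidy == "haploid") 4L else 10L
  if (!identical(dim(object@probs), c(4L, nG)))
    return(sprintf("prior matrix must be 4x%d for %s", nG, object@ploidy))
  if (any(object@probs < 0))
    return("prior entries must be non-negative")
  if (any(abs(rowSums(object@probs) - 1) > 1e-12))
    return("every prior row must sum to 1 (within 1e-12)")
  TRUE
})

#' Pileup: a parsed stack of mpileup -s columns
#'
#' Columnar container for one pileup file: per-position scalars plus
#' list-columns holding the per-read observations. Base observations are
#' stored as integer codes into [BASES]; qualities are integer Phred
#' scores (ASCII offset already removed). Reads showing \code{N}, deletion
#' placeholders \code{*} and reference skips are dropped from the
#' observation lists but counted in \code{skipped}.
#'
#' @slot chrom character vector of chromosome names.
#' @slot pos integer vector of 1-based positions.
#' @slot ref character vector of reference bases (possibly "N").
#' @slot obsBase list of integer vectors (codes 1..4 into [BASES]).
#' @slot obsQual list of integer vectors, per-read base qualities.
#' @slot obsMapq list of integer vectors, per-read mapping qualities.
#' @slot obsStrand list of character vectors ("+"/"-").
#' @slot indels list of data.frames (kind, seq, strand, qual) per column.
#' @slot skipped integer vector, dropped-read count per column.
#' @seealso [readPileup()]
#' @export
setClass("Pileup",
         representation(chrom = "character", pos = "integer",
                        ref = "character", obsBase = "list",
                        obsQual = "list", obsMapq = "list",
                        obsStrand = "list", indels = "list",
                        skipped = "integer"))

setValidity("Pileup", function(object) {
  n <- length(object@pos)
  lens <- c(length(object@chrom), length(object@ref), length(object@obsBase),
            length(object@obsQual), length(object@obsMapq),
            length(object@obsStrand), length(object@indels),
            length(object@skipped))
  if (any(lens != n))
    return("all slots must have one entry per pileup column")
  nb <- lengths(object@obsBase)
  if (any(nb != lengths(object@obsQual)) || any(nb != lengths(object@obsMapq)))
    return("observation and quality vectors must be index-aligned")
  TRUE
})

#' GenotypeCalls: per-position genotype posteriors
#'
#' One row per called position: the MAP genotype, the full posterior
#' vector, the Phred-scaled confidence -10*log10(1 - posterior[MAP])
#' (capped at 9999), the read depth used after capping, the mean mapping
#' quality of the reads used, and the number of reads supporting a
#' non-reference allele of the MAP genotype.
#'
#' @slot chrom,pos,ref position identity as in [Pileup].
#' @slot genotype character, MAP genotype per position.
#' @slot phred numeric, Phred-scaled posterior confidence.
#' @slot depthUsed integer, reads used after depth capping.
#' @slot meanMapq numeric, mean mapping quality of reads used.
#' @slot altSupport integer, reads whose base equals a non-reference
#'   allele of the MAP genotype.
#' @slot posterior numeric matrix, positions x genotypes, rows sum to 1.
#' @slot baseTally list of per-position base-count vectors (A,C,G,T) of
#'   the reads used, backing the VCF AD field.
#' @slot ploidy "haploid" or "diploid".
#' @slot params list of run parameters (echoed into the VCF header).
#' @seealso [callGenotypes()], [writeVcf()]
#' @export
setClass("GenotypeCalls",
         representation(chrom = "character", pos = "integer",
                        ref = "character", genotype = "character",
                        phred = "numeric", depthUsed = "integer",
                        meanMapq = "numeric", altSupport = "integer",
                        posterior = "matrix", baseTally = "list",
                        ploidy = "character", params = "list"))

setValidity("GenotypeCalls", function(object) {
  n <- length(object@pos)
  if (length(object@genotype) != n || length(object@phred) != n ||
      length(object@depthUsed) != n || nrow(object@posterior) != n)
    return("all per-position slots must have equal length")
  if (n > 0 && any(abs(rowSums(object@posterior) - 1) > 1e-9))
    return("posterior rows must sum to 1 (within 1e-9)")
  TRUE
})

#' CallSet: a labelled set of variant sites
#'
#' The unit of comparison for call-set evaluation: unique variant
#' positions with their alternative allele(s) and zygosity.
#'
#' @slot label character scalar naming the set.
#' @slot variants data.frame with columns chrom, pos, alt, zygosity.
#' @seealso [callSet()], [overlapMatrix()], [truthEval()]
#' @export
setClass("CallSet",
         representation(label = "character", variants = "data.frame"))

setValidity("CallSet", function(object) {
  v <- object@variants
  need <- c("chrom", "pos", "alt", "zygosity")
  if (!all(need %in% names(v)))
    return("variants must have columns chrom, pos, alt, zygosity")
  if (anyDuplicated(paste(v$chrom, v$pos)))
    return("variant positions must be unique within a set")
  TRUE
})
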