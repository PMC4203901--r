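#' @rdname SubstitutionMatrix-class
#' @param object,x a package object.
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname SubstitutionMatrix-class
#' @export
setGeneric("tau", function(x) standardGeneric("tau"))

#' @rdname SubstitutionMatrix-class
#' @export
setGeneric("delta", function(x) standardGeneric("delta"))

#' @rdname GenotypePrior-class
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname GenotypePrior-class
#' @export
setGeneric("snpRate", function(x, ...) standardGeneric("snpRate"))

#' @rdname GenotypePrior-class
#' @export
setGeneric("altAlleleProb", function(x) standardGeneric("altAlleleProb"))

#' @export
#' @rdname GenotypePrior-class
setMethod("snpRate", "GenotypePrior", function(x, ...) x@snpRate)

#' @export
#' @rdname SubstitutionMatrix-class
setMethod("probs", "SubstitutionMatrix", function(x) x@probs)
#' @export
#' @rdname GenotypePrior-class
setMethod("probs", "GenotypePrior", function(x) x@probs)
#' @export
#' @rdname ReferencePrior-class
setMethod("probs", "ReferencePrior", function(x) x@probs)
#' @export
#' @rdname SubstitutionMatrix-class
setMethod("tau", "SubstitutionMatrix", function(x) x@tau)
#' @export
#' @rdname SubstitutionMatrix-class
setMethod("delta", "SubstitutionMatrix", function(x) x@delta)
#' @export
#' @rdname GenotypePrior-class
setMethod("ploidy", "GenotypePrior", function(x) x@ploidy)
#' @export
#' @rdname GenotypeCalls-class
setMethod("ploidy", "GenotypeCalls", function(x) x@ploidy)
#' @export
#' @rdname GenotypePrior-class
setMethod("altAlleleProb", "GenotypePrior", function(x) x@altAlleleProb)

setMethod("show", "SubstitutionMatrix", function(object) {
  cat(sprintf("SubstitutionMatrix P(R|S)  tau=%g  delta=%g\n",
              object@tau, object@delta))
  print(round(object@probs, 6))
})

setMethod("show", "GenotypePrior", function(object) {
  cat(sprintf("GenotypePrior P(G|H)  ploidy=%s  snpRate=%g", object@ploidy,
              object@snpRate))
  if (object@ploidy == "diploid")
    cat(sprintf("  p=%g", object@altAlleleProb))
  cat("\n")
  print(signif(object@probs, 4))
})

setMethod("show", "ReferencePrior", function(object) {
  cat(sprintf("ReferencePrior P(H)  mode=%s\n", object@mode))
  if (object@mode != "observed")
    print(setNames(object@probs, BASES))
})

#' @export
#' @rdname Pileup-class
setMethod("length", "Pileup", function(x) length(x@pos))

#' @rdname Pileup-class
#' @param i index vector.
#' @export
setMethod("[", "Pileup", function(x, i) {
  new("Pileup", chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i],
      obsBase = x@obsBase[i], obsQual = x@obsQual[i],
      obsMapq = x@obsMapq[i], obsStrand = x@obsStrand[i],
      indels = x@indels[i], skipped = x@skipped[i])
})

#' @rdname Pileup-class
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))
#' @export
#' @rdname Pileup-class
setMethod("depth", "Pileup", function(x) lengths(x@obsBase) + x@skipped)

setMethod("show", "Pileup", function(object) {
  n <- length(object)
  cat(sprintf("Pileup with %d column%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    d <- lengths(object@obsBase)
    cat(sprintf("  %s:%d-%d  depth used: mean %.1f, max %d; skipped reads: %d\n",
                object@chrom[1], min(object@pos), max(object@pos),
                mean(d), max(d), sum(object@skipped)))
  }
})

#' @export
#' @rdname GenotypeCalls-class
setMethod("length", "GenotypeCalls", function(x) length(x@pos))

#' @rdname GenotypeCalls-class
#' @export
setMethod("[", "GenotypeCalls", function(x, i) {
  new("GenotypeCalls", chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i],
      genotype = x@genotype[i], phred = x@phred[i],
      depthUsed = x@depthUsed[i], meanMapq = x@meanMapq[i],
      altSupport = x@altSupport[i],
      posterior = x@posterior[i, , drop = FALSE],
      baseTally = x@baseTally[i], ploidy = x@ploidy, params = x@params)
})

setMethod("show", "GenotypeCalls", function(object) {
  cat(sprintf("GenotypeCalls: %d position%s, ploidy=%s\n", length(object),
              if (length(object) == 1) "" else "s", object@ploidy))
  if (length(object) > 0) {
    v <- sum(isVariant(object))
    cat(sprintf("  variant calls: %d; median phred: %.1f; mean depth used: %.1f\n",
                v, stats::median(object@phred), mean(object@depthUsed)))
  }
})

#' Extract call fields as a data.frame
#'
#' @param x a [GenotypeCalls-class] object.
#' @param ... unused.
#' @return data.frame with one row per position (posterior omitted).
#' @export
as.data.frame.GenotypeCalls <- function(x, ...) {
  data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref,
             genotype = x@genotype, phred = x@phred,
             depthUsed = x@depthUsed, meanMapq = x@meanMapq,
             altSupport = x@altSupport, stringsAsFactors = FALSE)
}

setMethod("show", "CallSet", function(object) {
  cat(sprintf("CallSet '%s': %d variant site%s\n", object@label,
              nrow(object@variants),
              if (nrow(object@variants) == 1) "" else "s"))
})

#' @rdname CallSet-class
#' @export
setGeneric("label", function(x) standardGeneric("label"))
#' @export
#' @rdname CallSet-class
setMethod("label", "CallSet", function(x) x@label)
#' @rdname CallSet-class
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @export
#' @rdname CallSet-class
setMethod("variants", "CallSet", function(x) x@variants)
#' @export
#' @rdname CallSet-class
setMethod("length", "CallSet", function(x) nrow(x@variants))
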