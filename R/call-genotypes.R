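## Whole-pileup genotype calling. Per-read likelihoods depend only on the
## (called base, effective quality) pair, so the log genotype likelihood
## for every combination is precomputed once into a lookup table and each
## column reduces to an indexed row-sum — the exact same marginalisation
## as genotypePosterior(), just batched.

.MAXQ <- 93L

## log P(obs | G = g) for every (base b, effective quality q) pair,
## as an nG x (4 * (.MAXQ+1)) matrix, column index 4*q + b.
.likelihoodLookup <- function(sub, ploidy, cap = 0.75) {
  S <- .sampleDistMatrix(ploidy)
  e <- phredToErrorProb(0:.MAXQ, cap = cap)
  call <- matrix(0, 4, 4L * (.MAXQ + 1L))
  for (q in 0:.MAXQ) {
    block <- matrix(e[q + 1] / 3, 4, 4)
    diag(block) <- 1 - e[q + 1]
    call[, 4L * q + (1:4)] <- block
  }
  log(S %*% (sub@probs %*% call))
}

#' Call genotypes over a whole pileup
#'
#' Runs the generative model position by position: per-read effective
#' qualities (min of base and mapping quality) are converted to base-call
#' distributions, folded through the substitution/damage matrix, combined
#' across reads in log space, weighted by the genotype prior, and
#' normalised to a posterior over genotypes. Positions deeper than
#' \code{maxDepth} are first downsampled uniformly at random (seeded).
#' Equivalent to applying [genotypePosterior()] at every column.
#'
#' @param pileup a [Pileup-class] object.
#' @param ploidy "haploid" or "diploid".
#' @param snpRate expected SNP rate for the genotype prior.
#' @param tau substitution error rate (see [errorMatrix()]).
#' @param delta damage rate; 0 selects the standard error model, > 0 the
#'   ancient-DNA damage model (see [damageMatrix()]).
#' @param useReference use the pileup's reference base as an observed
#'   prior P(H) (TRUE) or a flat prior over the four bases (FALSE).
#' @param maxDepth depth cap; deeper columns are randomly downsampled.
#' @param seed integer seed driving the downsampling.
#' @param cap error-probability cap (see [phredToErrorProb()]).
#' @param sub optional [SubstitutionMatrix-class] overriding the tau/delta
#'   built-ins (user-supplied error models).
#' @return a [GenotypeCalls-class] object.
#' @export
callGenotypes <- function(pileup, ploidy = c("haploid", "diploid"),
                          snpRate = 0.001, tau = 0.002, delta = 0,
                          useReference = TRUE, maxDepth = 60L, seed = 1L,
                          cap = 0.75, sub = NULL) {
  stopifnot(is(pileup, "Pileup"))
  ploidy <- match.arg(ploidy)
  if (is.null(sub))
    sub <- if (delta > 0) damageMatrix(tau, delta) else errorMatrix(tau)
  gtPrior <- genotypePrior(ploidy, snpRate)
  refPrior <- referencePrior(if (useReference) "observed" else "flat")
  gts <- if (ploidy == "haploid") BASES else DIPLOID_GENOTYPES
  nG <- length(gts)

  LG <- .likelihoodLookup(sub, ploidy, cap)
  ## log prior per reference base (row 5 = unknown/flat-marginal context)
  lpByRef <- rbind(t(vapply(BASES, function(h)
    .logGenotypePrior(gtPrior, referencePrior("observed"), h), numeric(nG))),
    .logGenotypePrior(gtPrior, refPrior, NA_character_))
  if (!useReference)
    lpByRef[1:4, ] <- matrix(lpByRef[5, ], 4, nG, byrow = TRUE)

  n <- length(pileup)
  genotype <- character(n); phred <- numeric(n)
  depthUsed <- integer(n); meanMapq <- numeric(n)
  altSupport <- integer(n); posterior <- matrix(0, n, nG,
                                                dimnames = list(NULL, gts))
  baseTally <- vector("list", n)
  set.seed(seed)
  refCode <- match(pileup@ref, BASES)
  for (i in seq_len(n)) {
    b <- pileup@obsBase[[i]]
    q <- effectiveQuality(pileup@obsQual[[i]], pileup@obsMapq[[i]])
    mq <- pileup@obsMapq[[i]]
    if (length(b) > maxDepth) {
      keep <- sort(sample.int(length(b), maxDepth))
      b <- b[keep]; q <- q[keep]; mq <- mq[keep]
    }
    q[q > .MAXQ] <- .MAXQ
    h <- refCode[i]
    lp <- lpByRef[if (is.na(h)) 5L else h, ]
    if (length(b) > 0)
      lp <- lp + rowSums(LG[, 4L * q + b, drop = FALSE])
    lp <- lp - max(lp)
    w <- exp(lp)
    post <- w / sum(w)
    k <- which.max(post)
    genotype[i] <- gts[k]
    phred[i] <- phredFromPosterior(post[k])
    depthUsed[i] <- length(b)
    meanMapq[i] <- if (length(mq)) mean(mq) else 0
    posterior[i, ] <- post
    tally <- tabulate(b, nbins = 4L)
    baseTally[[i]] <- tally
    alt <- setdiff(unique(.gtAlleles(gts[k])), pileup@ref[i])
    altSupport[i] <- sum(tally[match(alt, BASES)])
  }
  new("GenotypeCalls", chrom = pileup@chrom, pos = pileup@pos,
      ref = pileup@ref, genotype = genotype, phred = phred,
      depthUsed = depthUsed, meanMapq = meanMapq,
      altSupport = altSupport, posterior = posterior,
      baseTally = baseTally, ploidy = ploidy,
      params = list(ploidy = ploidy, snpRate = snpRate, tau = sub@tau,
                    delta = sub@delta, useReference = useReference,
                    maxDepth = maxDepth, seed = seed, cap = cap))
}

#' Which calls are variants?
#'
#' A call is a variant when its MAP genotype contains at least one allele
#' different from the pileup reference base (positions with unknown
#' reference "N" are never classified as variants).
#'
#' @param calls a [GenotypeCalls-class].
#' @return logical vector.
#' @export
isVariant <- function(calls) {
  stopifnot(is(calls, "GenotypeCalls"))
  ref <- calls@ref
  ok <- ref %in% BASES
  vapply(seq_along(ref), function(i) {
    ok[i] && any(.gtAlleles(calls@genotype[i]) != ref[i])
  }, logical(1))
}

#' Zygosity of each call
#'
#' @param calls a [GenotypeCalls-class].
#' @return "hom" or "het" per position (haploid calls are all "hom").
#' @export
zygosity <- function(calls) {
  stopifnot(is(calls, "GenotypeCalls"))
  vapply(calls@genotype, function(g) {
    al <- .gtAlleles(g)
    if (length(al) == 2L && al[1] != al[2]) "het" else "hom"
  }, character(1), USE.NAMES = FALSE)
}
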