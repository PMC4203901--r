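## The generative model: priors over reference and genotype, the sampled
## allele distribution P(S|G), and exact posterior inference over
## genotypes by marginalisation. The joint at one position factorises as
##   P(H) P(G|H) prod_i P(S_i|G) P(R_i|S_i) P(I_i|R_i)
## and summing out S and R per read leaves a product of per-read genotype
## likelihoods; everything is done in natural-log space with log-sum-exp.

#' Hardy-Weinberg alternative-allele probability
#'
#' With an expected SNP rate mu, the diploid genotype prior distributes
#' the off-homozygote mass under Hardy-Weinberg equilibrium: three
#' genotypes with one alternative allele at p(1-p) each, six with two
#' alternative alleles at p^2 each. Setting 3p(1-p) + 6p^2 = mu gives the
#' second-degree equation 3p + 3p^2 = mu; this returns its positive root
#' p = (sqrt(9 + 12*mu) - 3) / 6. At the default mu = 0.001,
#' p = 3.332e-4, i.e. 0.0333\%.
#'
#' @param snpRate expected SNP rate mu in [0, 1).
#' @return the alternative-allele probability p.
#' @examples
#' solveAltAlleleProb(0.001) * 100   # 0.0333 (percent)
#' @export
solveAltAlleleProb <- function(snpRate) {
  if (snpRate < 0 || snpRate >= 1) stop("snpRate must lie in [0, 1)")
  p <- (sqrt(9 + 12 * snpRate) - 3) / 6
  if (p < 0 || p >= 1) stop("no valid root in [0, 1)")  # unreachable for valid input
  p
}

#' Build the genotype prior P(G | H)
#'
#' Haploid: each row puts 1 - mu on the reference base and mu/3 on each of
#' the other three. Diploid: each row puts 1 - mu on the homozygous
#' reference genotype, p(1-p) on each of the three heterozygotes carrying
#' the reference allele, and p^2 on each of the six remaining genotypes,
#' with p from [solveAltAlleleProb()]; each row sums to 1 by construction.
#'
#' @param ploidy "haploid" or "diploid".
#' @param snpRate expected SNP rate (default 0.001).
#' @return a [GenotypePrior-class].
#' @export
genotypePrior <- function(ploidy = c("diploid", "haploid"), snpRate = 0.001) {
  ploidy <- match.arg(ploidy)
  if (snpRate < 0 || snpRate >= 1) stop("snpRate must lie in [0, 1)")
  if (ploidy == "haploid") {
    m <- matrix(snpRate / 3, 4, 4, dimnames = list(H = BASES, G = BASES))
    diag(m) <- 1 - snpRate
    return(new("GenotypePrior", ploidy = ploidy, snpRate = snpRate,
               altAlleleProb = 0, probs = m))
  }
  p <- solveAltAlleleProb(snpRate)
  m <- matrix(p^2, 4, 10, dimnames = list(H = BASES, G = DIPLOID_GENOTYPES))
  for (h in 1:4) {
    het <- which(xor(.GT_ALLELES[, 1] == h, .GT_ALLELES[, 2] == h))
    hom <- which(.GT_ALLELES[, 1] == h & .GT_ALLELES[, 2] == h)
    m[h, het] <- p * (1 - p)
    m[h, hom] <- 1 - snpRate
  }
  ## exact row-stochasticity: absorb the tiny closure residual of the
  ## quadratic root into the homozygous-reference entry
  for (h in 1:4) {
    hom <- which(.GT_ALLELES[, 1] == h & .GT_ALLELES[, 2] == h)
    m[h, hom] <- m[h, hom] + (1 - sum(m[h, ]))
  }
  new("GenotypePrior", ploidy = ploidy, snpRate = snpRate,
      altAlleleProb = p, probs = m)
}

#' Reference-base prior P(H)
#'
#' @param mode "flat" (default; 0.25 each), "observed" (the reference base
#'   at each position is used as a point-mass prior), or "custom".
#' @param probsVec length-4 distribution over A,C,G,T for custom mode.
#' @return a [ReferencePrior-class].
#' @export
referencePrior <- function(mode = c("flat", "observed", "custom"),
                           probsVec = NULL) {
  mode <- match.arg(mode)
  p <- switch(mode,
              flat = rep(0.25, 4),
              observed = rep(NA_real_, 4),
              custom = {
                if (is.null(probsVec)) stop("custom mode needs 'probsVec'")
                as.numeric(probsVec)
              })
  new("ReferencePrior", mode = mode, probs = p)
}

#' Sampled-allele distribution P(S | G) for one genotype
#'
#' Haploid genotypes sample their own base with certainty (the identity
#' matrix). A diploid homozygote aa samples a with probability 1; a
#' heterozygote ab samples each allele with probability 0.5.
#'
#' @param genotype genotype string, e.g. "A" (haploid) or "AC" (diploid).
#' @return named length-4 probability vector over A,C,G,T.
#' @examples
#' sampleDistribution("AA")  # (1,0,0,0)
#' sampleDistribution("AC")  # (0.5,0.5,0,0)
#' @export
sampleDistribution <- function(genotype) {
  p <- setNames(numeric(4), BASES)
  if (nchar(genotype) == 1L) {
    b <- match(genotype, BASES)
    if (is.na(b)) stop("unknown haploid genotype: ", genotype)
    p[b] <- 1
  } else {
    g <- match(genotype, DIPLOID_GENOTYPES)
    if (is.na(g)) stop("unknown diploid genotype: ", genotype)
    a <- .GT_ALLELES[g, ]
    p[a[1]] <- p[a[1]] + 0.5
    p[a[2]] <- p[a[2]] + 0.5
  }
  p
}

## full P(S|G) matrix, genotypes x 4
.sampleDistMatrix <- function(ploidy) {
  gts <- if (ploidy == "haploid") BASES else DIPLOID_GENOTYPES
  t(vapply(gts, sampleDistribution, numeric(4)))
}

## log prior over genotypes for a given reference context.
## observed mode: row of P(G|H) for the reference base (flat marginal if
## the reference base is N/unknown); flat/custom: P(H) marginalised in.
.logGenotypePrior <- function(gtPrior, refPrior, refBase = NA_character_) {
  m <- gtPrior@probs
  if (refPrior@mode == "observed") {
    h <- match(refBase, BASES)
    pri <- if (is.na(h)) colMeans(m) else m[h, ]
  } else {
    pri <- as.vector(refPrior@probs %*% m)
  }
  log(pri)
}

#' Phred-scale a posterior probability
#'
#' -10*log10(1 - p), capped at 9999 when p rounds to 1 in double
#' precision.
#' @param p posterior probability of the MAP genotype.
#' @return non-negative numeric.
#' @export
phredFromPosterior <- function(p) {
  q <- -10 * log10(pmax(1 - p, 0))
  pmin(ifelse(is.finite(q), q, 9999), 9999)
}

#' Exact genotype posterior at one position
#'
#' Marginalises the generative model at a single position: for each
#' genotype g, posterior(g) is proportional to prior(g) times the product
#' over reads of sum_s P(S=s|g) L_i(s), where L_i is the per-read
#' likelihood from [readLikelihood()] (substitution matrix folded into the
#' quality-derived base-call distribution). Computed in log space with a
#' log-sum-exp normalisation. With zero reads the posterior equals the
#' prior exactly.
#'
#' @param bases character or integer vector of called bases (one per read).
#' @param quals integer base qualities.
#' @param mapqs integer mapping qualities (effective quality is the
#'   per-read minimum of the two).
#' @param gtPrior a [GenotypePrior-class].
#' @param refPrior a [ReferencePrior-class] (default flat).
#' @param refBase reference base for observed mode (may be NA/"N").
#' @param sub a [SubstitutionMatrix-class] (default \code{errorMatrix(0.002)}).
#' @param cap error-probability cap (see [phredToErrorProb()]).
#' @return list with elements \code{posterior} (named, sums to 1),
#'   \code{genotype} (MAP; ties broken towards the lexicographically
#'   smallest), \code{phred}, and \code{depth}.
#' @export
genotypePosterior <- function(bases, quals, mapqs,
                              gtPrior, refPrior = referencePrior("flat"),
                              refBase = NA_character_,
                              sub = errorMatrix(0.002), cap = 0.75) {
  b <- if (is.character(bases)) match(bases, BASES) else as.integer(bases)
  n <- length(b)
  stopifnot(length(quals) == n, length(mapqs) == n)
  S <- .sampleDistMatrix(gtPrior@ploidy)
  lp <- .logGenotypePrior(gtPrior, refPrior, refBase)
  if (n > 0) {
    e <- phredToErrorProb(effectiveQuality(quals, mapqs), cap = cap)
    ## 4 x n matrix of base-call distributions
    call <- matrix(rep(e / 3, each = 4), 4, n)
    call[cbind(b, seq_len(n))] <- 1 - e
    L <- sub@probs %*% call          # 4 x n: per-read P(obs|S=s)
    G <- S %*% L                     # nG x n: per-read P(obs|G=g)
    lp <- lp + rowSums(log(G))
  }
  if (all(!is.finite(lp)))
    return(list(posterior = setNames(rep(NA_real_, length(lp)), rownames(S)),
                genotype = NA_character_, phred = 0, depth = n))
  lp <- lp - max(lp)
  post <- exp(lp) / sum(exp(lp))
  gts <- if (gtPrior@ploidy == "haploid") BASES else DIPLOID_GENOTYPES
  k <- which.max(post)               # first max = lexicographically smallest
  list(posterior = setNames(post, gts), genotype = gts[k],
       phred = phredFromPosterior(post[[k]]), depth = n)
}

#' Randomly cap the read depth at a position
#'
#' If more than \code{maxDepth} reads cover a position, a uniform random
#' subset of size \code{maxDepth} is chosen without replacement (read
#' order preserved); otherwise the input is returned unchanged.
#' Deterministic for a fixed seed.
#'
#' @param x a vector of per-read observations, a data.frame with one row
#'   per read, or a list of equal-length per-read vectors.
#' @param maxDepth maximum number of reads to keep (>= 1).
#' @param seed optional integer seed for the subsampling; when NULL the
#'   current RNG stream is used.
#' @return object of the same shape as \code{x}, reduced to at most
#'   \code{maxDepth} reads.
#' @export
capDepth <- function(x, maxDepth, seed = NULL) {
  if (maxDepth < 1) stop("maxDepth must be >= 1")
  n <- if (is.data.frame(x)) nrow(x) else if (is.list(x)) length(x[[1]]) else
    length(x)
  if (n <= maxDepth) return(x)
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(n, maxDepth))
  if (is.data.frame(x)) x[keep, , drop = FALSE]
  else if (is.list(x)) lapply(x, `[`, keep)
  else x[keep]
}
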