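## Quality handling and the substitution / damage matrices P(R|S).

#' Convert a Phred score to an error probability
#'
#' Implements the Phred relation e = 10^(-Q/10), capped at \code{cap}
#' (default 0.75). The cap handles Q = 0, whose nominal error probability 1
#' would make a read anti-informative; at e = 0.75 the base-call
#' distribution is flat, i.e. the read carries no information at that base.
#'
#' @param score integer Phred score(s), must be non-negative. A negative
#'   score indicates a wrong ASCII offset upstream and is an error.
#' @param cap maximum error probability (default 0.75).
#' @return numeric vector of error probabilities, monotone non-increasing
#'   in \code{score}.
#' @examples
#' phredToErrorProb(40)   # 1e-4
#' phredToErrorProb(0)    # 0.75 (capped)
#' @export
phredToErrorProb <- function(score, cap = 0.75) {
  if (any(score < 0))
    stop("negative Phred score: check the quality ASCII offset")
  pmin(10^(-score / 10), cap)
}

#' Effective quality of a read observation
#'
#' The model weighs each read by the smaller of its base quality and its
#' mapping quality, so an uncertain alignment caps the trust in a
#' confidently sequenced base and vice versa.
#'
#' @param readQ,mapQ non-negative integer Phred scores (vectorised).
#' @return pmin(readQ, mapQ).
#' @export
effectiveQuality <- function(readQ, mapQ) {
  if (any(readQ < 0) || any(mapQ < 0))
    stop("quality scores must be non-negative")
  pmin(readQ, mapQ)
}

#' Base-call distribution P(R | I) for one read base
#'
#' Under a flat prior over the four nucleotides, the distribution over the
#' true read base given the observed call and its error probability e puts
#' mass 1 - e on the called base and e/3 on each alternative.
#'
#' @param calledBase one of "A","C","G","T" (or its integer code 1..4).
#' @param errorProb error probability in [0, 0.75].
#' @return named length-4 probability vector over A,C,G,T.
#' @examples
#' baseCallDistribution("A", 0)       # (1,0,0,0)
#' baseCallDistribution("C", 0.75)    # flat
#' @export
baseCallDistribution <- function(calledBase, errorProb) {
  b <- if (is.character(calledBase)) match(calledBase, BASES) else
    as.integer(calledBase)
  if (is.na(b) || b < 1L || b > 4L)
    stop("calledBase must be one of A, C, G, T")
  if (errorProb < 0 || errorProb > 0.75)
    stop("errorProb must lie in [0, 0.75]")
  p <- rep(errorProb / 3, 4)
  p[b] <- 1 - errorProb
  setNames(p, BASES)
}

## Complement partner (the rarest substitution target) for each base:
## A->T, C->G, G->C, T->A, per the observed mismatch pattern where the
## smallest off-diagonal probability pairs each base with its complement.
.COMPLEMENT <- c(4L, 3L, 2L, 1L)

#' Structured substitution-error matrix
#'
#' Builds the 4x4 error matrix P(R|S) with total off-diagonal mass tau per
#' row, structured so the rarest substitution (each base to its
#' complement: A->T, C->G, G->C, T->A) carries exactly 1/3 of the mass of
#' each of the two common substitutions. Solving 2x + x/3 = tau gives the
#' two common entries 3*tau/7 and the rare entry tau/7.
#'
#' @param tau error rate in [0, 1); default 0.002 (0.2\%).
#' @return a [SubstitutionMatrix-class] object.
#' @examples
#' errorMatrix(0)       # identity
#' errorMatrix(0.002)
#' @export
errorMatrix <- function(tau = 0.002) {
  if (tau < 0 || tau >= 1) stop("tau must lie in [0, 1)")
  m <- matrix(3 * tau / 7, 4, 4, dimnames = list(S = BASES, R = BASES))
  for (s in 1:4) {
    m[s, .COMPLEMENT[s]] <- tau / 7
    m[s, s] <- 1 - tau
  }
  new("SubstitutionMatrix", probs = m, tau = tau, delta = 0)
}

#' Ancient-DNA damage matrix
#'
#' Post-mortem deamination converts cytosine to uracil, read as thymine:
#' an excess of C-to-T mismatches and, on the opposite strand, of G-to-A
#' mismatches. Starting from [errorMatrix()] with rate \code{tau}, an
#' overall expected damage rate \code{delta} is moved from the diagonal:
#' P(R=T|S=C) and P(R=A|S=G) each gain delta at the expense of the
#' matching diagonal entry. Default delta = 0.03 (3\%).
#'
#' @param tau error rate in [0, 1).
#' @param delta damage rate in [0, 1); tau + delta must be < 1.
#' @return a [SubstitutionMatrix-class] object.
#' @export
damageMatrix <- function(tau = 0.002, delta = 0.03) {
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)")
  if (tau + delta >= 1)
    stop("tau + delta must be < 1 (diagonal would go non-positive)")
  sm <- errorMatrix(tau)
  m <- sm@probs
  m["C", "T"] <- m["C", "T"] + delta
  m["C", "C"] <- m["C", "C"] - delta
  m["G", "A"] <- m["G", "A"] + delta
  m["G", "G"] <- m["G", "G"] - delta
  new("SubstitutionMatrix", probs = m, tau = tau, delta = delta)
}

#' Per-read likelihood contribution P(observation | S)
#'
#' Folds the substitution matrix into a base-call distribution:
#' L[s] = sum_r P(R=r|S=s) P(R=r|I), the likelihood of the observation for
#' each possible sampled base s (up to a constant). With tau = delta = 0
#' the matrix is the identity and the reported qualities are trusted
#' completely: L equals the raw base-call distribution.
#'
#' @param sub a [SubstitutionMatrix-class].
#' @param call length-4 base-call distribution (see
#'   [baseCallDistribution()]).
#' @return named length-4 numeric vector over sampled bases A,C,G,T.
#' @export
readLikelihood <- function(sub, call) {
  stopifnot(is(sub, "SubstitutionMatrix"), length(call) == 4L)
  setNames(as.vector(sub@probs %*% call), BASES)
}

#' Write a substitution matrix to a plain-text file
#'
#' Four tab-separated rows (A, C, G, T order) with 12 significant digits,
#' preceded by comment lines recording tau and delta. Files in this format
#' can be read back with [readSubstitutionMatrix()], allowing novel error
#' models to replace the built-ins.
#'
#' @param sub a [SubstitutionMatrix-class].
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeSubstitutionMatrix <- function(sub, file) {
  stopifnot(is(sub, "SubstitutionMatrix"))
  lines <- c(sprintf("# substitution matrix P(R|S), rows/cols A C G T"),
             sprintf("# tau=%g delta=%g", sub@tau, sub@delta),
             apply(sub@probs, 1, function(r)
               paste(sprintf("%.12g", r), collapse = "\t")))
  writeLines(lines, file)
  invisible(file)
}

#' Read a substitution matrix from a plain-text file
#'
#' @param file path to a file written by [writeSubstitutionMatrix()] or in
#'   the same format (comment lines starting with '#' ignored; four rows
#'   of four probabilities, rows A,C,G,T).
#' @return a [SubstitutionMatrix-class]; tau/delta recovered from the
#'   header comments when present, else NA-free defaults of 0.
#' @export
readSubstitutionMatrix <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) != 4L)
    stop("expected exactly 4 matrix rows in ", file)
  m <- do.call(rbind, lapply(body, function(l) {
    v <- strsplit(trimws(l), "[\t ]+")[[1]]
    as.numeric(v[nzchar(v)])
  }))
  if (!identical(dim(m), c(4L, 4L)) || anyNA(m))
    stop("malformed matrix file: ", file)
  dimnames(m) <- list(S = BASES, R = BASES)
  td <- regmatches(hdr, regexec("tau=([0-9.eE+-]+) delta=([0-9.eE+-]+)", hdr))
  td <- Filter(function(x) length(x) == 3L, td)
  tau <- if (length(td)) as.numeric(td[[1]][2]) else 0
  delta <- if (length(td)) as.numeric(td[[1]][3]) else 0
  new("SubstitutionMatrix", probs = m, tau = tau, delta = delta)
}
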