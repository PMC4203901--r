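# Brute-force oracle: the genotype posterior computed by enumerating the
# FULL joint P(H, G, S_1..n, R_1..n) state by state and summing out
# everything but G. Independent of the package's factorised
# marginalisation; priors and sampling distributions are rebuilt here
# from first principles (the quadratic root numerically, by uniroot).

.oracleBases <- c("A", "C", "G", "T")
.oracleDipGts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

oracleAltProb <- function(snpRate) {
  if (snpRate == 0) return(0)
  stats::uniroot(function(p) 3 * p * (1 - p) + 6 * p^2 - snpRate,
                 c(0, 0.5), tol = 1e-15)$root
}

oracleGtPrior <- function(ploidy, snpRate) {
  if (ploidy == "haploid") {
    m <- matrix(snpRate / 3, 4, 4,
                dimnames = list(.oracleBases, .oracleBases))
    diag(m) <- 1 - snpRate
    return(m)
  }
  p <- oracleAltProb(snpRate)
  m <- matrix(NA_real_, 4, 10, dimnames = list(.oracleBases, .oracleDipGts))
  for (h in 1:4) for (g in 1:10) {
    al <- strsplit(.oracleDipGts[g], "")[[1]]
    nAlt <- sum(al != .oracleBases[h])
    m[h, g] <- if (nAlt == 0) 1 - snpRate else if (nAlt == 1) p * (1 - p)
      else p^2
  }
  m
}

oracleSampleProb <- function(gt, s) {
  al <- strsplit(gt, "")[[1]]
  mean(al == .oracleBases[s])
}

# bases: integer codes 1..4; subProbs: 4x4 matrix P(R|S); cap as in the
# package. refMode "observed" needs refBase (code 1..4); "flat" is 0.25.
oraclePosterior <- function(bases, quals, mapqs, ploidy, snpRate, subProbs,
                            refMode = "flat", refBase = NA_integer_,
                            cap = 0.75) {
  gts <- if (ploidy == "haploid") .oracleBases else .oracleDipGts
  nG <- length(gts)
  n <- length(bases)
  stopifnot(n <= 4)   # 4^(2n) joint read states: keep enumeration tractable
  refP <- if (refMode == "observed") replace(numeric(4), refBase, 1) else
    rep(0.25, 4)
  gtP <- oracleGtPrior(ploidy, snpRate)
  e <- pmin(10^(-pmin(quals, mapqs) / 10), cap)
  callP <- lapply(seq_len(n), function(i) {
    v <- rep(e[i] / 3, 4); v[bases[i]] <- 1 - e[i]; v
  })
  sampP <- matrix(NA_real_, nG, 4)
  for (g in seq_len(nG)) for (s in 1:4)
    sampP[g, s] <- oracleSampleProb(gts[g], s)

  vars <- c(list(h = 1:4, g = seq_len(nG)),
            stats::setNames(rep(list(1:4), 2 * n),
                            c(if (n) paste0("s", 1:n), if (n) paste0("r", 1:n))))
  grid <- do.call(expand.grid, vars)
  w <- refP[grid$h] * gtP[cbind(grid$h, grid$g)]
  for (i in seq_len(n)) {
    si <- grid[[paste0("s", i)]]
    ri <- grid[[paste0("r", i)]]
    w <- w * sampP[cbind(grid$g, si)] * subProbs[cbind(si, ri)] *
      callP[[i]][ri]
  }
  post <- tapply(w, grid$g, sum)
  post <- post / sum(post)
  stats::setNames(as.numeric(post), gts)
}
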