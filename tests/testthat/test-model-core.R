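test_that("Hardy-Weinberg allele probability solves 3p + 3p^2 = mu", {
  expect_equal(solveAltAlleleProb(0), 0)
  # default SNP rate 0.1% gives p = 0.0333% (three significant figures)
  expect_equal(signif(solveAltAlleleProb(0.001) * 100, 3), 0.0333)
  # substituting the root back recovers the SNP rate
  p <- solveAltAlleleProb(0.01)
  expect_equal(3 * p + 3 * p^2, 0.01, tolerance = 1e-12)
  expect_equal(p, oracleAltProb(0.01), tolerance = 1e-12)
  expect_error(solveAltAlleleProb(1), "\\[0, 1\\)")
})

test_that("genotype priors have the stated structure and are stochastic", {
  hp <- genotypePrior("haploid", 0.001)
  expect_equal(unname(probs(hp)[1, ]),
               c(0.999, 0.001 / 3, 0.001 / 3, 0.001 / 3))
  dp0 <- genotypePrior("diploid", 0)
  for (h in 1:4)
    expect_equal(unname(probs(dp0)[h, ]),
                 as.numeric(DIPLOID_GENOTYPES == strrep(BASES[h], 2)))
  dp <- genotypePrior("diploid", 0.001)
  p <- altAlleleProb(dp)
  rowA <- probs(dp)["A", ]
  expect_equal(unname(rowA["AA"]), 1 - 0.001, tolerance = 1e-12)
  expect_equal(unname(rowA[c("AC", "AG", "AT")]), rep(p * (1 - p), 3),
               tolerance = 1e-12)
  expect_equal(unname(rowA[c("CC", "CG", "CT", "GG", "GT", "TT")]),
               rep(p^2, 6), tolerance = 1e-12)
  for (mu in c(0, 1e-4, 0.001, 0.05, 0.3)) {
    expect_equal(unname(rowSums(probs(genotypePrior("haploid", mu)))),
                 rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(rowSums(probs(genotypePrior("diploid", mu)))),
                 rep(1, 4), tolerance = 1e-12)
  }
})

test_that("sampled-allele distribution is identity / 50-50", {
  expect_equal(unname(sampleDistribution("AA")), c(1, 0, 0, 0))
  expect_equal(unname(sampleDistribution("AC")), c(0.5, 0.5, 0, 0))
  expect_equal(unname(sampleDistribution("T")), c(0, 0, 0, 1))
  expect_equal(unname(sampleDistribution("GT")), c(0, 0, 0.5, 0.5))
  expect_error(sampleDistribution("AX"), "unknown")
})

test_that("zero reads return the genotype prior exactly", {
  for (pl in c("haploid", "diploid")) {
    gp <- genotypePrior(pl, 0.001)
    # observed reference
    r <- genotypePosterior(integer(0), integer(0), integer(0), gp,
                           referencePrior("observed"), refBase = "C")
    expect_equal(unname(r$posterior), unname(probs(gp)["C", ]))
    # flat reference marginalises H into the prior
    r2 <- genotypePosterior(integer(0), integer(0), integer(0), gp,
                            referencePrior("flat"))
    expect_equal(unname(r2$posterior),
                 unname(as.vector(rep(0.25, 4) %*% probs(gp))))
    expect_equal(r$depth, 0)
  }
})

test_that("posterior matches full-joint enumeration on spec'd cases", {
  # haploid, tau = delta = 0, observed ref A, one read A at Q20
  gp <- genotypePrior("haploid", 0.001)
  r <- genotypePosterior("A", 20L, 60L, gp, referencePrior("observed"),
                         refBase = "A", sub = errorMatrix(0))
  orc <- oraclePosterior(1L, 20L, 60L, "haploid", 0.001, diag(4),
                         refMode = "observed", refBase = 1L)
  expect_equal(unname(r$posterior), unname(orc), tolerance = 1e-12)
  expect_identical(r$genotype, "A")
  # diploid, reads A and C at Q40, flat reference, defaults. At the
  # default SNP rate the heterozygote prior p(1-p) is so small that two
  # reads cannot overcome it: the MAP stays homozygous and only deeper
  # balanced coverage flips it to AC. Both regimes must match the oracle.
  gpd <- genotypePrior("diploid", 0.001)
  sub <- errorMatrix(0.002)
  r2 <- genotypePosterior(c("A", "C"), c(40L, 40L), c(60L, 60L), gpd,
                          referencePrior("flat"), sub = sub)
  orc2 <- oraclePosterior(c(1L, 2L), c(40L, 40L), c(60L, 60L), "diploid",
                          0.001, probs(sub))
  expect_equal(unname(r2$posterior), unname(orc2), tolerance = 1e-12)
  expect_identical(r2$genotype, names(which.max(orc2)))
  r3 <- genotypePosterior(rep(c("A", "C"), 2), rep(40L, 4), rep(60L, 4),
                          gpd, referencePrior("flat"), sub = sub)
  orc3 <- oraclePosterior(rep(c(1L, 2L), 2), rep(40L, 4), rep(60L, 4),
                          "diploid", 0.001, probs(sub))
  expect_equal(unname(r3$posterior), unname(orc3), tolerance = 1e-12)
  expect_identical(r3$genotype, "AC")
})

test_that("posterior normalises and is prior-dominated at tiny SNP rates", {
  set.seed(19)
  for (k in 1:200) {
    pl <- sample(c("haploid", "diploid"), 1)
    n <- sample(0:6, 1)
    gp <- genotypePrior(pl, runif(1, 0, 0.1))
    r <- genotypePosterior(sample(1:4, n, TRUE), sample(0:60, n, TRUE),
                           sample(0:60, n, TRUE), gp,
                           sub = damageMatrix(runif(1, 0, 0.1),
                                              runif(1, 0, 0.1)))
    expect_equal(sum(r$posterior), 1, tolerance = 1e-9)
  }
  # one read of quality <= 40 never overturns an almost-certain prior
  gp <- genotypePrior("diploid", 1e-6)
  gph <- genotypePrior("haploid", 1e-6)
  for (ref in BASES) for (b in BASES) for (q in c(0L, 10L, 20L, 40L)) {
    r <- genotypePosterior(b, q, 60L, gp, referencePrior("observed"),
                           refBase = ref)
    expect_identical(r$genotype, strrep(ref, 2))
    rh <- genotypePosterior(b, q, 60L, gph, referencePrior("observed"),
                            refBase = ref)
    expect_identical(rh$genotype, ref)
  }
})

test_that("adding a concordant read never lowers the supported genotype", {
  set.seed(5)
  for (k in 1:50) {
    pl <- sample(c("haploid", "diploid"), 1)
    gp <- genotypePrior(pl, 0.001)
    b <- sample(1:4, 1); q <- sample(5:60, 1)
    gt <- if (pl == "haploid") BASES[b] else strrep(BASES[b], 2)
    n0 <- sample(0:5, 1)
    bases <- rep(b, n0)
    prev <- -Inf
    for (n in n0:(n0 + 4)) {
      r <- genotypePosterior(rep(b, n), rep(q, n), rep(60L, n), gp)
      expect_gte(r$posterior[[gt]], prev - 1e-12)
      prev <- r$posterior[[gt]]
    }
  }
})

test_that("relabelling the bases permutes the posterior consistently", {
  set.seed(23)
  perms <- list(c(2L, 1L, 4L, 3L), c(3L, 4L, 1L, 2L), c(4L, 1L, 2L, 3L))
  for (perm in perms) for (k in 1:5) {
    n <- sample(1:4, 1)
    bases <- sample(1:4, n, TRUE); q <- sample(10:50, n, TRUE)
    tau <- runif(1, 0, 0.2)
    A <- matrix(runif(16), 4, 4); A <- A / rowSums(A)
    subA <- new("SubstitutionMatrix", probs = A, tau = tau, delta = 0)
    Ap <- A                                   # P A P^T

    for (s in 1:4) for (r in 1:4) Ap[perm[s], perm[r]] <- A[s, r]
    subP <- new("SubstitutionMatrix", probs = Ap, tau = tau, delta = 0)
    gp <- genotypePrior("haploid", 0.01)
    ref <- sample(1:4, 1)
    r1 <- genotypePosterior(bases, q, rep(60L, n), gp,
                            referencePrior("observed"), BASES[ref],
                            sub = subA)
    r2 <- genotypePosterior(perm[bases], q, rep(60L, n), gp,
                            referencePrior("observed"), BASES[perm[ref]],
                            sub = subP)
    expect_equal(unname(r2$posterior[perm]), unname(r1$posterior),
                 tolerance = 1e-12)
  }
})

test_that("depth capping is a seeded uniform subset that preserves order", {
  obs <- data.frame(base = 1:5, q = 11:15)
  expect_identical(capDepth(obs, 10), obs)            # under the cap
  big <- data.frame(base = rep(1:4, 15), q = seq_len(60))
  s1 <- capDepth(big, 5, seed = 99)
  s2 <- capDepth(big, 5, seed = 99)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 5L)
  expect_true(all(diff(s1$q) > 0))                    # original order kept
  expect_identical(capDepth(big, 60, seed = 1), big)  # cap at n keeps all
  lst <- list(b = 1:20, q = 21:40)
  c1 <- capDepth(lst, 7, seed = 3)
  expect_identical(lengths(c1), c(b = 7L, q = 7L))
  expect_identical(c1$q - c1$b, rep(20L, 7))          # alignment preserved
  expect_error(capDepth(lst, 0), "maxDepth")
})

test_that("posterior Phred scaling caps at 9999", {
  expect_equal(phredFromPosterior(0.999), -10 * log10(0.001))
  expect_equal(phredFromPosterior(1), 9999)
  expect_equal(phredFromPosterior(0), 0)
})
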