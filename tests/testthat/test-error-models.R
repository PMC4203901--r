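test_that("Phred conversion follows the Phred definition with a cap", {
  expect_equal(phredToErrorProb(40), 1e-4)
  expect_equal(phredToErrorProb(30), 1e-3)  # the QC threshold: error < 1e-3
  expect_equal(phredToErrorProb(0), 0.75)   # capped from 1.0
  e <- phredToErrorProb(0:93)
  expect_true(all(diff(e) <= 0))            # monotone non-increasing
  expect_error(phredToErrorProb(-1), "offset")
})

test_that("effective quality is the per-read minimum of base and mapping quality", {
  expect_identical(effectiveQuality(40, 25), 25)
  expect_identical(effectiveQuality(10, 10), 10)
  expect_identical(effectiveQuality(0, 60), 0)
  expect_identical(effectiveQuality(c(40, 5), c(20, 50)), c(20, 5))
  expect_error(effectiveQuality(-1, 10), "non-negative")
})

test_that("base-call distribution puts 1-e on the call and e/3 elsewhere", {
  expect_equal(unname(baseCallDistribution("A", 0)), c(1, 0, 0, 0))
  expect_equal(unname(baseCallDistribution("C", 0.75)), rep(0.25, 4))
  expect_equal(unname(baseCallDistribution("G", 1e-3)),
               c(1e-3 / 3, 1e-3 / 3, 1 - 1e-3, 1e-3 / 3))
  expect_error(baseCallDistribution("N", 0.1), "A, C, G, T")
  expect_error(baseCallDistribution("A", 0.8), "0, 0.75")
  # called base always carries at least as much mass as any alternative
  for (e in seq(0, 0.75, by = 0.05)) {
    d <- baseCallDistribution("T", e)
    expect_true(all(d["T"] >= d))
  }
})

test_that("error matrix has the 3:3:1 off-diagonal structure with mass tau", {
  expect_equal(probs(errorMatrix(0)), diag(4),
               ignore_attr = TRUE)
  m <- probs(errorMatrix(0.002))
  expect_equal(unname(m[1, ]), c(0.998, 3 * 0.002 / 7, 3 * 0.002 / 7,
                                 0.002 / 7))
  # the common off-diagonal entry solves 2x + x/3 = tau; check against an
  # independent numeric root
  x <- uniroot(function(x) 2 * x + x / 3 - 0.002, c(0, 1), tol = 1e-15)$root
  expect_equal(m[1, 2], x, tolerance = 1e-12)
  expect_equal(m[1, 4], x / 3, tolerance = 1e-12)
  # complement pairing: rarest targets are A->T, C->G, G->C, T->A
  for (s in 1:4) {
    off <- m[s, -s]
    expect_equal(unname(min(off) / max(off)), 1 / 3)
    expect_equal(unname(which.min(m[s, setdiff(1:4, s)])),
                 which(setdiff(1:4, s) == c(4, 3, 2, 1)[s]))
  }
  expect_error(errorMatrix(1), "\\[0, 1\\)")
})

test_that("substitution matrices are row-stochastic across random rates", {
  set.seed(42)
  for (k in 1:50) {
    tau <- runif(1, 0, 0.5)
    delta <- runif(1, 0, 0.5)
    expect_equal(rowSums(probs(errorMatrix(tau))), c(A = 1, C = 1, G = 1, T = 1),
                 tolerance = 1e-12)
    expect_equal(rowSums(probs(damageMatrix(tau, delta))),
                 c(A = 1, C = 1, G = 1, T = 1), tolerance = 1e-12)
    off <- probs(errorMatrix(tau)); diag(off) <- NA
    expect_equal(min(off, na.rm = TRUE) / max(off, na.rm = TRUE), 1 / 3)
  }
})

test_that("damage matrix adds delta to C->T and G->A only", {
  expect_equal(probs(damageMatrix(0.002, 0)), probs(errorMatrix(0.002)))
  m <- probs(damageMatrix(0, 0.03))
  expect_equal(unname(m["C", ]), c(0, 0.97, 0, 0.03))
  expect_equal(unname(m["G", ]), c(0.03, 0, 0.97, 0))
  expect_equal(unname(m["A", ]), c(1, 0, 0, 0))
  expect_equal(unname(m["T", ]), c(0, 0, 0, 1))
  md <- probs(damageMatrix(0.002, 0.03))
  me <- probs(errorMatrix(0.002))
  expect_equal(md["C", "T"] - me["C", "T"], 0.03)
  expect_equal(md["G", "A"] - me["G", "A"], 0.03)
  expect_equal(md[c(1, 4), ], me[c(1, 4), ])
  expect_error(damageMatrix(0.5, 0.5), "tau \\+ delta")
})

test_that("read likelihood equals explicit double-sum enumeration", {
  # identity matrix passes the call through; flat call is uninformative
  callA <- baseCallDistribution("A", 1e-4)
  expect_equal(readLikelihood(errorMatrix(0), callA), callA,
               ignore_attr = TRUE)
  sub <- damageMatrix(0.01, 0.1)
  expect_equal(unname(readLikelihood(sub, rep(0.25, 4))), rep(0.25, 4))
  set.seed(7)
  for (k in 1:1000) {
    sub <- damageMatrix(runif(1, 0, 0.3), runif(1, 0, 0.3))
    call <- baseCallDistribution(sample(BASES, 1), runif(1, 0, 0.75))
    L <- readLikelihood(sub, call)
    brute <- numeric(4)
    for (s in 1:4) for (r in 1:4)
      brute[s] <- brute[s] + probs(sub)[s, r] * call[r]
    expect_equal(unname(L), brute, tolerance = 1e-14)
  }
})

test_that("tau = delta = 0 trusts the reported qualities completely", {
  sub <- errorMatrix(0)
  for (b in BASES) {
    call <- baseCallDistribution(b, 0.01)
    expect_equal(readLikelihood(sub, call), call, ignore_attr = TRUE)
  }
})

test_that("matrix files round-trip through the plain-text format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  sub <- damageMatrix(0.002, 0.03)
  writeSubstitutionMatrix(sub, f)
  back <- readSubstitutionMatrix(f)
  expect_equal(probs(back), probs(sub), tolerance = 1e-11)
  expect_equal(tau(back), 0.002)
  expect_equal(delta(back), 0.03)
  expect_error(readSubstitutionMatrix(
    withr::local_tempfile(lines = c("1 0 0 0", "0 1 0 0"))), "4 matrix rows")
})
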