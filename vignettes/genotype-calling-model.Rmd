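---
title: "A generative model for genotype calling from pileup data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generative model for genotype calling from pileup data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pileupCall)
```

## The model

pileupCall infers the genotype at each genomic position from the stack of
sequencing reads covering it, using a generative graphical model of the
whole path from the sample's DNA to the base caller's output. At one
position with $n$ covering reads the joint distribution factorises as

$$
P(H, G, S, R, I) \;=\; P(H)\, P(G \mid H) \prod_{i=1}^{n}
P(S_i \mid G)\, P(R_i \mid S_i)\, P(I_i \mid R_i),
$$

where $H$ is the reference base, $G$ the genotype of the sequenced
individual, and, per read $i$, $S_i$ the allele actually sampled from the
genome, $R_i$ the base present in the sequenced fragment, and $I_i$ the
base-caller's observation. The genotype posterior $P(G \mid I, H)$ is
obtained exactly by summing out $S$ and $R$ — read by read, since the
reads are conditionally independent given $G$ — and normalising. The
call is the MAP genotype, and its confidence is reported on the Phred
scale as $-10\log_{10}(1 - P(G_{\mathrm{MAP}} \mid I, H))$.

The five factors are:

* **Reference prior $P(H)$** — flat over `A,C,G,T` by default; in
  "observed" mode the base in the reference genome is used as a point
  mass (selectable per run); a custom distribution may be supplied.
* **Genotype prior $P(G \mid H)$** — built from an expected SNP rate
  $\mu$ (default 0.1%). Haploid: $1-\mu$ on the reference base, $\mu/3$
  on each alternative. Diploid (10 unordered genotypes): $1-\mu$ on the
  homozygous-reference genotype and, under Hardy–Weinberg equilibrium
  with alternative-allele probability $p$, mass $p(1-p)$ on each of the
  three heterozygotes carrying the reference allele and $p^2$ on each of
  the six remaining genotypes. Setting $3p(1-p) + 6p^2 = \mu$ and
  solving the quadratic gives $p$; at $\mu = 0.001$, $p = 0.0333\%$.
* **Sampling $P(S_i \mid G)$** — identity for haploid genomes; for
  diploid genotypes, 100% on the allele of a homozygote and 50%/50% for
  a heterozygote.
* **Substitution errors $P(R_i \mid S_i)$** — a 4×4 row-stochastic
  matrix with total off-diagonal mass $\tau$ per row (default 0.2%).
  Empirically the substitution spectrum is structured: each base's
  rarest read target is its complement (A→T, C→G, G→C, T→A) at a third
  of the probability of the two common targets, which gives off-diagonal
  entries $3\tau/7, 3\tau/7, \tau/7$. The ancient-DNA damage model adds
  a deamination rate $\delta$ (default 3%) to $P(R{=}T \mid S{=}C)$ and
  $P(R{=}A \mid S{=}G)$ at the expense of the matching diagonal —
  post-mortem cytosine deamination is read as thymine, and as adenine on
  the opposite strand.
* **Base calling $P(I_i \mid R_i)$** — not modelled directly; under a
  flat prior over bases it is proportional to $P(R_i \mid I_i)$, which
  the Phred quality string supplies: error probability
  $e = 10^{-Q/10}$, so mass $1-e$ on the called base and $e/3$ on each
  alternative. The effective $Q$ per read is the *minimum* of the base
  quality and the mapping quality, so neither an untrustworthy base nor
  an untrustworthy alignment can dominate a call.

With $\tau = \delta = 0$ the substitution matrix is the identity and the
reported qualities are trusted completely.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `snpRate` | expected SNP rate $\mu$ | 0.001 | drives both priors |
| `tau` | substitution error rate | 0.002 | off-diagonal row mass |
| `delta` | deamination damage rate | 0 (damage model: 0.03) | C→T / G→A excess |
| `useReference` | observed vs flat $P(H)$ | per run | biases towards ref |
| `maxDepth` | depth cap per position | 60 | seeded downsampling |
| `cap` | max per-base error probability | 0.75 | see below |
| `qualityOffset` | ASCII offset $\Delta$ | 33 | 64 selectable |
| `minPhred` / `minSupport` | QC filter | 30 / 10 | strict ">30" |

## Numerical choices

* All per-position work is done in natural-log space with a
  log-sum-exp normalisation: a product over 60 reads of probabilities
  around $10^{-4}$ underflows in linear space.
* Phred 0 nominally means error probability 1, which would make a read
  *anti*-informative (its called base the least likely). Error
  probabilities are therefore capped at 0.75, where the base-call
  distribution is flat and the read simply carries no information. The
  cap also guarantees the all-zero-likelihood failure mode cannot occur.
* MAP ties break towards the lexicographically smallest genotype
  string; determinism matters more than any particular choice.
* The Phred-scaled confidence is $-10\log_{10}(1-p_{\mathrm{MAP}})$,
  capped at 9999 once $p_{\mathrm{MAP}}$ rounds to 1 in double
  precision. (An alternative would be the posterior of the runner-up
  genotype; the two agree except at the cap.)
* Zero-depth positions would return the prior and always fail QC; since
  the pileup input only contains covered positions, they are simply
  never emitted.
* In flat-reference mode $H$ is marginalised into the genotype prior
  once per run, not per position.
* Whole-pileup calling precomputes the log genotype likelihood for
  every (called base, effective quality) pair — there are only
  $4 \times 94$ — so each column reduces to an indexed row sum. This is
  algebraically identical to the per-position marginalisation (the test
  suite checks both paths against a brute-force enumeration of the full
  joint).

## Filtering and indels

The QC set keeps variant calls with Phred quality strictly above 30
that are supported by at least `minSupport` reads carrying a
non-reference allele of the called genotype. The 10-read default mirrors
standard diploid practice; 5 is a common relaxed setting, and
`minSupport = 1` reduces the filter to the quality-only rule used for
haploid data. Support is counted among the reads actually used, i.e.
after depth capping — the model never saw the discarded reads.

The model itself has no indel channel. `callIndels()` is a deliberately
minimal extension: at each column carrying indel records, the most
frequent indel allele is genotyped against the reference allele with a
two-allele version of the diploid machinery — per-read correctness from
the effective quality, prior mass $(1-\mu,\, p(1-p),\, p^2)$
renormalised over {hom-ref, het, hom-indel} — and the same QC policy is
applied. It should be read as a pragmatic screen, not a calibrated indel
caller.

## The simulator

`simulateGenome()` / `simulateReads()` / `simulatePileup()` generate
fully self-contained test data: a random reference with configurable GC
content, planted SNPs (diploid SNPs heterozygous with probability
`hetFraction`, default 5/9 so that planted hom:het ≈ 0.8), uniform read
starts and strands, and a linear Phred profile along the read emulating
the 3' signal decay of short-read sequencers. Deamination damage is
applied to the template *before* sequencing error, with per-base
probability $d_{\max} e^{-\lambda j}$ at distance $j$ from the 5' end
for C→T and mirrored from the 3' end for G→A, strand-aware; the quality
string knows nothing about it — exactly the failure mode the damage
model addresses. The defaults $(d_{\max}, \lambda) = (0.3, 0.3)$ give a
pronounced terminal C→T excess decaying within ~15 bp, qualitatively
matching published ancient-DNA damage profiles. Reads are placed
perfectly (the pileup is emitted directly), so the genotyper is tested
in isolation from any mapper.

What the simulator does *not* emulate: indel errors, coverage biases
(GC, mappability), PCR duplicates, mapping errors and paired-end
structure. Passing the simulation-based checks therefore demonstrates
correct inference under the model's own assumptions, not performance on
real libraries.

A single integer seed drives genome construction, read sampling, damage,
sequencing error and depth capping; all outputs are byte-identical for a
fixed seed.

## Scale of the built-in analyses

The test suite runs three end-to-end experiments on 100 kb genomes with
36 bp reads: a clean haploid run at 27× (no QC SNPs expected at depth
caps 10/20/60), an ancient-DNA haploid run at 5× comparing the standard
and damage models (the damage model must strictly reduce QC false
SNPs), and a diploid run at 30× with $\mu = 0.001$ (genotype concordance
at truth sites ≥ 99%, recovered hom:het within ±0.15 of planted). These
sizes keep each experiment in the tens of seconds while leaving expected
counts (~100 planted SNPs; thousands of damaged positions) large enough
for stable comparisons.

## Worked example

```{r example}
cfg <- simConfig(genomeLength = 20000L, meanDepth = 30, seed = 42,
                 ploidy = "diploid", snpRate = 0.001)
genome <- simulateGenome(cfg)
reads  <- simulateReads(genome, cfg)
pileup <- readPileup(text = simulatePileup(genome, reads, cfg))
calls  <- callGenotypes(pileup, ploidy = "diploid", useReference = TRUE,
                        seed = 1)
qc <- qcFilter(calls, minPhred = 30, minSupport = 10)
truthEval(callSetFromCalls(qc), truthRecords(genome),
          genotypeCalls = calls)
```

## Known limitations

* No polyploid genotype spaces, multi-sample joint calling or
  haplotype-aware calling.
* Strand is parsed and retained but unused by the model (the
  likelihood is strand-agnostic; damage-by-strand modelling would be a
  natural extension).
* Overlapping mate pairs are not deduplicated — pileup text carries no
  mate identity.
* Transition/transversion-specific error rates are not modelled; a
  user-supplied substitution matrix (see
  `writeSubstitutionMatrix()`/`readSubstitutionMatrix()`) can encode
  them.
* The heterozygote prior follows the $p(1-p)$ parameterisation whose
  closure $3p(1-p)+6p^2=\mu$ reproduces the documented
  $p = 0.0333\%$; with few reads this prior strongly favours homozygous
  calls, which is visible at 2–4× depth.
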