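# pileupCall

Probabilistic genotype and SNP calling from next-generation sequencing
pileup data, for haploid and diploid genomes, with an explicit
ancient-DNA damage model.

Given the reads covering a genomic position — their called bases, base
qualities and mapping qualities, as produced by `samtools mpileup -s` —
pileupCall computes the exact posterior distribution over genotypes
under a generative model

P(H, G, S, R, I) = P(H) · P(G|H) · ∏ᵢ P(Sᵢ|G) · P(Rᵢ|Sᵢ) · P(Iᵢ|Rᵢ)

with H the reference base, G the genotype, and per read i the sampled
allele Sᵢ, the fragment base Rᵢ and the observed call Iᵢ. Qualities
enter through P(Rᵢ|Iᵢ) with error probability 10^(−Q/10), where Q is the
minimum of the base and mapping quality; P(Rᵢ|Sᵢ) is a structured
substitution matrix with error rate τ (default 0.2%) and, optionally, a
cytosine-deamination damage rate δ (default 3%) that absorbs the C→T /
G→A excess of ancient or FFPE DNA instead of mistaking it for variation.
The diploid genotype prior spreads an expected SNP rate μ (default 0.1%)
over the nine non-reference genotypes under Hardy–Weinberg equilibrium;
the implied alternative-allele probability at the default rate is
p = 0.0333%. Calls are reported as VCF with Phred-scaled posteriors, and
a post-hoc filter produces the high-quality (QC) subset (quality > 30,
configurable minimum read support).

The package is aimed at anyone calling variants from pileup text —
particularly for shallow or damaged libraries (ancient DNA, FFPE) where
modelling the damage explicitly makes the difference between a clean and
a false-positive-ridden call set. A seeded simulator (reference, planted
SNPs, reads with quality decay and end-clustered deamination, FASTQ /
truth-VCF / pileup output) makes the whole method testable without any
external data.

## Worked example

Simulate a 20 kb diploid genome at 30×, call genotypes using the
reference as prior, filter, and score against the planted truth:

```r
library(pileupCall)

cfg    <- simConfig(genomeLength = 20000L, meanDepth = 30, seed = 42,
                    ploidy = "diploid", snpRate = 0.001)
genome <- simulateGenome(cfg)
reads  <- simulateReads(genome, cfg)
pileup <- readPileup(text = simulatePileup(genome, reads, cfg))

calls <- callGenotypes(pileup, ploidy = "diploid", useReference = TRUE,
                       seed = 1)
calls
#> GenotypeCalls: 19999 positions, ploidy=diploid
#>   variant calls: 21; median phred: 120.2; mean depth used: 30.0

qc <- qcFilter(calls, minPhred = 30, minSupport = 10)
truthEval(callSetFromCalls(qc), truthRecords(genome),
          genotypeCalls = calls)
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $concordance
#> [1] 1
#> $nTruth
#> [1] 21
#> $nCalled
#> [1] 21
```

All 21 planted SNPs are recovered with the correct genotype and no
false positives. The VCF writer emits one record per covered position
(or variants only), e.g.:

```
sim1  112  .  A  T  9999.00  PASS  DP=27;MQ=60.0  GT:DP:GQ:AD  0/1:27:9999:12,15
sim1  762  .  T  A  43.45    PASS  DP=26;MQ=60.0  GT:DP:GQ:AD  1/1:26:43:0,26
```

A command-line interface covering the same pipeline ships as
`inst/exec/pileupcall` with subcommands `call`, `filter`, `simulate`,
`eval` and `matrix`.

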