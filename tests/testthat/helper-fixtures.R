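# Hand-built GenotypeCalls objects for filter/evaluation tests.

makeCalls <- function(pos, ref, genotype, phred, ploidy = "diploid",
                      altSupport = NULL, depthUsed = NULL,
                      chrom = "chr1", baseTally = NULL) {
  n <- length(pos)
  gts <- if (ploidy == "haploid") BASES else DIPLOID_GENOTYPES
  post <- matrix(0, n, length(gts), dimnames = list(NULL, gts))
  for (i in seq_len(n)) {
    p <- 1 - 10^(-phred[i] / 10)
    post[i, ] <- (1 - p) / (length(gts) - 1)
    post[i, match(genotype[i], gts)] <- p
  }
  if (is.null(depthUsed)) depthUsed <- rep(30L, n)
  if (is.null(altSupport)) altSupport <- rep(15L, n)
  if (is.null(baseTally)) {
    baseTally <- lapply(seq_len(n), function(i) {
      tally <- integer(4)
      al <- unique(strsplit(genotype[i], "")[[1]])
      alt <- setdiff(al, ref[i])
      rc <- match(ref[i], BASES)
      if (!is.na(rc)) tally[rc] <- depthUsed[i] - altSupport[i]
      if (length(alt) > 0)
        tally[match(alt, BASES)] <- rep(altSupport[i] %/% length(alt),
                                        length(alt))
      tally
    })
  }
  new("GenotypeCalls", chrom = rep(chrom, n), pos = as.integer(pos),
      ref = ref, genotype = genotype, phred = as.numeric(phred),
      depthUsed = as.integer(depthUsed), meanMapq = rep(60, n),
      altSupport = as.integer(altSupport), posterior = post,
      baseTally = baseTally, ploidy = ploidy,
      params = list(ploidy = ploidy))
}
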