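# Brute-force per-read counting oracle: enumerates each read's loci,
# applies the mismatch and rRNA filters, and distributes 1/(k*m) weights
# with plain loops and interval comparisons. Deliberately shares no code
# with the package's GRanges-based path.
oracle_quantify <- function(loci, annotation) {
  genes <- annotation$cds
  rr <- annotation$rrna
  counts <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  retained <- 0L
  for (rid in unique(loci$read_id)) {
    L <- loci[loci$read_id == rid, , drop = FALSE]
    keep <- logical(nrow(L))
    for (j in seq_len(nrow(L))) {
      ok <- L$nm[j] == 0
      if (ok && nrow(rr) > 0) {
        for (q in seq_len(nrow(rr))) {
          if (L$replicon[j] == rr$replicon[q] &&
              L$start[j] <= rr$end[q] && L$end[j] >= rr$start[q]) {
            ok <- FALSE
            break
          }
        }
      }
      keep[j] <- ok
    }
    L <- L[keep, , drop = FALSE]
    k <- nrow(L)
    if (k == 0) next
    retained <- retained + 1L
    for (j in seq_len(k)) {
      hit <- which(genes$replicon == L$replicon[j] &
                     genes$start <= L$end[j] & genes$end >= L$start[j])
      m <- length(hit)
      if (m > 0) counts[hit] <- counts[hit] + 1 / (k * m)
    }
  }
  list(counts = counts, retained = retained)
}
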