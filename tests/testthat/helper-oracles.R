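# Independent brute-force oracles used to cross-check the interval engine
# and set partitioning. Deliberately simple O(n*m) computations, kept free
# of the package's own overlap code.

toy_genome <- function(n = 3, len = 1e6) {
  genome_model(paste0("chr", seq_len(n)), rep(len, n))
}

overlaps1 <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

# fraction (%) of reference fragments overlapped by >=1 query fragment
bf_fragment_similarity <- function(query, reference, digits = 1) {
  hit <- vapply(seq_len(nrow(reference)), function(i) {
    any(overlaps1(reference$chrom[i], reference$start[i], reference$end[i],
                  query$chrom, query$start, query$end))
  }, logical(1))
  round(100 * sum(hit) / nrow(reference), digits)
}

# per-reference-fragment bp covered by the union of query fragments
bf_bp_similarity <- function(query, reference, digits = 1) {
  covered <- vapply(seq_len(nrow(reference)), function(i) {
    qs <- pmax(query$start[query$chrom == reference$chrom[i]],
               reference$start[i])
    qe <- pmin(query$end[query$chrom == reference$chrom[i]],
               reference$end[i])
    keep <- qs < qe
    qs <- qs[keep]; qe <- qe[keep]
    if (length(qs) == 0L) return(0)
    o <- order(qs)
    qs <- qs[o]; qe <- qe[o]
    tot <- 0; cur_s <- qs[1]; cur_e <- qe[1]
    for (j in seq_along(qs)[-1]) {
      if (qs[j] <= cur_e) cur_e <- max(cur_e, qe[j])
      else { tot <- tot + cur_e - cur_s; cur_s <- qs[j]; cur_e <- qe[j] }
    }
    tot + cur_e - cur_s
  }, numeric(1))
  round(100 * sum(covered) / sum(reference$end - reference$start), digits)
}

# membership tabulation for 2- or 3-set Venn regions
bf_venn_counts <- function(sets) {
  universe <- unique(unlist(sets))
  patterns <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(patterns)
}

random_fragments <- function(genome, n, max_len = 5000) {
  idx <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome$length[idx] - len))
  tibble::tibble(chrom = genome$chrom[idx], start = start,
                 end = start + len, fpkm = rlnorm(n, 1, 2),
                 sample = "rand")
}
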