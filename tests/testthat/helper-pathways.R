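# Fixture builders for pathway coverage tests: the five-pathway layout
# (sizes 31/28/76/55/130) and gene sets hitting prescribed per-pathway
# counts.

five_pathways <- function() {
  sizes <- c(TCA = 31, pentose_phosphate = 28,
             oxidative_phosphorylation = 76,
             glycolysis_gluconeogenesis = 55, cell_cycle = 130)
  purrr::map_dfr(names(sizes), function(p) {
    tibble::tibble(pathway = p,
                   gene_id = paste0(p, "_", seq_len(sizes[[p]])))
  })
}

set_with_counts <- function(pw, counts) {
  unlist(lapply(names(counts), function(p) {
    pw$gene_id[pw$pathway == p][seq_len(counts[[p]])]
  }), use.names = FALSE)
}
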