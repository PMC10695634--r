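# Comparative engine: interval overlap between fragment sets and the three
# similarity metrics used to compare secreted exDNA against a reference
# fragment set (typically eccDNA): overlapping-fragment count, shared bp,
# and shared genes. All metrics are reference-normalized and strand-blind;
# the overlap predicate is >= 1 shared bp on the same chromosome.

# Internal: tibble (0-based half-open) -> GRanges (1-based closed).
fragments_to_granges <- function(fragments) {
  GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1,
                              end = fragments$end)
  )
}

#' Build an interval index over a fragment set
#'
#' Wraps the fragments in a `GRanges` container supporting fast overlap
#' queries; results are identical to a linear scan.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`, ...).
#' @return A `GRanges` object parallel to the input rows.
#' @export
build_index <- function(fragments) {
  fragments_to_granges(fragments)
}

#' Query an interval index
#'
#' @param index A `GRanges` index from [build_index()].
#' @param chrom,start,end Query interval (0-based half-open).
#' @return Integer vector of row indices of fragments overlapping the query
#'   by at least 1 bp.
#' @export
query_index <- function(index, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  S4Vectors::subjectHits(GenomicRanges::findOverlaps(q, index))
}

#' Fragment-based similarity between two fragment sets
#'
#' The percentage of reference fragments overlapped (by at least 1 bp, same
#' chromosome) by at least one query fragment. Directional: the denominator
#' is the reference set size.
#'
#' @param query,reference Fragment tibbles on the same genome.
#' @param digits Decimal places for the percentage (default 1).
#' @return A percentage in `[0, 100]`.
#' @export
fragment_similarity <- function(query, reference, digits = 1) {
  if (nrow(reference) == 0L)
    stop("fragment similarity undefined for an empty reference set")
  if (nrow(query) == 0L) return(0)
  hits <- GenomicRanges::countOverlaps(fragments_to_granges(reference),
                                       fragments_to_granges(query))
  round(100 * sum(hits > 0) / nrow(reference), digits)
}

#' Base-pair similarity between two fragment sets
#'
#' The percentage of total reference length covered by the query footprint.
#' Query fragments are merged (union) before intersection so shared bp are
#' never double counted on the query side; the reference side is not merged,
#' matching a reference-normalized "overlapping bp over total reference
#' length" definition.
#'
#' @inheritParams fragment_similarity
#' @return A percentage in `[0, 100]`.
#' @export
bp_similarity <- function(query, reference, digits = 1) {
  if (nrow(reference) == 0L)
    stop("bp similarity undefined for an empty reference set")
  total_bp <- sum(reference$end - reference$start)
  if (nrow(query) == 0L) return(0)
  ref_gr <- fragments_to_granges(reference)
  qry_gr <- GenomicRanges::reduce(fragments_to_granges(query))
  ov <- GenomicRanges::findOverlaps(ref_gr, qry_gr)
  if (length(ov) == 0L) return(0)
  inter <- GenomicRanges::pintersect(ref_gr[S4Vectors::queryHits(ov)],
                                     qry_gr[S4Vectors::subjectHits(ov)])
  round(100 * sum(GenomicRanges::width(inter)) / total_bp, digits)
}

#' Genes represented in a fragment set
#'
#' A gene counts as represented when at least one fragment overlaps its
#' interval by at least 1 bp (complete or partial overlap both count; a gene
#' merely abutting a fragment under the half-open convention does not).
#'
#' @param fragments Fragment tibble.
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return Character vector of represented gene IDs (sorted).
#' @export
genes_in_set <- function(fragments, genes) {
  if (nrow(fragments) == 0L || nrow(genes) == 0L) return(character())
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::countOverlaps(gene_gr,
                                       fragments_to_granges(fragments))
  sort(genes$gene_id[hits > 0])
}

#' Venn partition of two or three gene-ID sets
#'
#' Exclusive and intersection region counts, plus per-set totals and derived
#' pairwise shares expressed as percentages of either set.
#'
#' @param sets Named list of 2 or 3 character vectors of gene IDs.
#' @return An object of class `venn_partition`: a list with `regions` (tibble
#'   of region membership pattern and count), `totals` (named totals per
#'   set), and `pairwise` (tibble of pairwise shared counts and percentages
#'   of either set).
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L)
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  pattern_keys <- apply(member, 1L, function(m) paste(names(sets)[m],
                                                      collapse = "&"))
  all_patterns <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&")
  }))
  counts <- vapply(all_patterns, function(p) {
    sum(pattern_keys == p)
  }, numeric(1))
  regions <- tibble::tibble(region = all_patterns, count = unname(counts))
  totals <- vapply(sets, length, numeric(1))
  pairs <- utils::combn(names(sets), 2L)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    shared <- length(intersect(sets[[a]], sets[[b]]))
    tibble::tibble(
      set_a = a, set_b = b, shared = shared,
      pct_of_a = round(100 * shared / max(1L, totals[[a]]), 1),
      pct_of_b = round(100 * shared / max(1L, totals[[b]]), 1)
    )
  })
  structure(list(regions = regions, totals = totals, pairwise = pairwise,
                 union_size = length(universe)),
            class = "venn_partition")
}

#' Full similarity report between two fragment sets
#'
#' Bundles the three similarity metrics — overlapping reference fragments,
#' overlapped reference bp, and shared genes — with raw values and
#' percentages normalized by either side.
#'
#' @param query,reference Fragment tibbles on the same genome.
#' @param genes Optional gene annotation tibble; when supplied, shared gene
#'   counts are included.
#' @return An object of class `similarity_report` (a list), with elements
#'   `query_label`, `reference_label`, `fragments` (counts and percentage),
#'   `bp` (lengths and percentage), and `genes` (shared/percentages, or NULL).
#' @export
similarity_report <- function(query, reference, genes = NULL) {
  qlab <- if (nrow(query) > 0 && "sample" %in% names(query))
    query$sample[1] else "query"
  rlab <- if (nrow(reference) > 0 && "sample" %in% names(reference))
    reference$sample[1] else "reference"
  ref_gr <- fragments_to_granges(reference)
  qry_gr <- fragments_to_granges(query)
  n_overlap <- sum(GenomicRanges::countOverlaps(ref_gr, qry_gr) > 0)
  frag_pct <- fragment_similarity(query, reference)
  total_ref_bp <- sum(reference$end - reference$start)
  bp_pct <- bp_similarity(query, reference)
  genes_part <- NULL
  if (!is.null(genes)) {
    gq <- genes_in_set(query, genes)
    gr <- genes_in_set(reference, genes)
    shared <- intersect(gq, gr)
    genes_part <- list(
      query_genes = length(gq), reference_genes = length(gr),
      shared = length(shared),
      pct_of_query = round(100 * length(shared) / max(1L, length(gq)), 1),
      pct_of_reference = round(100 * length(shared) / max(1L, length(gr)), 1)
    )
  }
  structure(list(
    query_label = qlab, reference_label = rlab,
    fragments = list(overlapping = n_overlap, total = nrow(reference),
                     pct = frag_pct),
    bp = list(overlapped = round(total_ref_bp * bp_pct / 100),
              total = total_ref_bp, pct = bp_pct),
    genes = genes_part
  ), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Similarity of %s (query) against %s (reference)\n",
              x$query_label, x$reference_label))
  cat(sprintf("  fragments: %d / %d overlapping (%.1f%%)\n",
              x$fragments$overlapping, x$fragments$total, x$fragments$pct))
  cat(sprintf("  bp:        %s / %s overlapped (%.1f%%)\n",
              format(x$bp$overlapped, big.mark = ","),
              format(x$bp$total, big.mark = ","), x$bp$pct))
  if (!is.null(x$genes))
    cat(sprintf("  genes:     %d shared (%.1f%% of query, %.1f%% of reference)\n",
                x$genes$shared, x$genes$pct_of_query,
                x$genes$pct_of_reference))
  invisible(x)
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition of %d sets (union %d)\n",
              length(x$totals), x$union_size))
  print(x$regions)
  invisible(x)
}
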