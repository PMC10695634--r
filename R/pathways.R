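# Pathway coverage: for each sample gene set, how many genes of each
# pathway it contains, as counts and integer percentages of pathway size.

#' Pathway coverage table
#'
#' For each (sample, pathway) pair, counts the pathway genes present in the
#' sample gene set and expresses the count as a percentage of pathway size,
#' rounded half away from zero to an integer. Gene matching is exact-string
#' on IDs; pass an `alias` map to fold synonyms first.
#'
#' @param gene_sets Named list of character vectors (gene IDs per sample).
#' @param pathways Tibble with columns `pathway`, `gene_id` (memberships),
#'   as returned by [read_pathways()] or [make_pathways()].
#' @param alias Optional named character vector mapping alias -> canonical
#'   gene ID, applied to the sample sets.
#' @return A tibble of class `coverage_table` with columns `sample`,
#'   `genes_in_sample`, `pathway`, `pathway_size`, `count`, `percent`.
#' @export
coverage_table <- function(gene_sets, pathways, alias = NULL) {
  stopifnot(is.list(gene_sets), length(gene_sets) > 0L,
            !is.null(names(gene_sets)))
  stopifnot(all(c("pathway", "gene_id") %in% names(pathways)))
  sizes <- dplyr::count(pathways, .data$pathway, name = "pathway_size")
  if (any(sizes$pathway_size == 0L) || nrow(sizes) == 0L)
    stop("empty pathway")
  members <- split(pathways$gene_id, pathways$pathway)
  if (any(vapply(members, anyDuplicated, integer(1)) > 0L))
    stop("duplicate gene IDs within a pathway")
  purrr::map_dfr(names(gene_sets), function(s) {
    genes <- unique(gene_sets[[s]])
    if (!is.null(alias)) {
      hit <- genes %in% names(alias)
      genes[hit] <- alias[genes[hit]]
      genes <- unique(genes)
    }
    purrr::map_dfr(names(members), function(p) {
      size <- length(members[[p]])
      cnt <- length(intersect(genes, members[[p]]))
      tibble::tibble(
        sample = s, genes_in_sample = length(genes),
        pathway = p, pathway_size = size, count = cnt,
        percent = round_half_away(100 * cnt / size)
      )
    })
  }) -> out
  class(out) <- c("coverage_table", class(out))
  out
}
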