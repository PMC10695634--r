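# Descriptive metrics for a genome-mapped fragment set: stratified counts
# and lengths by length class and FPKM class, per-chromosome contig
# densities, and the fraction of the genome the fragments account for.

#' Round half away from zero
#'
#' Percentage cells in coverage tables use half-away-from-zero rounding
#' (`round()` in R rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Stratified descriptive metrics for a fragment set
#'
#' Cross-tabulates fragments by length class (shorter/longer than a
#' threshold, default 100 bp) and FPKM class (default breaks 10, 100, 1000,
#' giving classes `<10`, `10-100`, `100-1000`, `>1000`), with per-length-class
#' and grand-total roll-ups. Class boundaries are half-open: FPKM classes
#' `[0,10)`, `[10,100)`, `[100,1000)`, `[1000,Inf)`; the long length class is
#' `[threshold, Inf)`.
#'
#' @param fragments Fragment tibble.
#' @param length_threshold Length-class boundary in bp (default 100).
#' @param fpkm_breaks Increasing FPKM class breaks (default `c(10,100,1000)`).
#' @return A tibble of class `metrics_table` with columns `length_class`,
#'   `fpkm_class`, `n`, `total_length_bp`, `total_length_kbp` (rounded,
#'   half-to-even), `mean_length_bp` (rounded), `mean_fpkm` (rounded), and
#'   the unrounded `mean_length_bp_exact`, `mean_fpkm_exact`. Empty strata
#'   report `n = 0` and `NA` means.
#' @export
stratify_metrics <- function(fragments, length_threshold = 100,
                             fpkm_breaks = c(10, 100, 1000)) {
  stopifnot(all(diff(fpkm_breaks) > 0))
  if (!"fpkm" %in% names(fragments)) fragments$fpkm <- 0
  len <- fragments$end - fragments$start
  fpkm <- fragments$fpkm
  brk <- c(0, fpkm_breaks, Inf)
  lab <- character(length(brk) - 1L)
  lab[1] <- paste0("<", fpkm_breaks[1])
  lab[length(lab)] <- paste0(">", fpkm_breaks[length(fpkm_breaks)])
  if (length(lab) > 2L)
    lab[2:(length(lab) - 1L)] <-
      paste0(fpkm_breaks[-length(fpkm_breaks)], "-", fpkm_breaks[-1])

  row_for <- function(keep, length_class, fpkm_class) {
    l <- len[keep]; f <- fpkm[keep]
    tibble::tibble(
      length_class = length_class, fpkm_class = fpkm_class,
      n = sum(keep),
      total_length_bp = sum(l),
      mean_length_bp_exact = if (sum(keep) > 0) mean(l) else NA_real_,
      mean_fpkm_exact = if (sum(keep) > 0) mean(f) else NA_real_
    )
  }

  long <- len >= length_threshold
  long_lab <- paste0(">", length_threshold, "bp")
  short_lab <- paste0("<", length_threshold, "bp")
  rows <- purrr::map_dfr(rev(seq_along(lab)), function(i) {
    keep <- long & fpkm >= brk[i] & fpkm < brk[i + 1L]
    row_for(keep, long_lab, lab[i])
  })
  rows <- dplyr::bind_rows(
    rows,
    row_for(long, long_lab, "all"),
    row_for(!long, short_lab, "all"),
    row_for(rep(TRUE, length(len)), "all", "all")
  )
  rows$total_length_kbp <- round(rows$total_length_bp / 1000)
  rows$mean_length_bp <- round_half_away(rows$mean_length_bp_exact)
  rows$mean_fpkm <- round_half_away(rows$mean_fpkm_exact)
  out <- rows[, c("length_class", "fpkm_class", "n", "total_length_bp",
                  "total_length_kbp", "mean_length_bp", "mean_fpkm",
                  "mean_length_bp_exact", "mean_fpkm_exact")]
  class(out) <- c("metrics_table", class(out))
  out
}

#' Per-chromosome fragment density
#'
#' Fragment counts per Mbp for every chromosome, the unweighted mean and
#' sample standard deviation over nuclear chromosomes, and the mitochondrial
#' density reported separately.
#'
#' @param fragments Fragment tibble.
#' @param genome A `genome_model` tibble covering all fragment chromosomes.
#' @return An object of class `density_report`: a list with `per_chromosome`
#'   (tibble: `chrom`, `n`, `length_mbp`, `density_per_mbp`, `is_mito`),
#'   `nuclear_mean`, `nuclear_sd`, and `mito_density` (NA when the model has
#'   no mitochondrial chromosome).
#' @export
chromosome_density <- function(fragments, genome) {
  genome <- assert_genome(genome)
  fragments <- validate_fragments(fragments, genome)
  counts <- table(factor(fragments$chrom, levels = genome$chrom))
  per <- tibble::tibble(
    chrom = genome$chrom,
    n = as.numeric(counts),
    length_mbp = genome$length / 1e6,
    is_mito = genome$is_mito
  )
  per$density_per_mbp <- per$n / per$length_mbp
  nuc <- per$density_per_mbp[!per$is_mito]
  structure(list(
    per_chromosome = per,
    nuclear_mean = mean(nuc),
    nuclear_sd = if (length(nuc) > 1L) stats::sd(nuc) else NA_real_,
    mito_density = if (any(per$is_mito))
      per$density_per_mbp[per$is_mito][1] else NA_real_
  ), class = "density_report")
}

#' Fraction of the genome accounted for by a fragment set
#'
#' `mode = "sum"` (default) divides the plain sum of fragment lengths by the
#' total genome length, so overlapping fragments count every time they occur;
#' `mode = "union"` divides the merged fragment footprint by the genome
#' length, counting each genomic bp at most once. Union-mode is never larger
#' than sum-mode, with equality exactly when fragments are disjoint.
#'
#' @param fragments Fragment tibble.
#' @param genome A `genome_model` tibble.
#' @param mode `"sum"` or `"union"`.
#' @param digits Decimal places of the percentage (default 1).
#' @return Percentage of genome length.
#' @export
genome_fraction <- function(fragments, genome, mode = c("sum", "union"),
                            digits = 1) {
  mode <- match.arg(mode)
  genome <- assert_genome(genome)
  genome_bp <- sum(genome$length)
  if (genome_bp <= 0) stop("empty genome")
  if (nrow(fragments) == 0L) return(0)
  covered <- if (mode == "sum") {
    sum(fragments$end - fragments$start)
  } else {
    sum(GenomicRanges::width(GenomicRanges::reduce(
      fragments_to_granges(fragments))))
  }
  round(100 * covered / genome_bp, digits)
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("Nuclear density: %.0f +/- %.0f fragments per Mbp\n",
              x$nuclear_mean, x$nuclear_sd))
  if (!is.na(x$mito_density))
    cat(sprintf("Mitochondrial density: %.0f fragments per Mbp\n",
                x$mito_density))
  print(x$per_chromosome)
  invisible(x)
}
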