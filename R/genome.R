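# Reference genome model: a tibble of chromosome names, lengths and a
# nuclear/mitochondrial flag. All interval arithmetic in the package is
# 0-based, half-open.

# S288C R64 chromosome lengths (bp); 16 nuclear chromosomes plus chrM,
# total 12,157,105 bp.
.s288c_r64 <- list(
  chrom = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrVI", "chrVII",
            "chrVIII", "chrIX", "chrX", "chrXI", "chrXII", "chrXIII",
            "chrXIV", "chrXV", "chrXVI", "chrM"),
  length = c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L, 1090940L,
             562643L, 439888L, 745751L, 666816L, 1078177L, 924431L, 784333L,
             1091291L, 948066L, 85779L)
)

#' Build a genome model
#'
#' A genome model is a tibble with one row per chromosome: `chrom` (unique
#' name), `length` (bp, > 0) and `is_mito` (logical; at most one
#' mitochondrial chromosome). It supplies the reference-length denominator
#' for genome-fraction and per-chromosome density computations.
#'
#' @param chroms Character vector of chromosome names (unique).
#' @param lengths Integer vector of chromosome lengths in bp (positive).
#' @param mito Name or index of the mitochondrial chromosome, or `NULL` for
#'   an all-nuclear model.
#' @return A tibble of class `genome_model` with columns `chrom`, `length`,
#'   `is_mito`.
#' @examples
#' genome_model("chrI", 230218)
#' yeast_genome()
#' @export
genome_model <- function(chroms, lengths, mito = NULL) {
  if (length(chroms) == 0L) stop("genome model needs at least one chromosome")
  if (length(chroms) != length(lengths))
    stop("`chroms` and `lengths` must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  is_mito <- rep(FALSE, length(chroms))
  if (!is.null(mito)) {
    idx <- if (is.character(mito)) match(mito, chroms) else as.integer(mito)
    if (length(idx) != 1L || is.na(idx) || idx < 1L || idx > length(chroms))
      stop("`mito` does not identify a chromosome")
    is_mito[idx] <- TRUE
  }
  out <- tibble::tibble(chrom = as.character(chroms), length = lengths,
                        is_mito = is_mito)
  class(out) <- c("genome_model", class(out))
  out
}

#' The bundled S288C r64 yeast genome model
#'
#' Sixteen nuclear chromosomes plus the mitochondrial chromosome (`chrM`),
#' totalling 12,157,105 bp.
#'
#' @return A `genome_model` tibble with 17 rows.
#' @export
yeast_genome <- function() {
  genome_model(.s288c_r64$chrom, .s288c_r64$length, mito = "chrM")
}

# Internal: check that a data frame is a usable genome model.
assert_genome <- function(genome) {
  stopifnot(is.data.frame(genome),
            all(c("chrom", "length") %in% names(genome)))
  if (nrow(genome) == 0L) stop("empty genome model")
  if (!"is_mito" %in% names(genome)) genome$is_mito <- FALSE
  genome
}

#' Validate a fragment table against a genome model
#'
#' Fragments use 0-based, half-open coordinates. Every fragment must satisfy
#' `0 <= start < end <= chromosome length` and lie on a chromosome present in
#' the genome model; FPKM must be non-negative.
#'
#' @param fragments Tibble with columns `chrom`, `start`, `end` and
#'   optionally `fpkm`, `sample`, `mapping`.
#' @param genome A `genome_model` tibble.
#' @return The validated fragment tibble (invisibly unchanged apart from
#'   filled-in default columns `fpkm = 0`, `sample = "sample"`).
#' @export
validate_fragments <- function(fragments, genome) {
  genome <- assert_genome(genome)
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (!"fpkm" %in% names(fragments)) fragments$fpkm <- 0
  if (!"sample" %in% names(fragments)) fragments$sample <- "sample"
  bad_chrom <- setdiff(unique(fragments$chrom), genome$chrom)
  if (length(bad_chrom) > 0L)
    stop("fragment chromosome(s) not in genome model: ",
         paste(bad_chrom, collapse = ", "))
  if (any(fragments$start < 0))
    stop("fragment with negative start coordinate")
  bad <- which(fragments$start >= fragments$end)
  if (length(bad) > 0L)
    stop(sprintf("fragment %d: empty or inverted interval [%s, %s)",
                 bad[1], fragments$start[bad[1]], fragments$end[bad[1]]))
  chrom_len <- genome$length[match(fragments$chrom, genome$chrom)]
  over <- which(fragments$end > chrom_len)
  if (length(over) > 0L)
    stop(sprintf("fragment %d: end %s exceeds %s length %s", over[1],
                 fragments$end[over[1]], fragments$chrom[over[1]],
                 chrom_len[over[1]]))
  if (any(fragments$fpkm < 0)) stop("FPKM values must be non-negative")
  tibble::as_tibble(fragments)
}
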