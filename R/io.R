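# Readers and writers for the plain-text formats the pipeline touches:
# BED/TSV fragment tables, GFF3/BED gene annotations, pathway TSVs,
# spectra and growth-series CSVs, and TSV/JSON result reports.

#' Read a genome-mapped fragment table
#'
#' Accepts BED3 (chrom, start, end), BED with a 4th FPKM column, or a
#' headered TSV with columns `chrom`, `start`, `end` and optionally `fpkm`,
#' `sample`, `mapping`. BED input is 0-based half-open, which is also the
#' internal convention, so coordinates pass through unchanged.
#'
#' @param path File path.
#' @param genome A `genome_model` tibble used for validation.
#' @param format `"bed"` (headerless, tab-separated) or `"tsv"` (headered).
#' @param sample Sample label attached to the fragments (BED input only;
#'   TSV input may carry its own `sample` column).
#' @return A validated fragment tibble with columns `chrom`, `start`, `end`,
#'   `fpkm`, `sample` (and `mapping` when present).
#' @export
read_fragments <- function(path, genome, format = c("bed", "tsv"),
                           sample = "sample") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(raw) < 3L) stop("BED input needs at least 3 columns")
    frags <- tibble::tibble(
      chrom = as.character(raw[[1]]),
      start = as.numeric(raw[[2]]),
      end = as.numeric(raw[[3]]),
      fpkm = if (ncol(raw) >= 4L) as.numeric(raw[[4]]) else 0,
      sample = sample
    )
  } else {
    frags <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    frags <- tibble::as_tibble(frags)
  }
  validate_fragments(frags, genome)
}

#' Write a fragment table as BED
#'
#' Emits chrom, start, end, FPKM as a headerless tab-separated file
#' (0-based half-open), the format [read_fragments()] reads back.
#'
#' @param fragments Fragment tibble.
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  out <- fragments[, c("chrom", "start", "end", "fpkm")]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation
#'
#' GFF3 input (1-based, closed intervals; rows with `type == "gene"` and an
#' `ID` or `gene_id` attribute) or BED input (0-based, half-open; name in
#' column 4). Either way the result uses the internal 0-based half-open
#' convention, so the same locus read from both dialects yields an identical
#' interval.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed"`.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_genes <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stop("malformed ", format, " input: ",
                             conditionMessage(e))
  )
  if (format == "gff3") {
    keep <- as.character(gr$type) == "gene"
    if (any(keep)) gr <- gr[keep]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else gr$Name
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  }
  if (is.null(ids) || anyNA(ids))
    ids <- paste0("G", sprintf("%06d", seq_along(gr)))
  out <- tibble::tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GRanges is 1-based closed; internal convention is 0-based half-open
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
  if (anyDuplicated(out$gene_id)) stop("duplicate gene IDs in annotation")
  out
}

#' Read a pathway membership table
#'
#' Two-column TSV (`pathway`, `gene_id`), one membership per line.
#'
#' @param path File path.
#' @return Tibble with columns `pathway`, `gene_id`.
#' @export
read_pathways <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("pathway", "gene_id"),
                         show_col_types = FALSE, comment = "#")
  dupes <- dplyr::count(raw, .data$pathway, .data$gene_id)
  if (any(dupes$n > 1L)) stop("duplicate gene IDs within a pathway")
  tibble::as_tibble(raw)
}

#' Read a time-resolved spectrum matrix
#'
#' CSV with the ppm axis in the first column and one column per time point;
#' the header row carries the times in hours.
#'
#' @param path File path.
#' @return A list with `ppm` (numeric vector), `time` (numeric vector of
#'   hours) and `intensity` (time x ppm matrix).
#' @export
read_spectra <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  ppm <- raw[[1]]
  times <- as.numeric(names(raw)[-1])
  if (anyNA(times)) stop("spectra header must carry numeric time points")
  mat <- t(as.matrix(raw[, -1, drop = FALSE]))
  dimnames(mat) <- NULL
  list(ppm = ppm, time = times, intensity = mat)
}

#' Read a growth series
#'
#' CSV with columns `time_h`, `biomass_g_per_L` and optionally `od590`,
#' `substrate`, `inhibitor`.
#'
#' @param path File path.
#' @return Tibble with the same columns, times strictly increasing.
#' @export
read_growth <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_h", "biomass_g_per_L") %in% names(g)))
    stop("growth series needs columns time_h, biomass_g_per_L")
  if (is.unsorted(g$time_h, strictly = TRUE))
    stop("growth series time points must be strictly increasing")
  if (any(g$biomass_g_per_L < 0)) stop("negative biomass")
  tibble::as_tibble(g)
}

#' Write a result object to TSV or JSON
#'
#' Tabular results are written as TSV with their columns in place; any
#' result is written as JSON with deterministic key order. Floats are
#' serialized at full precision so a serialize/parse round trip is the
#' identity.
#'
#' @param report A result tibble or list.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(report)) stop("TSV output needs a tabular report")
    readr::write_tsv(tibble::as_tibble(report), path)
  } else {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble (TSV) or list (JSON).
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
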