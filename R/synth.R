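# Synthetic-data generators: every input type of the pipeline can be
# produced with controlled statistical structure, so all downstream stages
# are testable without external downloads. All generators are pure
# functions of their arguments and a seed: identical calls give identical
# output.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                            envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a genome model
#'
#' With no arguments, returns the bundled S288C r64 model (17 chromosomes,
#' 12,157,105 bp). Otherwise builds a toy model from the given lengths.
#'
#' @param lengths Chromosome lengths in bp, or `NULL` for the bundled model.
#' @param mito_index Index of the mitochondrial chromosome, or `NULL`.
#' @return A `genome_model` tibble.
#' @export
make_genome <- function(lengths = NULL, mito_index = NULL) {
  if (is.null(lengths)) return(yeast_genome())
  if (length(lengths) == 0L) stop("need at least one chromosome length")
  genome_model(paste0("chr", seq_along(lengths)), lengths, mito = mito_index)
}

# complement of the merged reference footprint, per chromosome
reference_gaps <- function(reference, genome) {
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]; L <- genome$length[i]
    ref <- reference[reference$chrom == ch, , drop = FALSE]
    if (nrow(ref) == 0L)
      return(tibble::tibble(chrom = ch, start = 0, end = L))
    o <- order(ref$start)
    s <- ref$start[o]; e <- ref$end[o]
    # merge
    ms <- s[1]; me <- e[1]; gaps_s <- numeric(); gaps_e <- numeric()
    for (j in seq_along(s)[-1]) {
      if (s[j] <= me) me <- max(me, e[j])
      else { gaps_s <- c(gaps_s, me); gaps_e <- c(gaps_e, s[j])
             ms <- s[j]; me <- e[j] }
    }
    starts <- c(if (min(s) > 0) 0 else numeric(), gaps_s)
    ends <- c(if (min(s) > 0) min(s) else numeric(), gaps_e)
    if (me < L) { starts <- c(starts, me); ends <- c(ends, L) }
    tibble::tibble(chrom = ch, start = starts, end = ends)
  })
}

#' Generate a synthetic fragment set
#'
#' Fragment lengths are log-normal and FPKM values heavy-tailed
#' (log-normal), emulating assembled exDNA contig tables in which a handful
#' of fragments exceed FPKM 1000 while thousands sit below 10. When a
#' `reference` set and a target `similarity` s are given, a fraction s of
#' the reference fragments (chosen at random) each receive one query
#' fragment placed inside their interval, and the remaining query fragments
#' are placed in reference-free gaps, so the realized fragment-based
#' similarity against the reference is controlled directly.
#'
#' @param genome A `genome_model` tibble.
#' @param n Number of fragments.
#' @param similarity Target fragment-based similarity in `[0, 1]`, or
#'   `NULL` for unconstrained placement.
#' @param reference Reference fragment tibble (required with `similarity`).
#' @param length_meanlog,length_sdlog Log-normal length parameters
#'   (defaults 5.2, 1.3: mean ~420 bp, range from tens of bp to tens of
#'   kbp). Lengths are clamped to a minimum of 11 bp.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal FPKM parameters (defaults 1,
#'   2).
#' @param sample Sample label.
#' @param seed Random seed.
#' @return A validated fragment tibble.
#' @export
make_fragments <- function(genome, n, similarity = NULL, reference = NULL,
                           length_meanlog = 5.2, length_sdlog = 1.3,
                           fpkm_meanlog = 1, fpkm_sdlog = 2,
                           sample = "synthetic", seed = NULL) {
  genome <- assert_genome(genome)
  stopifnot(n > 0)
  if (!is.null(similarity)) {
    if (is.null(reference)) stop("similarity targeting needs a reference set")
    if (similarity < 0 || similarity > 1) stop("similarity must be in [0, 1]")
  }
  with_seed(seed, {
    lens <- pmax(11, round(stats::rlnorm(n, length_meanlog, length_sdlog)))
    fpkm <- stats::rlnorm(n, fpkm_meanlog, fpkm_sdlog)
    if (max(lens) > max(genome$length) && is.null(similarity))
      lens <- pmin(lens, max(genome$length))

    place_in <- function(regions, lens) {
      # sample a region per fragment proportional to width, clamp length,
      # uniform start
      w <- regions$end - regions$start
      idx <- sample.int(nrow(regions), length(lens), replace = TRUE,
                        prob = w)
      len <- pmin(lens, w[idx])
      start <- regions$start[idx] +
        floor(stats::runif(length(lens)) * (w[idx] - len + 1))
      tibble::tibble(chrom = regions$chrom[idx], start = start,
                     end = start + len)
    }

    if (is.null(similarity)) {
      frags <- place_in(
        tibble::tibble(chrom = genome$chrom, start = 0, end = genome$length),
        lens)
    } else {
      n_ref <- nrow(reference)
      k <- round(similarity * n_ref)
      if (k > n) stop(sprintf(
        "need at least %d fragments to overlap %d reference intervals", k, k))
      chosen <- if (k > 0) sample.int(n_ref, k) else integer()
      over <- if (k > 0) {
        # exactly one query fragment inside each chosen reference interval
        w <- reference$end[chosen] - reference$start[chosen]
        len <- pmin(lens[seq_len(k)], w)
        start <- reference$start[chosen] +
          floor(stats::runif(k) * (w - len + 1))
        tibble::tibble(chrom = reference$chrom[chosen], start = start,
                       end = start + len)
      } else tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric())
      rest <- n - k
      away <- NULL
      if (rest > 0) {
        gaps <- reference_gaps(reference, genome)
        gaps <- gaps[gaps$end - gaps$start >= 11, , drop = FALSE]
        if (nrow(gaps) == 0L)
          stop("no reference-free gaps left for non-overlapping fragments")
        away <- place_in(gaps, lens[k + seq_len(rest)])
      }
      frags <- dplyr::bind_rows(over, away)
    }
    frags$fpkm <- fpkm
    frags$sample <- sample
    validate_fragments(frags, genome)
  })
}

#' Generate a synthetic gene annotation
#'
#' Genes placed uniformly on the genome, IDs `G000001`, `G000002`, ...
#'
#' @param genome A `genome_model` tibble.
#' @param n_genes Number of genes (> 0).
#' @param gene_length Mean gene length in bp (default 1500); actual lengths
#'   uniform in `[0.5, 1.5] *` this value, clamped to the chromosome.
#' @param seed Random seed.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
make_gene_annotation <- function(genome, n_genes, gene_length = 1500,
                                 seed = NULL) {
  genome <- assert_genome(genome)
  if (n_genes <= 0) stop("n_genes must be positive")
  with_seed(seed, {
    idx <- sample.int(nrow(genome), n_genes, replace = TRUE,
                      prob = genome$length)
    len <- pmin(round(stats::runif(n_genes, 0.5, 1.5) * gene_length),
                genome$length[idx])
    len <- pmax(len, 1)
    start <- floor(stats::runif(n_genes) * (genome$length[idx] - len + 1))
    tibble::tibble(
      gene_id = paste0("G", sprintf("%06d", seq_len(n_genes))),
      chrom = genome$chrom[idx],
      start = start, end = start + len
    )
  })
}

#' Generate synthetic pathway gene sets
#'
#' Samples member genes for each pathway without replacement within a
#' pathway; a gene may belong to several pathways. Defaults give the five
#' KEGG pathways used for respiratory/fermentative coverage comparisons,
#' with sizes 31, 28, 76, 55 and 130.
#'
#' @param genes Gene annotation tibble (the gene universe).
#' @param sizes Named integer vector of pathway sizes.
#' @param seed Random seed.
#' @return Tibble with columns `pathway`, `gene_id`.
#' @export
make_pathways <- function(genes,
                          sizes = c(TCA = 31, pentose_phosphate = 28,
                                    oxidative_phosphorylation = 76,
                                    glycolysis_gluconeogenesis = 55,
                                    cell_cycle = 130),
                          seed = NULL) {
  if (any(sizes <= 0)) stop("pathway sizes must be positive")
  if (any(sizes > nrow(genes)))
    stop("pathway size exceeds the gene universe")
  if (is.null(names(sizes))) names(sizes) <- paste0("pathway", seq_along(sizes))
  with_seed(seed, {
    purrr::map_dfr(names(sizes), function(p) {
      tibble::tibble(pathway = p,
                     gene_id = sample(genes$gene_id, sizes[[p]]))
    })
  })
}

#' Deterministic logistic growth series
#'
#' Convenience generator for a biomass trajectory approaching a carrying
#' capacity, used as the growth input of synthetic NMR experiments.
#'
#' @param times Observation times (h), strictly increasing.
#' @param x0 Initial biomass (g L^-1), default 1.
#' @param capacity Final biomass plateau (g L^-1), default 30.
#' @param rate Logistic rate (h^-1), default 0.25.
#' @return Growth tibble (`time_h`, `biomass_g_per_L`, `od590`).
#' @export
make_growth_series <- function(times, x0 = 1, capacity = 30, rate = 0.25) {
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  x <- capacity / (1 + (capacity - x0) / x0 * exp(-rate * times))
  tibble::tibble(time_h = times, biomass_g_per_L = x,
                 od590 = biomass_to_od(x))
}

#' Default bin association labels for synthetic spectra
#'
#' `"negative"` for bins inside DNA-constituent regions, `"positive"` inside
#' nutrient regions, `"null"` elsewhere, mirroring the structure of a
#' culture-medium correlation fingerprint.
#'
#' @param bins Bin table from [nmr_bins()].
#' @param regions Region tibble, default [nmr_regions()].
#' @return Character vector of labels, one per bin.
#' @export
default_bin_labels <- function(bins = nmr_bins(), regions = nmr_regions()) {
  labels <- rep("null", nrow(bins))
  for (j in seq_len(nrow(regions))) {
    inside <- bins$center >= regions$lo[j] & bins$center < regions$hi[j]
    labels[inside] <- ifelse(regions$expected_sign[j] == "positive",
                             "positive", "negative")
  }
  labels
}

#' Generate a synthetic time-resolved NMR spectrum series
#'
#' Bins labeled positive/negative get intensity
#' `baseline +/- effect * z(rate) + noise`, where `z(rate)` is the
#' standardized growth rate at each time point; null bins get
#' `baseline + noise`. Noise is Gaussian, truncated at zero. With zero
#' noise a negative-labeled bin correlates with the growth rate at exactly
#' r = -1.
#'
#' @param growth Growth tibble covering the desired time grid; spectra are
#'   generated at every growth time (the first time point reuses the first
#'   interval's rate).
#' @param labels Per-bin association labels (`"positive"`, `"negative"`,
#'   `"null"`), default [default_bin_labels()].
#' @param effect Effect magnitude in intensity units per rate SD, default 2.
#' @param noise_sd Gaussian noise SD, default 1 (so the default
#'   effect-to-noise ratio is 2).
#' @param baseline Baseline intensity, default 10.
#' @param bins Bin table, default [nmr_bins()].
#' @param seed Random seed.
#' @return List with `time`, `ppm` (bin centers), `intensity` (time x bin
#'   matrix, non-negative) and `labels`.
#' @export
make_nmr_series <- function(growth, labels = default_bin_labels(),
                            effect = 2, noise_sd = 1, baseline = 10,
                            bins = nmr_bins(), seed = NULL) {
  stopifnot(length(labels) == nrow(bins), noise_sd >= 0)
  rates <- growth_rate_series(growth)
  r <- c(rates$rate[1], rates$rate)  # first spectrum reuses first interval
  if (length(r) != nrow(growth)) stop("mismatched time grids")
  z <- if (stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else r * 0
  sign_of <- c(positive = 1, negative = -1, null = 0)[labels]
  if (anyNA(sign_of)) stop("labels must be positive/negative/null")
  with_seed(seed, {
    signal <- outer(z, sign_of * effect)           # time x bin
    noise <- matrix(stats::rnorm(length(signal), 0, noise_sd),
                    nrow = nrow(signal))
    intensity <- pmax(baseline + signal + noise, 0)
    dimnames(intensity) <- NULL
    list(time = growth$time_h, ppm = bins$center, intensity = intensity,
         labels = unname(labels))
  })
}
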