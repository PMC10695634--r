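# 1H-NMR metabolomic fingerprinting of culture media: spectral binning at
# fixed ppm width, per-mille normalization with solvent exclusion, per-bin
# Pearson correlation with the culture growth rate, two-level significance
# classification, and annotation with diagnostic chemical-shift regions.

#' Bin edges and centers for a ppm range
#'
#' @param bin_width Bin width in ppm (default 0.01).
#' @param range Two-element ppm range (default `c(0, 10)`); `bin_width` must
#'   divide it.
#' @return Tibble with columns `bin`, `lo`, `hi`, `center` (1-based bin
#'   index; bin i covers `[lo, hi)`, the last bin closing at the range end).
#' @export
nmr_bins <- function(bin_width = 0.01, range = c(0, 10)) {
  n <- (range[2] - range[1]) / bin_width
  if (abs(n - round(n)) > 1e-9) stop("bin width must divide the ppm range")
  n <- round(n)
  lo <- range[1] + (seq_len(n) - 1) * bin_width
  tibble::tibble(bin = seq_len(n), lo = lo, hi = lo + bin_width,
                 center = lo + bin_width / 2)
}

#' Bin a raw spectrum into equal-width ppm buckets
#'
#' Each bin integrates (sums) the intensities of points falling in
#' `[lo, lo + width)`; points at exactly the upper range limit fall in the
#' last bin. Defaults give 1000 bins over 0-10 ppm.
#'
#' @param ppm Numeric vector of chemical shifts.
#' @param intensity Matching intensity vector (>= 0).
#' @param bin_width Bin width in ppm (default 0.01).
#' @param range ppm range (default `c(0, 10)`); points outside are dropped.
#' @return Numeric vector of binned intensities, length `range / bin_width`.
#' @export
bin_spectrum <- function(ppm, intensity, bin_width = 0.01, range = c(0, 10)) {
  if (length(ppm) == 0L) stop("empty spectrum")
  stopifnot(length(ppm) == length(intensity))
  bins <- nmr_bins(bin_width, range)
  keep <- ppm >= range[1] & ppm <= range[2]
  ppm <- ppm[keep]; intensity <- intensity[keep]
  idx <- pmin(floor((ppm - range[1]) / bin_width) + 1L, nrow(bins))
  out <- numeric(nrow(bins))
  agg <- tapply(intensity, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Per-mille normalization with solvent exclusion
#'
#' Sets bins inside the residual-solvent window to `NA` and rescales the
#' remaining bins so they sum to exactly 1000. Scale-invariant: multiplying
#' the input by any positive constant leaves the output unchanged.
#'
#' @param binned Numeric vector of binned intensities (one spectrum), or a
#'   time x bin matrix (each row normalized independently).
#' @param solvent_region ppm interval excluded as residual solvent, default
#'   `c(4.60, 4.80)` around the D2O resonance at 4.70 ppm; `NULL` excludes
#'   nothing.
#' @param bins Bin table from [nmr_bins()] matching the vector length.
#' @return Same shape as `binned`, solvent bins `NA`, the rest summing to
#'   1000 per spectrum.
#' @export
normalize_permille <- function(binned, solvent_region = c(4.60, 4.80),
                               bins = nmr_bins()) {
  if (is.matrix(binned)) {
    out <- t(apply(binned, 1L, normalize_permille,
                   solvent_region = solvent_region, bins = bins))
    dimnames(out) <- dimnames(binned)
    return(out)
  }
  stopifnot(length(binned) == nrow(bins))
  solvent <- if (is.null(solvent_region)) rep(FALSE, nrow(bins))
             else bins$lo < solvent_region[2] & bins$hi > solvent_region[1]
  total <- sum(binned[!solvent])
  if (!is.finite(total) || total <= 0)
    stop("spectrum has no signal outside the solvent region")
  out <- 1000 * binned / total
  out[solvent] <- NA_real_
  out
}

#' Correlate every spectral bin with the culture growth rate
#'
#' Pairs the spectrum acquired at time `t_i` with the backward-difference
#' growth rate over `(t_{i-1}, t_i]` (the first spectrum has no rate and is
#' dropped), then computes a per-bin Pearson r and its two-sided p-value
#' from the t-transform with n-2 degrees of freedom. Bins with zero variance
#' (or solvent-masked `NA` bins) are flagged undefined and never significant.
#'
#' @param spectra List with `time` (hours) and `intensity` (time x bin
#'   matrix), as from [read_spectra()] or [make_nmr_series()]; or a bare
#'   matrix with times in `rownames`.
#' @param growth Growth tibble (`time_h`, `biomass_g_per_L`) covering the
#'   spectra times, or a precomputed rate tibble from [growth_rate_series()].
#' @param bins Bin table from [nmr_bins()].
#' @param thresholds Two p-value cutoffs `(strong, weak)`, default
#'   `c(0.001, 0.05)`; strict inequalities.
#' @return A tibble of class `correlation_profile` with columns `bin`,
#'   `ppm` (bin center), `r`, `p`, `class` (`"strong"`, `"weak"`, `"none"`,
#'   `"undefined"`), and attribute `n` (number of paired observations).
#' @export
correlate_growth <- function(spectra, growth, bins = nmr_bins(),
                             thresholds = c(0.001, 0.05)) {
  if (is.matrix(spectra))
    spectra <- list(time = as.numeric(rownames(spectra)), intensity = spectra)
  rates <- if (all(c("time_h", "rate") %in% names(growth))) growth
           else growth_rate_series(growth)
  idx <- match(round(rates$time_h, 9), round(spectra$time, 9))
  ok <- !is.na(idx)
  if (sum(ok) < 3L) stop("need at least 3 paired time points")
  y <- rates$rate[ok]
  mat <- spectra$intensity[idx[ok], , drop = FALSE]
  n <- length(y)
  r <- suppressWarnings(as.numeric(stats::cor(y, mat)))
  # undefined when the bin (or the rate) has zero variance or missing values
  r[!is.finite(r)] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[is.na(r)] <- NA_real_
  out <- tibble::tibble(bin = bins$bin, ppm = bins$center, r = r, p = p)
  out <- classify_significance(out, thresholds)
  attr(out, "n") <- n
  attr(out, "thresholds") <- thresholds
  attr(out, "expected_false_positives") <-
    thresholds[2] * sum(is.finite(out$p))
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Classify correlation significance at two thresholds
#'
#' `"strong"` if p < the first threshold, `"weak"` if p < the second,
#' `"none"` otherwise (strict inequalities; the sign of the association is
#' carried by `r`). Undefined correlations stay `"undefined"`. No
#' multiple-testing correction is applied; with 1000 bins at the weak
#' threshold, about 50 false positives are expected by chance.
#'
#' @param profile Tibble with columns `r`, `p`.
#' @param thresholds Two cutoffs `(strong, weak)`, default `c(0.001, 0.05)`.
#' @return The profile with a `class` column (re)computed.
#' @export
classify_significance <- function(profile, thresholds = c(0.001, 0.05)) {
  stopifnot(thresholds[1] < thresholds[2])
  cls <- dplyr::case_when(
    is.na(profile$p) ~ "undefined",
    profile$p < thresholds[1] ~ "strong",
    profile$p < thresholds[2] ~ "weak",
    TRUE ~ "none"
  )
  profile$class <- cls
  profile
}

#' Diagnostic chemical-shift regions for yeast culture media
#'
#' Named ppm intervals with their chemical assignments: nutrient signals
#' (aliphatic and aromatic amino acids) expected to correlate positively
#' with growth, and DNA-constituent signals (deoxyribose protons, anomeric
#' protons, nitrogen-base protons) expected to correlate negatively.
#'
#' @return Tibble with columns `region`, `lo`, `hi` (ppm), `assignment`,
#'   `expected_sign` (`"positive"`/`"negative"`).
#' @export
nmr_regions <- function() {
  tibble::tribble(
    ~region, ~lo, ~hi, ~assignment, ~expected_sign,
    "aliphatic amino acids (0.60-0.75)", 0.60, 0.75,
      "aliphatic amino acid side chains", "positive",
    "dT methyl (1.75-1.85)", 1.75, 1.85, "Me, dT", "negative",
    "aliphatic amino acids (1.80-2.20)", 1.80, 2.20,
      "aliphatic amino acid side chains", "positive",
    "deoxyribose H-2I/H-2II (2.30-2.80)", 2.30, 2.80,
      "deoxyribose H-2I/H-2II", "negative",
    "deoxyribose H-3I/H-4I/H-5I/H-5II (3.40-4.40)", 3.40, 4.40,
      "deoxyribose H-3I/H-4I/H-5I/H-5II", "negative",
    "anomeric H-1' (5.60-6.30)", 5.60, 6.30,
      "deoxyribose anomeric H-1'", "negative",
    "dC H-5 (5.90-6.05)", 5.90, 6.05, "H-5, dC", "negative",
    "aromatic amino acids (6.50-7.30)", 6.50, 7.30,
      "aromatic amino acid ring protons", "positive",
    "dT H-6 (7.15-7.30)", 7.15, 7.30, "H-6, dT", "negative",
    "dC H-6 (7.70-7.85)", 7.70, 7.85, "H-6, dC", "negative",
    "dG H-8 (7.85-7.95)", 7.85, 7.95, "H-8, dG", "negative",
    "dA H-2 (8.10-8.20)", 8.10, 8.20, "H-2, dA", "negative",
    "dA H-8 (8.30-8.40)", 8.30, 8.40, "H-8, dA", "negative"
  )
}

#' Annotate a correlation profile with chemical-shift regions
#'
#' Labels every significant bin with each region containing its center
#' (overlapping regions all reported) and summarizes each region: counts of
#' strong/weak bins and the majority sign of significant correlations.
#'
#' @param profile A `correlation_profile` tibble.
#' @param regions Region tibble (`region`, `lo`, `hi`, ...), default
#'   [nmr_regions()].
#' @return A list with `bins` (significant bins with a `region` column; one
#'   row per bin x containing region, `NA` region for unannotated bins) and
#'   `regions` (per-region summary: `n_strong`, `n_weak`, `sign_majority`).
#' @export
annotate_regions <- function(profile, regions = nmr_regions()) {
  stopifnot(all(regions$lo >= 0), all(regions$hi <= 10))
  sig <- dplyr::filter(profile, .data$class %in% c("strong", "weak"))
  bins_out <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
    hit <- regions$lo <= sig$ppm[i] & sig$ppm[i] < regions$hi
    tibble::tibble(
      bin = sig$bin[i], ppm = sig$ppm[i], r = sig$r[i], p = sig$p[i],
      class = sig$class[i],
      region = if (any(hit)) regions$region[hit] else NA_character_
    )
  })
  region_summary <- purrr::map_dfr(seq_len(nrow(regions)), function(j) {
    inside <- sig$ppm >= regions$lo[j] & sig$ppm < regions$hi[j]
    rs <- sig$r[inside]
    tibble::tibble(
      region = regions$region[j],
      lo = regions$lo[j], hi = regions$hi[j],
      n_strong = sum(sig$class[inside] == "strong"),
      n_weak = sum(sig$class[inside] == "weak"),
      sign_majority = if (length(rs) == 0) NA_character_
                      else if (sum(rs > 0) >= sum(rs < 0)) "positive"
                      else "negative"
    )
  })
  list(bins = bins_out, regions = region_summary)
}
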