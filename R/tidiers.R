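# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.similarity_report <- function(x, ...) {
  rows <- tibble::tibble(
    metric = c("fragments", "bp"),
    overlapping = c(x$fragments$overlapping, x$bp$overlapped),
    total = c(x$fragments$total, x$bp$total),
    pct = c(x$fragments$pct, x$bp$pct)
  )
  if (!is.null(x$genes))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = "genes", overlapping = x$genes$shared,
      total = x$genes$reference_genes, pct = x$genes$pct_of_reference))
  rows$query <- x$query_label
  rows$reference <- x$reference_label
  rows
}

#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(
    query = x$query_label, reference = x$reference_label,
    fragment_pct = x$fragments$pct, bp_pct = x$bp$pct,
    shared_genes = if (is.null(x$genes)) NA_integer_ else x$genes$shared
  )
}

#' @export
tidy.venn_partition <- function(x, ...) x$regions

#' @export
glance.venn_partition <- function(x, ...) {
  tibble::tibble(n_sets = length(x$totals), union_size = x$union_size,
                 full_intersection =
                   x$regions$count[which.max(nchar(x$regions$region))])
}

#' @export
tidy.density_report <- function(x, ...) x$per_chromosome

#' @export
glance.density_report <- function(x, ...) {
  tibble::tibble(nuclear_mean = x$nuclear_mean, nuclear_sd = x$nuclear_sd,
                 mito_density = x$mito_density)
}

#' @export
tidy.correlation_profile <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "correlation_profile")
  out
}

#' @export
glance.correlation_profile <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x), n = attr(x, "n"),
    n_strong = sum(x$class == "strong"),
    n_weak = sum(x$class == "weak"),
    n_undefined = sum(x$class == "undefined"),
    expected_false_positives = attr(x, "expected_false_positives")
  )
}

#' @export
glance.metrics_table <- function(x, ...) {
  all_row <- x[x$length_class == "all" & x$fpkm_class == "all", ]
  tibble::tibble(n = all_row$n,
                 total_length_kbp = all_row$total_length_kbp,
                 mean_length_bp = all_row$mean_length_bp,
                 mean_fpkm = all_row$mean_fpkm)
}

#' @export
glance.fedbatch_sim <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    final_time_h = max(x$time_h),
    final_biomass = x$biomass_g_per_L[nrow(x)],
    final_inhibitor = x$inhibitor[nrow(x)],
    max_mu = max(x$mu)
  )
}
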