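test_that("stratification matches a brute-force per-fragment classification", {
  set.seed(21)
  g <- toy_genome(3, 1e6)
  for (rep in 1:25) {
    fr <- random_fragments(g, 400)
    mt <- stratify_metrics(fr)
    len <- fr$end - fr$start
    long <- len >= 100
    bf <- function(length_class, fpkm_class, keep) {
      row <- mt[mt$length_class == length_class &
                  mt$fpkm_class == fpkm_class, ]
      expect_equal(row$n, sum(keep))
      expect_equal(row$total_length_bp, sum(len[keep]))
      if (sum(keep) > 0)
        expect_equal(row$mean_fpkm_exact, mean(fr$fpkm[keep]))
    }
    bf(">100bp", ">1000", long & fr$fpkm >= 1000)
    bf(">100bp", "100-1000", long & fr$fpkm >= 100 & fr$fpkm < 1000)
    bf(">100bp", "10-100", long & fr$fpkm >= 10 & fr$fpkm < 100)
    bf(">100bp", "<10", long & fr$fpkm < 10)
    bf(">100bp", "all", long)
    bf("<100bp", "all", !long)
    bf("all", "all", rep(TRUE, nrow(fr)))
  }
})

test_that("roll-ups are exactly the stratum-wise aggregates", {
  set.seed(4)
  fr <- random_fragments(toy_genome(2, 1e6), 800)
  mt <- stratify_metrics(fr)
  strata <- mt[mt$length_class == ">100bp" & mt$fpkm_class != "all", ]
  long_all <- mt[mt$length_class == ">100bp" & mt$fpkm_class == "all", ]
  expect_equal(sum(strata$n), long_all$n)
  expect_equal(sum(strata$total_length_bp), long_all$total_length_bp)
  grand <- mt[mt$length_class == "all", ]
  short_all <- mt[mt$length_class == "<100bp", ]
  expect_equal(long_all$n + short_all$n, grand$n)
  expect_equal(long_all$total_length_bp + short_all$total_length_bp,
               grand$total_length_bp)
  # mean = length-sum / count
  expect_equal(grand$mean_length_bp_exact,
               grand$total_length_bp / grand$n)
})

test_that("count-weighted mean of engineered strata recovers the overall mean", {
  # two strata: 1556 long fragments of mean 428 bp, 577 short of mean 26 bp
  long <- tibble::tibble(chrom = "chr1",
                         start = seq(0, by = 1000, length.out = 1556))
  long$end <- long$start + 428
  short <- tibble::tibble(chrom = "chr1",
                          start = seq(2e6, by = 500, length.out = 577))
  short$end <- short$start + 26
  fr <- dplyr::bind_rows(long, short)
  fr$fpkm <- 1
  mt <- stratify_metrics(fr)
  grand <- mt[mt$length_class == "all", ]
  expect_equal(grand$n, 2133L)
  expect_equal(grand$mean_length_bp, 319)
  expect_equal(grand$mean_length_bp_exact,
               (1556 * 428 + 577 * 26) / 2133)
})

test_that("empty fragment sets yield zero counts and undefined means", {
  mt <- stratify_metrics(tibble::tibble(chrom = character(),
                                        start = numeric(), end = numeric(),
                                        fpkm = numeric()))
  expect_true(all(mt$n == 0))
  expect_true(all(is.na(mt$mean_length_bp)))
})

test_that("chromosome density separates nuclear and mitochondrial statistics", {
  g <- genome_model(c("nuc1", "nuc2", "mt"), c(1e6, 1e6, 1e5), mito = "mt")
  fr <- dplyr::bind_rows(
    tibble::tibble(chrom = "nuc1", start = seq(0, by = 100,
                                               length.out = 100)),
    tibble::tibble(chrom = "nuc2", start = seq(0, by = 100,
                                               length.out = 200)),
    tibble::tibble(chrom = "mt", start = seq(0, by = 10, length.out = 50))
  )
  fr$end <- fr$start + 10
  d <- chromosome_density(fr, g)
  expect_equal(d$per_chromosome$density_per_mbp[1:2], c(100, 200))
  expect_equal(d$nuclear_mean, 150)
  expect_equal(d$nuclear_sd, sd(c(100, 200)))
  expect_equal(d$nuclear_sd, 70.71068, tolerance = 1e-6)
  expect_equal(d$mito_density, 500)
})

test_that("single-chromosome density is plain arithmetic", {
  g <- genome_model("chr1", 1e6)
  fr <- tibble::tibble(chrom = "chr1",
                       start = seq(0, by = 1000, length.out = 165))
  fr$end <- fr$start + 50
  d <- chromosome_density(fr, g)
  expect_equal(d$per_chromosome$density_per_mbp, 165)
  expect_true(is.na(d$mito_density))
})

test_that("genome fraction: sum mode counts duplicates, union does not", {
  g <- genome_model("chr1", 1e6)
  dup <- tibble::tibble(chrom = "chr1", start = c(0, 0), end = c(1000, 1000))
  expect_equal(genome_fraction(dup, g, "sum"), 0.2)
  expect_equal(genome_fraction(dup, g, "union"), 0.1)
  expect_equal(genome_fraction(dup[0, ], g), 0)
  expect_error(genome_fraction(dup, genome_model("chr1", 1)[0, ]), "genome")
})

test_that("union-mode fraction never exceeds sum mode; equal iff disjoint", {
  set.seed(13)
  g <- toy_genome(2, 1e5)
  for (rep in 1:25) {
    fr <- random_fragments(g, 50, max_len = 3000)
    s <- genome_fraction(fr, g, "sum", digits = 10)
    u <- genome_fraction(fr, g, "union", digits = 10)
    expect_lte(u, s)
    any_overlap <- any(vapply(seq_len(nrow(fr) - 1), function(i) {
      any(overlaps1(fr$chrom[i], fr$start[i], fr$end[i],
                    fr$chrom[-seq_len(i)], fr$start[-seq_len(i)],
                    fr$end[-seq_len(i)]))
    }, logical(1)))
    expect_equal(u == s, !any_overlap)
  }
})
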