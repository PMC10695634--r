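test_that("interval index answers overlap queries like a linear scan", {
  set.seed(31)
  g <- toy_genome(3, 1e5)
  fr <- random_fragments(g, 500, max_len = 2000)
  idx <- build_index(fr)
  for (rep in 1:200) {
    ch <- sample(g$chrom, 1)
    s <- sample(0:99000, 1); e <- s + sample(1:2000, 1)
    got <- sort(query_index(idx, ch, s, e))
    want <- which(overlaps1(fr$chrom, fr$start, fr$end, ch, s, e))
    expect_equal(got, want)
  }
  expect_length(query_index(idx, "chr1", 99999, 100000 + 0),
                sum(overlaps1(fr$chrom, fr$start, fr$end, "chr1",
                              99999, 100000)))
})

test_that("fragment similarity honours its boundary cases", {
  x <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(100, 600),
                      fpkm = 0, sample = "x")
  expect_equal(fragment_similarity(x, x), 100)
  ref <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  q1 <- tibble::tibble(chrom = "chr1", start = 199, end = 300)
  expect_equal(fragment_similarity(q1, ref), 100)  # 1 bp overlap counts
  q2 <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
  expect_equal(fragment_similarity(q2, ref), 0)    # abutting does not
  expect_error(fragment_similarity(q1, ref[0, ]), "empty reference")
})

test_that("bp similarity uses the merged query footprint", {
  ref <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  half <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  expect_equal(bp_similarity(half, ref), 50)
  dbl <- tibble::tibble(chrom = "chr1", start = c(0, 40), end = c(60, 100))
  expect_equal(bp_similarity(dbl, ref), 100)  # no double counting
  expect_equal(bp_similarity(ref, ref), 100)
})

test_that("similarity metrics equal brute force on random set pairs", {
  set.seed(17)
  g <- toy_genome(2, 5e4)
  for (rep in 1:300) {
    nq <- sample(5:60, 1); nr <- sample(5:60, 1)
    q <- random_fragments(g, nq, max_len = 2000)
    r <- random_fragments(g, nr, max_len = 2000)
    expect_identical(fragment_similarity(q, r), bf_fragment_similarity(q, r))
    expect_identical(bp_similarity(q, r), bf_bp_similarity(q, r))
  }
})

test_that("metrics are invariant to fragment order and to splitting a query", {
  set.seed(23)
  g <- toy_genome(2, 1e5)
  q <- random_fragments(g, 60, max_len = 4000)
  r <- random_fragments(g, 60, max_len = 4000)
  perm <- sample(nrow(q))
  expect_equal(fragment_similarity(q[perm, ], r), fragment_similarity(q, r))
  expect_equal(bp_similarity(q[perm, ], r), bp_similarity(q, r))
  # split the first query fragment into two abutting pieces
  mid <- floor((q$start[1] + q$end[1]) / 2)
  split_q <- dplyr::bind_rows(
    tibble::tibble(chrom = q$chrom[1], start = q$start[1], end = mid,
                   fpkm = 0, sample = "s"),
    tibble::tibble(chrom = q$chrom[1], start = mid, end = q$end[1],
                   fpkm = 0, sample = "s"),
    q[-1, ])
  expect_equal(fragment_similarity(split_q, r), fragment_similarity(q, r))
  expect_equal(bp_similarity(split_q, r), bp_similarity(q, r))
})

test_that("similarity is directional: swapping sides changes the value", {
  g <- toy_genome(1, 1e5)
  big <- tibble::tibble(chrom = "chr1", start = seq(0, 90000, 10000),
                        end = seq(0, 90000, 10000) + 5000)
  small <- big[1:2, ]
  expect_equal(fragment_similarity(big, small), 100)
  expect_equal(fragment_similarity(small, big), 20)
  expect_equal(bp_similarity(big, small), 100)
  expect_lt(bp_similarity(small, big), 100)
})

test_that("gene extraction follows the partial-overlap, half-open contract", {
  genes <- tibble::tibble(gene_id = c("inside", "edge", "abut", "far"),
                          chrom = "chr1",
                          start = c(120, 0, 200, 5000),
                          end = c(160, 101, 300, 5100))
  fr <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  expect_equal(genes_in_set(fr, genes), c("edge", "inside"))
  expect_equal(genes_in_set(fr[0, ], genes), character())
})

test_that("venn partition equals brute-force tabulation on random triples", {
  set.seed(9)
  universe <- paste0("G", 1:6000)
  for (rep in 1:20) {
    sets <- list(ecc = sample(universe, 2000),
                 efc = sample(universe, 1000),
                 lfc = sample(universe, 4600))
    v <- venn_partition(sets)
    bf <- bf_venn_counts(sets)
    for (i in seq_len(nrow(v$regions))) {
      reg <- v$regions$region[i]
      expect_equal(v$regions$count[i],
                   if (reg %in% names(bf)) as.numeric(bf[[reg]]) else 0)
    }
    expect_equal(sum(v$regions$count), v$union_size)
    # per-set totals recovered from the regions containing the set
    for (nm in names(sets)) {
      in_reg <- grepl(nm, v$regions$region, fixed = TRUE)
      expect_equal(sum(v$regions$count[in_reg]), length(sets[[nm]]))
    }
  }
})

test_that("venn handles degenerate configurations", {
  a <- c("x", "y"); b <- c("p", "q")
  v <- venn_partition(list(A = a, B = b))
  expect_equal(v$regions$count[v$regions$region == "A&B"], 0)
  same <- venn_partition(list(A = a, B = a))
  expect_equal(same$regions$count[same$regions$region == "A&B"], 2)
  expect_equal(sum(same$regions$count), 2)
  expect_error(venn_partition(list(a)), "length")
})

test_that("similarity report bundles all three metrics coherently", {
  g <- toy_genome(1, 1e5)
  genes <- make_gene_annotation(g, 100, gene_length = 500, seed = 2)
  x <- random_fragments(g, 50, max_len = 2000)
  rep_xx <- similarity_report(x, x, genes)
  expect_equal(rep_xx$fragments$pct, 100)
  expect_equal(rep_xx$bp$pct, 100)
  expect_equal(rep_xx$genes$shared, length(genes_in_set(x, genes)))
  far <- tibble::tibble(chrom = "chr1", start = 0, end = 10,
                        fpkm = 0, sample = "far")
  away <- tibble::tibble(chrom = "chr1", start = 99000, end = 99010,
                         fpkm = 0, sample = "away")
  rep0 <- similarity_report(far, away, genes)
  expect_equal(rep0$fragments$pct, 0)
  expect_equal(rep0$bp$pct, 0)
  td <- tidy(rep_xx)
  expect_equal(nrow(td), 3L)
  expect_true(all(td$pct <= 100))
})

test_that("generator-targeted similarity is recovered by the report", {
  g <- yeast_genome()
  ref <- make_fragments(g, 500, seed = 41, sample = "ecc")
  q <- make_fragments(g, 500, similarity = 0.5, reference = ref, seed = 42)
  rep <- similarity_report(q, ref)
  expect_lt(abs(rep$fragments$pct - 50), 5)
})
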