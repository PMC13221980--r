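test_that("gene length is the closed-interval base count", {
  expect_equal(gene_length(mk_genes(1, 1)), 1L)
  expect_equal(gene_length(mk_genes(101, 400)), 300L)
  withr::with_seed(1, {
    starts <- sample(1000, 50)
    ends <- starts + sample(0:500, 50, replace = TRUE)
    # Enumeration oracle: count the positions in the closed interval.
    expect_equal(gene_length(tibble::tibble(start = starts, end = ends)),
                 vapply(seq_len(50), function(i) length(seq(starts[i], ends[i])), integer(1)))
  })
})

test_that("intergenic distance handles gaps, abutting genes, and overlaps", {
  a <- mk_genes(1, 100)
  expect_equal(intergenic_distance(a, mk_genes(131, 200, ids = "g2")), 30L)
  expect_equal(intergenic_distance(a, mk_genes(101, 200, ids = "g2")), 0L)
  # Overlap: the negated distance equals the number of shared bases.
  b <- mk_genes(95, 200, ids = "g2")
  d <- intergenic_distance(a, b)
  shared <- length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
  expect_equal(d, -6L)
  expect_equal(-d, shared)
  expect_error(intergenic_distance(a, mk_genes(131, 200, contig = "other", ids = "g2")),
               class = "operotext_usage_error")
})

test_that("distance plus downstream length equals the end-to-end offset", {
  withr::with_seed(7, {
    g <- mk_genes(starts = cumsum(sample(50:400, 30, replace = TRUE)), ends = integer(30))
    g$end <- g$start + sample(10:200, 30, replace = TRUE)
    p <- adjacent_pairs(g)
    expect_equal(intergenic_distance(p) + (p$end_b - p$start_b + 1L), p$end_b - p$end_a)
  })
})

test_that("strand orientation compares the two strands", {
  f <- mk_genes(1, 10)
  r <- mk_genes(1, 10, strand = "reverse")
  expect_equal(strand_orientation(f, f), "same")
  expect_equal(strand_orientation(f, r), "opposite")
  expect_equal(strand_orientation(r, r), "same")
})

test_that("GC percent counts unambiguous bases case-insensitively", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("atgc"), 50)
  expect_equal(gc_percent("ATGCNNN"), 50) # ambiguity codes excluded
  expect_error(gc_percent("NNNN"), class = "operotext_usage_error")
})

test_that("GC percent is strand-symmetric", {
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  withr::with_seed(3, {
    seqs <- replicate(20, rand_dna(sample(20:200, 1)))
    expect_equal(gc_percent(vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)),
                 gc_percent(seqs))
  })
})

test_that("GC difference is absolute, rounded, and symmetric", {
  contigs <- c(c1 = "GGGGATATGGGG")
  a <- mk_genes(1, 4)
  b <- mk_genes(5, 8, ids = "g2")
  expect_equal(gc_difference(a, contigs, a), 0)
  expect_equal(gc_difference(a, contigs, b), 100)
  withr::with_seed(4, {
    contigs2 <- c(c1 = rand_dna(2000))
    for (i in 1:10) {
      s1 <- sample(1500, 1); s2 <- sample(1500, 1)
      x <- mk_genes(s1, s1 + sample(100:400, 1))
      y <- mk_genes(s2, s2 + sample(100:400, 1), ids = "g2")
      expect_equal(gc_difference(x, contigs2, y), gc_difference(y, contigs2, x))
    }
  })
  expect_error(gc_difference(mk_genes(1990, 2100), c(c1 = rand_dna(2000)),
                             mk_genes(1, 10, ids = "g2")),
               class = "operotext_usage_error")
})

test_that("adjacency index counts each genome once per family pair", {
  idx <- build_adjacency_index(toy_adjacency_panel())
  expect_equal(idx$panel_size, 4L)
  # F1-F2 adjacent in P1 (twice, counted once), P2 (reversed order), P3.
  expect_equal(unname(idx$counts[family_key("F1", "F2")]), 3L)
  expect_equal(adjacency_percent(idx, "F1", "F2"), 75.0)
  expect_equal(adjacency_percent(idx, "F2", "F1"), 75.0)
  # Pair with one empty family never indexed.
  expect_false(family_key("F3", "") %in% names(idx$counts))
  expect_equal(adjacency_percent(idx, "F3", ""), 0)
  expect_equal(adjacency_percent(idx, "FX", "FY"), 0)
  expect_error(build_adjacency_index(list()), class = "operotext_usage_error")
})

test_that("adjacency percentages are order-invariant and bounded", {
  panel <- toy_adjacency_panel()
  idx1 <- build_adjacency_index(panel)
  withr::with_seed(5, idx2 <- build_adjacency_index(panel[sample(nrow(panel)), ]))
  keys <- names(idx1$counts)
  expect_setequal(keys, names(idx2$counts))
  expect_equal(idx2$counts[keys], idx1$counts[keys])
  pct <- 100 * idx1$counts / idx1$panel_size
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(all(pct < 100 | idx1$counts == idx1$panel_size))
})

test_that("shared-genome denominator rescales conservation", {
  idx <- build_adjacency_index(toy_adjacency_panel())
  # F1 occurs in P1..P4, F2 in P1..P3: 3 shared genomes, adjacent in all 3.
  expect_equal(adjacency_percent(idx, "F1", "F2", denominator = "shared"), 100)
  expect_equal(adjacency_percent(idx, "F1", "F2"), 75)
})

test_that("adjacency index round-trips through its on-disk format", {
  idx <- build_adjacency_index(toy_adjacency_panel())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency_index(idx, path)
  got <- read_adjacency_index(path)
  expect_equal(got$panel_size, idx$panel_size)
  expect_equal(adjacency_percent(got, "F1", "F2"), adjacency_percent(idx, "F1", "F2"))
  expect_equal(adjacency_percent(got, "F1", "F2", "shared"),
               adjacency_percent(idx, "F1", "F2", "shared"))
})

test_that("pair features agree with componentwise computation", {
  contigs <- c(c1 = paste0(strrep("G", 100), strrep("A", 30), strrep("C", 120)))
  genes <- mk_genes(c(1, 131), c(100, 250), strand = c("forward", "reverse"),
                    ids = c("gA", "gB"), product = c("kinase", "permease"),
                    family = c("F1", "F2"))
  idx <- build_adjacency_index(toy_adjacency_panel())
  scores <- tibble::tibble(gene_a = "gB", gene_b = "gA", combined_score = 850)
  ft <- pair_features(adjacent_pairs(genes), contigs, idx, scores)
  expect_equal(ft$length_a, 100L)
  expect_equal(ft$length_b, 120L)
  expect_equal(ft$distance, 30L)
  expect_equal(ft$strand_orientation, "opposite")
  expect_equal(ft$gc_diff, 0)
  expect_equal(ft$adjacency_percent, 75.0)
  # STRING lookup falls back to the reversed key.
  expect_equal(ft$string_score, 850)
  # Without an index the conservation defaults to zero; no score -> NA.
  ft0 <- pair_features(adjacent_pairs(genes), contigs)
  expect_equal(ft0$adjacency_percent, 0)
  expect_true(is.na(ft0$string_score))
})

test_that("feature oracles agree with brute force on random gene pairs", {
  withr::with_seed(99, {
    contigs <- c(c1 = rand_dna(60000))
    starts_a <- sample(20000, 1000)
    ends_a <- starts_a + sample(50:800, 1000, replace = TRUE)
    starts_b <- ends_a + sample(-40:500, 1000, replace = TRUE)
    ends_b <- starts_b + sample(50:800, 1000, replace = TRUE)
    a <- tibble::tibble(start = starts_a, end = ends_a, contig_id = "c1")
    b <- tibble::tibble(start = starts_b, end = ends_b, contig_id = "c1")
    # Brute force per-base enumeration.
    gc_of <- function(s, e) {
      bases <- strsplit(substr(contigs[["c1"]], s, e), "")[[1]]
      100 * sum(bases %in% c("G", "C")) / sum(bases %in% c("A", "C", "G", "T"))
    }
    i <- sample(1000, 60) # spot-check the slow oracle on a subsample
    expect_equal(gene_length(a)[i], ends_a[i] - starts_a[i] + 1L)
    brute_dist <- vapply(i, function(k) {
      pos <- seq(starts_a[k], ends_b[k])
      if (starts_b[k] > ends_a[k]) {
        sum(pos > ends_a[k] & pos < starts_b[k])
      } else {
        -length(intersect(seq(starts_a[k], ends_a[k]), seq(starts_b[k], ends_b[k])))
      }
    }, numeric(1))
    expect_equal(as.numeric(intergenic_distance(a, b)[i]), brute_dist)
    brute_gc <- vapply(i, function(k) {
      round(abs(gc_of(starts_a[k], ends_a[k]) - gc_of(starts_b[k], ends_b[k])), 2)
    }, numeric(1))
    pairs <- tibble::tibble(contig_id = "c1", start_a = starts_a, end_a = ends_a,
                            start_b = starts_b, end_b = ends_b)
    expect_equal(gc_difference(pairs, contigs)[i], brute_gc)
  })
})
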