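# Compact gene-table constructor used across tests.
mk_genes <- function(starts, ends, strand = "forward", contig = "c1",
                     genome = "G1", ids = NULL, product = "", family = "",
                     type = "CDS") {
  n <- length(starts)
  tibble::tibble(
    gene_id = ids %||% sprintf("%s_g%02d", genome, seq_len(n)),
    genome_id = genome, contig_id = rep_len(contig, n),
    start = as.integer(starts), end = as.integer(ends),
    strand = rep_len(strand, n), product = rep_len(product, n),
    family_id = rep_len(family, n), feature_type = rep_len(type, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random uppercase DNA string.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# A 4-genome toy panel in which families F1-F2 are adjacent in exactly the
# first three genomes; genome G1 carries the pair twice.
toy_adjacency_panel <- function() {
  g1 <- dplyr::bind_rows(
    mk_genes(c(1, 201, 401, 601, 801), c(100, 300, 500, 700, 900), genome = "P1",
             ids = sprintf("P1_g%d", 1:5),
             family = c("F1", "F2", "F9", "F1", "F2")),
    mk_genes(c(1, 201), c(100, 300), genome = "P1", contig = "c2",
             ids = c("P1_h1", "P1_h2"), family = c("F3", ""))
  )
  g2 <- mk_genes(c(1, 151), c(100, 350), genome = "P2", ids = c("P2_g1", "P2_g2"),
                 family = c("F2", "F1"))
  g3 <- mk_genes(c(1, 151, 301), c(100, 250, 400), genome = "P3",
                 ids = sprintf("P3_g%d", 1:3), family = c("F1", "F2", "F3"))
  g4 <- mk_genes(c(1, 151), c(100, 250), genome = "P4", ids = c("P4_g1", "P4_g2"),
                 family = c("F1", "F3"))
  dplyr::bind_rows(g1, g2, g3, g4)
}

# One fully specified feature row matching the documented template example.
template_features <- function() {
  tibble::tibble(
    pair_id = "G1:gA|gB", genome_id = "G1",
    length_a = 300L, length_b = 450L,
    function_a = "ABC transporter", function_b = "permease",
    family_a = "PGF_00001", family_b = "PGF_00002",
    distance = 30L, gc_diff = 1.25, strand_orientation = "same",
    adjacency_percent = 75.0, string_score = NA_real_
  )
}

template_expected <- paste(
  "Gene A is 300 bp long, annotated as 'ABC transporter', and is part of the PGF_00001 family.",
  "It is followed by Gene B, 450 bp long, annotated as 'permease', and is part of the PGF_00002 family.",
  "The intergenic distance is 30 base pairs.",
  "The GC content difference is 1.25%.",
  "They are on the same strand.",
  "They are adjacent in 75% of representative genomes."
)

# Planted-signal corpus: operonic iff short distance; strand carries partial
# signal. Built directly at the feature level so model tests are independent
# of the genome simulator.
planted_corpus <- function(n, seed, mask = mask_preset("baseline")) {
  withr::with_seed(seed, {
    label <- sample(rep(c("operonic", "non_operonic"), length.out = n))
    pos <- label == "operonic"
    ft <- tibble::tibble(
      pair_id = sprintf("G1:p%04d", seq_len(n)), genome_id = "G1",
      length_a = sample(200:1500, n, replace = TRUE),
      length_b = sample(200:1500, n, replace = TRUE),
      function_a = sample(c("kinase", "permease", "hydrolase"), n, replace = TRUE),
      function_b = sample(c("kinase", "permease", "hydrolase"), n, replace = TRUE),
      family_a = sprintf("PGF_%05d", sample(50, n, replace = TRUE)),
      family_b = sprintf("PGF_%05d", sample(50, n, replace = TRUE)),
      distance = ifelse(pos, sample(-10:80, n, replace = TRUE),
                        sample(100:400, n, replace = TRUE)),
      gc_diff = round(stats::runif(n, 0, 10), 2),
      strand_orientation = ifelse(pos, "same",
                                  sample(c("same", "opposite"), n, replace = TRUE)),
      adjacency_percent = 0,
      string_score = NA_real_,
      label = label
    )
  })
  serialize_pairs(ft, mask)
}

# A small separable panel shared by evaluation tests (cached per session).
small_panel_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- generate_panel(simulation_config(n_genomes = 3, genes_per_genome = 150,
                                            seed = 101))
      cache <<- build_dataset(p$genes, p$operons, p$contigs,
                              string_scores = p$string_scores)
    }
    cache
  }
})
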