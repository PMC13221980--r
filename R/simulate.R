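default_function_vocab <- c(
  "ABC transporter ATP-binding protein", "permease", "DNA-binding regulator",
  "ribosomal protein", "oxidoreductase", "membrane protein", "hydrolase",
  "aminotransferase", "two-component sensor kinase", "acyl carrier protein",
  "glycosyltransferase", "efflux pump subunit"
)

#' Configuration for the synthetic genome-panel generator
#'
#' The generator emulates the statistical structure the classifier relies on:
#' operons are drawn from a shared pool of conserved archetypes (so operonic
#' family pairs recur adjacently across genomes), members of one operon share
#' a strand and a GC level, intra-operon intergenic gaps are short (possibly
#' negative, i.e. overlapping), and operon boundaries carry longer gaps with
#' optional strand flips. With `null_signal = TRUE` every class-conditional
#' rule is removed (one shared gap distribution, random strands, per-gene
#' random families/functions/GC), giving a panel on which no classifier
#' should beat chance.
#'
#' @param n_genomes Number of genomes in the panel.
#' @param genes_per_genome Approximate genes per genome.
#' @param operon_size_mean Mean operon size; sizes are `1 + Geometric`. The
#'   default of 2 makes within-operon pairs and boundary negatives roughly
#'   balanced, matching the near-balanced class composition of curated operon
#'   pair datasets.
#' @param intra_op_gap Integer range (lo, hi) of intra-operon gaps in bp.
#' @param boundary_gap Integer range of between-operon gaps in bp.
#' @param gene_length Integer range of gene lengths in bp.
#' @param p_strand_flip Probability of a strand flip at an operon boundary.
#' @param p_same_strand_within Probability each successive operon member keeps
#'   the operon strand (1 = operons are strictly single-strand).
#' @param family_vocab_size Size of the protein-family identifier vocabulary.
#' @param p_conserved_adjacency Probability an operon archetype is present in
#'   any given panel genome (hence the expected adjacency conservation of its
#'   internal pairs).
#' @param gc_noise_sd Per-gene GC noise around the operon GC level, in
#'   percentage points.
#' @param function_vocab Functional-annotation strings to sample from.
#' @param string_high,string_low Integer score ranges for operonic and
#'   non-operonic pairs in the emulated STRING table.
#' @param null_signal Remove all class-conditional structure (see above).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 6L, genes_per_genome = 240L,
                              operon_size_mean = 2, intra_op_gap = c(-10L, 80L),
                              boundary_gap = c(100L, 400L),
                              gene_length = c(200L, 1500L),
                              p_strand_flip = 0.5, p_same_strand_within = 1,
                              family_vocab_size = 2000L,
                              p_conserved_adjacency = 0.75,
                              gc_noise_sd = 3,
                              function_vocab = default_function_vocab,
                              string_high = c(700L, 999L),
                              string_low = c(0L, 299L),
                              null_signal = FALSE, seed = 1L) {
  if (operon_size_mean < 1) abort_usage("operon_size_mean must be >= 1")
  probs <- c(p_strand_flip, p_same_strand_within, p_conserved_adjacency)
  if (any(probs < 0 | probs > 1)) abort_usage("probabilities must lie in [0, 1]")
  if (null_signal) {
    # Class-independent sampling rules: one shared gap distribution, per-gene
    # families/functions/GC, fully overlapping score ranges. Strands are held
    # constant (no flips) so the strand feature is uninformative AND the
    # strand-aware boundary-negative rule fires for every operon, keeping the
    # class prior balanced; random strands would silently skew the prior by
    # suppressing negatives whose terminal gene points into its own operon.
    intra_op_gap <- c(0L, 300L)
    boundary_gap <- c(0L, 300L)
    p_strand_flip <- 0
    p_same_strand_within <- 1
    string_high <- c(0L, 999L)
    string_low <- c(0L, 999L)
  }
  structure(
    list(n_genomes = as.integer(n_genomes),
         genes_per_genome = as.integer(genes_per_genome),
         operon_size_mean = operon_size_mean,
         intra_op_gap = as.integer(intra_op_gap),
         boundary_gap = as.integer(boundary_gap),
         gene_length = as.integer(gene_length),
         p_strand_flip = p_strand_flip,
         p_same_strand_within = p_same_strand_within,
         family_vocab_size = as.integer(family_vocab_size),
         p_conserved_adjacency = p_conserved_adjacency,
         gc_noise_sd = gc_noise_sd,
         function_vocab = function_vocab,
         string_high = as.integer(string_high),
         string_low = as.integer(string_low),
         null_signal = isTRUE(null_signal),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Shared operon archetypes: the unit of conservation across the panel.
# Deterministic in config$seed, so every genome regenerates the same pool.
make_archetypes <- function(config) {
  withr::with_seed(config$seed, {
    m <- config$operon_size_mean
    p_present <- max(config$p_conserved_adjacency, 0.05)
    n_arch <- max(2L, ceiling(config$genes_per_genome / (p_present * m)))
    sizes <- if (m > 1) 1L + stats::rgeom(n_arch, prob = 1 / m) else rep(1L, n_arch)
    sizes <- pmax(sizes, 1L)
    total <- sum(sizes)
    fam_ids <- sprintf("PGF_%05d", if (config$family_vocab_size >= total) {
      sample.int(config$family_vocab_size, total)
    } else {
      sample.int(config$family_vocab_size, total, replace = TRUE)
    })
    funs <- sample(config$function_vocab, total, replace = TRUE)
    gc <- stats::runif(n_arch, 35, 65)
    offsets <- cumsum(c(0L, sizes[-n_arch]))
    lapply(seq_len(n_arch), function(i) {
      sl <- offsets[i] + seq_len(sizes[i])
      list(id = i, size = sizes[i], families = fam_ids[sl],
           functions = funs[sl], gc = gc[i])
    })
  })
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else sample(seq(range[1], range[2]), n, replace = TRUE)
}

gc_span <- function(len, gc) {
  gc <- min(max(gc, 5), 95) / 100
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate one synthetic genome
#'
#' Lays operon instances (drawn from the panel's shared archetype pool)
#' left-to-right on a single contig with sampled intra-operon and boundary
#' gaps, assigns strands, families, functions, and GC-controlled sequence,
#' and records the ground-truth pair labels the layout implies.
#'
#' @param config A [simulation_config()].
#' @param genome_index 1-based index of the genome within the panel.
#' @param seed Integer seed for this genome (derived from the config seed by
#'   default).
#' @param archetypes Shared archetype pool; regenerated from the config when
#'   omitted.
#' @return List with `record` (genome_id, contigs, genes), `operons`, and
#'   `truth` (pair_id, genome_id, gene_a, gene_b, label).
#' @export
generate_genome <- function(config, genome_index, seed = NULL, archetypes = NULL) {
  if (is.null(archetypes)) archetypes <- make_archetypes(config)
  if (is.null(seed)) seed <- derive_seed(config$seed, genome_index)
  genome_id <- sprintf("SYN%03d", genome_index)
  contig_id <- paste0(genome_id, "_c1")
  withr::with_seed(seed, {
    present <- which(stats::runif(length(archetypes)) < config$p_conserved_adjacency)
    if (length(present) == 0L) present <- 1L
    order_idx <- sample(present)

    gene_rows <- list()
    operon_rows <- list()
    truth_rows <- list()
    cursor <- 1L + sample(100:300, 1)
    gene_counter <- 0L
    strand <- sample(c("forward", "reverse"), 1)

    for (k in seq_along(order_idx)) {
      arch <- archetypes[[order_idx[k]]]
      size <- arch$size
      ids <- character(size)
      strands <- character(size)
      starts <- integer(size)
      ends <- integer(size)
      op_gc <- if (config$null_signal) NA_real_ else arch$gc
      gcs <- numeric(size)
      for (j in seq_len(size)) {
        gene_counter <- gene_counter + 1L
        ids[j] <- sprintf("%s_g%04d", genome_id, gene_counter)
        len <- sample_range(1, config$gene_length)
        starts[j] <- cursor
        ends[j] <- cursor + len - 1L
        strands[j] <- strand
        gcs[j] <- if (config$null_signal) stats::runif(1, 35, 65) else {
          op_gc + stats::rnorm(1, sd = config$gc_noise_sd)
        }
        if (j < size) {
          cursor <- ends[j] + 1L + sample_range(1, config$intra_op_gap)
          if (stats::runif(1) >= config$p_same_strand_within) {
            strand <- if (strand == "forward") "reverse" else "forward"
          }
        }
      }
      fams <- if (config$null_signal) {
        sprintf("PGF_%05d", sample.int(config$family_vocab_size, size, replace = TRUE))
      } else arch$families
      funs <- if (config$null_signal) {
        sample(config$function_vocab, size, replace = TRUE)
      } else arch$functions
      gene_rows[[k]] <- tibble::tibble(
        gene_id = ids, genome_id = genome_id, contig_id = contig_id,
        start = starts, end = ends, strand = strands,
        product = funs, family_id = fams, feature_type = "CDS", .gc = gcs
      )
      # Transcription order: reverse-strand operons are annotated right-to-left.
      op_strand <- strands[1]
      tx_ids <- if (op_strand == "reverse") rev(ids) else ids
      operon_rows[[k]] <- tibble::tibble(
        genome_id = genome_id,
        operon_id = sprintf("%s_op%03d", genome_id, k),
        gene_ids = list(tx_ids)
      )
      # Advance past the operon boundary.
      cursor <- ends[size] + 1L + sample_range(1, config$boundary_gap)
      if (stats::runif(1) < config$p_strand_flip) {
        strand <- if (strand == "forward") "reverse" else "forward"
      }
    }
    genes <- dplyr::bind_rows(gene_rows)
    operons <- dplyr::bind_rows(operon_rows)

    # Contig: neutral backbone overwritten by GC-controlled gene spans.
    contig_len <- max(genes$end) + 200L
    backbone <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
    for (i in seq_len(nrow(genes))) {
      span <- strsplit(gc_span(genes$end[i] - genes$start[i] + 1L, genes$.gc[i]), "")[[1]]
      backbone[genes$start[i]:genes$end[i]] <- span
    }
    contigs <- stats::setNames(paste(backbone, collapse = ""), contig_id)
    genes$.gc <- NULL
  })
  truth <- label_pairs(genes, operons)
  truth <- tibble::tibble(pair_id = truth$pair_id, genome_id = truth$genome_id,
                          gene_a = truth$gene_a, gene_b = truth$gene_b,
                          label = truth$label)
  list(record = list(genome_id = genome_id, contigs = contigs, genes = genes),
       operons = operons, truth = truth)
}

#' Generate a synthetic genome panel
#'
#' Generates `n_genomes` genomes from a shared archetype pool and (optionally)
#' writes them to disk as per-genome FASTA, features.tab and operon tables,
#' plus a combined truth manifest and an emulated STRING score table. All
#' emitted files round-trip through the package's own readers.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; omitted = in-memory only.
#' @param string_scores Emit/return an emulated STRING score table.
#' @return List with `genes` (all genomes), `contigs` (named vector across
#'   genomes), `operons`, `truth`, `string_scores` (or NULL), `config`, and
#'   `genomes` (per-genome records). Invisible when writing to `dir`.
#' @export
generate_panel <- function(config = simulation_config(), dir = NULL,
                           string_scores = TRUE) {
  if (config$n_genomes < 1L) abort_usage("n_genomes must be >= 1")
  archetypes <- make_archetypes(config)
  gl <- lapply(seq_len(config$n_genomes), function(i) {
    generate_genome(config, i, archetypes = archetypes)
  })
  genes <- dplyr::bind_rows(lapply(gl, function(x) x$record$genes))
  operons <- dplyr::bind_rows(lapply(gl, function(x) x$operons))
  truth <- dplyr::bind_rows(lapply(gl, function(x) x$truth))
  contigs <- unlist(lapply(gl, function(x) x$record$contigs))
  scores <- if (string_scores) write_string_scores(truth, config) else NULL

  out <- list(genes = genes, contigs = contigs, operons = operons,
              truth = truth, string_scores = scores, config = config,
              genomes = lapply(gl, function(x) x$record))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (x in gl) {
      gid <- x$record$genome_id
      seqs <- Biostrings::DNAStringSet(x$record$contigs)
      Biostrings::writeXStringSet(seqs, file.path(dir, paste0(gid, ".fna")))
      write_features_tab(x$record$genes, file.path(dir, paste0(gid, ".features.tab")))
      write_operon_table(x$operons, file.path(dir, paste0(gid, ".operons.tsv")))
    }
    readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
    if (!is.null(scores)) {
      readr::write_tsv(scores, file.path(dir, "string_scores.tsv"), progress = FALSE)
    }
    jsonlite::write_json(unclass(config), file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Emulated STRING combined scores for labeled pairs
#'
#' Operonic pairs draw from the high score range and non-operonic pairs from
#' the low range (ranges from the config; overlapping ranges emulate noisy
#' interaction evidence).
#'
#' @param truth Labeled pair tibble with `gene_a`, `gene_b`, `label`.
#' @param config A [simulation_config()].
#' @param seed Integer seed (derived from the config seed by default).
#' @param path Optional output path for the tab-delimited table.
#' @return Tibble `gene_a, gene_b, combined_score`.
#' @export
write_string_scores <- function(truth, config, seed = NULL, path = NULL) {
  if (is.null(seed)) seed <- derive_seed(config$seed, 7777L)
  withr::with_seed(seed, {
    hi <- sample_range(nrow(truth), config$string_high)
    lo <- sample_range(nrow(truth), config$string_low)
  })
  out <- tibble::tibble(
    gene_a = truth$gene_a, gene_b = truth$gene_b,
    combined_score = as.numeric(ifelse(truth$label == "operonic", hi, lo))
  )
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}

#' Read a genome panel directory back into memory
#'
#' Reads every `*.features.tab`, its sibling FASTA and operon table, and the
#' STRING score table if present — the layout written by [generate_panel()].
#'
#' @param dir Panel directory.
#' @return List with `genes`, `contigs`, `operons`, `string_scores` (or NULL).
#' @export
read_panel <- function(dir) {
  feats <- sort(list.files(dir, pattern = "\\.features\\.tab$", full.names = TRUE))
  if (length(feats) == 0L) abort_format(sprintf("no *.features.tab files in '%s'", dir))
  genes <- dplyr::bind_rows(lapply(feats, read_features_tab))
  fastas <- sub("\\.features\\.tab$", ".fna", feats)
  contigs <- unlist(lapply(fastas[file.exists(fastas)], read_fasta))
  optabs <- sub("\\.features\\.tab$", ".operons.tsv", feats)
  operons <- dplyr::bind_rows(lapply(optabs[file.exists(optabs)], read_operon_table))
  sf <- file.path(dir, "string_scores.tsv")
  scores <- if (file.exists(sf)) read_string_scores(sf) else NULL
  list(genes = genes, contigs = contigs, operons = operons, string_scores = scores)
}

#' Build the labeled, featurized gene-pair dataset for a panel
#'
#' Runs [label_pairs()] per genome, builds (or reuses) the adjacency
#' conservation index over the panel, and attaches all serializable features.
#'
#' @param genes Gene tibble covering the panel.
#' @param operons Operon tibble covering the panel.
#' @param contigs Named contig sequence vector covering the panel.
#' @param index Optional prebuilt [build_adjacency_index()]; built from
#'   `genes` when omitted.
#' @param string_scores Optional STRING score tibble.
#' @param denominator Conservation denominator, see [adjacency_percent()].
#' @return Labeled feature tibble ready for [serialize_pairs()].
#' @export
build_dataset <- function(genes, operons, contigs, index = NULL,
                          string_scores = NULL,
                          denominator = c("panel", "shared")) {
  denominator <- match.arg(denominator)
  if (is.null(index)) index <- build_adjacency_index(genes)
  labeled <- dplyr::bind_rows(lapply(split(seq_len(nrow(genes)), genes$genome_id), function(ix) {
    g <- genes[ix, , drop = FALSE]
    ops <- operons[operons$genome_id == g$genome_id[1], , drop = FALSE]
    label_pairs(g, ops)
  }))
  pair_features(labeled, contigs, index, string_scores, denominator)
}
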