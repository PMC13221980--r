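#' Gene length in base pairs
#'
#' Coordinates are 1-based inclusive, so the length of a span is
#' `end - start + 1`.
#'
#' @param genes Gene tibble (or any data frame with `start`/`end` columns).
#' @return Integer vector of lengths.
#' @export
gene_length <- function(genes) {
  as.integer(genes$end - genes$start + 1L)
}

#' Intergenic distance between adjacent genes
#'
#' For a pair with the upstream gene `a` (lower start) and downstream gene
#' `b`, the distance is `start_b - end_a - 1`: 0 for abutting genes and
#' negative when the genes overlap.
#'
#' @param pairs Pair tibble as returned by [adjacent_pairs()], or a one-row
#'   gene tibble when `b` is supplied.
#' @param b Optional downstream gene (one-row tibble) when calling on two
#'   individual genes.
#' @return Integer vector of signed distances in bp.
#' @export
intergenic_distance <- function(pairs, b = NULL) {
  if (!is.null(b)) {
    a <- pairs
    if (any(a$contig_id != b$contig_id)) {
      abort_usage("intergenic_distance: genes lie on different contigs")
    }
    return(as.integer(b$start - a$end - 1L))
  }
  if (any(pairs$contig_id != pairs$contig_id)) abort_usage("inconsistent contigs")
  as.integer(pairs$start_b - pairs$end_a - 1L)
}

#' Strand orientation of a gene pair
#'
#' @param pairs Pair tibble, or a one-row gene tibble when `b` is supplied.
#' @param b Optional second gene.
#' @return Character vector, `"same"` or `"opposite"`.
#' @export
strand_orientation <- function(pairs, b = NULL) {
  if (!is.null(b)) return(ifelse(pairs$strand == b$strand, "same", "opposite"))
  ifelse(pairs$strand_a == pairs$strand_b, "same", "opposite")
}

#' GC content of a nucleotide sequence, in percent
#'
#' Case-insensitive; ambiguity codes are excluded from both numerator and
#' denominator. Strand-symmetric (G+C is preserved by reverse complement).
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  gc <- stringr::str_count(seq, "[GgCc]")
  at <- stringr::str_count(seq, "[AaTt]")
  den <- gc + at
  if (any(den == 0L)) {
    abort_usage("gc_percent: sequence contains no unambiguous A/C/G/T bases")
  }
  100 * gc / den
}

gene_span_seq <- function(contigs, contig_id, start, end) {
  seqs <- unname(contigs[contig_id])
  if (anyNA(seqs)) {
    abort_usage(sprintf("contig '%s' not present in supplied sequences",
                        contig_id[which(is.na(seqs))[1]]))
  }
  too_long <- end > nchar(seqs)
  if (any(too_long)) {
    abort_usage(sprintf("gene span exceeds contig length on '%s'",
                        contig_id[which(too_long)[1]]))
  }
  substring(seqs, start, end)
}

#' Absolute GC-content difference of a gene pair
#'
#' GC is computed on each annotated gene span of the forward contig sequence
#' (strand is irrelevant for GC); the result is the absolute difference in
#' percentage points, rounded to 2 decimals.
#'
#' @param pairs Pair tibble, or a one-row gene tibble when `b` is supplied.
#' @param contigs Named character vector of contig sequences.
#' @param b Optional second gene.
#' @return Numeric vector in `[0, 100]`.
#' @export
gc_difference <- function(pairs, contigs, b = NULL) {
  if (!is.null(b)) {
    a <- pairs
    ga <- gc_percent(gene_span_seq(contigs, a$contig_id, a$start, a$end))
    gb <- gc_percent(gene_span_seq(contigs, b$contig_id, b$start, b$end))
    return(round(abs(ga - gb), 2))
  }
  ga <- gc_percent(gene_span_seq(contigs, pairs$contig_id, pairs$start_a, pairs$end_a))
  gb <- gc_percent(gene_span_seq(contigs, pairs$contig_id, pairs$start_b, pairs$end_b))
  round(abs(ga - gb), 2)
}

family_key <- function(fam_a, fam_b) {
  paste(pmin(fam_a, fam_b), pmax(fam_a, fam_b), sep = "\t")
}

#' Build a family-pair adjacency conservation index over a genome panel
#'
#' For every genome in the panel and every adjacent gene pair in which both
#' genes carry a non-empty protein-family identifier, the unordered family
#' pair records that genome once (multiple occurrences within one genome
#' still count once). The index supports the conservation feature: the
#' percentage of panel genomes in which a homologous (same-family) pair is
#' adjacent.
#'
#' @param panel Either a gene tibble covering one or more genomes (with a
#'   `genome_id` column) or a list of genome records, each a list with a
#'   `genes` element.
#' @return An object of class `adjacency_index` with fields `panel_size`,
#'   `genomes`, `presence` (named list: family-pair key to genome set),
#'   `counts` and `family_genomes`.
#' @export
build_adjacency_index <- function(panel) {
  genes <- if (is.data.frame(panel)) panel else {
    dplyr::bind_rows(lapply(panel, function(x) if (is.data.frame(x)) x else x$genes))
  }
  if (is.null(genes) || nrow(genes) == 0L) abort_usage("empty genome panel")
  pairs <- adjacent_pairs(genes)
  pp <- pairs[nzchar(pairs$family_a) & nzchar(pairs$family_b), , drop = FALSE]
  pres <- dplyr::distinct(tibble::tibble(
    key = family_key(pp$family_a, pp$family_b),
    genome_id = pp$genome_id
  ))
  presence <- split(pres$genome_id, pres$key)
  fam <- dplyr::distinct(tibble::tibble(
    family_id = c(genes$family_id[nzchar(genes$family_id)]),
    genome_id = genes$genome_id[nzchar(genes$family_id)]
  ))
  structure(
    list(
      panel_size = dplyr::n_distinct(genes$genome_id),
      genomes = sort(unique(genes$genome_id)),
      presence = presence,
      counts = vapply(presence, length, integer(1)),
      family_genomes = split(fam$genome_id, fam$family_id)
    ),
    class = "adjacency_index"
  )
}

#' @export
print.adjacency_index <- function(x, ...) {
  cat(sprintf("<adjacency_index> %d family pairs over %d genomes\n",
              length(x$counts), x$panel_size))
  invisible(x)
}

#' Adjacency conservation percentage for a family pair
#'
#' Order-insensitive in the two families; unknown or empty families yield 0.
#' The default denominator is the full panel size (the serialized sentence
#' reads "adjacent in X% of representative genomes"); `denominator =
#' "shared"` instead divides by the number of genomes containing both
#' families.
#'
#' @param index An [build_adjacency_index()] result.
#' @param fam_a,fam_b Character vectors of family identifiers (recycled).
#' @param denominator `"panel"` (default) or `"shared"`.
#' @return Numeric vector of percentages in `[0, 100]`, rounded to 1 decimal.
#' @export
adjacency_percent <- function(index, fam_a, fam_b,
                              denominator = c("panel", "shared")) {
  denominator <- match.arg(denominator)
  n <- unname(index$counts[family_key(fam_a, fam_b)])
  n[is.na(n)] <- 0L
  n[!nzchar(fam_a) | !nzchar(fam_b)] <- 0L
  if (denominator == "panel") {
    den <- rep(index$panel_size, length(n))
  } else {
    den <- mapply(function(a, b) {
      if (!nzchar(a) || !nzchar(b)) return(0L)
      length(intersect(index$family_genomes[[a]], index$family_genomes[[b]]))
    }, fam_a, fam_b, USE.NAMES = FALSE)
  }
  out <- ifelse(den > 0, round(100 * n / den, 1), 0)
  pmin(pmax(out, 0), 100)
}

#' Persist an adjacency index
#'
#' Writes a tab-delimited table `family_a, family_b, n_genomes_adjacent,
#' panel_size` plus a JSON sidecar (`<path>.json`) with panel metadata.
#'
#' @param index An `adjacency_index`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency_index <- function(index, path) {
  keys <- names(index$counts)
  fams <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
  tab <- tibble::tibble(
    family_a = if (length(keys)) fams[, 1] else character(),
    family_b = if (length(keys)) fams[, 2] else character(),
    n_genomes_adjacent = unname(index$counts),
    panel_size = index$panel_size
  )
  readr::write_tsv(tab, path, progress = FALSE)
  jsonlite::write_json(
    list(panel_size = index$panel_size, genomes = index$genomes,
         family_genomes = index$family_genomes),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a persisted adjacency index
#'
#' @param path Path written by [write_adjacency_index()].
#' @return An `adjacency_index` (presence sets are restored as counts).
#' @export
read_adjacency_index <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ccii", progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  counts <- tab$n_genomes_adjacent
  names(counts) <- family_key(tab$family_a, tab$family_b)
  fg <- lapply(meta$family_genomes, as.character)
  structure(
    list(panel_size = meta$panel_size, genomes = as.character(meta$genomes),
         presence = NULL, counts = counts, family_genomes = fg),
    class = "adjacency_index"
  )
}

#' Read a STRING combined-score table
#'
#' Tab-delimited with header `gene_a, gene_b, combined_score`.
#'
#' @param path Path to the score table.
#' @return Tibble of pairwise scores.
#' @export
read_string_scores <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("STRING score table not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(), gene_b = readr::col_character(),
    combined_score = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(c("gene_a", "gene_b", "combined_score"), names(tab))
  if (length(missing)) {
    abort_format(sprintf("STRING table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  tab
}

# Ordered lookup with fallback to the reversed key.
string_lookup <- function(scores, gene_a, gene_b) {
  if (is.null(scores) || nrow(scores) == 0L) return(rep(NA_real_, length(gene_a)))
  fwd <- scores$combined_score[match(paste0(gene_a, "|", gene_b),
                                     paste0(scores$gene_a, "|", scores$gene_b))]
  rev <- scores$combined_score[match(paste0(gene_b, "|", gene_a),
                                     paste0(scores$gene_a, "|", scores$gene_b))]
  dplyr::coalesce(fwd, rev)
}

#' Compute all per-pair features
#'
#' Adds the serializable feature columns to a pair tibble: gene lengths,
#' functional annotations, families, signed intergenic distance, absolute GC
#' difference, strand orientation, adjacency conservation percentage, and the
#' optional STRING combined score (`NA` when no score is available).
#'
#' @param pairs Pair tibble from [adjacent_pairs()] or [label_pairs()].
#' @param contigs Named character vector of contig sequences covering every
#'   contig referenced by `pairs`.
#' @param index Optional `adjacency_index`; without it conservation is 0.
#' @param string_scores Optional score tibble from [read_string_scores()].
#' @param denominator Conservation denominator, see [adjacency_percent()].
#' @return The input tibble with feature columns `length_a`, `length_b`,
#'   `function_a`, `function_b`, `distance`, `gc_diff`, `strand_orientation`,
#'   `adjacency_percent`, `string_score` appended.
#' @export
pair_features <- function(pairs, contigs, index = NULL, string_scores = NULL,
                          denominator = c("panel", "shared")) {
  denominator <- match.arg(denominator)
  out <- pairs
  out$length_a <- as.integer(pairs$end_a - pairs$start_a + 1L)
  out$length_b <- as.integer(pairs$end_b - pairs$start_b + 1L)
  out$function_a <- pairs$product_a
  out$function_b <- pairs$product_b
  out$distance <- as.integer(pairs$start_b - pairs$end_a - 1L)
  out$gc_diff <- if (nrow(pairs)) gc_difference(pairs, contigs) else numeric()
  out$strand_orientation <- strand_orientation(pairs)
  out$adjacency_percent <- if (is.null(index)) rep(0, nrow(pairs)) else {
    adjacency_percent(index, pairs$family_a, pairs$family_b, denominator)
  }
  out$string_score <- string_lookup(string_scores, pairs$gene_a, pairs$gene_b)
  out
}
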