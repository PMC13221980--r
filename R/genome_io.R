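#' Read a FASTA file into a named vector of contig sequences
#'
#' Sequences are uppercased and the header token before the first whitespace
#' is used as the contig identifier, matching how coordinates in annotation
#' files reference contigs.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector mapping `contig_id` to an uppercase
#'   nucleotide sequence.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">c1 some description", "acgtACGT", ">c2", "GGCC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort_format(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(seqs) == 0L) abort_format(sprintf("FASTA '%s' contains no records", path))
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

# Required columns of the BV-BRC features.tab dialect consumed here.
features_tab_columns <- c(
  "genome_id", "patric_id", "sequence_id", "feature_type",
  "start", "end", "strand", "product", "pgfam_id"
)

parse_strand <- function(x, rows) {
  out <- dplyr::case_when(
    x %in% c("+", "forward") ~ "forward",
    x %in% c("-", "reverse") ~ "reverse",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) abort_row("unrecognized strand value", rows[which(is.na(out))[1]])
  out
}

parse_coord <- function(x, what, rows) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) | as.character(v) != trimws(x)
  if (any(bad)) abort_row(sprintf("non-integer %s coordinate", what), rows[which(bad)[1]])
  v
}

validate_genes <- function(genes, rows) {
  bad <- which(genes$start < 1L)
  if (length(bad)) abort_row("start coordinate < 1", rows[bad[1]])
  bad <- which(genes$end < genes$start)
  if (length(bad)) abort_row("end coordinate precedes start", rows[bad[1]])
  genes
}

#' Read gene annotations in the BV-BRC features.tab dialect
#'
#' Expects a tab-delimited file with a header naming at least
#' `genome_id, patric_id, sequence_id, feature_type, start, end, strand,
#' product, pgfam_id`; extra columns are ignored. Coordinates are 1-based
#' inclusive and kept as such throughout the package.
#'
#' @param path Path to the tab-delimited annotation file.
#' @param keep_types Feature types to retain (default `"CDS"`).
#' @return A tibble of genes with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand` (`"forward"`/`"reverse"`), `product`,
#'   `family_id`, `feature_type`. Missing products/families become `""`.
#' @export
read_features_tab <- function(path, keep_types = "CDS") {
  if (!file.exists(path)) abort_format(sprintf("annotation file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(features_tab_columns, names(raw))
  if (length(missing)) {
    abort_format(sprintf("features.tab '%s' lacks mandatory column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  raw$.row <- seq_len(nrow(raw))
  raw <- raw[raw$feature_type %in% keep_types, , drop = FALSE]
  genes <- tibble::tibble(
    gene_id = raw$patric_id,
    genome_id = raw$genome_id,
    contig_id = raw$sequence_id,
    start = parse_coord(raw$start, "start", raw$.row),
    end = parse_coord(raw$end, "end", raw$.row),
    strand = parse_strand(raw$strand, raw$.row),
    product = dplyr::coalesce(raw$product, ""),
    family_id = dplyr::coalesce(raw$pgfam_id, ""),
    feature_type = raw$feature_type
  )
  validate_genes(genes, raw$.row)
}

#' Write genes to the features.tab dialect
#'
#' Inverse of [read_features_tab()]; round-trips losslessly.
#'
#' @param genes Gene tibble as returned by [read_features_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tab <- function(genes, path) {
  out <- tibble::tibble(
    genome_id = genes$genome_id,
    patric_id = genes$gene_id,
    sequence_id = genes$contig_id,
    feature_type = genes$feature_type,
    start = genes$start,
    end = genes$end,
    strand = ifelse(genes$strand == "forward", "+", "-"),
    product = genes$product,
    pgfam_id = genes$family_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Functional annotation is taken from the `product` attribute and the protein
#' family from a configurable attribute key. Coordinates stay 1-based
#' inclusive as in the GFF3 specification.
#'
#' @param path Path to a GFF3 file.
#' @param keep_types Feature types to retain (default `"CDS"`).
#' @param family_attr Attribute key holding the protein-family identifier
#'   (default `"pgfam"`).
#' @param genome_id Genome identifier to assign (GFF3 carries none); defaults
#'   to the file name without extension.
#' @return Gene tibble with the same schema as [read_features_tab()].
#' @export
read_gff3 <- function(path, keep_types = "CDS", family_attr = "pgfam",
                      genome_id = NULL) {
  if (!file.exists(path)) abort_format(sprintf("GFF3 file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (any(grepl("^##FASTA", lines))) {
    fasta_at <- which(grepl("^##FASTA", lines))[1]
    data_idx <- data_idx[data_idx < fasta_at]
  }
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) abort_format(sprintf("GFF3 '%s' line %d does not have 9 fields", path, i))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) abort_row("non-integer coordinate in GFF3", i)
    if (s > e) abort_row("GFF3 start coordinate exceeds end", i)
  }
  if (length(data_idx) == 0L) abort_format(sprintf("GFF3 '%s' contains no feature lines", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort_format(sprintf("malformed GFF3 '%s': %s", path, conditionMessage(e)))
  )
  gr <- gr[as.character(gr$type) %in% keep_types]
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(key) {
    if (key %in% names(mc)) {
      v <- mc[[key]]
      if (is(v, "CharacterList") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x)) paste(x, collapse = ",") else "", character(1))
      }
      dplyr::coalesce(as.character(v), "")
    } else rep("", length(gr))
  }
  ids <- get_attr("ID")
  ids[!nzchar(ids)] <- sprintf("gff_feature_%d", which(!nzchar(ids)))
  gid <- genome_id %||% sub("\\.(gff3?|gff)$", "", basename(path))
  genes <- tibble::tibble(
    gene_id = ids,
    genome_id = gid,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "reverse", "forward"),
    product = get_attr("product"),
    family_id = get_attr(family_attr),
    feature_type = as.character(gr$type)
  )
  validate_genes(genes, seq_len(nrow(genes)))
}

#' Read an operon annotation table
#'
#' Tab-delimited with header `genome_id, operon_id, gene_ids`; `gene_ids` is a
#' comma-separated list in order of transcription (style of the ODB "Known
#' Operons" tables).
#'
#' @param path Path to the table.
#' @return Tibble with `genome_id`, `operon_id` and a list-column `gene_ids`.
#' @export
read_operon_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("operon table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(c("genome_id", "operon_id", "gene_ids"), names(raw))
  if (length(missing)) {
    abort_format(sprintf("operon table '%s' lacks column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  key <- paste(raw$genome_id, raw$operon_id)
  if (anyDuplicated(key)) abort_row("duplicate operon_id within genome", anyDuplicated(key))
  gene_ids <- lapply(strsplit(dplyr::coalesce(raw$gene_ids, ""), ","), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  empty <- which(lengths(gene_ids) == 0L)
  if (length(empty)) abort_row("operon with empty gene list", empty[1])
  tibble::tibble(genome_id = raw$genome_id, operon_id = raw$operon_id,
                 gene_ids = gene_ids)
}

#' Write an operon annotation table
#'
#' @param operons Operon tibble as returned by [read_operon_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_operon_table <- function(operons, path) {
  out <- tibble::tibble(
    genome_id = operons$genome_id,
    operon_id = operons$operon_id,
    gene_ids = vapply(operons$gene_ids, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

pair_schema_empty <- function() {
  tibble::tibble(
    pair_id = character(), genome_id = character(), contig_id = character(),
    gene_a = character(), start_a = integer(), end_a = integer(),
    strand_a = character(), product_a = character(), family_a = character(),
    gene_b = character(), start_b = integer(), end_b = integer(),
    strand_b = character(), product_b = character(), family_b = character()
  )
}

make_pairs <- function(a, b) {
  tibble::tibble(
    pair_id = paste0(a$genome_id, ":", a$gene_id, "|", b$gene_id),
    genome_id = a$genome_id, contig_id = a$contig_id,
    gene_a = a$gene_id, start_a = a$start, end_a = a$end,
    strand_a = a$strand, product_a = a$product, family_a = a$family_id,
    gene_b = b$gene_id, start_b = b$start, end_b = b$end,
    strand_b = b$strand, product_b = b$product, family_b = b$family_id
  )
}

#' Enumerate adjacent gene pairs
#'
#' Genes are sorted by `(contig_id, start, end, gene_id)` and consecutive
#' genes on the same contig are paired in coordinate order; pairs never span
#' contigs (or genomes), so a contig with n genes yields n - 1 pairs. The
#' result is invariant to the input row order.
#'
#' @param genes Gene tibble (one or several genomes).
#' @return Tibble of pairs with per-gene columns suffixed `_a`/`_b` and a
#'   `pair_id` of the form `"genome:geneA|geneB"`.
#' @export
adjacent_pairs <- function(genes) {
  if (nrow(genes) < 2L) return(pair_schema_empty())
  g <- dplyr::arrange(genes, .data$genome_id, .data$contig_id, .data$start,
                      .data$end, .data$gene_id)
  a <- g[-nrow(g), , drop = FALSE]
  b <- g[-1L, , drop = FALSE]
  keep <- a$genome_id == b$genome_id & a$contig_id == b$contig_id
  if (!any(keep)) return(pair_schema_empty())
  make_pairs(a[keep, , drop = FALSE], b[keep, , drop = FALSE])
}
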