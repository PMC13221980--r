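# Coordinate-order comparison used to orient emitted pairs: a gene precedes
# another iff its (start, end, gene_id) sorts first.
precedes <- function(a, b) {
  (a$start < b$start) |
    (a$start == b$start & a$end < b$end) |
    (a$start == b$start & a$end == b$end & a$gene_id < b$gene_id)
}

#' Label adjacent gene pairs from operon annotations
#'
#' Positive (operonic) pairs are the consecutive gene pairs within each
#' multi-gene operon (an operon of k genes yields k - 1 positives). Negative
#' (non-operonic) pairs pair the terminal gene of each annotated operon —
#' including single-gene operons — with its immediately adjacent downstream
#' genomic neighbour outside the operon boundary, where "downstream" follows
#' the transcription direction of the terminal gene (forward strand: the
#' neighbour with the next-higher start; reverse strand: the next-lower). A
#' terminal gene at a contig end emits no negative. Every emitted pair is
#' stored in coordinate order; duplicates are removed with the positive label
#' taking precedence.
#'
#' @param genes Gene tibble for one genome.
#' @param operons Operon tibble (see [read_operon_table()]) for that genome.
#' @return Labeled pair tibble: the [adjacent_pairs()] schema plus a `label`
#'   column with values `"operonic"` / `"non_operonic"`.
#' @export
label_pairs <- function(genes, operons) {
  if (nrow(operons) == 0L) {
    out <- pair_schema_empty()
    out$label <- character()
    return(out)
  }
  g <- dplyr::arrange(genes, .data$contig_id, .data$start, .data$end, .data$gene_id)
  g$.pos <- stats::ave(seq_len(nrow(g)), g$contig_id, FUN = seq_along)
  row_of <- function(ids) {
    idx <- match(ids, g$gene_id)
    if (anyNA(idx)) {
      abort_annotation(sprintf("operon references unknown gene id(s): %s",
                               paste(ids[is.na(idx)], collapse = ", ")))
    }
    idx
  }

  acc_a <- integer(); acc_b <- integer(); acc_lab <- character()
  for (i in seq_len(nrow(operons))) {
    ids <- operons$gene_ids[[i]]
    idx <- tryCatch(row_of(ids), error = function(e) {
      rlang::abort(sprintf("operon '%s': %s", operons$operon_id[i], conditionMessage(e)),
                   class = "operotext_annotation_error")
    })
    if (length(idx) >= 2L) {
      acc_a <- c(acc_a, idx[-length(idx)])
      acc_b <- c(acc_b, idx[-1L])
      acc_lab <- c(acc_lab, rep("operonic", length(idx) - 1L))
    }
    # Boundary negative from the terminal (last transcribed) gene.
    term <- idx[length(idx)]
    dir <- if (g$strand[term] == "forward") 1L else -1L
    nb <- which(g$contig_id == g$contig_id[term] & g$.pos == g$.pos[term] + dir)
    if (length(nb) == 1L && !(g$gene_id[nb] %in% ids)) {
      acc_a <- c(acc_a, term)
      acc_b <- c(acc_b, nb)
      acc_lab <- c(acc_lab, "non_operonic")
    }
  }
  if (length(acc_a) == 0L) {
    out <- pair_schema_empty()
    out$label <- character()
    return(out)
  }
  # Orient each pair in coordinate order.
  swap <- !precedes(g[acc_a, ], g[acc_b, ])
  first <- ifelse(swap, acc_b, acc_a)
  second <- ifelse(swap, acc_a, acc_b)
  out <- make_pairs(g[first, , drop = FALSE], g[second, , drop = FALSE])
  out$label <- acc_lab
  # Deduplicate on the unordered gene pair; operonic wins.
  out <- dplyr::arrange(out, .data$label != "operonic")
  out <- out[!duplicated(out$pair_id), , drop = FALSE]
  dplyr::arrange(out, .data$contig_id, .data$start_a, .data$end_a, .data$gene_a)
}

#' Intersect two operon annotation sets
#'
#' Keeps operons of the first set whose gene-id sets appear (as identical
#' sets, order-insensitively) in the second, the construction used for
#' high-confidence benchmark test sets confirmed in two databases.
#'
#' @param db_a,db_b Operon tibbles for the same genome.
#' @return The matching rows of `db_a`.
#' @export
intersect_operons <- function(db_a, db_b) {
  set_key <- function(db) {
    paste(db$genome_id,
          vapply(db$gene_ids, function(x) paste(sort(unique(x)), collapse = ","),
                 character(1)))
  }
  db_a[set_key(db_a) %in% set_key(db_b), , drop = FALSE]
}

# Largest-remainder stratified draw: per-genome validation quotas that sum
# exactly to round(val_frac * n).
stratified_take <- function(genome_ids, val_frac) {
  n_val <- round(val_frac * length(genome_ids))
  tab <- table(genome_ids)
  quota <- val_frac * as.numeric(tab)
  base <- floor(quota)
  names(base) <- names(tab)
  extra <- n_val - sum(base)
  if (extra > 0) {
    rem_order <- order(quota - base, decreasing = TRUE)
    base[rem_order[seq_len(extra)]] <- base[rem_order[seq_len(extra)]] + 1
  } else if (extra < 0) {
    rem_order <- order(quota - base)
    take <- rem_order[base[rem_order] > 0][seq_len(-extra)]
    base[take] <- base[take] - 1
  }
  take_val <- logical(length(genome_ids))
  for (gname in names(tab)) {
    idx <- which(genome_ids == gname)
    k <- base[[gname]]
    if (k > 0) take_val[idx[seq_len(k)]] <- TRUE
  }
  take_val
}

#' Leave-one-species-out split
#'
#' All pairs of the held-out genome form the test set; the remaining pairs
#' are split into train/validation by a seeded uniform shuffle, with the
#' validation draw stratified by genome so every training genome contributes.
#' No held-out pair ever enters train or validation.
#'
#' @param pairs Labeled pair tibble covering at least two genomes.
#' @param held_out Genome id to hold out.
#' @param val_frac Fraction of the non-held-out pairs used for validation
#'   (default 0.1).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with elements `train`, `val`, `test`.
#' @export
loso_split <- function(pairs, held_out, val_frac = 0.1, seed = 1L) {
  if (!held_out %in% pairs$genome_id) {
    abort_usage(sprintf("held-out genome '%s' absent from pairs", held_out))
  }
  if (dplyr::n_distinct(pairs$genome_id) < 2L) {
    abort_usage("LOSO split needs at least two genomes")
  }
  test <- pairs[pairs$genome_id == held_out, , drop = FALSE]
  rest <- pairs[pairs$genome_id != held_out, , drop = FALSE]
  withr::with_seed(seed, {
    rest <- rest[sample.int(nrow(rest)), , drop = FALSE]
  })
  is_val <- stratified_take(rest$genome_id, val_frac)
  list(train = rest[!is_val, , drop = FALSE],
       val = rest[is_val, , drop = FALSE],
       test = test)
}

#' Random train/validation/test split
#'
#' Seeded shuffle followed by contiguous slicing into the given fractions
#' (default 80/10/10); the partition is exhaustive and disjoint.
#'
#' @param pairs Labeled pair tibble.
#' @param fractions Numeric triple summing to 1.
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test`.
#' @export
random_split <- function(pairs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    abort_usage("fractions must be three non-negative values summing to 1")
  }
  n <- nrow(pairs)
  withr::with_seed(seed, {
    shuffled <- pairs[sample.int(n), , drop = FALSE]
  })
  n_train <- round(fractions[1] * n)
  n_val <- min(round(fractions[2] * n), n - n_train)
  list(train = shuffled[seq_len(n_train), , drop = FALSE],
       val = shuffled[seq_len(n_val) + n_train, , drop = FALSE],
       test = shuffled[seq(n_train + n_val + 1, length.out = n - n_train - n_val), , drop = FALSE])
}

#' Write a labeled pair table
#'
#' Tab-delimited with the full pair/feature schema; list columns are not
#' expected.
#'
#' @param pairs Labeled (optionally featurized) pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Read a labeled pair table written by [write_pair_table()]
#'
#' @param path Input path.
#' @return Pair tibble with coordinate and feature columns restored to their
#'   native types.
#' @export
read_pair_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE)
  for (col in c("start_a", "end_a", "start_b", "end_b", "length_a", "length_b", "distance")) {
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  }
  tab
}
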