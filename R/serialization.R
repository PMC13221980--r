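#' Feature mask controlling which template clauses are serialized
#'
#' The baseline features (gene lengths, intergenic distance, GC difference,
#' strand orientation) are always included and cannot be masked off; the mask
#' controls the functional-annotation clauses, the protein-family clauses, the
#' conservation sentence, and the optional STRING sentence.
#'
#' @param include_function Include the "annotated as ..." clauses.
#' @param include_family Include the "is part of the ... family" clauses.
#' @param include_conservation Include the adjacency-conservation sentence.
#' @param include_string Append the STRING score sentence when a score exists.
#' @return An object of class `feature_mask`.
#' @export
feature_mask <- function(include_function = TRUE, include_family = TRUE,
                         include_conservation = TRUE, include_string = FALSE) {
  structure(
    list(include_function = isTRUE(include_function),
         include_family = isTRUE(include_family),
         include_conservation = isTRUE(include_conservation),
         include_string = isTRUE(include_string)),
    class = "feature_mask"
  )
}

#' @export
print.feature_mask <- function(x, ...) {
  on <- names(which(vapply(x, isTRUE, logical(1))))
  cat("<feature_mask> baseline +", if (length(on)) paste(sub("include_", "", on), collapse = ", ") else "nothing extra", "\n")
  invisible(x)
}

#' Named feature-mask presets
#'
#' `mask_preset("full")` is the full non-STRING configuration used for the
#' main evaluations; `"baseline"` keeps only the sequence-derived features;
#' `"full_string"` additionally appends STRING sentences.
#'
#' @param name One of `"full"`, `"baseline"`, `"full_string"`.
#' @return A `feature_mask`.
#' @export
mask_preset <- function(name = c("full", "baseline", "full_string")) {
  name <- match.arg(name)
  switch(name,
    full = feature_mask(TRUE, TRUE, TRUE, FALSE),
    baseline = feature_mask(FALSE, FALSE, FALSE, FALSE),
    full_string = feature_mask(TRUE, TRUE, TRUE, TRUE)
  )
}

# Fixed-decimal rounding followed by trailing-zero trimming, so serialization
# is byte-deterministic: 1.25 -> "1.25", 1.20 -> "1.2", 75.0 -> "75".
fmt_dec <- function(x, digits) {
  s <- formatC(round(x, digits), format = "f", digits = digits)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  s[s == "-0"] <- "0"
  s
}

fmt_int <- function(x) {
  as.character(as.integer(x))
}

#' Serialize gene-pair features into natural-language paragraphs
#'
#' Instantiates the deterministic template: *"Gene A is \{length_A\} bp long,
#' annotated as '\{function_A\}', and is part of the \{family_A\} family. It
#' is followed by Gene B, \{length_B\} bp long, annotated as '\{function_B\}',
#' and is part of the \{family_B\} family. The intergenic distance is
#' \{distance\} base pairs. The GC content difference is \{gc_diff\}%. They
#' are on the \{strand_orientation\} strand. They are adjacent in
#' \{adjacency_percent\}% of representative genomes."* Numerical values are
#' inserted directly without discretization; masked features are removed as
#' whole clauses/sentences; an empty functional annotation or family drops its
#' clause exactly as a masked feature would. When the mask includes STRING and
#' a score is present, one sentence is appended: *"STRING reports a combined
#' interaction score of \{score\} between these genes."*
#'
#' @param features Feature tibble from [pair_features()] (a `label` column,
#'   if present, is carried through).
#' @param mask A [feature_mask()].
#' @return Tibble with `pair_id`, `genome_id`, optional `label`, and `text`.
#' @export
serialize_pairs <- function(features, mask = feature_mask()) {
  f <- features
  clause_fn <- function(fun) {
    ifelse(mask$include_function & nzchar(fun),
           paste0(", annotated as '", fun, "'"), "")
  }
  clause_fam <- function(fam) {
    ifelse(mask$include_family & nzchar(fam),
           paste0(", and is part of the ", fam, " family"), "")
  }
  s1 <- paste0("Gene A is ", fmt_int(f$length_a), " bp long",
               clause_fn(f$function_a), clause_fam(f$family_a), ".")
  s2 <- paste0("It is followed by Gene B, ", fmt_int(f$length_b), " bp long",
               clause_fn(f$function_b), clause_fam(f$family_b), ".")
  s3 <- paste0("The intergenic distance is ", fmt_int(f$distance), " base pairs.")
  s4 <- paste0("The GC content difference is ", fmt_dec(f$gc_diff, 2), "%.")
  s5 <- paste0("They are on the ", f$strand_orientation, " strand.")
  s6 <- if (mask$include_conservation) {
    paste0(" They are adjacent in ", fmt_dec(f$adjacency_percent, 1),
           "% of representative genomes.")
  } else ""
  s7 <- if (mask$include_string) {
    ifelse(!is.na(f$string_score),
           paste0(" ", string_sentence(f$string_score)), "")
  } else ""
  out <- tibble::tibble(
    pair_id = f$pair_id, genome_id = f$genome_id,
    text = paste0(s1, " ", s2, " ", s3, " ", s4, " ", s5, s6, s7)
  )
  if ("label" %in% names(f)) out <- dplyr::mutate(out, label = f$label, .before = "text")
  out
}

string_sentence <- function(score) {
  paste0("STRING reports a combined interaction score of ", fmt_dec(score, 1),
         " between these genes.")
}

#' Serialize a single gene pair
#'
#' Convenience wrapper around [serialize_pairs()] for one feature row.
#'
#' @param features One-row feature tibble (or list coercible to one).
#' @param mask A [feature_mask()].
#' @return The serialized paragraph as a length-1 character vector.
#' @export
serialize_pair <- function(features, mask = feature_mask()) {
  f <- tibble::as_tibble(features)
  if (!"pair_id" %in% names(f)) f$pair_id <- "pair"
  if (!"genome_id" %in% names(f)) f$genome_id <- "genome"
  if (!"string_score" %in% names(f)) f$string_score <- NA_real_
  serialize_pairs(f, mask)$text
}

#' Render the STRING score sentence for one pair
#'
#' @param features One-row feature tibble with a non-missing `string_score`.
#' @return The appended sentence as a character scalar.
#' @export
render_string_sentence <- function(features) {
  score <- features$string_score
  if (length(score) != 1L || is.na(score)) {
    abort_usage("render_string_sentence: pair has no STRING score")
  }
  string_sentence(score)
}

#' Write a serialized corpus
#'
#' Tab-delimited `pair_id, genome_id, label, text` (and, with
#' `format = "jsonl"`, one JSON object per line).
#'
#' @param corpus Tibble from [serialize_pairs()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(corpus, path, progress = FALSE)
  } else {
    writeLines(vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(as.list(corpus[i, ]), auto_unbox = TRUE)
    }, character(1)), path)
  }
  invisible(path)
}

#' Read a serialized corpus written by [write_corpus()]
#'
#' @param path Path to a TSV corpus.
#' @return Corpus tibble.
#' @export
read_corpus <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
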