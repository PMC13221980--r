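#' Average precision (PR-AUC) of the operonic class
#'
#' Step-function average precision with no interpolation: tied scores are
#' grouped, and precision at each recall step is weighted by the recall
#' increment. Invariant to strictly monotone transformations of the scores.
#'
#' @param labels Labels (`"operonic"`/`"non_operonic"`, logical, or 0/1).
#' @param scores Numeric scores, higher meaning more operonic.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  y <- as_binary_label(labels)
  if (sum(y) == 0L) abort_usage("average precision undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- y[o]
  n <- length(y)
  last_of_group <- c(s[-1] != s[-n], TRUE)
  tp <- cumsum(y)[last_of_group]
  k <- seq_len(n)[last_of_group]
  prec <- tp / k
  rec <- tp / sum(y)
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Binary classification metrics for gene-pair predictions
#'
#' Computes sensitivity, specificity, precision, F1, accuracy (all as
#' percentages) and PR-AUC (average precision of the operonic class, as a
#' percentage) at a fixed threshold: a pair is called operonic when its score
#' is at least `threshold`.
#'
#' @param labels True labels (`"operonic"`/`"non_operonic"`, logical, or 0/1);
#'   both classes must be present.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @param context Optional label describing the evaluation cell (genome,
#'   feature set, mask).
#' @return One-row tibble of class `operotext_metrics`.
#' @export
binary_metrics <- function(labels, scores, threshold = 0.5, context = NA_character_) {
  if (length(labels) != length(scores)) abort_usage("labels and scores differ in length")
  y <- as_binary_label(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L) abort_usage("sensitivity undefined: no operonic pairs in input")
  if (n_neg == 0L) abort_usage("specificity undefined: no non-operonic pairs in input")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  out <- tibble::tibble(
    context = context,
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    precision = 100 * prec,
    f1 = 100 * f1,
    accuracy = 100 * (tp + tn) / length(y),
    pr_auc = 100 * average_precision(y, scores),
    n_pos = n_pos,
    n_neg = n_neg
  )
  as_metrics(out)
}

as_metrics <- function(x) {
  class(x) <- c("operotext_metrics", setdiff(class(x), "operotext_metrics"))
  x
}

serialize_or_die <- function(pairs, mask) {
  need <- c("length_a", "distance", "gc_diff", "strand_orientation")
  if (!all(need %in% names(pairs))) {
    abort_usage("pairs lack feature columns; run pair_features() first")
  }
  serialize_pairs(pairs, mask)
}

#' Leave-one-species-out evaluation
#'
#' For each genome in turn: hold out all of its pairs, split the rest into
#' train/validation, serialize under the mask, train, score the held-out
#' genome, and compute metrics. The default mask is the full non-STRING
#' configuration.
#'
#' @param pairs Labeled, featurized pair tibble covering >= 2 genomes.
#' @param config A [classifier_config()].
#' @param mask Training/evaluation [feature_mask()].
#' @param val_frac Validation fraction within each fold.
#' @return Metrics tibble, one row per genome (`context` = held-out genome).
#' @export
run_loso <- function(pairs, config = classifier_config(), mask = mask_preset("full"),
                     val_frac = 0.1) {
  genomes <- sort(unique(pairs$genome_id))
  if (length(genomes) < 2L) abort_usage("LOSO evaluation needs at least two genomes")
  rows <- lapply(genomes, function(g) {
    sp <- loso_split(pairs, g, val_frac = val_frac, seed = config$seed)
    model <- train_classifier(serialize_or_die(sp$train, mask),
                              serialize_or_die(sp$val, mask), config, mask)
    test <- serialize_or_die(sp$test, mask)
    binary_metrics(test$label, predict_scores(model, test$text),
                   config$threshold, context = g)
  })
  as_metrics(dplyr::bind_rows(rows))
}

#' The feature-ablation mask ladder
#'
#' The six progressively enriched configurations evaluated in the ablation
#' analysis, from the sequence-derived baseline to the fully enriched
#' STRING-bearing set.
#'
#' @return Named list of [feature_mask()] objects in evaluation order.
#' @export
ablation_masks <- function() {
  list(
    "Baseline" = feature_mask(FALSE, FALSE, FALSE, FALSE),
    "+Function" = feature_mask(TRUE, FALSE, FALSE, FALSE),
    "+Conservation" = feature_mask(FALSE, FALSE, TRUE, FALSE),
    "+Function+Conservation" = feature_mask(TRUE, FALSE, TRUE, FALSE),
    "+Function+Conservation+Family" = feature_mask(TRUE, TRUE, TRUE, FALSE),
    "+Function+Conservation+Family+String" = feature_mask(TRUE, TRUE, TRUE, TRUE)
  )
}

#' Feature-ablation evaluation
#'
#' Trains and evaluates one model per feature mask on a shared mixed-species
#' split (same seed for every mask, so differences reflect features rather
#' than partitioning).
#'
#' @param pairs Labeled, featurized pair tibble.
#' @param config A [classifier_config()].
#' @param masks Named list of masks (default [ablation_masks()]).
#' @param fractions Train/val/test fractions for the shared split.
#' @return Metrics tibble, one row per mask in the given order.
#' @export
run_ablation <- function(pairs, config = classifier_config(),
                         masks = ablation_masks(), fractions = c(0.8, 0.1, 0.1)) {
  if (length(masks) == 0L) abort_usage("masks must be a non-empty list")
  sp <- random_split(pairs, fractions, seed = config$seed)
  rows <- lapply(seq_along(masks), function(i) {
    mask <- masks[[i]]
    model <- train_classifier(serialize_or_die(sp$train, mask),
                              serialize_or_die(sp$val, mask), config, mask)
    test <- serialize_or_die(sp$test, mask)
    binary_metrics(test$label, predict_scores(model, test$text),
                   config$threshold, context = names(masks)[i])
  })
  as_metrics(dplyr::bind_rows(rows))
}

#' The inference-time feature-removal ladder
#'
#' Masks applied at evaluation only, for a model trained on the full
#' non-STRING configuration: nothing removed, family removed, function and
#' family removed, and function, family and conservation removed (leaving the
#' sequence-derived baseline).
#'
#' @return Named list of [feature_mask()] objects.
#' @export
resilience_masks <- function() {
  list(
    "None" = feature_mask(TRUE, TRUE, TRUE, FALSE),
    "Family" = feature_mask(TRUE, FALSE, TRUE, FALSE),
    "Function, family" = feature_mask(FALSE, FALSE, TRUE, FALSE),
    "Function, family, conservation" = feature_mask(FALSE, FALSE, FALSE, FALSE)
  )
}

#' Inference-time resilience evaluation
#'
#' The same trained model scores the test pairs re-serialized under each
#' inference mask; no retraining occurs. The model must have been trained
#' without STRING sentences (models trained with STRING depend on that signal
#' and degrade badly when it is removed, so the protocol rejects them).
#'
#' @param model An `operotext_model` trained under a non-STRING mask.
#' @param test_pairs Labeled, featurized pair tibble to evaluate on.
#' @param masks Named list of inference masks (default [resilience_masks()]).
#' @return Metrics tibble, one row per inference mask.
#' @export
run_resilience <- function(model, test_pairs, masks = resilience_masks()) {
  if (isTRUE(model$mask$include_string)) {
    abort_usage("resilience protocol requires a model trained without STRING features")
  }
  rows <- lapply(seq_along(masks), function(i) {
    test <- serialize_or_die(test_pairs, masks[[i]])
    binary_metrics(test$label, predict_scores(model, test$text),
                   model$config$threshold, context = names(masks)[i])
  })
  as_metrics(dplyr::bind_rows(rows))
}

#' Assemble operon calls from pairwise predictions
#'
#' Maximal runs of consecutive operonic-called adjacent pairs on one contig
#' become one operon call; runs are additionally broken at strand changes
#' (an opposite-strand pair cannot be co-transcribed even if called positive),
#' and singleton genes are not reported.
#'
#' @param pairs Pair tibble for one genome (coordinate columns required).
#' @param labels Predicted labels for each pair: logical, 0/1, or
#'   `"operonic"`/`"non_operonic"`.
#' @param scores Optional numeric scores recorded per supporting pair.
#' @return Tibble of operon calls: `genome_id`, `contig_id`, `start`, `end`,
#'   `n_genes`, list-columns `gene_ids` and `pair_scores`.
#' @export
chain_operons <- function(pairs, labels, scores = NULL) {
  if (nrow(pairs) == 0L) return(operon_call_empty())
  pos <- as_binary_label(labels) == 1L
  ord <- order(pairs$contig_id, pairs$start_a, pairs$end_a, pairs$gene_a)
  p <- pairs[ord, , drop = FALSE]
  pos <- pos[ord]
  sc <- if (is.null(scores)) rep(NA_real_, nrow(p)) else scores[ord]
  usable <- pos & p$strand_a == p$strand_b

  calls <- list()
  cur_genes <- character(0); cur_scores <- numeric(0)
  cur_contig <- NA_character_; cur_start <- NA_integer_; cur_end <- NA_integer_
  flush <- function() {
    if (length(cur_genes) >= 2L) {
      calls[[length(calls) + 1L]] <<- tibble::tibble(
        genome_id = p$genome_id[1], contig_id = cur_contig,
        start = cur_start, end = cur_end, n_genes = length(cur_genes),
        gene_ids = list(cur_genes), pair_scores = list(cur_scores)
      )
    }
    cur_genes <<- character(0); cur_scores <<- numeric(0)
    cur_contig <<- NA_character_; cur_start <<- NA_integer_; cur_end <<- NA_integer_
  }
  for (i in seq_len(nrow(p))) {
    if (!usable[i]) { flush(); next }
    extends <- length(cur_genes) > 0L &&
      identical(cur_contig, p$contig_id[i]) &&
      identical(cur_genes[length(cur_genes)], p$gene_a[i])
    if (!extends) {
      flush()
      cur_genes <- p$gene_a[i]
      cur_contig <- p$contig_id[i]
      cur_start <- p$start_a[i]
    }
    cur_genes <- c(cur_genes, p$gene_b[i])
    cur_scores <- c(cur_scores, sc[i])
    cur_end <- max(cur_end, p$end_b[i], na.rm = TRUE)
  }
  flush()
  if (length(calls) == 0L) return(operon_call_empty())
  dplyr::bind_rows(calls)
}

operon_call_empty <- function() {
  tibble::tibble(
    genome_id = character(), contig_id = character(), start = integer(),
    end = integer(), n_genes = integer(), gene_ids = list(), pair_scores = list()
  )
}

#' Write operon calls as GFF3 and/or a flat table
#'
#' @param calls Tibble from [chain_operons()].
#' @param path Output path; `.gff3` suffix writes GFF3 `operon` features,
#'   anything else a tab-delimited table with comma-joined gene lists.
#' @return `path`, invisibly.
#' @export
write_operon_calls <- function(calls, path) {
  if (grepl("\\.gff3?$", path)) {
    header <- "##gff-version 3"
    lines <- vapply(seq_len(nrow(calls)), function(i) {
      attrs <- sprintf("ID=operon_%d;genes=%s", i,
                       paste(calls$gene_ids[[i]], collapse = ","))
      paste(calls$contig_id[i], "operotext", "operon", calls$start[i],
            calls$end[i], ".", ".", ".", attrs, sep = "\t")
    }, character(1))
    writeLines(c(header, lines), path)
  } else {
    flat <- dplyr::mutate(
      calls,
      gene_ids = vapply(.data$gene_ids, paste, character(1), collapse = ","),
      pair_scores = vapply(.data$pair_scores, function(x) paste(signif(x, 6), collapse = ","),
                           character(1))
    )
    readr::write_tsv(flat, path, progress = FALSE)
  }
  invisible(path)
}

#' Plot an evaluation metrics table
#'
#' Grouped bars of the headline metrics per evaluation cell.
#'
#' @param object An `operotext_metrics` tibble.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.operotext_metrics <- function(object,
                                       metrics = c("sensitivity", "specificity",
                                                   "f1", "pr_auc", "accuracy"),
                                       ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$context <- factor(long$context, levels = unique(object$context))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$context, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Check gene-pair counts of a constructed dataset against expectations
#'
#' Intended for verifying externally deposited datasets (per-genome totals
#' and class counts) when those files are available locally; also usable on
#' synthetic panels. Purely a reporting helper: it never alters the data.
#'
#' @param pairs Labeled pair tibble.
#' @param expected Tibble with columns `genome_id`, `n_pairs`, `n_pos`,
#'   `n_neg`.
#' @return Tibble joining observed and expected counts with a `match` flag.
#' @export
verify_pair_counts <- function(pairs, expected) {
  obs <- pairs |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_pos = sum(.data$label == "operonic"),
      n_neg = sum(.data$label == "non_operonic"),
      .groups = "drop"
    )
  out <- dplyr::left_join(expected, obs, by = "genome_id",
                          suffix = c("_expected", "_observed"))
  dplyr::mutate(out, match = .data$n_pairs_expected == .data$n_pairs_observed &
                  .data$n_pos_expected == .data$n_pos_observed &
                  .data$n_neg_expected == .data$n_neg_observed)
}
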