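# Independent brute-force metrics used as the oracle.
brute_metrics <- function(y, s, thr = 0.5) {
  pred <- as.integer(s >= thr)
  tp <- sum(pred & y); fp <- sum(pred & !y); tn <- sum(!pred & !y); fn <- sum(!pred & y)
  prec_at <- function(t) sum(s >= t & y) / sum(s >= t)
  rec_at <- function(t) sum(s >= t & y) / sum(y)
  ts <- sort(unique(s), decreasing = TRUE)
  recs <- vapply(ts, rec_at, numeric(1))
  precs <- vapply(ts, prec_at, numeric(1))
  ap <- sum((recs - c(0, recs[-length(recs)])) * precs)
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       prec = if (tp + fp) tp / (tp + fp) else 0,
       acc = (tp + tn) / length(y), ap = ap)
}

test_that("binary metrics match hand arithmetic on a fixed confusion matrix", {
  # TP=3, FP=1, TN=4, FN=2.
  labels <- c(rep("operonic", 5), rep("non_operonic", 5))
  scores <- c(rep(0.9, 3), rep(0.1, 2), rep(0.8, 1), rep(0.2, 4))
  m <- binary_metrics(labels, scores)
  expect_equal(m$sensitivity, 60)
  expect_equal(m$specificity, 80)
  expect_equal(m$precision, 75)
  expect_equal(m$accuracy, 70)
  expect_equal(m$f1, 200 * (0.75 * 0.6) / (0.75 + 0.6), tolerance = 1e-10)
  expect_equal(m$n_pos, 5L)
  expect_equal(m$n_neg, 5L)
})

test_that("perfect predictions score 100 everywhere", {
  labels <- rep(c("operonic", "non_operonic"), 10)
  scores <- ifelse(labels == "operonic", 0.99, 0.01)
  m <- binary_metrics(labels, scores)
  expect_equal(unlist(m[c("sensitivity", "specificity", "precision", "f1",
                          "accuracy", "pr_auc")], use.names = FALSE),
               rep(100, 6))
})

test_that("metrics agree with brute-force confusion arithmetic on random inputs", {
  withr::with_seed(61, {
    for (rep in 1:15) {
      n <- sample(20:200, 1)
      y <- c(1, 0, sample(0:1, n - 2, replace = TRUE)) # both classes guaranteed
      s <- round(runif(n), sample(c(1, 2, 6), 1))      # sometimes heavy ties
      m <- binary_metrics(y, s)
      o <- brute_metrics(y, s)
      expect_equal(m$sensitivity, 100 * o$sens)
      expect_equal(m$specificity, 100 * o$spec)
      expect_equal(m$precision, 100 * o$prec)
      expect_equal(m$accuracy, 100 * o$acc)
      expect_equal(m$pr_auc, 100 * o$ap, tolerance = 1e-10)
    }
  })
})

test_that("one-class inputs raise errors naming the undefined metric", {
  expect_error(binary_metrics(rep("operonic", 5), runif(5)), regexp = "specificity")
  expect_error(binary_metrics(rep("non_operonic", 5), runif(5)), regexp = "sensitivity")
  expect_error(binary_metrics(c(1, 0), c(0.5, 0.5, 0.5)), class = "operotext_usage_error")
})

test_that("average precision is invariant to monotone score transforms", {
  withr::with_seed(62, {
    y <- sample(0:1, 100, replace = TRUE)
    s <- runif(100)
    expect_equal(average_precision(y, plogis(3 * s + 1)), average_precision(y, s))
    expect_equal(average_precision(y, rank(s)), average_precision(y, s))
  })
})

test_that("random scores on balanced labels give average precision near 0.5", {
  withr::with_seed(63, {
    y <- rep(0:1, 2000)
    s <- runif(4000)
    expect_equal(100 * average_precision(y, s), 50, tolerance = 3 / 50) # 50 +/- 3
  })
})

test_that("operon chaining decomposes positive runs and respects strand", {
  genes <- mk_genes(seq(1, by = 200, length.out = 5),
                    seq(100, by = 200, length.out = 5),
                    ids = sprintf("g%d", 1:5))
  pairs <- adjacent_pairs(genes)
  calls <- chain_operons(pairs, c(1, 1, 0, 1))
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$gene_ids[[1]], c("g1", "g2", "g3"))
  expect_equal(calls$gene_ids[[2]], c("g4", "g5"))
  expect_equal(calls$n_genes, c(3L, 2L))
  expect_equal(calls$start[1], 1L)
  expect_equal(calls$end[1], genes$end[3])

  expect_equal(nrow(chain_operons(pairs, rep(0, 4))), 0L)

  # Strand flip inside a positive run splits the call.
  genes2 <- genes
  genes2$strand <- c("forward", "forward", "reverse", "reverse", "reverse")
  pairs2 <- adjacent_pairs(genes2)
  calls2 <- chain_operons(pairs2, rep(1, 4))
  expect_equal(lapply(calls2$gene_ids, identity),
               list(c("g1", "g2"), c("g3", "g4", "g5")))

  # Every reported call has >= 2 genes and covers genes of positive pairs only.
  labels <- c(1, 0, 0, 1)
  calls3 <- chain_operons(pairs, labels, scores = c(.9, .1, .2, .8))
  expect_true(all(calls3$n_genes >= 2))
  expect_setequal(unlist(calls3$gene_ids),
                  unique(c(pairs$gene_a[labels == 1], pairs$gene_b[labels == 1])))
  expect_equal(calls3$pair_scores, list(0.9, 0.8))
})

test_that("operon calls serialize to GFF3 and flat tables", {
  genes <- mk_genes(c(1, 201, 401), c(100, 300, 500), ids = c("g1", "g2", "g3"))
  calls <- chain_operons(adjacent_pairs(genes), c(1, 1))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_operon_calls(calls, gff)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  expect_match(lines[2], "\toperon\t1\t500\t")
  expect_match(lines[2], "genes=g1,g2,g3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_operon_calls(calls, tsv)
  expect_equal(readr::read_tsv(tsv, show_col_types = FALSE)$gene_ids, "g1,g2,g3")
})

test_that("LOSO evaluation isolates each genome and is reproducible", {
  d <- small_panel_dataset()
  cfg <- classifier_config(learning_rate = 0.1, seed = 7)
  m <- run_loso(d, cfg, mask_preset("full"))
  expect_equal(nrow(m), 3L)
  expect_setequal(m$context, unique(d$genome_id))
  expect_equal(m$n_pos + m$n_neg,
               vapply(m$context, function(g) sum(d$genome_id == g), integer(1),
                      USE.NAMES = FALSE))
  m2 <- run_loso(d, cfg, mask_preset("full"))
  expect_equal(m, m2)
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("the ablation grid evaluates each mask on one shared split", {
  d <- small_panel_dataset()
  cfg <- classifier_config(learning_rate = 0.1, seed = 7, max_epochs = 4L)
  tab <- run_ablation(d, cfg)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$context[1], "Baseline")
  expect_equal(tab$context[6], "+Function+Conservation+Family+String")
  # The shared split means every row evaluates the same pair count.
  expect_equal(length(unique(tab$n_pos + tab$n_neg)), 1L)
  # Masks genuinely change the serialized corpus.
  t_on <- serialize_pairs(d, feature_mask(include_conservation = TRUE))$text
  t_off <- serialize_pairs(d, feature_mask(include_conservation = FALSE))$text
  expect_false(any(t_on == t_off))
})

test_that("resilience re-serializes under inference masks without retraining", {
  d <- small_panel_dataset()
  cfg <- classifier_config(learning_rate = 0.1, seed = 7)
  sp <- loso_split(d, sort(unique(d$genome_id))[1], seed = cfg$seed)
  mask <- mask_preset("full")
  model <- train_classifier(serialize_pairs(sp$train, mask),
                            serialize_pairs(sp$val, mask), cfg, mask)
  tab <- run_resilience(model, sp$test)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$context, c("None", "Family", "Function, family",
                              "Function, family, conservation"))
  # The "None" row is the identity mask: equals a plain evaluation.
  test <- serialize_pairs(sp$test, mask)
  direct <- binary_metrics(test$label, predict_scores(model, test$text),
                           cfg$threshold, context = "None")
  expect_equal(tab[1, ], direct)

  # Models trained with STRING are rejected by the protocol.
  mask_s <- mask_preset("full_string")
  model_s <- train_classifier(serialize_pairs(sp$train, mask_s),
                              serialize_pairs(sp$val, mask_s), cfg, mask_s)
  expect_error(run_resilience(model_s, sp$test), class = "operotext_usage_error")
})

test_that("pair-count verification joins observed and expected tallies", {
  d <- small_panel_dataset()
  expected <- d |>
    dplyr::group_by(genome_id) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_pos = sum(label == "operonic"),
                     n_neg = sum(label == "non_operonic"), .groups = "drop")
  chk <- verify_pair_counts(d, expected)
  expect_true(all(chk$match))
  expected$n_pos[1] <- expected$n_pos[1] + 1L
  expect_false(all(verify_pair_counts(d, expected)$match))
})
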