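#' Classifier configuration
#'
#' Defaults follow the published training protocol: AdamW with learning rate
#' 3e-5, weight decay 0.01, batch size 32, at most 10 epochs, a linear-decay
#' learning-rate schedule, a 512-token input limit, and per-epoch validation
#' with post-hoc checkpoint selection. The `"bow-linear"` backbone — token
#' count vectors feeding a linear decision rule trained with exactly this
#' protocol — is the backbone shipped with this package; it trains in seconds
#' on a CPU. Note the default learning rate is tuned to fine-tuning a large
#' pretrained encoder; a linear model trained from zero initialization needs a
#' larger step size (0.1 is a good choice, see the methods vignette).
#'
#' @param backbone Backbone identifier; only `"bow-linear"` is runnable here.
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param batch_size Mini-batch size.
#' @param max_epochs Training epoch budget.
#' @param max_tokens Maximum tokenized input length; longer inputs truncate.
#' @param scheduler `"linear_decay"` or `"constant"`.
#' @param seed Integer seed controlling shuffling; fixed seed gives
#'   reproducible training.
#' @param threshold Decision threshold on the operonic-class probability.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(backbone = "bow-linear", learning_rate = 3e-5,
                              weight_decay = 0.01, batch_size = 32L,
                              max_epochs = 10L, max_tokens = 512L,
                              scheduler = c("linear_decay", "constant"),
                              seed = 42L, threshold = 0.5) {
  scheduler <- match.arg(scheduler)
  if (threshold <= 0 || threshold >= 1) abort_usage("threshold must lie in (0, 1)")
  if (max_epochs < 1L) abort_usage("max_epochs must be >= 1")
  structure(
    list(backbone = backbone, learning_rate = learning_rate,
         weight_decay = weight_decay, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), max_tokens = as.integer(max_tokens),
         scheduler = scheduler, seed = as.integer(seed), threshold = threshold),
    class = "classifier_config"
  )
}

# Word/number tokenizer. Numbers additionally decompose into magnitude
# subtokens (sign, digit count, leading digit x order) so that numeric
# magnitude generalizes beyond the exact values seen in training — the
# counting analogue of what subword tokenization gives an encoder model.
expand_number_token <- function(tok) {
  neg <- startsWith(tok, "-")
  ip <- sub("\\..*$", "", sub("^-", "", tok))
  if (!nzchar(ip)) ip <- "0"
  nd <- nchar(ip)
  lead <- substr(ip, 1, 1)
  c(tok, if (neg) "#neg", paste0("#d", nd), paste0("#m", lead, "e", nd - 1L))
}

#' Tokenize texts with the package tokenizer
#'
#' Splits on words (`[A-Za-z_][A-Za-z0-9_]*`) and signed numbers; punctuation
#' carries no signal and is dropped. With `split_numbers = TRUE` each numeric
#' token additionally emits magnitude subtokens.
#'
#' @param texts Character vector.
#' @param split_numbers Emit magnitude subtokens for numbers (default TRUE).
#' @param max_tokens Truncate each token sequence to this length.
#' @return List of character vectors, one per text.
#' @export
tokenize_texts <- function(texts, split_numbers = TRUE, max_tokens = Inf) {
  toks <- stringr::str_extract_all(texts, "-?[0-9]+(?:\\.[0-9]+)?|[A-Za-z_][A-Za-z0-9_]*")
  if (split_numbers && length(toks)) {
    uniq <- unique(unlist(toks, use.names = FALSE))
    is_num <- grepl("^-?[0-9]", uniq)
    ext <- vector("list", length(uniq))
    names(ext) <- uniq
    ext[!is_num] <- as.list(uniq[!is_num])
    ext[is_num] <- lapply(uniq[is_num], expand_number_token)
    toks <- lapply(toks, function(tt) unlist(ext[tt], use.names = FALSE) %||% character())
  }
  if (is.finite(max_tokens)) {
    toks <- lapply(toks, function(tt) tt[seq_len(min(length(tt), max_tokens))])
  }
  toks
}

#' Audit tokenized lengths of a corpus
#'
#' Reports the maximum tokenized length and the number of texts that would be
#' truncated at the configured limit, the check used to confirm that inputs
#' fit the model's input window.
#'
#' @param corpus Corpus tibble (with a `text` column) or character vector.
#' @param config A [classifier_config()] supplying `max_tokens`.
#' @return List with `max_len` and `n_truncated`.
#' @export
tokenize_audit <- function(corpus, config = classifier_config()) {
  texts <- if (is.data.frame(corpus)) corpus$text else corpus
  lens <- lengths(tokenize_texts(texts))
  list(max_len = if (length(lens)) max(lens) else 0L,
       n_truncated = sum(lens > config$max_tokens))
}

as_binary_label <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label)) return(as.integer(label != 0))
  as.integer(as.character(label) == "operonic")
}

make_dtm <- function(tokens, vocab) {
  idx <- lapply(tokens, function(tt) match(tt, vocab))
  i <- rep.int(seq_along(idx), vapply(idx, length, integer(1)))
  j <- unlist(idx, use.names = FALSE)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(length(tokens), length(vocab)))
}

bce_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the gene-pair text classifier
#'
#' Mirrors the published protocol: binary cross-entropy minimized with AdamW
#' (decoupled weight decay), mini-batches over a seeded shuffle, an optional
#' linear-decay learning-rate schedule, evaluation and checkpointing at the
#' end of every epoch, and selection of the checkpoint with the best
#' (minimum) validation loss, ties broken by the earliest epoch. The
#' `"bow-linear"` backbone scores a text by a linear function of its token
#' counts; training is deterministic for a fixed seed.
#'
#' @param train,val Corpus tibbles with `text` and `label` columns; the
#'   training set must contain both classes.
#' @param config A [classifier_config()].
#' @param mask The [feature_mask()] the corpora were serialized under
#'   (recorded on the model; required by the resilience protocol).
#' @return An object of class `operotext_model` with the selected weights,
#'   vocabulary, config snapshot, training-time mask, and per-epoch `history`.
#' @export
train_classifier <- function(train, val, config = classifier_config(),
                             mask = NULL) {
  if (config$backbone != "bow-linear") {
    abort_usage(sprintf(paste(
      "backbone '%s' is not runnable in this installation; the package ships",
      "the 'bow-linear' backbone, which trains under the same protocol",
      "(AdamW, linear decay, per-epoch checkpoint selection)"), config$backbone))
  }
  if (nrow(train) == 0L || nrow(val) == 0L) abort_usage("train and val must be non-empty")
  y <- as_binary_label(train$label)
  if (length(unique(y)) < 2L) abort_usage("training set contains a single class")
  yv <- as_binary_label(val$label)

  tr_tok <- tokenize_texts(train$text, max_tokens = config$max_tokens)
  va_tok <- tokenize_texts(val$text, max_tokens = config$max_tokens)
  vocab <- sort(unique(unlist(tr_tok, use.names = FALSE)))
  X <- make_dtm(tr_tok, vocab)
  Xv <- make_dtm(va_tok, vocab)

  n <- nrow(X)
  V <- length(vocab)
  bs <- max(1L, min(config$batch_size, n))
  n_batches <- ceiling(n / bs)
  total_steps <- config$max_epochs * n_batches
  w <- numeric(V); b <- 0
  mw <- vw <- numeric(V); mb <- vb <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  snaps <- vector("list", config$max_epochs)
  hist <- vector("list", config$max_epochs)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(n_batches)
      for (k in seq_len(n_batches)) {
        idx <- ord[seq((k - 1L) * bs + 1L, min(k * bs, n))]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        p <- stats::plogis(as.numeric(Xb %*% w) + b)
        batch_losses[k] <- bce_loss(yb, p)
        r <- (p - yb) / length(idx)
        gw <- as.numeric(Matrix::crossprod(Xb, r))
        gb <- sum(r)
        step <- step + 1L
        lr_t <- if (config$scheduler == "linear_decay") {
          config$learning_rate * (1 - (step - 1L) / total_steps)
        } else config$learning_rate
        mw <- beta1 * mw + (1 - beta1) * gw
        vw <- beta2 * vw + (1 - beta2) * gw^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        w <- w - lr_t * ((mw / bc1) / (sqrt(vw / bc2) + eps)) -
          lr_t * config$weight_decay * w
        b <- b - lr_t * ((mb / bc1) / (sqrt(vb / bc2) + eps))
      }
      pv <- stats::plogis(as.numeric(Xv %*% w) + b)
      snaps[[epoch]] <- list(w = w, b = b)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = mean(batch_losses),
        val_loss = bce_loss(yv, pv),
        val_accuracy = mean((pv >= config$threshold) == (yv == 1L))
      )
    }
  })
  history <- dplyr::bind_rows(hist)
  sel <- select_checkpoint(history)
  structure(
    list(backbone = config$backbone, vocab = vocab,
         weights = snaps[[sel]]$w, bias = snaps[[sel]]$b,
         config = config, mask = mask %||% feature_mask(),
         selected_epoch = sel, history = history),
    class = "operotext_model"
  )
}

#' Select the best checkpoint from a training history
#'
#' The checkpoint with minimum validation loss; ties break to the earliest
#' epoch.
#'
#' @param history Tibble with `epoch` and `val_loss` columns.
#' @return Selected epoch (integer).
#' @export
select_checkpoint <- function(history) {
  if (nrow(history) == 0L) abort_usage("empty training history")
  as.integer(history$epoch[which.min(history$val_loss)])
}

#' Score texts with a trained classifier
#'
#' @param model An `operotext_model`.
#' @param texts Character vector (order preserved; empty input gives empty
#'   output). Tokens unseen in training are ignored.
#' @return Numeric vector of operonic-class probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, texts) {
  if (length(texts) == 0L) return(numeric(0))
  tok <- tokenize_texts(texts, max_tokens = model$config$max_tokens)
  X <- make_dtm(tok, model$vocab)
  as.numeric(stats::plogis(as.numeric(X %*% model$weights) + model$bias))
}

#' @export
predict.operotext_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  texts <- if (is.data.frame(newdata)) newdata$text else newdata
  p <- predict_scores(object, texts)
  if (type == "prob") p else ifelse(p >= object$config$threshold, "operonic", "non_operonic")
}

#' @export
print.operotext_model <- function(x, ...) {
  cat(sprintf("<operotext_model> backbone=%s vocab=%d selected_epoch=%d val_loss=%.4f\n",
              x$backbone, length(x$vocab), x$selected_epoch,
              x$history$val_loss[x$selected_epoch]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted classifier into a term/weight table
#'
#' @param x An `operotext_model`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`, sorted by `|estimate|`
#'   descending; the intercept appears as `"(bias)"`.
#' @export
tidy.operotext_model <- function(x, ...) {
  out <- tibble::tibble(term = c("(bias)", x$vocab),
                        estimate = c(x$bias, x$weights))
  dplyr::arrange(out, dplyr::desc(abs(.data$estimate)))
}

#' One-row summary of a fitted classifier
#'
#' @param x An `operotext_model`.
#' @param ... Unused.
#' @return Tibble with backbone, vocabulary size, selected epoch and its
#'   validation loss/accuracy.
#' @export
glance.operotext_model <- function(x, ...) {
  tibble::tibble(
    backbone = x$backbone,
    vocab_size = length(x$vocab),
    epochs_trained = nrow(x$history),
    selected_epoch = x$selected_epoch,
    val_loss = x$history$val_loss[x$selected_epoch],
    val_accuracy = x$history$val_accuracy[x$selected_epoch]
  )
}

#' Plot a training history
#'
#' Training and validation loss per epoch, with the selected checkpoint
#' marked.
#'
#' @param object An `operotext_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.operotext_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Save a trained classifier to a directory
#'
#' Writes a JSON config/mask snapshot, the vocabulary, weights, and the
#' training history as plain text.
#'
#' @param model An `operotext_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(backbone = model$backbone,
         config = unclass(model$config),
         mask = unclass(model$mask),
         bias = model$bias,
         selected_epoch = model$selected_epoch),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(tibble::tibble(token = model$vocab, weight = model$weights),
                   file.path(dir, "weights.tsv"), progress = FALSE)
  readr::write_tsv(model$history, file.path(dir, "history.tsv"), progress = FALSE)
  invisible(dir)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param dir Model directory.
#' @return An `operotext_model`.
#' @export
load_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  wt <- readr::read_tsv(file.path(dir, "weights.tsv"), col_types = "cd", progress = FALSE)
  history <- readr::read_tsv(file.path(dir, "history.tsv"), col_types = "iddd", progress = FALSE)
  cfg <- do.call(classifier_config, meta$config)
  msk <- do.call(feature_mask, meta$mask)
  structure(
    list(backbone = meta$backbone, vocab = wt$token, weights = wt$weight,
         bias = meta$bias, config = cfg, mask = msk,
         selected_epoch = meta$selected_epoch, history = history),
    class = "operotext_model"
  )
}
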