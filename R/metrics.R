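#' Classification metrics for influence/relevance predictions
#'
#' Thresholds the scores, counts the confusion matrix, and reports
#' precision, recall, F1 (the harmonic mean of precision and recall),
#' accuracy, ROC AUC (trapezoidal, via ranking — ties handled by the
#' rank/Mann-Whitney convention), and PR AUC (average precision with
#' step-wise interpolation). Ratios with a zero denominator are reported as
#' 0 and flagged in the `flag` column with a warning.
#'
#' @param truth Ground-truth labels; anything > 0 is the positive class
#'   (both {1, -1} and {1, 0} codings work).
#' @param scores Numeric scores (higher = more positive).
#' @param threshold Decision threshold: predicted positive iff
#'   `score >= threshold`.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f1`, `accuracy`, `roc_auc`, `pr_auc`, `n`, `flag` (`NA` or a
#'   semicolon-separated list of undefined ratios reported as 0).
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5) {
  if (length(truth) != length(scores)) {
    abort("`truth` and `scores` must have the same length.")
  }
  if (length(truth) == 0L) abort("need at least one observation.")
  y <- as.integer(truth > 0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  flags <- character(0)
  rate <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      0
    } else num / den
  }
  precision <- rate(tp, tp + fp, "precision")
  recall <- rate(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    flags <- c(flags, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / length(y)

  if (length(unique(y)) < 2L) {
    flags <- c(flags, "roc_auc", "pr_auc")
    roc_auc <- 0
    pr_auc <- 0
  } else {
    roc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = scores, levels = c(0, 1),
      direction = "<", quiet = TRUE)))
    pr_auc <- average_precision(y, scores)
  }
  if (length(flags)) {
    warn(paste0("undefined metric(s) reported as 0: ",
                paste(unique(flags), collapse = ", ")))
  }
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall, f1 = f1,
         accuracy = accuracy, roc_auc = roc_auc, pr_auc = pr_auc,
         n = length(y),
         flag = if (length(flags)) paste(unique(flags), collapse = ";")
                else NA_character_)
}

# average precision with step-wise interpolation: sum over distinct score
# thresholds (descending) of (recall step) * (precision at that threshold);
# tied scores enter as one block
average_precision <- function(y, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1L)
  ap <- 0
  prev_recall <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(y[sel] == 1L)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Deterministic train/test split
#'
#' Shuffles rows (or elements) with a seeded permutation and takes the first
#' `ceiling(n * ratio)` as the training set. With 853 items at the default
#' ratio this gives 768 training and 85 test items.
#'
#' @param items A data frame (split by rows) or a vector/list.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed; the same seed always reproduces the split.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(items, ratio = 0.9, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must lie in (0, 1).")
  n <- if (is.data.frame(items)) nrow(items) else length(items)
  if (n == 0L) abort("`items` is empty.")
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- ceiling(n * ratio)
  take <- function(idx) {
    if (is.data.frame(items)) items[idx, , drop = FALSE] else items[idx]
  }
  list(train = take(perm[seq_len(n_train)]),
       test = take(perm[-seq_len(n_train)]))
}

# Baseline decisions come from the three-way threshold rule, not from
# thresholding the product score, so the confusion counts use the rule
# labels while the AUCs rank by the product score.
baseline_metrics <- function(pred) {
  conf <- compute_metrics(pred$label, as.numeric(pred$baseline_label > 0),
                          threshold = 0.5)
  aucs <- compute_metrics(pred$label, pred$baseline_score, threshold = 0.5)
  conf$roc_auc <- aucs$roc_auc
  conf$pr_auc <- aucs$pr_auc
  conf
}

#' Run the full influence-identification pipeline on a labeled corpus
#'
#' Ties the modules together the way the method is evaluated: split the
#' labeled triples 90/10; train word embeddings on the training posts; train
#' the text-relevance matcher on the post pairs belonging to training
#' triples; build feature bundles; train the deep feature-fusion model on
#' the training bundles; and score the held-out triples with both the deep
#' model and the product-threshold baseline.
#'
#' @param corpus A `synth_corpus` (from [generate_corpus()] or
#'   [read_corpus()]), or any list with `posts`, `pairs`, `triples`.
#' @param arch Relevance architecture, `"arc1"` or `"matchpyramid"`.
#' @param combine_op `"dot"` or `"cat"`.
#' @param split_ratio Training fraction of triples.
#' @param relevance_hyper,influence_hyper Hyperparameter lists.
#' @param rules A [question_rules()] table.
#' @param seed Integer seed driving the split and both trainings.
#' @return A list of class `influence_pipeline`: `embeddings`,
#'   `relevance_model`, `influence_model`, `split` (train/test triples),
#'   `test_predictions` (held-out bundles with deep `score`/`pred_label`
#'   and baseline `baseline_score`/`baseline_label`), and one-row metric
#'   tibbles `metrics_deep` and `metrics_baseline`.
#' @export
run_influence_pipeline <- function(corpus,
                                   arch = c("arc1", "matchpyramid"),
                                   combine_op = c("dot", "cat"),
                                   split_ratio = 0.9,
                                   relevance_hyper = ohcinfluence::relevance_hyper(),
                                   influence_hyper = ohcinfluence::influence_hyper(),
                                   rules = question_rules(),
                                   seed = 7L) {
  arch <- match.arg(arch)
  combine_op <- match.arg(combine_op)
  posts <- corpus$posts
  triples <- corpus$triples

  split <- split_train_test(triples, ratio = split_ratio, seed = seed)

  # pair labels follow the triple split: train pairs come from train triples
  pair_text <- function(tr) {
    txt <- setNames(posts$text, paste(posts$thread_id, posts$post_id))
    dplyr::bind_rows(
      tibble(text_a = txt[paste(tr$thread_id, tr$a_id)],
             text_b = txt[paste(tr$thread_id, tr$b_id)],
             label = as.integer(tr$rel_ab)),
      tibble(text_a = txt[paste(tr$thread_id, tr$b_id)],
             text_b = txt[paste(tr$thread_id, tr$c_id)],
             label = as.integer(tr$rel_bc))
    )
  }
  train_pairs <- pair_text(split$train)

  train_post_ids <- unique(c(paste(split$train$thread_id, split$train$a_id),
                             paste(split$train$thread_id, split$train$b_id),
                             paste(split$train$thread_id, split$train$c_id)))
  train_texts <- posts$text[paste(posts$thread_id, posts$post_id) %in%
                              train_post_ids]
  emb <- train_embeddings(train_texts, seed = seed)

  rel_model <- train_relevance_model(train_pairs, arch = arch,
                                     embeddings = emb,
                                     hyper = relevance_hyper, seed = seed)

  train_bundles <- build_feature_bundles(split$train, posts, rel_model, rules)
  test_bundles <- build_feature_bundles(split$test, posts, rel_model, rules)

  inf_model <- train_influence_model(train_bundles, combine_op = combine_op,
                                     hyper = influence_hyper, seed = seed)

  pred <- predict(inf_model, test_bundles)
  base <- baseline_classify(pred$p_ab, pred$p_bc, pred$q, pred$a)
  pred$baseline_score <- base$score
  pred$baseline_label <- base$pred_label

  structure(list(
    embeddings = emb,
    relevance_model = rel_model,
    influence_model = inf_model,
    split = split,
    test_predictions = pred,
    metrics_deep = compute_metrics(pred$label, pred$score,
                                   influence_hyper$threshold),
    metrics_baseline = baseline_metrics(pred)
  ), class = "influence_pipeline")
}
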