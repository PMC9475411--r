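test_that("combine implements dot and cat exactly", {
  expect_equal(combine(c(1, 2, 3), 0.5, "dot"), c(0.5, 1.0, 1.5))
  expect_equal(combine(c(1, 2, 3), 1, "dot"), c(1, 2, 3))
  expect_equal(combine(c(1, 2, 3), 0, "dot"), c(0, 0, 0))
  expect_equal(combine(c(1, 2, 3), 0.9, "cat"), c(1, 2, 3, 0.9))
  expect_length(combine(c(1, 2, 3), 0.9, "cat"), 4L)
  expect_error(combine(numeric(0), 0.5), "non-empty")
  expect_error(combine(c(1, 2), 1.5), "\\[0, 1\\]")
})

test_that("baseline rule scores and thresholds as specified", {
  r1 <- baseline_classify(1, 1, 1, 0.5)
  expect_equal(r1$score, 1.0)
  expect_equal(r1$pred_label, 1L)

  r2 <- baseline_classify(0.6, 0.7, 0.95, 0.5)
  expect_equal(r2$score, 0.6 * 0.7 * 0.95)
  expect_equal(r2$pred_label, 1L)

  # positive product but a failing component threshold
  r3 <- baseline_classify(0.4, 0.9, 1.0, 1.0)
  expect_equal(r3$score, 0.36)
  expect_equal(r3$pred_label, -1L)

  expect_error(baseline_classify(1.2, 0.5, 0.5, 0.5), "\\[0, 1\\]")

  # data-frame-first form appends the columns
  df <- tibble::tibble(p_ab = c(1, 0.4), p_bc = c(1, 0.9),
                       q = c(1, 1), a = c(0.5, 1))
  out <- baseline_classify(df)
  expect_equal(out$pred_label, c(1L, -1L))
})

test_that("baseline agrees with brute-force rule evaluation at scale", {
  withr::with_seed(31, {
    n <- 2000
    p_ab <- runif(n); p_bc <- runif(n); q <- runif(n)
    a <- sample(c(0.5, 1), n, replace = TRUE)
    got <- baseline_classify(p_ab, p_bc, q, a)
    for (i in sample(n, 200)) {
      expect_equal(got$score[i], p_ab[i] * p_bc[i] * max(q[i], a[i]))
      want <- if (p_ab[i] >= 0.5 && p_bc[i] >= 0.5 &&
                  max(q[i], a[i]) >= 0.9) 1L else -1L
      expect_identical(got$pred_label[i], want)
    }
  })
})

test_that("feature bundles wire relevance, question, and action together", {
  fix <- make_figure2_fixture()
  rel <- extract_relationships(fix)
  emb <- train_embeddings(fix$text, dim = 10, seed = 3)
  pairs <- tibble::tibble(text_a = fix$text[1:2], text_b = fix$text[2:3],
                          label = c(1L, 0L))
  rm <- train_relevance_model(pairs, "arc1", emb,
                              relevance_hyper(epochs = 1L, n_filters = 8L,
                                              vector_width = 16L), seed = 3)
  b <- build_feature_bundles(rel, fix, rm)
  # p_C of the first triple asks a question; of the second, announces action
  expect_equal(b$q[1], 1.0)
  expect_equal(b$a[2], 1.0)
  expect_equal(b$a[1], 0.5)
  expect_true(all(lengths(b$v_ab) == 16L))
  expect_true(all(lengths(b$v_bc) == 16L))
  expect_true(all(b$p_ab >= 0 & b$p_ab <= 1))

  bad <- rel
  bad$c_id[1] <- "missing"
  expect_error(build_feature_bundles(bad, fix, rm), "absent")
})

test_that("a question-free thankful counter-reply gets q = 0, a = 0.5", {
  th <- build_reply_tree(tibble::tibble(
    author_id = c("u1", "u2", "u1"), depth = c(0, 1, 2),
    text = c("Is a lumpectomy the right call for me?",
             "For me the lumpectomy was the right call.",
             "Thanks!")))
  rel <- extract_relationships(th)
  emb <- train_embeddings(th$text, dim = 6, seed = 3)
  pairs <- tibble::tibble(text_a = th$text[c(1, 2)], text_b = th$text[c(2, 3)],
                          label = c(1L, 0L))
  rm <- train_relevance_model(pairs, "arc1", emb,
                              relevance_hyper(epochs = 0L, n_filters = 4L,
                                              vector_width = 8L), seed = 3)
  b <- build_feature_bundles(rel, th, rm)
  expect_equal(b$q, 0)
  expect_equal(b$a, 0.5)
})

test_that("deep model outputs a softmax distribution and is deterministic", {
  bundles <- make_synthetic_bundles(n = 80, width = 8, seed = 7)
  m <- train_influence_model(bundles, "dot",
                             influence_hyper(epochs = 5L, units = 8L),
                             seed = 7)
  pr <- predict(m, bundles, type = "prob")
  expect_true(all(abs(pr$prob_neg + pr$prob_pos - 1) < 1e-6))
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_identical(pr$score, predict(m, bundles, type = "prob")$score)
  expect_true(all(pr$pred_label %in% c(-1L, 1L)))
  expect_equal(pr$pred_label, ifelse(pr$score >= 0.5, 1L, -1L))
})

test_that("dot combine with q = a = 0 collapses to a constant score", {
  bundles <- make_synthetic_bundles(n = 40, width = 8, seed = 7)
  m <- train_influence_model(bundles, "dot",
                             influence_hyper(epochs = 2L, units = 8L),
                             seed = 7)
  zeroed <- bundles
  zeroed$q <- 0
  zeroed$a <- 0
  sc <- predict(m, zeroed)$score
  expect_true(all(abs(sc - sc[1]) < 1e-12))
})

test_that("cat models carry one extra input dimension than dot models", {
  bundles <- make_synthetic_bundles(n = 60, width = 8, seed = 7)
  m_dot <- train_influence_model(bundles, "dot",
                                 influence_hyper(epochs = 1L, units = 8L),
                                 seed = 7)
  m_cat <- train_influence_model(bundles, "cat",
                                 influence_hyper(epochs = 1L, units = 8L),
                                 seed = 7)
  expect_equal(nrow(m_cat$params$W1), nrow(m_dot$params$W1) + 1L)
  expect_gt(glance(m_cat)$n_params, glance(m_dot)$n_params)

  # width mismatch between bundle and model errors out
  wrong <- make_synthetic_bundles(n = 10, width = 5, seed = 7)
  expect_error(predict(m_dot, wrong), "width")
})

test_that("the deep model learns the separable bundle corpus", {
  bundles <- make_synthetic_bundles(n = 400, width = 8, seed = 7)
  split <- split_train_test(bundles, ratio = 0.8, seed = 7)
  m <- train_influence_model(split$train, "dot",
                             influence_hyper(epochs = 40L, units = 16L),
                             seed = 7)
  expect_lt(tail(m$loss, 1), m$loss[1])
  expect_true(all(is.finite(m$loss)))
  pred <- predict(m, split$test)
  auc <- compute_metrics(split$test$label, pred$score)$roc_auc
  expect_gte(auc, 0.85)
})

test_that("an untrained model scores at chance level", {
  bundles <- make_synthetic_bundles(n = 300, width = 8, seed = 7)
  m0 <- train_influence_model(bundles, "dot",
                              influence_hyper(epochs = 0L, units = 16L),
                              seed = 7)
  expect_length(m0$loss, 1L)
  auc0 <- compute_metrics(bundles$label, predict(m0, bundles)$score)$roc_auc
  expect_gte(auc0, 0.3)
  expect_lte(auc0, 0.7)
})

test_that("training reproducibility and label handling", {
  bundles <- make_synthetic_bundles(n = 60, width = 8, seed = 7)
  m1 <- train_influence_model(bundles, "dot",
                              influence_hyper(epochs = 3L, units = 8L),
                              seed = 13)
  m2 <- train_influence_model(bundles, "dot",
                              influence_hyper(epochs = 3L, units = 8L),
                              seed = 13)
  expect_identical(m1$params, m2$params)

  one_class <- bundles[bundles$label == 1L, ]
  expect_error(train_influence_model(one_class, "dot"), "both classes")
})

test_that("label codings round-trip between {+1,-1} and {1,0}", {
  lab <- c(1L, -1L, 1L, -1L, -1L)
  expect_identical(ohcinfluence:::label_to_pm1(
    ohcinfluence:::label_to_01(lab)), lab)
  y01 <- c(1, 0, 0, 1)
  expect_identical(ohcinfluence:::label_to_01(
    ohcinfluence:::label_to_pm1(y01)), y01)
})
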