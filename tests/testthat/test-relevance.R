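# One small pair set + embeddings shared by the matcher tests.
pairs_200 <- make_topic_pairs(n = 200, seed = 7)
emb_200 <- train_embeddings(c(pairs_200$text_a, pairs_200$text_b),
                            dim = 20, seed = 7)
fast_hyper <- relevance_hyper(epochs = 6L, n_filters = 16L, vector_width = 32L)

test_that("both architectures honour the output contract", {
  for (arch in c("arc1", "matchpyramid")) {
    m <- train_relevance_model(pairs_200[1:40, ], arch, emb_200,
                               relevance_hyper(epochs = 1L, n_filters = 8L,
                                               vector_width = 16L), seed = 3)
    out <- relevance_score(m, pairs_200[41:50, ])
    expect_true(all(out$score >= 0 & out$score <= 1))
    expect_true(all(lengths(out$vector) == 16L))
    # inference determinism: identical calls, identical outputs
    out2 <- relevance_score(m, pairs_200[41:50, ])
    expect_identical(out$score, out2$score)
    expect_identical(out$vector, out2$vector)
  }
})

test_that("training is reproducible under a fixed seed", {
  m1 <- train_relevance_model(pairs_200[1:60, ], "arc1", emb_200,
                              relevance_hyper(epochs = 2L), seed = 21)
  m2 <- train_relevance_model(pairs_200[1:60, ], "arc1", emb_200,
                              relevance_hyper(epochs = 2L), seed = 21)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss, m2$loss)
})

test_that("zero training epochs returns the seeded initialization", {
  m <- train_relevance_model(pairs_200[1:40, ], "arc1", emb_200,
                             relevance_hyper(epochs = 0L), seed = 5)
  m2 <- train_relevance_model(pairs_200[1:40, ], "arc1", emb_200,
                              relevance_hyper(epochs = 0L), seed = 5)
  expect_identical(m$params, m2$params)
  expect_length(m$loss, 1L)
})

test_that("single-class labels are rejected", {
  one_class <- pairs_200[pairs_200$label == 1, ][1:10, ]
  expect_error(train_relevance_model(one_class, "arc1", emb_200),
               "both classes")
})

test_that("over-long texts are truncated, not rejected", {
  long_pair <- tibble::tibble(
    text_a = paste(rep("alphaterm1", 50), collapse = " "),
    text_b = "alphaterm2 alphaterm3"
  )
  m <- train_relevance_model(pairs_200[1:40, ], "arc1", emb_200,
                             relevance_hyper(epochs = 0L, max_len = 16L),
                             seed = 5)
  expect_no_error(suppressMessages(relevance_score(m, long_pair)))
})

test_that("trained matchers separate topics on held-out pairs", {
  split <- split_train_test(pairs_200, ratio = 0.8, seed = 7)
  for (arch in c("arc1", "matchpyramid")) {
    m <- train_relevance_model(split$train, arch, emb_200, fast_hyper,
                               seed = 7)
    # training reduced the loss
    expect_lt(tail(m$loss, 1), m$loss[1])
    out <- relevance_score(m, split$test)
    same <- out$score[split$test$label == 1]
    cross <- out$score[split$test$label == 0]
    expect_gt(mean(same), mean(cross))
  }
})

test_that("held-out accuracy exceeds 0.8 on the separable pair corpus", {
  split <- split_train_test(pairs_200, ratio = 0.8, seed = 7)
  m <- train_relevance_model(split$train, "matchpyramid", emb_200,
                             fast_hyper, seed = 7)
  acc <- mean((relevance_score(m, split$test)$score >= 0.5) ==
                (split$test$label == 1))
  expect_gt(acc, 0.8)

  # label symmetry: inverting the labels trains an equally good model
  inv_train <- split$train
  inv_train$label <- 1L - inv_train$label
  m_inv <- train_relevance_model(inv_train, "matchpyramid", emb_200,
                                 fast_hyper, seed = 7)
  acc_inv <- mean((relevance_score(m_inv, split$test)$score >= 0.5) ==
                    (split$test$label == 0))
  expect_gt(acc_inv, 0.8)
})

test_that("an all-OOV pair yields the model's zero-matrix constant", {
  m <- train_relevance_model(pairs_200[1:40, ], "matchpyramid", emb_200,
                             relevance_hyper(epochs = 1L, n_filters = 8L,
                                             vector_width = 16L), seed = 9)
  oov <- tibble::tibble(text_a = c("zzz qqq", "nope never"),
                        text_b = c("vvv www", "gone words"))
  out <- relevance_score(m, oov)
  expect_equal(out$score[1], out$score[2])
  expect_equal(out$vector[[1]], out$vector[[2]])
})

test_that("tidy and glance summarise a fit", {
  m <- train_relevance_model(pairs_200[1:40, ], "arc1", emb_200,
                             relevance_hyper(epochs = 1L), seed = 2)
  td <- tidy(m)
  expect_setequal(td$layer, c("Wc", "bc", "Wh", "bh", "Wo", "bo"))
  gl <- glance(m)
  expect_equal(gl$arch, "arc1")
  expect_equal(gl$n_params, sum(td$n_params))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
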