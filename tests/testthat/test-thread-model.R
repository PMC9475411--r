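test_that("reply tree attaches each post to the most recent shallower post", {
  th <- build_reply_tree(tibble::tibble(
    author_id = c("u1", "u2", "u1", "u3", "u1"),
    depth = c(0, 1, 2, 1, 2),
    text = paste("text", 1:5)
  ))
  expect_equal(th$parent_id, c(NA, "p1", "p2", "p1", "p4"))
  expect_equal(th$order_index, 0:4)
  expect_no_error(validate_thread(th))

  # siblings at equal depth both attach to the most recent depth-1 post
  th2 <- build_reply_tree(tibble::tibble(
    author_id = c("u1", "u2", "u3", "u4"),
    depth = c(0, 1, 2, 2),
    text = paste("text", 1:4)
  ))
  expect_equal(th2$parent_id, c(NA, "p1", "p2", "p2"))

  # degenerate single post
  th3 <- build_reply_tree(tibble::tibble(
    author_id = "u1", depth = 0, text = "hello there"
  ))
  expect_equal(nrow(th3), 1L)
  expect_true(is.na(th3$parent_id))
})

test_that("malformed or empty input is rejected", {
  expect_error(build_reply_tree(tibble::tibble(
    author_id = character(0), depth = integer(0), text = character(0)
  )), "empty thread")
  # depth jump with no depth-(d-1) predecessor
  expect_error(build_reply_tree(tibble::tibble(
    author_id = c("u1", "u2"), depth = c(0, 2), text = c("a", "b")
  )), "malformed indent")
  expect_error(build_reply_tree(tibble::tibble(
    author_id = c("u1", "u2"), depth = c(1, 2), text = c("a", "b")
  )), "malformed indent")
})

test_that("blank posts are dropped with a warning and descendants re-attach", {
  expect_warning(
    th <- build_reply_tree(tibble::tibble(
      author_id = c("u1", "u2", "u3", "u4"),
      depth = c(0, 1, 1, 2),
      text = c("root", "first reply", "   ", "reply to deleted")
    )),
    "dropping"
  )
  expect_equal(nrow(th), 3L)
  # the depth-2 post re-attaches to the surviving depth-1 post
  expect_equal(th$parent_id[th$post_id == "p4"], "p2")
})

test_that("extraction returns exactly the qualifying triples in order", {
  fix <- make_figure2_fixture()
  rel <- extract_relationships(fix)
  expect_equal(nrow(rel), 2L)
  expect_equal(rel$a_id, c("pA", "pA"))
  expect_equal(rel$b_id, c("pB", "pBp"))
  expect_equal(rel$c_id, c("pC", "pCp"))

  # single-post thread: nothing to extract
  single <- build_reply_tree(tibble::tibble(
    author_id = "u1", depth = 0, text = "alone"))
  expect_equal(nrow(extract_relationships(single)), 0L)

  # chain a <- b <- c with the wrong counter-reply author
  chain <- build_reply_tree(tibble::tibble(
    author_id = c("u1", "u2", "u3"), depth = c(0, 1, 2),
    text = paste("t", 1:3)))
  expect_equal(nrow(extract_relationships(chain)), 0L)

  # deep chain: only the triple anchored at the initial post qualifies
  deep <- build_reply_tree(tibble::tibble(
    author_id = c("u1", "u2", "u1", "u2", "u1"), depth = 0:4,
    text = paste("t", 1:5)))
  rel_deep <- extract_relationships(deep)
  expect_equal(nrow(rel_deep), 1L)
  expect_equal(unlist(rel_deep[1, c("a_id", "b_id", "c_id")],
                      use.names = FALSE), c("p1", "p2", "p3"))
})

test_that("extraction equals the brute-force definition on random trees", {
  withr::with_seed(42, {
    for (i in 1:30) {
      spec <- random_thread_spec(sample(2:30, 1))
      th <- build_reply_tree(spec)
      got <- extract_relationships(th)
      want <- brute_force_triples(th)
      expect_equal(got[order(got$b_id, got$c_id), c("a_id", "b_id", "c_id")],
                   want[order(want$b_id, want$c_id), ],
                   ignore_attr = TRUE)
      # count bounded by the number of grandchildren of the root
      root <- th$post_id[th$order_index == 0]
      kids <- th$post_id[!is.na(th$parent_id) & th$parent_id == root]
      grandkids <- sum(!is.na(th$parent_id) & th$parent_id %in% kids)
      expect_lte(nrow(got), grandkids)
    }
  })
})

test_that("building a tree preserves the input depth sequence", {
  withr::with_seed(99, {
    for (i in 1:10) {
      spec <- random_thread_spec(sample(2:25, 1))
      th <- build_reply_tree(spec)
      expect_equal(th$depth, spec$depth)
      expect_equal(th$author_id, spec$author_id)
    }
  })
})

test_that("extraction handles several threads at once, per thread", {
  two <- dplyr::bind_rows(
    make_figure2_fixture(),
    build_reply_tree(tibble::tibble(
      author_id = c("x1", "x2", "x1"), depth = c(0, 1, 2),
      text = paste("t", 1:3)), thread_id = "other")
  )
  rel <- extract_relationships(two)
  expect_equal(sort(unique(rel$thread_id)), c("fig2", "other"))
  expect_equal(nrow(rel), 3L)
})
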