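# Independent oracles and small fixture builders shared across tests.

# Brute-force enumeration of all ordered post triples, filtered by the four
# relationship predicates. Independent of extract_relationships().
brute_force_triples <- function(posts) {
  root <- posts$post_id[which.min(posts$order_index)]
  root_author <- posts$author_id[posts$post_id == root]
  parent <- setNames(posts$parent_id, posts$post_id)
  author <- setNames(posts$author_id, posts$post_id)
  ids <- posts$post_id
  out <- list()
  for (a in ids) for (b in ids) for (c in ids) {
    if (a == b || b == c || a == c) next
    if (a != root) next
    if (is.na(parent[b]) || parent[b] != a) next
    if (is.na(parent[c]) || parent[c] != b) next
    if (author[a] != author[c]) next
    if (author[b] == author[a]) next
    out[[length(out) + 1L]] <- c(a = a, b = b, c = c)
  }
  if (!length(out)) {
    return(tibble::tibble(a_id = character(0), b_id = character(0),
                          c_id = character(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(a_id = m[, "a"], b_id = m[, "b"], c_id = m[, "c"])
}

# Random indent-annotated thread honoring the builder preconditions
# (first post depth 0; each later depth <= running max + 1).
random_thread_spec <- function(n_posts, n_authors = 4) {
  authors <- paste0("u", seq_len(n_authors))
  depth <- integer(n_posts)
  for (i in seq_len(n_posts)[-1]) {
    depth[i] <- sample.int(max(depth[seq_len(i - 1L)]) + 1L, 1L)
  }
  tibble::tibble(
    author_id = c(authors[1], sample(authors, n_posts - 1L, replace = TRUE)),
    depth = depth,
    text = paste("post text number", seq_len(n_posts))
  )
}

# Mann-Whitney U normalization of ROC AUC: P(score_pos > score_neg) with
# ties counting one half.
mwu_auc <- function(y, scores) {
  pos <- scores[y > 0]
  neg <- scores[y <= 0]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# Tiny deterministic embedding table over an explicit vector list.
manual_embeddings <- function(vecs) {
  m <- do.call(rbind, vecs)
  structure(list(
    vocabulary = setNames(seq_along(vecs), names(vecs)),
    dim = ncol(m), vectors = m, oov_policy = "zero"
  ), class = "embedding_table")
}

# Balanced labeled pairs over two disjoint topic vocabularies: same-topic
# pairs are relevant, cross-topic pairs are not.
make_topic_pairs <- function(n = 200, seed = 7, n_words = 8) {
  vocab <- list(paste0("alphaterm", 1:20), paste0("betaterm", 1:20))
  withr::with_seed(seed, {
    mk <- function(topic) paste(sample(vocab[[topic]], n_words, TRUE),
                                collapse = " ")
    half <- n %/% 2
    same <- tibble::tibble(
      text_a = replicate(half, mk(sample(1:2, 1))), text_b = NA_character_,
      label = 1L)
    same$text_b <- vapply(same$text_a, \(x) {
      topic <- if (grepl("alpha", x)) 1 else 2
      mk(topic)
    }, character(1), USE.NAMES = FALSE)
    diff <- tibble::tibble(
      text_a = replicate(n - half, mk(1)),
      text_b = replicate(n - half, mk(2)), label = 0L)
    dplyr::slice_sample(dplyr::bind_rows(same, diff), prop = 1)
  })
}

# Synthetic separable feature bundles for the deep combiner: relevance
# vectors shifted by their gold relevance flag, labels by the influence
# definition.
make_synthetic_bundles <- function(n = 400, width = 8, seed = 7) {
  withr::with_seed(seed, {
    rel_ab <- runif(n) < 0.7
    rel_bc <- runif(n) < 0.7
    has_q <- runif(n) < 0.45
    has_a <- runif(n) < 0.45
    mkv <- function(rel) {
      lapply(rel, \(r) rnorm(width, mean = if (r) 1 else -1, sd = 0.8))
    }
    tibble::tibble(
      v_ab = mkv(rel_ab), v_bc = mkv(rel_bc),
      q = ifelse(has_q, 1.0, 0),
      a = ifelse(has_a, 1.0, 0.5),
      label = ifelse(rel_ab & rel_bc & (has_q | has_a), 1L, -1L)
    )
  })
}

# Small end-to-end corpus + light hyperparameters for fast pipeline tests.
small_pipeline <- function(n_threads = 30, seed = 11, combine_op = "dot",
                           arch = "arc1") {
  corp <- generate_corpus(synth_config(n_threads = n_threads, seed = seed))
  run_influence_pipeline(
    corp, arch = arch, combine_op = combine_op,
    relevance_hyper = relevance_hyper(epochs = 3L),
    influence_hyper = influence_hyper(epochs = 20L),
    seed = seed
  )
}
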