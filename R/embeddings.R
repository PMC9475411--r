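#' Tokenize text
#'
#' Lowercases and extracts word tokens (letters, digits, apostrophes,
#' underscores). Contracted "'ll" splits off as its own token so the future
#' construction is visible to the action rules and the embedding vocabulary.
#'
#' @param text Character vector.
#' @return A list of character vectors of tokens (a plain character vector
#'   if `text` has length 1).
#' @export
tokenize <- function(text) {
  out <- lapply(tolower(text), \(x) {
    x <- gsub("'ll\\b", " 'll", x)
    toks <- regmatches(x, gregexpr("[[:alnum:]_']+", x))[[1]]
    toks[nzchar(toks)]
  })
  if (length(text) == 1L) out[[1]] else out
}

#' Train word embeddings on a corpus
#'
#' Learns dense word vectors from token co-occurrence within a sliding
#' window, by truncated SVD of the positive pointwise mutual information
#' (PPMI) matrix — the count-based counterpart of skip-gram training, with
#' the advantage of being exactly deterministic. The embedding of token w is
#' row w of U %*% diag(sqrt(s)) for the top `dim` singular triplets.
#'
#' @param corpus A list of token vectors (documents), e.g. from
#'   [tokenize()], or a character vector of raw texts.
#' @param dim Embedding width. Reduced (with a warning) if the vocabulary is
#'   smaller than `dim`.
#' @param window Co-occurrence window: tokens at distance 1..`window` count
#'   as context.
#' @param min_count Minimum corpus frequency for a token to get a vector.
#' @param seed Kept for interface symmetry with stochastic trainers; the
#'   factorization is deterministic and does not consume randomness.
#' @return An object of class `embedding_table`: list with `vocabulary`
#'   (named index), `dim`, `vectors` (|V| x dim matrix), and `oov_policy`
#'   (`"zero"`: out-of-vocabulary tokens embed to the zero vector).
#' @export
train_embeddings <- function(corpus, dim = 50, window = 5, min_count = 1,
                             seed = 1L) {
  if (is.character(corpus)) corpus <- tokenize_corpus(corpus)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) abort("empty corpus: nothing to train embeddings on.")

  counts <- table(unlist(corpus, use.names = FALSE))
  vocab_tokens <- sort(names(counts[counts >= min_count]))
  if (length(vocab_tokens) == 0L) abort("min_count filtered out the whole vocabulary.")
  vocab <- setNames(seq_along(vocab_tokens), vocab_tokens)
  v <- length(vocab)

  pair_i <- integer(0)
  pair_j <- integer(0)
  for (doc in corpus) {
    ids <- unname(vocab[doc])
    ids <- ids[!is.na(ids)]
    n <- length(ids)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      pair_i <- c(pair_i, ids[seq_len(n - off)])
      pair_j <- c(pair_j, ids[seq_len(n - off) + off])
    }
  }
  half <- unclass(table(factor(pair_i, levels = seq_len(v)),
                        factor(pair_j, levels = seq_len(v))))
  co <- half + t(half)  # symmetric window counts
  dimnames(co) <- list(vocab_tokens, vocab_tokens)

  total <- sum(co)
  if (total == 0) {
    # single-token documents only: no co-occurrence signal, fall back to
    # an identity-like embedding so the contract (a row per token) holds
    pm <- diag(v)
  } else {
    pw <- rowSums(co) / total
    pij <- co / total
    pmi <- log(pmax(pij, .Machine$double.xmin) / outer(pw, pw))
    pmi[co == 0] <- 0
    pm <- pmax(pmi, 0)
  }

  k <- min(dim, v)
  if (k < dim) {
    warn(paste0("vocabulary (", v, ") smaller than dim (", dim,
                "); using dim = ", k, "."))
  }
  dec <- svd(pm, nu = k, nv = 0)
  u <- dec$u
  # fix the sign indeterminacy of each singular vector
  for (j in seq_len(k)) {
    s <- sign(u[which.max(abs(u[, j])), j])
    if (s < 0) u[, j] <- -u[, j]
  }
  vectors <- u %*% diag(sqrt(dec$d[seq_len(k)]), k, k)
  rownames(vectors) <- vocab_tokens

  structure(list(vocabulary = vocab, dim = k, vectors = vectors,
                 oov_policy = "zero"),
            class = "embedding_table")
}

tokenize_corpus <- function(text) {
  out <- lapply(text, \(x) tokenize(x))
  out
}

#' Look up embeddings for a token sequence
#'
#' @param tokens Character vector of tokens.
#' @param emb An [train_embeddings()] table.
#' @return A `length(tokens)` x `emb$dim` matrix; out-of-vocabulary tokens
#'   map to the zero vector.
#' @export
embed_tokens <- function(tokens, emb) {
  idx <- emb$vocabulary[tokens]
  out <- matrix(0, length(tokens), emb$dim)
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- emb$vectors[idx[hit], , drop = FALSE]
  out
}

#' Word-by-word interaction matrix of two token sequences
#'
#' Cell (i, j) is the dot product of the embedding of token i of the first
#' text with the embedding of token j of the second — the local relevance
#' signal that the interaction-based matcher convolves over.
#'
#' @param tokens_a,tokens_b Non-empty character vectors of tokens.
#' @param emb An [train_embeddings()] table.
#' @return A `length(tokens_a)` x `length(tokens_b)` numeric matrix.
#' @export
interaction_matrix <- function(tokens_a, tokens_b, emb) {
  if (length(tokens_a) == 0L || length(tokens_b) == 0L) {
    abort("both token sequences must be non-empty.")
  }
  embed_tokens(tokens_a, emb) %*% t(embed_tokens(tokens_b, emb))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", length(x$vocabulary), " tokens x ", x$dim,
      " dims (oov -> zero vector)\n", sep = "")
  invisible(x)
}
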