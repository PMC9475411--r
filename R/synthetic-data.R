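#' Configuration for the synthetic thread generator
#'
#' The generator emulates the statistical structure the influence pipeline
#' relies on, without natural-language realism: each thread has a topic;
#' posts are bags of topic-vocabulary tokens mixed with shared tokens and
#' uniform noise; a reply shares its parent's topic with probability
#' `p_reply_relevant` (pairwise relevance is therefore purely topical); and
#' counter-replies by the initial author optionally carry a templated
#' question sentence and/or future-action sentence. Gold labels follow the
#' influence definition: a triple is positive iff both pairs are topically
#' relevant and p_C received a question or action sentence.
#'
#' Default rates are chosen so the positive-triple fraction
#' (`p_reply_relevant^2 * (p_question + p_action - p_question*p_action)`
#' = 0.34 at the defaults) sits near the class imbalance typical of
#' hand-labeled forum relationship data (roughly 0.3).
#'
#' @param n_threads Number of threads.
#' @param topics Number of disjoint topic vocabularies.
#' @param topic_vocab_size Tokens per topic vocabulary.
#' @param shared_vocab_size Topic-neutral tokens available to every post.
#' @param sentence_length Tokens per generated sentence.
#' @param branching Maximum direct replies to the initial post.
#' @param p_reply_relevant Probability a reply keeps its parent's topic.
#' @param p_question Probability a counter-reply gets a question sentence.
#' @param p_action Probability a counter-reply gets an action sentence.
#' @param noise_rate Per-token probability of replacement by a random token
#'   from the union vocabulary.
#' @param seed Integer seed; the whole corpus is a deterministic function of
#'   the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_threads = 200L, topics = 4L,
                         topic_vocab_size = 40L, shared_vocab_size = 15L,
                         sentence_length = 7L, branching = 3L,
                         p_reply_relevant = 0.7, p_question = 0.45,
                         p_action = 0.45, noise_rate = 0.15, seed = 7L) {
  probs <- c(p_reply_relevant, p_question, p_action, noise_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  sizes <- c(n_threads, topics, topic_vocab_size, shared_vocab_size,
             sentence_length, branching)
  if (any(sizes < 1)) abort("sizes must be positive.")
  structure(list(n_threads = as.integer(n_threads), topics = as.integer(topics),
                 topic_vocab_size = as.integer(topic_vocab_size),
                 shared_vocab_size = as.integer(shared_vocab_size),
                 sentence_length = as.integer(sentence_length),
                 branching = as.integer(branching),
                 p_reply_relevant = p_reply_relevant,
                 p_question = p_question, p_action = p_action,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# token banks: lowercase pseudo-terms, guaranteed free of question-rule
# trigger words and modal auxiliaries so only inserted sentences fire rules
synth_vocab <- function(config) {
  topics <- lapply(seq_len(config$topics), \(t) {
    sprintf("topic%dterm%02d", t, seq_len(config$topic_vocab_size))
  })
  shared <- sprintf("shared%02d", seq_len(config$shared_vocab_size))
  list(topics = topics, shared = shared, all = c(unlist(topics), shared))
}

question_bank <- function() {
  c("what is the best option for %s?",
    "what does %s feel like?",
    "how do people manage %s?",
    "where did you learn about %s?",
    "when does %s usually start?")
}

action_bank <- function() {
  c("i will consider %s for my plan.",
    "i will ask my doctor about %s.",
    "i think i should try %s soon.",
    "i am going to start %s next week.",
    "maybe i could look into %s.")
}

synth_sentence <- function(topic_words, shared, all_vocab, config) {
  n <- config$sentence_length
  base <- sample(topic_words, n, replace = TRUE)
  sh <- runif(n) < 0.2
  base[sh] <- sample(shared, sum(sh), replace = TRUE)
  nz <- runif(n) < config$noise_rate
  base[nz] <- sample(all_vocab, sum(nz), replace = TRUE)
  paste0(paste(base, collapse = " "), ".")
}

synth_post_text <- function(topic, vocab, config, n_sentences = 2L) {
  paste(replicate(n_sentences,
                  synth_sentence(vocab$topics[[topic]], vocab$shared,
                                 vocab$all, config)),
        collapse = " ")
}

#' Generate a synthetic labeled corpus
#'
#' Produces threads, gold-labeled relevance pairs, and gold-labeled
#' influence triples from a [synth_config()]. Thread shape: an initial post;
#' 1..`branching` direct replies by distinct other authors; each direct
#' reply gets a counter-reply by the initial author with probability 0.8
#' (triples need a counter-reply) or by a further author otherwise.
#'
#' Pair labels: relevant (1) iff the two posts share a topic. Triple labels:
#' +1 iff both its pairs are relevant and p_C received a question and/or
#' action sentence; otherwise -1. Inserted question sentences always end in
#' `?` and inserted action sentences always contain a modal or periphrastic
#' future, so the rule modules detect them by construction.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_corpus`: `posts` (all threads, reply maps
#'   built), `pairs` (thread_id, post_id_a, post_id_b, label), `triples`
#'   (thread_id, a_id, b_id, c_id, label, plus the generator's gold flags
#'   `rel_ab`, `rel_bc`, `has_question`, `has_action`), and `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  vocab <- synth_vocab(config)
  withr::with_seed(config$seed, {
    threads <- lapply(seq_len(config$n_threads), \(t) {
      synth_thread(t, vocab, config)
    })
  })
  posts <- dplyr::bind_rows(purrr::map(threads, "posts"))
  pairs <- dplyr::bind_rows(purrr::map(threads, "pairs"))
  triples <- dplyr::bind_rows(purrr::map(threads, "triples"))
  structure(list(posts = posts, pairs = pairs, triples = triples,
                 config = config),
            class = "synth_corpus")
}

# sample() treats a length-1 numeric as 1:x; this keeps set semantics
resample <- function(x, n) x[sample.int(length(x), n)]

synth_thread <- function(t, vocab, config) {
  tid <- sprintf("t%04d", t)
  init_author <- sprintf("%s_u0", tid)
  topic_a <- sample.int(config$topics, 1L)
  rows <- list(tibble(author_id = init_author, depth = 0L,
                      text = synth_post_text(topic_a, vocab, config),
                      topic = topic_a, question = FALSE, action = FALSE))
  n_replies <- sample.int(config$branching, 1L)
  gold <- list()
  for (r in seq_len(n_replies)) {
    rel_ab <- runif(1) < config$p_reply_relevant
    topic_b <- if (rel_ab) topic_a else
      resample(setdiff(seq_len(config$topics), topic_a), 1L)
    rows <- c(rows, list(tibble(
      author_id = sprintf("%s_u%d", tid, r), depth = 1L,
      text = synth_post_text(topic_b, vocab, config),
      topic = topic_b, question = FALSE, action = FALSE)))
    if (runif(1) < 0.8) {
      # counter-reply by the initial author: completes a triple
      rel_bc <- runif(1) < config$p_reply_relevant
      topic_c <- if (rel_bc) topic_b else
        resample(setdiff(seq_len(config$topics), topic_b), 1L)
      has_q <- runif(1) < config$p_question
      has_a <- runif(1) < config$p_action
      txt <- synth_post_text(topic_c, vocab, config)
      tw <- \() sample(vocab$topics[[topic_c]], 1L)
      if (has_q) txt <- paste(txt, sprintf(sample(question_bank(), 1L), tw()))
      if (has_a) txt <- paste(txt, sprintf(sample(action_bank(), 1L), tw()))
      rows <- c(rows, list(tibble(
        author_id = init_author, depth = 2L, text = txt,
        topic = topic_c, question = has_q, action = has_a)))
      gold <- c(gold, list(tibble(
        b_pos = length(rows) - 1L, c_pos = length(rows),
        rel_ab = rel_ab, rel_bc = rel_bc,
        has_question = has_q, has_action = has_a)))
    } else if (runif(1) < 0.5) {
      # counter-reply by yet another author: no triple arises
      topic_c <- if (runif(1) < config$p_reply_relevant) topic_b else
        sample.int(config$topics, 1L)
      rows <- c(rows, list(tibble(
        author_id = sprintf("%s_u%d", tid, config$branching + r), depth = 2L,
        text = synth_post_text(topic_c, vocab, config),
        topic = topic_c, question = FALSE, action = FALSE)))
    }
  }
  raw <- dplyr::bind_rows(rows)
  raw$post_id <- sprintf("%s_p%d", tid, seq_len(nrow(raw)))
  th <- build_reply_tree(raw[, c("post_id", "author_id", "depth", "text")],
                         thread_id = tid)
  th$topic <- raw$topic

  gold <- dplyr::bind_rows(gold)
  if (nrow(gold)) {
    triples <- tibble(
      thread_id = tid,
      a_id = raw$post_id[1],
      b_id = raw$post_id[gold$b_pos],
      c_id = raw$post_id[gold$c_pos],
      rel_ab = gold$rel_ab, rel_bc = gold$rel_bc,
      has_question = gold$has_question, has_action = gold$has_action
    )
    triples$label <- ifelse(triples$rel_ab & triples$rel_bc &
                              (triples$has_question | triples$has_action),
                            1L, -1L)
    pairs <- dplyr::bind_rows(
      tibble(thread_id = tid, post_id_a = triples$a_id,
             post_id_b = triples$b_id, label = as.integer(triples$rel_ab)),
      tibble(thread_id = tid, post_id_a = triples$b_id,
             post_id_b = triples$c_id, label = as.integer(triples$rel_bc))
    )
  } else {
    triples <- tibble(thread_id = character(0), a_id = character(0),
                      b_id = character(0), c_id = character(0),
                      rel_ab = logical(0), rel_bc = logical(0),
                      has_question = logical(0), has_action = logical(0),
                      label = integer(0))
    pairs <- tibble(thread_id = character(0), post_id_a = character(0),
                    post_id_b = character(0), label = integer(0))
  }
  list(posts = th, pairs = pairs, triples = triples)
}

#' Five-post worked-example thread
#'
#' The canonical two-chain thread: initial post p_A by the initial author;
#' two direct replies p_B and p_B' by two different other users; a
#' counter-reply p_C (under p_B) asking a follow-up question and a
#' counter-reply p_C' (under p_B') announcing a future action, both by the
#' initial author. Relationship extraction on this thread yields exactly the
#' two triples (p_A, p_B, p_C) and (p_A, p_B', p_C').
#'
#' @return A posts tibble of the five-post thread, reply map built.
#' @export
make_figure2_fixture <- function() {
  build_reply_tree(tibble(
    post_id = c("pA", "pB", "pC", "pBp", "pCp"),
    author_id = c("u1", "u2", "u1", "u3", "u1"),
    depth = c(0L, 1L, 2L, 1L, 2L),
    text = c(
      "Should I have chemo before the surgery for my mom?",
      "My doctor suggested chemo first to shrink the tumor; it worked for me.",
      "Thank you. What does the chemo schedule look like?",
      "A wig helped me a lot with the hair loss during chemo.",
      "Thanks so much. I will consider this suggestion for my mom."
    )
  ), thread_id = "fig2")
}

#' Write a synthetic corpus to disk
#'
#' Writes `threads.jsonl` (JSON thread schema), `pairs.tsv` and
#' `triples.tsv` (the labeled TSV interfaces), and `manifest.json`
#' (config and seed) under `dir`.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synth_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_threads_jsonl(corpus$posts, file.path(dir, "threads.jsonl"))
  write_pair_labels(corpus$pairs, file.path(dir, "pairs.tsv"))
  readr::write_tsv(corpus$triples, file.path(dir, "triples.tsv"))
  jsonlite::write_json(unclass(corpus$config),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a synthetic corpus written by [write_corpus()]
#'
#' @param dir Directory containing `threads.jsonl`, `pairs.tsv`,
#'   `triples.tsv`, and `manifest.json`.
#' @return A `synth_corpus` list.
#' @export
read_corpus <- function(dir) {
  posts <- read_threads_json(file.path(dir, "threads.jsonl"))
  pairs <- read_pair_labels(file.path(dir, "pairs.tsv"))
  triples <- readr::read_tsv(file.path(dir, "triples.tsv"),
                             col_types = readr::cols(
                               thread_id = readr::col_character(),
                               a_id = readr::col_character(),
                               b_id = readr::col_character(),
                               c_id = readr::col_character(),
                               rel_ab = readr::col_logical(),
                               rel_bc = readr::col_logical(),
                               has_question = readr::col_logical(),
                               has_action = readr::col_logical(),
                               label = readr::col_integer()
                             ))
  cfg <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  config <- do.call(synth_config, cfg)
  structure(list(posts = posts, pairs = pairs, triples = triples,
                 config = config),
            class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("<synth_corpus> ", length(unique(x$posts$thread_id)), " threads, ",
      nrow(x$posts), " posts, ", nrow(x$pairs), " labeled pairs, ",
      nrow(x$triples), " labeled triples (",
      sum(x$triples$label > 0), " positive)\n", sep = "")
  invisible(x)
}
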