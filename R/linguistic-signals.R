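#' Question-detection rule table
#'
#' The question detector is rule based: a sentence containing a question mark
#' is a question with confidence `qmark_confidence`; otherwise, a sentence
#' whose initial tokens match a 5W1H pattern (an interrogative word followed
#' by an auxiliary, e.g. "what is", "who can", "how do") is a question with
#' the lower `pattern_confidence`. Bare interrogative words are deliberately
#' not matched: "what is a port" is a question, "what happened to me was
#' rough" is not flagged by the pattern rule.
#'
#' @param qmark_confidence Confidence assigned to sentences containing `?`.
#' @param pattern_confidence Confidence for sentence-initial 5W1H patterns;
#'   must be strictly below `qmark_confidence`.
#' @param patterns Character vector of lowercase sentence-initial token
#'   sequences, each beginning with a 5W1H word. Defaults to the full
#'   5W1H-by-auxiliary expansion of [default_question_patterns()].
#' @return A list of class `question_rules`.
#' @export
question_rules <- function(qmark_confidence = 1.0,
                           pattern_confidence = 0.9,
                           patterns = default_question_patterns()) {
  if (!(pattern_confidence >= 0 && pattern_confidence < qmark_confidence &&
        qmark_confidence <= 1)) {
    abort("need 0 <= pattern_confidence < qmark_confidence <= 1.")
  }
  patterns <- tolower(patterns)
  w5h1 <- c("what", "who", "when", "where", "why", "how")
  first <- vapply(strsplit(patterns, "\\s+"), `[[`, "", 1L)
  if (!all(first %in% w5h1)) {
    abort("every pattern must begin with a 5W1H word.")
  }
  structure(list(qmark_confidence = qmark_confidence,
                 pattern_confidence = pattern_confidence,
                 patterns = patterns),
            class = "question_rules")
}

#' @rdname question_rules
#' @export
default_question_patterns <- function() {
  w5h1 <- c("what", "who", "when", "where", "why", "how")
  aux <- c("is", "are", "was", "were", "do", "does", "did",
           "can", "could", "should", "would", "will")
  as.vector(outer(w5h1, aux, paste))
}

#' Split a text into sentences
#'
#' Lightweight rule-based segmentation: sentences end at `.`, `!`, or `?`
#' (runs of them, so ellipses do not split) followed by whitespace or end of
#' text. Trailing text without terminal punctuation forms a final sentence.
#' Empty segments are dropped.
#'
#' @param text Character vector; each element is segmented independently.
#' @return A list of character vectors, one per element of `text` (a plain
#'   character vector if `text` has length 1).
#' @export
split_sentences <- function(text) {
  out <- lapply(text, \(x) {
    x <- gsub("\\s+", " ", trimws(x))
    if (!nzchar(x)) return(character(0))
    pieces <- unlist(strsplit(x, "(?<=[.!?])(?<![.!?][.!?])\\s+", perl = TRUE))
    pieces <- trimws(pieces)
    pieces[nzchar(pieces)]
  })
  if (length(text) == 1L) out[[1]] else out
}

#' Question probability of a sentence
#'
#' Applies the rule table: `qmark_confidence` if the sentence contains a
#' question mark, else `pattern_confidence` if the sentence begins
#' (case-insensitively, ignoring leading punctuation) with one of the 5W1H
#' patterns, else 0.
#'
#' @param sentence Character vector of sentences.
#' @param rules A [question_rules()] table.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
sentence_question_prob <- function(sentence, rules = question_rules()) {
  lead <- tolower(sub("^[^[:alnum:]]+", "", sentence))
  pattern_re <- paste0("^(", paste(rules$patterns, collapse = "|"), ")\\b")
  ifelse(grepl("?", sentence, fixed = TRUE), rules$qmark_confidence,
         ifelse(grepl(pattern_re, lead), rules$pattern_confidence, 0))
}

#' Question probability of a post
#'
#' The post-level question probability Q(p) is the maximum sentence-level
#' question probability over the post's sentences: the likelihood that the
#' post contains at least one question. A post with no sentences scores 0.
#'
#' @param text Character vector of post texts (each segmented with
#'   [split_sentences()]), or a list of pre-segmented sentence vectors.
#' @param rules A [question_rules()] table.
#' @return Numeric vector of Q values, one per post.
#' @export
post_question_prob <- function(text, rules = question_rules()) {
  sent <- if (is.list(text)) text else lapply(text, \(x) split_sentences(x))
  vapply(sent, \(s) {
    if (length(s) == 0L) return(0)
    max(sentence_question_prob(s, rules))
  }, numeric(1))
}

# Penn-tag MD modal auxiliaries: a closed word class.
modal_lexicon <- function() {
  c("will", "would", "shall", "should", "can", "could",
    "may", "might", "must", "'ll", "ll")
}

#' Future-action probability of a post
#'
#' A post indicates a future action when any sentence contains a modal
#' auxiliary (Penn tag MD: will, would, can, could, may, might, must, shall,
#' should, or the 'll contraction) or a periphrastic future ("going
#' to"/"gonna" followed by a verb): probability 1.0. When no rule fires the
#' probability falls back to 0.5, reflecting that informal forum writing can
#' express intent without detectable future tense. Negation is deliberately
#' ignored: "I will not do chemo" still signals engagement with the
#' suggestion, and polarity is left to the relevance vectors.
#'
#' @param text Character vector of post texts, or a list of pre-segmented
#'   sentence vectors.
#' @return Numeric vector with values in {0.5, 1.0}.
#' @export
post_action_prob <- function(text) {
  sent <- if (is.list(text)) text else lapply(text, \(x) split_sentences(x))
  modal_re <- paste0("\\b(", paste(c("will", "would", "shall", "should", "can",
                                     "could", "may", "might", "must"),
                                   collapse = "|"), ")\\b")
  future_re <- "\\b(going\\s+to|gonna)\\s+[[:alpha:]]+|'ll\\b"
  vapply(sent, \(s) {
    if (length(s) == 0L) return(0.5)
    s <- tolower(s)
    if (any(grepl(modal_re, s)) || any(grepl(future_re, s))) 1.0 else 0.5
  }, numeric(1))
}

#' Attach question and action signals to posts
#'
#' Convenience wrapper computing the two dense features of the influence
#' model for every post: `q = post_question_prob(text)` and
#' `a = post_action_prob(text)`.
#'
#' @param posts A posts tibble with a `text` column.
#' @param rules A [question_rules()] table.
#' @return `posts` with numeric columns `q` and `a` appended.
#' @export
add_signal_scores <- function(posts, rules = question_rules()) {
  sent <- lapply(posts$text, \(x) split_sentences(x))
  posts$q <- post_question_prob(sent, rules)
  posts$a <- post_action_prob(sent)
  posts
}
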