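#' Build a reply tree from ordered, indent-annotated posts
#'
#' Reconstructs the reply structure of a single discussion thread from posts
#' given in chronological order with an indent depth per post (in forum HTML
#' dumps, depth is the number of leading tab characters). Each post at depth
#' `d >= 1` is attached to the most recent preceding post at depth `d - 1`;
#' the depth-0 post is the thread's initial post and the root of the tree.
#'
#' Posts whose text is empty after whitespace normalization (deleted posts)
#' are dropped with a warning before the tree is built; the depths of their
#' descendants are shifted so that orphans re-attach by the same
#' most-recent-shallower-post rule.
#'
#' @param posts A data frame with one row per post in chronological order,
#'   with columns `author_id`, `depth`, `text`, and optionally `post_id`
#'   (generated as `"p1"`, `"p2"`, ... when absent) and `thread_id`.
#' @param thread_id Thread identifier used when `posts` has no `thread_id`
#'   column.
#'
#' @return A tibble of posts (class `ohc_thread`) with columns `thread_id`,
#'   `post_id`, `author_id`, `order_index` (0-based chronological rank),
#'   `depth`, `text`, and `parent_id` (`NA` for the initial post). The
#'   `parent_id` column is the reply map: it sends each reply to the post it
#'   answers.
#'
#' @examples
#' posts <- tibble::tibble(
#'   author_id = c("u1", "u2", "u1", "u3", "u1"),
#'   depth     = c(0, 1, 2, 1, 2),
#'   text      = c("Should I do chemo first?", "I would do chemo first.",
#'                 "What does the recovery look like?", "Ask your oncologist.",
#'                 "I will ask at my next visit.")
#' )
#' build_reply_tree(posts)
#' @export
build_reply_tree <- function(posts, thread_id = "t1") {
  if (!is.data.frame(posts)) abort("`posts` must be a data frame.")
  required <- c("author_id", "depth", "text")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols)) {
    abort(paste0("`posts` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  posts <- as_tibble(posts)
  if (nrow(posts) == 0L) abort("empty thread: no posts to build a tree from.")

  if (!"post_id" %in% names(posts)) {
    posts$post_id <- paste0("p", seq_len(nrow(posts)))
  }
  if (!"thread_id" %in% names(posts)) posts$thread_id <- thread_id

  # drop deleted/blank posts; descendants re-attach to the nearest surviving
  # shallower post because attachment only looks at *preceding surviving* rows
  blank <- !nzchar(trimws(posts$text))
  if (any(blank)) {
    warn(paste0("dropping ", sum(blank), " empty post(s): ",
                paste(posts$post_id[blank], collapse = ", ")))
    posts <- posts[!blank, , drop = FALSE]
    if (nrow(posts) == 0L) abort("empty thread: all posts were blank.")
  }

  depth <- as.integer(posts$depth)
  if (depth[1] != 0L) abort("malformed indent: first post must have depth 0.")
  if (nrow(posts) > 1L && any(depth[-1] < 1L)) {
    abort("malformed indent: only the first post may have depth 0.")
  }

  n <- nrow(posts)
  parent_id <- rep(NA_character_, n)
  # last_at[d + 1] = post_id of most recent post seen at depth d
  last_at <- character(0)
  for (i in seq_len(n)) {
    d <- depth[i]
    if (d > 0L) {
      if (length(last_at) < d || is.na(last_at[d])) {
        abort(paste0("malformed indent: post ", posts$post_id[i], " at depth ",
                     d, " has no preceding post at depth ", d - 1L, "."))
      }
      parent_id[i] <- last_at[d]
    }
    last_at[d + 1L] <- posts$post_id[i]
  }

  out <- tibble(
    thread_id = posts$thread_id,
    post_id = posts$post_id,
    author_id = posts$author_id,
    order_index = seq_len(n) - 1L,
    depth = depth,
    text = posts$text,
    parent_id = parent_id
  )
  class(out) <- c("ohc_thread", class(out))
  out
}

#' Extract relationship triples from one or more threads
#'
#' Enumerates all ordered triples (p_A, p_B, p_C) such that p_A is the
#' thread's initial post, p_B replies directly to p_A and is written by a
#' different author, and p_C replies directly to p_B and is written by the
#' initial author. These triples are the unit of influence-relationship
#' classification: p_B may have influenced the initial author, and p_C is
#' where the influence (a follow-up question or a planned action) would show.
#'
#' @param posts A posts tibble as returned by [build_reply_tree()] (columns
#'   `thread_id`, `post_id`, `author_id`, `order_index`, `depth`,
#'   `parent_id`). May contain several threads; triples are extracted per
#'   thread.
#'
#' @return A tibble with columns `thread_id`, `a_id`, `b_id`, `c_id`, ordered
#'   by thread, then by `order_index` of p_B, then of p_C. Zero rows when no
#'   triple qualifies.
#' @export
extract_relationships <- function(posts) {
  if (!is.data.frame(posts)) abort("`posts` must be a data frame.")
  required <- c("thread_id", "post_id", "author_id", "order_index", "parent_id")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols)) {
    abort(paste0("`posts` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  posts <- as_tibble(posts)
  split_threads <- split(posts, posts$thread_id)
  out <- purrr::map(split_threads, extract_relationships_one)
  out <- dplyr::bind_rows(out)
  # deterministic order across threads follows thread id order of appearance
  out[order(match(out$thread_id, unique(posts$thread_id))), , drop = FALSE]
}

extract_relationships_one <- function(th) {
  root <- th$post_id[th$order_index == min(th$order_index)]
  root_author <- th$author_id[th$post_id == root]
  b <- th[!is.na(th$parent_id) & th$parent_id == root &
            th$author_id != root_author, , drop = FALSE]
  if (nrow(b) == 0L) {
    return(tibble(thread_id = character(0), a_id = character(0),
                  b_id = character(0), c_id = character(0)))
  }
  c_cand <- th[!is.na(th$parent_id) & th$parent_id %in% b$post_id &
                 th$author_id == root_author, , drop = FALSE]
  if (nrow(c_cand) == 0L) {
    return(tibble(thread_id = character(0), a_id = character(0),
                  b_id = character(0), c_id = character(0)))
  }
  b_order <- setNames(b$order_index, b$post_id)
  out <- tibble(
    thread_id = c_cand$thread_id,
    a_id = root,
    b_id = c_cand$parent_id,
    c_id = c_cand$post_id,
    .b_ord = b_order[c_cand$parent_id],
    .c_ord = c_cand$order_index
  )
  out <- out[order(out$.b_ord, out$.c_ord), , drop = FALSE]
  out$.b_ord <- NULL
  out$.c_ord <- NULL
  out
}

#' Validate thread invariants
#'
#' Checks that a posts tibble describes a well-formed thread: unique post ids
#' and order indices, exactly one root (depth 0, minimal order index), every
#' non-root post pointing to an earlier parent, and an acyclic reply map.
#'
#' @param posts A single-thread posts tibble.
#' @return `posts`, invisibly; signals an error describing the first violated
#'   invariant otherwise.
#' @export
validate_thread <- function(posts) {
  if (anyDuplicated(posts$post_id)) abort("duplicate post_id within thread.")
  if (anyDuplicated(posts$order_index)) abort("duplicate order_index within thread.")
  roots <- posts$post_id[is.na(posts$parent_id)]
  if (length(roots) != 1L) abort("thread must have exactly one root post.")
  root_row <- posts[posts$post_id == roots, ]
  if (root_row$depth != 0L || root_row$order_index != min(posts$order_index)) {
    abort("root must be the depth-0 post with the smallest order_index.")
  }
  nonroot <- posts[!is.na(posts$parent_id), , drop = FALSE]
  if (nrow(nonroot)) {
    if (!all(nonroot$parent_id %in% posts$post_id)) {
      abort("reply map points to unknown post_id.")
    }
    ord <- setNames(posts$order_index, posts$post_id)
    if (!all(ord[nonroot$parent_id] < nonroot$order_index)) {
      abort("a parent post must precede its replies chronologically.")
    }
  }
  invisible(posts)
}
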