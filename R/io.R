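#' Read threads from the JSON thread schema
#'
#' Reads discussion threads stored either as a single JSON document
#' (`{"thread_id": ..., "posts": [...]}`, or a JSON array of such objects) or
#' as JSON-lines (one thread object per line, file extension `.jsonl`). Each
#' post object carries `post_id`, `author_id`, `depth`, and `text`, in
#' chronological order; the reply tree is rebuilt from the depths with
#' [build_reply_tree()].
#'
#' @param path Path to a `.json` or `.jsonl` file.
#' @return A posts tibble covering all threads in the file, with the reply
#'   map (`parent_id`) reconstructed.
#' @export
read_threads_json <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    threads <- purrr::map(lines, \(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  } else {
    parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    threads <- if (!is.null(parsed$thread_id)) list(parsed) else parsed
    threads <- purrr::map(threads, \(th) {
      th$posts <- dplyr::bind_rows(purrr::map(th$posts, as_tibble))
      th
    })
  }
  purrr::map(threads, \(th) {
    build_reply_tree(as_tibble(th$posts), thread_id = th$thread_id)
  }) |>
    dplyr::bind_rows()
}

#' Write threads to JSON-lines
#'
#' Inverse of [read_threads_json()]: one thread object per line, posts in
#' chronological order with `post_id`, `author_id`, `depth`, `text`.
#'
#' @param posts A posts tibble (possibly many threads).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threads_jsonl <- function(posts, path) {
  threads <- split(as_tibble(posts), factor(posts$thread_id,
                                            levels = unique(posts$thread_id)))
  lines <- purrr::map_chr(threads, \(th) {
    th <- th[order(th$order_index), ]
    jsonlite::toJSON(list(
      thread_id = th$thread_id[1],
      posts = th[, c("post_id", "author_id", "depth", "text")]
    ), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read threads from an indented HTML dump
#'
#' Parses forum HTML where each post is a `<div class="post">` block with a
#' `data-author` attribute, grouped in `<div class="thread">` blocks carrying
#' an `id`. The reply depth of a post is the number of leading tab characters
#' in its text, as in forum dumps that encode the reply tree by indentation.
#'
#' @param path Path to an HTML file.
#' @return A posts tibble with the reply map reconstructed.
#' @export
read_threads_html <- function(path) {
  doc <- xml2::read_html(path)
  thread_nodes <- xml2::xml_find_all(doc, "//div[@class='thread']")
  if (length(thread_nodes) == 0L) abort("no <div class='thread'> blocks found.")
  purrr::map(seq_along(thread_nodes), \(i) {
    tn <- thread_nodes[[i]]
    id <- xml2::xml_attr(tn, "id")
    if (is.na(id)) id <- paste0("thread", i)
    post_nodes <- xml2::xml_find_all(tn, ".//div[@class='post']")
    raw <- purrr::map_chr(post_nodes, xml2::xml_text)
    tibble(
      author_id = purrr::map_chr(post_nodes, \(p) xml2::xml_attr(p, "data-author")),
      depth = nchar(raw) - nchar(sub("^\t*", "", raw)),
      text = trimws(raw)
    ) |>
      build_reply_tree(thread_id = id)
  }) |>
    dplyr::bind_rows()
}

#' Read or write labeled post pairs
#'
#' The labeled-pair TSV has columns `thread_id`, `post_id_a`, `post_id_b`,
#' `label` (1 = relevant, 0 = irrelevant). Pairs are directional: (p_A, p_B)
#' follows the reply direction and is distinct from (p_B, p_A).
#'
#' @param path TSV path.
#' @param pairs A pairs tibble.
#' @return `read_pair_labels()` returns the tibble; `write_pair_labels()`
#'   returns `path` invisibly.
#' @export
read_pair_labels <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    thread_id = readr::col_character(),
    post_id_a = readr::col_character(),
    post_id_b = readr::col_character(),
    label = readr::col_integer()
  ))
}

#' @rdname read_pair_labels
#' @export
write_pair_labels <- function(pairs, path) {
  readr::write_tsv(pairs[, c("thread_id", "post_id_a", "post_id_b", "label")],
                   path)
  invisible(path)
}

#' Read or write labeled relationship triples
#'
#' The labeled-triple TSV has columns `thread_id`, `a_id`, `b_id`, `c_id`,
#' `label` in {1, -1} (+1 = influence relationship). Prediction files append
#' `score` and `pred_label`.
#'
#' @param path TSV path.
#' @param triples A triples tibble; extra columns `score`/`pred_label` are
#'   written when present.
#' @return `read_triple_labels()` returns the tibble; `write_triple_labels()`
#'   returns `path` invisibly.
#' @export
read_triple_labels <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    thread_id = readr::col_character(),
    a_id = readr::col_character(),
    b_id = readr::col_character(),
    c_id = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' @rdname read_triple_labels
#' @export
write_triple_labels <- function(triples, path) {
  keep <- intersect(c("thread_id", "a_id", "b_id", "c_id", "label",
                      "score", "pred_label"), names(triples))
  readr::write_tsv(triples[, keep], path)
  invisible(path)
}

#' Save or load a model checkpoint
#'
#' Checkpoints are single-file binary snapshots embedding the model object
#' and a manifest (package version, class, creation time) so a prediction
#' run can verify what it loaded.
#'
#' @param model A fitted `relevance_model` or `influence_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the model.
#' @export
write_model <- function(model, path) {
  manifest <- list(
    package = "ohcinfluence",
    version = as.character(utils::packageVersion("ohcinfluence")),
    class = class(model)[1],
    created = format(Sys.time(), tz = "UTC")
  )
  saveRDS(list(manifest = manifest, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$manifest) || is.null(obj$model)) {
    abort("not an ohcinfluence checkpoint.")
  }
  obj$model
}
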