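#' Hyperparameters for the text-relevance matchers
#'
#' @param max_len Token-sequence cap; longer posts are truncated (with a
#'   one-time message), never rejected.
#' @param n_filters Number of convolution filters.
#' @param kernel Convolution kernel width (1-D for the representation-based
#'   matcher; `kernel` x `kernel` for the interaction-based one).
#' @param vector_width Width of the relevance vector (the last hidden layer
#'   before the scoring unit).
#' @param pool_grid Dynamic-pooling grid for the interaction-based matcher
#'   (`pool_grid` x `pool_grid` cells).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @return A list of hyperparameters.
#' @export
relevance_hyper <- function(max_len = 128L, n_filters = 32L, kernel = 3L,
                            vector_width = 64L, pool_grid = 4L,
                            epochs = 10L, batch_size = 32L,
                            learning_rate = 1e-3) {
  list(max_len = max_len, n_filters = n_filters, kernel = kernel,
       vector_width = vector_width, pool_grid = pool_grid,
       epochs = epochs, batch_size = batch_size,
       learning_rate = learning_rate)
}

init_relevance_params <- function(arch, emb_dim, hyper) {
  nf <- hyper$n_filters
  vw <- hyper$vector_width
  k <- hyper$kernel
  if (arch == "arc1") {
    # conv weights shared between the two text branches
    list(Wc = glorot(k * emb_dim, nf), bc = numeric(nf),
         Wh = glorot(2L * nf, vw), bh = numeric(vw),
         Wo = glorot(vw, 1L), bo = 0)
  } else {
    g <- hyper$pool_grid
    list(Wc = glorot(k * k, nf), bc = numeric(nf),
         Wh = glorot(g * g * nf, vw), bh = numeric(vw),
         Wo = glorot(vw, 1L), bo = 0)
  }
}

prep_tokens <- function(text, max_len) {
  toks <- lapply(text, \(x) tokenize(x))
  too_long <- lengths(toks) > max_len
  if (any(too_long)) {
    inform(paste0("truncating ", sum(too_long), " text(s) to max_len = ",
                  max_len, " tokens."),
           .frequency = "once", .frequency_id = "ohcinfluence_truncate")
    toks[too_long] <- lapply(toks[too_long], \(t) t[seq_len(max_len)])
  }
  # a text with no word tokens still needs one (OOV -> zero-vector) slot
  lapply(toks, \(t) if (length(t) == 0L) "" else t)
}

relevance_fwd <- function(params, arch, ta, tb, emb, hyper) {
  if (arch == "arc1") {
    ca <- conv1d_pool_fwd(embed_tokens(ta, emb), params$Wc, params$bc,
                          hyper$kernel)
    cb <- conv1d_pool_fwd(embed_tokens(tb, emb), params$Wc, params$bc,
                          hyper$kernel)
    f <- c(ca$p, cb$p)
    hd <- head_fwd(f, params)
    list(score = hd$score, vector = hd$h,
         cache = list(ca = ca, cb = cb, hd = hd))
  } else {
    M <- interaction_matrix(ta, tb, emb)
    cc <- conv2d_pool_fwd(M, params$Wc, params$bc, hyper$kernel,
                          hyper$pool_grid)
    hd <- head_fwd(cc$p, params)
    list(score = hd$score, vector = hd$h, cache = list(cc = cc, hd = hd))
  }
}

relevance_bwd <- function(params, arch, fwd, y, hyper) {
  dzo <- fwd$score - y
  hb <- head_bwd(fwd$cache$hd, params, dzo)
  g <- hb$grads
  if (arch == "arc1") {
    nf <- hyper$n_filters
    ga <- conv1d_pool_bwd(fwd$cache$ca, hb$df[seq_len(nf)])
    gb <- conv1d_pool_bwd(fwd$cache$cb, hb$df[nf + seq_len(nf)])
    list(Wc = ga$dWc + gb$dWc, bc = ga$dbc + gb$dbc,
         Wh = g$dWh, bh = g$dbh, Wo = g$dWo, bo = g$dbo)
  } else {
    gc2 <- conv2d_pool_bwd(fwd$cache$cc, hb$df)
    list(Wc = gc2$dWc, bc = gc2$dbc,
         Wh = g$dWh, bh = g$dbh, Wo = g$dWo, bo = g$dbo)
  }
}

#' Train a text-relevance matcher
#'
#' Fits one of two neural matchers over fixed, corpus-trained word
#' embeddings, by minibatch Adam on binary cross-entropy:
#'
#' * `"arc1"` (representation-based): each text passes through embedding,
#'   1-D convolution, and global max pooling; the two pooled feature vectors
#'   are concatenated and fed to a fully connected layer whose activations
#'   form the relevance vector, then a sigmoid scoring unit.
#' * `"matchpyramid"` (interaction-based): the pairwise word-embedding
#'   dot-product matrix is convolved (2-D), dynamically max-pooled to a
#'   fixed grid, flattened, and fed through the same dense head.
#'
#' Both produce the identical output contract — a relevance score in
#' \[0, 1\] and a fixed-width relevance vector — so downstream influence
#' models are architecture-agnostic.
#'
#' @param pairs A data frame with columns `text_a`, `text_b`, and `label`
#'   (1 = relevant, 0 = irrelevant).
#' @param arch `"arc1"` or `"matchpyramid"`.
#' @param embeddings An [train_embeddings()] table (fixed during training).
#' @param hyper A [relevance_hyper()] list.
#' @param seed Integer seed controlling initialization and batch shuffling;
#'   the same seed reproduces the fit exactly.
#' @return An object of class `relevance_model` with elements `arch`,
#'   `params`, `embeddings`, `hyper`, and `loss` (training-loss trajectory:
#'   entry 1 is the pre-training loss, entry e + 1 the mean minibatch loss
#'   of epoch e).
#' @export
train_relevance_model <- function(pairs, arch = c("arc1", "matchpyramid"),
                                  embeddings, hyper = relevance_hyper(),
                                  seed = 1L) {
  arch <- match.arg(arch)
  if (!all(c("text_a", "text_b", "label") %in% names(pairs))) {
    abort("`pairs` needs columns text_a, text_b, label.")
  }
  y <- as.numeric(pairs$label)
  if (length(unique(y)) < 2L) {
    abort("training labels must contain both classes.")
  }
  ta <- prep_tokens(pairs$text_a, hyper$max_len)
  tb <- prep_tokens(pairs$text_b, hyper$max_len)
  n <- length(y)

  withr::with_seed(seed, {
    params <- init_relevance_params(arch, embeddings$dim, hyper)
    state <- adam_init(params)
    eval_loss <- function() {
      mean(vapply(seq_len(n), \(i) {
        bce_loss(relevance_fwd(params, arch, ta[[i]], tb[[i]],
                               embeddings, hyper)$score, y[i])
      }, numeric(1)))
    }
    loss_traj <- eval_loss()
    if (hyper$epochs > 0L) {
      for (ep in seq_len(hyper$epochs)) {
        ord <- sample.int(n)
        batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
        ep_losses <- numeric(0)
        for (b in batches) {
          acc <- zero_like(params)
          bl <- 0
          for (i in b) {
            fwd <- relevance_fwd(params, arch, ta[[i]], tb[[i]],
                                 embeddings, hyper)
            bl <- bl + bce_loss(fwd$score, y[i])
            acc <- add_grads(acc, relevance_bwd(params, arch, fwd, y[i], hyper))
          }
          upd <- adam_step(params, scale_grads(acc, 1 / length(b)), state,
                           lr = hyper$learning_rate)
          params <- upd$params
          state <- upd$state
          ep_losses <- c(ep_losses, bl / length(b))
        }
        loss_traj <- c(loss_traj, mean(ep_losses))
      }
    }
  })

  structure(list(arch = arch, params = params, embeddings = embeddings,
                 hyper = hyper, loss = loss_traj, seed = seed),
            class = "relevance_model")
}

#' Score post pairs with a trained relevance matcher
#'
#' @param model A [train_relevance_model()] fit.
#' @param pairs A data frame with columns `text_a` and `text_b`.
#' @return `pairs` with a numeric `score` column (relevance probability) and
#'   a `vector` list-column (the relevance vector of each pair) appended.
#'   Inference is deterministic: identical inputs give identical outputs.
#' @export
relevance_score <- function(model, pairs) {
  stopifnot(inherits(model, "relevance_model"))
  ta <- prep_tokens(pairs$text_a, model$hyper$max_len)
  tb <- prep_tokens(pairs$text_b, model$hyper$max_len)
  out <- lapply(seq_along(ta), \(i) {
    relevance_fwd(model$params, model$arch, ta[[i]], tb[[i]],
                  model$embeddings, model$hyper)
  })
  pairs <- as_tibble(pairs)
  pairs$score <- vapply(out, `[[`, numeric(1), "score")
  pairs$vector <- lapply(out, `[[`, "vector")
  pairs
}

#' @export
predict.relevance_model <- function(object, newdata, ...) {
  relevance_score(object, newdata)
}

#' @export
print.relevance_model <- function(x, ...) {
  cat("<relevance_model> arch=", x$arch,
      " | vector width ", x$hyper$vector_width,
      " | ", length(x$loss) - 1L, " epochs",
      " | final loss ", signif(tail(x$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

n_params <- function(params) sum(vapply(params, length, integer(1)))
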