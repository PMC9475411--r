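#' Combine a relevance vector with a scalar signal
#'
#' The two feature-combination operators of the deep influence model:
#' `"dot"` scales every dimension of the relevance vector by the probability
#' (so the question/action signal touches each relevance dimension), while
#' `"cat"` appends the probability as one extra dimension.
#'
#' @param v A numeric vector (relevance vector).
#' @param s A probability in \[0, 1\].
#' @param op `"dot"` or `"cat"`.
#' @return For `"dot"`, `s * v` (same width); for `"cat"`, `c(v, s)`
#'   (width + 1).
#' @export
combine <- function(v, s, op = c("dot", "cat")) {
  op <- match.arg(op)
  if (length(v) == 0L) abort("`v` must be non-empty.")
  if (s < 0 || s > 1) abort("`s` must lie in [0, 1].")
  if (op == "dot") s * v else c(v, s)
}

combine_mat <- function(V, s, op) {
  if (op == "dot") V * s else cbind(V, s)
}

#' Baseline influence classifier (product-threshold rule)
#'
#' Scores a relationship triple as
#' `score = p_ab * p_bc * max(q, a)` and predicts an influence relationship
#' (+1) exactly when all three components clear their thresholds:
#' `p_ab >= thresholds[1]`, `p_bc >= thresholds[2]`, and
#' `max(q, a) >= thresholds[3]` (defaults 0.5, 0.5, 0.9).
#'
#' @param p_ab,p_bc Relevance scores for (p_A, p_B) and (p_B, p_C), or a
#'   data frame with columns `p_ab`, `p_bc`, `q`, `a` as the first argument.
#' @param q,a Question and action probabilities of p_C.
#' @param thresholds Length-3 numeric vector of component cutoffs.
#' @return A tibble with columns `score` and `pred_label` (+1/-1); when a
#'   data frame was supplied, that data frame with the two columns appended.
#' @export
baseline_classify <- function(p_ab, p_bc = NULL, q = NULL, a = NULL,
                              thresholds = c(0.5, 0.5, 0.9)) {
  if (is.data.frame(p_ab)) {
    df <- p_ab
    res <- baseline_classify(df$p_ab, df$p_bc, df$q, df$a, thresholds)
    df$score <- res$score
    df$pred_label <- res$pred_label
    return(as_tibble(df))
  }
  vals <- c(p_ab, p_bc, q, a)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1)) {
    abort("all probabilities must lie in [0, 1].")
  }
  m <- pmax(q, a)
  tibble(
    score = p_ab * p_bc * m,
    pred_label = ifelse(p_ab >= thresholds[1] & p_bc >= thresholds[2] &
                          m >= thresholds[3], 1L, -1L)
  )
}

#' Build feature bundles for relationship triples
#'
#' For each triple (p_A, p_B, p_C) this computes everything the influence
#' classifiers consume: the relevance score and vector of (p_A, p_B) and of
#' (p_B, p_C) from a trained matcher, the question probability Q(p_C), and
#' the action probability A(p_C).
#'
#' @param relationships A triples tibble (`thread_id`, `a_id`, `b_id`,
#'   `c_id`, optionally `label`), e.g. from [extract_relationships()].
#' @param posts The posts tibble the ids refer to.
#' @param relevance_model A [train_relevance_model()] fit.
#' @param rules A [question_rules()] table.
#' @return `relationships` with columns `p_ab`, `p_bc`, `q`, `a` and
#'   list-columns `v_ab`, `v_bc` appended.
#' @export
build_feature_bundles <- function(relationships, posts, relevance_model,
                                  rules = question_rules()) {
  key <- paste(posts$thread_id, posts$post_id)
  txt <- setNames(posts$text, key)
  need <- c(paste(relationships$thread_id, relationships$a_id),
            paste(relationships$thread_id, relationships$b_id),
            paste(relationships$thread_id, relationships$c_id))
  if (!all(need %in% key)) {
    abort("relationship references post ids absent from `posts`.")
  }
  ta <- txt[paste(relationships$thread_id, relationships$a_id)]
  tb <- txt[paste(relationships$thread_id, relationships$b_id)]
  tc <- txt[paste(relationships$thread_id, relationships$c_id)]

  ab <- relevance_score(relevance_model,
                        tibble(text_a = unname(ta), text_b = unname(tb)))
  bc <- relevance_score(relevance_model,
                        tibble(text_a = unname(tb), text_b = unname(tc)))

  out <- as_tibble(relationships)
  out$p_ab <- ab$score
  out$v_ab <- ab$vector
  out$p_bc <- bc$score
  out$v_bc <- bc$vector
  out$q <- post_question_prob(unname(tc), rules)
  out$a <- post_action_prob(unname(tc))
  out
}

#' Hyperparameters for the deep feature-fusion model
#'
#' @param units Width of the four summarizing dense layers and of the merge
#'   layer.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param threshold Decision threshold on the positive-class probability.
#' @return A list of hyperparameters.
#' @export
influence_hyper <- function(units = 32L, epochs = 60L, batch_size = 32L,
                            learning_rate = 1e-3, threshold = 0.5) {
  list(units = units, epochs = epochs, batch_size = batch_size,
       learning_rate = learning_rate, threshold = threshold)
}

init_influence_params <- function(vec_width, combine_op, units) {
  din <- if (combine_op == "cat") vec_width + 1L else vec_width
  list(W1 = glorot(din, units), b1 = numeric(units),
       W2 = glorot(din, units), b2 = numeric(units),
       W3 = glorot(din, units), b3 = numeric(units),
       W4 = glorot(din, units), b4 = numeric(units),
       Wm = glorot(4L * units, units), bm = numeric(units),
       Wo = glorot(units, 2L), bo = numeric(2L))
}

influence_fwd_mat <- function(params, op, Vab, Vbc, q, a) {
  X1 <- combine_mat(Vab, q, op)
  X2 <- combine_mat(Vab, a, op)
  X3 <- combine_mat(Vbc, q, op)
  X4 <- combine_mat(Vbc, a, op)
  Z1 <- sweep(X1 %*% params$W1, 2, params$b1, "+"); S1 <- relu(Z1)
  Z2 <- sweep(X2 %*% params$W2, 2, params$b2, "+"); S2 <- relu(Z2)
  Z3 <- sweep(X3 %*% params$W3, 2, params$b3, "+"); S3 <- relu(Z3)
  Z4 <- sweep(X4 %*% params$W4, 2, params$b4, "+"); S4 <- relu(Z4)
  S <- cbind(S1, S2, S3, S4)
  Zm <- sweep(S %*% params$Wm, 2, params$bm, "+"); Hm <- relu(Zm)
  Zo <- sweep(Hm %*% params$Wo, 2, params$bo, "+")
  # row-wise softmax over the 2 classes
  Zs <- Zo - apply(Zo, 1, max)
  E <- exp(Zs)
  P <- E / rowSums(E)
  list(prob = P, score = P[, 2],
       cache = list(X = list(X1, X2, X3, X4), Z = list(Z1, Z2, Z3, Z4),
                    S = S, Zm = Zm, Hm = Hm))
}

influence_bwd_mat <- function(params, cache, score, y) {
  n <- length(y)
  # BCE on the softmax positive class: d/dZo = [-(s - y), s - y] / n
  d <- (score - y) / n
  dZo <- cbind(-d, d)
  g <- list()
  g$Wo <- crossprod(cache$Hm, dZo)
  g$bo <- colSums(dZo)
  dHm <- dZo %*% t(params$Wo)
  dZm <- dHm * (cache$Zm > 0)
  g$Wm <- crossprod(cache$S, dZm)
  g$bm <- colSums(dZm)
  dS <- dZm %*% t(params$Wm)
  u <- ncol(cache$Zm)
  for (l in 1:4) {
    dSl <- dS[, (l - 1L) * u + seq_len(u), drop = FALSE]
    dZl <- dSl * (cache$Z[[l]] > 0)
    g[[paste0("W", l)]] <- crossprod(cache$X[[l]], dZl)
    g[[paste0("b", l)]] <- colSums(dZl)
  }
  g
}

#' Train the deep feature-fusion influence model
#'
#' Combines the two relevance vectors with the question and action
#' probabilities via the chosen operator into four feature vectors
#' (V_AB(x)Q, V_AB(x)A, V_BC(x)Q, V_BC(x)A), summarizes each with a dense +
#' ReLU layer (S1..S4), concatenates, passes a merge dense + ReLU layer and
#' a 2-way softmax output, and minimizes binary cross-entropy between the
#' positive-class probability and the ground-truth label with Adam.
#'
#' @param bundles A feature-bundle tibble from [build_feature_bundles()]
#'   with a `label` column in {1, -1} (or {1, 0}).
#' @param combine_op `"dot"` or `"cat"` (see [combine()]).
#' @param hyper An [influence_hyper()] list.
#' @param seed Integer seed; the same seed reproduces the fit exactly.
#' @return An object of class `influence_model` with `combine_op`, `params`,
#'   `hyper`, `vec_width`, and `loss` (trajectory as in
#'   [train_relevance_model()]).
#' @export
train_influence_model <- function(bundles, combine_op = c("dot", "cat"),
                                  hyper = influence_hyper(), seed = 1L) {
  combine_op <- match.arg(combine_op)
  y <- label_to_01(bundles$label)
  if (length(unique(y)) < 2L) abort("training labels must contain both classes.")
  Vab <- do.call(rbind, bundles$v_ab)
  Vbc <- do.call(rbind, bundles$v_bc)
  if (ncol(Vab) != ncol(Vbc)) abort("v_ab and v_bc widths differ.")
  q <- bundles$q
  a <- bundles$a
  n <- length(y)
  vw <- ncol(Vab)

  withr::with_seed(seed, {
    params <- init_influence_params(vw, combine_op, hyper$units)
    state <- adam_init(params)
    fwd0 <- influence_fwd_mat(params, combine_op, Vab, Vbc, q, a)
    loss_traj <- bce_loss(fwd0$score, y)
    if (hyper$epochs > 0L) {
      for (ep in seq_len(hyper$epochs)) {
        ord <- sample.int(n)
        batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
        ep_losses <- numeric(0)
        for (b in batches) {
          fwd <- influence_fwd_mat(params, combine_op,
                                   Vab[b, , drop = FALSE],
                                   Vbc[b, , drop = FALSE], q[b], a[b])
          l <- bce_loss(fwd$score, y[b])
          if (!is.finite(l)) abort("NaN/Inf training loss; lower the learning rate.")
          grads <- influence_bwd_mat(params, fwd$cache, fwd$score, y[b])
          upd <- adam_step(params, grads, state, lr = hyper$learning_rate)
          params <- upd$params
          state <- upd$state
          ep_losses <- c(ep_losses, l)
        }
        loss_traj <- c(loss_traj, mean(ep_losses))
      }
    }
  })

  structure(list(combine_op = combine_op, params = params, hyper = hyper,
                 vec_width = vw, loss = loss_traj, seed = seed),
            class = "influence_model")
}

label_to_01 <- function(label) {
  if (is.null(label)) abort("`label` column is required.")
  as.numeric(label > 0)
}

label_to_pm1 <- function(y01) ifelse(y01 > 0, 1L, -1L)

#' Predict influence relationships with a trained deep model
#'
#' @param object An [train_influence_model()] fit.
#' @param newdata A feature-bundle tibble from [build_feature_bundles()].
#' @param type `"response"` appends `score` (positive-class probability) and
#'   `pred_label` (+1/-1 by the model's decision threshold); `"prob"`
#'   additionally appends `prob_neg` and `prob_pos` (the two softmax
#'   outputs).
#' @param ... Unused.
#' @return `newdata` with prediction columns appended.
#' @export
predict.influence_model <- function(object, newdata,
                                    type = c("response", "prob"), ...) {
  type <- match.arg(type)
  Vab <- do.call(rbind, newdata$v_ab)
  Vbc <- do.call(rbind, newdata$v_bc)
  if (ncol(Vab) != object$vec_width) {
    abort(paste0("bundle vector width ", ncol(Vab),
                 " does not match model width ", object$vec_width, "."))
  }
  fwd <- influence_fwd_mat(object$params, object$combine_op, Vab, Vbc,
                           newdata$q, newdata$a)
  out <- as_tibble(newdata)
  out$score <- fwd$score
  out$pred_label <- ifelse(fwd$score >= object$hyper$threshold, 1L, -1L)
  if (type == "prob") {
    out$prob_neg <- fwd$prob[, 1]
    out$prob_pos <- fwd$prob[, 2]
  }
  out
}

#' @export
print.influence_model <- function(x, ...) {
  cat("<influence_model> combine=", x$combine_op,
      " | vector width ", x$vec_width,
      " | ", length(x$loss) - 1L, " epochs",
      " | final loss ", signif(tail(x$loss, 1), 4), "\n", sep = "")
  invisible(x)
}
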