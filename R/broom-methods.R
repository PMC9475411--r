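#' Tidy a fitted relevance matcher
#'
#' @param x A `relevance_model`.
#' @param ... Unused.
#' @return A tibble with one row per parameter tensor: `layer`, `rows`,
#'   `cols`, `n_params`.
#' @export
tidy.relevance_model <- function(x, ...) {
  param_table(x$params)
}

#' @rdname tidy.relevance_model
#' @export
tidy.influence_model <- function(x, ...) {
  param_table(x$params)
}

param_table <- function(params) {
  tibble(
    layer = names(params),
    rows = vapply(params, \(p) if (is.matrix(p)) nrow(p) else length(p),
                  numeric(1)),
    cols = vapply(params, \(p) if (is.matrix(p)) ncol(p) else 1, numeric(1)),
    n_params = vapply(params, length, integer(1))
  )
}

#' One-row summary of a fitted relevance matcher
#'
#' @param x A `relevance_model`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, vector width, epochs trained,
#'   initial and final training loss, total parameter count.
#' @export
glance.relevance_model <- function(x, ...) {
  tibble(arch = x$arch,
         vector_width = x$hyper$vector_width,
         epochs = length(x$loss) - 1L,
         initial_loss = x$loss[1],
         final_loss = tail(x$loss, 1),
         n_params = n_params(x$params))
}

#' @rdname glance.relevance_model
#' @export
glance.influence_model <- function(x, ...) {
  tibble(combine_op = x$combine_op,
         vector_width = x$vec_width,
         epochs = length(x$loss) - 1L,
         initial_loss = x$loss[1],
         final_loss = tail(x$loss, 1),
         n_params = n_params(x$params),
         threshold = x$hyper$threshold)
}

#' Plot a training-loss trajectory
#'
#' @param object A `relevance_model` or `influence_model`.
#' @param ... Unused.
#' @return A ggplot of mean training loss per epoch (epoch 0 is the
#'   pre-training loss).
#' @export
autoplot.relevance_model <- function(object, ...) {
  loss_plot(object$loss, paste0("relevance matcher (", object$arch, ")"))
}

#' @rdname autoplot.relevance_model
#' @export
autoplot.influence_model <- function(object, ...) {
  loss_plot(object$loss, paste0("influence model (", object$combine_op, ")"))
}

loss_plot <- function(loss, label) {
  df <- tibble(epoch = seq_along(loss) - 1L, loss = loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "training BCE loss", title = label) +
    ggplot2::theme_minimal()
}

#' ROC curve plot for scored predictions
#'
#' @param truth Ground-truth labels (> 0 = positive).
#' @param scores Numeric scores.
#' @return A ggplot of the ROC curve with the AUC in the subtitle.
#' @export
plot_roc <- function(truth, scores) {
  y <- as.integer(truth > 0)
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  df <- tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "ROC curve",
                  subtitle = paste0("AUC = ",
                                    signif(as.numeric(pROC::auc(r)), 3))) +
    ggplot2::theme_minimal()
}
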