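# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an optimizer trace
#'
#' @param x A `samd_trace`.
#' @param ... Unused.
#' @return The per-iteration tibble (`t`, `objective`, `step_norm`,
#'   `alpha`, `beta`, `gamma`).
#' @export
tidy.samd_trace <- function(x, ...) x$iterates

#' @rdname tidy.samd_trace
#' @return `glance()` returns a one-row run summary.
#' @export
glance.samd_trace <- function(x, ...) {
  n <- nrow(x$iterates)
  tibble::tibble(iterations = n,
                 final_objective = x$iterates$objective[n],
                 final_step_norm = x$iterates$step_norm[n],
                 stop_reason = x$stop_reason,
                 converged = x$converged)
}

#' Plot an optimizer trace
#'
#' Objective value of the averaged iterate against the iteration counter,
#' on log-log axes.
#'
#' @param object A `samd_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.samd_trace <- function(object, ...) {
  ggplot2::ggplot(object$iterates, ggplot2::aes(x = t, y = objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration t", y = "F(averaged iterate)",
                  title = "SAMD convergence") +
    ggplot2::theme_minimal()
}

#' Tidy training curves
#'
#' @param x An `arcnn_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `epoch`, `metric`, `value`.
#' @export
tidy.arcnn_fit <- function(x, ...) {
  cv <- x$curves
  if (nrow(cv) == 0) {
    return(tibble::tibble(epoch = integer(), metric = character(),
                          value = numeric()))
  }
  tibble::tibble(
    epoch = rep(cv$epoch, 3),
    metric = rep(c("train_loss", "train_acc", "val_acc"), each = nrow(cv)),
    value = c(cv$train_loss, cv$train_acc, cv$val_acc)
  )
}

#' @rdname tidy.arcnn_fit
#' @export
glance.arcnn_fit <- function(x, ...) {
  n <- nrow(x$curves)
  tibble::tibble(task = x$config$task, optimizer = x$config$optimizer,
                 epochs = n,
                 final_train_acc = if (n) x$curves$train_acc[n] else NA_real_,
                 final_val_acc = if (n) x$curves$val_acc[n] else NA_real_)
}

#' Plot training curves
#'
#' @param object An `arcnn_fit`.
#' @param ... Unused.
#' @return A ggplot object of train/validation accuracy by epoch.
#' @export
autoplot.arcnn_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$metric != "train_loss", ]
  ggplot2::ggplot(d, ggplot2::aes(x = epoch, y = value,
                                  colour = metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per metric.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(metric = c("acc", "sen", "spe", "auc"),
                 value = c(x$acc, x$sen, x$spe, x$auc))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(task = x$task, acc = x$acc, sen = x$sen, spe = x$spe,
                 auc = x$auc, n = sum(x$confusion),
                 degenerate = x$degenerate)
}

#' Plot the ROC curve of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  sc <- object$scores
  thr <- sort(unique(c(-Inf, sc$score, Inf)), decreasing = TRUE)
  pos <- sc$truth == 2
  tpr <- vapply(thr, function(t) mean(sc$score[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sc$score[!pos] >= t), numeric(1))
  ggplot2::ggplot(tibble::tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}
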