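# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained sequence model: per-epoch accuracy curves
#'
#' @param x A `seq2seq_transformer`.
#' @param ... Unused.
#' @return Tibble `epoch`, `loss`, `partial`, `perfect`.
#' @method tidy seq2seq_transformer
#' @export
tidy.seq2seq_transformer <- function(x, ...) {
  x$curves
}

#' @rdname tidy.seq2seq_transformer
#' @method glance seq2seq_transformer
#' @export
glance.seq2seq_transformer <- function(x, ...) {
  last <- utils::tail(x$curves, 1)
  tibble::tibble(conditioned = x$conditioned, epochs = nrow(x$curves),
                 loss = last$loss, partial_accuracy = last$partial,
                 perfect_accuracy = last$perfect)
}

#' Tidy a template classifier: held-out top-k accuracy
#'
#' @param x A `gcn_model`.
#' @param ... Unused.
#' @return Tibble `metric`, `value`.
#' @method tidy gcn_model
#' @export
tidy.gcn_model <- function(x, ...) {
  tidyr::pivot_longer(x$report, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.gcn_model
#' @method glance gcn_model
#' @export
glance.gcn_model <- function(x, ...) {
  dplyr::mutate(x$report, n_templates = x$n_templates,
                best_epoch = x$best_epoch)
}

#' Tidy a QSAR model: held-out report
#'
#' @param x A `qsar_model`.
#' @param ... Unused.
#' @return One-row tibble `accuracy`, `auc`, `n_train`, `n_test`.
#' @method tidy qsar_model
#' @export
tidy.qsar_model <- function(x, ...) {
  x$report
}

#' @rdname tidy.qsar_model
#' @method glance qsar_model
#' @export
glance.qsar_model <- function(x, ...) {
  dplyr::mutate(x$report, preset = x$hp$preset,
                n_trees = x$hp$n_estimators)
}

#' Tidy a search result: the generated set
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return The deduplicated generated tibble.
#' @method tidy search_result
#' @export
tidy.search_result <- function(x, ...) {
  x$generated
}

#' @rdname tidy.search_result
#' @param reference Reference corpus for the novelty column.
#' @param tau Reward threshold.
#' @method glance search_result
#' @export
glance.search_result <- function(x, reference = character(0), tau = 0.5,
                                 ...) {
  summarize_search(x, reference = reference, tau = tau)
}

#' Plot a search result
#'
#' Reaction-step distribution and reward histogram of the generated set.
#'
#' @param object A `search_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot search_result
#' @export
autoplot.search_result <- function(object, ...) {
  g <- object$generated
  dat <- dplyr::bind_rows(
    tibble::tibble(panel = "reaction steps", value = as.numeric(g$depth)),
    tibble::tibble(panel = "reward", value = g$reward))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "molecules",
                  title = paste("Search from", object$start)) +
    ggplot2::theme_minimal()
}

#' Plot training curves of a sequence model
#'
#' @param object A `seq2seq_transformer`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seq2seq_transformer
#' @export
autoplot.seq2seq_transformer <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$curves, c("partial", "perfect"),
                             names_to = "accuracy", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epoch, y = .data$value,
                                    colour = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "validation accuracy") +
    ggplot2::theme_minimal()
}
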