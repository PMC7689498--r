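#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_abline
#'   labs theme_minimal scale_colour_manual geom_raster
#'   scale_fill_gradient coord_fixed
#' @export
ggplot2::autoplot

#' Training-progress plot
#'
#' The trainer's two progress curves against the number of accepted
#' changes: the error rate (the acceptance criterion, non-increasing by
#' construction) and the score (the argmax accuracy, a subsidiary reference
#' that may fluctuate).
#'
#' @param object An `mc_net`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mc_net
#' @export
autoplot.mc_net <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace, c("error_rate", "score"),
                           names_to = "curve", values_to = "value")
  ggplot(d, aes(x = .data$accepted_changes, y = .data$value,
                colour = .data$curve)) +
    geom_line() +
    scale_colour_manual(values = c(error_rate = "#2166ac", score = "#b2182b")) +
    labs(x = "accepted changes", y = NULL,
         title = "Monte Carlo training progress") +
    theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(colour = "#2166ac") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "false-positive rate", y = "true-positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    coord_fixed() +
    theme_minimal()
}

#' Display a square image
#'
#' @param x A `square_image`.
#' @param ... Unused.
#' @return A ggplot (raster heat map, radiological grayscale).
#' @method autoplot square_image
#' @export
autoplot.square_image <- function(x, ...) {
  px <- x$pixels
  d <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  d$value <- as.vector(t(px))
  ggplot(d, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    coord_fixed() +
    labs(title = sprintf("%s (subdivision %s)", x$case_id,
                         as.character(x$subdivision)),
         x = NULL, y = NULL, fill = "gray") +
    theme_minimal()
}
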