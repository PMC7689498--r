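#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted Monte Carlo network
#'
#' One row per layer with its shape and summary statistics of the fitted
#' weights and biases.
#'
#' @param x An `mc_net`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `n_in`, `n_out`, `n_weights`,
#'   `n_biases`, `weight_mean`, `weight_sd`, `bias_mean`.
#' @method tidy mc_net
#' @export
tidy.mc_net <- function(x, ...) {
  layout <- param_layout(x$spec)
  purrr::imap_dfr(layout, function(l, i) {
    w <- x$theta[l$w_idx]
    b <- x$theta[l$b_idx]
    tibble(layer = i, n_in = l$n_in, n_out = l$n_out,
           n_weights = length(w), n_biases = length(b),
           weight_mean = mean(w), weight_sd = stats::sd(w),
           bias_mean = mean(b))
  })
}

#' Glance at a fitted Monte Carlo network
#'
#' @param x An `mc_net`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, variable count, accepted-change
#'   count, final training error and score.
#' @method glance mc_net
#' @export
glance.mc_net <- function(x, ...) {
  tibble(
    architecture = paste(x$spec$layer_sizes, collapse = "-"),
    n_variables = count_variables(x$spec),
    accepted_changes = x$accepted_changes,
    final_error = x$final_error,
    final_score = x$final_score
  )
}

#' Tidy/glance methods for ROC results
#'
#' `tidy()` returns the threshold sweep (one row per threshold);
#' `glance()` a one-row summary with the AUC and class counts.
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname tidy.roc_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         n_thresholds = nrow(x$points))
}
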