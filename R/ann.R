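#' Fully-connected network architecture
#'
#' Describes a small dense feedforward network: input size (the number of
#' pixels R^2 of the reduced-resolution square image), one to three hidden
#' layers of 10-240 nodes, and 2 (detection) or 3 (subtype classification)
#' output nodes. The logistic sigmoid is applied at every layer including
#' the output, so outputs live in (0, 1).
#'
#' @param layer_sizes Integer vector, e.g. `c(400, 40, 20, 10, 2)`.
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @return An object of class `network_spec`.
#' @examples
#' spec <- network_spec(c(400, 40, 20, 10, 2))
#' count_variables(spec)  # 17092
#' @export
network_spec <- function(layer_sizes, activation = c("sigmoid", "tanh")) {
  activation <- match.arg(activation)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3) {
    abort("A network needs at least one hidden layer.", class = "ich_spec_error")
  }
  n_out <- layer_sizes[length(layer_sizes)]
  if (!n_out %in% c(2L, 3L)) {
    abort("Output layer must have 2 (detection) or 3 (subtype) nodes.",
          class = "ich_spec_error")
  }
  if (any(layer_sizes < 1)) {
    abort("All layer sizes must be positive.", class = "ich_spec_error")
  }
  structure(list(layer_sizes = layer_sizes, activation = activation),
            class = "network_spec")
}

#' Total number of trainable variables
#'
#' Sum over layers of the weight-matrix entries plus the bias entries; these
#' are exactly the scalars the Monte Carlo trainer perturbs.
#'
#' @param spec A [network_spec()].
#' @return Integer count.
#' @export
count_variables <- function(spec) {
  ls <- spec$layer_sizes
  n_in <- ls[-length(ls)]
  n_out <- ls[-1]
  sum(n_in * n_out) + sum(n_out)
}

# Parameter layout: one flat numeric vector, per layer the weight matrix
# (column-major, n_in x n_out) followed by the bias vector. The flat view is
# what the trainer perturbs; `param_matrices()` reshapes it for the forward
# pass.
param_layout <- function(spec) {
  ls <- spec$layer_sizes
  layers <- list()
  offset <- 0L
  for (l in seq_len(length(ls) - 1)) {
    nw <- ls[l] * ls[l + 1]
    layers[[l]] <- list(n_in = ls[l], n_out = ls[l + 1],
                        w_idx = offset + seq_len(nw),
                        b_idx = offset + nw + seq_len(ls[l + 1]))
    offset <- offset + nw + ls[l + 1]
  }
  layers
}

param_matrices <- function(spec, theta) {
  lapply(param_layout(spec), function(l) {
    list(W = matrix(theta[l$w_idx], l$n_in, l$n_out), b = theta[l$b_idx])
  })
}

act_fun <- function(name) {
  switch(name, sigmoid = function(z) 1 / (1 + exp(-z)), tanh = tanh)
}

#' Forward pass of a dense network
#'
#' Evaluates `activation(W x + b)` layer by layer. Accepts a single input
#' vector or a row-per-sample matrix; the batched form is what the trainer
#' uses so every error evaluation is one set of BLAS calls.
#'
#' @param spec A [network_spec()].
#' @param theta Flat parameter vector of length [count_variables()].
#' @param x Numeric vector of length `layer_sizes[1]`, or an n x input matrix.
#' @return Output activations: a vector (single input) or n x output matrix.
#' @export
forward <- function(spec, theta, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else x
  if (ncol(X) != spec$layer_sizes[1]) {
    abort("Input length does not match the network's input layer.",
          class = "ich_shape_error")
  }
  if (length(theta) != count_variables(spec)) {
    abort("Parameter vector length does not match the spec.",
          class = "ich_shape_error")
  }
  f <- act_fun(spec$activation)
  for (l in param_matrices(spec, theta)) {
    X <- f(sweep(X %*% l$W, 2, l$b, `+`))
  }
  if (single) drop(X) else X
}

#' Training error and score of a network on a dataset
#'
#' `training_error()` is the mean over samples of the summed squared
#' difference between output and target nodes (the trainer's acceptance
#' criterion). `score_fraction()` is the fraction of samples whose argmax
#' output node matches the argmax target node (ties broken toward the lowest
#' node index) — for detection this equals accuracy at a 0.5 cutoff on the
#' detection value.
#'
#' @param spec,theta Network architecture and flat parameters.
#' @param dataset An [input_dataset()].
#' @return A non-negative scalar (`training_error`); a fraction in \[0, 1\]
#'   (`score_fraction`).
#' @export
training_error <- function(spec, theta, dataset) {
  out <- forward(spec, theta, dataset$X)
  mean(rowSums((out - dataset$targets)^2))
}

#' @rdname training_error
#' @export
score_fraction <- function(spec, theta, dataset) {
  out <- forward(spec, theta, dataset$X)
  mean(max.col(out, ties.method = "first") ==
         max.col(dataset$targets, ties.method = "first"))
}

#' Scalar detection value from the two output nodes
#'
#' Maps the positive-node and negative-node outputs to a single value in
#' \[0, 1\]: `(p - n + 1) / 2`. A confident positive gives 1, a confident
#' negative 0, and equal outputs 0.5; these values feed the ROC analysis.
#'
#' @param output_p,output_n Outputs of the positive and negative node, each
#'   in \[0, 1\] (vectorised).
#' @return Detection value(s) in \[0, 1\].
#' @export
detection_value <- function(output_p, output_n) {
  (output_p - output_n + 1) / 2
}

#' Prevalence-weighted accuracy from sensitivity and specificity
#'
#' `(n_pos * sensitivity + n_neg * specificity) / (n_pos + n_neg)`, with
#' sensitivity and specificity on the 0-100 scale. When sensitivity and
#' specificity are themselves count-derived this equals plain accuracy
#' (TP + TN) / total.
#'
#' @param sensitivity,specificity Percentages in \[0, 100\].
#' @param n_pos,n_neg Positive and negative case counts.
#' @return Accuracy percentage (unrounded; round at report time).
#' @examples
#' weighted_accuracy(82.5, 84.1, 40, 44)  # 83.3 to one decimal
#' @export
weighted_accuracy <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(all(n_pos >= 0), all(n_neg >= 0))
  if (any(n_pos + n_neg == 0)) {
    abort("Need at least one case.", class = "ich_precondition_error")
  }
  (n_pos * sensitivity + n_neg * specificity) / (n_pos + n_neg)
}

#' Bundle input vectors into a training/validation dataset
#'
#' Stacks a list of [to_input_vector()] results into the row-per-sample
#' input matrix and target matrix the network operations consume.
#'
#' @param vectors Non-empty list of `input_vector`s with matching dimensions.
#' @param name Dataset name, e.g. `"training"` or `"validation"`.
#' @return A list with matrices `X` (n x R^2) and `targets` (n x 2 or
#'   n x 3), of class `ann_dataset`.
#' @export
input_dataset <- function(vectors, name = "training") {
  if (length(vectors) == 0) {
    abort("Empty dataset.", class = "ich_precondition_error")
  }
  lens <- vapply(vectors, function(v) length(v$values), integer(1))
  tlen <- vapply(vectors, function(v) length(v$target), integer(1))
  if (length(unique(lens)) > 1 || length(unique(tlen)) > 1) {
    abort("Input vectors have inhomogeneous dimensions.", class = "ich_shape_error")
  }
  structure(
    list(X = do.call(rbind, lapply(vectors, `[[`, "values")),
         targets = do.call(rbind, lapply(vectors, `[[`, "target")),
         name = name),
    class = "ann_dataset"
  )
}

#' Save or load a trained network as JSON
#'
#' Serialises the architecture, flat parameter vector and training metadata
#' to a plain-text JSON file so trained networks are reloadable and
#' diffable.
#'
#' @param net A fitted `mc_net` (see [mc_train()]).
#' @param path JSON file path.
#' @return `path` invisibly (`save_network`); an `mc_net` (`load_network`).
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "mc_net"))
  obj <- list(
    layer_sizes = net$spec$layer_sizes,
    activation = net$spec$activation,
    theta = net$theta,
    seed = net$seed,
    final_error = net$final_error,
    final_score = net$final_score,
    accepted_changes = net$accepted_changes
  )
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(spec = network_spec(obj$layer_sizes, obj$activation),
         theta = as.numeric(obj$theta), seed = obj$seed,
         final_error = obj$final_error, final_score = obj$final_score,
         accepted_changes = obj$accepted_changes,
         trace = NULL, config = NULL),
    class = "mc_net"
  )
}
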