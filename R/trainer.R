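#' Monte Carlo training configuration
#'
#' Hyperparameters of the derivative-free random-optimization trainer. A
#' training *session* is `cycles` training cycles; within each cycle a
#' fraction `ratio` of all variables is drawn at random per selection event
#' and perturbed, and the number of events is set so the cumulative drawn
#' fraction reaches `cycle_budget` (9.0 = 900% of the variable count). The
#' selection ratio decays steadily from `ratio_start` (15%) on the first
#' cycle to `ratio_end` (1.5%) on the last.
#'
#' @param init_range Half-width of the uniform initialisation (default 0.2).
#' @param delta_range Half-width of the uniform perturbation (default 0.1).
#' @param attempts_per_event Perturbation attempts per drawn index set
#'   (default 30).
#' @param cycles Training cycles per session (default 10).
#' @param ratio_start,ratio_end Selection ratios for the first and last
#'   cycle (defaults 0.15 and 0.015).
#' @param cycle_budget Cumulative drawn fraction per cycle (default 9.0).
#' @param ratio_schedule `"linear"` (default) or `"geometric"` decay.
#' @param keep_best If `TRUE`, each event evaluates all attempts from the
#'   incoming state and keeps the best improving one; the default greedily
#'   accepts any improving attempt and continues from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(init_range = 0.2, delta_range = 0.1,
                         attempts_per_event = 30, cycles = 10,
                         ratio_start = 0.15, ratio_end = 0.015,
                         cycle_budget = 9.0,
                         ratio_schedule = c("linear", "geometric"),
                         keep_best = FALSE) {
  ratio_schedule <- match.arg(ratio_schedule)
  stopifnot(init_range > 0, delta_range >= 0, attempts_per_event >= 1,
            cycles >= 0, cycle_budget > 0,
            ratio_end > 0, ratio_end <= ratio_start, ratio_start < 1)
  structure(
    list(init_range = init_range, delta_range = delta_range,
         attempts_per_event = as.integer(attempts_per_event),
         cycles = as.integer(cycles), ratio_start = ratio_start,
         ratio_end = ratio_end, cycle_budget = cycle_budget,
         ratio_schedule = ratio_schedule, keep_best = keep_best),
    class = "train_config"
  )
}

#' Random parameter initialisation
#'
#' Every weight and bias is drawn i.i.d. uniform on
#' (-`init_range`, +`init_range`); draws come from the current RNG state so a
#' fixed seed reproduces the parameters exactly.
#'
#' @param spec A [network_spec()].
#' @param init_range Half-width of the uniform range (default 0.2).
#' @return Flat numeric parameter vector.
#' @export
init_params <- function(spec, init_range = 0.2) {
  runif(count_variables(spec), -init_range, init_range)
}

#' Draw the variable subset for one selection event
#'
#' Uniform sampling without replacement of
#' `max(1, round(ratio * variable_count))` variable indices.
#'
#' @param variable_count Total number of trainable variables.
#' @param ratio Selection ratio in (0, 1\].
#' @return Integer index vector.
#' @export
select_variables <- function(variable_count, ratio) {
  stopifnot(ratio > 0, ratio <= 1)
  k <- max(1L, round(ratio * variable_count))
  sample.int(variable_count, k)
}

#' Cycle selection ratios of a session
#'
#' Linear (default) or geometric interpolation from `ratio_start` to
#' `ratio_end` across the session's cycles.
#'
#' @param config A [train_config()].
#' @return Numeric vector of length `config$cycles`.
#' @export
cycle_ratios <- function(config) {
  if (config$cycles == 0) return(numeric(0))
  if (config$cycles == 1) return(config$ratio_start)
  k <- seq_len(config$cycles) - 1
  f <- k / (config$cycles - 1)
  r <- if (config$ratio_schedule == "linear") {
    config$ratio_start + (config$ratio_end - config$ratio_start) * f
  } else {
    config$ratio_start * (config$ratio_end / config$ratio_start)^f
  }
  # pin the endpoints so float drift cannot alter the event arithmetic
  r[1] <- config$ratio_start
  r[config$cycles] <- config$ratio_end
  r
}

# Fast forward pass on a prebuilt layout; returns the output matrix.
forward_fast <- function(layout, act, theta, X) {
  for (l in layout) {
    Z <- X %*% matrix(theta[l$w_idx], l$n_in, l$n_out)
    X <- act(sweep(Z, 2, l$b_vals(theta), `+`))
  }
  X
}

build_layout <- function(spec) {
  lapply(param_layout(spec), function(l) {
    b_idx <- l$b_idx
    l$b_vals <- function(theta) theta[b_idx]
    l
  })
}

#' One perturbation attempt on a drawn index set
#'
#' Each selected variable receives its own i.i.d. uniform
#' (-`delta_range`, +`delta_range`) delta. The adjustment is accepted only
#' if it strictly decreases the average training error over *all* training
#' samples; otherwise the parameters are restored exactly.
#'
#' @param spec,theta Architecture and current flat parameters.
#' @param indices Variable indices drawn by [select_variables()].
#' @param dataset An [input_dataset()].
#' @param delta_range Perturbation half-width.
#' @param current_error Error of `theta` on `dataset` (recomputed if `NULL`).
#' @return List with `theta`, `accepted`, `error` (error of the returned
#'   parameters).
#' @export
attempt_adjustment <- function(spec, theta, indices, dataset,
                               delta_range = 0.1, current_error = NULL) {
  stopifnot(length(indices) >= 1)
  if (is.null(current_error)) current_error <- training_error(spec, theta, dataset)
  cand <- theta
  cand[indices] <- cand[indices] + runif(length(indices), -delta_range, delta_range)
  err <- training_error(spec, cand, dataset)
  if (err < current_error) {
    list(theta = cand, accepted = TRUE, error = err)
  } else {
    list(theta = theta, accepted = FALSE, error = current_error)
  }
}

#' Run one training cycle
#'
#' Performs `ceiling(cycle_budget / ratio)` selection events. Each event
#' draws one random variable subset of size `ratio * variable_count` and
#' makes `attempts_per_event` sequential perturbation attempts on it,
#' greedily accepting any attempt that strictly lowers the training error
#' and reverting the rest.
#'
#' @param spec,theta Architecture and incoming flat parameters.
#' @param dataset An [input_dataset()].
#' @param ratio This cycle's selection ratio.
#' @param config A [train_config()].
#' @return List with `theta`, `error`, `score`, `accepted` (count), `events`
#'   and `trace` (tibble rows recorded after every accepted change).
#' @export
run_cycle <- function(spec, theta, dataset, ratio, config = train_config()) {
  state <- new.env(parent = emptyenv())
  state$theta <- theta
  state$accepted_total <- 0L
  layout <- build_layout(spec)
  act <- act_fun(spec$activation)
  tmax <- max.col(dataset$targets, ties.method = "first")
  eval_theta <- function(th) {
    out <- forward_fast(layout, act, th, dataset$X)
    list(error = mean(rowSums((out - dataset$targets)^2)),
         score = mean(max.col(out, ties.method = "first") == tmax))
  }
  cur <- eval_theta(state$theta)
  run_cycle_impl(state, dataset, ratio, config, eval_theta, cur)
}

# Core event/attempt loop shared by run_cycle() and mc_train(); mutates
# `state` ($theta, $accepted_total, $trace list) and returns cycle stats.
run_cycle_impl <- function(state, dataset, ratio, config, eval_theta, cur) {
  nvar <- length(state$theta)
  n_events <- ceiling(config$cycle_budget / ratio - 1e-9)
  accepted_cycle <- 0L
  if (is.null(state$trace)) state$trace <- list()
  for (ev in seq_len(n_events)) {
    idx <- select_variables(nvar, ratio)
    if (config$keep_best) {
      best <- NULL
      for (a in seq_len(config$attempts_per_event)) {
        cand <- state$theta
        cand[idx] <- cand[idx] + runif(length(idx), -config$delta_range,
                                       config$delta_range)
        res <- eval_theta(cand)
        if (res$error < cur$error && (is.null(best) || res$error < best$res$error)) {
          best <- list(cand = cand, res = res)
        }
      }
      if (!is.null(best)) {
        state$theta <- best$cand
        cur <- best$res
        accepted_cycle <- accepted_cycle + 1L
        state$accepted_total <- state$accepted_total + 1L
        state$trace[[length(state$trace) + 1L]] <-
          c(state$accepted_total, cur$error, cur$score)
      }
    } else {
      for (a in seq_len(config$attempts_per_event)) {
        cand <- state$theta
        cand[idx] <- cand[idx] + runif(length(idx), -config$delta_range,
                                       config$delta_range)
        res <- eval_theta(cand)
        if (res$error < cur$error) {
          state$theta <- cand
          cur <- res
          accepted_cycle <- accepted_cycle + 1L
          state$accepted_total <- state$accepted_total + 1L
          state$trace[[length(state$trace) + 1L]] <-
            c(state$accepted_total, cur$error, cur$score)
        }
      }
    }
  }
  list(theta = state$theta, error = cur$error, score = cur$score,
       accepted = accepted_cycle, events = n_events, cur = cur,
       trace = trace_tibble(state$trace))
}

trace_tibble <- function(rows) {
  if (length(rows) == 0) {
    return(tibble(accepted_changes = integer(0), error_rate = numeric(0),
                  score = numeric(0)))
  }
  m <- do.call(rbind, rows)
  tibble(accepted_changes = as.integer(m[, 1]), error_rate = m[, 2],
         score = m[, 3])
}

#' Train a network by Monte Carlo random optimization
#'
#' Runs a full training session: random uniform initialisation, then
#' `config$cycles` training cycles with the decaying selection-ratio
#' schedule, each cycle spending its 900% selection budget in random-subset
#' perturbation events. There is no gradient anywhere — candidate moves are
#' random deltas, and the only signal used is whether the average training
#' error over all samples went down. The error curve along accepted changes
#' is therefore non-increasing by construction; the score curve may
#' fluctuate.
#'
#' @param spec A [network_spec()].
#' @param dataset A non-empty [input_dataset()].
#' @param config A [train_config()].
#' @param seed Integer seed making the whole session reproducible
#'   (`NULL` to continue from the current RNG state).
#' @return An object of class `mc_net`: the fitted flat parameters
#'   (`theta`), the architecture, the per-acceptance `trace` tibble
#'   (columns `accepted_changes`, `error_rate`, `score` — the progress
#'   curves), a per-cycle summary tibble, and final error/score.
#' @examples
#' xor <- xor_dataset()
#' net <- mc_train(network_spec(c(2, 8, 2)), xor,
#'                 train_config(cycles = 2), seed = 1)
#' glance(net)
#' @export
mc_train <- function(spec, dataset, config = train_config(), seed = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(dataset, "ann_dataset"))
  check_seed(seed)
  layout <- build_layout(spec)
  act <- act_fun(spec$activation)
  tmax <- max.col(dataset$targets, ties.method = "first")
  eval_theta <- function(th) {
    out <- forward_fast(layout, act, th, dataset$X)
    list(error = mean(rowSums((out - dataset$targets)^2)),
         score = mean(max.col(out, ties.method = "first") == tmax))
  }

  state <- new.env(parent = emptyenv())
  state$theta <- init_params(spec, config$init_range)
  state$accepted_total <- 0L
  state$trace <- list()
  cur <- eval_theta(state$theta)

  ratios <- cycle_ratios(config)
  cycle_rows <- vector("list", config$cycles)
  for (k in seq_along(ratios)) {
    stats <- run_cycle_impl(state, dataset, ratios[k], config, eval_theta, cur)
    cur <- stats$cur
    cycle_rows[[k]] <- tibble(
      cycle = k, ratio = ratios[k], events = stats$events,
      accepted = stats$accepted, error_rate = stats$error, score = stats$score
    )
  }

  structure(
    list(spec = spec, theta = state$theta, config = config, seed = seed,
         trace = trace_tibble(state$trace),
         cycle_summary = dplyr::bind_rows(cycle_rows),
         final_error = cur$error, final_score = cur$score,
         accepted_changes = state$accepted_total),
    class = "mc_net"
  )
}

#' @export
print.mc_net <- function(x, ...) {
  cat(sprintf("<mc_net %s> %d variables, %d accepted changes, error %.4f, score %.3f\n",
              paste(x$spec$layer_sizes, collapse = "-"),
              count_variables(x$spec), x$accepted_changes,
              x$final_error, x$final_score))
  invisible(x)
}

#' Predict network outputs for new inputs
#'
#' @param object An `mc_net`.
#' @param newdata An `ann_dataset` or row-per-sample input matrix.
#' @param ... Unused.
#' @return Matrix of output activations (n x 2 or n x 3).
#' @export
predict.mc_net <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "ann_dataset")) newdata$X else newdata
  out <- forward(object$spec, object$theta, X)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' The XOR toy dataset
#'
#' Four binary samples whose positive class is the exclusive-or of the two
#' inputs — the classic minimal non-linearly-separable problem, used as a
#' convergence check for the trainer.
#'
#' @return An `ann_dataset` with 4 samples and 2-node targets.
#' @export
xor_dataset <- function() {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  pos <- c(FALSE, TRUE, TRUE, FALSE)
  targets <- t(vapply(pos, function(p) if (p) c(1, 0) else c(0, 1), numeric(2)))
  structure(list(X = X, targets = targets, name = "xor"), class = "ann_dataset")
}
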