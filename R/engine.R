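#' A k x k microcell array
#'
#' The physical engine: a square grid of microcells, one merge module per row
#' and one reaction pipeline per row. Each row accumulates one neuron's
#' products (its merge module produces that neuron's pre-activation) and
#' activated outputs re-enter the array column-wise for the next layer, with
#' the input value of column j broadcast to all cells of that column. A
#' degenerate `k = 1` array (a scalar engine) is permitted for testing.
#'
#' @param k_physical Array dimension (positive integer).
#' @return An object of class `microcell_array`.
#' @export
microcell_array <- function(k_physical) {
  if (k_physical < 1 || k_physical != round(k_physical)) {
    stop("`k_physical` must be a positive integer", call. = FALSE)
  }
  structure(list(k_physical = as.integer(k_physical)),
            class = "microcell_array")
}

#' @export
print.microcell_array <- function(x, ...) {
  cat(sprintf("<microcell_array: %d x %d cells, %d merge modules + pipelines>\n",
              x$k_physical, x$k_physical, x$k_physical))
  invisible(x)
}

#' Specification of one network layer
#'
#' A layer is a nonnegative weight matrix with entries in \[0, 1\] (rows are
#' neurons, columns inputs) plus its activation gate. The activation
#' threshold lives on the 1/k-normalised pre-activation scale: a neuron's
#' pre-activation is `(1 / input_dim) * sum_j w_ij x_j`, the direct
#' consequence of dosing each weight droplet at `E = b * t * (1/k)` and
#' merging k unit droplets.
#'
#' @param weights Numeric matrix, entries in \[0, 1\]; rows = neurons.
#' @param activation A [seesaw_gate()].
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(weights, activation = seesaw_gate()) {
  weights <- as.matrix(weights)
  if (any(is.na(weights)) || any(weights < 0) || any(weights > 1)) {
    stop("layer weights must lie in [0, 1]; use compile_network() to clip and rescale raw weights",
         call. = FALSE)
  }
  stopifnot(inherits(activation, "seesaw_gate"))
  structure(
    list(weights = weights, input_dim = ncol(weights),
         n_neurons = nrow(weights), activation = activation),
    class = "layer_spec"
  )
}

#' Execute one layer on the array
#'
#' Runs one weight layer: for each pass, the input values of up to
#' `k_physical` columns are encoded into DNA droplets, every microcell mixes
#' its DNA droplet with its weight-enzyme droplet (product `w_ij * x_j` of
#' double-nicked molecules), each row's droplets merge into that neuron's
#' accumulating dot product, and — when the input dimension exceeds the
#' array — partial pre-activations are held as fragment counts in an
#' external reservoir across `ceiling(input_dim / k_physical)` serialized
#' passes. A single seesaw activation per neuron closes the layer. Ideal mode
#' performs the species algebra exactly (output equals
#' `step((1/input_dim) * w %*% x)` to machine precision); sampled mode draws
#' the per-molecule binomial chain for every cell.
#'
#' @param array A [microcell_array()].
#' @param layer A [layer_spec()].
#' @param inputs Numeric vector of input fractions in \[0, 1\], length
#'   `input_dim`.
#' @param mode `"ideal"` or `"sampled"`.
#' @param t Molecules per unit droplet in sampled mode.
#' @param seed Optional integer seed (sampled mode).
#' @param timing A [timing_params()] or [calibrate_timing()] fit used for the
#'   elapsed-time breakdown.
#' @return A list with `outputs` (tibble: neuron, pre_activation, output),
#'   `elapsed` (tibble with the serialized stage decomposition), and
#'   `passes` (the computational serialization factor).
#' @export
execute_layer <- function(array, layer, inputs,
                          mode = c("ideal", "sampled"), t = 10000L,
                          seed = NULL, timing = default_timing()) {
  stopifnot(inherits(array, "microcell_array"), inherits(layer, "layer_spec"))
  mode <- match.arg(mode)
  if (length(inputs) != layer$input_dim) {
    stop(sprintf("dimension mismatch: layer expects %d inputs, got %d",
                 layer$input_dim, length(inputs)), call. = FALSE)
  }
  check_fraction(inputs, "layer inputs")
  k <- array$k_physical
  W <- layer$weights
  n_in <- layer$input_dim
  passes <- ceiling(n_in / k)
  chunks <- split(seq_len(n_in), ceiling(seq_len(n_in) / k))

  if (mode == "ideal") {
    # exact species algebra, accumulated chunk by chunk as the reservoir does
    reservoir <- numeric(layer$n_neurons)
    for (idx in chunks) {
      reservoir <- reservoir + as.numeric(W[, idx, drop = FALSE] %*% inputs[idx])
    }
    pre <- reservoir / n_in
  } else {
    draws <- with_seed_opt(seed, {
      reservoir <- numeric(layer$n_neurons)
      for (idx in chunks) {
        # per column j: input x_j encoded as nicks at site A in each cell's
        # droplet of t molecules; the weight enzyme then nicks site B
        nA <- matrix(stats::rbinom(layer$n_neurons * length(idx), t,
                                   rep(inputs[idx], each = layer$n_neurons)),
                     nrow = layer$n_neurons)
        both <- matrix(stats::rbinom(length(nA), as.vector(nA),
                                     as.vector(W[, idx, drop = FALSE])),
                       nrow = layer$n_neurons)
        reservoir <- reservoir + rowSums(both)
      }
      reservoir
    })
    pre <- draws / (n_in * t)
    pre <- pmin(pre, 1)
  }
  out <- seesaw_activate(pre, layer$activation)
  elapsed <- layer_elapsed(timing, k_layer = layer$n_neurons, k_physical = k)
  list(
    outputs = tibble::tibble(neuron = seq_len(layer$n_neurons),
                             pre_activation = pre, output = out),
    elapsed = elapsed,
    passes = as.integer(passes)
  )
}

#' Compile raw weight matrices into an engine-ready network
#'
#' The chemistry only represents nonnegative fractions, so raw weights are
#' compiled: negative entries are clipped to zero (with a per-layer count
#' reported) and any layer whose largest entry exceeds 1 is divided by that
#' maximum, with the scale stored so downstream consumers can undo it.
#' Activation thresholds are interpreted on the 1/k-normalised
#' pre-activation scale.
#'
#' @param raw_weights A list of numeric matrices (rows = neurons of the
#'   layer, columns = inputs), ordered input-side first.
#' @param activation A single [seesaw_gate()] applied to every layer, or a
#'   list of gates, one per layer.
#' @return An object of class `network_spec`: layers, per-layer `scales` and
#'   `clipped_counts`, and the layer dimensions.
#' @export
compile_network <- function(raw_weights, activation = seesaw_gate()) {
  if (is.matrix(raw_weights)) raw_weights <- list(raw_weights)
  stopifnot(length(raw_weights) >= 1)
  if (inherits(activation, "seesaw_gate")) {
    activation <- rep(list(activation), length(raw_weights))
  }
  stopifnot(length(activation) == length(raw_weights))
  for (i in seq_along(raw_weights)[-1]) {
    if (ncol(raw_weights[[i]]) != nrow(raw_weights[[i - 1]])) {
      stop(sprintf("incompatible consecutive layer dims at layer %d", i),
           call. = FALSE)
    }
  }
  scales <- numeric(length(raw_weights))
  clipped <- integer(length(raw_weights))
  layers <- vector("list", length(raw_weights))
  for (i in seq_along(raw_weights)) {
    W <- as.matrix(raw_weights[[i]])
    clipped[i] <- sum(W < 0)
    W[W < 0] <- 0
    mx <- max(W)
    if (mx == 0) {
      warning(sprintf("layer %d is degenerate: all weights zero after clipping", i),
              call. = FALSE)
      scales[i] <- 1
    } else if (mx > 1) {
      scales[i] <- mx
      W <- W / mx
    } else {
      scales[i] <- 1
    }
    layers[[i]] <- layer_spec(W, activation[[i]])
  }
  structure(
    list(layers = layers, scales = scales, clipped_counts = clipped,
         dims = c(ncol(raw_weights[[1]]),
                  vapply(raw_weights, nrow, integer(1)))),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec: %s network, scales %s, %s negative weights clipped>\n",
              paste(x$dims, collapse = "-"),
              paste(signif(x$scales, 4), collapse = "/"),
              paste(x$clipped_counts, collapse = "/")))
  invisible(x)
}

#' Stage serialization factors of a network on an array
#'
#' The per-stage serialization factors of the latency model: the input stage
#' counts the input dimension, each subsequent stage its neuron count, and
#' every stage of width w needs `ceiling(w / k_physical)` sequential passes.
#' A 784-784-10 network on a 196 x 196 array has factors (4, 4, 1); on a
#' 4 x 4 array the output stage is serialized by a factor of 3.
#'
#' @param net A [compile_network()] result.
#' @param k_physical Array dimension.
#' @return Integer vector of factors, one per stage (input stage first).
#' @export
serialization_factors <- function(net, k_physical) {
  stopifnot(inherits(net, "network_spec"))
  as.integer(ceiling(net$dims / k_physical))
}

#' Run a compiled network on the array
#'
#' Layer-wise execution: the outputs of each layer (activated fractions,
#' re-encoded into fresh singly nicked pools by the reaction pipeline) are
#' split and re-entered column-wise as the next layer's inputs. Total time is
#' the sum of the per-stage serialized delays of the latency model, with the
#' input-encoding stage counted as a stage of width `input_dim`.
#'
#' @inheritParams execute_layer
#' @param net A [compile_network()] result.
#' @param inputs Numeric vector of input fractions, length `net$dims[1]`.
#' @return An object of class `engine_run`: per-layer output tibbles, final
#'   `outputs`, `timing` tibble (stage, width, factor, hours), and
#'   `total_hours`.
#' @export
run_network <- function(array, net, inputs, mode = c("ideal", "sampled"),
                        t = 10000L, seed = NULL, timing = default_timing()) {
  stopifnot(inherits(array, "microcell_array"), inherits(net, "network_spec"))
  mode <- match.arg(mode)
  x <- inputs
  layer_results <- vector("list", length(net$layers))
  seeds <- if (is.null(seed)) vector("list", length(net$layers)) else
    as.list(seed + seq_along(net$layers) - 1L)
  for (i in seq_along(net$layers)) {
    res <- execute_layer(array, net$layers[[i]], x, mode = mode, t = t,
                         seed = seeds[[i]], timing = timing)
    layer_results[[i]] <- res$outputs
    x <- res$outputs$output
  }
  factors <- serialization_factors(net, array$k_physical)
  delays <- vapply(net$dims, function(w) {
    layer_delay(timing, k_layer = w, k_physical = array$k_physical)
  }, numeric(1))
  timing_tbl <- tibble::tibble(
    stage = c("input", paste0("layer", seq_along(net$layers))),
    width = net$dims,
    factor = factors,
    hours = delays
  )
  structure(
    list(layers = layer_results,
         outputs = layer_results[[length(layer_results)]],
         timing = timing_tbl,
         total_hours = sum(delays),
         mode = mode, t = if (mode == "sampled") t else NA_real_,
         dims = net$dims, k_physical = array$k_physical),
    class = "engine_run"
  )
}

#' @export
print.engine_run <- function(x, ...) {
  cat(sprintf("<engine_run: %s network on %d x %d array, %s mode, %.2f h>\n",
              paste(x$dims, collapse = "-"), x$k_physical, x$k_physical,
              x$mode, x$total_hours))
  print(x$outputs)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
#' @rdname engine_run_methods
#' @param x An `engine_run`.
#' @param ... Unused.
tidy.engine_run <- function(x, ...) {
  purrr::imap_dfr(x$layers, function(tbl, i) {
    dplyr::mutate(tbl, layer = i, .before = 1)
  })
}

#' Broom-style summaries of an engine run
#'
#' `tidy()` returns one row per neuron per layer (`layer`, `neuron`,
#' `pre_activation`, `output`); `glance()` one row with the run's shape,
#' mode, serialization and total latency.
#'
#' @name engine_run_methods
NULL

#' @importFrom generics glance
#' @export
#' @rdname engine_run_methods
glance.engine_run <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$layers),
    dims = paste(x$dims, collapse = "-"),
    k_physical = x$k_physical,
    mode = x$mode,
    molecules_per_droplet = x$t,
    max_factor = max(x$timing$factor),
    total_hours = x$total_hours
  )
}

#' Reference step-activation network (independent oracle)
#'
#' Direct floating-point computation of the same network semantics — for each
#' layer, `out = step_gate((1/input_dim) * W %*% x)` — without any pool,
#' droplet or trace machinery. Used to verify engine equivalence.
#'
#' @param net A [compile_network()] result.
#' @param inputs Input vector.
#' @return Numeric vector of final-layer outputs.
#' @export
reference_network <- function(net, inputs) {
  stopifnot(inherits(net, "network_spec"))
  x <- inputs
  for (layer in net$layers) {
    pre <- numeric(layer$n_neurons)
    for (i in seq_len(layer$n_neurons)) {
      pre[i] <- sum(layer$weights[i, ] * x) / layer$input_dim
    }
    x <- seesaw_activate(pre, layer$activation)
  }
  x
}

#' Classify by final-layer argmax
#'
#' @param run An [run_network()] result or a numeric output vector.
#' @return The 1-based index of the maximal output (ties: lowest index).
#' @export
classify <- function(run) {
  out <- if (inherits(run, "engine_run")) run$outputs$output else run
  which.max(out)
}
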