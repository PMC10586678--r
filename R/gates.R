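#' Stochastic logic gate algebra
#'
#' Values in \[0, 1\] interpreted as probabilities of a 1 in a random
#' bitstream turn Boolean gates into arithmetic on the unit interval: NOT
#' computes `1 - x`, AND multiplies (`x * y`), OR gives `x + y - x*y`, and the
#' composed gates NAND/NOR/XOR/XNOR follow. `gate_eval()` evaluates these
#' closed forms (vectorised with recycling); [bitstream_oracle()] estimates
#' the same quantity by Monte Carlo on actual bitstreams.
#'
#' @param gate One of `"NOT"`, `"AND"`, `"OR"`, `"NAND"`, `"NOR"`, `"XOR"`,
#'   `"XNOR"`.
#' @param x,y Input probabilities in \[0, 1\]; `y` must be absent for NOT and
#'   present otherwise.
#' @return Numeric vector of output probabilities in \[0, 1\].
#' @examples
#' gate_eval("NOT", 3 / 8) # 5/8
#' gate_eval("AND", 0.5, 0.5) # 0.25
#' @export
gate_eval <- function(gate, x, y = NULL) {
  gate <- match.arg(toupper(gate), stochastic_gates())
  check_fraction(x, "`x`")
  if (gate == "NOT") {
    if (!is.null(y)) stop("NOT takes a single input", call. = FALSE)
    return(1 - x)
  }
  if (is.null(y)) stop(sprintf("%s takes two inputs", gate), call. = FALSE)
  check_fraction(y, "`y`")
  # NAND/NOR/XNOR are the NOT-compositions of AND/OR/XOR, computed as such
  # so the composition identities hold to the last bit
  switch(gate,
    AND = x * y,
    OR = x + y - x * y,
    NAND = 1 - x * y,
    NOR = 1 - (x + y - x * y),
    XOR = x + y - 2 * x * y,
    XNOR = 1 - (x + y - 2 * x * y)
  )
}

#' @rdname gate_eval
#' @export
stochastic_gates <- function() {
  c("NOT", "AND", "OR", "NAND", "NOR", "XOR", "XNOR")
}

gate_boolean <- function(gate, bx, by = NULL) {
  switch(gate,
    NOT = !bx,
    AND = bx & by,
    OR = bx | by,
    NAND = !(bx & by),
    NOR = !(bx | by),
    XOR = xor(bx, by),
    XNOR = !xor(bx, by)
  )
}

#' Bitstream Monte Carlo oracle for a stochastic gate
#'
#' Generates independent Bernoulli bitstreams encoding `x` (and `y`), applies
#' the Boolean gate bitwise, and returns the empirical fraction of 1s. This is
#' the simulation-level definition of the stochastic gate functions and serves
#' as an independent check of the closed forms in [gate_eval()]; the standard
#' error of the estimate is `sqrt(p * (1 - p) / n)`.
#'
#' @inheritParams gate_eval
#' @param n Bitstream length.
#' @param seed Optional integer seed.
#' @return A single empirical fraction.
#' @export
bitstream_oracle <- function(gate, x, y = NULL, n = 1e5, seed = NULL) {
  gate <- match.arg(toupper(gate), stochastic_gates())
  stopifnot(n >= 1)
  check_fraction(x, "`x`")
  if (gate == "NOT" && !is.null(y)) stop("NOT takes a single input", call. = FALSE)
  if (gate != "NOT") {
    if (is.null(y)) stop(sprintf("%s takes two inputs", gate), call. = FALSE)
    check_fraction(y, "`y`")
  }
  with_seed_opt(seed, {
    bx <- stats::runif(n) < x
    by <- if (gate == "NOT") NULL else stats::runif(n) < y
    mean(gate_boolean(gate, bx, by))
  })
}

#' Evaluate the gate algebra over a grid
#'
#' Convenience for sweeping the closed forms (and optionally the bitstream
#' oracle) over a grid of input probabilities.
#'
#' @param gates Character vector of gate names (default: all seven).
#' @param x,y Grid values for the two inputs.
#' @param oracle_n When nonzero, also run [bitstream_oracle()] with this
#'   stream length at each grid point (seeded from `seed`).
#' @param seed Base seed for the oracle streams.
#' @return A tibble with columns `gate`, `x`, `y` (`NA` for NOT), `value`,
#'   and, when `oracle_n > 0`, `empirical` and `se`.
#' @export
gate_grid <- function(gates = stochastic_gates(),
                      x = seq(0, 1, by = 0.05), y = x,
                      oracle_n = 0, seed = 1L) {
  rows <- purrr::map_dfr(gates, function(g) {
    if (g == "NOT") {
      tibble::tibble(gate = g, x = x, y = NA_real_,
                     value = gate_eval(g, x))
    } else {
      grid <- tidyr::expand_grid(x = x, y = y)
      tibble::tibble(gate = g, x = grid$x, y = grid$y,
                     value = gate_eval(g, grid$x, grid$y))
    }
  })
  if (oracle_n > 0) {
    seeds <- seed + seq_len(nrow(rows))
    rows$empirical <- purrr::map_dbl(seq_len(nrow(rows)), function(i) {
      yv <- if (is.na(rows$y[i])) NULL else rows$y[i]
      bitstream_oracle(rows$gate[i], rows$x[i], yv, n = oracle_n,
                       seed = seeds[i])
    })
    rows$se <- sqrt(rows$value * (1 - rows$value) / oracle_n)
  }
  rows
}
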