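# Independent oracles used across tests. Deliberately written with plain
# loops and base R, not via the package's engine path.

# step-activation MLP computed directly from the closed form:
# out = step((1/n_in) * W %*% x), per layer
ref_step_mlp <- function(weights, x, threshold = 0.5, cap = 1) {
  for (W in weights) {
    pre <- numeric(nrow(W))
    for (i in seq_len(nrow(W))) {
      acc <- 0
      for (j in seq_len(ncol(W))) acc <- acc + W[i, j] * x[j]
      pre[i] <- acc / ncol(W)
    }
    x <- ifelse(pre > threshold, cap, 0)
  }
  x
}

# closed-form moments of the both-nicked count for a sampled pool of t
# molecules encoded with independent per-molecule nicks at fractions a, b
binom_both_moments <- function(t, a, b) {
  p <- a * b
  list(mean = t * p, var = t * p * (1 - p))
}

# truth table evaluation of a gate by brute enumeration over bits
truth_gate <- function(gate, bx, by = NULL) {
  switch(gate,
    NOT = 1L - bx,
    AND = bx * by,
    OR = as.integer(bx + by > 0),
    NAND = 1L - bx * by,
    NOR = as.integer(bx + by == 0),
    XOR = as.integer(bx != by),
    XNOR = as.integer(bx == by)
  )
}

# exact stochastic-gate output by total-probability enumeration over the
# four input bit combinations (two-input gates) or two (NOT)
enum_gate_prob <- function(gate, x, y = NULL) {
  if (gate == "NOT") {
    return(sum(vapply(0:1, function(bx) {
      pb <- if (bx == 1) x else 1 - x
      pb * truth_gate(gate, bx)
    }, numeric(1))))
  }
  acc <- 0
  for (bx in 0:1) for (by in 0:1) {
    pb <- (if (bx == 1) x else 1 - x) * (if (by == 1) y else 1 - y)
    acc <- acc + pb * truth_gate(gate, bx, by)
  }
  acc
}
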