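dna_drop <- function(a, mode = "ideal", t = 1) {
  pool <- encode_by_split(molecule_pool(t, mode), "A", a)
  droplet(pool, kind = "dna")
}

enzyme_drop <- function(b, t = 1, k = 1) {
  droplet(dose_for_fraction(b, t, turnover = k), kind = "enzyme")
}

test_that("a microcell cycle replays as the six-step valve sequence", {
  res <- microcell_cycle(microcell(), dna_drop(0.5), enzyme_drop(0.5))
  tr <- res$trace
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$action,
               c("set_valves(L=open,R=closed)", "load_left",
                 "set_valves(L=closed,R=open)", "load_right",
                 "set_valves(L=open,R=open)", "release"))
  expect_equal(tr$valve_L, c("open", "open", "closed", "closed", "open", "open"))
  expect_equal(tr$valve_R, c("closed", "closed", "open", "open", "open", "open"))
  # the mixed droplet carries the product
  expect_equal(measure(res$droplet$payload, "both"), 0.25)
  # zero-dose enzyme leaves the pool unchanged
  res0 <- microcell_cycle(microcell(), dna_drop(0.5), enzyme_drop(0))
  expect_equal(measure(res0$droplet$payload, "both"), 0)
  expect_equal(measure(res0$droplet$payload, "nickA"), 0.5)
})

test_that("no droplet ever moves through a closed valve", {
  # loading the left slot with the left valve closed is rejected
  cell <- microcell_step(microcell(), "set_valves", valve_L = "closed",
                         valve_R = "open")
  expect_error(microcell_step(cell, "load_left", drop = dna_drop(0.5)),
               "scheduling error")
  # loading the right slot while R is closed is rejected
  cell2 <- microcell_step(microcell(), "set_valves", valve_L = "open",
                          valve_R = "closed")
  expect_error(microcell_step(cell2, "load_right", drop = enzyme_drop(0.5)),
               "scheduling error")
  # release demands both valves open and both slots filled
  cell3 <- microcell_step(microcell(), "set_valves", valve_L = "open",
                          valve_R = "open")
  expect_error(microcell_step(cell3, "release"), "scheduling error")
  # property: in every legal cycle trace, droplet movements only happen in
  # valve states that permit them
  for (s in 1:20) {
    ab <- withr::with_seed(300 + s, runif(2))
    tr <- microcell_cycle(microcell(), dna_drop(ab[1]), enzyme_drop(ab[2]))$trace
    moved <- tr[tr$droplet_moved, ]
    legal <- (moved$action == "load_left" & moved$valve_L == "open" & moved$valve_R == "closed") |
      (moved$action == "load_right" & moved$valve_R == "open" & moved$valve_L == "closed") |
      (moved$action == "release" & moved$valve_L == "open" & moved$valve_R == "open")
    expect_true(all(legal))
  }
})

test_that("row merging averages product fractions with a two-phase valve trace", {
  d1 <- microcell_cycle(microcell(), dna_drop(0.4), enzyme_drop(0.5))$droplet
  d2 <- microcell_cycle(microcell(), dna_drop(0.8), enzyme_drop(0.5))$droplet
  m <- row_merge(list(d1, d2))
  expect_equal(measure(m$droplet$payload, "both"), mean(c(0.2, 0.4)))
  expect_equal(m$droplet$volume, d1$volume + d2$volume)
  expect_equal(m$trace$valve_Y, c("open", "closed"))
  expect_equal(m$trace$valve_Z, c("closed", "open"))
  # all-zero products merge to zero
  z <- row_merge(list(dna_drop(0), dna_drop(0)))
  expect_equal(measure(z$droplet$payload, "both"), 0)
  # unequal volumes refuse to merge
  big <- droplet(molecule_pool(), volume = 2)
  expect_error(row_merge(list(dna_drop(0.5), big)), "equal volume")
})

test_that("sampled-mode row merge tracks the mean of products within 4 sigma", {
  k <- 10
  t <- 1e4
  ab <- withr::with_seed(31, matrix(runif(2 * k), ncol = 2))
  drops <- lapply(seq_len(k), function(j) {
    p <- encode_by_split(molecule_pool(t, "sampled"), "A", ab[j, 1], seed = 400 + j)
    p <- encode_by_split(p, "B", ab[j, 2], seed = 500 + j)
    droplet(p, kind = "merged")
  })
  m <- row_merge(drops)
  target <- mean(ab[, 1] * ab[, 2])
  # sum of k independent binomials: var = sum p_j (1 - p_j) * t
  sd_sum <- sqrt(sum(ab[, 1] * ab[, 2] * (1 - ab[, 1] * ab[, 2]) * t))
  expect_lt(abs(measure(m$droplet$payload, "both") - target), 4 * sd_sum / (k * t))
})

test_that("the reaction pipeline thresholds and re-encodes at site A", {
  p <- encode_by_split(encode_by_split(molecule_pool(), "A", 1), "B", 0.6)
  res <- reaction_pipeline(droplet(p, kind = "merged"), seesaw_gate(0.5))
  expect_equal(res$activated, 1)
  expect_equal(measure(res$droplet$payload, "nickA"), 1)
  expect_equal(measure(res$droplet$payload, "both"), 0)
  # below threshold everything is waste
  p2 <- encode_by_split(encode_by_split(molecule_pool(), "A", 1), "B", 0.3)
  res2 <- reaction_pipeline(droplet(p2, kind = "merged"), seesaw_gate(0.5))
  expect_equal(res2$activated, 0)
  expect_equal(measure(res2$droplet$payload, "nickA"), 0)
  # the strand ledger balances released vs bound at displacement
  lg <- res$ledger
  disp <- lg[lg$stage == "displace_separate", ]
  expect_equal(sum(disp$quantity), 1) # ssdna_input + beads_bound == total
  expect_equal(res$stages$stage,
               c("heat_toehold", "displace_separate", "seesaw_activate",
                 "translate", "nick_fresh"))
})

test_that("splitting preserves fractions (ideal) and molecules (sampled)", {
  p <- encode_by_split(encode_by_split(molecule_pool(), "A", 0.6), "B", 0.5)
  big <- droplet(p, volume = 4, kind = "merged")
  parts <- split_droplet(big, 4)
  fr <- vapply(parts, function(d) measure(d$payload, "both"), numeric(1))
  expect_equal(fr, rep(0.3, 4))
  expect_equal(vapply(parts, `[[`, numeric(1), "volume"), rep(1, 4))
  # split then re-merge restores the original exactly
  back <- row_merge(parts)
  expect_equal(measure(back$droplet$payload, "both"), 0.3)
  expect_equal(back$droplet$volume, 4)
  # sampled multinomial split: counts conserved, per-part fraction near parent
  t <- 1e5
  ps <- encode_by_split(molecule_pool(t, "sampled"), "A", 0.6, seed = 61)
  ps <- encode_by_split(ps, "B", 0.5, seed = 62)
  parent_frac <- measure(ps, "both")
  parts_s <- split_droplet(droplet(ps, volume = 10), 10, seed = 63)
  tot <- sum(vapply(parts_s, function(d) d$payload$total, numeric(1)))
  expect_equal(tot, t)
  for (d in parts_s) {
    n_i <- d$payload$total
    se <- sqrt(parent_frac * (1 - parent_frac) / n_i)
    expect_lt(abs(measure(d$payload, "both") - parent_frac), 4 * se)
  }
  expect_error(split_droplet(big, 0), "positive integer")
})

test_that("execute_layer matches the closed form in saturating and zero cases", {
  arr <- microcell_array(2)
  up <- layer_spec(matrix(1, 1, 2), seesaw_gate(0.5))
  res <- execute_layer(arr, up, c(1, 1))
  expect_equal(res$outputs$pre_activation, 1)
  expect_equal(res$outputs$output, 1)
  zero <- layer_spec(matrix(0, 1, 2), seesaw_gate(0.5))
  expect_equal(execute_layer(arr, zero, c(1, 1))$outputs$output, 0)
  expect_error(execute_layer(arr, up, c(1, 1, 1)), "dimension mismatch")
})

test_that("an 8 x 8 ideal layer equals the reference step network", {
  arr <- microcell_array(8)
  for (s in 1:5) {
    W <- withr::with_seed(700 + s, matrix(runif(64), 8, 8))
    x <- withr::with_seed(800 + s, runif(8))
    res <- execute_layer(arr, layer_spec(W, seesaw_gate(0.25)), x)
    expect_equal(res$outputs$output, ref_step_mlp(list(W), x, threshold = 0.25))
  }
})

test_that("serialization accumulates partial pre-activations correctly", {
  # a 2-wide array forced into 3 passes over 6 inputs must agree with the
  # full-width result
  W <- withr::with_seed(91, matrix(runif(12), 2, 6))
  x <- withr::with_seed(92, runif(6))
  small <- execute_layer(microcell_array(2), layer_spec(W, seesaw_gate(0.3)), x)
  wide <- execute_layer(microcell_array(8), layer_spec(W, seesaw_gate(0.3)), x)
  expect_equal(small$passes, 3L)
  expect_equal(wide$passes, 1L)
  expect_equal(small$outputs$pre_activation, wide$outputs$pre_activation,
               tolerance = 1e-12)
  expect_equal(small$outputs$output, wide$outputs$output)
})

test_that("compile_network clips, rescales and reports", {
  W <- matrix(c(0.2, 0.8, 0.5, 0.1), 2, 2)
  net <- compile_network(list(W))
  expect_equal(net$scales, 1)
  expect_equal(net$clipped_counts, 0L)
  expect_equal(net$layers[[1]]$weights, W)
  W2 <- matrix(c(2, -1, 0.5, 1), 2, 2)
  net2 <- compile_network(list(W2))
  expect_equal(net2$scales, 2)
  expect_equal(net2$clipped_counts, 1L)
  expect_equal(max(net2$layers[[1]]$weights), 1)
  expect_warning(compile_network(list(matrix(-1, 2, 2))), "degenerate")
  expect_error(compile_network(list(matrix(1, 2, 2), matrix(1, 2, 3))),
               "incompatible")
})

test_that("network serialization factors follow the ceiling rule", {
  net <- compile_network(list(matrix(0.5, 784, 784), matrix(0.5, 10, 784)))
  expect_equal(serialization_factors(net, 196), c(4L, 4L, 1L))
  expect_equal(serialization_factors(net, 4), c(196L, 196L, 3L))
  expect_equal(serialization_factors(net, 49), c(16L, 16L, 1L))
})

test_that("run_network reduces to execute_layer for one layer and chains for two", {
  arr <- microcell_array(4)
  W <- withr::with_seed(17, matrix(runif(16), 4, 4))
  x <- withr::with_seed(18, runif(4))
  net1 <- compile_network(list(W), seesaw_gate(0.3))
  run1 <- run_network(arr, net1, x)
  lay1 <- execute_layer(arr, net1$layers[[1]], x)
  expect_equal(run1$outputs$output, lay1$outputs$output)
  # two layers equal the reference oracle exactly
  W2 <- withr::with_seed(19, matrix(runif(8), 2, 4))
  net2 <- compile_network(list(W, W2), seesaw_gate(0.3))
  run2 <- run_network(arr, net2, x)
  expect_equal(run2$outputs$output, ref_step_mlp(list(W, W2), x, threshold = 0.3))
  # tidy/glance surfaces
  td <- tidy(run2)
  expect_equal(nrow(td), 4 + 2)
  expect_equal(glance(run2)$n_layers, 2L)
  expect_equal(glance(run2)$total_hours, sum(run2$timing$hours))
})

test_that("sampled-mode engine output converges toward the ideal reference", {
  arr <- microcell_array(4)
  W <- withr::with_seed(41, matrix(runif(16, 0.2, 0.8), 4, 4))
  net <- compile_network(list(W), seesaw_gate(0.35))
  x <- withr::with_seed(42, runif(4, 0.3, 0.9))
  ideal <- run_network(arr, net, x)$outputs$output
  mae <- vapply(c(1e2, 1e3, 1e4), function(t) {
    errs <- vapply(1:60, function(s) {
      out <- run_network(arr, net, x, mode = "sampled", t = t,
                         seed = 1000 + s)$outputs$output
      mean(abs(out - ideal))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) <= 0))
})
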