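#' Droplets: transportable units of fluid
#'
#' A droplet carries a payload — a [molecule_pool()], an [enzyme_dose()], a
#' probe or gate mix, or a merged product — plus a volume in unit-droplet
#' multiples and a symbolic channel position. Volume is conserved under
#' merging (volumes add) and splitting (equal parts).
#'
#' @param payload The carried object.
#' @param volume Positive volume in unit droplets (default 1).
#' @param kind Payload kind tag: `"dna"`, `"enzyme"`, `"probe"`, `"gate"`,
#'   or `"merged"`.
#' @param position Symbolic channel location string.
#' @return An object of class `droplet`.
#' @export
droplet <- function(payload, volume = 1,
                    kind = c("dna", "enzyme", "probe", "gate", "merged"),
                    position = "channel") {
  kind <- match.arg(kind)
  if (!is.numeric(volume) || volume <= 0) {
    stop("droplet `volume` must be positive", call. = FALSE)
  }
  structure(list(payload = payload, volume = volume, kind = kind,
                 position = position), class = "droplet")
}

#' @export
print.droplet <- function(x, ...) {
  cat(sprintf("<droplet: %s payload, volume %g, at %s>\n",
              x$kind, x$volume, x$position))
  invisible(x)
}

trace_row <- function(step, action, valve_L, valve_R, moved, slot_left,
                      slot_right) {
  tibble::tibble(step = step, action = action, valve_L = valve_L,
                 valve_R = valve_R, droplet_moved = moved,
                 slot_left = slot_left, slot_right = slot_right)
}

#' A valved microcell and its legal state transitions
#'
#' A microcell is the chamber in which one multiplication happens: a DNA
#' droplet is parked on the left channel, a weight-enzyme droplet on the
#' right, and opening both pneumatic (Quake) valves pushes the two out
#' together to mix. The cell enforces protocol legality: a droplet may enter
#' the left slot only while the left valve is open and the right closed (the
#' flow is routed left), enter the right slot only in the swapped valve
#' state, and exit only with both valves open. Any other movement is a
#' scheduling error — a droplet never passes a closed valve.
#'
#' @param row,col Grid position of the cell.
#' @return An object of class `microcell`.
#' @seealso [microcell_cycle()] which drives a cell through the six-step
#'   load/mix protocol.
#' @export
microcell <- function(row = 1L, col = 1L) {
  structure(
    list(valve_L = "open", valve_R = "open", slot_left = NULL,
         slot_right = NULL, row = row, col = col,
         trace = trace_row(integer(), character(), character(), character(),
                           logical(), logical(), logical())[0, ]),
    class = "microcell"
  )
}

cell_record <- function(cell, action, moved = FALSE) {
  cell$trace <- dplyr::bind_rows(
    cell$trace,
    trace_row(nrow(cell$trace) + 1L, action, cell$valve_L, cell$valve_R,
              moved, !is.null(cell$slot_left), !is.null(cell$slot_right))
  )
  cell
}

#' @rdname microcell
#' @param cell A `microcell`.
#' @param action One of `"set_valves"`, `"load_left"`, `"load_right"`,
#'   `"release"`.
#' @param valve_L,valve_R Target valve states for `"set_valves"` (`"open"` or
#'   `"closed"`).
#' @param drop Droplet being loaded for the load actions.
#' @return `microcell_step()`: the updated cell; for `"release"` the mixed
#'   pair of droplets is attached as `cell$released`.
#' @export
microcell_step <- function(cell, action, valve_L = NULL, valve_R = NULL,
                           drop = NULL) {
  stopifnot(inherits(cell, "microcell"))
  switch(action,
    set_valves = {
      stopifnot(valve_L %in% c("open", "closed"),
                valve_R %in% c("open", "closed"))
      cell$valve_L <- valve_L
      cell$valve_R <- valve_R
      cell_record(cell, sprintf("set_valves(L=%s,R=%s)", valve_L, valve_R))
    },
    load_left = {
      if (cell$valve_L != "open" || cell$valve_R != "closed") {
        stop("scheduling error: a droplet may enter the left slot only with L open and R closed",
             call. = FALSE)
      }
      if (!is.null(cell$slot_left)) {
        stop("scheduling error: left slot already occupied", call. = FALSE)
      }
      cell$slot_left <- drop
      cell_record(cell, "load_left", moved = TRUE)
    },
    load_right = {
      if (cell$valve_R != "open" || cell$valve_L != "closed") {
        stop("scheduling error: a droplet may enter the right slot only with R open and L closed",
             call. = FALSE)
      }
      if (!is.null(cell$slot_right)) {
        stop("scheduling error: right slot already occupied", call. = FALSE)
      }
      cell$slot_right <- drop
      cell_record(cell, "load_right", moved = TRUE)
    },
    release = {
      if (cell$valve_L != "open" || cell$valve_R != "open") {
        stop("scheduling error: release requires both valves open", call. = FALSE)
      }
      if (is.null(cell$slot_left) || is.null(cell$slot_right)) {
        stop("scheduling error: release requires both slots occupied", call. = FALSE)
      }
      cell$released <- list(cell$slot_left, cell$slot_right)
      cell$slot_left <- NULL
      cell$slot_right <- NULL
      cell_record(cell, "release", moved = TRUE)
    },
    stop(sprintf("unknown microcell action '%s'", action), call. = FALSE)
  )
}

#' Run one microcell load/mix cycle
#'
#' Drives a microcell through the six-step protocol: (1) left valve open,
#' right closed, routing flow left; (2) the DNA droplet enters and parks on
#' the left channel; (3) valves swap (L closed, R open); (4) the enzyme
#' droplet enters the right channel while the DNA droplet sits in static
#' fluid; (5) both valves open, pushing both droplets; (6) the droplets exit
#' together and mix as the channels merge. The emitted droplet's pool has
#' been nicked by the dose (via [nick_with_enzyme()]); the cycle trace
#' records the six steps with their valve states for replay testing.
#'
#' @param cell A [microcell()] (empty).
#' @param dna A `"dna"` [droplet()] carrying a [molecule_pool()].
#' @param enzyme An `"enzyme"` [droplet()] carrying an [enzyme_dose()].
#' @param seed Optional seed forwarded to sampled-mode nicking.
#' @return A list with `droplet` (the mixed product), `cell` (reset), and
#'   `trace` (a six-row tibble).
#' @export
microcell_cycle <- function(cell, dna, enzyme, seed = NULL) {
  stopifnot(inherits(cell, "microcell"), inherits(dna, "droplet"),
            inherits(enzyme, "droplet"))
  if (!is.null(cell$slot_left) || !is.null(cell$slot_right)) {
    stop("scheduling error: microcell must be empty at cycle start", call. = FALSE)
  }
  if (!inherits(dna$payload, "molecule_pool") ||
      !inherits(enzyme$payload, "enzyme_dose")) {
    stop("cycle payloads must be a molecule pool (left) and an enzyme dose (right)",
         call. = FALSE)
  }
  cell$trace <- cell$trace[0, ]
  cell <- microcell_step(cell, "set_valves", valve_L = "open", valve_R = "closed")
  cell <- microcell_step(cell, "load_left", drop = dna)
  cell <- microcell_step(cell, "set_valves", valve_L = "closed", valve_R = "open")
  cell <- microcell_step(cell, "load_right", drop = enzyme)
  cell <- microcell_step(cell, "set_valves", valve_L = "open", valve_R = "open")
  cell <- microcell_step(cell, "release")
  pool <- nick_with_enzyme(dna$payload, enzyme$payload, seed = seed)
  out <- droplet(pool, volume = dna$volume + enzyme$volume, kind = "merged",
                 position = sprintf("exit(%d,%d)", cell$row, cell$col))
  trace <- cell$trace
  cell$released <- NULL
  list(droplet = out, cell = cell, trace = trace)
}

#' Merge one row of product droplets into a dot-product droplet
#'
#' The row merge module combines the k mixed droplets of a row into one large
#' droplet in two valve phases: first the Y valves are open and the Z valves
#' closed, producing rightward flow with no vertical pressure difference;
#' then Y closes and Z opens, forcing each droplet up the merge channels to
#' arrive at the merge point simultaneously. Fragment counts and totals add,
#' so the merged both-species fraction is the mean of the k product
#' fractions — i.e. `(1/k) * sum(a_j * b_j)`, the 1/k-normalised dot product.
#'
#' @param droplets List of k product [droplet()]s of equal volume, each
#'   carrying a [molecule_pool()].
#' @return A list with `droplet` (the merged droplet, volume k) and `trace`
#'   (the two-phase valve tibble).
#' @export
row_merge <- function(droplets) {
  stopifnot(length(droplets) >= 1,
            all(vapply(droplets, inherits, logical(1), "droplet")))
  vols <- vapply(droplets, `[[`, numeric(1), "volume")
  if (max(vols) - min(vols) > 1e-12 * max(vols)) {
    stop("merge error: all droplets in a row must have equal volume", call. = FALSE)
  }
  pools <- lapply(droplets, `[[`, "payload")
  if (!all(vapply(pools, inherits, logical(1), "molecule_pool"))) {
    stop("merge error: all droplets must carry molecule pools", call. = FALSE)
  }
  modes <- unique(vapply(pools, `[[`, character(1), "mode"))
  if (length(modes) != 1L) {
    stop("merge error: cannot merge pools of mixed fidelity modes", call. = FALSE)
  }
  merged <- pools[[1L]]
  merged$species <- Reduce(`+`, lapply(pools, `[[`, "species"))
  merged$total <- sum(vapply(pools, `[[`, numeric(1), "total"))
  merged$seed_lineage <- unlist(lapply(pools, `[[`, "seed_lineage"))
  validate_pool(merged)
  trace <- tibble::tibble(
    phase = 1:2,
    action = c("rightward_flow", "upward_merge"),
    valve_Y = c("open", "closed"),
    valve_Z = c("closed", "open")
  )
  list(droplet = droplet(merged, volume = sum(vols), kind = "merged",
                         position = "merge_module"),
       trace = trace)
}

#' Run the closing reaction pipeline on a merged droplet
#'
#' Chains the five post-merge stages that turn a dot-product pool into the
#' next layer's input: gentle heat creates toeholds on the double-nicked
#' molecules ([create_toeholds()]); excess probe strands displace the
#' fragment ssDNA and bead separation removes everything else
#' ([displace_and_separate()]); the seesaw gate thresholds and amplifies the
#' ssDNA fraction ([seesaw_activate()]); the translation reaction converts
#' the output ssDNA into a proportional nicking-enzyme dose
#' ([translate_to_enzyme()]); and that dose nicks a fresh un-nicked pool at
#' site A ([nick_with_enzyme()]), re-encoding the activated value.
#'
#' @param merged A merged [droplet()] carrying a double-nicked pool.
#' @param gate A [seesaw_gate()].
#' @param fresh_total Total of the fresh pool the activated value is encoded
#'   into (defaults to the merged pool's per-unit total).
#' @param seed Optional seed for sampled-mode re-encoding.
#' @return A list with `droplet` (fresh pool encoding the activated value at
#'   site A), `activated` (the numeric output value), `ledger` (the strand
#'   audit tibble), and `stages` (a stage-by-stage tibble of the pipeline).
#' @export
reaction_pipeline <- function(merged, gate = seesaw_gate(),
                              fresh_total = NULL, seed = NULL) {
  stopifnot(inherits(merged, "droplet"),
            inherits(merged$payload, "molecule_pool"))
  pool <- merged$payload
  if (is.null(fresh_total)) {
    fresh_total <- if (pool$mode == "ideal") 1 else round(pool$total / merged$volume)
  }
  mix <- create_toeholds(pool)
  mix <- displace_and_separate(mix, probe_excess = TRUE)
  u <- mix$ssdna_input / mix$total_reference
  v <- seesaw_activate(u, gate)
  waste <- if (v == 0) mix$ssdna_input else 0
  mix$waste <- waste
  mix <- log_stage(mix, "seesaw_activate", ssdna_output = v * mix$total_reference,
                   waste = waste)
  mix$ssdna_output <- v * mix$total_reference
  dose <- translate_to_enzyme(v, proportionality = 1, total = fresh_total,
                              turnover = 1L, target_site = "A")
  fresh <- molecule_pool(total = fresh_total, mode = pool$mode,
                         template = pool$template)
  fresh <- nick_with_enzyme(fresh, dose, seed = seed)
  stages <- tibble::tibble(
    stage = c("heat_toehold", "displace_separate", "seesaw_activate",
              "translate", "nick_fresh"),
    value = c(measure(pool, "both"), u, v, implied_fraction(dose, fresh_total),
              measure(fresh, "nickA"))
  )
  list(droplet = droplet(fresh, volume = 1, kind = "dna",
                         position = "pipeline_exit"),
       activated = v, ledger = mix_ledger(mix), stages = stages)
}

#' Split a large droplet into k equal droplets
#'
#' The droplet separator applies a pinching pressure at regular intervals,
#' cutting a merged droplet into k equally sized, equally spaced droplets for
#' column-wise re-entry into the array. In ideal mode every part carries the
#' identical species fractions and 1/k of the material; in sampled mode the
#' molecules of each species are partitioned by a seeded multinomial draw.
#'
#' @param large A [droplet()] carrying a [molecule_pool()].
#' @param k Number of parts (positive integer).
#' @param seed Optional seed for the sampled-mode multinomial partition.
#' @return A list of k [droplet()]s.
#' @export
split_droplet <- function(large, k, seed = NULL) {
  stopifnot(inherits(large, "droplet"),
            inherits(large$payload, "molecule_pool"))
  if (k <= 0 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  pool <- large$payload
  if (pool$mode == "ideal") {
    parts <- replicate(k, {
      p <- pool
      p$species <- pool$species / k
      p$total <- pool$total / k
      p
    }, simplify = FALSE)
  } else {
    counts <- with_seed_opt(seed, {
      vapply(pool$species, function(n) {
        if (n == 0) return(rep(0, k))
        as.numeric(stats::rmultinom(1L, as.integer(n), rep(1 / k, k)))
      }, numeric(k))
    })
    counts <- matrix(counts, nrow = k,
                     dimnames = list(NULL, names(pool$species)))
    parts <- lapply(seq_len(k), function(i) {
      p <- pool
      p$species[] <- counts[i, ]
      p$total <- sum(counts[i, ])
      if (!is.null(seed)) p$seed_lineage <- c(p$seed_lineage, as.integer(seed))
      p
    })
  }
  lapply(seq_along(parts), function(i) {
    droplet(parts[[i]], volume = large$volume / k, kind = "dna",
            position = sprintf("split_%d", i))
  })
}
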