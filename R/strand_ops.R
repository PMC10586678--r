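#' Strand mixes: the readout bookkeeping container
#'
#' A strand mix tracks the fragment strand population of a pool through
#' readout: fragments still bound on their bead-attached template
#' (`beads_bound`), displaced free input ssDNA (`ssdna_input`), seesaw gate
#' output ssDNA (`ssdna_output`), and material consumed as waste by the
#' threshold reaction (`waste`). Quantities are in the same units as the
#' originating pool (`total_reference`), so fractions are quantities divided
#' by `total_reference`. Every stage appends to a reaction ledger (a tibble of
#' stage/species/quantity rows) for audit tests.
#'
#' @param toeholds Quantity of molecules carrying an exposed toehold.
#' @param ssdna_input,ssdna_output,waste,beads_bound Stage quantities; see
#'   description.
#' @param total_reference The originating pool total `t`.
#' @return An object of class `strand_mix`.
#' @export
strand_mix <- function(toeholds = 0, ssdna_input = 0, ssdna_output = 0,
                       waste = 0, beads_bound = 0, total_reference) {
  q <- c(toeholds, ssdna_input, ssdna_output, waste, beads_bound)
  if (any(q < 0)) stop("strand quantities must be nonnegative", call. = FALSE)
  structure(
    list(toeholds = toeholds, ssdna_input = ssdna_input,
         ssdna_output = ssdna_output, waste = waste,
         beads_bound = beads_bound, total_reference = total_reference,
         ledger = tibble::tibble(stage = character(), species = character(),
                                 quantity = numeric())),
    class = "strand_mix"
  )
}

#' @export
print.strand_mix <- function(x, ...) {
  cat(sprintf("<strand_mix: reference total %g>\n", x$total_reference))
  for (f in c("toeholds", "ssdna_input", "ssdna_output", "waste", "beads_bound")) {
    cat(sprintf("  %-12s %g\n", f, x[[f]]))
  }
  invisible(x)
}

log_stage <- function(mix, stage, ...) {
  vals <- c(...)
  mix$ledger <- dplyr::bind_rows(
    mix$ledger,
    tibble::tibble(stage = stage, species = names(vals),
                   quantity = unname(vals))
  )
  mix
}

#' Reaction ledger of a strand mix
#'
#' @param mix A [strand_mix()].
#' @return The ledger tibble (`stage`, `species`, `quantity`).
#' @export
mix_ledger <- function(mix) mix$ledger

#' Create toeholds by gentle heating
#'
#' Gentle heat selectively denatures the short fragment between the two nick
#' sites. Only molecules nicked at both sites release that region into an
#' exposed toehold, so the toehold-bearing count equals the `both` species
#' exactly; the other three species stay inert duplex. Requires the template's
#' nick pair distance to be within its maximum toehold gap — a wider gap will
#' not denature under gentle heat and is a design error.
#'
#' @param pool A double-encoded [molecule_pool()].
#' @return A [strand_mix()] with `toeholds` set and everything still
#'   bead-bound.
#' @export
create_toeholds <- function(pool) {
  stopifnot(inherits(pool, "molecule_pool"))
  tmpl <- pool$template
  if (tmpl$pair_distance > tmpl$max_toehold_gap) {
    stop(sprintf(
      "nick pair distance %d bp exceeds the maximum toehold gap %d bp; the fragment cannot be released",
      tmpl$pair_distance, tmpl$max_toehold_gap), call. = FALSE)
  }
  both <- pool$species[["both"]]
  mix <- strand_mix(toeholds = both, beads_bound = pool$total,
                    total_reference = pool$total)
  log_stage(mix, "heat_toehold", toeholds = both, beads_bound = pool$total)
}

#' Displace the fragment with probe strands and separate on beads
#'
#' Excess probe strands bind the exposed toeholds and displace the fragment
#' ssDNA (complete displacement assumed). A magnetic field then pulls down all
#' bead-attached material — the template duplexes and any surplus probes —
#' leaving only the free displaced ssDNA, whose count equals the toehold
#' count. Fragment bookkeeping: of the `total_reference` fragment strands, the
#' displaced ones become `ssdna_input` and the rest remain `beads_bound`, so
#' `ssdna_input + beads_bound == total_reference` at every stage.
#'
#' @param mix A [strand_mix()] from [create_toeholds()].
#' @param probe_excess Must be `TRUE`; sub-stoichiometric probe regimes are
#'   unsupported.
#' @param efficiency Optional displacement efficiency multiplier in (0, 1\],
#'   default 1 (complete displacement). Values below 1 are for leakage studies
#'   only.
#' @return The updated [strand_mix()] containing only free ssDNA plus the
#'   bead-bound remainder.
#' @export
displace_and_separate <- function(mix, probe_excess = TRUE, efficiency = 1) {
  stopifnot(inherits(mix, "strand_mix"))
  if (!isTRUE(probe_excess)) {
    stop("sub-stoichiometric probe regime is unsupported; supply probes in excess",
         call. = FALSE)
  }
  check_fraction(efficiency, "displacement `efficiency`")
  released <- mix$toeholds * efficiency
  mix$ssdna_input <- released
  mix$beads_bound <- mix$total_reference - released
  mix$toeholds <- 0
  log_stage(mix, "displace_separate",
            ssdna_input = released, beads_bound = mix$beads_bound)
}

#' Seesaw gate specification
#'
#' Parameters of the seesaw activation stage: a threshold strand concentration
#' `threshold` (as a fraction of the reference total) that consumes input
#' ssDNA into waste, a replenishment strand supply that drives catalytic
#' regeneration of input until the gate output saturates at
#' `replenishment_cap`, and the gate molecule supply itself (in excess by
#' default). Together these realise a sharp sigmoid — a step function with a
#' user-defined transition point — whose output can be capped below 1 by
#' limiting replenishment.
#'
#' @param threshold Transition point in (0, 1).
#' @param replenishment_cap Output saturation level in (0, 1\], default 1.
#' @param gate_supply Gate molecule supply as a fraction, default 1 (excess).
#' @return An object of class `seesaw_gate`.
#' @export
seesaw_gate <- function(threshold = 0.5, replenishment_cap = 1,
                        gate_supply = 1) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (replenishment_cap <= 0 || replenishment_cap > 1) {
    stop("`replenishment_cap` must lie in (0, 1]", call. = FALSE)
  }
  if (gate_supply <= 0 || gate_supply > 1) {
    stop("`gate_supply` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(threshold = threshold, replenishment_cap = replenishment_cap,
                 gate_supply = gate_supply), class = "seesaw_gate")
}

#' @export
print.seesaw_gate <- function(x, ...) {
  cat(sprintf("<seesaw_gate: threshold %g, replenishment cap %g, gate supply %g>\n",
              x$threshold, x$replenishment_cap, x$gate_supply))
  invisible(x)
}

#' Apply the seesaw activation to an input fraction
#'
#' Stoichiometric endpoint semantics of the threshold/gate/replenishment
#' cascade: input at or below the threshold is consumed entirely into waste
#' (output 0); input above the threshold survives thresholding and the excess
#' replenishment drives catalytic amplification until the output saturates at
#' `min(replenishment_cap, gate_supply)`. No rate constants enter: the cascade
#' is modelled at its fixed point, a step function.
#'
#' @param u Input ssDNA fraction(s) in \[0, 1\] (vectorised).
#' @param gate A [seesaw_gate()].
#' @return Activated output fraction(s).
#' @examples
#' g <- seesaw_gate(threshold = 0.5)
#' seesaw_activate(c(0.4, 0.6), g) # 0, 1
#' @export
seesaw_activate <- function(u, gate = seesaw_gate()) {
  stopifnot(inherits(gate, "seesaw_gate"))
  check_fraction(u, "input `u`")
  cap <- min(gate$replenishment_cap, gate$gate_supply)
  ifelse(u > gate$threshold, cap, 0)
}

#' Smooth sigmoid variant of the seesaw response
#'
#' A logistic relaxation `cap * plogis((u - threshold) / slope)` of the step
#' endpoint, for numerical experiments on threshold sharpness. This smooth
#' curve is a convenience of the simulator, not a fitted kinetic model of the
#' cascade; all engine and acceptance paths use the step form
#' [seesaw_activate()].
#'
#' @inheritParams seesaw_activate
#' @param slope Transition width (default 0.01).
#' @return Smoothly activated output fraction(s).
#' @export
seesaw_activate_smooth <- function(u, gate = seesaw_gate(), slope = 0.01) {
  stopifnot(inherits(gate, "seesaw_gate"), slope > 0)
  check_fraction(u, "input `u`")
  cap <- min(gate$replenishment_cap, gate$gate_supply)
  cap * stats::plogis((u - gate$threshold) / slope)
}

#' Translate an output ssDNA fraction into a nicking-enzyme dose
#'
#' The translation reaction unties a tagged nicking enzyme in proportion to
#' the output ssDNA, mapping each output strand one-to-one to an enzyme
#' (proportionality 1 by default). The returned dose produces an implied
#' nicked fraction of `proportionality * v` on a fresh pool of `total`
#' molecules, clipped to \[0, 1\] with the dose's `clipped` flag set when
#' clipping occurred.
#'
#' @param v Output ssDNA fraction in \[0, 1\].
#' @param proportionality Nonnegative enzymes released per output strand
#'   (default 1).
#' @param total Fresh-pool total the dose is destined for.
#' @param turnover Enzyme turnover `k` for the dose (default 1).
#' @param target_site Site the enzyme nicks on the fresh pool (default `"A"`,
#'   preparing the next layer's input).
#' @return An [enzyme_dose()].
#' @export
translate_to_enzyme <- function(v, proportionality = 1, total = 1,
                                turnover = 1L, target_site = "A") {
  check_fraction(v, "output fraction `v`")
  if (!is.numeric(proportionality) || proportionality < 0) {
    stop("`proportionality` must be nonnegative", call. = FALSE)
  }
  f <- proportionality * v
  clipped <- f > 1
  f <- min(max(f, 0), 1)
  dose <- enzyme_dose(f * total / turnover, target_site = target_site,
                      turnover = turnover)
  dose$clipped <- clipped
  if (clipped) {
    warning("translated dose exceeded a full-pool fraction and was clipped to 1",
            call. = FALSE)
  }
  dose
}
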