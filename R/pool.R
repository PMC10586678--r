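#' Create a pool of template DNA molecules
#'
#' A molecule pool is the carrier of a fractionally encoded value: every
#' template molecule has two designated nicking sites (labelled `"A"` and
#' `"B"`), and a value in \[0, 1\] is stored as the fraction of molecules
#' nicked at a given site. The pool tracks the four joint nick species
#' (`unnicked`, `nickA`, `nickB`, `both`).
#'
#' Two fidelity modes are supported. In `"ideal"` mode the species are real
#' valued fractions of a normalised total concentration and all operations are
#' exact algebra on fractions. In `"sampled"` mode the pool holds an integer
#' number of molecules and nicking is a seeded per-molecule Bernoulli draw, so
#' repeated runs exhibit binomial counting noise of the kind a finite droplet
#' would.
#'
#' @param total Total amount of template material. In `"ideal"` mode this is a
#'   normalised concentration (default `1`); in `"sampled"` mode it must be a
#'   positive integer number of molecules.
#' @param mode `"ideal"` or `"sampled"`.
#' @param template A [template_design()] describing the molecule layout;
#'   defaults to [default_template()].
#' @return An object of class `molecule_pool`.
#' @examples
#' p <- molecule_pool()
#' p <- encode_by_split(p, "A", 0.9)
#' p <- encode_by_split(p, "B", 0.8)
#' measure(p, "both") # 0.72
#' @seealso [encode_by_split()], [nick_with_enzyme()], [measure()]
#' @export
molecule_pool <- function(total = if (mode == "ideal") 1 else 10000L,
                          mode = c("ideal", "sampled"),
                          template = default_template()) {
  mode <- match.arg(mode)
  if (mode == "sampled") {
    if (total < 1 || total != round(total)) {
      stop("in sampled mode `total` must be a positive integer molecule count",
           call. = FALSE)
    }
    total <- as.numeric(round(total))
  } else if (total <= 0) {
    stop("`total` must be positive", call. = FALSE)
  }
  species <- c(unnicked = total, nickA = 0, nickB = 0, both = 0)
  structure(
    list(species = species, total = total, mode = mode,
         template = template, seed_lineage = integer()),
    class = "molecule_pool"
  )
}

#' @export
print.molecule_pool <- function(x, ...) {
  cat(sprintf("<molecule_pool: %s mode, total %g>\n", x$mode, x$total))
  fr <- x$species / x$total
  for (s in names(x$species)) {
    cat(sprintf("  %-8s %12g  (fraction %.6g)\n", s, x$species[[s]], fr[[s]]))
  }
  invisible(x)
}

validate_pool <- function(pool, tol = 1e-12) {
  stopifnot(inherits(pool, "molecule_pool"))
  if (any(pool$species < -tol)) {
    stop("species quantities must be nonnegative", call. = FALSE)
  }
  drift <- abs(sum(pool$species) - pool$total)
  lim <- if (pool$mode == "ideal") tol * max(1, pool$total) else 0.5
  if (drift > lim) {
    stop("species do not sum to the pool total (conservation violated)",
         call. = FALSE)
  }
  invisible(pool)
}

# transitions for gaining a nick at one site: which species feed which
site_transition <- function(site) {
  switch(site,
    A = list(from = c("unnicked", "nickB"), to = c("nickA", "both")),
    B = list(from = c("unnicked", "nickA"), to = c("nickB", "both")),
    stop(sprintf("unknown nick site label '%s'", site), call. = FALSE)
  )
}

check_fraction <- function(x, what = "fraction") {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  x
}

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

apply_nick <- function(pool, site, frac, seed = NULL) {
  tr <- site_transition(site)
  sp <- pool$species
  if (pool$mode == "ideal") {
    moved <- frac * sp[tr$from]
  } else {
    moved <- with_seed_opt(seed, {
      vapply(sp[tr$from], function(n) stats::rbinom(1L, as.integer(n), frac),
             numeric(1))
    })
    if (is.null(seed)) {
      # deterministic expected counts: half away from zero, repair the
      # largest moved class so totals are conserved
      moved <- round_half_away(frac * sp[tr$from])
      moved <- pmin(moved, sp[tr$from])
    } else {
      pool$seed_lineage <- c(pool$seed_lineage, as.integer(seed))
    }
  }
  sp[tr$from] <- sp[tr$from] - moved
  sp[tr$to] <- sp[tr$to] + moved
  pool$species <- sp
  validate_pool(pool)
}

#' Round half away from zero, preserving a vector's (rounded) total
#'
#' Deterministic count rounding used by sampled-mode operations that are not
#' stochastic: each entry is rounded half away from zero and the largest entry
#' is then adjusted so the rounded vector sums to the rounded input total.
#' Conservation of molecule counts outranks rounding symmetry.
#'
#' @param x Numeric vector of nonnegative quantities.
#' @return Integer-valued numeric vector with `sum(out) == round(sum(x))`.
#' @export
round_half_away <- function(x) {
  r <- sign(x) * floor(abs(x) + 0.5)
  target <- sign(sum(x)) * floor(abs(sum(x)) + 0.5)
  if (length(x) && sum(r) != target) {
    i <- which.max(r)
    r[i] <- r[i] + (target - sum(r))
  }
  r
}

#' Encode a fraction by split-and-nick
#'
#' Encodes value `a` at a nick site by the volume-split preparation: the pool
#' is conceptually split in ratio `a : 1 - a`, every molecule in the first
#' part is nicked at `site`, and the parts are remixed. In ideal mode exactly
#' fraction `a` of the material not yet nicked at `site` gains the nick; in
#' sampled mode each molecule gains it independently with probability `a`
#' (Bernoulli, seeded). Nick states at the other site are untouched, so after
#' encoding both sites the four species follow the independent-nicking joint
#' distribution and the both-nicked fraction is the product of the two values.
#'
#' @param pool A [molecule_pool()].
#' @param site Site label, `"A"` or `"B"`.
#' @param a Value to encode, in \[0, 1\].
#' @param seed Optional integer seed for the sampled-mode Bernoulli draws.
#'   When `NULL` in sampled mode, deterministic expected counts are used
#'   (rounded by [round_half_away()]).
#' @return The updated `molecule_pool`.
#' @export
encode_by_split <- function(pool, site, a, seed = NULL) {
  stopifnot(inherits(pool, "molecule_pool"))
  check_fraction(a, "encoded value `a`")
  tr <- site_transition(site)
  already <- sum(pool$species[tr$to])
  if (already > 0) {
    stop(sprintf("site '%s' already carries nicks; encode each value on a fresh site",
                 site), call. = FALSE)
  }
  apply_nick(pool, site, a, seed)
}

#' Enzyme doses and the 1/k dosing rule
#'
#' An enzyme dose is a count `E` of nicking enzymes targeting one site, each
#' given enough reaction time to nick `turnover = k` molecules. The implied
#' nicked fraction on a pool of `t` molecules is `b = E * k / t`, the inverse
#' of the dosing rule `E = b * t * (1/k)` used when one weight droplet is
#' distributed over the k microcells of an array row.
#'
#' @param count Nonnegative enzyme count (or concentration units) `E`.
#' @param target_site Site label the enzyme nicks (default `"B"`).
#' @param turnover Integer `k >= 1`, molecules each enzyme may nick.
#' @return An object of class `enzyme_dose`.
#' @examples
#' dose_for_fraction(0.5, total = 1000, turnover = 10) # E = 50
#' @export
enzyme_dose <- function(count, target_site = "B", turnover = 1L) {
  if (!is.numeric(count) || length(count) != 1L || is.na(count) || count < 0) {
    stop("enzyme `count` must be a single nonnegative number", call. = FALSE)
  }
  if (turnover < 1 || turnover != round(turnover)) {
    stop("`turnover` must be a positive integer", call. = FALSE)
  }
  structure(
    list(count = count, target_site = target_site,
         turnover = as.integer(turnover), clipped = FALSE),
    class = "enzyme_dose"
  )
}

#' @export
print.enzyme_dose <- function(x, ...) {
  cat(sprintf("<enzyme_dose: E = %g at site %s, turnover k = %d%s>\n",
              x$count, x$target_site, x$turnover,
              if (isTRUE(x$clipped)) ", clipped" else ""))
  invisible(x)
}

#' @rdname enzyme_dose
#' @param b Nicked fraction the dose should produce on a pool of `total`
#'   molecules.
#' @param total Pool total the dose is destined for.
#' @export
dose_for_fraction <- function(b, total, turnover = 1L, target_site = "B") {
  check_fraction(b, "target fraction `b`")
  enzyme_dose(b * total / turnover, target_site = target_site,
              turnover = turnover)
}

implied_fraction <- function(dose, total) {
  dose$count * dose$turnover / total
}

#' Nick a pool with a dosed enzyme droplet
#'
#' Applies an enzyme dose to a pool. With sufficient reaction time the
#' fraction `b = E * k / t` of molecules not yet nicked at the target site
#' gains a nick there (exact in ideal mode; Bernoulli per molecule in sampled
#' mode). Kinetic sub-models of partial reactions are out of scope, so
#' `reaction_time_sufficient = FALSE` is an error rather than a partial nick.
#'
#' @inheritParams encode_by_split
#' @param dose An [enzyme_dose()].
#' @param reaction_time_sufficient Must be `TRUE`; the endpoint model assumes
#'   each enzyme has had time to nick its `turnover` molecules.
#' @return The updated `molecule_pool`.
#' @export
nick_with_enzyme <- function(pool, dose, reaction_time_sufficient = TRUE,
                             seed = NULL) {
  stopifnot(inherits(pool, "molecule_pool"), inherits(dose, "enzyme_dose"))
  if (!isTRUE(reaction_time_sufficient)) {
    stop("insufficient reaction time: nicking kinetics are not modelled; ",
         "allow the reaction to complete", call. = FALSE)
  }
  b <- implied_fraction(dose, pool$total)
  if (b > 1 + 1e-9) {
    stop(sprintf(
      "enzyme overdose: dose implies nicked fraction %.4g > 1 (E = %g, k = %d, t = %g)",
      b, dose$count, dose$turnover, pool$total), call. = FALSE)
  }
  b <- min(b, 1)
  if (b == 0) return(pool)
  apply_nick(pool, dose$target_site, b, seed)
}

#' Joint species distribution of two independent nick fractions
#'
#' Closed form for the four molecule species after independently encoding `a`
#' at site A and `b` at site B: `((1-a)(1-b), a(1-b), (1-a)b, ab)`. The
#' both-nicked entry is the product of the encoded values, which is what makes
#' double nicking a multiplier.
#'
#' @param a,b Fractions in \[0, 1\] (vectorised, recycled).
#' @return A tibble with columns `a`, `b`, `unnicked`, `nickA`, `nickB`,
#'   `both`; rows sum to 1 across the four species columns.
#' @examples
#' species_distribution(0.5, 0.5)
#' @export
species_distribution <- function(a, b) {
  check_fraction(a, "`a`")
  check_fraction(b, "`b`")
  tibble::tibble(
    a = a, b = b,
    unnicked = (1 - a) * (1 - b),
    nickA = a * (1 - b),
    nickB = (1 - a) * b,
    both = a * b
  )
}

#' Measure a species fraction in a pool
#'
#' The readout primitive: the ratio of a species quantity to the overall pool
#' total. After encoding `a` and `b` on the two sites, `measure(pool, "both")`
#' is the stored product (exactly `a * b` in ideal mode).
#'
#' @param pool A [molecule_pool()].
#' @param species One of `"both"`, `"nickA"`, `"nickB"`, `"unnicked"`.
#' @return A single numeric fraction.
#' @export
measure <- function(pool, species = c("both", "nickA", "nickB", "unnicked")) {
  stopifnot(inherits(pool, "molecule_pool"))
  species <- match.arg(species)
  if (pool$total <= 0) stop("cannot measure an empty pool", call. = FALSE)
  unname(pool$species[[species]] / pool$total)
}

#' Tidy view of a pool's species
#'
#' @param pool A [molecule_pool()].
#' @return A tibble with one row per species: `species`, `quantity`,
#'   `fraction`.
#' @export
measure_all <- function(pool) {
  stopifnot(inherits(pool, "molecule_pool"))
  tibble::tibble(
    species = names(pool$species),
    quantity = unname(pool$species),
    fraction = unname(pool$species) / pool$total
  )
}

#' Serialise / restore a pool as a structured text record
#'
#' @param pool A [molecule_pool()].
#' @param path Optional file path; when given the JSON is written there.
#' @return `pool_to_json()`: a JSON string (invisibly, when `path` is given);
#'   `pool_from_json()`: a `molecule_pool`.
#' @export
pool_to_json <- function(pool, path = NULL) {
  stopifnot(inherits(pool, "molecule_pool"))
  rec <- list(
    species = as.list(pool$species),
    total = pool$total,
    mode = pool$mode,
    seed_lineage = pool$seed_lineage,
    template = list(
      domain_lengths = pool$template$domain_lengths,
      pair_distance = pool$template$pair_distance,
      bead_attached = pool$template$bead_attached,
      nick_sites = lapply(pool$template$nick_sites, function(s) {
        list(label = s$label, position = s$position, strand = s$strand)
      })
    )
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname pool_to_json
#' @param json A JSON string or a path to a JSON file produced by
#'   [pool_to_json()].
#' @export
pool_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  rec <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  sites <- lapply(seq_len(nrow(rec$template$nick_sites)), function(i) {
    s <- rec$template$nick_sites[i, ]
    nick_site(s$label, s$position, s$strand)
  })
  tmpl <- template_design(domain_lengths = rec$template$domain_lengths,
                          nick_sites = sites,
                          bead_attached = rec$template$bead_attached)
  pool <- molecule_pool(total = rec$total, mode = rec$mode, template = tmpl)
  pool$species[] <- unlist(rec$species)[names(pool$species)]
  pool$seed_lineage <- as.integer(rec$seed_lineage)
  validate_pool(pool)
}
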