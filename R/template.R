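#' Nick sites and template molecule layout
#'
#' A template molecule carries a leading (unnamed) domain followed by domains
#' 0 to 4, with a magnetic bead on the leading end and two designated nicking
#' sites on the bottom strand: site A between the leading domain and domain 0,
#' site B between domains 0 and 1. The short region between the two nicks is
#' the fragment that denatures into a toehold during readout, so the two sites
#' must sit within `max_toehold_gap` base pairs of each other (around 18 bp).
#'
#' @param label Short site identifier, e.g. `"A"`.
#' @param position Integer 0-based base-pair offset on the template.
#' @param strand `"top"` or `"bottom"` (the nicked strand).
#' @return `nick_site()`: an object of class `nick_site`.
#' @export
nick_site <- function(label, position, strand = c("bottom", "top")) {
  strand <- match.arg(strand)
  if (position < 0 || position != round(position)) {
    stop("`position` must be a nonnegative integer", call. = FALSE)
  }
  structure(list(label = label, position = as.integer(position),
                 strand = strand), class = "nick_site")
}

#' @rdname nick_site
#' @param domain_lengths Integer bp lengths of the leading domain followed by
#'   domains 0..4 (six entries).
#' @param nick_sites List of exactly two [nick_site()]s designated for value
#'   storage; labels must be unique.
#' @param bead_attached Whether the template carries a magnetic bead for
#'   pull-down separation.
#' @param max_toehold_gap Maximum bp between the two nicks for the fragment to
#'   denature into a toehold (default 18).
#' @return `template_design()`: an object of class `template_design` with the
#'   computed `pair_distance`.
#' @export
template_design <- function(domain_lengths = c(20L, 8L, 20L, 20L, 20L, 20L),
                            nick_sites = NULL,
                            bead_attached = TRUE,
                            max_toehold_gap = 18L) {
  if (length(domain_lengths) != 6L || any(domain_lengths < 1)) {
    stop("`domain_lengths` must give six positive lengths: leading domain then domains 0..4",
         call. = FALSE)
  }
  domain_lengths <- as.integer(domain_lengths)
  if (is.null(nick_sites)) {
    # A after the leading domain, B after domain 0
    nick_sites <- list(
      nick_site("A", domain_lengths[1L]),
      nick_site("B", domain_lengths[1L] + domain_lengths[2L])
    )
  }
  if (length(nick_sites) != 2L) {
    stop("exactly two nick sites must be designated for value storage",
         call. = FALSE)
  }
  labels <- vapply(nick_sites, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("nick-site labels must be unique within a template", call. = FALSE)
  }
  pair_distance <- abs(nick_sites[[2L]]$position - nick_sites[[1L]]$position)
  structure(
    list(domain_lengths = domain_lengths, nick_sites = nick_sites,
         bead_attached = bead_attached, pair_distance = pair_distance,
         max_toehold_gap = as.integer(max_toehold_gap)),
    class = "template_design"
  )
}

#' @rdname nick_site
#' @export
default_template <- function() template_design()

#' @export
print.template_design <- function(x, ...) {
  cat(sprintf(
    "<template_design: %d bp, nick pair distance %d bp (max toehold gap %d), bead %s>\n",
    sum(x$domain_lengths), x$pair_distance, x$max_toehold_gap,
    if (x$bead_attached) "attached" else "absent"))
  invisible(x)
}

random_domain <- function(len, gc_range) {
  repeat {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    gc <- mean(s %in% c("G", "C"))
    if (gc >= gc_range[1] && gc <= gc_range[2]) return(s)
  }
}

hamming_frac <- function(a, b) {
  n <- min(length(a), length(b))
  mean(a[seq_len(n)] != b[seq_len(n)])
}

#' Generate a placeholder template sequence with orthogonal domains
#'
#' Draws a seeded random nucleotide sequence for each domain of a template,
#' constrained to GC fraction in `gc_range` and pairwise Hamming distance (over
#' the shared prefix) of at least `min_hamming` of the shorter domain length,
#' as a stand-in for properly designed orthogonal domains. This is synthesis
#' plumbing for export, not a thermodynamic design tool.
#'
#' @param design A [template_design()].
#' @param seed Integer seed.
#' @param gc_range Allowed GC fraction range (default `c(0.4, 0.6)`).
#' @param min_hamming Minimum pairwise Hamming distance as a fraction of the
#'   compared length (default 0.4).
#' @param max_tries Rejection-sampling cap per domain.
#' @return A list with `domains` (character vector of domain sequences, named
#'   `leading`, `d0`..`d4`) and `sequence` (their concatenation).
#' @export
generate_template_sequence <- function(design = default_template(), seed = 1L,
                                       gc_range = c(0.4, 0.6),
                                       min_hamming = 0.4,
                                       max_tries = 10000L) {
  withr::with_seed(as.integer(seed), {
    lens <- design$domain_lengths
    accepted <- list()
    for (i in seq_along(lens)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- random_domain(lens[i], gc_range)
        if (all(vapply(accepted, function(p) hamming_frac(p, cand) >= min_hamming,
                       logical(1)))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not generate mutually orthogonal domains", call. = FALSE)
      accepted[[i]] <- cand
    }
    domains <- vapply(accepted, paste0, character(1), collapse = "")
    names(domains) <- c("leading", paste0("d", 0:4))
    list(domains = domains, sequence = paste0(domains, collapse = ""))
  })
}

#' Export a template sequence as FASTA and its nick sites as BED
#'
#' `write_template_fasta()` writes the generated template sequence via
#' Biostrings. `write_nick_sites_bed()` writes each nick site as a 1-bp BED
#' feature at the 0-based nick position, with the BED strand column taken from
#' the nicked strand.
#'
#' @param seq_record Result of [generate_template_sequence()].
#' @param path Output file path.
#' @param name Sequence name used in the FASTA header / BED chrom column.
#' @return The path, invisibly.
#' @export
write_template_fasta <- function(seq_record, path, name = "template") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA export", call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(seq_record$sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_template_fasta
#' @param design A [template_design()].
#' @export
write_nick_sites_bed <- function(design, path, name = "template") {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GenomicRanges and rtracklayer are required for BED export",
         call. = FALSE)
  }
  pos <- vapply(design$nick_sites, `[[`, integer(1), "position")
  strands <- vapply(design$nick_sites, `[[`, character(1), "strand")
  labels <- vapply(design$nick_sites, `[[`, character(1), "label")
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L),
    strand = ifelse(strands == "top", "+", "-")
  )
  names(gr) <- labels
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
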