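#' Generate a seeded random nonnegative MLP fixture
#'
#' Draws weight matrices with entries uniform on \[0, 1\] for a network of
#' the given layer dimensions. Reproducible: the same `dims` and `seed` give
#' identical matrices (and byte-for-byte identical CSV files when `dir` is
#' supplied).
#'
#' @param dims Integer vector of layer widths, length >= 2 (e.g.
#'   `c(784, 784, 10)` gives two weight matrices, 784 x 784 and 10 x 784).
#' @param seed Integer seed.
#' @param dir Optional directory; when given, one CSV per weight matrix
#'   (`weights_1.csv`, ...) is written there (header row, row-major: rows are
#'   neurons).
#' @return A list of weight matrices, invisibly carrying `paths` as an
#'   attribute when files were written.
#' @export
generate_fixture_mlp <- function(dims, seed = 1L, dir = NULL) {
  if (length(dims) < 2L || any(dims < 1) || any(dims != round(dims))) {
    stop("`dims` must give at least two positive integer layer widths",
         call. = FALSE)
  }
  dims <- as.integer(dims)
  mats <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(length(dims) - 1L), function(i) {
      matrix(stats::runif(dims[i + 1L] * dims[i]), nrow = dims[i + 1L],
             ncol = dims[i])
    })
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(seq_along(mats), function(i) {
      p <- file.path(dir, sprintf("weights_%d.csv", i))
      write_weights_csv(mats[[i]], p)
      p
    }, character(1))
    attr(mats, "paths") <- paths
  }
  mats
}

#' Read and write weight/input matrices as CSV
#'
#' Matrices are stored row-major with a header row (`x1`, `x2`, ...); for
#' weight matrices rows are neurons and columns inputs, for input files rows
#' are samples.
#'
#' @param m A numeric matrix.
#' @param path File path.
#' @return `write_weights_csv()`: the path invisibly;
#'   `read_weights_csv()`: a numeric matrix.
#' @export
write_weights_csv <- function(m, path) {
  m <- as.matrix(m)
  colnames(m) <- paste0("x", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: file '%s' does not exist", path),
         call. = FALSE)
  }
  as.matrix(utils::read.csv(path, header = TRUE))
}

toy_strokes <- function() {
  # simple 28 x 28 stroke painters, each returning a binary matrix
  list(
    vbar = function(offset) {
      m <- matrix(0, 28, 28)
      m[, pmin(pmax(13 + offset, 2), 26) + (-1:1)] <- 1
      m
    },
    hbar = function(offset) {
      m <- matrix(0, 28, 28)
      m[pmin(pmax(13 + offset, 2), 26) + (-1:1), ] <- 1
      m
    },
    cross = function(offset) {
      m <- matrix(0, 28, 28)
      c0 <- pmin(pmax(13 + offset, 2), 26)
      m[c0 + (-1:1), ] <- 1
      m[, c0 + (-1:1)] <- 1
      m
    },
    box = function(offset) {
      m <- matrix(0, 28, 28)
      lo <- pmax(5 + offset, 2)
      hi <- pmin(23 + offset, 27)
      m[lo:hi, c(lo, hi)] <- 1
      m[c(lo, hi), lo:hi] <- 1
      m
    },
    diag = function(offset) {
      m <- matrix(0, 28, 28)
      for (i in 1:28) {
        j <- pmin(pmax(i + offset, 1), 28)
        m[i, j] <- 1
        if (j < 28) m[i, j + 1] <- 1
      }
      m
    }
  )
}

#' Generate toy 28 x 28 digit-like binary patterns
#'
#' Seeded synthetic stand-in for handwritten-digit frames: binary 784-vectors
#' painting simple strokes (vertical bar, horizontal bar, cross, box,
#' diagonal) with a small random positional jitter. These emulate the shape
#' and sparsity of 28 x 28 digit frames for end-to-end engine tests; they are
#' not real handwriting.
#'
#' @param n Number of patterns (>= 1).
#' @param seed Integer seed.
#' @param path Optional CSV output path for the n x 784 matrix.
#' @return A list with `x` (n x 784 matrix of 0/1), `label` (integer stroke
#'   class, 1..5) and `class_names`.
#' @export
generate_toy_digits <- function(n, seed = 1L, path = NULL) {
  stopifnot(n >= 1)
  strokes <- toy_strokes()
  res <- withr::with_seed(as.integer(seed), {
    label <- sample(seq_along(strokes), n, replace = TRUE)
    offset <- sample(-3:3, n, replace = TRUE)
    x <- t(vapply(seq_len(n), function(i) {
      as.numeric(strokes[[label[i]]](offset[i]))
    }, numeric(784)))
    list(x = x, label = label)
  })
  res$class_names <- names(strokes)
  if (!is.null(path)) write_weights_csv(res$x, path)
  res
}

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON (by extension) with fields: `mode`
#' (`ideal`/`sampled`), `t` (molecules per droplet), `seed`, `k_physical`,
#' `activation` (`threshold`, `replenishment_cap`), optional `timing`
#' (`t_transport`, ... overrides) and `weights`/`inputs`/`output` paths.
#' Missing optional fields take documented defaults; unknown fields, values
#' out of range, or missing referenced files are configuration errors.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: config file '%s' not found", path),
         call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("configuration error: config must be .yaml/.yml or .json", call. = FALSE)
  }
  validate_run_config(raw, dir = dirname(path))
}

#' @rdname read_run_config
#' @param raw A config list (as parsed from file).
#' @param dir Directory against which relative file paths are resolved.
#' @export
validate_run_config <- function(raw, dir = ".") {
  known <- c("mode", "t", "seed", "k_physical", "activation", "timing",
             "weights", "inputs", "output")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop(sprintf("configuration error: unknown field(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  cfg <- list(
    mode = raw$mode %||% "ideal",
    t = raw$t %||% 10000L,
    seed = raw$seed %||% 1L,
    k_physical = raw$k_physical %||% 16L,
    activation = seesaw_gate(
      threshold = raw$activation$threshold %||% 0.5,
      replenishment_cap = raw$activation$replenishment_cap %||% 1
    ),
    weights = raw$weights,
    inputs = raw$inputs,
    output = raw$output
  )
  if (!cfg$mode %in% c("ideal", "sampled")) {
    stop("configuration error: `mode` must be 'ideal' or 'sampled'", call. = FALSE)
  }
  if (cfg$t < 1 || cfg$k_physical < 1) {
    stop("configuration error: `t` and `k_physical` must be positive", call. = FALSE)
  }
  cfg$timing <- if (is.null(raw$timing)) default_timing() else {
    base <- default_timing()
    do.call(timing_params, utils::modifyList(
      list(t_transport = base$t_transport, t_mult = base$t_mult,
           t_merge = base$t_merge, t_gate = base$t_gate),
      raw$timing))
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    full <- if (file.exists(p)) p else file.path(dir, p)
    full
  }
  cfg$weights <- if (!is.null(cfg$weights)) {
    vapply(cfg$weights, resolve, character(1))
  }
  cfg$inputs <- resolve(cfg$inputs)
  for (f in c(cfg$weights, cfg$inputs)) {
    if (!is.null(f) && !file.exists(f)) {
      stop(sprintf("configuration error: referenced file '%s' does not exist", f),
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Run a simulation described by a config
#'
#' Glue over the engine: reads the weight and input CSVs, compiles the
#' network, runs every input row through [run_network()], and (optionally)
#' writes the outputs CSV next to a human-readable timing report.
#'
#' @param cfg A [read_run_config()] result.
#' @return A list with `outputs` (matrix, rows = input samples), `runs`
#'   (list of `engine_run`s) and `timing` (tibble of the first run).
#' @export
simulate_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$weights) || is.null(cfg$inputs)) {
    stop("configuration error: `weights` and `inputs` paths are required",
         call. = FALSE)
  }
  mats <- lapply(cfg$weights, read_weights_csv)
  net <- compile_network(mats, activation = cfg$activation)
  X <- read_weights_csv(cfg$inputs)
  array <- microcell_array(cfg$k_physical)
  runs <- lapply(seq_len(nrow(X)), function(i) {
    run_network(array, net, as.numeric(X[i, ]), mode = cfg$mode,
                t = cfg$t, seed = cfg$seed + i - 1L, timing = cfg$timing)
  })
  outputs <- t(vapply(runs, function(r) r$outputs$output,
                      numeric(nrow(net$layers[[length(net$layers)]]$weights))))
  if (!is.null(cfg$output)) write_weights_csv(outputs, cfg$output)
  list(outputs = outputs, runs = runs, timing = runs[[1]]$timing)
}

#' Read an IDX file of images or labels (optional harness)
#'
#' Minimal reader for the big-endian IDX format used to distribute standard
#' handwritten-digit corpora, for users who want to drive the engine with
#' their own externally trained data. Never required by the package's tests
#' or results: all shipped fixtures are synthetic.
#'
#' @param path Path to an uncompressed IDX file.
#' @return For 3-D image files, an `n x (rows*cols)` numeric matrix scaled to
#'   \[0, 1\]; for 1-D label files, an integer vector.
#' @export
read_idx <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: IDX file '%s' not found", path),
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  ndim <- magic %% 256L
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  data <- readBin(con, "integer", n = prod(dims), size = 1L, signed = FALSE)
  if (ndim == 1L) return(as.integer(data))
  if (ndim == 3L) {
    return(matrix(data, nrow = dims[1L], byrow = TRUE) / 255)
  }
  stop("unsupported IDX dimensionality", call. = FALSE)
}

#' Quick package self-test
#'
#' Runs a handful of core invariants (exact product encoding, gate algebra
#' identities, calibration round trip, protocol trace shape) and returns
#' `TRUE` if all hold. Used by the command-line `selftest` subcommand.
#'
#' @return `TRUE` invisibly; errors on any violated invariant.
#' @export
selftest <- function() {
  p <- encode_by_split(encode_by_split(molecule_pool(), "A", 0.9), "B", 0.8)
  stopifnot(isTRUE(all.equal(measure(p, "both"), 0.72)))
  stopifnot(gate_eval("NOT", 3 / 8) == 5 / 8,
            gate_eval("AND", 0.5, 0.5) == 0.25)
  fit <- calibrate_timing(reference_delay_points())
  stopifnot(abs(layer_delay(fit, 784, 196) - 14.17) < 1e-9)
  cyc <- microcell_cycle(
    microcell(), droplet(encode_by_split(molecule_pool(), "A", 0.5)),
    droplet(dose_for_fraction(0.5, 1), kind = "enzyme"))
  stopifnot(nrow(cyc$trace) == 6L,
            isTRUE(all.equal(measure(cyc$droplet$payload, "both"), 0.25)))
  invisible(TRUE)
}
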