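# Internal helpers: structured errors, seeded RNG streams, window statistics.

hilo_abort <- function(message, class) {
  stop(structure(
    class = c(paste0("hilosect_", class), "hilosect_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

hilo_warn <- function(message, class) {
  warning(structure(
    class = c(paste0("hilosect_", class), "hilosect_warning",
              "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    hilo_abort(sprintf("`%s` must be a numeric matrix", name), "data")
  if (!all(is.finite(x)))
    hilo_abort(sprintf("`%s` contains non-finite values", name), "data")
  invisible(x)
}

check_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    hilo_abort(sprintf("%s have mismatched dimensions (%s vs %s)",
                       what, paste(dim(a), collapse = "x"),
                       paste(dim(b), collapse = "x")), "shape")
  invisible(TRUE)
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' A single master seed drives every random stage (speckle realizations,
#' noise draws); each stage uses its own derived stream so stages stay
#' decorrelated but bit-reproducible. Values stay below 2^31 - 1.
#'
#' @param seed master seed (integer-valued).
#' @param stream non-negative integer identifying the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  m <- 2147483647
  s <- ((as.numeric(seed) %% m) * 48271 + as.numeric(stream) * 9349 + 1) %% m
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Symmetric (reflective) padding by `h` samples on every side.
reflect_pad <- function(x, h) {
  nr <- nrow(x); nc <- ncol(x)
  if (h >= nr || h >= nc)
    hilo_abort("padding exceeds image size", "configuration")
  ri <- c(h:1, seq_len(nr), nr:(nr - h + 1))
  ci <- c(h:1, seq_len(nc), nc:(nc - h + 1))
  x[ri, ci]
}

# Sliding-window mean over a w x w neighbourhood, reflective padding,
# output same size as input. Separable running mean via stats::filter.
box_mean <- function(x, w) {
  if (w %% 2 == 0) hilo_abort("window side must be odd", "parameter")
  if (w < 3) hilo_abort("window side must be >= 3", "parameter")
  if (w >= nrow(x) || w >= ncol(x))
    hilo_abort("window side too large for image", "configuration")
  h <- (w - 1L) / 2L
  p <- reflect_pad(x, h)
  k <- rep(1 / w, w)
  # filter() runs down each column; do rows by transposing.
  p <- stats::filter(p, k, sides = 2)
  p <- t(stats::filter(t(p), k, sides = 2))
  out <- p[(h + 1):(h + nrow(x)), (h + 1):(h + ncol(x)), drop = FALSE]
  matrix(as.numeric(out), nrow(x), ncol(x))
}
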