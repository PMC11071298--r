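#' Modimizer sketch of a window
#'
#' Sketches the hash values of one genomic interval by keeping the distinct
#' hashes divisible by the sparsity `s` (equivalently, those whose
#' `log2(s)` least-significant bits are zero). Sketching is performed on the
#' set of distinct k-mer hashes, not the multiset, and `NA` (invalid)
#' positions are dropped. With `s = 1` every distinct hash is kept.
#'
#' @param hashes Numeric vector of canonical k-mer hashes for one interval
#'   (a slice of a `hash_stream`; may contain `NA`).
#' @param s Sparsity: a positive power of two.
#' @param interval Optional `c(start, end)` position range, stored for
#'   provenance.
#' @return An object of class `mod_sketch`: list with `hashes` (sorted
#'   distinct modimizer values), `s` (effective sparsity), `distinct_count`
#'   (distinct valid k-mer hashes in the interval before sketching), and
#'   `interval`.
#' @examples
#' modimizer_sketch(c(0, 4, 5, 8, 8), s = 4)  # keeps {0, 4, 8}
#' @export
modimizer_sketch <- function(hashes, s, interval = NULL) {
  check_sparsity(s)
  distinct <- unique(hashes[!is.na(hashes)])
  keep <- if (s == 1) distinct else distinct[distinct %% s == 0]
  new_sketch(sort(keep), s, length(distinct), interval)
}

new_sketch <- function(hashes, s, distinct_count, interval = NULL) {
  structure(
    list(hashes = hashes, s = s, distinct_count = distinct_count,
         interval = interval),
    class = "mod_sketch"
  )
}

check_sparsity <- function(s) {
  if (length(s) != 1 || is.na(s) || s < 1 || log2(s) %% 1 != 0) {
    stop("sparsity must be a positive power of two, got ", s, call. = FALSE)
  }
  invisible(s)
}

#' @export
print.mod_sketch <- function(x, ...) {
  cat("<mod_sketch> ", length(x$hashes), " modimizers (s=", x$s,
      ", distinct k-mers=", x$distinct_count, ")\n", sep = "")
  invisible(x)
}

#' Modimizer sketch with adaptive sparsity
#'
#' Highly repetitive windows contain far fewer distinct k-mers than random
#' sequence, so a fixed sparsity can leave them with too few modimizers for a
#' reliable containment estimate. Starting from the nominal sparsity, this
#' sketch is recomputed at half the sparsity until it holds at least half the
#' target sketch size (`ceiling(m / 2)`) or the sparsity reaches one, at
#' which point every distinct k-mer in the window is included.
#'
#' @inheritParams modimizer_sketch
#' @param nominal_s Starting sparsity (positive power of two).
#' @param m Target sketch size (expected modimizers per window; >= 1).
#' @return A `mod_sketch` whose `s` records the final effective sparsity
#'   (never larger than `nominal_s`).
#' @export
adaptive_sketch <- function(hashes, nominal_s, m, interval = NULL) {
  check_sparsity(nominal_s)
  stopifnot(m >= 1)
  floor_size <- ceiling(m / 2)
  sk <- modimizer_sketch(hashes, nominal_s, interval)
  while (length(sk$hashes) < floor_size && sk$s > 1) {
    sk <- modimizer_sketch(hashes, sk$s / 2, interval)
  }
  sk
}

#' Re-filter a sketch at a coarser sparsity
#'
#' Applies the modimizer membership test at `s_new` (an integer multiple of
#' the sketch's own sparsity) to the stored hashes. By the hierarchical
#' subset property the result is exactly the sketch that direct computation
#' from the window at `s_new` would give, so two sketches with different
#' effective sparsities can be brought to a common sparsity before
#' [containment()].
#'
#' @param sketch A `mod_sketch`.
#' @param s_new Target sparsity (power of two, multiple of `sketch$s`).
#' @return A `mod_sketch` at sparsity `s_new`.
#' @export
refilter_sketch <- function(sketch, s_new) {
  check_sparsity(s_new)
  if (s_new == sketch$s) return(sketch)
  if (s_new %% sketch$s != 0) {
    stop("cannot refilter a sketch at s=", sketch$s, " to s=", s_new,
         " (not an integer multiple)", call. = FALSE)
  }
  new_sketch(sketch$hashes[sketch$hashes %% s_new == 0], s_new,
             sketch$distinct_count, sketch$interval)
}

#' Uniform random hash values
#'
#' Draws i.i.d. uniform 53-bit hash values, composed from two independent
#' uniform draws so that the low-order bits (the ones modimizer membership
#' examines) are themselves uniform. Used for calibration experiments and
#' tests of the expected sketch size `w / s`.
#'
#' @param n Number of values.
#' @return Numeric vector of `n` values uniform on `[0, 2^53)`.
#' @export
random_hashes <- function(n) {
  lo <- floor(runif(n) * 2^26)
  hi <- floor(runif(n) * 2^27)
  hi * 2^26 + lo
}
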