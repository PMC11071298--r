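#' Canonical k-mer hash stream of a sequence
#'
#' Decomposes a DNA sequence into its n - k + 1 constituent k-mers and hashes
#' each one together with its reverse complement, keeping the smaller of the
#' two values, so that a sequence and its reverse complement produce the same
#' multiset of hashes. Positions whose k-mer contains a non-ACGT character
#' (e.g. N) are flagged invalid and excluded from all downstream sketches.
#'
#' Hashing is a seeded MurmurHash3-style 64-bit finalizer applied to the
#' 2-bit-packed k-mer code, truncated to 53 bits so values are exactly
#' representable as R doubles. The method only requires a uniform hash; the
#' seed is a reproducibility knob and must match between any two sketches
#' that are to be compared.
#'
#' @param seq A DNA sequence: a single character string, or a one-row record
#'   tibble from [read_fasta()].
#' @param k K-mer length in bases (1--32); odd values give strand-unambiguous
#'   canonicalization. Default 21.
#' @param seed Integer hash seed (default 42).
#' @param name Optional sequence name (taken from a record tibble if given).
#' @return An object of class `hash_stream`: a list with `name`, `k`, `seed`,
#'   `n` (bases), `hashes` (numeric vector of length n - k + 1, `NA` at
#'   invalid positions).
#' @examples
#' hs <- canonical_hashes("ACGTACGTACGTACGTACGTACGTACGT", k = 21)
#' length(hs$hashes)
#' @export
canonical_hashes <- function(seq, k = 21, seed = 42, name = NULL) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    if (is.null(name)) name <- seq$name[[1]]
    seq <- seq$seq[[1]]
  }
  stopifnot(is.character(seq), length(seq) == 1)
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer", call. = FALSE)
  n <- nchar(seq)
  if (k > n) stop("k (", k, ") exceeds sequence length (", n, ")", call. = FALSE)
  structure(
    list(
      name = if (is.null(name)) "seq" else name,
      k = k,
      seed = as.integer(seed),
      n = n,
      hashes = .canonical_hashes_cpp(seq, k, as.double(seed))
    ),
    class = "hash_stream"
  )
}

#' @export
print.hash_stream <- function(x, ...) {
  cat("<hash_stream> ", x$name, ": ", length(x$hashes), " k-mer positions (k=",
      x$k, ", seed=", x$seed, ", ", sum(is.na(x$hashes)), " invalid)\n",
      sep = "")
  invisible(x)
}

#' Partition k-mer positions into fixed-size windows
#'
#' Tiles the k-mer start positions `[0, n - k + 1)` into consecutive
#' non-overlapping intervals of `w` positions. A trailing partial window is
#' retained as its own (shorter) interval; the number of intervals is the
#' plot resolution `r = ceiling((n - k + 1) / w)`.
#'
#' @param stream A `hash_stream`, or an integer number of k-mer positions.
#' @param w Window size in k-mer positions (>= 1).
#' @return A tibble with columns `start`, `end` (0-based half-open position
#'   ranges) and attributes `w` and `r`.
#' @examples
#' partition_windows(10, w = 4)  # [0,4) [4,8) [8,10)
#' @export
partition_windows <- function(stream, w) {
  npos <- if (inherits(stream, "hash_stream")) length(stream$hashes)
          else as.integer(stream)
  w <- as.integer(w)
  stopifnot(npos >= 1)
  if (is.na(w) || w < 1) stop("window size must be >= 1", call. = FALSE)
  if (w > npos) {
    warning("window size ", w, " exceeds the ", npos,
            " available k-mer positions; using a single window", call. = FALSE)
    w <- npos
  }
  starts <- seq(0L, npos - 1L, by = w)
  out <- tibble::tibble(start = starts, end = pmin(starts + w, npos))
  attr(out, "w") <- w
  attr(out, "r") <- nrow(out)
  out
}

#' Derive window size and sparsity from a target resolution
#'
#' Given a sequence length, a target heatmap resolution `r` and a target
#' sketch size `m`, computes the window size `w = ceiling((n - k + 1) / r)`
#' and the modimizer sparsity `s`, the largest power of two not exceeding
#' `w / m` (so the expected sketch size `w / s` is at least `m`). When
#' `w <= m` no downsampling is possible and `s = 1`.
#'
#' @param n Sequence length in bases.
#' @param r Target resolution (number of windows; >= 1).
#' @param m Target modimizer sketch size (>= 1). Default 1000.
#' @param k K-mer length (default 21).
#' @param round_up If `TRUE`, round the sparsity exponent up instead of down
#'   (expected sketch size at most `m` rather than at least `m`).
#' @return A list with elements `w` and `s`.
#' @examples
#' derive_parameters(4e6, r = 1000, m = 1000)
#' @export
derive_parameters <- function(n, r, m = 1000, k = 21, round_up = FALSE) {
  stopifnot(r >= 1, m >= 1, n >= k)
  npos <- n - k + 1
  w <- as.integer(ceiling(npos / r))
  list(w = w, s = sparsity_for(w, m, round_up = round_up))
}

# largest (or smallest, if round_up) power of two ~ w/m, floored at 1
sparsity_for <- function(w, m, round_up = FALSE) {
  if (w <= m) return(1)
  ex <- log2(w / m)
  2^(if (round_up) ceiling(ex) else floor(ex))
}
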