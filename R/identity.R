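#' Bias-corrected containment of one sketch in another
#'
#' Estimates the containment index of interval A in interval B — the
#' fraction of A's distinct k-mers found in B — from their modimizer
#' sketches. Because fractional minhash sampling is biased when the two sets
#' differ greatly in size, the expected sampling fraction
#' `1 - (1 - 1/s)^|A|` (with `|A|` the distinct k-mer count of A) enters the
#' denominator, giving an unbiased estimate that is finally clamped to
#' `[0, 1]`.
#'
#' Both sketches must be at the same effective sparsity; use
#' [refilter_sketch()] to bring the denser one up to the sparser one's
#' sparsity first (the hierarchical subset property makes this exact).
#'
#' @param sketch_a,sketch_b `mod_sketch` objects at a common sparsity.
#' @return An object of class `containment_estimate`: list with `value`
#'   (clamped to `[0, 1]`), `raw` (before clamping), `intersection_size`,
#'   `denominator_size` (`|MOD_s(A)|`), and `correction`.
#' @export
containment <- function(sketch_a, sketch_b) {
  stopifnot(inherits(sketch_a, "mod_sketch"), inherits(sketch_b, "mod_sketch"))
  if (sketch_a$s != sketch_b$s) {
    stop("sketches have different sparsities (", sketch_a$s, " vs ",
         sketch_b$s, "); refilter to a common sparsity first", call. = FALSE)
  }
  s <- sketch_a$s
  na <- length(sketch_a$hashes)
  if (na == 0) {
    warning("empty sketch for interval A; containment undefined, returning 0",
            call. = FALSE)
    return(structure(
      list(value = 0, raw = NA_real_, intersection_size = 0L,
           denominator_size = 0L, correction = NA_real_),
      class = "containment_estimate"
    ))
  }
  correction <- if (s == 1) 1 else 1 - (1 - 1 / s)^sketch_a$distinct_count
  inter <- sum(sketch_a$hashes %in% sketch_b$hashes)
  raw <- inter / (na * correction)
  structure(
    list(value = min(1, max(0, raw)), raw = raw, intersection_size = inter,
         denominator_size = na, correction = correction),
    class = "containment_estimate"
  )
}

#' @export
print.containment_estimate <- function(x, ...) {
  cat("<containment_estimate> ", format(x$value, digits = 6), " (",
      x$intersection_size, "/", x$denominator_size, ", correction=",
      format(x$correction, digits = 4), ")\n", sep = "")
  invisible(x)
}

# fast path used by the matrix loops: plain numeric in, numeric out
cont_value <- function(a_hashes, a_distinct, b_hashes, s) {
  na <- length(a_hashes)
  if (na == 0) return(NA_real_)
  correction <- if (s == 1) 1 else 1 - (1 - 1 / s)^a_distinct
  min(1, sum(a_hashes %in% b_hashes) / (na * correction))
}

#' Convert a containment index to percent identity
#'
#' Under a per-base binomial mutation model a k-mer survives mutation with
#' probability `(1 - p)^k`, so the containment index is inverted to an
#' average nucleotide identity estimate `ANI = 100 * c^(1/k)`; `c = 0` maps
#' to 0.
#'
#' @param c Containment index (or vector), each in `[0, 1]`, or a
#'   `containment_estimate`.
#' @param k K-mer length.
#' @return Percent identity in `{0} U (0, 100]`.
#' @examples
#' ani_from_containment(0.9, k = 21)
#' @export
ani_from_containment <- function(c, k) {
  if (inherits(c, "containment_estimate")) c <- c$value
  stopifnot(k >= 1, all(c >= 0 & c <= 1, na.rm = TRUE))
  out <- 100 * c^(1 / k)
  out[!is.na(c) & c == 0] <- 0
  out
}

#' Expand an interval symmetrically
#'
#' Window partitioning can split a repeat copy across two adjacent windows
#' ("out of register" with its partner copy), halving the apparent
#' containment. Expanding the second interval by half a window on each side
#' before sketching captures matches that straddle the boundary; since B
#' never appears in the containment denominator this cannot bias the
#' estimate downward.
#'
#' @param start,end 0-based half-open interval in k-mer positions.
#' @param w Window size the expansion is relative to.
#' @param factor Expansion factor: each side grows by `floor(factor * w / 2)`
#'   positions (default 1; 0 disables expansion).
#' @param bound Number of available positions (clamp limit).
#' @return `c(start', end')`, clamped to `[0, bound]`.
#' @examples
#' expand_interval(100, 200, w = 100, factor = 1, bound = 1000)  # [50, 250)
#' @export
expand_interval <- function(start, end, w, factor = 1, bound = Inf) {
  stopifnot(factor >= 0, end > start)
  pad <- floor(factor * w / 2)
  c(max(0, start - pad), min(bound, end + pad))
}

# Sketch of the expanded window j of `layer`, at that window's effective
# sparsity, materialized on demand from the retained hash stream.
expanded_sketch <- function(index, layer, j, factor) {
  a <- layer$windows$start[j]
  b <- layer$windows$end[j]
  if (factor == 0) return(layer$sketches[[j]])
  ex <- expand_interval(a, b, layer$window_size, factor,
                        bound = length(index$stream$hashes))
  modimizer_sketch(stream_slice(index$stream, ex[1], ex[2]),
                   layer$sketches[[j]]$s, interval = ex)
}

#' Directional identity of one matrix cell
#'
#' Computes `ANI_c(A, B')`: the containment of window `i`'s sketch in the
#' sketch of window `j` expanded by `expansion` half-windows each side,
#' converted to percent identity. The two sketches are brought to their
#' common (coarser) effective sparsity before intersecting.
#'
#' @param index A `mod_index` (the A side).
#' @param i,j 1-based window indices at `level`.
#' @param level Hierarchy level (default 0).
#' @param expansion Expansion factor for B (default 1).
#' @param index_b Optional second `mod_index` supplying window `j`
#'   (comparative case); defaults to `index`.
#' @return Percent identity (scalar).
#' @export
cell_identity <- function(index, i, j, level = 0, expansion = 1,
                          index_b = NULL) {
  if (is.null(index_b)) index_b <- index
  la <- get_layer(index, level)
  lb <- get_layer(index_b, level)
  ska <- la$sketches[[i]]
  skb <- expanded_sketch(index_b, lb, j, expansion)
  s <- max(ska$s, skb$s)
  c_ab <- cont_value(refilter_sketch(ska, s)$hashes, ska$distinct_count,
                     refilter_sketch(skb, s)$hashes, s)
  if (is.na(c_ab)) return(0)
  ani_from_containment(c_ab, index$k)
}
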