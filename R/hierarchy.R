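#' Number of layers of a hierarchical modimizer index
#'
#' The hierarchy stacks sketch layers with window sizes `w, 2w, 4w, ...`
#' (and sparsities doubling in step) until the next doubling would drop the
#' plot resolution below `r_min`: the layer count is the largest `l` such
#' that `2^(l-1) * w_hat <= n / r_min`, and at least 1.
#'
#' @param n Sequence length in bases.
#' @param w_hat Minimum (finest) window size in k-mer positions.
#' @param r_min Minimum resolution (default 1000).
#' @return Integer layer count.
#' @examples
#' layer_count(250e6, w_hat = 10000, r_min = 1000)  # 5
#' @export
layer_count <- function(n, w_hat, r_min = 1000) {
  stopifnot(n >= 1, w_hat >= 1, r_min >= 1)
  l <- floor(log2(n / r_min / w_hat)) + 1
  max(1L, as.integer(l))
}

# hashes of the k-mer position range [start, end), 0-based half-open
stream_slice <- function(stream, start, end) {
  stream$hashes[(start + 1L):end]
}

#' Build a hierarchical modimizer index for one sequence
#'
#' Level 0 partitions the k-mer positions into `w_hat`-sized windows and
#' sketches each with [adaptive_sketch()] at the base sparsity
#' `s_hat = 2^floor(log2(w_hat / m_hat))`. Each coarser level merges adjacent
#' window pairs: because modimizer sets at sparsity `2s` are subsets of those
#' at sparsity `s`, the parent sketch is sampled from the union of its two
#' children by the membership test alone, never rescanning the sequence
#' (unless the parent window itself triggers an adaptive sparsity
#' reduction). Levels are added while the window size stays within
#' `n / r_min` (see [layer_count()]).
#'
#' @param seq A DNA sequence string, a one-row record tibble, or a
#'   `hash_stream` from [canonical_hashes()].
#' @param k K-mer length (default 21); ignored when `seq` is a `hash_stream`.
#' @param w_hat Minimum window size in k-mer positions. Default `NULL`:
#'   derived from `resolution` so that level 0 has about `resolution`
#'   windows (a single-layer index; pass a smaller `w_hat` to enable zoom).
#' @param m_hat Target sketch size per window (default 1000).
#' @param r_min Minimum resolution for the coarsest layer (default 1000).
#' @param resolution Target resolution used to derive `w_hat` when it is not
#'   given (default 1000).
#' @param seed Hash seed (default 42); ignored when `seq` is a `hash_stream`.
#' @param name Sequence name override.
#' @param max_layers Optional cap on the number of layers (e.g. 1 for a
#'   flat, static-mode index).
#' @return An object of class `mod_index`: list with `name`, `n`, `k`,
#'   `seed`, `m_hat`, `w_hat`, `s_hat`, the retained hash `stream`, and
#'   `layers` (level 0 = finest). Each layer holds the window table, one
#'   `mod_sketch` per window, and the per-window effective sparsities.
#' @export
build_index <- function(seq, k = 21, w_hat = NULL, m_hat = 1000, r_min = 1000,
                        resolution = 1000, seed = 42, name = NULL,
                        max_layers = NULL) {
  stream <- if (inherits(seq, "hash_stream")) seq
            else canonical_hashes(seq, k = k, seed = seed, name = name)
  npos <- length(stream$hashes)
  if (is.null(w_hat)) {
    w_hat <- as.integer(ceiling(npos / resolution))
  }
  w_hat <- as.integer(w_hat)
  stopifnot(w_hat >= 1, m_hat >= 1)
  if (w_hat > npos) {
    warning("minimum window size exceeds available positions; clamped",
            call. = FALSE)
    w_hat <- npos
  }
  s_hat <- sparsity_for(w_hat, m_hat)
  nl <- layer_count(stream$n, w_hat, r_min)
  if (!is.null(max_layers)) nl <- min(nl, as.integer(max_layers))
  if (2 * w_hat > npos && nl > 1) {
    warning("sequence shorter than two base windows; single-layer index",
            call. = FALSE)
    nl <- 1L
  }

  layers <- vector("list", nl)
  layers[[1]] <- build_base_layer(stream, w_hat, s_hat, m_hat)
  for (lev in seq_len(nl - 1)) {
    layers[[lev + 1]] <- merge_layer(stream, layers[[lev]], m_hat)
  }

  structure(
    list(name = stream$name, n = stream$n, k = stream$k, seed = stream$seed,
         m_hat = m_hat, w_hat = w_hat, s_hat = s_hat, r_min = r_min,
         stream = stream, layers = layers),
    class = "mod_index"
  )
}

build_base_layer <- function(stream, w, s, m) {
  windows <- partition_windows(stream, w)
  sketches <- purrr::map2(windows$start, windows$end, function(a, b) {
    adaptive_sketch(stream_slice(stream, a, b), s, m, interval = c(a, b))
  })
  new_layer(0L, w, s, windows, sketches)
}

new_layer <- function(level, window_size, sparsity, windows, sketches) {
  list(level = level, window_size = window_size, sparsity = sparsity,
       windows = windows, sketches = sketches,
       eff_s = vapply(sketches, `[[`, numeric(1), "s"),
       r = nrow(windows))
}

# Merge adjacent window pairs of `layer` into the next coarser layer.
# The parent sketch is the union of its children filtered at the doubled
# sparsity; distinct counts still require one pass over the parent slice.
# If the filtered union is undersized the parent falls back to an adaptive
# rescan of its own slice at progressively halved sparsity.
merge_layer <- function(stream, layer, m) {
  npos <- length(stream$hashes)
  w2 <- layer$window_size * 2L
  s2 <- layer$sparsity * 2
  starts <- layer$windows$start[seq(1L, layer$r, by = 2L)]
  ends <- pmin(starts + w2, npos)
  floor_size <- ceiling(m / 2)

  sketches <- purrr::map2(seq_along(starts), ends, function(i, b) {
    a <- starts[i]
    kids <- layer$sketches[c(2L * i - 1L, min(2L * i, layer$r))]
    pooled <- unique(unlist(lapply(kids, `[[`, "hashes")))
    slice <- stream_slice(stream, a, b)
    distinct <- length(unique(slice[!is.na(slice)]))
    sk <- new_sketch(sort(pooled[pooled %% s2 == 0]), s2, distinct, c(a, b))
    while (length(sk$hashes) < floor_size && sk$s > 1) {
      sk <- modimizer_sketch(slice, sk$s / 2, interval = c(a, b))
    }
    sk
  })
  windows <- tibble::tibble(start = starts, end = ends)
  attr(windows, "w") <- w2
  attr(windows, "r") <- nrow(windows)
  new_layer(layer$level + 1L, w2, s2, windows, sketches)
}

#' @export
print.mod_index <- function(x, ...) {
  cat("<mod_index> ", x$name, ": ", x$n, " bp, k=", x$k, ", m=", x$m_hat,
      ", seed=", x$seed, "\n", sep = "")
  for (ly in x$layers) {
    cat("  level ", ly$level, ": w=", ly$window_size, ", s=", ly$sparsity,
        ", r=", ly$r, "\n", sep = "")
  }
  invisible(x)
}

#' Select the hierarchy layer for a viewport
#'
#' Picks the coarsest level whose window count across the viewport is at
#' least the number of display cells (so each rendered cell maps to at least
#' one matrix cell), falling back to the finest level when even it cannot
#' supply that many windows.
#'
#' @param index A `mod_index`.
#' @param viewport_bases Genomic span of the viewport in bases.
#' @param display_cells Number of cells (pixels) across the display.
#' @return Integer level (0 = finest).
#' @export
select_layer <- function(index, viewport_bases, display_cells) {
  stopifnot(viewport_bases >= 1, display_cells >= 1)
  for (lev in rev(seq_along(index$layers)) - 1L) {
    w <- index$layers[[lev + 1L]]$window_size
    if (viewport_bases / w >= display_cells) return(lev)
  }
  0L
}

#' Save / load a hierarchical index
#'
#' Lossless round-trip of a `mod_index` (all layers, the retained hash
#' stream and the build parameters) so that repeated zoom queries need not
#' rebuild it. Loading validates the container; downstream comparisons
#' still verify k / seed / sketch-size compatibility.
#'
#' @param index A `mod_index`.
#' @param path File path.
#' @return `save_index()`: `path`, invisibly. `load_index()`: the
#'   `mod_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "mod_index"))
  saveRDS(list(format = "anidot_mod_index", version = 1L, index = index),
          path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read index file '", path, "' (corrupt or truncated): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "anidot_mod_index") ||
      !inherits(obj$index, "mod_index")) {
    stop("'", path, "' is not an anidot index file", call. = FALSE)
  }
  obj$index
}

get_layer <- function(index, level) {
  if (level < 0 || level >= length(index$layers)) {
    stop("index has no level ", level, " (levels 0..",
         length(index$layers) - 1, ")", call. = FALSE)
  }
  index$layers[[level + 1L]]
}
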