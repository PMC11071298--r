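new_identity_matrix <- function(values, x_name, y_name, x_windows, y_windows,
                                window_size, self_plot, t, params,
                                x_offset = 0, y_offset = 0) {
  structure(
    list(values = values, x_name = x_name, y_name = y_name,
         x_windows = x_windows, y_windows = y_windows,
         window_size = window_size, x_offset = x_offset, y_offset = y_offset,
         self_plot = self_plot, t = t, params = params),
    class = "identity_matrix"
  )
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("<identity_matrix> ", x$x_name, if (!x$self_plot) paste0(" vs ", x$y_name),
      ": ", nrow(x$values), "x", ncol(x$values), " cells, window ",
      x$window_size, ", t=", x$t, "\n", sep = "")
  nz <- x$values[x$values > 0]
  if (length(nz)) {
    cat("  identity range of colored cells: ",
        paste(format(range(nz), digits = 4), collapse = " - "), "\n", sep = "")
  }
  invisible(x)
}

# Shared engine for self-, comparative and viewport matrices.
# rows/cols are 1-based window indices into the two layers.
compute_grid <- function(index_x, index_y, level, rows, cols, t, expansion,
                         direction = "max", symmetric = FALSE) {
  lx <- get_layer(index_x, level)
  ly <- get_layer(index_y, level)
  k <- index_x$k

  sk_x <- lx$sketches[rows]
  sk_y <- ly$sketches[cols]
  ex_x <- lapply(rows, function(i) expanded_sketch(index_x, lx, i, expansion))
  ex_y <- lapply(cols, function(j) expanded_sketch(index_y, ly, j, expansion))

  empties <- 0L
  vals <- matrix(0, nrow = length(rows), ncol = length(cols))
  for (a in seq_along(rows)) {
    jstart <- if (symmetric) a else 1L
    for (b in jstart:length(cols)) {
      if (symmetric && rows[a] == cols[b]) {
        vals[a, b] <- 100
        next
      }
      ska <- sk_x[[a]]; skb <- sk_y[[b]]
      s <- max(ska$s, skb$s)
      c_xy <- cont_value(refilter_sketch(ska, s)$hashes, ska$distinct_count,
                         refilter_sketch(ex_y[[b]], s)$hashes, s)
      c_yx <- cont_value(refilter_sketch(skb, s)$hashes, skb$distinct_count,
                         refilter_sketch(ex_x[[a]], s)$hashes, s)
      if (is.na(c_xy) || is.na(c_yx)) empties <- empties + 1L
      ani_xy <- ani_from_containment(if (is.na(c_xy)) 0 else c_xy, k)
      ani_yx <- ani_from_containment(if (is.na(c_yx)) 0 else c_yx, k)
      v <- switch(direction,
                  max = max(ani_xy, ani_yx),
                  xy = ani_xy,
                  yx = ani_yx,
                  stop("direction must be one of max/xy/yx", call. = FALSE))
      if (v < t) v <- 0
      vals[a, b] <- v
      if (symmetric) vals[b, a] <- v
    }
  }
  if (empties > 0) {
    warning(empties, " cell(s) involved an empty sketch (e.g. an all-N ",
            "window); rendered uncolored", call. = FALSE)
  }
  vals
}

matrix_params <- function(index, level, expansion, direction = "max") {
  ly <- get_layer(index, level)
  list(k = index$k, m_hat = index$m_hat, w = ly$window_size,
       s = ly$sparsity, seed = index$seed, expansion = expansion,
       level = ly$level, direction = direction)
}

#' Self-identity matrix of a sequence
#'
#' Estimates percent identity between every pair of windows of one sequence
#' at the given hierarchy level. Each unordered pair is scored in both
#' directions (with window expansion applied to the second argument) and the
#' maximum is kept, so the matrix is symmetric; the diagonal is 100 and
#' entries below the identity threshold `t` are zeroed (rendered uncolored).
#'
#' @param index A `mod_index` from [build_index()].
#' @param level Hierarchy level (default 0 = finest).
#' @param t Identity threshold in percent (default 86; values below 80 are
#'   not recommended, the estimate loses accuracy there).
#' @param expansion Window expansion factor (default 1; 0 disables).
#' @return An `identity_matrix`.
#' @seealso [comparative_identity()], [query_identity()], [tidy.identity_matrix()]
#' @export
self_identity <- function(index, level = 0, t = 86, expansion = 1) {
  ly <- get_layer(index, level)
  idx <- seq_len(ly$r)
  vals <- compute_grid(index, index, level, idx, idx, t, expansion,
                       symmetric = TRUE)
  new_identity_matrix(vals, index$name, index$name, ly$windows, ly$windows,
                      ly$window_size, TRUE, t,
                      matrix_params(index, level, expansion))
}

#' Comparative identity matrix between two sequences
#'
#' As [self_identity()] but between the windows of two different sequences;
#' the grid is rX x rY and not structurally symmetric. Both indices must
#' have been built with the same k-mer length, target sketch size and hash
#' seed, otherwise their sketches are incomparable.
#'
#' @param index_x,index_y `mod_index` objects for the two sequences.
#' @param direction How to combine the two directional estimates per cell:
#'   `"max"` (default, matches the self-plot convention and makes the plot
#'   rotation-invariant), `"xy"` (containment of x-window in y-window only)
#'   or `"yx"`.
#' @inheritParams self_identity
#' @return An `identity_matrix`.
#' @export
comparative_identity <- function(index_x, index_y, level = 0, t = 86,
                                 expansion = 1, direction = "max") {
  check_compatible(index_x, index_y)
  lx <- get_layer(index_x, level)
  ly <- get_layer(index_y, level)
  vals <- compute_grid(index_x, index_y, level, seq_len(lx$r), seq_len(ly$r),
                       t, expansion, direction = direction)
  new_identity_matrix(vals, index_x$name, index_y$name, lx$windows,
                      ly$windows, lx$window_size, FALSE, t,
                      matrix_params(index_x, level, expansion, direction))
}

check_compatible <- function(ix, iy) {
  for (f in c("k", "seed", "m_hat")) {
    if (!identical(ix[[f]], iy[[f]])) {
      stop("indices are incomparable: ", f, " differs (", ix[[f]], " vs ",
           iy[[f]], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Identity matrix for a zoomed viewport
#'
#' Answers a zoom query against the hierarchical index: selects the coarsest
#' layer that still provides at least `display_cells` windows across the
#' viewport (see [select_layer()]) and computes the identity submatrix for
#' the windows overlapping the region.
#'
#' @param index A `mod_index`.
#' @param region `c(start, end)` in 0-based half-open base coordinates, or
#'   `NULL` for the whole sequence. See [parse_region()] for the 1-based CLI
#'   string form.
#' @param display_cells Cells across the display (default 1000).
#' @param region_y Optional second region on the same sequence (an
#'   off-diagonal zoom); defaults to `region`.
#' @inheritParams self_identity
#' @return An `identity_matrix` covering the viewport; `x_offset`/`y_offset`
#'   record the genomic position of cell (1, 1).
#' @export
query_identity <- function(index, region = NULL, display_cells = 1000,
                           t = 86, expansion = 1, region_y = NULL) {
  npos <- length(index$stream$hashes)
  if (is.null(region)) region <- c(0, index$n)
  symmetric <- is.null(region_y) || identical(region_y, region)
  if (is.null(region_y)) region_y <- region
  for (rg in list(region, region_y)) {
    if (rg[1] < 0 || rg[2] > index$n || rg[2] <= rg[1]) {
      stop("region [", rg[1], ", ", rg[2], ") outside sequence bounds [0, ",
           index$n, ")", call. = FALSE)
    }
  }
  level <- select_layer(index, region[2] - region[1], display_cells)
  ly <- get_layer(index, level)
  windows_in <- function(rg) {
    which(ly$windows$end > rg[1] & ly$windows$start < min(rg[2], npos))
  }
  sel_x <- windows_in(region)
  sel_y <- windows_in(region_y)
  if (length(sel_x) == 0 || length(sel_y) == 0) {
    stop("region selects no windows", call. = FALSE)
  }
  vals <- compute_grid(index, index, level, sel_x, sel_y, t, expansion,
                       symmetric = symmetric)
  new_identity_matrix(vals, index$name, index$name,
                      ly$windows[sel_x, ], ly$windows[sel_y, ],
                      ly$window_size, symmetric, t,
                      matrix_params(index, level, expansion),
                      x_offset = ly$windows$start[sel_x[1]],
                      y_offset = ly$windows$start[sel_y[1]])
}

#' Parse a samtools-style region string
#'
#' Converts `"name:start-end"` (1-based, inclusive, as pasted from genome
#' browsers) to 0-based half-open coordinates; `"name"` alone means the full
#' sequence.
#'
#' @param region Region string.
#' @param available Optional character vector of valid sequence names.
#' @return List with `name`, `start`, `end` (`NULL` start/end for full
#'   sequence).
#' @export
parse_region <- function(region, available = NULL) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9,]+)-([0-9,]+))?$", region))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) {
    stop("cannot parse region '", region, "' (expected name:start-end)",
         call. = FALSE)
  }
  name <- m[2]
  if (!is.null(available) && !name %in% available) {
    stop("unknown sequence '", name, "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  if (!nzchar(m[3])) return(list(name = name, start = NULL, end = NULL))
  start <- as.numeric(gsub(",", "", m[4]))
  end <- as.numeric(gsub(",", "", m[5]))
  if (start < 1 || end < start) stop("invalid region coordinates", call. = FALSE)
  list(name = name, start = start - 1, end = end)  # to 0-based half-open
}

#' Tidy an identity matrix into one row per cell
#'
#' @param x An `identity_matrix`.
#' @param keep_zero Keep cells below the identity threshold (value 0)?
#'   Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with `x_name`, `x_start`, `x_end`, `y_name`, `y_start`,
#'   `y_end` (0-based half-open base coordinates) and `identity` (percent).
#' @method tidy identity_matrix
#' @export
tidy.identity_matrix <- function(x, keep_zero = FALSE, ...) {
  grid <- tidyr::expand_grid(i = seq_len(nrow(x$values)),
                             j = seq_len(ncol(x$values)))
  out <- tibble::tibble(
    x_name = x$x_name,
    x_start = x$x_windows$start[grid$i],
    x_end = x$x_windows$end[grid$i],
    y_name = x$y_name,
    y_start = x$y_windows$start[grid$j],
    y_end = x$y_windows$end[grid$j],
    identity = x$values[cbind(grid$i, grid$j)]
  )
  if (!keep_zero) out <- dplyr::filter(out, .data$identity > 0)
  out
}

#' One-row summary of an identity matrix
#'
#' @param x An `identity_matrix`.
#' @param ... Unused.
#' @return A tibble with dimensions, window size, threshold, and the count
#'   and mean identity of colored (above-threshold) off-diagonal cells.
#' @method glance identity_matrix
#' @export
glance.identity_matrix <- function(x, ...) {
  off <- x$values
  if (x$self_plot) diag(off) <- 0
  nz <- off[off > 0]
  tibble::tibble(
    x_name = x$x_name, y_name = x$y_name,
    n_x = nrow(x$values), n_y = ncol(x$values),
    window_size = x$window_size, threshold = x$t,
    k = x$params$k, sparsity = x$params$s,
    n_colored = length(nz),
    mean_identity = if (length(nz)) mean(nz) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
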