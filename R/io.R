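#' Write an identity matrix to a gzip-compressed BED file
#'
#' One row per cell with identity at or above the threshold, in a pairwise
#' ("bedpe-like") 7-column layout: `query_name query_start query_end
#' reference_name reference_start reference_end perID`. Coordinates are
#' 0-based half-open base positions; `perID` is printed with 6 significant
#' digits. Two header lines beginning with `#` embed the run parameters (as
#' JSON) and the column names, so [read_bed()] can reconstruct the matrix.
#' For self plots only the upper triangle (including the diagonal) is
#' emitted unless `full = TRUE`.
#'
#' @param m An `identity_matrix`.
#' @param path Output path (a `.gz` suffix is conventional; the file is
#'   gzip-compressed regardless).
#' @param full Emit all cells of a self matrix instead of the upper
#'   triangle.
#' @return `path`, invisibly.
#' @export
write_bed <- function(m, path, full = FALSE) {
  stopifnot(inherits(m, "identity_matrix"))
  meta <- bed_metadata(m, full)
  cells <- tidy(m)
  if (m$self_plot && !full) {
    cells <- dplyr::filter(cells, .data$y_start >= .data$x_start)
  }
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(paste0("#anidot ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  writeLines(paste("#query_name", "query_start", "query_end",
                   "reference_name", "reference_start", "reference_end",
                   "perID", sep = "\t"), con)
  if (nrow(cells) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                       cells$x_name, cells$x_start, cells$x_end,
                       cells$y_name, cells$y_start, cells$y_end,
                       formatC(cells$identity, digits = 6, format = "g")), con)
  }
  invisible(path)
}

bed_metadata <- function(m, full = FALSE) {
  list(version = 1L,
       x_name = m$x_name, y_name = m$y_name,
       x_starts = m$x_windows$start, x_ends = m$x_windows$end,
       y_starts = m$y_windows$start, y_ends = m$y_windows$end,
       window_size = m$window_size, x_offset = m$x_offset,
       y_offset = m$y_offset, self_plot = m$self_plot, t = m$t,
       upper_only = m$self_plot && !full, params = m$params)
}

#' Read an identity matrix back from a BED file written by [write_bed()]
#'
#' Reconstructs the matrix exactly for all cells at or above the threshold;
#' cells below the threshold were zero in the original and are zero again.
#'
#' @param path Path to a BED file produced by [write_bed()].
#' @return An `identity_matrix`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  con <- gzfile(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1)
  if (!startsWith(header, "#anidot ")) {
    stop("not an anidot BED file (missing #anidot header): ", path,
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^#anidot ", "", header))
  body <- utils::read.table(con, sep = "\t", comment.char = "#",
                            col.names = c("x_name", "x_start", "x_end",
                                          "y_name", "y_start", "y_end",
                                          "identity"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "integer", "integer",
                                           "numeric"))
  xw <- tibble::tibble(start = meta$x_starts, end = meta$x_ends)
  yw <- tibble::tibble(start = meta$y_starts, end = meta$y_ends)
  attr(xw, "w") <- as.integer(meta$window_size); attr(xw, "r") <- nrow(xw)
  attr(yw, "w") <- as.integer(meta$window_size); attr(yw, "r") <- nrow(yw)
  vals <- matrix(0, nrow = nrow(xw), ncol = nrow(yw))
  i <- match(body$x_start, xw$start)
  j <- match(body$y_start, yw$start)
  vals[cbind(i, j)] <- body$identity
  if (isTRUE(meta$upper_only)) vals[cbind(j, i)] <- body$identity
  new_identity_matrix(vals, meta$x_name, meta$y_name, xw, yw,
                      meta$window_size, meta$self_plot, meta$t,
                      as.list(meta$params), meta$x_offset, meta$y_offset)
}

#' Save / load an identity matrix as a binary file
#'
#' Lossless round-trip of the full matrix (including sub-threshold zeros)
#' and all provenance metadata (k, sketch size, window size, sparsity, hash
#' seed, expansion factor, threshold). Loading validates the container
#' before any reuse, and [check_matrix_compatible()] guards against mixing
#' matrices computed under different k or hash seeds.
#'
#' @param m An `identity_matrix`.
#' @param path File path.
#' @return `save_matrix()`: `path`, invisibly. `load_matrix()`: the
#'   `identity_matrix`.
#' @export
save_matrix <- function(m, path) {
  stopifnot(inherits(m, "identity_matrix"))
  saveRDS(list(format = "anidot_identity_matrix", version = 1L, matrix = m),
          path)
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read matrix file '", path, "' (corrupt or truncated): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "anidot_identity_matrix")) {
    stop("'", path, "' is not an anidot matrix file", call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported matrix file version: ", obj$version, call. = FALSE)
  }
  m <- obj$matrix
  if (!inherits(m, "identity_matrix")) {
    stop("matrix file '", path, "' is corrupt", call. = FALSE)
  }
  m
}

#' Check that two identity matrices were computed under compatible settings
#'
#' @param a,b `identity_matrix` objects.
#' @return `TRUE`, invisibly; errors if k, hash seed or sketch size differ.
#' @export
check_matrix_compatible <- function(a, b) {
  for (f in c("k", "seed", "m_hat")) {
    if (!identical(a$params[[f]], b$params[[f]])) {
      stop("matrices are incompatible: ", f, " differs (", a$params[[f]],
           " vs ", b$params[[f]], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}
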