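#' Read DNA sequences from a FASTA file
#'
#' Reads a plain or gzip-compressed FASTA file into a tibble of sequence
#' records. Headers are truncated at the first whitespace character and
#' sequences are uppercased, so record names round-trip unchanged into BED
#' output and plot axis labels.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A tibble with one row per record and columns `name` (character),
#'   `seq` (uppercase character string over A/C/G/T/N/...), and `length`
#'   (number of bases).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA test", "ACGTACGT", ">chrB", "GGGTTTAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("failed to parse FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) {
    return(tibble::tibble(name = character(), seq = character(),
                          length = integer()))
  }
  nm <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(nm))) stop("empty sequence name in '", path, "'", call. = FALSE)
  tibble::tibble(
    name = nm,
    seq = unname(toupper(as.character(set))),
    length = Biostrings::width(set)
  )
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with `name` and `seq` columns (as returned by
#'   [read_fasta()] or [make_hor_array()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("name", "seq") %in% names(records)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$name[i]), con)
    # wrap at 70 columns
    s <- records$seq[i]
    starts <- seq(1L, max(nchar(s), 1L), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}
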