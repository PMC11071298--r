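# Deterministic generators for sequences with known repeat structure.
# All generators are pure functions of their arguments and seed: they save
# and restore the caller's RNG state.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Uniform random DNA sequence
#'
#' @param length Number of bases (>= 0).
#' @param seed RNG seed; the same seed always yields the same sequence.
#' @return A character string over A/C/G/T.
#' @export
random_dna <- function(length, seed = 1) {
  stopifnot(length >= 0)
  if (length == 0) return("")
  with_local_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

#' Apply random substitutions to a sequence
#'
#' Each base is independently replaced by one of the three other bases with
#' probability `p` (so `p` is the expected per-base divergence from the
#' input, with no silent substitutions).
#'
#' @param seq DNA string.
#' @param p Per-base substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return The mutated sequence string.
#' @export
mutate_substitutions <- function(seq, p, seed = 1) {
  stopifnot(p >= 0, p <= 1)
  n <- nchar(seq)
  if (n == 0 || p == 0) return(seq)
  with_local_seed(seed, {
    bases <- strsplit(seq, "")[[1]]
    hit <- which(runif(n) < p)
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    if (length(hit)) {
      bases[hit] <- vapply(bases[hit],
                           function(b) sample(alt[[b]], 1), character(1),
                           USE.NAMES = FALSE)
    }
    paste(bases, collapse = "")
  })
}

#' Synthetic tandem higher-order repeat (HOR) array
#'
#' Builds an alpha-satellite-like array: a consensus HOR unit of
#' `monomers_per_hor` random monomers of `monomer_length` bases is
#' concatenated `hor_copies` times, each copy independently mutated from the
#' consensus at `per_copy_substitution_rate`, and the array is padded with
#' random flanks. Optional deletions remove a contiguous tail of monomers
#' from selected copies, mimicking non-canonical shorter HORs while keeping
#' the containment truth exact.
#'
#' Alongside the sequence, a truth table gives each copy's coordinates and,
#' for every ordered copy pair, the expected ANI implied by the realized
#' Hamming divergence over the monomers the two copies share
#' (`100 * (1 - d)`), which is what a k-mer containment estimator targets.
#'
#' @param hor_copies Number of HOR copies.
#' @param monomer_length Monomer length in bases (default 171).
#' @param monomers_per_hor Monomers per HOR unit (default 12).
#' @param per_copy_substitution_rate Per-base divergence of each copy from
#'   the consensus (default 0).
#' @param indel_spec Optional data frame with columns `copy` and `delete`:
#'   delete the last `delete` monomers of copy `copy`.
#' @param flank_length Random flank padding on each side (default 0).
#' @param seed RNG seed.
#' @param name Sequence name for the record.
#' @return A list with `record` (one-row tibble: name/seq/length), `copies`
#'   (tibble: copy, start, end, n_monomers; 0-based half-open base
#'   coordinates), and `truth` (tibble: copy_a, copy_b, divergence,
#'   expected_ani).
#' @export
make_hor_array <- function(hor_copies, monomer_length = 171,
                           monomers_per_hor = 12,
                           per_copy_substitution_rate = 0,
                           indel_spec = NULL, flank_length = 0, seed = 1,
                           name = "hor_array") {
  stopifnot(hor_copies >= 1, monomer_length >= 1, monomers_per_hor >= 1)
  if (!is.null(indel_spec)) {
    stopifnot(all(c("copy", "delete") %in% names(indel_spec)))
    if (any(indel_spec$copy < 1 | indel_spec$copy > hor_copies)) {
      stop("indel_spec references a nonexistent copy", call. = FALSE)
    }
    if (any(indel_spec$delete < 0 | indel_spec$delete >= monomers_per_hor)) {
      stop("indel_spec must delete between 0 and monomers_per_hor - 1 ",
           "monomers", call. = FALSE)
    }
  }
  unit_len <- monomer_length * monomers_per_hor
  consensus <- random_dna(unit_len, seed = seed)
  p <- per_copy_substitution_rate

  kept <- rep(monomers_per_hor, hor_copies)
  if (!is.null(indel_spec)) {
    kept[indel_spec$copy] <- monomers_per_hor - indel_spec$delete
  }
  copies_seq <- character(hor_copies)
  for (i in seq_len(hor_copies)) {
    s <- if (p > 0) mutate_substitutions(consensus, p, seed = seed + i) else
      consensus
    copies_seq[i] <- substr(s, 1, kept[i] * monomer_length)
  }

  flank_l <- random_dna(flank_length, seed = seed + hor_copies + 1)
  flank_r <- random_dna(flank_length, seed = seed + hor_copies + 2)
  lens <- nchar(copies_seq)
  starts <- flank_length + cumsum(c(0, head(lens, -1)))
  seq <- paste0(flank_l, paste(copies_seq, collapse = ""), flank_r)

  copies <- tibble::tibble(copy = seq_len(hor_copies), start = starts,
                           end = starts + lens, n_monomers = kept)

  pairs <- tidyr::expand_grid(copy_a = seq_len(hor_copies),
                              copy_b = seq_len(hor_copies))
  pairs <- dplyr::filter(pairs, .data$copy_a != .data$copy_b)
  div <- purrr::map2_dbl(pairs$copy_a, pairs$copy_b, function(a, b) {
    shared <- min(nchar(copies_seq[a]), nchar(copies_seq[b]))
    sa <- strsplit(substr(copies_seq[a], 1, shared), "")[[1]]
    sb <- strsplit(substr(copies_seq[b], 1, shared), "")[[1]]
    sum(sa != sb) / shared
  })
  truth <- dplyr::mutate(pairs, divergence = div,
                         expected_ani = 100 * (1 - div))

  list(
    record = tibble::tibble(name = name, seq = seq, length = nchar(seq)),
    copies = copies,
    truth = truth
  )
}

#' Offset repeat pair: two identical units out of register
#'
#' Places two identical random units of `unit_length` bases in a random
#' background so that the first starts on a window boundary and the second
#' is shifted by `offset` positions past a window boundary (default half a
#' window: the worst-case registration for windowed identity estimates).
#'
#' @param unit_length Length of the repeated unit (default 10000).
#' @param w Window size the offsets refer to (default `unit_length`).
#' @param offset Shift of the second copy past its window boundary (default
#'   `w / 2`).
#' @param seed RNG seed.
#' @param name Sequence name.
#' @return A list with `record` (tibble), `unit_starts` (0-based base
#'   positions of the two copies), and `w`.
#' @export
make_offset_pair <- function(unit_length = 10000, w = unit_length,
                             offset = floor(w / 2), seed = 1,
                             name = "offset_pair") {
  stopifnot(unit_length >= 1, w >= 1, offset >= 0, offset < w)
  unit <- random_dna(unit_length, seed = seed)
  # copy 1 occupies windows starting at position w; copy 2 starts `offset`
  # into a later window, leaving a full random window between them
  pos1 <- w
  pos2 <- (ceiling((pos1 + unit_length) / w) + 1) * w + offset
  total <- pos2 + unit_length + w
  bg <- random_dna(total, seed = seed + 1)
  seq <- paste0(substr(bg, 1, pos1), unit,
                substr(bg, pos1 + unit_length + 1, pos2), unit,
                substr(bg, pos2 + unit_length + 1, total))
  list(
    record = tibble::tibble(name = name, seq = seq, length = nchar(seq)),
    unit_starts = c(pos1, pos2),
    w = w
  )
}
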