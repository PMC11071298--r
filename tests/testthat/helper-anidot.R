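# shared helpers: string-level oracles kept independent of the hash pipeline

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# distinct canonical k-mers of a sequence interval as strings (lexicographic
# canonicalization: same strand-equivalence classes as the hash-based min)
canonical_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  ks <- substring(seq, 1:(n - k + 1), k:n)
  ks <- ks[!grepl("[^ACGT]", ks)]
  if (length(ks) == 0) return(character())
  rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ks)))
  unique(ifelse(ks <= rcs, ks, rcs))
}

# exact containment of interval A in interval B computed on k-mer strings
brute_containment <- function(seq_a, seq_b, k) {
  a <- canonical_kmer_set(seq_a, k)
  b <- canonical_kmer_set(seq_b, k)
  sum(a %in% b) / length(a)
}

write_temp_fasta <- function(records, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  write_fasta(records, path)
  path
}
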