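# anidot

Alignment-free identity heatmaps of genomic repeats, in R.

Tandem repeat arrays — centromeric alpha satellite, rDNA, segmental
duplications — are best explored as *identity heatmaps*: the sequence is cut
into windows and every pair of windows is colored by its percent identity.
Alignment-based pipelines make those heatmaps slowly and unreliably on
repetitive DNA. `anidot` estimates the cell values from k-mer sketches
instead, for anyone (genome assembly QC, satellite biology, comparative
genomics) who wants self- or cross-sequence dot plots of megabase repeat
regions in seconds on a laptop.

## Method in brief

For each window `A` of `w` k-mer positions, keep the distinct canonical
k-mer hashes divisible by a sparsity `s = 2^d` (the *modimizers*, a
fractional minhash sample of expected size `m = w/s`). For a pair of windows,
estimate the containment of `A` in `B` with a sampling-bias correction:

    c(A,B) = |MOD_s(A) ∩ MOD_s(B)| / ( |MOD_s(A)| · (1 − (1 − 1/s)^|A|) )

and convert it to average nucleotide identity under a binomial
per-base mutation model:

    ANI(A,B) = 100 · c(A,B)^(1/k)

Self-matrices store `max(ANI(A,B), ANI(B,A))`. Three refinements make this
robust on real repeats: the second window is expanded by `w/2` on each side
so out-of-register repeat copies are not under-scored; windows with too few
distinct k-mers adaptively halve their sparsity down to `s = 1`; and a stack
of layers with doubled window size and sparsity (each sampled from the
previous by a subset test) supports zoom queries at any scale.

Defaults: `k = 21`, resolution `r = 1000`, sketch size `m = 1000`, identity
threshold `t = 86`.

## Worked example

```r
library(anidot)

# synthetic alpha-satellite-like array: 8 HOR copies (12 monomers x 171 bp),
# each copy ~1% diverged from the consensus, 10 kb random flanks
hor <- make_hor_array(8, per_copy_substitution_rate = 0.01,
                      flank_length = 10000, seed = 1)

ix <- build_index(hor$record, w_hat = 2052, m_hat = 1000, max_layers = 1)
m  <- self_identity(ix, t = 86)
m
#> <identity_matrix> hor_array: 18x18 cells, window 2052, t=86
#>   identity range of colored cells:  92.14 - 100.00

tidy(m)[2, ]
#> # A tibble: 1 x 7
#>   x_name    x_start x_end y_name    y_start y_end identity
#>   <chr>       <int> <int> <chr>       <int> <int>    <dbl>
#> 1 hor_array       0  2052 hor_array    2052  4104     96.9

autoplot(m)                       # ggplot heatmap; style = "triangular" for self plots
write_bed(m, "hor.bed.gz")        # 7-column pairwise BED, gzip
render_static(m, "hor.png")       # or .pdf
```

The 18×18 matrix covers the 36.8 kb record in 2,052 bp windows (one HOR
unit). Windows inside the array form a dense block of 97–100% cells — each
pair of copies diverges by about 2 × 1%, and the estimator recovers
`100·(1−d)` within a few tenths of a point (windows straddling the
array/flank boundary score lower, here down to 92). The flanks show only the
diagonal: 100 by definition, plus a ~96.8% first off-diagonal that reflects
the half-window physical overlap between a window and its expanded
neighbor.

A command-line front end wraps the same functions:

```sh
anidot static -i seqs.fa --compare -o out          # self + pairwise plots
anidot query  -i seqs.fa --region chr1:1-2,000,000 # zoomed submatrix
```

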