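---
title: "Modimizer sketching and containment-based identity heatmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modimizer sketching and containment-based identity heatmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anidot)
```

## The problem

Tandem repeat arrays — centromeric alpha satellite, rDNA, other
heterochromatic blocks — are poorly served by classical dot plots, which show
only the positions of exact or aligned matches. A more informative display is
an *identity heatmap*: partition a sequence into `r
format(1000)`-or-so windows, estimate the percent identity between every pair
of windows, and color each cell by that estimate. Alignment-based estimates of
the cell values are expensive (quadratic in the number of cells, with each
alignment itself slow on repetitive sequence) and fragile when similar
sequences are split differently across window boundaries.

`anidot` instead estimates each cell's average nucleotide identity (ANI)
alignment-free, from k-mer sketches:

1. decompose the sequence into canonical k-mers and hash them;
2. keep, per window, only the hashes divisible by a sparsity `s`
   ("modimizers" — a fractional minhash sample that needs no windowed
   minimum and is context-independent);
3. estimate the containment of window A in window B from the sketch
   intersection, with a FracMinHash bias correction;
4. invert containment to ANI through a binomial mutation model.

## The estimator

For an interval $A$, the sketch is $\mathrm{MOD}_s(A) = \{a \in A_k : a
\equiv 0 \pmod s\}$ computed on the **set** of distinct canonical k-mer
hashes. With $s = 2^d$, membership is a test of the $d$ low bits, and
$\mathrm{MOD}_{2s}(A) \subseteq \mathrm{MOD}_s(A)$ — the hierarchical
property used throughout. The expected sketch size of a window of $w$
positions is $m = w/s$.

The containment of $A$ in $B$ is estimated as

$$c(A,B) = \frac{|\mathrm{MOD}_s(A) \cap \mathrm{MOD}_s(B)|}
{|\mathrm{MOD}_s(A)| \left(1 - (1 - 1/s)^{|A|}\right)},$$

where $|A|$ is the number of distinct k-mer hashes of $A$; the denominator
factor corrects the fractional-minhash sampling bias, and the estimate is
clamped to $[0, 1]$ (small sketches can overshoot slightly). Modeling
per-base substitutions as i.i.d., a k-mer survives with probability
$(1-p)^k$, so

$$\mathrm{ANI}(A,B) = 100 \cdot c(A,B)^{1/k}.$$

Self-matrices store $\max(\mathrm{ANI}(A,B), \mathrm{ANI}(B,A))$ so they are
symmetric; the same max is used (by default) for comparative matrices so the
plot does not depend on argument order — `direction = "xy"`/`"yx"` retains a
single direction.

```{r}
a <- random_dna(200000, seed = 7)
b <- mutate_substitutions(a, p = 0.01, seed = 8)
s <- 2^floor(log2(199980 / 1000))
sk_a <- modimizer_sketch(canonical_hashes(a, k = 21)$hashes, s)
sk_b <- modimizer_sketch(canonical_hashes(b, k = 21)$hashes, s)
ani_from_containment(containment(sk_a, sk_b), k = 21)  # ~ 99.0
```

## Parameters and defaults

* **k = 21** (1–32). Larger k is more specific, smaller more sensitive to
  diverged repeats; 21 keeps chance collisions negligible
  ($4^{21} \gg$ any window) while retaining sensitivity to a few percent
  divergence. Odd k avoids self-reverse-complementary k-mers.
* **resolution r = 1000** windows per axis: matches common display widths;
  the window size is derived as $w = \lceil (n-k+1)/r \rceil$, or set
  directly via `window`.
* **sketch size m = 1000**: the sparsity is the largest power of two with
  $w/s \ge m$ (`derive_parameters()`; a `round_up` flag flips the rounding).
  Estimator noise scales roughly as $1/\sqrt{m}$.
* **identity threshold t = 86** percent: cells below t are stored as 0 and
  left uncolored. Below ~80 the estimate degrades sharply — at k = 21 and
  20% divergence almost no k-mers survive, so such values are mostly noise.
* **expansion factor 1**: each *second* interval B is expanded by
  $\lfloor w/2 \rfloor$ on each side before sketching. Because B is absent
  from the containment denominator this never penalizes the estimate, and it
  rescues repeat copies that straddle window boundaries (a half-window
  offset drops containment to ~0.5 without it). Note one visible
  consequence: the first off-diagonal of a self plot always scores
  ~$100 \cdot 0.5^{1/21} \approx 96.8$ because the expanded neighbor
  physically overlaps half of A. Set `expansion = 0` to disable.
* **hash seed 42**: any uniform hash works; the seed only fixes
  reproducibility, and sketches built under different seeds (or k, or m) are
  refused for comparison.

### Adaptive sparsity

Low-complexity windows (satellite monomers, dinucleotide runs) contain far
fewer distinct k-mers than random sequence, so a fixed sparsity can leave
nearly empty sketches and false negatives. Whenever a window's sketch holds
fewer than $\lceil m/2 \rceil$ modimizers, it is recomputed at half the
sparsity, repeatedly, until the floor is met or $s = 1$ (every distinct
k-mer kept). Before two sketches are intersected, the denser one is
re-filtered up to the sparser one's sparsity (exact, by the subset
property), and the bias correction uses that common s.

## The hierarchical index

Zooming needs matrices at several window sizes. Rather than re-sketching,
layers are stacked with windows $\hat w, 2\hat w, 4\hat w, \dots$ and
sparsities $\hat s, 2\hat s, \dots$ (constant expected m per window). A
parent sketch is sampled from the union of its two children by the
membership test alone — no rescan of the sequence — which is exactly equal
to direct sketching when no adaptive reduction interferes (a tested
invariant). Layers are added while $2^{l-1} \hat w \le n / r_\min$
(`layer_count()`), so storage stays a geometric series bounded by twice the
base layer. A viewport query (`query_identity()`) picks the coarsest layer
that still supplies at least one matrix cell per display cell.

Expanded-interval (B′) sketches are materialized on demand from the retained
hash stream at every level; because modimizer membership is
context-independent this is set-identical to unioning the covering child
sketches, and nothing extra is stored.

## Synthetic data: what it does and does not emulate

The generators drive every calibration test:

* `random_dna()` — i.i.d. uniform ACGT background;
* `mutate_substitutions()` — i.i.d. substitutions, never silent, so the
  realized Hamming divergence concentrates at p;
* `make_hor_array()` — a consensus HOR unit (default 12 monomers × 171 bp,
  alpha-satellite-like) tandemly repeated, each copy independently diverged
  from the consensus; its truth table records the realized pairwise
  divergence d and the target ANI 100(1−d). Monomer deletions (a contiguous
  tail of a copy) model shorter non-canonical HORs whose k-mers remain fully
  contained in a canonical copy;
* `make_offset_pair()` — two identical units placed half a window out of
  register, the worst case for windowed partitioning.

These fixtures have uniform base composition, no indel processes beyond
whole-monomer deletion, no unequal-crossover structure, and no N-runs unless
added explicitly. Passing calibration on them validates the estimator math —
unbiasedness of corrected containment, the ANI inversion, expansion,
adaptive sparsity — but says nothing about, e.g., GC-skewed hashing of real
satellite DNA or alignment-level concordance on real centromeres, which
require real assemblies.

Problem sizes used by the test-suite calibrations (chosen to keep the
estimator in its intended regime: windows of thousands of k-mers, m ≈
100–1600): 200 kb sequence pairs at substitution rates 0.002–0.02 with 20
replicates, 2 Mb sequences for hierarchy equivalence, 10 kb units for offset
rescue.

## Numerical choices and degenerate inputs

* Hashes are a seeded MurmurHash3-style 64-bit mix of the 2-bit-packed
  canonical k-mer, truncated to 53 bits so they are exact in doubles (the
  low bits — the ones membership tests — are preserved). Collision
  probability over the largest tested streams is ≪ 1e-6.
* k-mers containing any non-ACGT base are dropped (not substituted),
  avoiding spurious identity between N-runs. An all-N window yields an empty
  sketch; its cells are 0 (uncolored) with a one-time warning.
* A trailing partial window is kept as its own interval; its expected sketch
  size shrinks proportionally and the bias correction uses its true distinct
  count, so no special-casing is needed (it may legitimately trigger an
  adaptive reduction).
* The corrected containment can exceed 1 on small sketches; it is clamped
  before the ANI transform so ANI ≤ 100. Diagonal self-cells are set to 100
  outright.
* BED output prints identities with 6 significant digits (round-trip exact
  to ~1e-5); the binary container (`save_matrix()`/`save_index()`) is
  bit-lossless and validates a format tag, version and parameter block on
  load.

## Worked example

```{r, fig.width = 6, fig.height = 5}
hor <- make_hor_array(8, per_copy_substitution_rate = 0.01,
                      flank_length = 10000, seed = 1)
ix <- build_index(hor$record, w_hat = 2052, m_hat = 1000, max_layers = 1)
m <- self_identity(ix, t = 86)
glance(m)
autoplot(m, bins = 11, palette = "viridis")
```

The satellite block appears as a dense square of colored cells (about
92–100% here: windows that fall wholly inside the array score near 99,
windows straddling an array/flank boundary lower) over the 10 kb–26 kb
span; the random flanks contribute only the diagonal (plus the
expansion-overlap first off-diagonal described above).

## Known limitations

* Containment ignores copy number and large indels by design: a 10-monomer
  HOR is ~100% contained in a 12-monomer HOR. This isolates the point
  mutation rate (local-alignment-like behavior) but differs from a global
  aligner's ANI on structurally variable pairs.
* Estimates below the recommended threshold regime (t < 80) are noisy and
  intentionally discarded.
* Cells pair one window with an *expanded* partner, so values near the
  diagonal (and band edges of small matrices) reflect partial physical
  overlap.
* The method detects shared k-mer content, not synteny: shuffled repeats at
  high identity are indistinguishable from collinear ones within a window.
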