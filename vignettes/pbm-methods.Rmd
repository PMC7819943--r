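---
title: "Methods: motif discovery from promoter-tiling PBM intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif discovery from promoter-tiling PBM intensities}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind `pbmotif`, every
tuning parameter and its default, the scope of the bundled simulator, the
numerical choices made in the implementation, and the method's
limitations. It is a source document; it is not built during installation.

## 1. The data and the model

A promoter-tiling protein-binding microarray (PBM) represents each gene by
a set of overlapping probes covering its upstream region. Each probe is a
40-nt gene-specific core followed by a constant primer linker
(`CGGAGTCACCTAGTGCAG`) and a poly-T spacer; tiling advances in 20-nt
steps, so a 1,000-nt promoter yields `(1000 - 40)/20 + 1 = 49` probes and
adjacent probes share 20 nt. After incubation with a tagged DNA-binding
protein, each probe reports one fluorescence intensity.

The analysis rests on three modelling assumptions:

1. **Two-regime rank plot.** Sorted by decreasing intensity, probe
   intensities decompose into a steep head of specific binders and a long,
   nearly flat tail of nonspecific background. Both regimes are modelled
   as straight lines in (rank, intensity) space.
2. **Additive attribution of intensity to k-mers.** Every k-mer occurrence
   in a probe inherits the probe's intensity ("pseudo-intensity"); a
   k-mer's signal is the mean over all its occurrences. True binding
   sites accumulate consistently high pseudo-intensities across many
   probes, while background k-mers regress to the array mean.
3. **One dominant motif per experiment.** Discovery is seeded from the
   single top-ranked k-mer; secondary clusters are reported but refinement
   focuses on the first.

### The two-segment fit

Probes at or below the scanner background are removed
(`filter_background()`, strict `intensity > background`). The remaining
intensities are sorted in decreasing order and indexed by rank
`x = 1..n`. For a candidate breakpoint `b`, ordinary least squares lines
are fitted to ranks `1..b` (steep) and `b+1..n` (tail); the chosen `b`
minimises the summed squared error. The **strong-binding cutoff** is the
y-intercept of the tail line: the intensity the background regime
extrapolates to at rank zero. Probes strictly above the cutoff are the
strong binders. The fit is affine-equivariant: rescaling intensities by
`a*y + c` rescales slopes, intercepts, and the cutoff accordingly and
leaves the breakpoint unchanged.

### From strong probes to a motif

Strong-probe cores are decomposed into all overlapping k-mers (forward
strand; windows containing `N` are skipped). Per k-mer the package
records the mean pseudo-intensity, total occurrence count, their product,
and the number of distinct within-probe positions. k-mers containing a
G or C homopolymer run of 4+ (`GGGG`/`CCCC`) are discarded as synthesis
and hybridisation artifacts.

Ranked k-mers are clustered greedily around the top seed: a candidate
joins if some ungapped sliding alignment (offsets up to `k - 5`) has at
most 2 mismatches in the overlap *and* a run of 5+ consecutive exact
matches. Members are stacked at their best offsets into a position
frequency matrix; columns supported by fewer than 25% of members are
trimmed from the ends; the consensus is the per-column argmax.

Refinement asks three questions of the k-mer table: how much intensity is
lost when each consensus position is mutated (`mutation_scan()`: wild type
minus the mean of its three point mutants); which flanking base extends
the motif best (`extend_motif()`: per side, the highest-intensity k-mer
window consistent with the current motif, extended greedily); and what
base preferences surround genomic occurrences (`flanking_preference()`).

### Enrichment and target genes

Above-background probes are split into motif-bearing and motif-free;
intensities are compared with the Wilcoxon–Mann–Whitney test. Genes whose
strong probes contain the motif are the putative targets; since adjacent
probes overlap by 20 nt, one genomic site can hit two probes, and the
gene list is deduplicated.

## 2. Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `probe_length` | 40 | standard gene-specific core length for tiling PBMs |
| `step` | 20 | half-overlap tiling; every 20-mer window is covered by two probes |
| `k` | 9 | shortest length that still spans typical plant cis-elements with flanks; a 40-nt probe yields 32 9-mers |
| `min_segment` | 50 | minimum ranks per regression segment; below this the line estimates are noise |
| `break_range` | 0.1%–50% of ranks | the steep head is never empty and never the majority of a real array |
| `max_candidates` | 10,000 | breakpoint grid cap; the grid is strided above this so the search stays linear |
| `min_run` (G/C filter) | 4 | `G{4,}`/`C{4,}` runs are known synthesis artifacts |
| `min_occurrence` | 1 (`"auto4x"` recommended) | see below |
| `max_mismatch` | 2 | permits one-to-two-base degeneracy without absorbing unrelated k-mers |
| `core_len` | 5 | an exact 5-nt run anchors the alignment register |
| `trim_support` | 0.25 | consensus columns supported by <25% of members are offset artifacts |
| `max_clusters` | 10 | reporting cap; discovery uses only the first cluster |
| `occupancy_min` | 0.5 | a consensus base must be the strict majority of a column |
| `min_distinct` | 6 | a consensus with <6 determined positions is uninformative |
| `max_rank` | 2,000 | k-mers fed to the quadratic greedy clustering pass |

### The `auto4x` occurrence floor

With a heavy-tailed background, the single brightest probes are often
background draws, and every k-mer unique to such a probe inherits its
full intensity. Ranked purely by mean pseudo-intensity, these singletons
can outrank the true motif. The `auto4x` rule keeps only k-mers whose
total occurrence is at least `ceiling(4 * mean occurrence)` — a genuine
binding site recurs across many probes, while background singletons do
not. This floor is what makes seeded recovery reliable in the planted-motif
study below; with `min_occurrence = 1` the top ranks are dominated by
lucky singletons.

## 3. The simulator and its scope

`simulate_pbm()` generates uniform-random ACGT promoters, overwrites the
planted motif at a random position in each selected gene (per-gene
probability `prob`), tiles them into the standard design, and draws probe
intensities as

```
intensity = baseline + LogNormal(meanlog = 7, sdlog = 1) * boost^(contains motif)
```

with a multiplicative `boost` applied when a planted occurrence lies fully
inside the probe core. The reported scanner background is the 5% quantile
of the lognormal plus baseline, so about 95% of null probes survive
background filtering. The lognormal is chosen because it reproduces the
steep-head/heavy-tail shape of real rank plots; the boost is
multiplicative for the same reason. Everything is driven by a single seed
and the caller's RNG state is restored afterwards.

The simulator is a test harness, not a biophysical model: it has no
sequence-dependent background, no spatial array artifacts, no dye or
position-within-probe effects, and plants a single exact motif (no
degenerate sites). Conclusions drawn from it are about the *algorithm*,
not about any particular protein.

### Study sizes

The recovery study in the test suite uses 2,000 genes (98,000 probes), an
8-mer planted at 8× boost in 10% of genes, and 100 seeded replicates.
These sizes are the package's own choice: large enough that the rank plot
shows both regimes clearly and the planted k-mers recur tens of times,
small enough that one replicate runs in a few seconds on one CPU. The
observed behavior is stable in the neighbourhood of these sizes; at a few
hundred genes the occurrence statistics thin out and recovery becomes
noisy.

## 4. Numerical choices

- **Breakpoint search.** The per-candidate OLS fits are computed from
  cumulative sums (`O(1)` per candidate after an `O(n)` pass), so the
  exhaustive grid is exact up to the 10,000-candidate stride. Ties in SSE
  keep the smallest breakpoint. Sorting is stable with `probe_id` as
  tie-break, so equal intensities order deterministically.
- **Tie-breaking is alphabetical everywhere a base is chosen** (consensus
  argmax, extension candidates), and by smallest absolute offset (negative
  first) in cluster alignment — every run of every stage is deterministic.
- **PWM trimming** removes only contiguous under-supported columns at the
  ends; interior columns are never removed, so the consensus is a
  substring of the stacked alignment.
- **Exact vs approximate Wilcoxon.** The exact null distribution is used
  when the smaller group has ≤8 observations and there are no ties;
  otherwise the tie-corrected normal approximation. Reported p-values are
  floored at `2.2e-16` with an explicit underflow flag, since smaller
  values carry no information.
- **Intensity formatting** in TSV exports is fixed at 2 decimals for
  diffability; JSON exports keep full precision (`digits = NA`).
- **Coordinates** are 0-based half-open internally and 1-based inclusive
  in exported TSVs, converted only at the IO boundary.

## 5. Limitations

- **Forward-strand pseudo-intensities.** k-mer statistics do not merge
  reverse-complement pairs; a palindromic or double-stranded signal is
  split between the two orientations. Scanning and enrichment can include
  the reverse complement (`include_rc`), but decomposition does not.
- **Single-seed discovery.** A protein with two unrelated binding modes
  will have its secondary mode reported only as a weaker cluster, not
  refined.
- **Literal-substring scanning.** Target-gene scans match the consensus
  exactly; degenerate sites matched by the PWM but not the consensus are
  missed. The PWM is exported in MEME format precisely so that external
  scanners can do probabilistic matching.
- **The cutoff is an extrapolation.** The tail intercept is a convention,
  not an error-rate guarantee; it has no false-discovery interpretation.
- **Greedy clustering.** Membership is decided against the seed only, so
  a cluster can drift if the seed is a flank-shifted variant of the true
  motif; the consensus (majority over members) is the robust output, not
  the seed.
- **The simulator's null is exchangeable across probes**, so it cannot
  detect methods that overfit sequence-dependent background present in
  real arrays.
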