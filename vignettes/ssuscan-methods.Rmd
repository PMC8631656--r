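---
title: "Methods: promoter translocation detection and shared-haplotype testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter translocation detection and shared-haplotype testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssuscan)
```

`ssuscan` analyses a single locus — a focal gene whose promoter is
recurrently rewired by reciprocal chromosomal translocations, modelled on
the *SSU1* sulfite-efflux gene of wine yeasts — across a collection of
annotated genome assemblies. This vignette records the models, the tunable
parameters, and the design decisions behind each stage, including the ones
the underlying problem left genuinely open.

## Data model and coordinate conventions

An `annotated_genome` holds chromosome sequences (A/C/G/T/N) and an ordered
gene table. All coordinates are 1-based inclusive, the GFF3 convention, and
every derived distance is converted explicitly at its computation site so no
off-by-one ambiguity accumulates. The **gene start** is strand-aware: the
translation-start-proximal coordinate on the coding strand (`start` for `+`
genes, `end` for `-` genes), because promoter offsets are measured upstream
of where transcription begins. `N` bases are legal in sequences but every
distance computation treats them (and alignment gaps) as missing sites.

Two neighbour-distance conventions coexist in the literature and both are
reported: the *end-to-start* gap (bases strictly between the previous gene's
nearest end and the focal start; overlapping genes give 0 with a warning)
and the *start-to-start* distance between strand-aware gene starts.

## Promoter classification

A strain is **ancestral** iff the ortholog immediately upstream of the focal
gene (on its coding strand) equals the reference strain's upstream ortholog;
anything else is **translocated**, with the partner chromosome read off the
reference location of the observed upstream ortholog. This deliberately uses
only gene-order evidence: it is robust to sequence divergence and needs no
alignment. A strain whose annotation lacks the focal ortholog is
*uncallable* and excluded from summary counts rather than guessed at.

## Breakpoint localisation and junction microhomology

For a translocated strain the promoter window (default `W = 5000` bp ending
at the gene start, coding orientation) is compared against both parental
chromosomes of the reference:

1. **Anchoring.** Exact 20-bp seeds taken from the gene-proximal end are
   searched in the ancestral focal chromosome (parent A), and seeds from the
   distal end in the partner chromosome (parent B, both orientations);
   seeds step inward until a unique hit is found. 20 bp is long enough to be
   unique in a yeast-sized genome and short enough that, at intraspecific
   divergence, a clean seed is found within a few steps. Failure on either
   side yields an `unresolved` call (this is also how an ancestral-looking
   window falls out: it has no partner anchor).
2. **Changepoint.** With per-base agreement vectors against each parent, the
   junction estimate maximises (distal bases explained by B) + (proximal
   bases explained by A). If either side then shows >10% residual mismatch,
   the call is `complex` — more than one switch point, or a rearrangement
   this single-junction model does not describe.
3. **Ambiguity interval.** Around the changepoint, any base matching *both*
   parents cannot be assigned to either side: the maximal such run is the
   junction microhomology, and the reported interval `[lo, hi]` (bp upstream
   of the gene start, `hi - lo` = microhomology length) brackets every
   placement consistent with the data. The breakpoint offset is reported at
   the focal-proximal edge `lo`, matching how single-number offsets are
   conventionally quoted; the interval is the honest answer.

Two refinements matter at non-zero divergence. Discriminating sites (bases
matching exactly one parent) bound the interval on each side, so an isolated
substitution *inside* the microhomology does not truncate it. And a
both-parent run of at least 4 bp lying one base away from the changepoint is
still accepted as the microhomology, covering the case where a point
substitution at the first base beyond the junction mimics a shifted
junction. The 4-bp floor keeps chance matches (each base matches the other
parent with probability 1/4) from inflating the interval: a spurious ≥4-bp
run occurs with probability < 0.5%.

One ambiguity is irreducible: with zero-length microhomology, a substitution
at the base adjacent to the junction that happens to match the other parent
is *indistinguishable* from a junction shifted by one base. No estimator can
recover the planted truth there. At intraspecific divergence (0.2–1%
substitutions/site, the scale separating conspecific wine-yeast strains)
this affects well under 1% of junctions, which is why the recovery tests run
on that divergence grid; at 5% divergence and beyond, single-base junction
assignment is intrinsically less reliable and the interval, not the point
offset, is the quantity to trust.

## Motif retention

The ancestral reference promoter window is scanned for exact IUPAC matches
of the motif (default `CTATCA`, the Fzf1p binding site; both strands).
Status is `absent` with no ancestral match; for a translocated strain the
motif is `lost` when its nearest ancestral match lies farther upstream than
the breakpoint offset — i.e. on the replaced side of the junction — and
`retained` otherwise. Matches are positioned by their gene-proximal edge.

## K81 distances and the shared identical block

Ortholog pairs are compared on their coding strands after end-to-end global
alignment (match +1, mismatch −1, gap open −4, gap extend −1; equal-length
pairs take the identity alignment, exact under the generator's
substitution-only evolution). Gap and N columns are excluded. The Kimura
(1981) three-substitution-type distance is

$$d = -\tfrac{1}{4}\left[\ln(1-2P-2Q) + \ln(1-2P-2R) + \ln(1-2Q-2R)\right]$$

with $P$ the transition proportion and $Q$ (A↔T, G↔C), $R$ (A↔C, G↔T) the
two transversion classes. When any logarithm argument is non-positive the
pair is flagged *saturated* and excluded from null pools (with a recorded
count) rather than silently dropped or clamped.

The **shared block** walks outward from the focal gene while the *raw
mismatch count* is zero. Identity, not model distance, is the criterion: an
"identical segment" claim is about sequence, and a rounded model distance of
zero would admit near-identical genes. A missing ortholog terminates the
walk — an unassembled or unannotated gene must not silently bridge a run.

## Random-window permutation test

The null distribution comes from windows of `window_size` (default 20)
consecutive shared orthologs sampled uniformly *with replacement* over valid
start positions (default `n_windows = 1000`), entirely on one chromosome and
entirely outside the focal exclusion interval (the focal window plus the
delimited shared block). The focal window is the focal gene plus its 19
nearest shared orthologs by rank — the window composition was not fully
pinned down in the source design, so the symmetric nearest-neighbour choice
is used and recorded here.

Two p-values are reported. The primary statistic is a two-sided
Mann–Whitney U comparing the focal window's per-gene distances against the
pooled null distances, using the normal approximation with tie and
continuity corrections (ties are structural here: identical genes give
exactly zero). The package's `mann_whitney()` also enumerates the exact
permutation distribution (valid under ties) when the assignment count is
small, which is how it is validated against an independent counting oracle.
Second, an empirical window-mean p-value,
$(1 + \#\{\text{null window means} \le \text{focal mean}\})/(n_\text{windows}+1)$,
is reported; it is bounded below by $1/(n_\text{windows}+1)$ and is the more
conservative, assumption-free summary. Because pooled null distances from
overlapping windows are not independent, the rank-test p-value is exact only
under the idealisation that per-gene distances are exchangeable; the
empirical window-mean p does not share that caveat, which is why both are
kept.

## qPCR quantification

Standard curves are least-squares fits of Ct on $\log_{10}$(dilution);
efficiency $E = 10^{-1/\text{slope}}$ ($E = 2$, slope −3.32, is perfect
doubling; curves outside $1 < E \le 2.2$ or with non-negative slope are
flagged invalid). Quantities are $10^{(ct - \text{intercept})/\text{slope}}$
— normalisation operates on quantities, not on ΔΔCt cycles, so unequal
per-gene efficiencies are handled exactly. Per replicate, the normalised
value is the target quantity over the *arithmetic* mean of the two
reference-gene quantities (the source protocol says "average"; the
geometric mean is available via `ref_average = "geometric"`). Ratios divide
each cell's replicate mean by the calibrator strain's mean at the same
condition and timepoint, so the calibrator's ratio is exactly 1 by
construction. With Ct noise of 0.2 cycles and triplicates, a single cell's
ratio has ~14% coefficient of variation; a strain-level fold-change is
therefore assessed on the geometric mean of its cell ratios, which pools
the 8 condition × timepoint cells.

## Drop-test tolerance

Growth scores are ordinal 0–6 on the 0–0.4 g/L metabisulfite grid (step
0.05). The maximum tolerated concentration is the highest grid point with
score ≥ 1 — any surviving spot counts as growth, since the assay's dilution
series already encodes vigour in the score itself. Strains growing nowhere
have undefined maxima and are excluded from class means with a recorded
count. Class comparisons use Welch's t-test by default (a pooled-variance
Student test is available); the source only says "t-test", and
unequal-variance robustness is the safer default for unbalanced classes
(52 vs 10).

## The synthetic-data generator

Every pipeline input can be generated with planted truth: uniformly spaced
1-kb genes (1-kb intergenic) on named chromosomes, uniform base composition
(K81 is composition-free, so nothing is lost), substitution-only K81
evolution using exact finite-time transition probabilities (so multiple hits
are modelled and the distance estimator is consistent), a reciprocal
translocation that first plants an identical k-bp microhomology immediately
5' of both parental breakpoints and then swaps the distal arms (base content
conserved; annotations remapped), an identical-by-state block copied from
one strain into another, Gaussian-noise Ct tables with per-gene standard
curves, and ordinal drop-test scores decaying from 6 at 0 g/L to 1 at each
strain's tolerated maximum. The bases flanking a planted microhomology are
forced to differ between the parents, making the planted junction ambiguity
*maximal by construction* — otherwise a chance flank match (probability 1/4
per side) would make the planted length a lower bound rather than the
truth.

Default study conditions: three 80-gene chromosomes; 17 ancestral strains,
3 strains sharing a chrVII event (offset 339 bp, 8 bp microhomology), 1
strain with an independent chrXI event (393 bp, 4 bp); per-strain branch
length 0.005 (intraspecific scale); a 33 + 21 gene identical block shared by
the first two translocated strains; ~10-fold target-gene overexpression in
translocated strains; tolerance class means 0.175 / 0.375 / 0.40 g/L
(sd 0.025). The bundled
`inst/extdata/droptest_collection_synthetic.tsv` is a synthetic stand-in for
a 63-strain collection (52 ancestral / 10 / 1, ancestral ceiling 0.2 g/L),
generated by `simulate_droptest()` and labelled synthetic in its filename.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: indels and assembly gaps inside genes (the
equal-length fast path would instead exercise the alignment route),
rate heterogeneity across sites and genes, GC-content structure, gene
gain/loss and introgression, annotation errors, and fermentation-level
biological variability in expression. Orthology is taken as given; the
synteny-based annotation transfer that produces it in practice is out of
scope.

## Numerical choices and problem sizes

All generators and samplers are pure functions of (configuration, seed);
per-stage seeds derive from one master seed via a fixed integer hash, and
the pipeline records them in its manifest. Grid snapping resolves exact
ties downward; saturated distances are excluded, never imputed. The test
suite runs its recovery checks at sizes chosen to keep the full suite
around a minute while leaving estimator noise well below the tested
margins: 100 permutation replicates on 200-gene genomes, 200
junction-recovery replicates on 40-gene genomes across microhomology
{0, 4, 8, 12} × divergence {0, 0.002, 0.005, 0.01}, 50 shared-block
replicates at pairwise divergence 0.03–0.08, 1000 K81 oracle pairs, a full
exact-enumeration sweep of the rank test to n = 8 plus a 1000-simulation
size check, and 200 qPCR recovery replicates.

## Known limitations

* Single-junction model: nested or serial rearrangements at the same locus
  produce `complex` calls, by design, rather than a forced answer.
* Junction placement at zero microhomology is exact only up to the
  irreducible one-base ambiguity described above.
* The permutation null treats gene windows as exchangeable; linked
  selection or rate variation along chromosomes would violate this in real
  genomes.
* qPCR normalisation assumes the two reference genes are truly constant
  across strains and conditions; the generator enforces this, real data may
  not.
* No MIC interpolation between drop-test grid points; the maximum tolerated
  concentration is grid-valued.
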