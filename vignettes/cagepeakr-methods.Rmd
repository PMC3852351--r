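---
title: "cagepeakr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cagepeakr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

CAGE-seq reads begin at the 5' cap of RNA molecules, so the first aligned
base of each read marks a position where a capped 5' end exists. Two
complications drive this package's design. First, transcription initiation
is positionally noisy: a single promoter produces a cluster ("peak") of
nearby start positions rather than one base, and clusters must be detected
against a background of scattered read starts. Second, cytoplasmic
cleavage-and-recapping produces genuine cap signals at positions with no
transcription initiation, typically inside exons; peak *detection* alone
therefore over-reports transcription start sites (TSSs), and a
*classification* stage must separate TSS peaks from recapping peaks.

## Stage 1: sliding-window peak calling with local Poisson nulls

Only read 5' starts are used (leftmost aligned base of a forward read,
rightmost of a reverse read — the cap-proximal end; the input may state
this only implicitly, but CAGE chemistry forces it). Reads with mapping
quality below 20 are discarded, as are secondary and supplementary
alignments; no deduplication is applied.

Per (chromosome, strand), a window of width `w = 50` bases slides in steps
of `w/2 = 25`. For each candidate window with at least `min_reads = 10`
read starts, the counts of the two adjacent 200-base flanks are scaled by
`w / flank_width` (i.e. divided by 4; truncated flanks at chromosome ends
use their actual width in the denominator but the nominal `w` in the
numerator) and rounded to the nearest integer, half away from zero. Each
scaled flank count serves as the mean of a Poisson null, and the candidate
passes when `P(X >= x)` falls below `1e-20` for **at least one** flank
("either" read literally; `require_both = TRUE` gives the AND reading —
the difference matters for candidates with one silent flank, which the OR
rule admits on the strength of the silent side alone). A flank with zero
scaled count gives the degenerate Poisson, whose upper tail at any
positive count is zero, so such candidates always pass; no pseudocount is
added because none is specified by the procedure. All tail probabilities
are computed and compared in log space (`ppois(..., log.p = TRUE)`), since
`1e-20` and far smaller values underflow naive summation.

Passing windows are trimmed to their outermost nonzero positions, merged
per strand when separated by fewer than `merge_gap = 30` bases (overlap
counts as negative separation; merging is transitive), and re-trimmed —
the re-trim is a structural no-op but enforces the nonzero-boundary
invariant by construction. Each peak carries its total count and summit
(maximum single-base count; ties break to the 5'-most base on the peak's
strand).

One behavioural consequence worth stating: two read clusters that both fit
inside a single 50-base candidate window are reported as one peak whatever
the merge gap, because the window's trimmed span covers both. Distinct
peaks on one strand therefore require a separation that no candidate
window bridges. The test suite pins this down against an independent
enumerate-every-window reference implementation.

## Stage 2: features, selection, classification

**Features.** Eight feature families are computed per peak:
Pearson's kurtosis of the read-start distribution (fourth central moment
over squared variance, population moments, each read one count-weighted
observation of its position; minimum 1, normal 3 — TSS peaks are taller
and narrower than recapping peaks); read density (count/width); counts of
all 256 4-mers in a 500-base window upstream and, separately, downstream
of the summit (512 columns; windows are strand-aware and read as reverse
complement for minus-strand peaks, so "upstream" is always promoter-side
sequence; the summit base belongs to neither window — a stated tie-break
worth one 4-mer at most); maximum TFBS, DNase hypersensitivity and
H3K4me3 track scores within 100 bases of the peak ends (0 when no signal
is in reach, since pooled tracks record only positive-signal regions);
mean per-base conservation inside the peak (over scored bases only;
fully unscored peaks are imputed with the per-cell-line minimum observed
mean); and the RNA-seq flank asymmetry `P(Y <= y_up; lambda = y_down)`
over 100-base flanks adjacent to the peak edges (strand-aware; read 5'
starts pooled over both RNA-seq strands are counted — full-read overlap
counting is a defensible alternative the input leaves open). Zero-variance
kurtosis (single-base peaks) takes the maximum kurtosis among
non-degenerate peaks of the same cell line, mirroring the conservation
imputation style and keeping single-base peaks "maximally peaked".

**Standardisation and selection.** Features are scaled to [0, 1] by
dividing by the per-feature, per-cell-line maximum. Selection pools all
peaks from all cell lines and runs PCA on the mean-centred matrix twice —
once for the single features, once for the 4-mer block, which would
otherwise dominate the pooled variance — and retains features with
|ρ| ≥ 0.5 against PC1.

*Design note on ρ.* The source procedure describes ρ as "the component
loading multiplied by its eigenvalue". Taken literally that product is the
**covariance** of the variable with PC1; it is scale-dependent and on
[0, 1]-standardised data its magnitude is generically far below 0.5, so a
0.5 cutoff would select nothing — while the reported ρ values (−0.92,
−0.91, −0.86, −0.53) are clearly bounded-by-1 correlations. The default
mode therefore computes the variable–component correlation,
loading × √eigenvalue / sd(feature), which is the only reading consistent
with both the reported values and a 0.5 threshold; the literal product
remains available as `mode = "paper"`. PC1's sign is fixed so the
largest-magnitude loading is negative, matching the reported negative ρ
convention (sign never affects selection). Selection is global, not
per-fold: pooling all cell lines before cross-validation introduces mild
leakage, accepted here because the procedure specifies it; the functions
compose so per-fold selection is a few lines if wanted.

**Scenario rescaling.** With *m* selected 4-mers (each in [0, 1]),
kurtosis is rescaled to [0, *m*] so the single internal feature carries
the same total weight as the 4-mer block; in the pooled-external scenario
TFBS, DNase and H3K4me3 are each rescaled to [0, 2*m*/3]; in the RNA-seq
scenario the asymmetry feature is rescaled to [0, 2*m*]. The constant 168
quoted in the source corresponds to *m* on its data and is replaced by the
actual *m* here.

**Classifier.** An L2-regularised, L2-loss (squared hinge) linear SVM in
the primal:

    min_{w,b} 0.5 ||w||^2 + C * sum_i weight(y_i) * max(0, 1 - y_i (w.x_i + b))^2

with the TSS weight n_nonTSS / n_TSS and non-TSS weight 1, an
unregularised bias, and TSS as the positive class. The squared hinge is
continuously differentiable, so the solver is BFGS from a zero start with
analytic gradients — deterministic, and adequate at the row/column counts
this pipeline produces (the primal is the right form precisely because
peaks vastly outnumber features). The usual LIBLINEAR backend is not a
dependency here; the separable, label-flip, weight-monotonicity and
direction-recovery tests pin the solver's behavioural contract instead.

**Evaluation.** Leave-one-cell-line-out: for each cost in a grid
(default powers of 10 from 1e-6 to 1e2; the published range is not
printed, so the grid is configurable) and each held-out line, train on
the pooled peaks of the remaining lines with weights computed on that
training pool, and record precision and recall on the held-out line, plus
per-cost min/mean/max summaries. Zero denominators yield `NA`, never a
silent 0.

**Labelling.** Peaks are labelled TSS when they overlap any
`[p - 500, p + 500)` window around an annotated transcript 5' start
(strand-blind by default, as the labelling is positional; a stranded mode
exists); overlap with multiple transcripts is still one TSS label.

## The synthetic world

The generator emulates exactly the statistical structure the method
assumes: homogeneous Poisson background (the caller's own null, stated
plainly so users know synthetic performance is an upper bound),
concentrated read starts at planted TSSs (geometric-decay spread 3 by
default, 60 reads), broader recapping-like non-TSS clusters (spread 25,
40 reads) with no promoter motif and symmetric RNA-seq flanks, a fixed
TATA/GC promoter cassette written upstream of each true TSS so 4-mer
features carry class signal, external tracks elevated only near true
TSSs (level 10 vs 0), and RNA-seq rates 20 downstream vs 1 upstream of
TSS peaks. Defaults (20 TSS + 20 non-TSS peaks per 200 kb line,
background 0.002 reads/base) were chosen once as a desk-scale world with
strong class-conditional effects. It does not attempt real CAGE count
distributions, real promoter composition, overlapping transcription, or
mappability artefacts — a green end-to-end test establishes that the
machinery composes correctly and recovers a planted signal that satisfies
the model's assumptions, not field performance.

## Numerical and degenerate-input choices

* Poisson tails: log-space throughout; finite and strictly ordered past
  1e-300; `P(X >= 0) = 1` always; `lam = 0` gives tail 1 at `x = 0`, else 0.
* Scaled-flank rounding: half away from zero (7/4 → 2, 10/4 → 3), stated
  so the enumeration oracle can match bit-exactly.
* Merge rule: strict inequality (`separation < 30` merges; exactly 30
  does not).
* All-zero candidate intervals trim to nothing and are dropped; empty
  profiles yield empty peak lists; empty peak sets yield feature matrices
  with full headers.
* Standardisation leaves all-zero (or non-positive-maximum) columns
  unchanged with a warning rather than dividing by zero.
* PCA on a constant matrix errors; selection with everything under
  threshold returns an empty set and downstream refuses to train.
* Internal coordinates are 0-based half-open everywhere; conversions
  happen only at format boundaries (GTF 1-based inclusive, BED 0-based
  half-open).

## Known limitations

* Extremely broad start regions (thousands of bases) are outside the
  caller's design envelope, as is any FDR-style multiple-testing
  correction — the procedure applies a fixed threshold.
* Real-data benchmark reproduction (ENCODE CAGE submissions, GENCODE v15)
  requires inputs not shipped here; the package reports whatever data it
  is given and the synthetic closure tests bound what is verified.
* The OR/AND flank-rule ambiguity and the strand orientation of sequence
  features are resolved as documented above, with flags preserving the
  alternative readings.
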