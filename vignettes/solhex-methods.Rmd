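---
title: "Methods: detecting, dating and dissecting ancient hexaploidizations"
author: "solhex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, dating and dissecting ancient hexaploidizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solhex)
```

## The problem

Many plant lineages descend from ancient whole-genome triplications
(paleohexaploidizations). Tens of millions of years later the only remaining
evidence is statistical: a genome that aligns to an outgroup reference at a
3:1 depth ratio, synonymous-substitution (Ks) distributions with extra peaks,
and three interleaved "subgenomes" that have lost genes at conspicuously
different rates. `solhex` implements the comparative pipeline that turns gene
annotations and all-vs-all protein homology into those statistics: collinear
synteny blocks, per-pair Ks, event peaks, rate-corrected dates, an
event-related multi-genome alignment table, fractionation statistics, the
P-index allo/autopolyploidy diagnostic, and a shared-breakpoint test of the
two-step duplication model. A fully labelled simulator generates hexaploid
genomes with known ground truth so that every stage is testable without any
external download.

## Synteny detection

Homology input is a BLAST tabular file filtered at E-value < 1e-5 and bit
score > 100; reciprocal duplicates are collapsed and self-hits removed. Genes
belonging to homolog clusters (single-linkage components of the pair graph)
with 50 or more members are removed before chaining: large families blanket
the dotplot and carry no positional signal.

Blocks are chains of anchors on gene order (`order_index`, the rank of a gene
along its chromosome), not base pairs; dotplots of gene order are the natural
coordinate system for collinearity, and gene-rank gaps are robust to
intergenic-length variation. Chaining is a longest-chain dynamic programme
run separately in both orientations, with

* strict monotonicity on both axes (increasing, or decreasing for
  antiparallel blocks),
* at most 50 intervening genes between consecutive anchors on either axis,
* a minimum of 4 anchors per block,
* chain score = anchor count.

Maximal chains are extracted greedily in decreasing score; anchors are
consumed, so every anchor belongs to at most one block, mirroring how blocks
are read off a dotplot. Ties between orientations go to parallel; all
tie-breaks are deterministic. No statistical significance test is applied to
blocks beyond the anchor-count and gap thresholds; the length/gap filter is
the block definition here, which is an approximation to chain-significance
testing as done by dedicated collinearity tools.

Orthologous depth ratios are reported as copies-in-A : copies-in-B, where
copies-in-A is the modal number of A-side orthologous blocks covering a gene
of genome B (computed over covered genes only, because heavy fractionation
makes the mean misleading). An unduplicated reference against a hexaploid
yields 1:3.

## Ks estimation and peak finding

Ks and Ka are computed by Nei–Gojobori (NG86) counting on codon-aligned CDS
pairs:

* synonymous site fractions per codon (changes creating a stop codon count
  as nonsynonymous), averaged over the two sequences;
* differences averaged over all equally weighted single-substitution
  pathways between the two codons, excluding pathways through stop codons
  (if every pathway is blocked, all are used);
* codons containing gaps, ambiguity characters or stops are excluded;
* Jukes–Cantor correction `d = -(3/4) log(1 - (4/3) p)`; `(4/3) p >= 1`
  raises a saturation flag instead of a number.

The implementation is verified against an independent pathway-enumeration
oracle to 1e-12 on a thousand random codon pairs.

Event peaks are found on the kernel density of a Ks sample (Gaussian kernel,
width 0.05 in Ks units, the width being the kernel standard deviation) over
the fit range (0.005, 3]: the lower cut removes the zero-inflation of
identical pairs, the upper cut the saturated tail. A sum of Gaussians is then
fitted to the density curve by least squares — the quantity of interest is
the curve, so the fit minimises squared error on the density grid rather
than a sample likelihood — adding components one at a time until
`R^2 = 1 - SSE/SST >= 0.95`; the smallest sufficient component count wins.
Each count is optimised from ten deterministic multi-starts (quantile-spread
means with seeded jitter) and the best SSE kept; if the target R-squared is
unreachable the best fit is returned flagged as not accepted. Distributions
are always fitted on per-pair Ks values; block medians are used only to
match homologous regions to events.

## Rate correction and dating

Lineages accumulate synonymous substitutions at different speeds, so one
event appears at different Ks in different genomes. With `mu_G` the
shared-event (ECH) peak of the slowest genome and `mu_i` the same peak in
genome *i*:

* relative rate `r = (mu_i - mu_G) / mu_G` (reported as a rounded
  percentage),
* correction coefficient `lambda_i = 1 / (1 + r)`,
* within-genome peaks are corrected as `lambda_i * mu`, which by
  construction maps every genome's ECH peak exactly onto `mu_G`,
* between-genome peaks use the algebraic mean
  `((lambda_x + lambda_y)/2) * mu_xy`,
* ages scale linearly: `age = (mu_corrected / mu_G) * t_ECH`, with the ECH
  calibration window 115–130 Mya.

One design point deserves emphasis. The published formulation of the
correction for a genome's *internal* WGD peak is printed in a self-referential
form (the corrected value appears on both sides of its own definition).
The only dimensionally consistent reading that uses the declared quantities
is to apply the genome's own coefficient:
`mu_corrected = mu_wgd * (mu_G / mu_ech_i)`, and that is what
`correct_inner_wgd_peak()` implements, prominently documented as an
interpretation. Its consequence is visible and deliberate: from an internal
peak of 0.721 beside an ECH peak of 1.497 and the 115–130 Mya calibration,
the implied age is roughly 55–63 Mya. The much younger 43–49 Mya sometimes
quoted for the same peak cannot be derived from these inputs under any
algebraic rearrangement of the printed cases, so this package reports the
dates its own formulas produce and documents the discrepancy rather than
guessing an unstated formula. Divergence-peak dating is unaffected (the
corrected 1.230 peak dates to ~93–106 Mya, matching the published ~92–105).

## The event-related alignment table

The table has one row per reference gene, in reference order, and one column
group per reference (ECH) copy; each group holds the reference column plus
three slot columns per hexaploid genome — `(1 + 3 g) x groups` columns, the
published 21-column layout for two hexaploids and a triplicated reference.
Orthologous blocks are packed into the three slots per reference chromosome
by descending anchor count, with two rules: blocks sharing a slot may not
overlap on the reference axis (beyond 2 genes of slack), and among feasible
slots a block prefers the one already aligning to its target chromosome, so
the pieces of a translocated subgenome reunite in one slot. Cells without a
surviving homolog hold a dot. Conserved-triplet and absence statistics
expose their numerator and denominator so the percentages are auditable.

## Fractionation statistics

Slots are ranked per region (reference chromosome x group) by retained-gene
count into LF, MF1 and MF2 (least/moderately/most fractionated); ties break
deterministically by span then slot index and are flagged. Retention
profiles use sliding windows of 20 genes, step 10, by default. The window
size is configurable, and one property depends on it: the "retention rates
differ by more than 0.05" criterion is only meaningful when binomial noise
in a window's rate is below 0.05, i.e. for windows of several hundred genes;
the discrimination tests therefore use large windows for the unbiased null
and the default for the biased alternative.

Gene-loss runs are maximal dot runs counted inside the covered interior of
each chromosome (between the subgenome's first and last retained gene):
leading and trailing dots are unaligned ends or translocated material, not
losses, and runs never span chromosome ends. Run-length histograms are
fitted to the geometric pmf `p (1-p)^(k-1)` by least squares on normalized
frequencies, alongside the closed-form MLE `1/mean(k)` as a cross-check,
with `R^2` and a standard regression F-test (fitted pmf against the
mean-only model). Published analyses of this kind report an F-test
convention in which values near 0.95 indicate a good fit; that convention is
toolbox-specific and not reconstructable, so the p-value reported here is
the standard one and is not comparable to those numbers.

## P-index

The published P-index formula leaves its `delta_i`, `delta` and chromosome
weights under-specified (they are attributed to earlier work). `solhex`
implements a reconstructed contract that satisfies every stated calibration
(bounded to [0, 1]; 0 for identically distributed losses; monotone toward 1
under consistent dominance; > 0.3 diagnosing allopolyploidy): for each
threshold `delta` in 0.1–1.0 and chromosome c with window retention rates
`A_i`, `B_i` and difference scale `s_c = max |A_i - B_i|`,

```
D_c(delta) = | sum_i sign(A_i - B_i) 1{|A_i - B_i| > delta s_c} | / N_c
P(delta)   = sum_c W_c D_c(delta),   W_c  proportional to window count
```

and the aggregate is the mean over the delta grid (per-delta values are
emitted too). Output is labelled "P-index (reconstructed contract)".
Windows are non-overlapping 10-gene windows, shrunk when a chromosome cannot
supply ~50 of them. The statistic is invariant under swapping the two
subgenomes. On simulated two-step allohexaploids (retention 0.55/0.30/0.15)
the LF-vs-MF2 value falls around 0.33, clearly above the 0.3 demarcation;
on one-step autopolyploids (equal thirds) around 0.05.

## Breakpoints and the two-step test

Within a subgenome's slot, blocks are ordered along the reference; a switch
of target chromosome between consecutive blocks is a translocation
signature, an orientation flip an inversion signature. The breakpoint is
placed at the midpoint between the flanking anchors (reported in gene-order
and base-pair coordinates), so localization error grows with local gene
loss — exact to a couple of genes on fully retained subgenomes, of the order
of the inter-anchor spacing under heavy fractionation. Breakpoints of
different subgenomes within 10 genes on the same reference chromosome and of
the same type are grouped as shared; a group private to exactly one
subgenome pair is evidence that those two subgenomes travelled together
before the third joined, and yields the verdict "two-step (X,Y first)".
Groups spanning all three subgenomes are uninformative; absent any private
pair the verdict is "inconclusive".

## Gene-family metrics

Family members (membership is an input; domain-based identification is out
of scope) are labelled by origin with precedence tandem > polyploidy >
retained: a member within 5 intervening genes of another member on the same
chromosome is a tandem gain (the downstream copy of the pair); a member
anchored in a polyploidy-labelled block whose partner is also a member is a
WGD gain; a member syntenic to a reference-family gene is retained
ancestral. With `N` = reference family size minus reference tandem gains:
`WGD-ER = 100 x wgd_gained / N`, `TD-ER = 100 x tandem_gained(ref) / N`, and
`CR = 100 x (reference members lost in the target lineage) / N`, the loss
count inferred from synteny (a reference member with no syntenic family
partner in the target) since gene-tree reconciliation is out of scope.
Subgenome placement reports the LF/MF1/MF2 fraction of members via the slot
that contains each member's block.

## The simulator

`simulate_hexaploid_dataset()` generates a reference ancestor (uniformly
spaced genes on near-equal chromosomes) and two hexaploid descendants:
three subgenome copies per genome; translocations and inversions planted
before the LF copy "joins" (two-step mode) so they are shared by exactly
MF1+MF2, or placed in one independently chosen subgenome (auto mode);
gene loss in geometric-length runs placed uniformly until each subgenome
hits its retention target within 0.5%; and a homolog table in which every
surviving relationship carries a true Ks drawn from its event's Gaussian.
Defaults are the study conditions used throughout: 5,000 genes on 5
chromosomes; retention 0.55/0.30/0.15 (equal thirds in auto mode); loss-run
parameters 0.42/0.40/0.38, inside the empirically observed 0.36–0.42 range;
rate multipliers 1, 1.42, 1.46; component standard deviation 0.12.

Scale conventions for event means required one decision. Within-genome
event means are stored on the slowest-genome scale and multiplied by the
genome's rate factor when drawn (shared triplication 1.054 -> observed
1.497/1.539; internal WGD 0.5077/0.5171 -> observed 0.721/0.755), because a
multiplicative rate model is the premise of the correction machinery.
Cross-genome divergence means are stored on the observed scale directly
(1.215/1.229/1.230): the arithmetic-mean correction used for between-genome
peaks is not the exact inverse of any multiplicative model, so no single
base value reproduces all printed numbers; specifying observed means keeps
the simulated peaks at the published positions. Because the simulated
reference is unduplicated (the target depth ratio is 1:3), the shared-event
rate-calibration signal is planted as non-syntenic ancient-paralog pairs in
every genome; peak fitting and rate recovery operate on per-pair Ks exactly
as they would on syntenic paralogs.

Structural-variant geometry matters for detectability and is controlled:
inversion segments are at least 110 genes, longer than twice the 50-gene
chaining gap, because a shorter inverted segment can be hopped by a parallel
chain through a single mid-segment anchor; and each variant is planted on
chromosomes untouched by earlier variants while any remain, keeping the
planted signals independent (an inversion straddling a translocation
junction fragments differently in differently fractionated subgenomes and
blurs the shared-breakpoint signal).

In `codon_evolution` mode each pair additionally receives a codon alignment
whose NG86 Ks approximates its target: ancestral codons are drawn from
4-fold degenerate boxes in which every codon has exactly one synonymous site
(the Leu CT\* and Arg CG\* boxes are excluded precisely because their A/G
third-base codons gain first-position degeneracy), and the exact number of
third-position synonymous differences implied by the inverse Jukes–Cantor
transform is planted. With 150-codon alignments the realized Ks is within
0.05 of target across the range used.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: nonsynonymous divergence and realistic codon
models; tandem arrays and dispersed duplicates (homology is one-to-one by
construction outside the planted paralog pairs); assembly and annotation
artifacts; overlapping or nested rearrangements; lineage-specific small-scale
duplications that real pipelines must separate from polyploidy-derived
copies. Results on real genomes depend on annotation quality and on the
homology search in ways the synthetic benchmarks cannot probe.

## Problem sizes and numerical choices

The test-suite simulations use 900–3,000-gene genomes for structural and
fractionation properties and 5,000-gene genomes (20 replicates) for the
P-index discrimination, sizes at which every property tested is stable under
reseeding while the whole suite runs in minutes on one CPU; the full
default-scale analysis (`run_pipeline(sim_config())`) takes a few seconds.
Degenerate inputs are handled explicitly: empty pair tables chain to empty
block sets; blocks with no Ks-annotated anchors are flagged rather than
classified; a mixture fit that cannot reach the acceptance R-squared is
returned flagged; an all-length-1 run histogram fits p = 1 exactly;
self-comparisons with no orthologous blocks raise an error in depth-ratio
inference. All stochastic routines take explicit seeds and all tie-breaks
are deterministic, so identical configurations give byte-identical outputs.

## Known limitations

* Block detection has no analytic significance test; very gene-poor regions
  can yield short spurious blocks that the 4-anchor minimum must absorb.
* Breakpoint localization degrades with fractionation (midpoints between
  surviving anchors), so shared-breakpoint grouping can miss heavily
  fractionated subgenome pairs at the default 10-gene tolerance.
* The P-index here is a reconstructed contract, comparable across analyses
  performed with this package but not numerically identical to published
  values computed with the original (under-specified) weighting.
* Internal-WGD dating follows the documented interpretation of a
  self-referential published formula; dates for those events should be read
  with that caveat.
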