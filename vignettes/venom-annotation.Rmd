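---
title: "Annotating venom-gland transcriptomes and screening for novel toxins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating venom-gland transcriptomes and screening for novel toxins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomscan)
```

## The problem

Venom glands transcribe two very different things at once: the ordinary
physiological program of any animal tissue, and a battery of short secreted
toxin genes. Given only an assembled transcriptome, the annotation question
is which transcripts are venom components, which toxin family they belong
to, and which highly expressed transcripts are candidate *novel* toxins that
no database can name. `venomscan` addresses this with two cooperating
procedures: a seven-step annotation pipeline over a venom-gland (telson)
assembly paired with a venom-free control tissue (chela), and a rule-based
novelty screen over the transcripts the pipeline could not identify.

This vignette explains the model behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer should know
about.

## Coverage as an expression proxy

Each transcript's coverage is

$$\mathrm{coverage} = \frac{L_\mathrm{read} \times \mathrm{read\ count}}{L_\mathrm{transcript}}$$

with `avg_read_len = 150` nt by default. This normalizes raw counts by
transcript length so transcripts are comparable within one assembly; it is
*not* a cross-sample normalization (there is no library-size or
housekeeping-gene standardization — single-library designs are the intended
input, and cross-species expression comparisons based on it should be read
qualitatively). Two thresholds key off coverage: the misassembly cutoff
(transcripts with coverage *strictly below* 5 are removed — a transcript at
exactly 5 survives, since removal is "lower than") and the high-expression
rule (a transcript is highly expressed when its coverage is at least 0.5 %
of the summed coverage, `high_expression_fraction = 0.005`).

## The search engine

Every similarity step runs on a built-in local aligner rather than an
external tool, so results are reproducible offline. It is a Smith–Waterman /
Gotoh dynamic program under affine gaps — a gap of length $L$ costs
$g_\mathrm{open} + (L-1)\,g_\mathrm{extend}$ — with one optimal alignment
reported per pair and traceback ties resolved deterministically (diagonal,
then up, then left). Scoring defaults are +2/−3 with gaps 5/2 for
nucleotides and BLOSUM62 with gaps 11/1 for proteins; ambiguity characters
(`N`, `X`) score 0 against everything so they can pad but never reward an
alignment.

Significance uses the Karlin–Altschul formulas,

$$\mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-\mathrm{bit}},$$

with fixed published gapped parameters per scheme (λ = 0.625, K = 0.41
nucleotide; λ = 0.267, K = 0.041 BLOSUM62). Exact parity with other search
tools' E-values is a non-goal: the pipeline's thresholds are calibrated on
this engine's own statistics, and the engine omits edge-effect and
composition corrections and HSP tiling. A seeded exact-k-mer prefilter
(k = 11 nucleotide, k = 4 protein) keeps database scans fast; every search
function takes an `exhaustive` flag that disables it, which the oracle tests
use, and cluster expansion always searches exhaustively because its E ≤ 1
threshold is precisely the regime where borderline homologs live.

"Percent coverage" in the orthologue filter is *query* coverage — the
aligned fraction of the telson transcript — a deliberate reading of an
ambiguous convention, chosen because the telson transcript is the object
being filtered.

## The annotation pipeline

The seven steps run strictly in order: coverage (i), orthologue subtraction
(ii), ORF prediction (iii), database annotation (iv), coverage cutoff (v),
orthologue relabeling (vi), signal validation (vii). Attrition is logged at
each step and the final labels partition the survivors into
`physiological`, `toxin:<family>`, `other_toxin` and `unidentified`. On
fixtures without borderline transcripts, annotating before or after the
coverage cutoff yields the same venom set (the test suite asserts this);
the pipeline nevertheless fixes the order above.

Orthologue subtraction removes a telson transcript only when its best
control-tissue hit passes all three bars (E ≤ 1e−50, identity ≥ 99 %, query
coverage ≥ 95 %) — near-identical housekeeping transcription — while
paralogous toxins at, say, 95 % identity survive. Step (vi) then relabels
surviving transcripts flagged in the orthologue map as `physiological`.
Because removal and relabeling key off the same map, the default `strict`
mode makes step (vi) vacuous by construction (everything flagged was already
removed); a `loose` mode re-tests survivors with query coverage recomputed
over the best ORF span, for assemblies whose untranslated ends dilute the
full-length coverage below the bar. Which behaviour the original procedure
intended is ambiguous; both are exposed, `strict` is the default.

ORF prediction is six-frame and ATG-only, reporting every ATG paired with
its next in-frame stop at span ≥ 75 nt (a common ORF-finder default; the
procedure this reimplements did not state one). ORFs that run off the
transcript end are kept and flagged `open_ended`, since assemblies truncate
3′ ends. Internally coordinates are 0-based half-open on the forward
strand; reports print 1-based inclusive. "Longest ORF" ties break by frame
order +1, +2, +3, −1, −2, −3 then leftmost start, purely for
reproducibility.

## Signal peptides

The built-in predictor is a transparent von-Heijne-style heuristic over the
three classical leader regions, returning a score in [0, 1] with weights
0.2 / 0.5 / 0.3:

* **n-region** (weight 0.2): at least one K/R among residues 2–6;
* **h-region** (weight 0.5): the best 8-residue window within residues
  3–20 must reach mean Kyte–Doolittle hydropathy 1.6, grading linearly and
  saturating at 3.0;
* **c-region** (weight 0.3): small residues (A, G, S, C, T, V) at −3 and
  −1 of a candidate cleavage site within residues 15–35; the first
  qualifying site is the predicted cleavage position.

Scores band as `high` (≥ 0.75), `some` (≥ 0.45) and `low`; the band cutoffs
are package inventions standing in for a qualitative high/some/low
convention. A peptide counts as *having* a signal peptide only when the
h-region component fires **and** the score reaches the presence cutoff
(0.45): the n- and c-components alone sum to 0.5, which a large fraction of
random ORFs reaches, and a leader without a hydrophobic core is not a
signal peptide in this model. Peptides shorter than 15 residues score 0.

Neural-network predictors are deliberately out of scope; an adapter
(`read_signal_predictions()`) imports any external predictor's tabular
output into the same type, and the pipeline behaves identically whichever
backend produced the scores. The synthetic fixtures plant leaders this
heuristic provably detects, so the test suite does not depend on matching
any external tool.

## The novelty screen

Unidentified transcripts at ≥ 0.5 % of total coverage are candidates. For
each, the ORF with the best signal score is chosen (score, then span, then
finder order), and candidates without a present signal peptide are dropped —
secretion leaders are obligatory for toxins. Clustering is single-linkage:
two candidates link iff their mature-region cysteine scaffolds fall in the
same class (equal cysteine count, each inter-cysteine gap within ±2
residues) *and* their leader regions align globally at ≥ 60 % identity. The
metric is an explicit stand-in for an informally described grouping
("signal peptide, C bridges and conserved domains"); both thresholds are
configurable.

Clusters expand against the pooled transcriptomes at E ≤ 1; a hit joins its
best seed's cluster only with a present signal peptide and coverage
*strictly above* 5. Note the asymmetry against the pipeline's own cutoff
(where exactly 5 survives): the two rules are worded differently at their
sources ("lower than 5" removal vs "coverage above 5" admission) and the
package preserves both readings deliberately. Transcripts the pipeline has
already labeled as a toxin family or `other_toxin` are excluded from the
default expansion pool: at E ≤ 1 they otherwise regularly join novelty
clusters and, via their database identity, relabel the whole cluster — the
screen is defined over *unidentified* material, and annotated toxins are
already output.

Each cluster gets a center-star MSA (gap costs 10/1): the center maximizes
summed pairwise global scores, rows merge under once-a-gap-always-a-gap, and
degapping any row reproduces its input exactly. Conserved-residue banding
takes the fraction *f* of gap-free columns where ≥ 80 % of members agree:
`high` at f ≥ 0.5, `some` at f ≥ 0.25; singlets band `high` by the
self-comparison convention.

Identification searches members against a known-protein set and maps the
best hit's description through keyword rules (a configured family-synonym
list → named family member; "toxin"/"venom peptide" → named toxin or venom
peptide; "hypothetical"/"uncharacterized"/"orphan"/"putative" →
hypothetical; otherwise no hit). Classification then applies, in order:

1. named family member → **new toxins in an existing family**;
2. conserved C pattern and (hypothetical / no hit / venom peptide with
   non-high signal) → **novel putative toxin family** (**novel putative
   toxin** for singlets);
3. description mentions "antimicrobial" → **novel putative AMP**;
4. otherwise → **novel putative secreted protein**.

The published 24-row worked example shipped in
`inst/extdata/scorpion_cluster_features.tsv` is not perfectly
rule-consistent; the rule order above maximizes agreement (22 of 24, with
exactly 6 novel putative toxin families) and the two disagreeing rows are
reported as disagreements rather than special-cased. In that transcription,
the conserved-C-pattern flag follows the source table's footnote marker,
which is the table's own definition of the flag and contradicts one cell's
text; `N.A.` band cells are transcribed as `low`, which never affects the
classification of those rows.

## The synthetic-data generator

`simulate_transcriptomes()` emulates the statistical structure the pipeline
assumes: housekeeping transcripts copied into both tissues (optionally
mutated, default rate 0 — exact orthologues), toxin transcripts only in the
telson built as planted leader + family-template mature peptide (mutation
rate 0.06 against the family reference, comfortably above the engine's
detection floor and ≥ 85 % identity; cysteines are never mutated, so the
planted scaffold class is exact), novel families sharing a leader and a
cysteine scaffold but absent from every database, and unstructured noise.
Back-translation chooses synonymous codons uniformly — codon bias is not
modeled — and each transcript is resampled until its planted ORF really is
the longest one, so spurious reverse-strand open-ended ORFs never shadow
the plant. Read counts follow a log-normal depth model
(meanlog 4, sdlog 1; toxins offset +1.5 so they dominate expression, noise
−2 so most of it falls under the coverage cutoff); these are generic
RNA-seq-like magnitudes chosen once for realism at desk scale. Novel-family
read counts are forced above the 0.5 % discovery threshold by default
(disable `force_high_expression` to exercise the exclusion branch).

The default problem size — 20 housekeeping, two toxin families of five, two
novel families of three, 10 noise transcripts — keeps a full
simulate/annotate/discover cycle under ~10 s on one CPU while exercising
every branch. What the generator does *not* emulate: sequencing error and
read-level artifacts, isoform structure, chimeric misassemblies, codon
bias, and realistic database incompleteness. Passing tests therefore show
the *procedures* are implemented correctly and recover planted structure;
they do not certify recall on real assemblies, where orthologue divergence,
fragmented ORFs and database gaps dominate.

The generator self-verifies before returning (planted toxins hit their
family record at E ≤ 1e−5 under the package's own engine; novel members hit
nothing), and fixed seeds give byte-identical output files.

## Numerical choices and degenerate inputs

* Alignment of a pair with no positive-scoring cell returns score 0 and an
  empty alignment, identity and coverage 0.
* Search ties sort by E-value, then bit score, then subject id; equal-best
  representative hits tie-break alphabetically by family name.
* Coverage fractions in a composition report sum to 1 within 1e−9.
* An empty control tissue disables subtraction (nothing is removed); an
  empty known-protein set yields `no_hit` for every cluster.
* Codons containing `N` translate to `X`; `X` never matches in alignments.
* Transcript labels move only forward from `unprocessed`; step (vi) is the
  single sanctioned relabeling.

## Known limitations

The engine reports one alignment per pair (no HSP tiling) and uses fixed
Karlin–Altschul constants, so its E-values differ from tools that estimate
edge corrections — thresholds tuned elsewhere should be re-examined here.
The signal-peptide heuristic is linear and transparent, not a trained
model; its bands are coarse. The novelty classifier inherits the
ambiguities of its worked example (two rows are knowingly irreproducible
under any consistent rule order). Multi-replicate designs, differential
expression and housekeeping-gene-relative normalization are out of scope.
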