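---
title: "Methods: quantifying and reducing adaptor-ligation bias in small RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and reducing adaptor-ligation bias in small RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligbias)
```

## The problem

Small RNA sequencing libraries are built by ligating a pre-adenylated DNA
adaptor to the 3' end of each RNA (truncated T4 RNA ligase 2) and an RNA
adaptor to the 5' end (T4 RNA ligase 1), then reverse transcribing and
amplifying. Both ligases discriminate strongly between substrates, so read
counts from the final library can misrepresent the true abundances of the
input RNAs by orders of magnitude. When the input is a *defined* pool —
every sequence and its concentration known — that bias becomes directly
measurable: each sequence has an expected share of the reads, and the
observed/expected ratio quantifies its over- or under-representation.

`ligbias` implements this defined-pool analysis end to end, the secondary
structure analysis that explains most of the bias, adaptor designs that
reduce it, and a synthetic-data generator that plants a known
structure-driven efficiency model so the whole pipeline can be validated
against ground truth without any external data.

## Normalization model

For a pool of $N$ unique sequences with relative concentrations $c_i$ and
per-sequence annotated read counts $k_i$, the package computes

* normalization factor $f = \sum_i k_i / N$ (annotated reads per unique
  sequence),
* normalized reads $u_i = k_i / f$, which average exactly 1 over the pool,
* expected value $e_i = N c_i / \sum_j c_j$, so an equimolar pool expects
  1 for every sequence, and
* ratio $r_i = u_i / e_i$, the quantity all bias metrics are built on.

The expected-value scaling for non-equimolar mixes keeps the mean expected
value at 1, which makes $r_i$ comparable across equimolar and spread mixes.
Annotation is full-length, zero-mismatch equality in the RNA alphabet:
since pool sequences are unique, a read can match at most one entry, and
anything else (including off-by-one lengths) is counted once as
unannotated, preserving `annotated + unannotated = total`.

Bias summaries follow the conventional bands: *within 2-fold* is the closed
interval $0.5 \le r \le 2$; *more than 10-fold under* is strict $r < 0.1$,
and a sequence with zero reads is included there (it is the limit of
under-representation) but excluded from the log10 spread, which needs
positive values. These inclusivity choices matter only for ratios exactly
on a boundary and are documented rather than configurable.

## Adaptor model and trimming

An adaptor is a defined sequence with at most one run of `N` marking a
randomized region (a pool of adaptors differing only there). The trimmer
anchors on the insert-proximal *defined* segment of each adaptor: rightmost
exact occurrence for the 3' adaptor (inserts may contain the flank
internally; the occurrence nearest the adaptor is the correct boundary),
leftmost for the 5' adaptor, with matching done after `T -> U` conversion.
When the randomized region sits between the anchor and the rest of the
adaptor, a candidate match is only accepted if the distal defined segment
is found at its expected distance — otherwise a random fill that happens to
recreate the flank would shift the cut. When the randomized region is
insert-proximal (or the proximal defined segment is shorter than
`min_flank`, like a single `C` after the N-run), the anchor moves to the
defined segment on the far side and the known number of intervening bases
is removed by length. Reads in which a required flank is not found at full
length are flagged untrimmed and excluded from annotation; `flank_width`
can shorten the anchored segment when partial adaptor matches are wanted.
`min_flank` defaults to 4 nt — anything shorter anchors too ambiguously —
but can be lowered deliberately for toy cases.

## Randomized-region composition analysis

For libraries built on a randomized oligo pool, positional nucleotide
composition is compared between an unligated "input" library and a ligated
"output" library. The package reports, per position and nucleotide, the
normalized nucleotide frequency percentage
$\mathrm{RNnp} = 25 \cdot f_\mathrm{out} / f_\mathrm{in}$ and plots
$\mathrm{RNnp} - 25$, so 0 means no preference. The ratio form is a
reconstruction: it is the simplest definition under which zero deviation
means identical composition, which is the property the quantity is defined
by. Cells with $f_\mathrm{in} = 0$ are emitted as explicit `NA`, never
dropped.

## Structure analysis

Two prediction tasks are kept separate, mirroring the use of two different
programs in practice:

* **Single-molecule folds** (`single_fold_backend()`): the default engine
  is RNAfold with default settings (37 °C). The analysis only consumes the
  *terminal unpaired-base group* — the length of the run of unpaired bases
  at the ligating end, with fully unstructured molecules forming their own
  `"no pairing"` group — which is robust to the choice of MFE predictor.
* **Pair folds** (`pair_fold_backend()`): RNAcofold at 25 °C with the 1999
  Turner parameter set, matching ligation reaction conditions. A joint
  structure is *accepted* only when the dimer MFE is below both monomer
  MFEs (computed under the same settings, i.e. without special treatment
  of the duplex initiation penalty — the simpler reading of the rule);
  otherwise no A:B structure is considered.

A self-contained `"toy"` engine (pair-energy dynamic program: G:C −3,
A:U −2, G:U −1 kcal/mol, no stacking, minimum hairpin loop of 3 intramolecular
bases, no loop minimum across the junction) serves dependency-free runs and
is small enough to validate exhaustively against structure enumeration. Its
energies are on their own scale and are never mixed with Turner energies.
Ties in either engine resolve to the single canonical structure the engine
reports (for the toy DP: a deterministic traceback preferring unpaired
5' bases, then the smallest partner index); no suboptimal ensemble is
considered.

### Junction categories

An accepted cofold is classified by the states of the two bases flanking
the ligation junction (`&`): `paired_inter` (partner across the junction),
`paired_intra` (partner within its own molecule), `loop_unpaired` (a dot
enclosed by at least one pair) or `exterior_unpaired` (a dot enclosed by
none). The 4 × 4 combinations give 16 categories; the package ships a
row-major default numbering (`junction_category_map()`) and every function
takes a replacement table, because published numberings of the same 16
classes are diagram-based and a faithful comparison may require remapping
ids. Four state pairs — exterior on one side with loop or inter on the
other — are geometrically unattainable in well-formed dot-bracket notation
(a pair spanning the junction high enough to enclose one flanking base
necessarily encloses or involves the other), which is consistent with
published category distributions in which four categories never acquire
representatives.

### Enrichment and favorability

Class enrichment uses the signed fraction `(subset − all) / all`, applied
either to output-vs-input libraries or to the well-represented subset
(normalized reads ≥ 0.5) versus the whole pool. A class is called
*unfavorable* at enrichment ≤ −10%, *favorable* at ≥ +20% for cofold
classes or ≥ +5% for single-molecule fold groups, else neutral. Each pool
sequence then carries four attribute slots — 3' fold of the bare insert,
5' fold of the insert with the 3' adaptor appended (the molecule that
actually enters the 5' ligation), and the two cofolds — and
`n_unfavorable` counts its unfavorable slots (0–4). A rejected cofold
contributes a neutral slot: no joint structure is considered, so there is
no structural evidence either way.

The package's default favorability tables encode the qualitative enzyme
preferences (paired terminal base unfavorable; more free terminal bases
favorable; fully unstructured molecules unfavorable for the 5'-end ligase
but favorable for the truncated 3'-end ligase; junction-in-a-broken-loop
cofolds favorable; junction next to an intramolecular stem unfavorable).
Real-data analyses should replace them with calls derived from measured
enrichments (`reproduce_reference_analysis()` does this refit
automatically).

## Adaptor design

* `make_c3_adaptor()` replaces the 3'-terminal *k* bases (default 7) of
  the 5' adaptor with the reverse complement of the 3' adaptor's first *k*
  bases, so the 5' adaptor can pair with the 3' adaptor already attached
  to every insert and pull the junction into a loop regardless of insert
  sequence.
* `make_randomized_adaptor()` inserts an N-run either at the
  insert-proximal end or internally; internal placement keeps defined
  sequence at the junction so insert termini remain identifiable, and must
  leave ≥ 4 defined insert-distal bases for the trimmer.
* `design_targeted_adaptor()` searches, for one target molecule, adaptor
  candidates built by appending the Watson–Crick reverse complement of a
  7-nt target window at offsets 2..6 (leaving unpaired target bases 5' of
  the helix so a loop can break at the junction), cofolds each candidate,
  and returns the first whose accepted cofold matches the requested state
  pair — by default loop-unpaired on both sides. The window search is a
  deliberately minimal deterministic procedure; if no candidate meets the
  request the best accepted candidate is returned flagged `met = FALSE`.
  Watson–Crick-only complementarity is used for design even though the
  folding engine may form G·U pairs when evaluating.

## The planted simulation model

`sim_config()` describes the synthetic study. The generator emulates a
defined pool of 20–25 nt random RNA sequences (equimolar, or a geometric
500-fold concentration spread), adaptor attachment including 6-nt
randomized regions, and multinomial read sampling. Ligation efficiency for
sequence $i$ in a given adaptor context is

$$ \eta_i \;=\; \prod_{s \in \text{4 slots}} m_{\text{call}(i,s)}
   \;\times\; \varepsilon_{i,\text{context}} $$

with default multipliers $m_\text{unfavorable} = 0.15$,
$m_\text{neutral} = 1$, $m_\text{favorable} = 2$, and
$\varepsilon \sim \mathrm{LogNormal}(0, 1)$ drawn once per
(sequence, adaptor context). The multiplicative form is the simplest model
consistent with a cumulative effect of the four attributes; the lognormal
residual represents the sequence-specific ligation variability the four
discrete attributes do not capture. It is needed for realism — observed
single-adaptor libraries show a *continuous* spread of roughly four orders
of magnitude, which 15 discrete multiplier products cannot produce — and
its sdlog of 1 (≈ 0.43 log10 units) was fixed a priori on that argument.
Because the residual is tied to the adaptor context, it is redrawn for
each member of a randomized-adaptor pool, while replicate libraries of the
*same* adaptor reuse it: replicate agreement is then limited only by
multinomial noise, matching the empirical observation that library
replicates correlate almost perfectly while different adaptors reshuffle
representation.

Reads are drawn from a single multinomial with
$p_i \propto c_i \eta_i$. No sequencing error or PCR bias is simulated by
default (amplification steps are known to contribute little, and
zero-mismatch annotation then stays exact); an optional uniform
substitution `error_rate` exists for robustness checks. All randomness
derives from one top-level seed through named substreams, so pool
construction, each efficiency context and each library draw are
independently reproducible.

What passing the simulation tests shows — and what it does not: the
pipeline recovers *planted* efficiencies (regression slope ≈ 1, Spearman
ρ > 0.99 at pool 200 / 2 × 10⁶ reads), group medians fall strictly with
each added unfavorable attribute, and averaging efficiencies over ≥ 16
adaptor variants provably tightens the ratio distribution. None of this
validates the *biological* form of the efficiency model; the planted model
is a test harness, not a claim about ligase kinetics.

## Problem sizes and numerical choices

The shipped test suite runs the invariant checks at desk scale (pools of
10–30 sequences, thousands of reads, toy folding engine), the exhaustive
folding-oracle sweep over all two-letter (G/C) sequence pairs of combined
length ≤ 10 (16 384 pairs), and the full-scale recovery study at pool 200
with 2 × 10⁶ multinomial reads and 16 adaptor variants using the
thermodynamic engine — sizes chosen so a complete run takes about a
minute on one core while the full-scale study still has single-digit
multinomial noise per sequence. At those study conditions the realized
`n_unfavorable` groups typically cover 0–3; the monotonicity check is
therefore asserted over the groups the pool realizes (at least three).
Normalization closure is asserted to 10⁻⁹; percentage partitions to 10⁻⁶;
folding energies are compared exactly in the toy model's integer scale and
to reported precision (0.01 kcal/mol) for the thermodynamic engine.

## Known limitations

* Only MFE structures are used; a partition-function treatment would
  weight structures by occupancy and may classify junctions differently
  for near-degenerate folds.
* The 16-category id numbering is convention; cross-study comparisons of
  category *numbers* require recalibrating the mapping table against the
  other study's diagrams (the state pairs themselves are unambiguous).
* DNA adaptors are folded as RNA after `T -> U` conversion; this inherits
  the approximation commonly made when feeding DNA adaptors to RNA
  (co)folding engines.
* Trimming requires a full flank match; severely truncated adaptors make
  reads fall out as untrimmed rather than being rescued by partial
  matching (`flank_width` can relax this deliberately).
* The planted efficiency model is multiplicative and context-lognormal by
  construction; real ligases need not factorize this way.
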