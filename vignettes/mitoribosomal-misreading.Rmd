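---
title: "Codon composition as a misreading reporter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon composition as a misreading reporter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofidelity)
```

## Background

Ribosomal misreading is the decoding of a codon by a tRNA that is not its
cognate. The dominant error mode is decoding by a *near-cognate* tRNA —
one whose anticodon forms a single mismatched pair with the codon.
A protein whose mRNA contains few cognate codons for a labelled amino
acid but many near-cognate ones is an amplifier: accurate ribosomes
incorporate almost none of the label, error-prone ribosomes measurably
more. Because mitochondria cannot be transfected with reporter genes,
mitoribosomal accuracy has to be measured on such endogenous amplifiers,
and this package exists to find them and to model their response.

The central statistic is the discrimination ratio of an ordered
amino-acid pair $(A, B)$, where $A$ is the misreading-gain label and $B$
the reference label:

$$R \;=\; \frac{NC_A / C_A}{NC_B / C_B}$$

with $C$ the cognate and $NC$ the near-cognate codon counts over the
sense codons of one CDS. The pair is ordered because the assay is
directional (gain of label $A$ against reference $B$); consistently,
$R(A,B)\,R(B,A) = 1$, which the test suite asserts on random counts.

## What counts as near-cognate

Two definitions are implemented in `codon_neighborhood()`, and the
difference between them matters.

**Geometric (`pairing = "any"`).** All codons at minimum Hamming distance
exactly one from the cognate set. This is the natural set-level
definition and the one used for neighbourhood-size reasoning: cysteine
has 14 such neighbours under the standard code, methionine 9 under the
standard code and 14 under the vertebrate mitochondrial code (where ATA
is a Met codon). The test suite checks this definition against a
brute-force 64-codon enumeration for every amino acid under tables 1, 2
and 11.

**Anticodon-centric (`pairing = "anticodon"`, the default for the
reporter statistic).** Misreading is an event at the codon:anticodon
duplex, and each amino acid in the mitochondrial system is read by a
single tRNA species. A decoding event tolerates at most one
non-Watson-Crick pair, and a wobble pair at the third position is itself
a non-Watson-Crick pair. The codons a tRNA can *misread* with exactly one
mismatch are therefore the single-mismatch neighbours of the codon that
pairs the anticodon fully Watson-Crick, with cognate codons excluded. For
cysteine (tRNA anticodon GCA, Watson-Crick codon TGC) this gives
{AGC, CGC, GGC, TAC, TCC, TTC, TGA, TGG}; for methionine (anticodon CAU,
Watson-Crick codon ATG): {AAG, ACG, AGG, ATC, ATT, CTG, GTG, TTG}.
Codons excluded relative to the geometric set are exactly those that
would need a mismatch *and* a wobble pair simultaneously — e.g. CUA for
Met, which combines a C:U first-position mismatch with the A:f5C wobble
at position 34.

The anticodon-centric set is always a subset of the geometric set, so
both satisfy the same neighbourhood invariants. On human MT-CO1 the two
definitions give Cys/Met near-cognate counts of 96/48 (anticodon) versus
130/130 (geometric); the anticodon counts are the ones that make MT-CO1
the canonical Cys/Met reporter with $R = 64.0$, and they are what the
acceptance tests pin down. The Watson-Crick reference codon is chosen per
amino acid by third-base preference C > G > T > A (NNY two-codon boxes
are read by G34 anticodons, NNR and four-fold boxes by U34/C34); it can
be overridden per call with `reference_codon =` when modelling a tRNA
with a different wobble base.

Codons near-cognate to both members of a pair are counted for each
independently; no exclusivity rule is applied.

## Reference data and coordinates

`human_mtdna_genome()` returns the complete human mitochondrial genome as
a circular `genome_record` with the 13 protein-coding genes annotated
under translation table 2. The sequence is the NC_001807.4 record
(16,571 bp) shipped as plain FASTA inside the seqinr package, so the
genome loads with no network access; the CDS coordinate table bundled
with this package uses that record's numbering (revised Cambridge
reference coordinates plus one).

NC_001807.4 differs from the revised Cambridge reference sequence
(J01415.2 / NC_012920) at a small number of mostly synonymous sites.
Both records give identical MT-CO1 results (513 residues, 1 Cys, 32 Met,
near-cognate counts 96/48, terminal AGA, stop-free 69-nt UTR in frames 0
and −1). For MT-CO2 the cysteine near-cognate count computed here is 28,
one below the value of 29 expected on the rCRS and asserted in the
acceptance tests; a single synonymous pyrimidine exchange in a
Tyr/Phe/Ser codon is enough to shift this count by one. The
corresponding MT-CO2 ratio is 3.59 here versus 3.72 from the rCRS
counts. The discrepancy is documented rather than patched: the package
computes from the sequence it is given.

External coordinates follow the GenBank convention (1-based, inclusive,
plus strand); internally the same convention is kept and all strand and
origin-wrap arithmetic is centralised in two tested helpers. Incomplete
stop codons (CDS completed to a stop by polyadenylation, annotated with a
1-2 nt overhang) are handled by dropping the partial triplet and flagging
the CDS `truncated`, so every counting operation sees full sense codons
only. Alternative initiators (ATT/ATC/GTG in table 2) translate as Met by
default, matching protein-level residue counting; this is a flag.

## Stop-codon context and read-through

`stop_context()` scans the 3′ UTR in three frames: frame 0 continues the
CDS reading frame, frame −1 is shifted one nucleotide 5′ (its first codon
borrows the last base of the terminal codon), frame +1 one nucleotide 3′.
Offsets are 0-based from the first UTR base, so frame −1 positions start
at −1.

A design decision worth making explicit: *hungry codons are not
termination stops.* AGA/AGG in the vertebrate mitochondrial code have no
decoding tRNA and are listed in the code's stop set, but they stall the
ribosome rather than recruit the release factor. `stop_context()`
therefore reports release-factor stops (the stop set minus hungry codons)
in `frame_stops` and hungry-codon positions separately in
`frame_hungry`. With this convention the MT-CO1 69-nt UTR is stop-free
in frames 0 and −1 (it does contain an AGG, which appears in the hungry
track), and the −1 triplet at the terminus is TAG — the geometry that
lets a stalled mitoribosome terminate via −1 frameshift while a
read-through ribosome runs into the polyA tail.

`predict_readthrough()` models the construct `CDS + terminal codon +
3′ UTR + polyA`: under `terminal_policy = "decode"` the terminal codon is
decoded under a caller-supplied code (AGA is Arg under the
standard/bacterial code, modelling hybrid-ribosome cell-free systems),
then decoding continues until a termination stop of that code or the end
of the message; a trailing partial codon is not decoded, and a 51-nt
polyA yields 17 lysines. A terminal codon that is a stop under the
decoding code blocks extension unless `suppress_stop` forces
read-through (the inserted residue defaults to Trp, the dominant UGA
read-through identity, and is a parameter).

Molecular weights use average residue masses with one water per chain, no
N-terminal formylation and no initiator-Met excision; each choice is a
flag, and the defaults reproduce 57.1 kDa for the 514-residue expression
construct (native MT-CO1 with an alanine inserted after the initiator)
and 62.1 kDa for its read-through product. Monoisotopic masses are
available via `mass_set`. Masses are compared at a 0.1 kDa tolerance in
the tests, matching one-decimal kDa reporting.

## The misreading model

The incorporation model is deliberately first-order. With per-event
misreading probability $\varepsilon$ (one near-cognate codon decoded by
the labelled tRNA in one translation event), expected labelled counts per
molecule are $C_A + \varepsilon NC_A$ and $C_B + \varepsilon NC_B$, and
the normalised fold change

$$f(\varepsilon) = \frac{(C_A + \varepsilon NC_A)/(C_B + \varepsilon
NC_B)}{C_A/C_B}, \qquad f(0) = 1$$

has slope $NC_A/C_A - NC_B/C_B$ at zero: 94.5 for the MT-CO1 counts,
about 3 for MT-CO2 — the quantitative reason the former responds to
misreading agents and the latter serves as a control. $f$ is strictly
increasing on $[0,1]$ exactly when that slope is positive.

Model simplifications, stated so they can be revisited: $\varepsilon$ is
a single pooled probability (no codon-, position- or tRNA-specific
rates), and only label *gain* at near-cognate sites is modelled — loss of
label at cognate sites misread by other tRNAs is a second-order effect
and neglected. `simulate_incorporation()` is the per-molecule Monte
Carlo counterpart (binomial incorporation at near-cognate sites,
delta-method standard error on the ratio of means) and agrees with the
closed form within three standard errors across the tested
$\varepsilon$ grid at $10^5$ molecules. `fit_epsilon()` inverts $f$ by a
bracketed monotone solve to $10^{-12}$; since $f$ is a Möbius function
of $\varepsilon$ the inverse also has a linear closed form, which the
tests use as an independent oracle. The round-trip error is below
$10^{-8}$ over the tested sweep.

`normalize_dual_reporter()` implements mean-of-ratios normalisation:
per-replicate test/reference signal ratios, fold change as the ratio of
group means, reference group normalised to 1 by construction, SEM and n
reported per group. Mean-of-ratios (rather than ratio-of-means) matches
per-sample normalisation practice in dual-luciferase work. A Welch
t-test convenience (`dual_reporter_t_test()`) compares normalised
ratios between groups.

## Synthetic data: what it emulates and what it does not

The generators exist so that every module can be tested against inputs
with known ground truth:

* `gen_cds()` plants exact reporter counts: requested
  $(C_A, NC_A, C_B, NC_B)$ are realised by drawing placement codons from
  the four disjoint membership pools, accounting for the initiator
  codon's own membership, and padding with filler codons at Hamming
  distance ≥ 2 from both cognate sets — exactness is preferred over
  compositional realism, and infeasible requests fail with the violated
  constraint named. The planting is verified against an independent
  counting loop for randomised specs in the test suite.
* `gen_genome()` assembles genes with random spacers, stores
  reverse-strand genes reverse-complemented, and round-trips losslessly
  through `extract_cds()`; `gen_stopfree_utr()` produces UTRs with the
  MT-CO1 no-stop property for read-through constructs.
* `gen_assay()` produces dual-reporter replicates with mean-1
  multiplicative log-normal noise parameterised by a coefficient of
  variation — signals are positive and ratio-scaled like luciferase
  readouts. With `noise_cv = 0` the normalised fold change equals the
  generative value exactly.

What passing these tests shows is that the statistics and the model are
computed correctly; what it does not show is realism of mitochondrial
base composition, codon-usage bias, tRNA abundance effects, or
position-specific error rates — none of which the generators attempt to
mimic beyond optional codon-usage weights. Conclusions about real
genomes rest on the real-sequence analyses, not on the generators.

All stochastic operations take an explicit seed and restore the global
RNG state, so runs are bit-reproducible; generation of gene $i$ under a
spec seeded $s$ depends only on $(s, i)$.

## Problem sizes and numerical choices

The test suite runs the full 13-gene human scan, exhaustive 64-codon
neighbourhood enumerations for 20 amino acids under three tables, Monte
Carlo simulations at $10^5$ molecules over a four-point $\varepsilon$
grid, and 40 randomised planting specs — a few seconds in total, chosen
so the whole suite stays interactive. Ratios are computed in double
precision (well over the 10 significant digits the statistic needs) and
displayed to one decimal, with the full-precision value always retained
in machine-readable output. Undefined ratios ($C_A$ or $C_B$ zero) and
infinite ratios ($NC_B = 0$) carry explicit flags and are never encoded
as sentinel numbers; ranked output lists them separately.

## Known limitations

* The near-cognate default encodes single-tRNA decoding with a
  heuristic Watson-Crick reference codon; organisms with multiple
  isoacceptors per amino acid, or modified wobble bases with different
  pairing ranges, need an explicit `reference_codon`/`anticodon` choice
  per tRNA.
* No wobble-position weighting, tRNA-abundance weighting, kinetic
  proofreading, or frameshift-efficiency model: the geometry is
  predicted, not its kinetics.
* Spliced CDS are rejected by design (mitochondrial genes are
  unspliced).
* Molecular weights are chemical formula masses, not gel-apparent
  masses.
* $\varepsilon$ recovery assumes the first-order model; at large
  $\varepsilon$ or for proteins where label loss is substantial the
  estimate is a lower bound.
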