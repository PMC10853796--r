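---
title: "Splicing signals of metal-coordinating exons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing signals of metal-coordinating exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalsplice)
```

## The scientific problem

Divalent metals bind proteins in a universal stability order (the
Irving–Williams series): Ca²⁺ and Mg²⁺ form the weakest complexes, Cu²⁺
and Zn²⁺ the tightest. Coordination chemistry therefore constrains amino
acid choice — Cys and His for tight metals, Asp and Glu for weak metals —
and, because exons encode both protein and splicing information, it
indirectly constrains the exonic splicing code. `metalsplice` quantifies
how exons encoding Zn²⁺- versus Ca²⁺-coordinating residues differ in
auxiliary splicing support (ESE/ESS content) and how traditional acceptor
signals (splice sites, branchpoints, polypyrimidine tracts, the −3
pyrimidine) compensate.

## Models and procedures

### Codon-level ESE/ESS scoring

A codon of interest is covered by at most four hexamer windows (starts
−3..0 relative to the codon start). The codon score averages the
enhancer-axis and silencer-axis scores of the non-neutral windows and
reports `ln(mean_ese / mean_ess)`. Two undefined states are kept explicit
rather than coerced to zero: `undefined_all_neutral` (every window is
splicing-neutral) and `undefined_no_context` (the codon sits within 3 nt
of an exon end, so fewer than four windows exist). Boundary codons are
dropped by default — they shape the splice-site consensus, not the
auxiliary code, and in genome-scale cohorts they are a few percent of the sample —
but `score_codons(context = "extended")` appends the flanking intron
sequence so they regain full context.

The log ratio requires positive means; tables containing non-positive raw
scores must declare an additive `offset`, because no principled default
exists for shifting a signed score scale.

### Codon frequency profiles

Each hexamer contributes its four complete in-frame triplets
(`codon_tokens()`), so a set of *k* hexamers yields exactly 4*k* tokens —
an identity asserted exactly in the tests (1182 → 4728, 1090 → 4360).
Token counts become frequencies with additive smoothing
`f(c) = (count + α)/(total + 64α)`; the default `α = 0.5` avoids infinite
log ratios for codons absent from one set and is recorded on the result.
`α = 0` is permitted only when no count is zero. The profile normalizes
over codon tokens, not over all hexamer occurrences; this is a disclosed
package choice where two readings are possible.

### Whole-exon profiles

Exons are trimmed of their first and last three nucleotides before
profiling. The exon mean averages per-hexamer `ln(ese/ess)` values
(neutral hexamers excluded). Averaging the logs is the default because it
is robust to a few extreme hexamers and weights windows equally; the
alternative — log of the ratio of averaged scores — is available via
`mean_mode = "ln_of_means"`. Exons longer than 350 nt are excluded from
group comparisons to avoid dilution by terminal and very large exons, and
exons are weighted equally (not by hexamer count) when aggregating.

### Acceptor architecture

Positions are counted with −1 = last intronic nucleotide. The components:

* **Terminal NAG** — last three intronic bases; class CAG/TAG/AAG/GAG when
  the intron ends in AG, `other` otherwise (AT–AC termini flag U12-type
  introns; donor-side U12 matrices are out of scope).
* **Branchpoints** — a transparent 7-mer log-odds weight model with the
  branch adenine at window position 6; every adenine at −60..−13 is
  scored, ties break to the 3′-most position (the dominant human
  positioning). Calls outside −13..−60 are ignored, matching where the
  vast majority of human branchpoints sit. Externally computed calls
  (e.g. from dedicated branchpoint predictors) can be imported from TSV
  and pass through the same window filter; the builtin model exists so
  the pipeline runs with no downloads, not as a reimplementation of those
  tools.
* **AG-exclusion zone** — nucleotides strictly between the nearest
  upstream AG and the 3′ss AG; when no upstream AG exists in the supplied
  sequence the zone is censored at the available scan length. The strict
  "between" anchoring is a disclosed choice; the returned zone is
  guaranteed AG-free and the tests rescan it.
* **PPT score** — published PPT strengths come from predictor internals
  with unpublished formulas, so the package substitutes a transparent
  maximum-sum-subsegment score (T = +1.0, C = +0.5, purines = −2.0) over
  the region strictly between the branch adenine and the 3′ss AG. It is
  non-negative (the empty segment is allowed), monotone under
  purine-to-T substitution, and validated against an exhaustive-segment
  oracle. Comparisons built on it are relative (group A vs group B), not
  absolute.
* **(U)₄ / (C)₄ motifs** — counted with overlaps in the same region;
  fractions use presence, counts report overlaps.
* **−3 association** — for each of the first six exon positions and each
  base, a 2×2 table of −3 T/C by base presence gives an odds ratio
  (Haldane +0.5 correction only when a cell is empty) and a 1-df χ²; the
  per-position maximum-OR base is flagged.

### Splice-site strength

The scoring interface is pluggable: the shipped default is a
position-weight matrix scored as log2 odds against a uniform background
(donor 9-mer: 3 exonic + 6 intronic; acceptor 23-mer: 20 intronic + 3
exonic), and externally derived maximum-entropy score tables load via
`read_site_score_table()` for the lookup path.

### Inclusion and validation

PSI is kept on the 0–100 scale; EST-derived levels are treated
identically. Nothing is imputed — stratum sizes accompany every mean.
Candidate exons for validation are those with mean PSI below 90% in at
least one target tissue (neural, muscle, testis, embryonal stem cells).
The microexon cutoff defaults to 28 nt; no authoritative value exists, so
it is configurable and logged. Validation outcomes are summarized as the
count (and integer percentage) of exons skipping in at least one assayed
transcriptome and in all of them.

### Disorder correlation

Codon-level `ln(ESEf/ESSf)` values collapse to amino acids by a
usage-weighted mean over synonymous codons (equal usage = uniform
weights; stop codons excluded). Weighting is applied in the averaging
over synonymous codons — the alternative (weighting after averaging)
collapses to the same thing only when synonyms agree, so the more general
form is implemented. Pearson correlations against 20-residue disorder
scales use the exact t transform with 18 degrees of freedom. Scales are
used as supplied, with no sign normalization: some published scales
correlate negatively by construction.

### Statistics

All classical procedures delegate to the standard R implementations
(`aov`, `TukeyHSD`, `kruskal.test`, `wilcox.test`, `chisq.test`,
`binom.test`) behind a uniform one-row-tibble result; the package's tests
check them against independent closed-form and enumeration oracles. The
Mann–Whitney test is exact for two samples of at most 8 without ties,
otherwise a tie-corrected normal approximation without continuity
correction. The binomial test defaults to one-sided, which is the form
directional minigene comparisons use; the two-sided p sums all outcomes
with point probability at most that of the observed count. No
multiple-testing correction is applied anywhere by default, matching the
analysis style this pipeline follows; `p.adjust` can be applied to the
−3 association table downstream.

## The synthetic-data generator

The generator exists so every stage has inputs with known truth:

* **Score table** — 1182 enhancer, 1090 silencer and 1824 neutral
  hexamers with positive scores (enhancers `ese > ess` in expectation,
  silencers the reverse). Class membership follows a compositional latent
  (purine-leaning hexamers tend to be enhancers, T-rich ones silencers,
  with Gaussian noise), mirroring the composition bias of the
  experimental resources; without that bias codon usage could not carry a
  splicing signal.
* **Exon cohort** — whole-codon exons of 75–249 nt (within the 350 nt
  comparison cap); coordinating codons from the Zn pool (TGC/TGT/CAC/CAT)
  or Ca pool (GAC/GAT/GAA/GAG) at 20% of slots. Background codons are
  drawn from a per-group exponentially tilted sense-codon distribution;
  the tilt is solved with `uniroot` against the *exact* expected
  per-hexamer log ratio under i.i.d. codon concatenation (marginalized
  over the three frame offsets, neutral hexamers handled as a ratio of
  expectations) so the two metal classes sit `delta` apart (default 0.3)
  in expected exon mean. An unachievable target raises a diagnostic
  error instead of silently under-delivering.
* **Introns** — length 120 by default; a TACTAAC-style branch heptamer
  planted uniformly in −50..−20 (inside the −60..−13 call window and
  upstream of the −4..−18 profile positions); a PPT with per-base
  `P(T) = ppt_u_content` (Zn default 0.55, Ca 0.40, direction matching
  the uridine-richer tracts preceding Zn exons) and remainder mostly C;
  the scan window is kept free of competing adenines so noise-free
  recovery is exact; terminal NAG drawn per group (Ca with a CAG excess,
  Zn with more TAG); U12-type AT–AC termini at 0.2% (Zn) and 3.5% (Ca).
  When the acceptor is TAG the first six exon bases are enriched for the
  +1G +2A +3A +4T +5T +6A haplotype at probability 0.55 per position.
* **PSI** — `100 × Beta(50, 1)` (mean ≈ 98), emulating
  close-to-constitutive inclusion.
* **Disorder scales** — drawn jointly with supplied amino-acid values at
  a target correlation by the Gaussian construction.
* **Validation outcomes** — a synthetic per-exon table constrained to
  match printed summary counts (38 tested, 18 skipping somewhere, 6
  everywhere); no per-exon truth exists to copy, and the table is
  labelled synthetic.

Everything is driven by one root seed split into per-component streams,
so cohorts are reproducible piecewise, and generated files round-trip
losslessly through the package readers.

### What passing tests do and do not show

The generator plants exactly the structure the pipeline measures:
recovery demonstrates internal consistency (scoring, windowing,
calibration, statistics), not biological truth. Real exons have phase
offsets, compositional autocorrelation, overlapping regulatory elements
and non-independent hexamer classes; real PPTs and branchpoints are far
noisier than the sanitized windows generated here. Conclusions about real
genomes require the external resources (experimental hexamer scores,
curated coordination datasets, maximum-entropy tables, genome-wide intron
sets) that the readers accept but the package does not ship.

## Numerical choices and problem sizes

Smoothing `α = 0.5`; branchpoint ties to the 3′-most adenine; empty PPT
segments score 0; undefined codon/exon means are NA and must be dropped
explicitly; RNA input is normalized to the DNA alphabet on entry. The
test suite runs its heavier checks at deliberately modest sizes chosen to
keep the suite quick while leaving comfortable statistical margins:
1000-case scoring oracles, 100-seed power checks at 200 exons per group,
2000-replicate null calibrations at 20 observations per group. The
methods scale linearly in cohort size, so larger runs are a matter of
patience, not code.

## Known limitations

* The builtin branchpoint and splice-site models are transparent
  stand-ins with a pluggable interface; they are not retrained predictors
  and their absolute scores are not comparable to published tools.
* The AGEZ definition (strict between-AG anchoring, censoring at the scan
  edge) is one of several defensible operationalizations.
* Amino-acid-level values depend on the codon-usage table supplied;
  bundled usage is synthetic or uniform.
* U12-type introns are flagged by termini only.
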