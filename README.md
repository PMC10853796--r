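# metalsplice

Human exons carry two codes at once: the protein code and an auxiliary
splicing code of exonic splicing enhancers (ESEs) and silencers (ESSs).
Exons encoding residues that coordinate divalent metals sit at an
interesting intersection of the two: coordination chemistry pins down the
amino acids (Cys/His for a tight binder like Zn²⁺, Asp/Glu for a weak
binder like Ca²⁺ — opposite ends of the Irving–Williams stability series),
and those amino acids pin down codons whose hexamer neighbourhoods differ
sharply in splicing activity. `metalsplice` is a tidyverse-native toolkit
for quantifying that interplay: it scores coordinating codons and whole
exons against hexamer ESE/ESS resources, profiles the traditional acceptor
signals that compensate weak exons (splice-site strength, branchpoints,
the AG-exclusion zone, polypyrimidine-tract composition, the −3 pyrimidine
of the 3′ splice site), aggregates percent-spliced-in (PSI) inclusion
levels, and correlates codon-level splicing propensities with
protein-disorder scales. A fully seeded synthetic-data generator emulates
every input with planted, recoverable structure, so the complete pipeline
is testable offline.

## The quantities at the core

* **Codon score** — for a coordinating codon, the mean ESEseq and ESSseq
  score of the (up to four) overlapping hexamers containing it, with
  splicing-neutral hexamers excluded, reported as
  ln(mean ESEseq / mean ESSseq).
* **Codon frequency profile** — per-codon token frequencies over the
  high-confidence ESE and ESS hexamer sets (reference sizes 1182 and 1090;
  each hexamer contributes its four in-frame triplets), reported as
  ln(ESEf/ESSf) with additive smoothing.
* **Whole-exon profile** — the mean per-hexamer ln(ESEseq/ESSseq) over the
  exon trimmed of its first and last three nucleotides (which belong to
  the splice-site consensus).
* **Acceptor architecture** — terminal NAG class and −3 base; branchpoint
  calls restricted to −13..−60 nt from the 3′ss; AG-exclusion-zone
  length; a maximum-sum-subsegment PPT score (T = +1, C = +0.5,
  purine = −2) between branchpoint and 3′ss AG; (U)₄/(C)₄ motif counts;
  odds-ratio association of the −3 pyrimidine with the first six exon
  bases.
* **Inclusion** — PSI means by exon/tissue/group, microexon exclusion, and
  selection of validation candidates with mean PSI < 90% in a target
  tissue.

Classical tests (one-way ANOVA with Tukey–Kramer, Kruskal–Wallis,
Mann–Whitney U, Mood's median test, Pearson χ², exact binomial) are
exposed as tidy one-row tibbles.

## Worked example

```r
library(metalsplice)

st <- gen_score_table(seed = 7)          # synthetic ESE/ESS resource
co <- gen_exon_cohort(st$table,          # Zn vs Ca cohort, planted delta 0.3
                      n_per_group = c(zn = 200, ca = 200), seed = 3)

prof <- exon_profile(st$table, filter_exons_for_comparison(co$exons))
cmp  <- compare_exon_groups(prof)
glance(cmp)
#> # A tibble: 1 × 6
#>   n_groups     n f_statistic  anova_p h_statistic kruskal_p
#>      <int> <int>       <dbl>    <dbl>       <dbl>     <dbl>
#> 1        2   400        256. 6.78e-45        163.  2.66e-37
cmp$summary
#>   group     n   mean ...
#>   ca      200  0.174
#>   zn      200 -0.107
```

The Ca-exon mean sits ~0.28 ln units above the Zn-exon mean — the planted
group difference — and both the parametric F and the non-parametric H
statistic reject equality overwhelmingly, which is the qualitative pattern
the pipeline is designed to detect: exons encoding weak-metal
(Ca²⁺-coordinating) residues carry stronger enhancer support than exons
encoding tight-metal (Zn²⁺-coordinating) residues.

Acceptor-side signals come from the same cohort:

```r
arch <- acceptor_architecture(co$introns)
dplyr::count(arch, group, terminal_nag)    # CAG/TAG composition by group
plot_ppt_profile(ppt_u_profile(co$introns |> dplyr::mutate(group = "zn")))
```

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` executes every
stage end to end and writes TSV tables plus a JSON summary; identical
config and seed give byte-identical summaries.

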