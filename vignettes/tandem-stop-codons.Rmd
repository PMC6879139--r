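---
title: "Quantifying tandem stop codon overrepresentation in 3' UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tandem stop codon overrepresentation in 3' UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemstop)
```

## The biological question

Stop codon readthrough — the ribosome failing to terminate at a gene's
primary stop codon — produces C-terminally extended proteins that misfold,
mislocalize or get degraded. An in-frame stop codon early in the 3' UTR (a
tandem stop codon, TSC) acts as a backup termination signal that caps the
damage. If TSCs are under selection, genomes should carry more of them near
the primary stop than their UTR base composition produces by chance.

The comparison is sharpest in organisms with reassigned stop codons. Most
ciliates translate UAA/UAG as glutamine, leaving UGA as the only stop: with
a one-codon stop dictionary and A/T-rich UTRs, chance TSCs are rare, so any
selective pressure has to work harder to maintain them — and an excess is
easier to interpret. `tandemstop` measures that excess, compares it across
organism groups, and asks whether it concentrates in highly expressed
genes.

## The measurement

**UTR windows.** For each annotated gene with an ATG start and a stop codon,
the 20 nt immediately downstream of the stop are extracted (reverse
complemented for minus-strand genes) into a per-organism library. A fixed
short window is deliberate: many ciliate 3' UTRs are only ~21–23 nt long,
and the closer a backup stop is to the primary stop, the shorter the
leaked extension. The first 18 nt provide six in-frame triplet positions,
+1..+6; all 20 nt feed the composition estimate, mirroring how the library
is compiled (the 2-nt difference is negligible and documented here rather
than "fixed").

**First-occurrence counting.** Within each window only the *first* in-frame
stop codon is counted: `obs_i` is the number of genes whose first stop sits
at position *i*. A second stop behind a first one adds no information about
backup termination and would double-count genes.

**The null model.** Let `P(B)` be the pooled base frequencies of the
library. Any codon has probability `p_codon = P(B1) P(B2) P(B3)`, and
`p_stop` is the sum over the code's stop dictionary. Treating the six
positions as i.i.d. draws, the first stop falls at position *i* with the
geometric (first-success) probability

$$q_i = p_\mathrm{stop}\,(1 - p_\mathrm{stop})^{i-1}, \qquad
  \mathrm{exp}_i = q_i \cdot n_\mathrm{genes}.$$

**Scores.** `SCO_i = ln(obs_i / exp_i)`; positive means overrepresentation.
The combined score `ln(Σ obs_i / Σ exp_i)` and the observed vs expected
fractions of TSC-bearing genes (`n_with_tsc / n_genes` vs `Σ q_i`)
summarize a genome in one row.

The model's assumptions are worth stating: mononucleotide composition only
(no dinucleotide structure, no position-specific composition), independence
between positions, and one pooled composition per organism. These are the
costs of a null that can be estimated reliably from 20-nt windows.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_nt` | 20 nt | UTR window; must be ≥ 18 so six triplets fit |
| positions scanned | 6 | in-frame triplets tested for stops |
| `alpha_family` | 0.01 | family-wise rate for group tests; Bonferroni over 6 positions gives ~0.0017 per test |
| CAI pseudo-count | 0.5 | count for codons unused in the reference set |
| reference set size | 225 genes | synthetic stand-in for an experimentally determined highly expressed set |

## Statistical procedures

**Group comparisons.** Per UTR position, per-organism SCOs are compared
between groups with a two-tailed Mann–Whitney test. The implementation
switches between the exact rank-sum distribution (both groups ≤ 8, no
ties) and the normal approximation with tie-corrected variance and *no*
continuity correction otherwise. The switch rule is an explicit choice:
realistic group sizes (9, 12, 60 organisms) always use the approximation,
while the exact path keeps small unit-test cases reproducible against
full permutation enumeration. Two samples with no distinct values return
p = 1. Missing per-position scores (an organism with `obs_i = 0`) are
dropped pairwise from that position's comparison.

**Composite species.** When one genus contributes several genomes, its
profiles can be averaged position-wise into a single composite
pseudo-organism (`composite_average()`) before testing, so a well-sampled
genus does not dominate a group.

**CAI and expression.** Relative adaptiveness `w` is codon usage in a
highly expressed reference set scaled by the most-used codon of each
synonym family; CAI is the geometric mean of `w` over a gene's codons.
Two details matter under reassigned codes: former stops are scored inside
their new amino acid's family (TAA/TAG join glutamine's family under
UAR→Gln, so AT-rich glutamine usage is captured rather than discarded),
and families with a single codon carry no bias information, so they are
skipped in the geometric mean. Genes are sorted by CAI and cut into four
contiguous quartiles with sizes as equal as possible; when the count is
not a multiple of 4 the spare genes go to the outer quartiles first
(order 1, 4, 2, 3), which reproduces the 6625/6624/6624/6625 pattern for
26498 genes. Quartile 4 (highest CAI, the expression proxy) is tested
against the genome-wide TSC rate with a df = 1 chi-square goodness-of-fit
without continuity correction; the statistic is reported unrounded and
rounded.

## Numerical choices and degenerate inputs

* Natural logarithms throughout; scores are printed to 3 decimals.
* `obs_i = 0` yields `SCO_i = NA` rather than −∞; counts are carried
  alongside so downstream tests can drop missing scores. Genome-scale
  data never hits this case, tiny simulations can.
* `exp_i = 0` with `obs_i > 0` (a composition assigning zero probability
  to every stop while stops are observed) is an error, not an NA: the
  null is misspecified for that library.
* UTR windows containing N are excluded entirely (and counted), keeping
  observed and expected counts defined on the same gene set.
* Ties in CAI keep input order when assigning quartiles, making the split
  deterministic.
* For multi-isoform genes the isoform with the longest total CDS is kept
  (ties: first in file) — one UTR per gene matches the per-gene counting.
* GFF dialects that exclude the stop codon from the CDS are detected
  per-gene: if the CDS-terminal triplet is not a stop under the organism's
  code, the 3 nt immediately downstream are tested; genes failing both
  checks are excluded as unresolvable rather than repaired.
* UGA→Cys codes share the TAA/TAG stop set with UGA→Trp codes; the SCO
  pipeline depends only on the stop dictionary, so the two differ only in
  which synonym family TGA joins for CAI.

## What the synthetic generator emulates

`synthetic_spec()` + `generate_genome()` build multi-contig genomes
(both strands, ~35% minus) in which each gene is ATG + sense codons (no
in-frame stops under the chosen code, so UAA/UAG appear freely inside
ciliate CDSs as glutamine) + a stop codon + a 20-nt UTR. The controllable
structure:

* **Composition**: UTR bases are i.i.d. from a stated profile; the
  `"ciliate_like"` preset (A = T = 0.35, G = C = 0.15) reflects typical
  A/T-rich ciliate UTRs, `"balanced"` is uniform.
* **Planted enrichment**: a chosen fraction of genes is forced to have its
  first stop at a chosen position; earlier triplets are rejection-sampled
  stop-free, the stop codon itself is drawn proportionally to its
  composition probability. Plantings perturb realized composition
  slightly; this is acceptable because composition is re-estimated from
  the realized library, exactly as the pipeline does on real data.
* **Codon bias**: per-gene bias levels run linearly from 0 to
  `codon_bias_gradient`; at bias *b* each family's preferred codon is
  drawn with probability `b + (1-b)/k`. The reference generator uses
  bias 1, standing in for an experimentally determined highly expressed
  set.
* **Expression coupling**: `tsc_bias_by_expression` plants TSCs with a
  higher probability in the top bias quartile, emulating
  expression-dependent selection.

One seed drives all randomness; identical specs produce byte-identical
files, and the seed is recorded in the truth-table header.

What it does **not** emulate: introns in the generated annotation (the
reader supports spliced CDSs, the generator does not emit them), real
ciliate gene architecture (macronuclear nanochromosomes, scrambled genes),
dinucleotide or positional composition structure, UTR-length variation, or
overlap between genes. Passing tests on synthetic data therefore validate
the *inference machinery* — extraction, counting, null calibration, test
behavior — not the biological realism of any particular genome.

## Validation design and problem sizes

The test suite pairs every counting path with an independent oracle:
observed counts against a brute-force character walk over 1000 random
libraries; exact Mann–Whitney p-values against exhaustive permutation
enumeration for all group sizes up to 7; the geometric masses against
`1 - (1-p)^6` and against direct Monte-Carlo simulation of i.i.d. stop
draws. Calibration studies use 200 null genomes of 2000 genes (the mean
combined SCO must sit within 3 standard errors of 0), a 5000-gene genome
with a planted 10% first-position excess (the estimated `SCO_1` must match
the closed form `ln((f_1 + (1-f_1)p_stop)/p_stop)` within 3 SE), and 1000
null replicates of the group test at sizes 9 vs 12 (type-I rate within 3
binomial SE of 0.05). These sizes give each check enough resolution to
fail meaningfully while keeping a full run to a few minutes.

For the expression-coupling check, TSCs are planted at 15% in the top
codon-bias quartile vs 10% elsewhere. Quartiles of 5000 genes give the
subgroup-vs-genome chi-square essentially full power at α = 0.001 under
this effect; at much smaller genome sizes the same effect is *not*
reliably detectable at that level, because the natural stop background
and the subgroup's own contribution to the genome-wide reference dilute
the signal — a useful reminder that the quartile test's power depends on
genome size, not only on the planted effect.

## Known limitations

* The composition null ignores selection on non-stop UTR features
  (termination-context hexamers, structure, miRNA sites); depressed SCOs
  in standard-code organisms may reflect selection *for* such features
  rather than against TSCs.
* Genes are excluded, never repaired: annotations whose CDS terminus
  cannot be reconciled with a stop codon drop out and are only visible in
  the exclusion log.
* CAI is a proxy for expression; the package does not quantify expression
  from sequencing data.
* Ambiguous, context-dependent stop codons (as described in some
  heterotrich ciliates) are outside the model: a codon either terminates
  or it does not.
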