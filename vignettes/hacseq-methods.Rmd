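---
title: "Calling m3C sites from chemical-cleavage sequencing: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m3C sites from chemical-cleavage sequencing: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hacseq)
options(hacseq.verbose = FALSE)
```

## The measurement

3-methylcytidine (m3C) carries its methyl group on the Watson–Crick face of
cytidine. Hydrazine under high-salt conditions attacks m3C specifically, and
aniline then cleaves the RNA backbone at the attacked base. The chemistry has
a property that turns cleavage into a sequencing signal: the 5′ product of
the scission is left with a damaged 3′ end that cannot be adapter-ligated,
while the 3′ product keeps a ligatable 5′ phosphate. After library
preparation only full-length fragments and 3′ cleavage products are
sequenced, so every realized cleavage at position $i$ contributes one read
whose first aligned base is $i + 1$.

The per-site statistic is the **cleavage ratio**

$$ r_i \;=\; \frac{\text{reads starting at } i+1}{\text{read depth at } i+1}, $$

the fraction of molecules covering $i+1$ that were cleaved at $i$. Because a
read starting at a position also covers it, $r_i \in [0, 1]$ wherever the
denominator is positive; zero depth leaves the ratio undefined (`NA`), which
excludes the site from calling rather than raising an error. With efficient
chemistry and a demethylation step before reverse transcription (which
removes reverse-transcriptase hard stops), $r_i$ is a semi-quantitative
estimate of modification stoichiometry at $i$.

A single treated library cannot distinguish modification-driven cleavage
from random fragmentation background, so three arms are contrasted:

* **Ctrl** — fragmented, end-repaired, never exposed to the chemistry;
* **HAC** — fragmented, then chemically cleaved;
* **DM-HAC** — demethylated first, then chemically cleaved.

A position $i$ is called m3C when all three criteria hold:

1. mean HAC cleavage ratio $\ge$ `r_min` (default 0.5);
2. at least a `fold_min`-fold (default 2.5) increase of HAC over Ctrl,
   significant at `alpha` (default 0.05);
3. at least a `fold_min`-fold decrease from HAC to DM-HAC, significant at
   `alpha` — the demethylase must erase the signal.

Criterion (iii) is what makes the call chemically specific: a cleavage that
survives demethylation (criterion iii fails while i and ii hold) is real
cleavage but not demethylase-sensitive m3C, the behaviour known from C32 of
A36-containing serine isoacceptors.

## Statistical core and numerical choices

The significance test is a two-sided, equal-variance (pooled) unpaired
Student's *t*-test applied to the per-replicate cleavage ratios. Two choices
here were genuinely open and are recorded as the definitions under test:

* **The test operates on replicate ratios, not raw counts.** Ratios are the
  quantity the criteria threshold, and replicate-level variation is the
  relevant error unit for a two-replicate design.
* **Fold changes use means of replicate ratios.** When the denominator mean
  is exactly zero and the HAC mean is positive, the fold component passes: a
  site absent from the control is the ideal positive, and an infinite
  empirical fold should not fail a finite threshold.

Degenerate inputs get explicit rules so that a two-replicate design remains
decisive: if the pooled variance is zero the p-value is defined as 0 when
the group means differ and 1 when all values coincide; with fewer than two
defined ratios in a group the site is untestable and criteria (ii)/(iii)
fail closed. All thresholds are inclusive (`>=` for ratios and folds,
strict `<` for p-values), resolving ties at exactly 0.5 or exactly 2.5 in
favour of the site.

Two guards are additions beyond the three criteria, both exposed in
`calling_config()`:

* `min_depth` (default 20) requires the position after the site to reach a
  minimum depth in **every** library before the site is evaluable. Apparent
  cleavage in thinly covered regions is the dominant false-positive mode;
  sites failing the floor are reported with status `"low_depth"`, never
  silently dropped.
* `p_adjust = "BH"` optionally replaces raw p-values with
  Benjamini–Hochberg adjusted ones computed over all evaluable sites. The
  default is raw p-values, matching standard practice for this assay class.

Calls are not restricted to reference base C by default: the base
composition of called sites is itself a specificity diagnostic (the
chemistry should select C almost exclusively), and pre-filtering would
destroy it. `base_filter = TRUE` opts in; reference `N` is never callable.

## What the simulator models

`simulate_experiment()` executes the library chemistry generatively, per
molecule and in protocol order: stochastic methylation of each planted site
(stoichiometry `s`), demethylation in the DM-HAC arm (efficiency `d`),
random fragmentation (independent per-bond break probability `lambda`,
with fragmentation ends repaired and therefore ligatable), chemical
cleavage of still-marked sites in the cleavage arms (probability `c`,
deleting the marked base and discarding everything 5′ of the 3′-most
realized cleavage), pre-library demethylation of surviving marks (with an
optional residual hard-stop probability `rt_stop`), and size selection.

Defaults are chosen to emulate a ribo-depleted total-RNA experiment: two
replicates per arm; `lambda = 1/200`, putting the mean fragment near 200 nt
for long RNAs while leaving tRNA-length molecules mostly intact;
`cleavage = 1`, since the protocol drives the chemistry to completion;
`rt_stop = 0`, because demethylation precedes reverse transcription (the
knob exists to probe criterion (iii) robustness); retained fragments of
15–300 nt. The built-in `synthetic_trna_set()` provides 13 synthetic
tRNA-length references named after the m3C-carrying human isoacceptors,
with 17 modifiable cytidines at the canonical structural positions (C32
anticodon loop, C47d variable loop, C20 D loop), each in a planted `GGNCU`
context; `synthetic_m3c_truth()` plants high default stoichiometries
(0.75–0.98) and offers demethylase-resistant and low-stoichiometry variants
mirroring the two characteristic failure modes.

Useful closed forms follow from the model. With `lambda = 0` and a single
site, the HAC-arm cleavage ratio at the site estimates `s * c` with
binomial error; with two sites on one molecule the 5′ site's **depth** is
reduced by cleavage at the 3′ site (those reads are lost entirely), yet the
ratio still estimates the 5′ site's own cleavage probability because
numerator and denominator are conditioned on the same surviving molecules.

The simulator deliberately omits base-level sequencing errors, quality
scores, PCR duplication, adapter artifacts and rRNA contamination, and
reads are emitted as exact fragment spans. Passing tests therefore
demonstrate correctness of the counting, statistics and decision logic
under the assay's generative assumptions — not robustness to alignment
artifacts or to misincorporation signatures, which the method does not use.

## Other design decisions

* **Duplicate references are collapsed before counting.** Multiple tRNA
  gene copies share one mature sequence; reads cannot distinguish them.
  Collapse keeps the first-seen id, is deterministic under input order and
  idempotent, and the alias map keeps collapsed ids resolvable, so
  alignments against the uncollapsed reference still count. This aggregates
  per-gene signals into one sequence-level site, which differs from
  per-gene listings.
* **Counting uses standard pileup semantics.** The start is the first
  reference-consumed base (soft clips excluded); depth is
  coverage-by-spanning-reads over the aligned span. Unmapped, secondary,
  supplementary and (by default) reverse-strand alignments are dropped;
  multimappers are counted once via their primary alignment, with no
  fractional assignment.
* **Coordinates are 1-based inclusive internally**; BED output converts to
  0-based half-open at the boundary.
* **Motif windows skip boundary sites** rather than padding them: a padded
  position frequency matrix misstates column frequencies. The skip count is
  reported alongside the matrix, and consensus ties break in `A < C < G <
  U` order.
* **Determinism.** One seeded RNG stream drives the simulator with a fixed
  `(group, replicate, transcript, molecule)` loop order, so identical
  inputs and seed give byte-identical outputs; the reference generator uses
  its own fixed internal seed and restores the caller's RNG state.

## Problem sizes used in validation

The test suite validates counting against a brute-force nested-loop oracle
on random read sets (up to 2,000 reads, 10 transcripts), ratio recovery on
a 5,000-molecule single-site grid over stoichiometry and cleavage
efficiency, and full-pipeline recovery of the 17-site planted map from 13
references at 250–400 molecules per transcript per library — sizes at which
every library still clears the depth floor while the whole suite runs in
well under a minute per file. The same experiments, regenerated from
scratch at a caller-supplied seed, back `scripts/acceptance.R`.

## Known limitations

Stoichiometry estimates are semi-quantitative: without spike-in standards
of known modification fraction there is no absolute calibration, and at a
5′ site the loss of molecules cleaved at a 3′ site thins the denominator,
widening its error. The method cannot separate co-located modifications
that both react with the chemistry, does not use misincorporation
signatures, and inherits the aligner's handling of multimapping beyond the
primary-alignment rule. Finally, the calling procedure assumes equal
replicate structure across the three arms and at least two replicates; it
refuses, rather than degrades, when that structure is absent.
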