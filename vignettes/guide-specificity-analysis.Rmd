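---
title: "Assessing CRISPRi guide specificity with crisprispec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing CRISPRi guide specificity with crisprispec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(crisprispec)
```

## The question

CRISPR interference (CRISPRi) represses a gene by parking a
nuclease-dead Cas protein, fused to repressor domains, near the gene's
transcription start site (TSS). Because the guide RNA tolerates some
mismatches, a guide may also bind elsewhere in the genome; if such a
site sits near another gene's TSS, that gene may be repressed
off-target. A standard way to audit this is to (i) enumerate every
genomic site the guide could plausibly bind, (ii) list the genes with a
TSS near such a site, and (iii) ask which of those genes actually
changed expression in an RNA-seq comparison of guide-treated versus
non-targeting-control (NTC) cells. A target-matched siRNA knockdown,
which shares the biology of losing the target but not the DNA-binding
mechanism, then separates pathway effects from genuine off-target
binding. `crisprispec` implements this audit as a tested pipeline.

## The binding-site model

A candidate site is a protospacer: a genomic window, on either strand,
of the spacer's length, followed immediately on its 3' side (on the
scanned strand) by a PAM matching an IUPAC pattern (default `NGG`, the
SpCas9 motif) with **zero** mismatches. Spacer-versus-genome mismatches
("flaws") are counted by Hamming comparison — substitutions only, no
bulges — and partitioned into:

* the **seed**: the PAM-proximal portion of the protospacer, where
  mismatches disrupt binding most, and
* the **non-seed** remainder.

A site qualifies when all three caps of the budget hold:
seed flaws ≤ 2, non-seed flaws ≤ 2, and total flaws ≤ 4 by default.
The total cap is independent of the regional caps, so tightening it
alone is meaningful. Each parameter is exposed via `flaw_budget()`.

Three modelling choices deserve mention because the underlying
convention varies across tools:

* **Seed length** defaults to 12 PAM-proximal nucleotides, the
  conventional SpCas9 seed; it is a parameter because published
  analyses rarely state it.
* **PAM flaws** are not allowed and do not draw on the mismatch
  budget. The pattern is configurable (e.g. `TTTV` for Cas12a-class
  enzymes) but always exact.
* A genomic `N` always counts as a protospacer mismatch and never
  satisfies a PAM position: an unresolved base cannot be confirmed to
  match.

Coordinates are 0-based half-open (BED convention) throughout, with
the PAM excluded from the reported interval. Output is sorted by
(chromosome, start, strand, guide) so runs are byte-reproducible.

Two independent implementations ship on purpose. `enumerate_sites()`
is the vectorized scanner; `brute_force_sites()` re-derives the same
contract as a literal per-position loop (refusing genomes over 1 Mb)
and acts as the oracle in the test suite and in `--verify-oracle`
runs. The acceptance suite compares them on 200 random
genome/spacer/budget triples.

```{r}
genome <- make_genome(c(chr1 = 5000), rng_seed = 1)
sp <- spacer("sg1", "ACGTACGTACGTACGTACGT")
planted <- plant_sites(genome, data.frame(
  spacer = sp$sequence, chrom = "chr1", position = 2000L, strand = "+",
  seed_flaws = 1L, nonseed_flaws = 2L, pam = "TGG"), rng_seed = 2)
enumerate_sites(planted$genome, sp, flaw_budget())
```

## TSS proximity

A site is *proximal* to a gene when the distance between any of the
gene's TSS coordinates and the nearest base of the site interval is at
most the window (500 bp by default), inclusive at the boundary. The
anchor (nearest edge rather than site midpoint or start) is the most
permissive literal reading of "within 500 bp of a TSS"; the boundary
case at exactly 500 bp is asserted in the tests so the convention
cannot drift silently. TSS strand is carried but unused — no
directional rule is part of the model. Sites flagged on-target (within
500 bp of the guide's declared intended TSS) are excluded before
annotation, so the distinct genes of `annotate_proximal()` are
exactly the "genes proximal to potential off-target binding sites" of
a specificity table.

The spreading check instead anchors at the **midpoint** of the
on-target site and collects genes with any TSS within ±1 Mb
(inclusive), the scale of a topologically associating domain; the
intended target is excluded. Significant genes in that neighbourhood
would indicate repression spreading beyond the target promoter.

## Differential-expression integration

The DE test itself (DESeq or similar) is an input, not recomputed: the
pipeline consumes a per-gene table of log2 fold change, p-value and
adjusted p-value. A gene is *significant* when |log2FC| > 1.5
(strictly) and p < 0.05 (strictly). Published descriptions of such
tables alternate between raw and adjusted p at the 0.05 cut;
`thresholds()` defaults to the adjusted p-value — the more
conservative choice — with `use_adjusted = FALSE` available. When
adjusted values are requested but entirely absent, the call falls back
to raw p with a warning rather than failing.

The report for one comparison is assembled by `build_report()`:

* `candidates` — significant ∩ proximal genes;
* `pathway_attributed` — candidates also significant in the
  target-matched siRNA comparison (orthogonal mechanism, so their
  change is most plausibly downstream of target knockdown);
* `possible_offtarget` — the remaining candidates, the genes whose
  change could reflect off-target guide binding;
* `neighborhood_flagged` — significant genes within ±1 Mb of the
  on-target site;
* `pearson_r` — Pearson correlation of log2(TPM + 1) between treated
  and control across shared genes, excluding the intended target. The
  pseudocount of one is added before the log; the correlation is on
  natural (not ranked) values.

The first two gene lists always partition the candidates — a property
the test suite asserts on random sets.

## The synthetic study

Nothing here requires external data: the `synthetic_data` module
builds every input with planted truth. `simulate_study()` emulates the
statistical structure such an audit assumes:

* a two-chromosome random genome (20 kb each, GC 0.41, the human
  average) — small enough that the literal oracle can verify every
  planted edit in seconds;
* one guide whose perfect-match site is planted on `chr1` within
  500 bp of the target gene's TSS;
* in-budget off-target sites and over-budget decoys planted on `chr2`
  with chosen (seed, non-seed) partitions on both strands; after
  editing, the whole genome is re-scanned with the oracle and the
  planting is redrawn with the next seed if an accidental extra
  in-budget site appeared;
* TSSs for two *pathway* genes and one *off-target* gene placed within
  500 bp of distinct planted sites; null-gene TSSs on a jittered grid
  kept at least 600 bp from any in-budget site;
* matched CRISPRi and siRNA DE tables (default 1200 genes):
  the target is planted at log2FC −3.5 in both tables, pathway genes
  near −2.2 in both, the off-target gene near −2.2 in the CRISPRi
  table only; null genes get log2FC ~ Normal(0, 0.4) and uniform
  p-values, with Benjamini–Hochberg adjustment computed over each
  table. Uniform null p-values are generated directly rather than by
  simulating counts, because DE testing is outside the model; this
  makes the raw-p false-positive rate exactly calibrated at α, which
  the null-calibration check exploits.

```{r}
study <- simulate_study(rng_seed = 1)
report <- run_specificity_pipeline(study$genome, study$guides,
                                   study$tss, study$de, study$sirna_de)
report
```

With the default parameters the planted truth is recovered exactly:
the two pathway genes are attributed to target knockdown, the single
planted off-target gene remains, and nothing within 1 Mb of the target
is significant. The acceptance suite repeats this over 20 seeds.

What the generator does **not** emulate: realistic genome composition
(repeats, homopolymers, segmental duplications that dominate real
off-target lists), correlated expression noise, count-level DE
uncertainty, or multi-mapping artefacts. Passing tests therefore
demonstrate that the *arithmetic* of the audit is correct under its
stated model, not that any particular genome-scale screen is clean.

## Readout arithmetic

`relative_expression()` implements the double-delta-Cq method:
2^−ΔΔCq with ΔΔCq = (Cq_target − Cq_housekeeping)_sample −
(Cq_target − Cq_housekeeping)_NTC. The housekeeping gene (GAPDH,
ACTB, ...) is a column selection, not a constant. Technical replicate
wells are averaged on the Cq scale before the formula — averaging the
exponentiated values instead would bias the ratio upward, and the Cq
scale is where qPCR noise is approximately additive.
`normalized_readout()` and `percent_knockdown()` cover
control-normalized fluorescence readouts.

```{r}
relative_expression(21, 20, 20, 20)   # one extra cycle = half expression
percent_knockdown(30, 200)            # 85% repression
```

## Numerical and design notes

* **Determinism**: every generator takes an integer seed and restores
  the RNG state afterwards; identical seeds give byte-identical
  fixtures.
* **Degenerate inputs**: spacers with IUPAC ambiguity codes are
  rejected; chromosomes shorter than spacer + PAM yield no sites
  rather than erroring; zero-variance expression vectors return `NA`
  from the correlation with a warning; a DE table with no adjusted
  p-values falls back to raw p with a warning.
* **Problem sizes**: the shipped checks use genomes up to 10 kb for
  the randomized oracle comparison, 20 kb fixtures for planted-site
  recovery, and 1000–1200-gene DE tables — sizes at which the literal
  oracle remains fast while every code path (both strands, every flaw
  partition, boundary distances) is exercised.
* **Known limitations**: no bulge-tolerant search, no off-target
  cleavage scoring (CFD/MIT), no transcript-isoform modelling (one
  TSS row per gene per position), no qPCR efficiency correction, and
  genome scanning is desk-scale rather than indexed — all deliberate
  non-goals.
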