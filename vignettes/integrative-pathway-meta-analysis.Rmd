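---
title: "Methods: integrative pathway meta-analysis of GWAS and regional expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative pathway meta-analysis of GWAS and regional expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmeta)
```

## Overview

`pathmeta` tests whether a genetic study and a transcriptional study of the
same disease converge on the same biological pathways. Four statistical
stages are chained: (1) SNP-to-gene window mapping turns GWAS summary
statistics into query/reference gene lists; (2) a within-subject subtraction
design turns a Braak-staged expression panel into a differential gene list;
(3) each list is tested per pathway with the hypergeometric upper tail; and
(4) the two per-pathway p-values are combined by Fisher's method with
Bonferroni correction. This vignette explains each stage's assumptions, the
parameters that matter, the numerical edge cases, and what the synthetic
validation does and does not establish.

## SNP-to-gene mapping

A SNP at position $x$ is assigned every protein-coding gene whose interval
$[\mathrm{start}, \mathrm{end}]$ intersects $[x - w, x + w]$ with
$w = 20{,}000$ bp (`window_bp`). Coordinates are 1-based and inclusive at
both ends, and the intersection is inclusive at exactly $w$: "20 kbp on
either side" is read as a closed interval. The default reflects the
observation that most regulatory variation affecting transcript levels lies
within 20 kbp of the transcript. When the window is empty — the SNP sits in
a gene desert — the nearest gene strictly left and strictly right of the SNP
are both assigned, whatever their distance, because desert SNPs often tag
distal enhancers; distance is $\min(|x-\mathrm{start}|, |x-\mathrm{end}|)$
and an exact tie on one side resolves to the smaller `gene_id` so the output
is deterministic. A gene overlapping the window always wins: the fallback
never fires alongside the window rule. SNPs on chromosomes absent from the
annotation produce an empty assignment and a warning with a count —
annotation mismatches should be visible, not silently dropped.

Gene lists are unions over SNP assignments, so a gene tagged by a cluster of
SNPs in linkage disequilibrium is counted once. The query uses the
`top_snp_count = 5000` SNPs with $p <$ `snp_p_threshold` $= 0.01$ (strict,
matching the selection rule "most significant association (p<0.01)"); the
reference uses every SNP. Because the query SNPs are a subset of the
reference SNPs, the query gene list is automatically a subset of the
reference list.

## Within-subject regional differential expression

The panel holds $\log_2$ expression (GCRMA-style output; the readers never
transform values) for every gene in every subject in five regions ordered by
Braak stage: DMV, LCER, SNGRA, PTMN, INSLA. The design compares *adjacent*
regions within one person, so each subject is their own reference for agonal
state, RNA quality and similar sample-level confounders, and subjects at
different stages of degeneration are never averaged against each other. Five
regions give four subtractions per subject,
$\Delta_s(g, r_i{\to}r_{i+1}) = x_s(g, r_{i+1}) - x_s(g, r_i)$.

Controls undergo the same subtractions and are treated as replicates: their
per-gene, per-pair mean $\bar\Delta_c$ and sample standard deviation $s$
(with $n-1$ denominator) summarise the *normal* inter-regional variation.
Each case delta is adjusted, $\Delta_\mathrm{adj} = \Delta_s - \bar\Delta_c$,
and referred to the control spread:

$$z = \frac{\Delta_\mathrm{adj}}{s\sqrt{1 + 1/n_c}},$$

with a two-sided normal p-value. The $\sqrt{1 + 1/n_c}$ factor propagates
the sampling error of the control mean estimated from $n_c$ replicates.
Classical two-group tests (t-test, one-way ANOVA) are not applicable here —
each subject and each region is unique, there is no replication within a
(subject, pair) cell — so referring a single adjusted delta to the control
replicate distribution is the natural test, and we document it as an
interpretation rather than a prescribed formula. Its known cost: with
$n_c = 4$ controls the spread estimate has 3 degrees of freedom, and a
normal reference on a 3-df-studentised statistic is heavy-tailed, i.e. the
per-stratum false-positive rate is inflated relative to its nominal level.
The calibration checks below quantify this; we keep the normal reference
because the design intends a descriptive screen whose downstream consumer
(pathway enrichment) compares the list against the same universe, not a
per-gene error-controlled discovery list.

Benjamini–Hochberg is applied across genes *within each (subject, pair)
stratum*, mirroring the per-individual, per-subtraction workflow; calls
require both $q <$ `q_threshold` $= 0.05$ and
$|\Delta_\mathrm{adj}| \ge \log_2($`fold_change_threshold`$)$ with the
default 1.6 interpreted on the linear scale
($\log_2 1.6 \approx 0.678$). Genes with $s = 0$ in a stratum are uncallable
— p is set to 1 and a count is reported — rather than infinitely
significant. The up and down lists are unions over strata; the merged list
(their union, each gene once) is what enters the expression-side pathway
analysis. The test is applied once, after control adjustment; applying a
per-individual screen both before and after the adjustment is a defensible
alternative reading of the workflow, but a single post-adjustment test is
the cleaner design and the one implemented.

## Pathway over-representation

For a query of size $n$ drawn from a reference universe of size $N$, a
pathway with $K$ members in the universe and $k$ in the query is scored by
the upper tail $P(X \ge k)$ of the hypergeometric distribution — inclusive,
the standard over-representation convention. Evaluation goes through the
log-space hypergeometric CDF, exact to well below $10^{-12}$ for any
configuration the tests enumerate ($N \le 30$) and stable deep in the tail
at realistic sizes. Query genes outside the reference are trimmed with a
message (they would make the urn model incoherent); pathways with $K = 0$
are reported as untested rather than given $p = 1$, so a pathway absent from
a platform is distinguishable from one present but unenriched; an empty
query warns and yields $p = 1$ everywhere. No minimum pathway size is
imposed beyond $K \ge 1$, and no multiple-testing correction is applied at
this stage — only the meta-analysis p-values are corrected. Significance for
the overlap view is inclusive, $p \le$ `pathway_alpha` $= 0.05$.

## Meta-analysis

Per pathway, $X^2 = -2(\ln p_\mathrm{gwas} + \ln p_\mathrm{expr})$ is
referred to $\chi^2$ with 4 degrees of freedom (two independent tests, two
each); for two inputs this has the closed form
$p_\mathrm{meta} = p_1 p_2 (1 - \ln p_1 p_2)$, which the test suite uses as
an independent oracle. Inputs must be in $(0, 1]$; upstream rounding
slightly above 1 is clamped with a warning, and $p \le 0$ is an error.

Only pathways testable ($K \ge 1$) in **both** studies are combined; their
count $M$ is the Bonferroni multiplier, $p_\mathrm{corr} = \min(1, M\,
p_\mathrm{meta})$, and the rest are listed as uncombined. This choice — the
tests actually performed, not the full catalogue — is the standard
Bonferroni universe, and it is the only multiplier consistent with the
published PD table bundled in `inst/extdata/`: all twenty printed
(combined, corrected) pairs imply an integer factor of 201, not the 205
human pathways the catalogue held. `infer_bonferroni_multiplier()` recovers
that factor as the rounded median of the uncapped ratios, and
`reported_pd_meta()` exposes the table. Ranking is ascending in
$p_\mathrm{meta}$ with ties broken lexicographically by pathway id; ranks
are invariant to $M$.

Equal weighting of the two studies is a known limitation of Fisher's method
here: a large GWAS and a small expression panel contribute symmetrically.
Weighted combinations are deliberately out of scope.

## The synthetic study

The generator (`simulation_spec()`, `gen_study()`) exists so every stage has
ground truth. Its default — frozen once, before any end-to-end measurement —
is: 2,000 non-overlapping protein-coding genes on 4 chromosomes with
exponential lengths and gaps (mean 10 kbp each, a gene-dense genome that
keeps every gene reachable by some SNP); 200 pathways with sizes uniform on
20–100 genes, of which PW001 is planted with exactly 50; 20,000 SNPs placed
uniformly, drawing $p \sim \mathrm{Beta}(0.2, 1)$ within 20 kbp of a planted
gene and $p \sim U(0,1)$ otherwise; and a panel of 7 cases and 4 controls in
which every value is gene baseline ($N(8, 1.5^2)$) + a shared region offset
+ case-only planted drift of 1.0 $\log_2$ per Braak transition +
$N(0, 0.3^2)$ noise. Beta$(a,1)$ was chosen for its closed-form mean
$a/(a+1)$, which the tests check directly; additive region offsets match the
subtraction design's implicit additivity. Each generator seeds its own RNG
stream from `rng_seed` plus a fixed offset, so changing `n_snps` never
perturbs the expression panel, and everything is byte-reproducible under a
fixed seed.

What the synthetic data does **not** emulate: linkage disequilibrium (SNPs
are placed independently), probe-level microarray noise and multi-probe
genes (the contract is one row per gene), realistic allele frequencies,
pathway overlap structure beyond independent sampling, and non-additive or
non-monotone regional expression profiles. Passing the planted-recovery and
null-calibration checks therefore shows the pipeline's statistics behave as
designed under its own model assumptions — not that the defaults match any
particular real cohort's effect sizes, which the underlying studies do not
report.

## Calibration behaviour and problem sizes

Two replicate-level properties are checked (in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, at 50 planted
and 20 null seeds; `analysis/06_calibration.R` runs a lighter narrative
version at 10 and 5):

* **Planted recovery** — the planted pathway must be over-represented
  ($p \le 0.05$) in both single-study analyses and rank first in the
  meta-analysis in at least 90% of studies.
* **Null calibration** — with $a = 1$ and zero stage shift, the median
  pathway p-value in each study must lie in $[0.35, 0.65]$ (the
  hypergeometric's discreteness makes p-values conservative, so the median
  sits somewhat above 0.5), and the differential-call rate must stay within
  an inflation-tolerant bound of 0.08 at $q < 0.05$.

The second point is where the heavy-tailed $z$ shows up: under the null the
per-stratum BH step finds a non-trivial number of "discoveries" (the
measured call rate is a few percent, within the bound above), which in turn
keeps the null merged list large and the expression-side enrichment
p-values well calibrated. The flip side is contamination under signal: in a
planted study a substantial fraction of non-planted genes also enters the
merged list. The pathway stage absorbs this because contamination is
spread uniformly over the universe while planted genes concentrate in one
pathway — the planted pathway's overlap is complete ($k = K$) and its
p-value separates from the field by many orders of magnitude. Consumers of
the *gene-level* lists, as opposed to the pathway ranking, should treat
them as screens, not error-controlled discoveries.

Unit tests run the generator at reduced scale (300 genes, 3,000 SNPs, 20
pathways) to keep the suite fast; the replicate-level checks above use the
full default scale.

## Degenerate inputs and numerical conventions

* Readers fail loudly with row/line numbers on malformed input; missing
  regions for a subject are an error, never imputed (the subtraction design
  is undefined without them); genes present in only one expression file are
  intersected away with a reported count.
* `p.adjust(method = "BH")` implements the step-up rule; the tests pin it to
  hand-derived values.
* Exactly equal control replicates give $s = 0$: uncallable, reported.
* All randomness flows from explicit seeds; generators restore the caller's
  RNG state.
* Ties: SNP selection breaks p-value ties by `snp_id`; fallback mapping
  breaks distance ties by `gene_id`; meta-analysis breaks $p_\mathrm{meta}$
  ties by pathway id. All outputs are order-independent in their inputs.
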