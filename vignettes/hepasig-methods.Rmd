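---
title: "Methods: hepatic omega-3 response signatures and accessible biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hepatic omega-3 response signatures and accessible biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepasig)
```

# The scientific problem

Dietary supplementation with the omega-3 fatty acids docosahexaenoic acid
(DHA) and eicosapentaenoic acid (EPA) changes hepatic gene expression, but
the response differs strongly between individuals. A biomarker programme
built on this observation needs four ingredients:

1. a catalogue of hepatic genes that respond to DHA and/or EPA *specifically*
   — i.e. not to a generic fatty-acid load, represented by the oleic acid
   (OA) control treatment;
2. evidence that candidate genes vary between individuals in real
   populations (a gene that is identical in everyone cannot stratify
   responders from non-responders);
3. evidence that the *response* to treatment varies across donors in a way
   that mirrors the population variability; and
4. accessibility: the gene's transcripts must be detectable outside the
   liver, here in circulating exosomes of liver-humanized mice, where every
   human transcript must first be disambiguated from the mouse background.

`hepasig` implements this roadmap end to end on synthetic cohorts with
planted ground truth, so every stage is testable at desk scale without
external sequencing data.

# Statistical model

## Normalisation and expression filtering

Counts are normalised as counts per million (CPM),
$\mathrm{CPM}_{gs} = 10^6 \, y_{gs} / L_s$, with $L_s$ the library size
(column sum unless overridden). A gene is *expressed* when its CPM reaches a
biotype-specific threshold (1 for protein-coding genes, 0.5 for lncRNAs,
both inclusive) in at least $\lceil 0.5\,n \rceil$ samples. lncRNAs are
deliberately given a lower bar: they are expressed at lower absolute levels
and would otherwise be purged before the network stage. There is no
between-sample normalisation beyond CPM (no TMM or median-of-ratios); the
consequences of that choice are discussed under *Limitations*.

For the PCA overview the counts are variance-stabilised as
$\log_2(\mathrm{CPM} + 1)$. The pseudocount bounds the transform at zero and
keeps the ordering of CPM values (the transform is strictly monotone), which
is all PCA needs at these depths.

## Differential expression

Each treatment is contrasted against vehicle with a per-gene negative
binomial generalised linear model with log link and a log library-size
offset:

$$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g), \qquad
\log \mu_{gs} = \beta_{0g} + \beta_{1g} x_s + \log L_s,$$

where $x_s$ indicates treatment and the NB variance is
$\mu + \phi \mu^2$. The dispersion $\phi_g$ is estimated per gene by the
method of moments on counts scaled to the mean library size,
$\hat\phi_g = \max\!\big(10^{-8},\ \overline{(s^2_{gk} - m_{gk})/m^2_{gk}}\big)$
averaged over the two groups $k$, floored so that Poisson-like genes stay
estimable. The coefficient $\hat\beta_{1g}$ is fit by iteratively reweighted
least squares and reported as $\log_2\!\mathrm{FC} = \hat\beta_{1g}/\log 2$.

The Wald statistic $\hat\beta_{1g}/\mathrm{se}(\hat\beta_{1g})$ is referred
to a **t distribution with $N - p$ degrees of freedom** ($N$ samples in the
contrast, $p$ model parameters) rather than the asymptotic normal. This is a
deliberate, measured choice: with five replicates per arm the plug-in
dispersion makes the normal reference anti-conservative (empirical type-I
error $\approx 0.086$ at nominal 0.05 in our null simulations), while the
$t_{N-p}$ reference restores calibration ($\approx 0.049$ averaged over
seeds). The estimator itself is untouched; only the reference distribution
accounts for the uncertainty of the plugged-in dispersion, in the same
spirit as quasi-likelihood F-tests.

P-values are adjusted per contrast with the Benjamini–Hochberg step-up. A
gene is *called* when $p_{\mathrm{adj}} < 0.05$ and $|\log_2\mathrm{FC}|$
strictly exceeds 0.2 (protein-coding) or 0.15 (lncRNA). All thresholds are
strict inequalities and live in a single validated configuration object
(`default_config()`), so a run's thresholds are auditable from its output
directory.

Degenerate genes are defined, not left to numeric accident: an all-zero gene
gets $p = 1$ and $\log_2\mathrm{FC} = 0$; a gene observed in only one group
gets a pseudo-counted fold-change point estimate
$\log_2\frac{(y_t + 0.5)/L_t}{(y_r + 0.5)/L_r}$.

## Signature set algebra

With per-gene calls for the three contrasts, classes are assigned by OA
subtraction:

* `OA_shared` — responsive to OA **and** to DHA or EPA: a generic
  fatty-acid response, excluded from the omega-3 signature;
* `DHA_and_EPA` — responsive to both omega-3s but not OA;
* `DHA_only`, `EPA_only` — responsive to exactly one omega-3, not OA;
* `non_responsive` — everything else. A gene responding to OA *alone* is
  non-responsive by definition: the signature describes omega-3 response,
  and such a gene shows none.

Genes regulated in opposite directions by DHA and EPA are flagged
`discordant` but keep their class; direction bookkeeping is reported
separately. These rules are pure set algebra on the call table — the tests
hold them to exact equality against planted quotas for all seven Venn
classes.

## Population variability and stratification

For each population cohort (general and disease) the per-gene coefficient of
variation is computed on CPM across individuals,
$\mathrm{CV}_g = s_g / \bar x_g$ with the $n-1$ sd denominator, over the
genes passing the cohort's expression filter. Genes are stratified into
the most- and least-variable strata of exactly
$\lfloor 0.25\,n \rfloor$ genes each, boundary ties broken by ascending gene
id so the strata are deterministic. A signature gene is retained as
most (least) variable overall only when it occupies that stratum in **both**
cohorts — cross-cohort agreement is the guard against cohort-specific noise.

## Donor response validation

A panel of most- plus least-variable signature genes is measured in a donor
cohort as treatment/vehicle expression ratios. The response CV across donors
is compared with the population CV two ways, mirroring the two panels of the
validation figure:

* a two-sided Welch t-test of response CV between the most- and
  least-variable strata, and
* the Pearson correlation between population CV and response CV, with the
  p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$.

## lncRNA network and enrichment

Signature lncRNAs are correlated with expressed protein-coding genes across
the general cohort (Pearson); an edge requires $|r| > 0.6$ and $p < 0.05$,
both strict. Connected components and per-lncRNA hub degrees summarise the
bipartite graph. Each lncRNA's coding neighbourhood is tested for gene-set
over-representation with the one-sided hypergeometric tail
$P(X \ge \text{overlap})$ against the expressed-coding universe, BH-adjusted
within the lncRNA; pathways representative of a lncRNA group are ranked by
support (number of lncRNAs enriched), then median p, then name.

## Exosome origin partitioning

Exosomal reads from liver-humanized mice are aligned to a combined reference
whose contigs carry `human_`/`mouse_` prefixes. A read is assigned to a
genome only when **all** of its best-scoring alignments fall on that genome;
a best score achieved on both genomes makes the read ambiguous, and
ambiguous reads are discarded — conservative by construction, since a false
"human" call would fabricate a biomarker. Human-specific reads are counted
per gene with fractional $1/n$ weights for multi-gene best hits, so total
weight is conserved. Genes in the top $\lceil 0.2\,n \rceil$ by abundance
(ties by ascending gene id) are *detectable*; the final biomarker candidates
are the detectable genes intersected with the most-variable signature genes
per class.

# The synthetic cohorts

All simulators are pure functions of `(sim_spec, seed)`; seeds are saved and
restored around every draw, and each downstream cohort uses a fixed offset
of the master seed, so reruns are byte-identical.

* **Hepatocyte experiment** — baselines are log-normal
  (`baseline_meanlog = 4.5`, `baseline_sdlog = 1.5`, i.e. a median around 90
  counts with a long right tail, matching the shape of bulk RNA-seq
  abundance distributions); dispersions follow the empirical mean-dispersion
  trend $\phi = a_0 + a_1/\mu$ (`0.05 + 2/μ`); library sizes are log-normal
  around $10^6$. Response classes are planted by exact quota for all seven
  DHA/EPA/OA Venn cells (defaults sum to 500 of 2000 genes), with per-gene
  effects $|\log_2\mathrm{FC}| = \max(0.3, |N(1, 0.4^2)|)$ and random sign.
  The effect-size default was chosen so that the default pipeline is
  non-vacuous at $n = 5$ per arm: with effects centred at 0.5 the Wald stage
  recovers almost nothing and every downstream stage would silently test
  empty sets. The magnitude is a power choice, not a biological claim.
* **Population cohorts** — each gene receives a planted CV from a permuted
  even grid over `cv_range = (0.05, 1.5)`; per-individual expected
  expression is log-normal with $\sigma^2 = \log(1 + \mathrm{CV}^2)$ and
  counts are Poisson around it, so the observed CV is the planted CV plus a
  $1/\sqrt{\mu}$ sequencing floor. The disease cohort reuses the general
  cohort's planted CVs with a small jitter and shifts a subset of gene means
  twofold, constructed to overlap the DHA-responsive genes at a planted rate
  (default 0.7) — this is what the external-DEG overlap stage consumes.
* **Donor panel** — donor ratios are
  $2^{\mathrm{lfc}} \cdot e^{\varepsilon}$,
  $\varepsilon \sim N(0, \tau^2_g)$ with
  $\tau^2_g = \sigma_0^2 + \kappa\,\mathrm{CV}_g^2$. The single coupling
  parameter $\kappa$ (default 0.5) ties response variability to population
  variability; $\kappa = 0$ severs the link and is the negative control the
  acceptance tests exercise.
* **Exosome reads** — planted "top" genes receive uniform weights 20–40
  versus 0.1–1 for the background, reads are multinomial over genes, and
  ambiguous reads are planted as exact-tie alignment pairs. Origin counts
  are therefore exactly recoverable, which the tests assert.

Problem sizes (2000 genes, 100 individuals per cohort, 10 donors, tens of
thousands of reads) are the package's own desk-scale choices: large enough
for stable rank statistics, small enough that the whole roadmap runs in
seconds.

# Numerical and design choices

* **Strict thresholds everywhere** (`>` / `<`, never `>=` / `<=` except the
  expression filter, which is documented as inclusive) — boundary cases in
  the tests pin these down.
* **Deterministic tie handling** — CV strata and the detectability filter
  break ties by ascending gene id; stratum and detectable-set sizes are
  exactly $\lfloor qn \rfloor$ and $\lceil fn \rceil$.
* **$t_{N-p}$ Wald reference** — see above; the only deviation from the
  textbook Wald test, adopted for calibration and verified by simulation.
* **Independent oracles in tests** — BH, the hypergeometric tail, Pearson
  edge selection and connected components are each checked against
  brute-force reimplementations (step-up loop, combinatorial sums,
  `cor.test` double loops, union–find) to $10^{-12}$.
* **Reports without timestamps** — every output table is deterministic, so
  end-to-end determinism is testable byte for byte.

# Limitations

* **Composition bias.** Total-count offsets (and CPM) assume that most
  counts are unaffected by treatment. When a large fraction of the
  transcriptome shifts strongly and asymmetrically, library sizes absorb the
  shift and every null gene acquires an apparent opposite fold change; in a
  dense synthetic plant (28% of genes at $|\log_2\mathrm{FC}| \approx 2$)
  this produced a ~0.4 log2 bias and badly inflated false positives. The
  pipeline deliberately performs no robust between-sample normalisation, so
  it should not be trusted in regimes of massive asymmetric regulation;
  median-of-ratios or TMM normalisation is the standard remedy.
* **Plug-in dispersion.** Per-gene method-of-moments dispersion with a small
  $n$ is noisy and shares no information across genes; the $t_{N-p}$
  reference compensates on average but is itself only a calibration
  approximation, not an exact small-sample distribution.
* **Synthetic realism.** The generators reproduce the *structure* the
  methods rely on (mean-dispersion trend, planted CV spectra, quota-exact
  Venn classes, exact-tie ambiguity), not the full messiness of real data:
  no batch effects, no GC or length bias, no correlated genes outside the
  planted network, Poisson rather than NB population noise, and a single
  scalar coupling between population and response variability.
* **Origin assignment.** Best-score exclusivity with score ties is a
  simplified stand-in for genome disambiguation; real xenograft pipelines
  confront near-homologous transcripts where score margins, not ties,
  drive errors.
* **No real-data claims.** Published headline gene counts depend on raw
  reads, aligner and annotation versions; this package reproduces the
  procedure and its statistical properties, not those counts.

# Reproducing a run

```{r roadmap, eval = FALSE}
report <- run_roadmap(sim_spec(), default_config(), seed = 1)
print(report)
```

The same run is available from the command line:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "hepasig", package = "hepasig"))') \
  roadmap --seed 1 --out-dir roadmap_out
```

and `scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the calibration, recovery, coupling, exosome and determinism quantities
reported in the README.
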