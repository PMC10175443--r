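---
title: "Partitioning technical and biological microbiome variation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning technical and biological microbiome variation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvar)
```

## The problem

Microbiome measurements mix biological signal (who the subject is, when the
sample was taken) with technical noise introduced at DNA extraction and at
library preparation/sequencing. Whether a measurement method can separate
these sources — and how much technical noise each method carries — is best
answered with a nested replicate design: several subjects, sampled on
consecutive days in two separate weeks, with duplicate DNA extractions per
sample and duplicate library preparations per extraction, measured with both
an amplicon-style (16S-like) and a shallow whole-genome shotgun-style
modality on the same extracts.

`microvar` implements that comparison end to end on synthetic data: a
hierarchical community simulator whose variance components mirror the design
levels, a shotgun read profiler implementing the standard post-alignment
annotation rules, diversity computation, a partition of pairwise
dissimilarities into five variation sources, and the accompanying
statistical battery.

## The simulation model

Let $t$ index taxa. Each taxon carries a global log abundance
$g_t \sim N(0, 1)$ and independent Gaussian perturbations at each design
level:

$$
z_t(\text{sample}) = g_t + a_{t,\mathrm{subject}} + w_{t,\mathrm{week}}
 + d_{t,\mathrm{day}} + e_{t,\mathrm{extraction}} + \ell_{t,\mathrm{library}},
$$

with $a \sim N(0, \sigma^2_{\mathrm{subject}})$,
$w \sim N(0, \sigma^2_{\mathrm{week}})$, and so on down the hierarchy. The
measured composition of a sample is the softmax of its $z$ vector, so each
$\sigma$ is the standard deviation of a multiplicative (log-scale) fold
change. The latent biological profile of a subject-day is the softmax of the
biological terms alone.

The two modalities share all biological terms *and* the technical terms
through library prep: the design sequences the same extracts both ways. The
amplicon modality additionally receives

* a **fixed per-taxon log bias** $b_t \sim N(0, \sigma^2_{\mathrm{bias}})$,
  constant across the whole study — modeling amplification bias, which is
  systematic within a protocol; and
* **extra library-level log noise**
  $x_{t,\mathrm{library}} \sim N(0, \sigma^2_{\mathrm{extra}})$ — modeling
  the additional run-to-run irreproducibility of amplification.

Because the fixed bias cancels in within-modality comparisons, it is the
extra library-level term that makes amplicon technical replicates more
dissimilar than shotgun ones; the bias term instead degrades cross-modality
concordance.

Sequencing is a multinomial draw of `read_depth` reads from the measured
composition. Reads are error-free and exactly 100 bp; alignment itself is
out of scope, so the shotgun path emits a post-alignment *hit table*: each
read starts at a uniform position on its taxon's genome, and with
probability `p_tie` it is reported as tied over all genomes of the taxon's
genus (the reference database places two taxa in each genus so such ties
exist). The amplicon path emits denoised features (ASVs) directly, one or
two per taxon, with lineages truncated at genus except for a
`p_species_16s` fraction of taxa — short amplicons rarely resolve species.

### Default parameter choices

The defaults encode the nested design itself (5 subjects, days 1, 2, 8, 9,
2 extractions, 2 library preps; 80 samples per modality) and one fixed
choice of variance components:

| parameter | default | rationale |
|---|---|---|
| `sigma_subject` | 1.0 | between-person differences dominate gut profiles (order-of-magnitude fold changes) |
| `sigma_week`, `sigma_day` | 0.4 | temporal drift is real but well below interpersonal variation |
| `sigma_extraction`, `sigma_libprep` | 0.1 | technical replicates are close but not identical |
| `amplicon_bias_sigma` | 0.5 | amplification bias is large but systematic |
| `amplicon_extra_libprep_sigma` | 0.2 | amplicon technical noise clearly, not overwhelmingly, exceeds shotgun |
| `read_depth_*` | 10,000 | a desk-scale stand-in for millions of reads; multinomial noise at this depth stays below the technical components |
| `n_taxa` | 50 | enough taxa for stable Bray–Curtis values at desk scale |
| `p_tie` | 0.3 | a minority of shotgun reads fall in genus-ambiguous regions |
| `p_species_16s` | 0.3 | a minority of amplicon features are species-resolved |

The ordering subject > day = week > extraction = libprep is the regime the
design is meant to resolve; all replicate-level analyses in the tests and
the acceptance script run at these defaults.

### What the simulator does not model

No sequencing errors, chimeras, contamination, or unequal extraction
efficiency; one genome per taxon (no pan-genomes); taxon perturbations are
independent across taxa (no ecological covariance); reads are drawn
proportional to composition rather than composition × genome length.
Passing tests therefore demonstrate correctness of the *pipeline machinery
and statistical procedures* under a clean compositional noise model — not
robustness to the full messiness of real sequence data.

## The shotgun profiler

Four rules, applied in order:

1. **Capitalist tie-breaking.** Reads tied over several genomes are
   assigned so as to minimize the number of distinct OTUs invoked — a
   minimum hitting set, approximated greedily (repeatedly take the genome
   covering the most unassigned reads; ties between genomes broken
   lexicographically). Exact minimization is NP-hard; on small instances the
   greedy solution is verified against exhaustive search in the tests.
2. **LCA assignment.** For taxonomy, each read receives the deepest lineage
   shared by at least 80% of its tie set — inclusive, so a 4-of-5 consensus
   at species level is assigned the species. Tabulating these per-read
   lineages yields the taxa table, whose resolution thus emerges from the
   tie structure.
3. **Genome-length normalization.** Counts are divided by genome length and
   rescaled by the mean genome length over the OTUs *detected in that
   sample* (not the whole database), keeping per-sample totals comparable.
4. **Filtering**, in the fixed order sample depth → abundance → coverage:
   samples with fewer than 10,000 mapped reads are discarded; OTUs below
   one millionth of all assigned reads are discarded; OTUs with less than
   0.01% of their unique genome regions covered *and* less than 1% of the
   whole genome covered are discarded. The coverage clause is read
   conjunctively — passing either coverage test retains the OTU — and both
   the reading and every threshold are configurable. Filter denominators
   (per-sample mapped depth, study-total assigned count) are frozen at
   tabulation time, which makes filtering idempotent. Every removal is
   logged with its rule and values.

Functional tables count reads hitting annotated genes per KEGG ortholog;
collapsing to enzymes gives each enzyme the full count of every ortholog
mapping to it (a deliberate many-to-many convention), then both tables are
converted to relative abundance. Amplicon tables need only the
taxonomy-collapse step: ASVs with identical lineage strings are summed.

## Diversity

Alpha diversity (Shannon with natural log, bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, observed features) and Bray–Curtis
dissimilarity are computed on tables rarefied to the smallest sample depth
of their modality; rarefaction precedes normalization to relative abundance
(both orderings are available, this one is the default). PCoA
Gower-centers $-D^2/2$ and eigendecomposes; negative eigenvalues
(non-Euclidean input) are excluded from the variance-explained denominator
and carry no coordinates — no Cailliez/Lingoes correction — except inside
the dispersion test, where they enter the distance-to-centroid correction.

## Partitioning variation

Each unordered same-modality sample pair is classified so that exactly one
design variable separates its members:

* **LIBPREP** — same subject, day, extraction; different library prep.
* **EXTRACTION** — same subject, day, library index; different extraction.
* **DAILY** — same subject, consecutive days within one week.
* **WEEKLY** — same subject, days exactly 7 apart.
* **SUBJECT** — different subjects (all cross-subject pairs, any days).

Pairs that vary two technical variables at once, or sit at day gaps of 6 or
8, remain unclassified; daily/weekly pairs span all replicate combinations
since replicate indices are arbitrary labels across days. On the default
design this gives 40/40/160/160/2560 pairs with 200 unclassified, out of
$\binom{80}{2} = 3160$.

Cross-modality genus concordance collapses both taxa tables to genus,
matches samples on their full design coordinates, zero-fills genera absent
from one table, and correlates the pooled sample × genus cells (a
per-sample averaging mode is available). The resolution summary reports,
per rank, the abundance-weighted fraction of the table assigned at that
rank or deeper.

## The statistical battery

All procedures are implemented from first principles (only distribution
tail functions come from base R); established implementations serve as
cross-checks in the test suite.

* **PERMANOVA** (one factor): $SS_{total} = \sum_{i<j} d_{ij}^2 / n$,
  within-group analogue per group, pseudo-
  $F = (SS_B/(a-1)) / (SS_W/(n-a))$, $R^2 = SS_B/SS_{total}$; p by label
  permutation with the $(c+1)/(m+1)$ convention, so $p = 0.001$ at 999
  permutations is the floor. An exhaustive mode enumerates all $n!$ label
  arrangements for small $n$ and reports the exact fraction. On
  one-dimensional Euclidean distances the pseudo-F equals the classical
  one-way ANOVA F, which the tests exploit as an oracle.
* **Dispersion homogeneity**: samples are embedded by PCoA; the distance of
  a sample to its group centroid is
  $\sqrt{d_+^2 - d_-^2}$ (real minus imaginary axes; negative squared
  values truncated to zero with a warning); a one-way ANOVA F on these
  distances is tested by permuting group labels and recomputing centroids.
  Centroids (not spatial medians) are used.
* **Kruskal–Wallis** with tie correction; **Dunn's post-hoc** z on the
  joint ranking with the tie term, two-sided normal p, BH-adjusted within
  the family of pairs.
* **Two-way ANOVA**, additive (no interaction — the analysis only reports
  two main effects), Type II sums of squares, which coincide with Type I on
  balanced layouts.
* **Student's t-test** with pooled variance, two-sided.
* **Benjamini–Hochberg** step-up adjustment. Note the step-up map is
  monotone and order-equivariant but *not* idempotent — re-adjusting
  already-adjusted values changes them — so the tests assert the former
  properties only.

Reported "R" values from distance-based tests are stored as $R^2$ (the
conventional output column of this analysis).

## Numerical and degenerate-input conventions

Consensus and threshold comparisons are inclusive with a $10^{-12}$
relative guard; permutation exceedance uses a $10^{-8}$ relative epsilon so
ties at the observed statistic count as exceedances. Zero total sum of
squares, zero pooled variance, and zero within-group dispersion variance
yield `NaN` statistics with warnings rather than errors. Rarefaction
refuses depths exceeding any sample's total; Bray–Curtis refuses pairs of
all-zero samples, naming them. All randomness flows from one root seed,
split per stage with small fixed offsets, making every pipeline output
bit-reproducible for a given config and seed.

## Problem sizes

Unit and property tests run on designs of 1–3 subjects and 6–30 taxa; the
convergence check uses one sample at $10^6$ reads; replicate-level analyses
(variance-ordering recovery over 20 replicate studies, modality power over
50, type-I calibration over 500 null datasets at $n = 12$ with 199
permutations) run at the default 160-sample design with 50 taxa and
10,000-read depth. These sizes were chosen so the whole suite exercises
every claim at desk scale.

## Known limitations

The profiler's abundance filter re-expresses "one millionth of all
species-level markers" as one millionth of all assigned reads, since marker
genes are not modeled. Coverage statistics are pooled across samples per
OTU (a per-sample alternative would drop low-prevalence OTUs more
aggressively). The SUBJECT category uses all cross-subject pairs rather
than restricting to same-day pairs. Multi-factor PERMANOVA, blocked
permutations, and phylogeny-aware metrics such as UniFrac are out of scope.
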