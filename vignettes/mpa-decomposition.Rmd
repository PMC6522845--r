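---
title: "Decomposing multi-phenotype association signatures in powerset space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing multi-phenotype association signatures in powerset space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpadecomp)
```

## The model

A multi-phenotype GWAS produces, after significance filtering, a binary
relation between SNPs and phenotypes. `mpadecomp` works with three derived
binary relations:

* **GP** (gene × phenotype): gene *g* contains a SNP significantly
  associated with phenotype *p*;
* **GM** (gene × module): an association module contains a SNP residing in
  *g*;
* **MP** (module × phenotype): *p* is associated with *every* SNP of the
  module.

An *association module* is a maximal set of SNPs whose rows of the GWAS
profile matrix `M` (`M[i, j] = 1` iff SNP *i* is associated with phenotype
*j*) are identical. Modules are found by thresholding the Proportional
Similarity index

$$PS(X, Y) = \frac{2\sum_i \min(x_i, y_i)}{\sum_i (x_i + y_i)}$$

at 1 over all SNP pairs and clustering the resulting graph. Each module is
an observed element of the powerset of phenotypes; together the modules span
a *powerset space* into which genes are mapped by their GM rows. The key
structural fact, checked on every run by `verify_decomposition()`, is the
boolean factorisation

$$GP = \mathrm{bool}(GM \cdot MP).$$

Classification follows directly from GM/MP degrees: one single-phenotype
module = SPA; one multi-phenotype module = Type 1; several modules = Type 2,
flagged *complex* when a member module is itself multi-phenotype. Where a
gene simultaneously shows both patterns (two or more modules, one of them
multi-phenotype) we classify it Type 2 with `complex = TRUE` rather than
Type 1: the classes then partition the gene set, which matches disjoint
class counting downstream, while the complex flag preserves the mixed
pattern. Signature clustering groups genes with identical GM rows — the
same PS = 1 machinery, applied one level up.

### Modelling assumptions

* Associations are consumed as given (summary statistics); the package
  performs no association testing, kinship correction or LD modelling.
* A gene is its annotated span (CDS plus UTRs); a SNP belongs to every gene
  whose span covers its position, regardless of strand, and no flanking
  window is added. SNPs outside all genes never enter `M`.
* "PS = 1" is evaluated as exact equality of binary profile supports, never
  as floating-point comparison against 1. For binary vectors the two are
  mathematically equivalent, and the set form cannot produce tolerance
  artifacts.

## Significance selection

Raw p-values are filtered with a two-stage, family-based procedure in which
each phenotype is one family of tests:

1. each family is summarised by its Simes combined p-value and the families
   are screened with the Benjamini–Hochberg step-up at `q1` (default 0.1);
2. within each surviving family the Gavrilov–Benjamini–Sarkar adaptive
   step-down runs at `q2` (default 7.9e-6), with critical values
   $c_i = iq/(m + 1 - i(1-q))$.

The composition of the two published levels into one procedure is a genuine
design choice: the per-phenotype-family two-stage screen is the reading we
adopt as default, and because a global interpretation of the step-down level
is equally defensible, `hierarchical_filter()` also offers a `flat` mode
(one pooled step-down at `q2`) and a `fixed` mode (a plain p-value
threshold) so either interpretation can be reproduced. The mode and both
levels are recorded in the output attributes and in every run report.

## Phenotype quality control

Metabolite intensity distributions are strongly right-skewed, so the outlier
screen computes the median and then a *separate raw MAD for each tail*
(median of distances of values strictly below / strictly above the median).
A value farther than `k = 5` tail-MADs from the median is removed; a
metabolite retaining fewer than `min_valid = 100` non-zero, non-outlier
measurements is dropped entirely (the boundary is inclusive at exactly 100).
Notable numerical choices:

* Raw MADs, no 1.4826 consistency constant — the `k = 5` cut-off is
  calibrated against raw distances; `scale_constant` exposes the constant
  for users who prefer the normal-consistent variant.
* Zeros (non-detections) participate in the median by default
  (`include_zeros`, configurable, since low intensities dominate these
  distributions); they can never be upper-tail outliers and never count
  toward `min_valid` whether flagged or not.
* Values equal to the median belong to neither tail; an empty or zero-MAD
  tail is not screened (with a warning) rather than flagging everything.

## Markov Clustering

`mcl_cluster()` is a self-contained MCL: add self-loops (weight 1), column-
normalise, then iterate expansion (matrix square), inflation (entrywise
power 2.0, the standard default, then renormalise) and pruning (drop
entries below 1e-5, never emptying a column) until the maximum entrywise
change falls below 1e-8 or 200 iterations. Clusters are the connected
components of the symmetrised support of the converged matrix — a reading
that is always a true partition and deterministic; cluster ids are numbered
by each cluster's byte-wise smallest member. On the threshold-1 graphs used
here (disjoint unions of cliques of identical-profile rows) MCL provably
returns the components, and the suite asserts equality with the exact
grouping across inflation 1.2–5; `method = "exact"` is the default route in
production because it is the same partition at a fraction of the cost. No
record of the original analysis' MCL version or parameters exists, so all
parameters are exposed and logged rather than hard-coded.

## The synthetic generator

`generate_truth()` plants a known signature per gene — a set of distinct
phenotype subsets realised by 1–3 SNPs each (SNP multiplicity within a
module standing in for local LD) — over a synthetic genome of 2 kb genes
separated by 1 kb gaps, 50 per chromosome, with equal default proportions
of SPA / Type 1 / Type 2 / complex classes and one null SNP per gene (half
intragenic, half intergenic). `emit_associations()` tests every SNP against
every phenotype: planted pairs draw p ~ U(0, 1e-12), i.e. below the
within-family step-down level by construction, and all other pairs draw
p ~ U(0, 1); effect sizes are |N(0, 1)| with a 0.8 probability of negative
sign, mirroring the predominance of minor alleles that lower metabolite
intensities. The generator emulates the *combinatorics* of MPA signatures,
not GWAS power: planted p-values are sampled below threshold rather than
derived from genotypes, there is no kinship structure, no haplotype LD and
no correlation between phenotypes. Passing recovery tests therefore
demonstrates the correctness of the decomposition machinery, not the
detectability of weak associations in real data.

`emit_phenotypes()` draws baseline intensities from a log-normal with
log-scale spread 0.4 truncated at |z| ≤ 1.8, which keeps every clean value
within about 3.5 raw MADs of its column median, so planted outliers
(displaced to median + 8 upper-MADs by default) are exactly the values a
k = 5 screen should find. Real metabolite data has heavier tails than this
truncated baseline; the truncation exists so that recovery tests have an
unambiguous ground truth. Outliers are planted on the upper tail only:
intensities are nonnegative and the lower tail of a log-normal leaves no
room for a 5-MAD displacement above zero.

## Parameters that matter

| parameter | default | where | meaning |
|---|---|---|---|
| `q1` | 0.1 | `hierarchical_filter` | BH level of the across-family screen |
| `q2` | 7.9e-6 | `hierarchical_filter` | GBS level within selected families |
| `mad_k` | 5 | `filter_metabolites` | tail-MAD distance cut-off |
| `min_valid` | 100 | `filter_metabolites` | minimum non-zero, non-outlier values per metabolite |
| `inflation` | 2.0 | `mcl_cluster` | MCL inflation exponent |
| `include_spa` | FALSE | `mpa_decompose` | extend the decomposition to single-phenotype genes |
| `method` | "exact" | module/signature clustering | equivalence classes vs MCL route |

`include_spa = FALSE` restricts module construction to SNPs in MPA genes,
the method's focus; setting it `TRUE` makes the decomposition identity hold
over every gene with a hit, at the cost of a much larger module set.

## Degenerate inputs and tie-breaking

* Empty intersections (no significant in-gene SNP) are errors, not empty
  results, so silent misconfiguration cannot masquerade as a negative
  finding.
* Module and cluster ids are assigned by byte-wise sorted phenotype-set /
  module-set keys; all tables and exports are radix-sorted. Two runs on the
  same input are byte-identical.
* A SNP in overlapping genes contributes to each covering gene (how the
  original analysis treated this case is unrecorded; mapping to all
  covering genes is the choice that loses no information, and it is
  recorded in the run report's parameters).
* Whether a reported Type 1 count should absorb mixed Type1/Type2 genes is
  ambiguous; our precedence rule (Type 2 wins, `complex` flags the
  mixture) is documented above and togglable downstream via the flag.

## Problem sizes

The shipped validation suite runs at deliberately modest scale: PS law
checks on ~1.2e4 random vector pairs, the decomposition identity on 1,000
random planted configurations (3–12 genes each), MCL-vs-exact equivalence
up to 500 SNPs / 200 genes, and a 200-gene × 40-phenotype end-to-end
recovery study (~3.7e4 association records). These sizes exercise every
code path; the algorithms themselves are sparse-matrix based and scale to
genome-sized inputs (the profile-matrix and module steps are linear in the
number of significant records once grouped).

## Known limitations

* The hierarchical filter's composition of the two FDR levels is a
  reconstruction (see above); both alternative modes are provided.
* MCL on graphs that are *not* threshold-1 cliques may split large sparse
  components; the exact route is authoritative for PS = 1 semantics and
  any divergence is surfaced by the equivalence tests, never silently
  accepted.
* The generator does not simulate genotypes, kinship, or phenotype
  correlation; conclusions about statistical power on real data are out of
  scope.
* GO/pathway enrichment of signature classes and co-expression integration
  are intentionally outside the package boundary; exports (SIF, GraphML,
  MatrixMarket, TSV) are designed to hand results to those tools.
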