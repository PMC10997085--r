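---
title: "Coverage- and missingness-based molecular sexing from RAD-seq data"
author: "sexRAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage- and missingness-based molecular sexing from RAD-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexRAD)
```

## The problem

Sex is a basic covariate in population ecology and conservation genetics,
yet many study systems make it hard to observe: monomorphic species,
juveniles, and non-invasively collected samples (scat, hair, carcasses at
various stages of decomposition). When a study already has
reduced-representation sequencing data (RAD-seq or GBS) and a
chromosome-level reference genome of a closely related species that
includes assembled sex chromosomes, sex can be read directly off two
properties of heteromorphic sex chromosome systems:

* **copy number**: in an XY system, males carry one X against two copies
  of every autosome, so the mean coverage depth of X-mapped loci is about
  half the autosomal mean in males and equal to it in females;
* **presence/absence**: females carry no Y at all, so Y-mapped loci are
  entirely missing in females, while in males Y loci are recovered about
  as completely as X loci.

`sexRAD` implements the sexing stage of that workflow. Its input contract
starts at an *all-sites VCF* — a VCF containing every position inside the
assembled RAD loci, fixed as well as variable, with a per-genotype depth
field — such as the output of `populations --vcf-all` in STACKS after
reads were mapped with a standard aligner. Everything upstream (read
mapping, locus assembly) is out of scope.

## The two indexes

For each individual and chromosome class $c \in \{\mathrm{A}, \mathrm{X},
\mathrm{Y}\}$ the package accumulates:

* $\mathrm{miss}(c)$: the fraction of the class's sites (counted over the
  whole population's VCF, not per individual) whose genotype is missing
  in the individual; completeness is $\mathrm{Com}(c) = 1 -
  \mathrm{miss}(c)$;
* $\mathrm{Depth}(c)$: the mean per-genotype depth over the individual's
  *non-missing* sites in the class.

The two indexes are

$$\mathrm{Index\,X} = \frac{\mathrm{Depth_X}}{\mathrm{Depth_A}}, \qquad
  \mathrm{Index\,Y} = \frac{\mathrm{Com_X} - \mathrm{Com_Y}}{\mathrm{Com_X}}.$$

Expected values are 1 and 1 for the homogametic sex (XX females) and 0.5
and 0 for the heterogametic sex (XY males). Index Y can fall below 0 in
low-coverage males — the Y loci that survive a locus-sharing filter tend
to be robustly recovered, while X loci drop out as coverage falls, so
$\mathrm{Com_Y}$ can exceed $\mathrm{Com_X}$. The negative sign only
widens the separation between the sexes.

**Only Index Y assigns sex.** Index X degrades at low coverage: the mean
depth of the sites an individual *does* retain is biased upward when
coverage is low (loci are observed only conditional on at least one
read), and the bias is stronger for the lower-coverage X loci of males,
pushing their ratio toward 1. Below roughly 10X overall depth Index X
misassigns males, so the package computes it and reports it as an
advisory second opinion, never as the call.

## The calling rule

The published analyses showed complete visual separation of the sexes
along Index Y but printed no numeric cutoff, so a decision threshold is
necessarily this package's own construction. The default,
`indexYFemaleThreshold = 0.5`, is the midpoint of the two expected values
(1 and 0), which maximises the margin to both; the comparison is
inclusive (`index_y >= threshold` calls the homogametic sex). The
threshold is a `runConfig()` parameter, and the dispersion plots draw it
as a horizontal blue line so users can audit it against their own
cohort's clustering. The advisory Index X call uses nearest-expected
value (midpoint 0.75) and is suppressed when the individual's overall
mean depth falls below `lowDepthWarning` (default 10X, the regime where
Index X is known to fail).

Unlike the original workflow — which never needed one, because
separation was complete — the package has an explicit `unassigned`
outcome: Index Y is undefined when X completeness is 0, and silent
miscalls are worse than abstention. A cohort whose VCF carries no Y-like
sites at all is treated as total Y absence ($\mathrm{Com_Y} = 0$), giving
Index Y = 1 for every individual with X data, with a warning.

## Chromosome classes and ZW systems

`ChromClassMap` assigns every reference contig to `X_LIKE`, `Y_LIKE`,
`AUTOSOME` or `EXCLUDED`. Contigs not listed default to `AUTOSOME`,
matching the chromosome-level assemblies the method presumes; `EXCLUDED`
is available as the default for references with many unplaced scaffolds,
which would otherwise dilute the autosomal depth with fragments of
unknown provenance. ZW systems need no new arithmetic: label the Z as
`X_LIKE`, the W as `Y_LIKE`, and swap the sex labels
(`homogameticLabel = "male"`) — the homogametic sex is then the ZZ male.

## Locus filters

Two retention filters mirror the upstream population-genetics filtering,
for users who arrive with unfiltered all-sites output:

* **locus sharing** (`r`, default 0.3): a locus is kept when present
  (at least one non-missing genotype among its member sites) in at least
  $\lceil rN \rceil$ of $N$ individuals. The ceiling implements "at least
  a proportion r" as an inclusive bound. A permissive 0.3 is deliberate:
  Y loci exist only in males, so a conventional 0.8 sharing filter would
  delete the very loci the method needs.
* **observed heterozygosity** (`maxObsHet`, default 0.7): any member site
  whose fraction of heterozygous genotypes among non-missing ones
  exceeds the bound vetoes its whole locus, purging paralog collapses.
  The per-site veto is the conservative reading of a locus-level filter.

The stage is optional (`locusFilter = FALSE` by default) because
cohorts processed through a populations-style pipeline have had these
filters applied already. Loci are delimited by the VCF ID column when
present (STACKS writes locus IDs there), otherwise by runs of
consecutive positions with inter-site gaps of at most `maxGap`
(default 1, i.e. strictly contiguous — the shape of single-end RAD loci
in an all-sites VCF).

## Numerical and edge-case choices

* A genotype is missing when any GT allele is `.`; half-missing diploid
  calls count as missing. This matches the per-individual missingness
  convention of the VCF toolchain the statistics emulate.
* Mean depth averages over non-missing sites only. A missing genotype's
  stale depth value is ignored; a non-missing genotype without a numeric
  depth value counts as depth 0. Whether the original workflow's depth
  report averaged over all or only non-missing sites is not documented;
  averaging over non-missing sites prevents zero-depth missing sites
  from penalising an individual through both statistics at once.
* The missingness denominator is the number of sites the population's
  VCF retains for the class, identical for every individual.
* Only GT missingness and depth are read, so invariant, multi-allelic
  and indel records are all handled identically: the indexes depend on
  the presence of loci, not of SNPs.
* Coordinates are 1-based VCF positions throughout; RAD loci are treated
  as strand-agnostic.
* `mean_depth` is NA (and the dependent index undefined) whenever an
  individual has no non-missing site in a class; the identities
  `missingness + completeness = 1` and
  `n_missing + n_nonmissing = n_sites` hold exactly and are enforced by
  the class validity.

## The synthetic cohort generator

`simulateCohort()` exists so that every stage — and the low-coverage
behaviour of the indexes — is testable without any external download.
Its generative model is deliberately minimal: the expected read count of
locus $l$ in individual $i$ is

$$\lambda_{il} = d_i \cdot \mathrm{copy}(\mathrm{sex}_i, \mathrm{class}_l)
  \cdot \rho_l,$$

with $d_i$ the individual's nominal depth, copy factors as in the table
below, and $\rho_l \in [0,1]$ a per-locus recoverability drawn once per
cohort. Realised counts are Poisson (negative binomial when an
overdispersion size is set); a locus is missing in an individual exactly
when its count is 0; all member sites of a locus share its depth and
missingness.

| class     | homogametic | heterogametic |
|-----------|-------------|---------------|
| autosome  | 1           | 1             |
| X-like    | 1           | `xCopyRatio` (0.5) |
| Y-like    | `yPresence` (0) | 1         |

Defaults reproduce the statistical structure of the published fur-seal
cohort: 150 bp loci, 11.5X nominal depth, locus counts 31775 autosomal /
19574 X / 551 Y. Recoverability defaults to Beta(2, 2) for autosomal and
X loci and Beta(8, 2) for Y loci: the locus-sharing filter, applied to
a marker class present in under half the cohort, enriches for robustly
captured Y loci, and this asymmetry is what lets the generator reproduce
the empirically observed negative male Index Y at low coverage. This is
a modelling choice of the package, not a published formula.

What the generator does *not* emulate: restriction-site dynamics, allele
frequencies (genotypes are homozygous placeholders — only missingness
and depth matter to the method), PCR duplicates, reference bias,
X/Y-homologous ("gametologous") loci that cross-map between the sex
chromosomes, and contamination. Passing simulation tests therefore
demonstrates the pipeline's arithmetic and its qualitative coverage
behaviour, not concordance on any real cohort.

Two consequences of the model worth knowing when choosing parameters:
the *observed* overall depth is roughly $d_i \,\mathrm{E}[\rho]$ (about
half the nominal depth under the default recoverability), and the
zero-truncated mean of observed loci exceeds $\lambda$ at low rates —
which is exactly the mechanism that degrades Index X below ~10X.

`degradeCohort()` re-uses one set of loci and recoverabilities across a
schedule of depths, re-seeding the count stream per sub-cohort so that
equal scheduled depths yield identical draws; this makes coverage the
only variable along the gradient.

## Problem sizes in the test-suite and validation runs

Validation simulations use cohorts of 60 individuals (30/30 sexes) with
locus counts scaled to 2000 autosomal / 500 X / 50 Y and 2 sites per
locus, over 20 seeds; the depth-gradient runs span 1.4X-15X, the
coverage range observed in the motivating datasets. Because depth and
missingness are locus-level quantities shared by member sites, short
loci give the same per-class statistics as 150 bp loci at a fraction of
the VCF size; the scaled locus counts keep each simulated VCF around
5000 records while leaving hundreds of loci per class, enough for the
index distributions to separate cleanly.

## Known limitations

* The method requires genuinely heteromorphic sex chromosomes and a
  reference whose X- and Y-like contigs are labelled; it cannot discover
  sex linkage de novo.
* Cross-mapping between X and Y gametologs biases both indexes in ways
  the package does not model; a conservative chromosome map (excluding
  pseudoautosomal contigs if annotated) is the available mitigation.
* The Index Y threshold is a fixed cutoff, not a model-based classifier;
  cohorts with intermediate clustering (contamination, aneuploidy) need
  manual review of the dispersion plots.
* Statistics stream in O(samples) memory, but the locus filter loads
  the VCF's genotype matrix in full; very large unfiltered VCFs should
  be filtered per chromosome or upstream.

## A worked run

```{r, eval = FALSE}
library(sexRAD)

vcf <- system.file("extdata", "synthetic_cohort.all.vcf",
                   package = "sexRAD")
map <- system.file("extdata", "synthetic_cohort_chrom_map.yaml",
                   package = "sexRAD")
report <- runSexingPipeline(vcf, map, outDir = tempdir())
sexCalls(report@calls)[, c("individual", "index_x", "index_y", "sex")]
```

The bundled cohort is synthetic (6 individuals, seed-reproducible); its
truth table sits next to it as `synthetic_cohort_truth.csv`.
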