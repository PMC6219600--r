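---
title: "Inferring allopolyploid progenitors from presence/absence markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring allopolyploid progenitors from presence/absence markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartpoly)
```

## The problem

Allopolyploid species such as bread wheat (*Triticum aestivum*, genome
ABD) carry the chromosome sets of two or more diploid ancestors in one
nucleus. For several polyploid *Aegilops* species the identity of one or
more of those diploid donors has been debated for decades, partly because
the classical evidence -- meiotic chromosome pairing in wide hybrids -- is
confounded by pairing regulators and environment. Genotyping-by-sequencing
platforms of the DArTseq type offer a different route: they score tens of
thousands of dominant presence/absence markers (PAV of restriction-fragment
tags, "SilicoDArT" markers) and codominant SNPs across whole genomes, and,
when the platform is anchored to a reference genome, each marker carries a
chromosome assignment.

`dartpoly` implements that route as a reusable, tested pipeline:

1. **Species-specific markers.** After call-rate filtering, a marker is
   *specific* to a diploid species if it is present in that species and
   absent in all others of the screen. Specific markers are clean probes:
   their presence in a polyploid is evidence that the diploid (or a close
   relative) contributed a subgenome.
2. **Retention (diploid--polyploid monomorphism).** For analyzer set $A$
   (the specific markers of a diploid) and polyploid presence set $T$, the
   retention is $|A \cap T| / |A|$. A diploid whose retention in a
   polyploid is considerably higher than the competition is called a
   putative progenitor.
3. **Analyzer selection by homoeology.** When a hexaploid reference with
   assigned chromosomes (1A--7D) is available, diploids are screened by the
   share of their markers assigned to each reference subgenome; species
   reaching at least 10% of a subgenome's reference marker total are
   retained as analyzers for that subgenome.
4. **Chromosome profiles.** Retention recomputed per chromosome (1..7
   within one subgenome letter) exposes segmental replacement of a
   parental chromosome.
5. **Clustering.** Species relationships are summarized by UPGMA on the
   Pearson correlation distance $d = 100(1 - r)$ computed between raw
   0/1/2 SNP score vectors.

## Score conventions and input handling

SilicoDArT markers are scored 1 (tag present) / 0 (absent); SNPs are
scored 0 (reference homozygote), 1 (alternate homozygote), 2
(heterozygote). Missing calls are written `-`; on input both `-` and the
empty cell are accepted, since both occur in DArT exports. Only the
one-row SNP dialect is supported -- a file in which every marker id appears
exactly twice is rejected with an explicit message rather than
misinterpreted. Call rates are always recomputed from the scores on read;
a stored call-rate column is compared and reported, never trusted. The
call rate is computed over the loaded panel's samples.

Call-rate filters are strict (`>`), following the conventional phrasing of
the thresholds: SNPs at `> 0.9` for clustering, presence/absence markers
at `> 0.7` for progenitor analysis (the looser threshold keeps more
markers and widens genomic coverage). Chromosome labels are normalized to
upper case over the declared set (default `1A`..`7D`); anything else
becomes `"unassigned"` with a warning. Unassigned markers are excluded
from homoeology and chromosome profiles but kept for specificity and
retention.

## Missing-call policy

Presence of a marker in a species uses the *any-sample* rule (a species
may have several samples, e.g. two bread-wheat cultivars): one score of 1
makes the marker present, and missing calls never create presence.
Absence -- which is what specificity quantifies over the background
species -- is policy-dependent:

* `lenient` (default): a missing call counts as absence; the filtered
  binary matrix is taken at face value. This is the natural reading after
  call-rate filtering has already removed poorly called markers.
* `strict`: any missing call in a species removes the marker from that
  species' absence judgement, so a marker can be neither present nor
  absent. Offered for sensitivity analysis; specific sets under `strict`
  are always subsets of the `lenient` ones.

## Calling progenitors: the margin rule

A polyploid of ploidy $2n$ has $n$ subgenome slots. Analyzers are ranked
by retention and the top $n$ fill the slots tentatively; slots are then
confirmed from the bottom up. A slot is **resolved** only when its
candidate exceeds, by at least the margin (default 0.10, an absolute
retention difference), the best analyzer left outside all slots. If not,
the slot is reported **unresolved**, listing the candidate together with
the unplaced analyzers within the margin of it; those analyzers are then
no longer competitors for the remaining slots. With margin 0 the procedure
degenerates to a pure arg-max fill.

This operationalizes "considerably higher retention" while refusing to
force a choice among near-tied, closely related analyzers: when two
relatives compete within the margin (the classic case being the S-genome
Sitopsis species, or *Ae. speltoides* versus *Ae. mutica* for the
unidentified X genomes), the slot surfaces the tied set as an
ancestral/unknown donor instead of picking a winner. The bottom-up order
matters: a clear winner above a tied cluster stays resolved (retentions
0.90, 0.85, 0.85 with margin 0.1 give a resolved top slot and an
unresolved second slot listing the 0.85 pair), because the tied pair
occupies the second slot and so does not count against the first.

## Homoeology accounting

For each screened diploid and each reference subgenome the table records
`total` markers assigned there, split into `shared` (present in at least
one other screened diploid) and `specific`, with `shared + specific =
total` asserted on every build. The percentage is
`100 * total / reference-subgenome-total`, rounded half-up to 1 decimal;
specificity percentages are rounded half-up to 2 decimals. Half-up
rounding matches how such tables are conventionally printed (R's own
`round()` rounds half to even). The shared/specific split is annotation
only -- the percentage uses totals -- and "shared" is defined relative to
the same screen, a choice recorded here because published tables rarely
state it.

Selection is inclusive (`>= 10%`), per the usual "at least 10%" phrasing.
On the reported survey counts shipped with the package
(`reported_homoeology_counts()`), the rule selects exactly 13 of the 16
screened diploids, the three distant relatives (rye, *Dasypyrum*, barley)
falling below threshold on every subgenome.

## Clustering choices

Pearson's $r$ is computed on raw 0/1/2 scores, pairwise-complete by
default (a listwise option exists); constant score vectors and pairs with
fewer than two shared calls are errors that name the offending samples,
not silent `NA`s. The transform $d = 100(1 - r)$ maps identical profiles
to 0 and perfect anti-correlation to 200.

UPGMA is the classical cluster-size-weighted average linkage: the merge
height is half the merge distance, and after merging clusters $i,j$ the
distance to any other cluster is
$(s_i d_{ik} + s_j d_{jk})/(s_i + s_j)$, so every leaf pair contributes
equally. Ties are broken by the lexicographically smallest concatenation
of sorted leaf labels, making output invariant to input order --
reproducibility is preferred over fidelity to any particular tool's
unspecified internals. The implementation is in-package because the tie
rule must be declared; `stats::hclust(method = "average")` serves as an
independent reference in the tests, never as the implementation. Trees
serialize to Newick with branch lengths on the $d$ scale; labels
containing reserved characters are single-quoted.

## The synthetic generator

No raw marker data are deposited for the survey the package's reported
tables come from, so validation rests on a generator that produces
matrices with the structure the analysis assumes, plus full bookkeeping
(`truth`) for oracle checks:

* an ancestral pool of presence/absence markers evolves down an
  ultrametric species tree; on each branch of length $\ell$ every marker
  is lost with probability $1 - e^{-\lambda_b \ell}$ and
  $\mathrm{round}(g\,\ell)$ new private markers are gained
  (per-marker independence -- the analysis only uses marginal presence,
  so linkage is deliberately not modelled);
* SNP scores evolve by symmetric 0/1 flips at rate per unit length, with
  a small residual heterozygosity injected at the tips;
* an allopolyploid's presence set is the union of its parents' sets with
  independent post-polyploidization loss $\lambda$ (optionally boosted on
  selected chromosomes to plant segmental replacement), and its SNP score
  is the parental consensus with code 2 where parents disagree, plus a
  small post-merger divergence;
* missing calls are injected per cell at rate $\mu$; chromosome labels
  are drawn at marker creation, with a fraction left unassigned.

The preset (`triticeae_preset()`) fixes the study conditions: 11 diploids
in five section-like clades, 12 polyploids (seven with two extant
parents, including one pair with identical parent sets; five carrying a
hidden donor `anc_X`, a close relative of `speltoides`/`mutica` pruned
before output), ancestral pool 12,000 markers, loss rate 0.25 and gain
rate 3,000 per unit depth, $\lambda = 0.2$, $\mu = 0.03$, 6,000 SNPs at
substitution rate 0.3. These values were chosen once so that species
totals (~10^4 markers) and specific-marker fractions (a few to ~35%) sit
in the range of the reported tables. The hidden-donor polyploids
reproduce the X-genome situation: their extant parents rank on top, while
the hidden slot surfaces as an unresolved tie between the two extant
relatives of the donor.

What passing tests on these data do show: the filtering, retention,
ranking, homoeology arithmetic and clustering recover planted structure
at realistic scale and noise. What they do not show: robustness to
linkage, ascertainment bias of the genotyping platform, reference-biased
chromosome assignment, or within-species polymorphism beyond the sampled
accessions -- real surveys carry all four.

```{r, eval = FALSE}
res <- simulate_panel(triticeae_preset(seed = 1))
out <- run_pipeline(run_config(markers = res$markers, snp = res$snp,
                               panel = res$panel, out_dir = "out"))
out$calls$columnaris
```

## Numerical and degenerate-input choices

* Retention over an empty analyzer set is undefined: the cell is `NA` and
  flagged, never silently 0/0; `call_progenitors()` refuses incomplete
  columns.
* Chromosome-profile buckets with fewer than `n_min = 20` markers are
  flagged `low_support` but kept -- small buckets mislead more often than
  they inform, yet dropping them would hide where data are thin.
* Cross-genome SNP monomorphism requires complete calls within the
  compared group ("consistently called" markers); by default identity
  means exact score identity, with an option to collapse heterozygous 2
  with 1 when allele presence is the relevant notion -- published values
  of this statistic rarely state which convention was used, so both are
  available.
* The pipeline writes a JSON run log with package version, seed and
  thresholds but no timestamp, so identical configurations produce
  byte-identical output trees.

## Problem sizes used in the automated checks

The test suite and the acceptance script run the preset at its default
scale (about 3 x 10^4 emitted markers x 23 samples per replicate; 100
replicates for the recovery rates), a 50-case UPGMA comparison against
the average-linkage reference, and exhaustive truth-table evaluation of
the specificity filter on 50 x 10 matrices -- sizes at which the
brute-force oracles are still exact while the vectorized paths are
exercised at realistic scale.

## Known limitations

* The progenitor margin is an absolute retention difference; with very
  small analyzer sets the binomial noise of retention can exceed it, and
  no formal significance is attached to a resolved slot.
* "Shared" in the homoeology table depends on the screen composition;
  percentages do not.
* UPGMA assumes clock-like divergence; for strongly rate-heterogeneous
  panels the topology can be distorted (no NJ/ML alternative is provided,
  and no bootstrap support is computed).
* The two-row SNP export dialect and raw tag sequences are out of scope;
  inputs must already carry chromosome assignments.
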