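---
title: "Mapping causative mutations from phenotype-pooled tetrad progeny"
author: "TetradMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causative mutations from phenotype-pooled tetrad progeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TetradMap)
```

## The problem

A UV mutagenesis screen in a haploid alga such as *Chlamydomonas
reinhardtii* produces mutants that carry tens of induced point mutations,
only one of which causes the phenotype of interest (here modelled on
temperature-sensitive photoautotrophy, "TSP").  Whole-genome sequencing of
such a mutant reports each variant with a *frequency value* — the percent
of mapped reads at the site that support the variant allele.  Identifying
the causative change among induced mutations, strain background
polymorphisms, and caller artifacts is a filtering problem, and the
genetics of the organism (haploidy, recoverable tetrads, cheap crossing)
makes three complementary experimental designs possible:

1. **Preliminary sequencing** — mutant vs its background wild type.
2. **Outcross pooling** (bulked segregant analysis) — cross to a divergent
   wild strain whose dense private SNPs serve as linkage markers, pool the
   progeny by phenotype, and sequence each pool once.
3. **Iterated backcrossing** — five selected backcross generations purge
   unlinked mutations by one half per generation before resequencing.

`TetradMap` implements the inference side of all three designs — the
frequency-value triage cascade, the pooled-progeny causal filter, origin
tagging with clean-flank linkage-region sizing, and coding-change
annotation — together with a forward-genetics simulator that generates
every input at desk scale, so the whole pipeline is testable without any
external sequencing data.

## The filtering model

**Frequency cutoff.**  In a haploid genome a real variant should be
supported by essentially all reads; a large bulk of artifact calls sits at
mid-range frequencies instead.  The cascade keeps records with frequency
value strictly over 80% (`TriageConfig(frequencyCutoff = 80)`); the strict
comparison is deliberate and `keepAtCutoff` exposes the boundary for
sensitivity runs.  The cutoff tolerates ambiguous base calls in up to 20%
of reads without admitting the mid-frequency artifact bulk.

**Subtraction.**  Variants present in a wild-type reference — or, in the
pooling design, in the phenotype-negative pool — are removed on *presence
at any frequency value*: a variant carried by even one phenotype-negative
progeny cannot be causing a fully penetrant phenotype.  Variant identity
is the exact site key `(chrom, pos, ref, alt)`; no indel left-normalization
is attempted because the simulator emits normalized records, and exact-key
matching keeps the operation reproducible.

**Non-synonymous selection.**  Records overlapping a CDS are projected
into coding coordinates (strand-aware) and applied to the CDS; records
that leave the protein unchanged are dropped.  "Non-synonymous" is read
broadly — missense, nonsense and frameshift-inducing indels all stay —
because loss-of-function candidates should not be discarded by an
annotation convention.

**Intersection.**  Independent experiments on the same mutant are
intersected at key level; a variant reported in the preliminary *and* the
backcross experiment is confirmed, and fields are reported from the first
table.

**Pooled-progeny filter.**  A causative variant must be carried by every
phenotype-positive progeny, hence reported near 100% in that pool;
`poolCausalFilter()` composes cutoff → subtraction (phenotype-negative
pool at any frequency, plus both wild types) → non-synonymous selection,
mirroring the order in which the designs apply them.

**Origin tagging and clean flanks.**  Every call in the positive pool is
tagged `background_wt`, `outcross_wt` or `novel` by key membership in the
two wild-type panels (panels sharing a key are rejected as contaminated).
For each candidate, the flanks to the nearest outcross SNP on either side
are summed into a *clean region*: phenotype selection drags the
background-strain haplotype around the causative site through the cross,
so the causative candidate sits in a clean region of megabase scale while
unlinked novel calls are hemmed in by outcross SNPs within a few kb.  At a
chromosome edge the flank runs through the terminus (left flank `pos`,
right flank `length - pos`), so a chromosome entirely free of outcross
SNPs scores its full length.  Candidates are ranked by region size, then
frequency value, with positional tie-breaks — a total, deterministic
ordering in which the top rank is the causal call.

## Coding-change annotation

`parseHgvsC()` supports exactly the descriptor classes the pipeline emits:
CDS substitutions (`c.479C>T`) and equal-length delins (MNPs,
`c.2044_2045delCCinsTT`).  Everything else — splice offsets, UTR
positions, duplications — errors loudly rather than being half-supported.
`applyCodingChange()` translates the affected codons before and after with
the standard nuclear genetic code (the genes of interest are
nucleus-encoded), reports the residue index `ceiling(cdsStart / 3)`, and
classifies the consequence.  For chloroplast-imported proteins,
`toMature()` renumbers residues by subtracting the transit-peptide length,
which is gene-model metadata (`transitPeptideLen`, default 0): a change at
precursor residue 160 with a 31-residue transit peptide is residue 129 of
the mature protein.

```{r annotation}
cds <- paste0(strrep("GCA", 159), "CCT", strrep("GCA", 40))
pc <- applyCodingChange(cds, parseHgvsC("c.479C>T"))
pc
toMature(pc, 31)
```

## What the simulator emulates

The simulator generates, from one integer seed, everything the pipeline
consumes: a haploid multi-chromosome reference with gene models written in
as clean ORFs, a divergent outcross strain, UV-style mutagenesis with one
planted causative missense change, tetrad meioses, breeding schemes, and
noisy pooled-sequencing variant tables.

**Meiosis.**  Crossovers are a Poisson process on the four-chromatid
bundle with rate `2d` per bivalent (`d` the chromosome's map length in
Morgans), no crossover interference (Haldane), each crossover involving
one randomly chosen chromatid of each parent (no chromatid interference).
Chromosomes are treated as acrocentric — the centromere sits at the left
end, so sister chromatids are never separated by a crossover before
meiosis I — and assort independently.  Two loci at physical distance `bp`
therefore recombine with fraction `c = (1 - exp(-2d))/2`,
`d = mapRate * bp / 1e8`.  Every inter-parental heterozygous site
segregates exactly 2:2 by construction, which is also what the package's
`segregationTest()` checks on observed tetrads.

**Genetic map.**  The map is uniform at `mapRate` cM/Mbp, default 6.  The
organism's average is of that order, and under Haldane this default makes
two loci 2 Mbp apart recombine at `c ≈ 0.11–0.12` — exactly the regime in
which a non-causative variant co-segregates with the causative locus often
enough to persist through five selected backcrosses and to appear at
~88% in a phenotype-selected outcross pool while the causative variant
sits at 100%.  A real recombination landscape is not uniform; this is a
modelling choice, not a biological claim.

**Mating type** is a single Mendelian locus placed on the last chromosome,
so it segregates 2:2 and progeny of both types are always available; the
backcross scheme uses the wild-type partner in whichever mating type is
opposite to the selected carrier, as laboratory wild types are kept in
both types.

**Phenotype.**  Penetrance is 1 and the phenotype is identical to
carriage of the causative allele.  Clean 2:2 phenotype segregation in
observed tetrads is what justifies this in the modelled screen; partially
penetrant or polygenic phenotypes are out of scope.

**Pooled sequencing.**  Per site, depth is Poisson(`meanCoverage`); each
read comes from a uniformly chosen pool member and is miscalled with
probability `baseErrorRate` (an erroneous read supports the specific
alternate allele with probability `baseErrorRate/3`).  The frequency value
is `100 * altReads / depth`, rounded to two decimals (the unit is percent
throughout, matching how callers report it).  A site is reported only when
at least `minAltReads` reads support it — variant callers apply exactly
such a minimum-count rule (a common default is 2), and without it
single-read noise in the phenotype-negative pool would occasionally
"report" the causative site and the any-frequency subtraction would delete
the true answer.  Artifact calls are added at `artifactRate` per Mbp with
frequencies `100 * Beta(8, 8)`, concentrating mass in the 35–65% band the
way real artifact bulks do; the generative process behind real artifacts
is unknown, so both the rate and the Beta shapes are exposed in
`SimConfig`.

**Defaults as study conditions.**  `SimConfig()` defaults encode the
modelled study: mean coverage 30 for pools and 20 for single strains (set
per design), about 60 induced mutations per mutant, 5 selected backcross
generations, 25 dissected tetrads per outcross (100 progeny, 50 per
phenotype pool; 15 tetrads give the smaller 60-progeny design), base error
rate 0.005, artifact rate 0.5/Mbp.  The default toy genome is 3
chromosomes of 4 Mbp with 30 genes and an outcross SNP density of
100/Mbp (mean spacing 10 kb) — desk-scale stand-ins for a ~110 Mbp
genome, chosen so a full simulated experiment runs in about a second while
preserving the statistical structure the inference relies on: multiple
linkage groups, a dense marker panel, and a realistic ratio of coding to
non-coding sequence is *not* preserved (gene density is far lower than
real), which only makes the non-synonymous filter less busy, not
different.

**What is deliberately not modelled** — and therefore what passing tests
do not demonstrate about real data: read-level artifacts (no FASTQ, no
alignment, no mapping bias), the UV mutational spectrum, indel mutagenesis
(induced mutations are SNVs), organellar inheritance, gene conversion,
crossover interference, non-uniform recombination, incomplete tetrads
(the simulator only emits complete ones, as incomplete tetrads are
discarded at the bench), and the behaviour of any particular variant
caller beyond the minimum-count rule.  Real call sets will violate the
exact-key matching assumption wherever callers normalize indels
differently between runs.

## Numerical choices and degenerate inputs

* Coordinates are 1-based and inclusive everywhere (VCF convention);
  frequency values are percent in `[0, 100]`, written with two decimals,
  and "exactly 100%" means equality after 2-decimal rounding.
* Variant tables are unique on `(chrom, pos, ref, alt, source)` and sorted
  by `(chrom, pos)`; sorting and de-duplication are idempotent, and
  writing is byte-stable for identical input.
* Ties in candidate ranking break on `(chrom, pos)`; ties between equal
  clean regions are real in the marker-free single-experiment designs,
  where ranking degenerates to frequency ordering by construction.
* Empty tables flow through every filter; an empty *input* to ranking or
  to the histogram is an error, because a report with no candidates and a
  histogram of nothing are analysis failures the user must see.
* All randomness flows from one integer seed per run; fixed seed, fixed
  output, byte for byte.

## What the tests establish

The test-suite verifies the tetrad 2:2 law across map rates, agreement of
recombinant-gamete frequencies with the Haldane closed form, backcross
retention of unlinked mutations at `2^-g`, exact 100% pooled frequency of
the causative allele, the ~88% mean pooled frequency of a variant at
recombination fraction 0.12, equality of every filter with brute-force
oracles on random tables, round-trips of all file formats (with an
independent VCF reader cross-checking the package's writer), agreement of
the annotation path with a mutate-genome-and-retranslate oracle, and
end-to-end recovery of the planted causative variant under sequencing
noise.  Simulation sizes in the suite (thousands of tetrads, hundreds of
end-to-end replicates) were chosen so the full suite runs in minutes on a
single core while keeping Monte-Carlo error well inside the asserted
tolerances.

## Limitations

The package identifies *candidates*; confirming causality still requires
independent evidence (targeted resequencing, complementation).  The
ranking uses only clean-region size and frequency — deliberately not the
"close vicinity" of two candidates, which in the modelled study was an
interpretive argument, not a rule.  And because the simulator is the only
data source the tests use, systematic properties of real sequencing
(caller idiosyncrasies, coverage biases, repeat regions) are untested by
construction.
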