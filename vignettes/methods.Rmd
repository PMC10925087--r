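---
title: "Tumour-only somatic mutation calling from phased long reads: models and methods"
author: "hapsomatic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumour-only somatic mutation calling from phased long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hapsomatic)
```

## The problem

Somatic mutations are normally identified by comparing tumour sequencing
data against a matched normal sample from the same individual. When no
normal is available, a caller must separate three hypotheses at every
genomic position from the tumour reads alone: the position is a somatic
mutation, an inherited heterozygous SNP, or reference with sequencing
error. With short reads this rests on small shifts in the variant allele
fraction (VAF) and on population databases; it degrades quickly with
purity and depth.

Long reads change the problem. Because a long read usually spans several
heterozygous SNPs, it can be assigned to a parental haplotype. On a single
haplotype, the three hypotheses predict qualitatively different allele
mixtures: a heterozygous SNP puts the alternate allele on *every* read of
its haplotype, a sequencing artifact puts it on a few reads of *both*
haplotypes, and a somatic mutation produces a *mixture* on one haplotype
-- the mutant allele from the tumour cells plus the inherited allele from
the contaminating normal cells. This only works when the sample is not
pure tumour: the normal cells are the internal control, so the methods
here require purity $0 < \alpha < 1$.

`hapsomatic` implements this idea twice: as closed-form count classifiers
inside a simulation framework that maps where tumour-only calling is
feasible, and as a full calling pipeline for BAM/FASTA/VCF inputs.

## The count-level feasibility model

`simPileup()` draws, for each of $G$ positions: a heterozygous SNP on each
haplotype with probability $\pi$ (default $10^{-3}$, the approximate human
heterozygosity), a somatic mutation on each somatic haplotype copy with
probability $\mu$ (default $5\times10^{-6}$, chosen so that a $10^7$-site
genome carries on the order of a hundred mutations -- enough for stable F1
estimates while keeping false positives observable), depth
$d \sim \mathrm{Poisson}(\lambda)$ split $\mathrm{Binom}(d, 1/2)$ across
haplotypes, mutant alleles on mutated haplotypes with probability $\alpha$
per read, and uniform base errors at rate $\epsilon$.

`classifyUnphased(a, r, ...)` compares binomial likelihoods for the count
$a$ of the modal non-reference base among $a+r$ reads, with success
probabilities

* somatic: $(1-\epsilon)\,\alpha/2 + \epsilon\,(1-\alpha/2)$,
* het: $1/2$ (the error terms cancel),
* reference: $\epsilon$,

and priors $(\mu, \pi, 1-\mu-\pi)$. `classifyPhased()` is the
per-haplotype analogue with the factor of 2 removed: success probabilities
$(1-\epsilon)\alpha + \epsilon(1-\alpha)$, $1-\epsilon$ and $\epsilon$.
Both are computed in log space; maximum-posterior labels break
somatic/het ties toward somatic. Sites with zero depth are uncallable and
skipped, not classified.

`puritySweep()` scores both classifiers over a (depth, error, purity)
grid. Two exact reformulations keep a $10^7$-site, 99-purity sweep inside
a couple of minutes on one CPU: counts at reference and het sites do not
depend on purity, so they are simulated once per (depth, error) cell and
only somatic sites are redrawn per purity; and classification depends on
the counts only through $(a, r)$, so each unique count pair is classified
once via a decision lookup table. Both shortcuts preserve the generative
law exactly; the per-site materialisation (`simPileup()`) and the sweep
share the same stratum code.

### What the sweep shows, and a known sensitivity

At 80x and 1% error the phased classifier holds F1 above 0.9 over a wide
purity band (roughly 0.25--0.85), the unphased one only over a narrow band
near 0.5; phased accuracy dominates unphased accuracy over the whole grid.
The *edges* of these bands, however, are not all equally robust: the lower
unphased endpoint is recall-limited, and the recall boundary (how many
alternate reads are needed before somatic beats reference) moves with
$\log \mu$. The default $\mu = 5\times10^{-6}$ is a modelling choice, and
readers comparing band endpoints across studies should expect the lower
unphased endpoint to shift by ~0.1 in purity per order of magnitude in the
assumed somatic rate. The phased endpoints and the upper unphased endpoint
are far less sensitive, because they are governed by the somatic/het
contrast whose prior ratio $\mu/\pi$ enters only logarithmically against a
much larger likelihood gap.

## The calling pipeline

For real reads, raw pileup counts are replaced by realignment likelihoods.

**Read-haplotype likelihoods** (`realignLikelihood()`): a banded pair-HMM
forward pass over a short window (default 20 bp flanks) around each site,
with match emissions derived from base qualities (correct base
$1 - 10^{-q/10}$, each other base $10^{-q/10}/3$, qualities capped at 40
to keep emissions off the floating-point floor), flat insertion emissions,
and gap open/extend probabilities $10^{-3}$/$10^{-1}$. The haplotype
flanks are free (uniform start mass, free right end), and paths start and
end in a match state -- the symmetric choice, which makes the likelihood
exactly invariant under joint reverse-complementation of read and window.
Windows substitute one candidate allele at a time; other variant sites
inside a window stay at reference in both hypotheses, so their mismatch
penalties largely cancel in the ref/alt likelihood ratio. At the default
SNP and candidate densities (~1 per kb against 41 bp windows) multi-site
windows are rare enough that enumerating combination haplotypes would add
complexity for little accuracy; this is the one place the implementation
deliberately simplifies the windowed-realignment scheme it models.

**Genotyping** (`genotypeSites()`): known population SNP sites are
genotyped with homozygous likelihoods as products of per-read allele
likelihoods and a heterozygous likelihood that averages two copy-number
orientations of per-read mixtures $f P(R_k \mid major) + (1-f) P(R_k \mid
minor)$. $f$ is the probability of drawing a read from the higher-copy
haplotype, fixed at 0.25 rather than fitted: the value deliberately
overweights allele imbalance so that heterozygous SNPs survive in regions
approaching loss of heterozygosity, where the balanced model collapses
them into homozygous calls. Priors: 1 site in 1000 is a variant, 2/3 of
variants heterozygous. Only confident 0/1 calls are emitted (phasing
corrupted by a false het is costlier than a lost site), sites with
Fisher-exact allele-by-strand association below $10^{-4}$ are left
uncalled, and at least 8 informative reads are required.

**Haplotagging** (`tagReads()`): phased het alleles form two strings
$B_0, B_1$ over the phased sites; a read's haplotype posterior multiplies
the read-allele likelihoods selected by each string under a uniform prior.
Reads are left unassigned when the PHRED-scaled probability of
mis-assignment is 20 or worse, when their best-supported alleles mismatch
more than 10% of the assigned haplotype, or when they span no phased site.
Reads crossing phase sets are scored against the set contributing the most
sites; the rejection rules then absorb the ambiguous ones.

**Calling** (`callWindow()`): positions are *callable* when both
haplotypes carry at least 10 assigned reads and together at most 400
(emitted as a BED footprint). Candidate discovery is deliberately
permissive -- the modal non-reference base on a haplotype with more than
10% of that haplotype's reads and at least 3 observations. Each candidate
is classified on its haplotype: reference expects every read to match the
reference allele, het expects every read to match the alternate, and
somatic models each read as a mixture with mutant probability
$\alpha\phi$, where the cancer cell fraction $\phi$ follows a mixture of a
clonal point mass $\rho = 0.95$ at $\phi = 1$ and a Beta(2,2) subclonal
component. The $\phi$ integral is taken per read (inside the product over
reads), the clonal mass analytically and the Beta part by a midpoint rule
on 100 equal bins; because the integrand is linear in $\phi$, the binned
sum reduces to the bin-weighted first moment, and agreement with a
$10^5$-bin reference grid is verified in the tests. Class priors default
to $10^{-5}$ (somatic) and $10^{-3}$ (het); QUAL is
$-10\log_{10}(1 - p_{somatic})$, capped at 60. When both haplotypes
produce a candidate at one position, the higher-QUAL call is emitted and
annotated.

**Filters**: six independent hard filters --
MaxOtherHaplotypeObservations (the variant on the non-called haplotype
more than twice or in >20% of its reads; the other haplotype is an
internal control), MinObsPerStrand (alt absent from either strand),
PossibleAlignmentArtifact (more than half the alt reads with >15% window
mismatch rate, the signature of reads crossing structural-variant
breakpoints; both thresholds are this package's operationalisation of a
qualitative criterion), LowQual (QUAL < 20), MinHaplotypeDepth (<10x
either haplotype), StrandBias (Fisher $p < 10^{-3}$, another unprinted
threshold chosen here). Calls carry the full filter set; PASS means none
fired.

**Burden and spectrum** (`estimateTMB()`, `mutationSpectrum()`): TMB is
PASS calls with QUAL $\ge$ 20 divided by the callable footprint in
megabases -- burden is a genome-wide property, so the phased, callable
subset extrapolates. The 96-context spectrum maps each passing SNV to its
pyrimidine-centred trinucleotide context (purine-reference calls
reverse-complemented) in COSMIC order; `cosineSimilarity()` compares
spectra.

## The synthetic fixture generator

`makeFixture()` emulates the pipeline's inputs end to end: a random
diploid region with het SNPs at rate $\pi$, somatic mutations on one
haplotype with CCFs from the clonal/Beta mixture, and pre-aligned long
reads sampled from a tumour/normal mixture of purity $\alpha$ with uniform
errors and qualities consistent with the error rate, written as indexed
FASTA, sorted BAM, phased germline truth VCF (GT|GT with PS), somatic
truth VCF and a per-read truth table. `makeMixtureSeries()` regenerates
read sets over a purity/depth grid against one shared truth architecture,
emulating titration experiments. An optional haplotype-sampling bias
(`hap0Fraction`) produces allele-imbalanced (LOH-like) regions for
genotyper testing. Reads are generated pre-aligned with exact coordinates
and pure-match CIGARs, sidestepping an aligner dependency; read counts
target the requested depth on the coverage plateau away from region edges.

What the generator does *not* emulate -- context-dependent (homopolymer)
error profiles, indels, mapping error, chimeric reads, structural
variation, copy-number segmentation, real phasing-tool imperfections --
bounds what green tests mean: they demonstrate correctness of the models
and machinery under the models' own assumptions, not performance on real
tumour genomes.

## Problem sizes and numerical choices

The test and acceptance workloads use $G = 10^7$ sites for classifier
sweeps, 1 Mbp regions at 80x with 20 kb reads for end-to-end calling, and
100 kb fixtures for unit tests; these sizes give stable statistics (about
a hundred somatic events per sweep, ~50 per calling run) at desk-scale
runtimes. All posterior computations run in log space with
log-sum-exp normalisation; the pair-HMM uses per-row rescaling rather
than log arithmetic in the inner loop. Ties in candidate-base selection
break by fixed base order A < C < G < T; degenerate inputs (zero-depth
sites, empty read sets, zero spectra, empty callable footprints) raise
typed errors or documented conventions (F1 of an empty truth/prediction
pair is 1; precision without predictions is 0 when positives exist).

## Known limitations

Purity is a fixed configuration value (default 0.5), not estimated;
allele-specific copy number is not modelled (only the global $f$ in
genotyping); indels and multi-nucleotide variants are out of scope;
per-variant CCF posteriors are not reported; phasing itself is delegated
to an external tool and phase-set boundaries are handled only by read
rejection. These mirror the method's stated boundaries rather than
engineering shortcuts.
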