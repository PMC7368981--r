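---
title: "Differential MNase sensitivity analysis with dnsatlas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential MNase sensitivity analysis with dnsatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnsatlas)
```

## The measurement and the score

Micrococcal nuclease (MNase) preferentially cleaves accessible, linker
DNA, leaving nucleosome-protected fragments behind. Digesting the same
chromatin with a light (10 U/mL) and a heavy (100 U/mL) concentration and
sequencing both libraries gives two coverage profiles whose difference
carries structural information: loci recovered better under the light
digest are *fragile* or accessible, loci recovered better under the heavy
digest are strongly protected.

`dnsatlas` implements the differential nuclease sensitivity (DNS) score
for large repeat-rich (allo)polyploid genomes such as hexaploid wheat:

1. aligned read intervals are binned at 10 bp, counting each read once in
   every bin it overlaps by at least one base (`binCoverage`);
2. each sample is scaled to counts per million mapped reads
   (`normalizeCpm`);
3. DNS = normalized light minus normalized heavy, per bin (`dnsScore`);
4. the two biological replicates are averaged (`averageReplicates`) and
   their Pearson correlation reported (`replicateCorrelation`).

Positive DNS marks MNase hyper-sensitive (open) chromatin, negative DNS
hyper-resistant (closed) chromatin. Bins with zero raw coverage in every
sample — unassembled or unmappable space, which would otherwise dominate
genome-wide moments — are masked from moments, correlations and interval
aggregation; their stored value is 0 but flagged.

Two conventions worth stating once:

* Internally every feature lives in 1-based closed GRanges coordinates,
  the Bioconductor convention; BED/bedGraph input and output convert at
  the boundary, and round-trips are identity up to the 6-significant-digit
  bedGraph formatting. Keeping the container library's native convention
  means the coordinate arithmetic the package does is checked by the same
  machinery every other Bioconductor package relies on.
* Interval summaries are *unweighted means over overlapping 10-bp bins*
  (the per-10-bp average that makes DNS comparable across regions of very
  different size); sums are also available. Partial terminal bins are kept
  at their true width and treated as ordinary bins.

## Footprint calling

The genome-wide DNS distribution is standardized per replicate
(`standardizeTrack`: the track's own mean and population SD over unmasked
bins). A *biological* cutoff of 1.5 genome-wide SD separates outlier
regions: maximal runs of bins with z ≥ 1.5 become MNase hyper-sensitive
footprints (MSF), runs with z ≤ −1.5 hyper-resistant footprints (MRF)
(`callFootprints`). Only loci surpassing the cutoff in *both* replicates
are kept: same-kind intervals are coordinate-intersected and rescored on
the replicate-averaged track (`consensusFootprints`; union is available
via `mode = "union"`).

The segmenter is deliberately explicit rather than a reimplementation of
any external changepoint program: the 1.5-SD rule is the scientific
contract, and the parameters that a practitioner might reasonably vary are
exposed:

* `maxGapBins` — sub-threshold gaps of up to this many bins are bridged
  when every gap bin keeps the run's sign, and the merged segment is
  retained only if its mean |z| still exceeds the cutoff. The default is
  0 (conservative). In our own analyses we use 5 bins (50 bp, half a
  nucleosomal fragment): MNase fragments are ~150 bp, so neighbouring
  bins share fragments and sampling dips in an otherwise continuous
  footprint extend over runs of a few bins — a gap tolerance at that
  scale repairs them without admitting sign changes.
* `minLenBins` — minimum segment length (default 1 bin; we use 5).

## The synthetic allopolyploid genome

Every stage is testable without any external data because the package
ships a generator (`generateTruth`, `simulateReads`,
`simulateExpression`, `simulateGenotypesPhenotypes`) that emulates the
statistical structure the analyses target, with full ground truth:

* **Assembly** — homoeologous groups across subgenomes A/B/D (default six
  chromosomes "1A".."2D" of 8 Mb; the acceptance fixture uses 21
  chromosomes "1A".."7D" of 2.3 Mb, ~48 Mb in total). Each chromosome is
  tiled by segments R1/R2a/C/R2b/R3 (0.20/0.25/0.10/0.25/0.20 of its
  length) with a CENH3 interval in the centre of C.
* **Accessibility surface** `a(x)` — the log-asymmetry of the light and
  heavy digest rates. Intergenic background declines linearly from the
  telomeres (+0.02) to the centromere (−0.35); gene bodies sit at
  0.25 + u and 500-bp promoters at 0.55 + u, with a per-gene deviation
  u ~ N(0, 0.35²) shared within a homoeologous triplet (homoeologs are
  regulatorily similar; a small 0.05-SD wobble differentiates them).
  Accessibility decays from gene edges into intergenic space as
  exp(−d/κ) with κ = 2 kb. TE families carry family-specific offsets
  (Gypsy families negative and placed preferentially toward the
  pericentromere; several DNA-transposon families mildly positive).
* **Reads** — per bin and sample, fragment counts are Poisson with rate
  depth·exp(±a/2) (+ for light, − for heavy), so the DNS sign tracks the
  sign of `a` while total coverage is accessibility-independent to first
  order. Fragment midpoints are uniform in the bin; lengths are
  clipped-normal(150, 20) on [100, 200] bp, the usual mononucleosomal
  size selection. The default depth (2 fragments/bin/sample ≈ 30× base
  coverage) matches the regime in which footprint calling is expected to
  work.
* **Planted footprints** — intergenic segments of 500–1000 bp (clear of
  genes, TEs and the centromere) whose `a` is set so that the *expected
  replicate-level standardized score* is ±3. That calibration is solved
  analytically from the depth model (per-million normalization equalizes
  the digest means, so the expected standardized signal of a bin is known
  in closed form); it is done on the replicate scale because that is
  where the 1.5-SD cutoff is applied. Fragment-length smearing spreads
  any footprint's signal by ±75 bp — the physical resolution limit of
  the assay — which is why the planted lengths sit comfortably above the
  smear and why called boundaries wander by a few bins.
* **Centromere signature** — inside CENH3 both digest rates are scaled by
  0.3 (the read-depth dip) while `a` is raised to +0.9: coverage is low
  but light exceeds heavy, the DNS peak that makes differential digestion
  a centromere locator. Cereba-family elements cover ~60% of the CENH3
  interval.
* **Triplets and expression** — log10 tpm = 0.5 + u + noise(0.1 SD).
  Triplet bias categories are planted with deterministic counts
  (25% balanced, 12.5% each dominant/suppressed per subgenome — chosen so
  a ~900-triplet fixture holds ≥100 triplets per category, the size at
  which the rank tests are run): dominant homoeologs get ×8 expression
  and +0.3 accessibility over regions b/c (promoter-proximal), suppressed
  homoeologs the converse. A 10% subset of genes carries a planted
  promoter MSF bump and a ×1.3 expression lift.
* **Genotypes/phenotypes** — SNPs inside genes ±1 kb, genotypes iid
  Binomial(2, p), p ~ U(0.05, 0.5). Causal effects are drawn only for a
  200-SNP subset per extreme accessibility quintile, contributing
  h²(open) = 0.5 and h²(closed) = 0.1. The genotypes carry no linkage
  disequilibrium, so a GRM built from a SNP sample tags only the causal
  SNPs it happens to contain; concentrating the genetic variance keeps
  the open/closed contrast detectable under subsampling, which real LD
  would otherwise provide.

What the generator does **not** emulate: sequence content and alignment
error, GC and mappability bias, LD, overdispersed counts (a Poisson model
is the default; real libraries are noisier), realistic TE landscape
(~15% TE content at desk scale versus ~85% in wheat). Passing recovery
tests therefore demonstrate correctness of the estimators under the
declared generative model, not robustness to every artefact of real
libraries.

## Annotation context, gradients and tests

`assignContext` assigns each footprint a single context by its midpoint
with precedence gene body > 2-kb upstream of the CDS > 2-kb downstream >
TE > unannotated intergenic (strand-aware, CDS-anchored), so proportions
sum to one; `precedence = "te-first"` is available because intronic or
UTR-proximal TEs make the ordering a genuine choice. Distances to genes
are midpoint-to-edge; their mode is the peak of a Gaussian KDE on
log10(distance + 1) with Silverman bandwidth, back-transformed — the
right summary for distributions whose means are dominated by a long right
tail. Enrichment uses Fisher's exact test (`fisherEnrichment`), with bp
counts for segment-level questions (segment sizes differ) and element
counts for family composition; the sample odds ratio ad/bc is reported,
and above 10⁵ total counts the two-sided p is evaluated directly on the
hypergeometric pmf, where the conditional-MLE machinery of
`fisher.test` adds nothing.

Metagene profiles (`metageneProfile`) and the four 500-bp regions a–d
around the CDS start (`regionABCD`) are strand-oriented; genes within
1 kb of a chromosome end are excluded from a–d so every gene contributes
a full fixed-width window. Intergenomic comparisons within a bias
category use Kruskal-Wallis across subgenomes plus pairwise Mann-Whitney
with Benjamini-Hochberg adjustment (`tripletBiasTests`).

Triplet categorization follows the nearest-centroid rule on relative
contributions (rA, rB, rD): balanced (⅓,⅓,⅓), X-dominant (1 on X),
X-suppressed (0 on X, ½ elsewhere), Euclidean distance, ties to
balanced. The centroid table is an argument, because published centroid
conventions differ slightly between studies.

## Intergenic structure

`intergenicIntervals` merges overlapping gene models into occupied blocks
and emits the gaps between adjacent blocks, classed <10 kb, 10–100 kb,
100 kb–1 Mb, ≥1 Mb (closed-left boundaries). `decayProfiles` lays 1-kb
windows from each flanking gene edge inward to the midpoint — both sides
contribute separate series — and `backgroundDns` takes the KDE mode of
the pooled window values per class (ties to the smaller value). When we
estimate the decay constant κ from these curves we fit windows 2–8 of a
composition-balanced panel (series with at least eight windows): window 1
sits inside the fragment-smear halo of the gene edge, and an unbalanced
panel mixes interval populations across window indices, both of which
bias a naive fit.

In the segment-level gradient analysis the CENH3 core (±2 kb) is
excluded from "intergenic space": centromeric chromatin is its own state
with a planted DNS peak, and including it would contaminate the
pericentromeric background estimate. Genic flatness across segments is
assessed on triplet-averaged gene-body scores, because the per-gene
accessibility deviation is shared within a homoeologous triplet and the
three copies are not independent observations.

## Centromere prediction

`predictCentromere` combines three window-level tracks (default 1 Mb on
full-size genomes; 30 kb on the desk-scale fixture, keeping the window
well under the CENH3 width): candidate regions are maximal runs of
windows whose Cereba coverage density reaches the 0.90 quantile of the
chromosome's nonzero densities; within candidates the predicted point is
the centre of the window maximizing the smoothed DNS. The DNS peak, not
the coverage minimum, is the primary locator — the coverage and
repeat-density minima can be displaced from the functional (CENH3)
centromere, while the differential-digest peak tracks it. Ties within 1%
resolve to the lower read depth, then the smaller coordinate; with no
Cereba annotation at all the global smoothed-DNS argmax is returned with
a low-confidence flag, and multiple candidate regions (the two-peak case
some chromosomes show) are all reported.

## Variance partitioning (GRM + REML)

`rankGenomeBins` sorts unmasked 10-bp bins by DNS (ties broken by genomic
order) into five groups of 20% of the assayed genome. `selectSnps`
filters MAF > 0.002, thins to the first SNP per 10-kb tile (deterministic
by construction; the published pipelines say only "one SNP every 10 kb"),
restricts to gene bodies ±1 kb and assigns each SNP the group of its bin.
The filter order MAF → thin → genic → bin is itself a choice (thinning
before the genic restriction keeps the inter-SNP spacing genome-defined)
and each step is an exposed argument.

The GRM is A = ZZ′/m with Z column-standardized genotypes (centre 2p,
scale √(2p(1−p)), missing values mean-imputed, monomorphic SNPs
dropped). `remlVgVp` fits y = μ + g + e, g ~ (0, Aσ²g), e ~ (0, Iσ²e) by
restricted maximum likelihood, profiling λ = σ²g/σ²e through the
eigendecomposition of A and maximizing the 1-D restricted likelihood over
log λ ∈ [−25, 25]; V(G)/V(p) = λ/(1+λ), clipped to [0,1] with a boundary
flag, SE from the profile curvature by the delta method. A likelihood
that barely moves across the whole λ range (A = I: the two components are
unidentifiable) is flagged flat. `partitionExperiment` repeats
sample-GRM-fit per bin with all randomness under one seed.

## Numerical and testing notes

* All pipeline stages are deterministic given (config, seed); writers
  format numbers explicitly (no locale- or width-dependent formatting),
  so repeated runs are byte-identical.
* Test problem sizes: the package's own recovery analyses run on a
  ~48-Mb 21-chromosome fixture at 30× (about 9 million fragments per
  library), with 105 planted footprints, ~900 triplets and a
  300-individual genotype panel; unit arithmetic is checked on
  hand-sized tracks, and the DNS core is verified exactly against an
  independent interval-overlap oracle on hundreds of random small
  instances.
* The REML maximizer is validated against a dense solve/determinant grid
  search (10⁴ log-spaced λ values) — a deliberately different route to
  the same restricted likelihood.
* Known limitations: footprint boundary resolution is limited by fragment
  length (±75 bp); the null calibration of consensus footprint length
  accounts for fragment-induced bin correlation with a conservative
  16-bin block bound; `readTrack` expects bedGraph records aligned to the
  bin grid (it reads what `writeTrack` emits, not arbitrary bedGraphs);
  BAM input is out of scope — alignments are consumed as BED intervals.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- syntheticConfig(chroms = c("1A", "1B", "1D"), chromLength = 2e6)
truth <- generateTruth(cfg, seed = 1)
reads <- simulateReads(truth, seed = 1)
pipe <- dnsPipeline(reads, truth$assembly)

z1 <- standardizeTrack(asDNSTrack(pipe$dnsReps[[1]]))
z2 <- standardizeTrack(asDNSTrack(pipe$dnsReps[[2]]))
fp <- consensusFootprints(callFootprints(z1, maxGapBins = 5, minLenBins = 5),
                          callFootprints(z2, maxGapBins = 5, minLenBins = 5),
                          pipe$dns)
footprintSummary(fp, truth$assembly, truth$segments)$byKind
```
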