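---
title: "Interpreting tumor/normal whole-genome call sets with oncointerpret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting tumor/normal whole-genome call sets with oncointerpret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncointerpret)
library(dplyr)
```

## What the package models

Clinical whole-genome sequencing of a tumor with a matched normal produces
caller output — somatic SNV/indel calls, structural variants (SVs),
allele-specific copy-number segments with purity (tumor cell fraction,
TCF) and ploidy, germline calls, and microsatellite repeat-length
histograms. `oncointerpret` implements everything downstream of the
callers: high-confidence somatic filtering, mutational-catalog
construction and signature refitting, genome phenotyping (TMB, WGD, HRD,
MSI), driver interpretation, germline screening with somatic second hits,
and a rule engine that maps the findings to clinical actionability
(approved therapy / trial / exclusion of ineffective therapy) and clarity
(resistance mechanism / tumor origin / familial evaluation) categories.
Read alignment, variant calling, purity/ploidy estimation and
complex-rearrangement classification are out of scope; their outputs are
inputs here.

Because the data that motivated these rules are private patient genomes,
the package ships a synthetic call-set generator with ground-truth
manifests, so every stage is testable end to end without any download.

## Somatic filtering

A point call passes when all of: tumor variant reads ≥ 2, normal variant
reads ≤ 1, mapping quality ≥ 15, normal-sample VAF ≤ 5%, panel-of-normals
allele frequency ≤ 1%. An SV passes when tumor support ≥ 2, normal
support ≤ 1, mapping quality ≥ 15 and panel-of-normals frequency ≤ 5%.
All boundaries are inclusive on the passing side, and every failing
record carries the names of the violated criteria.

Two clauses of the filter are genuinely ambiguous as usually stated and
were resolved as package decisions, both configurable:

* the normal-read cap is set to ≤ 1, mirroring the explicit SV criterion;
* the 5% VAF ceiling is applied to the **normal** sample. A 5% ceiling on
  tumor VAF would discard nearly every true somatic call in a purity-0.6
  tumor (expected VAF ≈ 0.3); a normal-VAF ceiling is a standard
  contamination guard. The tumor reading remains available via
  `filter_thresholds(vaf_ceiling_applies_to = "tumor")` and the choice is
  recorded in the pipeline's run log.

## Catalogs and signature refitting

Catalogs use 96 substitution channels (pyrimidine-strand trinucleotide
contexts), 83 indel channels (1-bp homopolymer indels, longer indels at
repeats, deletions with microhomology) and 32 rearrangement channels
({clustered, non-clustered} × {DEL, DUP, INV} × five size bins, plus
translocations). An SV counts as clustered when ≥ 8 breakpoints fall in
some 1-Mb window containing one of its breakpoints — a deterministic
density rule chosen over the piecewise-constant-fit convention from the
rearrangement-signature literature because it is directly checkable
against a brute-force oracle; this is a documented divergence.

Exposures solve min‖Mx − c‖₂ over x ≥ 0 (Lawson–Hanson NNLS via
`pracma::lsqnonneg`) restricted to an active signature set, then rescale
so attributed counts sum to the catalog total. Reconstruction quality is
the cosine similarity between the catalog and Mx; an all-zero catalog
reports cosine 1.0 with a degenerate flag rather than NaN.

Refitting starts from a cancer-type default signature set (a bundled,
fully overridable table). If the cosine reaches 0.90 the fit stands — the
trigger is strictly below 0.90, so exactly 0.90 does not refine.
Otherwise candidates from the full reference are added greedily by cosine
gain until the target is reached or no candidate gains more than 0.005,
after which signatures attributing < 1% of mutations are pruned when
removal costs < 0.005 cosine. The 0.005 and 1% knobs are package
defaults standing in for the manual review that a clinical service would
apply; unreached targets are flagged `best_effort` rather than hidden.

### The bundled signature reference is synthetic

COSMIC reference spectra are not redistributed with the package. Instead
`synthetic_signature_reference()` builds a deterministic stand-in: sparse
pseudo-random profiles with hand-coded emphases echoing the qualitative
character of the named signatures (SBS1 mass on N[C>T]G, SBS4 on C>A,
SBS3 flat, ID6 on microhomology-deletion channels, RS3/RS5 on small
non-clustered duplications/deletions, and so on). Simulation and
refitting are internally consistent against this reference, which is what
the test suite exercises; analyses of real data should load the genuine
COSMIC matrices with `read_signature_reference()`, which accepts any
TSV in the channels × signatures layout.

## Genome phenotypes

* **TMB** is the high-confidence somatic count divided by the callable
  genome size, default 2,800 Mb (configurable; the denominator is an
  assay property).
* **WGD** is called strictly at ploidy > 3.5.
* **HRD** combines six features: exposure fractions of SBS3 and SBS8,
  ID6, and RS3+RS5; the proportion of deletions carrying microhomology;
  and the count of LOH segments (minor copy number 0) at least 15 Mb
  long, excluding chromosomes that are one whole LOH segment — the
  standard HRD-LOH convention. Each feature is standardized as
  (x − center)/scale and combined through a logistic with intercept −3;
  the weights ship as editable JSON (`default_hrd_coefficients()`)
  following the HRDetect-style convention. Scores ≥ 0.7 (inclusive) are
  HRD positive. Whether exposures enter as counts, fractions or
  log-counts was an open choice; fractions were chosen because they are
  invariant to mutation burden.
* **MSI** uses two evidence sources, either of which suffices: a
  site-level instability score (percentage of evaluable microsatellite
  loci whose tumor and normal repeat-length histograms differ) and the
  exposure fraction on the seven MSI-associated substitution signatures
  (SBS6/15/20/21/26/30/44). Default thresholds are 3.5 and 0.20.

The site-level instability test deserves a note. A locus is evaluable
with ≥ 20 reads in each histogram, and counts as unstable when a
chi-square test gives p < 0.05 **and** at least 5 tumor reads sit on
repeat lengths unobserved in the normal. The second clause is this
package's concrete minimum-count guard: a calibrated two-sample
chi-square alone flags about 5% of perfectly stable loci, which would put
every stable sample above the 3.5-score threshold by construction;
requiring novel-length support drives the stable-locus false-positive
rate to near zero while leaving genuinely shifted loci untouched.

## Driver rules

Oncogene point drivers require an oncogene-class alteration (missense,
in-frame indel, or promoter — e.g. TERT) that is recurrent (hotspot count
≥ 10; the recurrence threshold is configurable since "frequently
reported" is not a number) or drug-linked. TSG drivers are truncating
alterations (frameshift, nonsense, splice — an interpretive closure of an
exemplary list), or missense predicted deleterious by SIFT/PolyPhen or
pathogenic in ClinVar.

Gene copy number is the length-weighted mean of overlapping segments'
total copy number (a max-segment rule is available; the definition over
multi-segment genes is unstated in the field's reports). Amplification
is called at CN ≥ ploidy + 5, relaxed to ploidy + 1 for genes with a
targeted drug — the literal reading of the relaxed cutoff; a fold-change
reading is conceivable but not implemented. CN ≥ 50 adds an ecDNA-scale
hyperamplification annotation (the reported cases run to 80+ and ~185
copies) without changing amplification status. Biallelic deletion:
CN ≤ 0.5, or CN < 1 over a zero-total-copy segment.

Fusions are reported when the two breakpoints fall in different
knowledgebase genes, the pair is allowlisted or the 3' partner is a known
fusion driver (ALK, NRG1, FGFR2), and the orientations are compatible
with a head-to-tail transcript. The breakend convention is that `+`
retains the segment left of the breakpoint on the derivative; mechanism
labels (e.g. chromothripsis) are deliberately not inferred.

Germline findings require population AF < 0.5% (strict), a
pathogenic/likely-pathogenic ClinVar class, and membership in the
predisposition-gene list. Second hits are LOH at the locus, a somatic
truncating variant, a biallelic deletion or a disruptive SV; TSGs with a
somatic disruption plus LOH and no germline hit are reported as somatic
biallelic inactivation.

## Category assignment

Within the actionability arm the precedence is I-1 > I-2 > I-3 > none
(mirroring a mutually exclusive reporting breakdown; no tie-break is
otherwise defined): approved drug or phenotype match (MSI-H → immune
checkpoint therapy; HRD-positive in approved indications → PARP
inhibitor) beats a trial match beats a resistance-rule exclusion. The
clarity arm uses II-1 > II-2 > II-3: a resistance/response mechanism —
specifically wild-type-allele hyperamplification, flagged when a
hyperamplified target gene's observed mutant VAF is under half the
allele-balanced expectation (the 0.5 factor is a package choice) — then
tumor-origin evidence restricted to the tobacco-etiology rule (SBS4
fraction ≥ 0.20 and ID3 fraction ≥ 0.20), then a concluded familial
evaluation (a germline finding, or confidently negative with HRD
probability < 0.2). No general tissue-of-origin classifier is attempted.
Samples with TCF < 15% (strict) are reported noninterpretable with all
downstream sections suppressed.

Printed percentages use half-up rounding (`round_half_up()`), the
convention that makes 13/16 print as 81% and 28/79 as 35.4%.

## The synthetic generator

`simulation_config()` fixes the study conditions: tumor depth
Poisson(40), normal depth Poisson(20) — the assay's nominal coverages —
with tumor depth scaled by local copy number; expected VAF =
purity × mutated copies / (purity × total CN + 2(1 − purity)); defaults
of purity 0.6, diploid genome, 4,000 substitutions, 600 indels, 120 SVs,
200 microsatellite loci and a 10% artifact fraction. Channels are drawn
multinomially from the configured signature mixture, so catalog builders
can be checked against the generator's tally exactly. HRD-true samples
move mass to SBS3/SBS8, ID6 and RS3/RS5 and carve twelve long LOH
segments; MSI-H samples put 60% of substitution mass on MSI signatures
and shift 30% of microsatellite loci by two repeat units in the tumor
fraction of reads. Injected artifacts each violate exactly one named
filter criterion, and clean records are clamped to pass (e.g. a stray
normal read forces ≥ 20× normal depth) so the manifest labels stay
truthful. Fusions are placed inside fictitious fixture gene intervals
with compatible orientations; clustered SVs are emitted in groups of
eight starts within 0.5 Mb so the density rule provably flags them, and
non-clustered SVs are spaced on a wide grid.

What the generator does **not** emulate: read-level data, FFPE artifact
spectra, caller-specific error models, subclonal structure, and real
inter-signature correlation. Passing tests therefore demonstrate that the
implementation honours its stated rules and recovers known truth under
idealized caller output — not that the thresholds would reproduce any
particular clinical cohort.

## Worked example

```{r example}
cfg <- simulation_config(
  seed = 11, cancer_type = "prostate", hrd_status = TRUE,
  germline_payload = tibble::tibble(
    gene = "BRCA2", hgvs_p = "p.C717*", population_af = 1e-4,
    clinvar_class = "pathogenic", predisposition_gene = TRUE,
    second_hit = "loh"
  )
)
res <- interpret_simulated(cfg)
res$report
res$report$phenotypes |> select(tmb, hrd_probability, hrd_positive, msi_call)
res$report$germline_findings
res$report$category
```

```{r plots, fig.width=7, fig.height=3}
sim <- simulate_callset(cfg)
fv <- filter_snv_indel(sim$variants)
autoplot(build_sbs96_catalog(filter(fv, pass)))
```

## Problem sizes and numerical choices

The bundled test and verification workloads use 200–5,000 mutations per
catalog, 10-seed sweeps for distributional checks, 40 samples for the HRD
separation suite, 37 for MSI, and a 20-sample cohort (run twice) for
end-to-end determinism — sizes at which every check runs in minutes on a
laptop while keeping multinomial sampling error well inside the stated
tolerances (±3 percentage points at n = 5,000). Tolerances: NNLS
recovery 1e-6 on noiseless catalogs; reference columns must sum to 1
within 1e-6 (renormalized within 1e-3); ties in printed percentages
round half-up; zero-denominator cases (empty catalogs, no deletions, no
evaluable microsatellite loci) return flagged zeros or errors rather than
NaN. Determinism everywhere comes from a single integer seed:
`simulate_callset()` is byte-reproducible and reports serialize
identically across runs.

## Known limitations

* The HRD coefficients are a transparent reimplementation of the
  published weighting convention, not any proprietary coefficient set;
  absolute probabilities on real data would need recalibration.
* The bundled knowledgebase covers only the couple of dozen genes the
  rule engine and simulator exercise, with fictitious intervals on a
  miniature genome.
* Cancer-type default signature sets are a small curated table, not a
  full tissue-prevalence catalog.
* MSI scoring works on repeat-length histograms supplied as input; no
  read-level microsatellite realignment is performed.
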