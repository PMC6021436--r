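---
title: "Designing bacterial CRISPRa experiments with crisprad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing bacterial CRISPRa experiments with crisprad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprad)
```

## The problem

Bacterial CRISPR activation (CRISPRa) recruits a transcriptional activator to
a promoter through a nuclease-dead Cas9 (dCas9) programmed by a guide RNA. In
*E. coli*, activation with scaffold-RNA-recruited activators such as MCP–SoxS
fusions is strikingly sensitive to where the guide binds: strong activation is
only observed in a narrow window of target positions upstream of the
transcription start site (TSS), and the effective window differs between the
two DNA strands. Designing a working CRISPRa experiment therefore comes down
to three sequence-level tasks, all of which this package implements:

1. **Finding and scoring target sites.** Enumerate every SpCas9 target (20-nt
   protospacer followed by an NGG PAM) near a promoter, measure each site's
   distance to the TSS, classify its strand relative to the gene, and score it
   against empirically determined activation windows.
2. **Building promoters that tile target sites.** When a natural promoter
   lacks usable sites, synthesize one: a tiling array built from the repeat
   unit 5′-NNNCCNNNGG-3′ guarantees an NGG PAM every 10 nt on *each* strand,
   so guides can be walked across the upstream region at fixed resolution.
3. **Assembling guide constructs.** The activator is recruited through an
   aptamer hairpin (MS2 or PP7) appended to the guide — a scaffold RNA
   (scRNA). Several scaffold dialects exist and differ in small but
   functionally decisive ways.

A fourth module collects the quantification formulas used to read out such
experiments (Miller units, ΔΔCt, OD-normalized fluorescence, ethanol yield)
and the geometry arithmetic used to reason about activator reach.

## Coordinates and the TSS frame

Internally all coordinates are 1-based and closed, the native convention of
R and of the IRanges/GenomicRanges containers this package builds on. BED
output is converted to 0-based half-open form by `rtracklayer` on export.
Human-facing positions use the promoter-biology convention: the TSS is +1,
the first base upstream is −1, and there is no position 0. A site "at −85"
has `tss_distance = 85` in the site tables; downstream sites are flagged and
carry negative distances.

Because a 20-nt protospacer spans 20 positions, "distance to the TSS" is only
defined once you pick an anchor base. The anchor is configurable
(`pam_proximal_end`, `pam_distal_end`, `protospacer_center`, `pam_start`)
with `pam_proximal_end` — the protospacer base adjacent to the PAM — as the
documented default. The synthetic fixtures are calibrated to whatever anchor
the caller requests, so the convention round-trips exactly.

## The window model

The default activation windows place full weight (score 1.0) on:

* **non-template strand:** 80–90 bases upstream of the TSS;
* **template strand:** 50–80 bases upstream.

Everything else, including every site downstream of the TSS, scores 0.
Downstream sites are still reported — they are the relevant ones for CRISPRi
repression — but the activation model never scores them.

Two things to know about these bounds. First, the template-strand range is
reported inconsistently in the literature for this system: a figure-caption
bound of −50 to −80 and a narrower in-text bound of −60 to −80 both appear.
The default follows the wider caption bound; the model is config data
(`window_model()`, `read_window_model()`), so recalibrating is a one-line
YAML change, and the discrepancy is deliberately surfaced here rather than
silently resolved. Second, the windows are *empirical*: they summarize
reporter measurements for one activator family and need not transfer to
other effectors. Scores are therefore kept as a simple banded step function
rather than dressed up as a continuous efficacy prediction.

## The tiling-array generator

`design_array()` reproduces the published generation procedure as a
deterministic pipeline:

1. Draw candidates of 500 nt (default) by repeating the 10-nt base unit
   5′-NNNCCNNNGG-3′ and sampling every N independently. The fixed CC/GG
   positions give an anchored NGG PAM every 10 nt on each strand: 50 per
   strand in a 500-nt array.
2. Reject candidates with a homopolymer run of four or more.
3. Reject candidates containing any known transcription-factor binding site
   (exact substring on either strand, RegulonDB-style site list).
4. Reject candidates sharing any exact k-mer (default k = 15) with a
   background genome on either strand.
5. Return the first survivor, plus a per-filter attrition table, and slice a
   170-bp fragment from its promoter-proximal (3′) end.

Choices worth recording, since the published description leaves them open:

* **GC calibration acts on the whole sequence, not just the N positions.**
  Each 10-nt unit fixes 4 G/C bases, so every N is drawn G/C with
  probability \(p = (10\,g - 4)/6\) for target GC fraction \(g\); at the
  default \(g = 0.508\) (the *E. coli* genomic GC content), \(p = 0.18\).
  Whole-sequence GC is the biologically meaningful quantity. Targets at or
  below 0.4 are infeasible because of the fixed-base floor and are rejected
  with an explanatory error.
* **The default 0.508 is a package default, not a measured constant of this
  toolkit**; it is exposed as `gc_target`.
* **TF-site exclusion is exact matching.** Motif/PWM scanning would require
  inventing a score threshold; exact matching of the listed site sequences
  on both strands is the one reading that needs no extra parameters. A PWM
  mode is an explicit non-goal.
* **The homology screen is exact shared-k-mer detection** (k configurable),
  a deterministic criterion for "no detectable homology" that needs no
  external aligner. At k = 15 a chance hit against a few-megabase genome is
  vanishingly unlikely (expected shared 15-mers ≈ \(2LN/4^{15}\)).
* **"Arbitrarily chose one" is made reproducible** as the first passing
  candidate under the seed: `(seed, params)` fully determine the output,
  byte for byte. Determinism beats fidelity to an unrecorded arbitrary
  choice.
* **Which 170-bp window of the array was cloned is not recorded** in the
  source procedure; the default takes the promoter-proximal 3′ end and the
  placement is configurable (`five_prime`, explicit offset).
* Filters are pure predicates of the candidate, so their order cannot change
  any accept/reject verdict — only the attribution of rejections in the
  attrition table. The fixed order (homopolymer → TF sites → genome
  homology) runs the cheapest test first.

## Scaffold templates are data, and the shipped ones are stubs

The full sequences of the scRNA variants are published only as
supplementary material alongside the original scaffold designs and are not
redistributed in this package. The shipped config
(`inst/extdata/synthetic_scaffold_stubs.yaml`) contains clearly-labelled
synthetic stand-ins built from the canonical sgRNA backbone and the public
MS2/PP7 aptamer motifs. They preserve exactly the structural relationships
the variants are defined by — scRNA.b1 drops the tracr terminator hairpin,
scRNA.b2 differs from b1 at exactly one base, the 2x MS2 design carries two
hairpins, sgRNA 2.0 embeds MS2 inside internal hairpins — so every piece of
assembly, diffing and validation logic is exercised without the supplement.
For bench work, paste the real sequences into a user config and pass it to
`load_scaffold_templates()`. `validate_guide()` flags sgRNA 2.0 with an
efficacy warning because that design, though effective in eukaryotes, shows
no detectable CRISPRa activity in *E. coli*. Guides are emitted in DNA form
for cloning (`guide_dna()`), with the RNA form on the construct itself.

## Quantification and geometry

`miller_units()` implements Miller Units = 1000·A420/(OD600·volume·time)
with the 0.02 mL aliquot as a default, not a constant. `ddct_fold_change()`
implements the classic single-efficiency 2^(−ΔΔCt) method (reference gene
per experiment, 16S rRNA in the standard bacterial protocol); the
amplification efficiency is exposed but defaults to 2, matching the cited
method. `reach_in_bp()` floors, since partial base pairs are meaningless,
with a 1e-9 tolerance so exact multiples of the 3.3 Å/bp rise are not
floored down by floating-point error. Replicate summaries default to
median ± s.d. for cytometry and mean ± s.d. for plate-reader data, matching
the conventions of the assays; both are available for either assay.

The geometry arithmetic encodes the reach argument: extending an activator
linker from 5 to 20 residues adds 15 × 3.8 = 57 Å of contour length, while
adjacent tiling-array sites are 10 × 3.3 = 33 Å apart, so such an extension
could in principle broaden the effective window by 10–20 bp. (Empirically it
does not — the package computes the geometry, not the biology.)

## What the synthetic fixtures emulate — and what they don't

`make_promoter_with_sites()` builds promoters in which the scanned upstream
window (plus a 2-nt margin past the TSS) contains *no* PAM on either strand
except the planted ones. It does this constructively: background bases are
sampled so that no two adjacent identical G/C bases occur, which removes
every NGG/CCN without biasing the sequence toward A/T as heavily as a
globally PAM-free rejection sampler would. Planted protospacers are sampled
under the same constraint and terminated with an AGG PAM (on the + strand)
or its reverse-complement CCT (on the −), with junction bases resampled so
no accidental PAM spans a boundary. The planted ground truth is therefore an
*exact* oracle: within the upstream window the scanner must return exactly
the planted sites, and the whole suite leans on that equality. Sequence
downstream of the margin is unconstrained, so unplanted downstream sites do
occur and exercise the downstream-flagging path.

What the fixtures do not emulate: real promoter composition (the PAM-free
window is a construction, not biology), chromatin/occupancy effects, and any
expression readout — measured activation levels are wet-lab outcomes, not
computable targets, and nothing in this package pretends to predict them.
Passing tests show the *computations* are right, not that a designed guide
will activate.

## Problem sizes used in the test suite

The suite regenerates everything from seeds at run time: scanner/oracle
equivalence on 200 random sequences up to 1 kb, 100 random instances per
constraint filter, and the GC calibration on the full 10,000 × 500-nt
candidate ensemble (mean GC within 3 standard errors of the 0.508 target,
with the standard error computed from the binomial sampling variance of the
300 N positions per candidate). These sizes were chosen to match the scale
of the procedure being reproduced while keeping a full run comfortably
interactive.

## Known limitations

* No off-target scoring beyond the exact k-mer screen, no mismatch-tolerance
  model, and no NAG PAM support (the design space is strictly NGG).
* Window scores are banded empirical summaries, not mechanistic predictions;
  CRISPRi repression strength is not modeled at all.
* The shipped scaffold sequences are synthetic stubs (see above).
* Fixture promoters currently place the gene on the forward strand;
  reverse-strand classification is covered directly by the truth-table
  tests of `classify_strand()`.
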