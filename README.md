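# crisprad

Design toolkit for bacterial CRISPR activation (CRISPRa) experiments in
*E. coli*-like systems: synthetic PAM-tiling promoters, TSS-anchored target
site scanning and scoring, scaffold-RNA guide assembly, and the standard
reporter-assay quantification formulas.

## Who this is for

Bacterial CRISPRa recruits a transcriptional activator (e.g. an MCP–SoxS
fusion) to a promoter through a dCas9/scaffold-RNA complex. Activation only
works when the guide targets a narrow, strand-specific window upstream of
the transcription start site (TSS): roughly −80 to −90 on the non-template
strand and −50 to −80 on the template strand. This package is for anyone
designing such experiments: it finds and scores candidate SpCas9 target
sites around a promoter, generates synthetic promoters that guarantee a
target site every 10 bp on both strands when the natural sequence offers
none, assembles the guide/scRNA constructs that recruit the activator, and
computes the standard assay readouts.

## What it computes

* **Site scanning and window scoring** — every 20-nt protospacer + NGG PAM
  on either strand, with TSS distance (configurable anchor base),
  template/non-template strand class, and a score from a configurable
  banded window model (default: non-template 80–90, template 50–80 bases
  upstream score 1.0, all else 0). Output as a ranked table and BED6.
* **PAM tiling-array design** — candidates built from the repeat unit
  5′-NNNCCNNNGG-3′ (an NGG PAM every 10 nt on each strand; 50 anchored PAMs
  per strand in a 500-nt array), with each N drawn so the expected
  whole-sequence GC fraction hits a target (default 0.508, *E. coli*
  genomic GC; per-N G/C probability p = (10·gc − 4)/6). Candidates are
  screened by a homopolymer filter (runs ≥ 4 rejected), exact-substring
  exclusion of known TF binding sites on both strands, and an exact
  shared-k-mer (k = 15) genome homology screen; the first survivor under
  the seed is the design, with a 170-bp promoter-proximal fragment sliced
  for cloning.
* **Guide construct assembly** — 20-nt spacers substituted into scaffold
  templates (gRNA, scRNA variants with MS2/PP7 hairpins, sgRNA 2.0), with
  hairpin-annotation validation and construct diffing. Shipped templates
  are clearly-labelled synthetic stubs; real sequences are user config.
* **Quantification** — Miller units 1000·A420/(OD600·vol·time), ΔΔCt fold
  change 2^(−ΔΔCt), fluorescence/OD600, ethanol yield vs 20 g/L glucose,
  and linker/B-DNA geometry (3.8 Å/residue, 3.3 Å/bp: a 5→20 aa linker
  extension adds 57 Å; 10 bp of B-DNA spans 33 Å).

## Worked example

```r
library(crisprad)

# A synthetic promoter with three planted sites at known TSS distances
spec <- fixture_spec(rng_seed = 42, promoter_length = 200, tss_offset = 150,
                     planted_sites = data.frame(
                       distance = c(85, 65, 120),
                       strand_class = c("non-template", "template",
                                        "non-template")))
fx <- make_promoter_with_sites(spec)
ranked <- rank_sites(fx$promoter, region = c(1, fx$promoter$tss_pos))
ranked[, c("label", "site_strand", "strand_class", "tss_distance",
           "window_score")]
#>                   label site_strand strand_class tss_distance window_score
#> 1      site-65_template           -     template           65            1
#> 2  site-85_non-template           + non-template           85            1
#> 3 site-120_non-template           + non-template          120            0
```

The site at −65 on the template strand and the site at −85 on the
non-template strand fall inside the empirical activation windows and score
1.0; the site at −120 is outside every band and scores 0. The top site's
protospacer becomes the spacer of a scaffold-RNA guide:

```r
g <- assemble_guide(ranked$protospacer[1], load_scaffold_templates()$scRNA.b1,
                    target_site_ref = ranked[1, ])
g
#> <guide_construct> scRNA.b1, 100 nt
#>   spacer (DNA): AGAGAATCTCACGTGCGCGA
#>   hairpins: MS2[82-100]
validate_guide(g)$ok
#> [1] TRUE
```

Designing a fresh tiling array reproduces the published generation
procedure deterministically:

```r
d <- design_array(design_params(rng_seed = 1, n_candidates = 100))
d
#> <tiling_design> 500 nt array (candidate 9, seed 1)
#>   fragment: 170 nt (three_prime)
#>   attrition: homopolymer=8, tf_sites=0, genome_homology=0
```

Candidate 9 is the first of the seeded stream to survive the homopolymer
filter (8 were rejected); its 3′ 170-bp fragment is what goes upstream of a
weak minimal promoter. The quantification formulas are one-liners:

```r
miller_units(a420 = 0.4, od600 = 0.5, time = 20)   # 2000
ddct_fold_change(20, 15, 21, 15)                   # ddCt = -1 -> fold 2
linker_extension_length(5, 20)                     # 57 (Angstrom)
bp_span_length(10)                                 # 33 (Angstrom)
```

A thin command-line wrapper (`exec/crisprad`) exposes the same pipeline as
`scan`, `design-array`, `build-guide`, `quant` and `fixtures` subcommands.

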