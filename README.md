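# islescan

Integrase-anchored detection and classification of integrative mobile
genetic elements (MGEs) in bacterial genomes, with the comparative
tools used to study them.

## What it does, and for whom

Bacterial chromosomes accumulate integrative elements — integrative
conjugative elements (ICEs), integrative mobilizable elements (IMEs),
genomic islands (GIs) and prophages — that enter by site-specific
recombination between an element attachment site (*attI*) and a
bacterial site (*attB*), usually at the 3' end of a tRNA gene.
Integration duplicates the recombination core into flanking direct
repeats (*attL*, *attR*); excision regenerates *attB* and a circular
intermediate carrying *attI*.

`islescan` is for microbial comparative genomicists who have assembled,
annotated replicons (FASTA + GFF3) and want to:

* map integrase genes and find the direct-repeat pairs that bracket
  candidate elements (`find_integrases`, `find_direct_repeats`,
  `scan_genome`);
* classify each element from its cargo modules — phage regulatory
  switch (cI/cII/Cro), type IV secretion (virB/trb), relaxase and
  coupling protein (VirD2/VirD4), partition (ParAB/PRTRC) and
  toxin–antitoxin systems (`classify_element`, `module_catalog`);
* reconstruct *attB*/*attI* junction sequences for excision assays and
  type element presence across strains as `+` (occupied site), `-, s`
  (empty site) or `-` (no site) (`att_junctions`,
  `cross_strain_presence`);
* partition two proteomes into orthologs and strain-specific genes by
  reciprocal best hits at a 95% identity cutoff, tally COG categories,
  and compute fragment-based average nucleotide identity
  (`reciprocal_orthologs`, `cog_tally`, `ani`);
* quantify excision from real-time PCR dilution series: standard
  curves, reaction efficiency `E = 10^(-1/slope) - 1`, absolute
  quantities and fold induction (`fit_standard_curve`, `quantify_ct`,
  `fold_induction`);
* generate seeded synthetic strain pairs with implanted, ground-truthed
  elements so every stage can be tested without downloads
  (`simulate_strain_pair`, `study_implants`).

All internal coordinates are 0-based half-open; conversion happens only
at the GFF3/BED boundaries.

## Worked example

Simulate a strain pair in which strain A carries a 104-kb ICE and a
14-kb genomic island, then scan A using B as the companion strain:

```r
library(islescan)

cfg <- sim_config(
  seed = 7,
  replicons = list(list(name = "chr", length = 200000, gc = 0.61)),
  implants = list(
    implant_spec("ICE", 104341, 77, 46, "Met-CAT",
                 modules = c("trb_t4ss", "parAB", "ta_mazF")),
    implant_spec("GI", 13719, 77, 77, "Arg-CCG",
                 modules = c("ta_vapC_phd"))))
sp <- simulate_strain_pair(cfg)
sc <- scan_genome(sp$A, companion = sp$B)
sc$report[, c("mge_id", "type", "start", "end", "size_bp", "orf_count",
              "gc_percent", "att_site", "dr", "ta_systems")]
```

```
  mge_id type  start    end size_bp orf_count gc_percent att_site          dr ta_systems
1 ICEA.1  ICE  66621 170962  104341       103      57.10  Met-CAT DR (46, 46)  mazF/mazE
2  GIA.1   GI 237551 251270   13719        12      56.94  Arg-CCG DR (77, 77)   vapC/phd
```

Each row is one recovered element: its extent on the replicon (0-based
half-open, here exactly the implanted coordinates), size, CDS count,
element G+C (depressed ~4 points below the 61% backbone, as expected
for recently acquired DNA), the tRNA att site (amino acid and
anticodon), the matched direct-repeat pair, and the paired
toxin–antitoxin system.  The ICE label comes from its six distinct
mating-pair (Trb) genes; the island has no mobility genes and falls
through to GI.  Presence typing against strain B reports both elements
as absent with the empty integration site present:

```r
compare_strains(sp$A, sp$B, scanA = sc, do_ani = FALSE)$presence
```

```
  element from_strain in_strain                 status symbol
1  ICEA.1           A         B absent_with_empty_site   -, s
2   GIA.1           A         B absent_with_empty_site   -, s
```

A thin command-line wrapper over the same functions ships at
`inst/cli/islescan.R` (subcommands `simulate`, `scan`, `compare`,
`ani`, `qpcr`).

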