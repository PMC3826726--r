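---
title: "Detecting and classifying integrative mobile genetic elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying integrative mobile genetic elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islescan)
```

## The problem and the model

Integrative mobile genetic elements — integrative conjugative elements
(ICEs), integrative mobilizable elements (IMEs), genomic islands (GIs)
and prophages — enter bacterial chromosomes by site-specific
recombination.  A tyrosine-family integrase recombines an attachment
site on the element (*attI*) with a bacterial attachment site (*attB*),
most often overlapping the 3' end of a tRNA gene.  Integration
duplicates the recombination core, leaving two direct repeats that
bracket the element: *attL* at the tRNA side and *attR* at the far end.
Excision reverses the reaction, regenerating *attB* in the chromosome
and *attI* on a circular intermediate.

`islescan` turns that biology into a detection pipeline with four
stages, mirroring how such elements are found in practice:

1. **Anchor on integrases.**  CDS annotations are screened for
   integrase products (keyword mode: an `integrase`/`site-specific
   recombinase` pattern that excludes transposases and retron
   integrases, or a COG4974 qualifier; similarity mode: translated CDS
   aligned to user-supplied query integrases at >= 30% identity over
   >= 50% of the query).
2. **Find flanking direct repeats.**  The sequence around each anchor
   is compared against the surrounding replicon; every maximal
   same-orientation local match above a length and identity floor is a
   candidate *attL*/*attR* pair.  Only pairs that bracket the anchor
   are kept, because the element must contain its own integrase.
3. **Pick one pair per anchor and define the element.**  Pairs are
   ranked by tRNA association, repeat length, span and position — a
   total order, so selection is deterministic.  When a second strain is
   available, the ranking is overridden by an *empty-site test*: the
   first candidate whose reconstructed *attB* junction occurs
   contiguously in the companion genome wins (see "Why the empty-site
   test", below).
4. **Classify from cargo.**  CDS products inside the element are
   matched against a module catalog (phage regulators cI/cII/Cro,
   excisionase, structural genes; mating-pair T4SS genes virB1–virB11 /
   trb; relaxase VirD2; coupling protein VirD4/TraD; ParAB / ParB-ThiF /
   PRTRC partition systems; type II toxin–antitoxin genes), and rules
   are applied in a fixed order: a phage marker set without a T4SS is a
   prophage; four or more distinct mating-pair genes make an ICE; a
   relaxase plus coupling protein without the mating-pair set makes an
   IME; anything else of at least 5 kb flanked by repeats with an
   integrase is a GI.

Around the scanner sit the comparative tools used to study such
elements: reciprocal-best-hit (RBH) orthologs and strain-unique gene
sets at a 95% identity cutoff, fragment-based average nucleotide
identity (ANI), COG-category tallies, cross-strain att-site presence
typing (`+` occupied site, `-, s` empty site, `-` neither), and the
standard-curve mathematics of excision qPCR.

## A worked example

```{r example, eval = FALSE}
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
sc$report
compare_strains(sp$A, sp$B, scanA = sc, do_ani = FALSE)$presence
```

## Why the empty-site test

Short repeats are statistically treacherous.  A 10-bp direct repeat —
the smallest the element model must handle — is expected to occur by
chance dozens of times between a 20-kb anchor flank and a 500-kb search
region (about \(2 \times 10^4 \times 5 \times 10^5 / 4^{10}\) exact
matches), and some of those chance pairs will sit near the same tRNA as
the real one.  No ranking of tRNA association, length or span can
reliably separate a 10-bp true repeat from longer chance repeats.

What does separate them is the companion strain.  For a true pair, the
reconstructed empty-site junction — upstream flank, one repeat core,
downstream flank — is exactly the unoccupied integration site, a
contiguous stretch of the companion chromosome.  For a spurious pair
the same construction glues two loci that are adjacent in no genome.
The scanner therefore walks down the ranked candidate list and takes
the first pair whose *attB* occurs contiguously (>= 90% identity over
>= 80% of the junction) in the companion.  Occupied-site (*attL*/*attR*)
windows are deliberately *not* used for corroboration: around a
spurious pair those windows are ordinary genomic sequence and are found
trivially.

Without a companion, selection falls back to the priority ranking,
which is reliable for repeat cores of roughly 20 bp and longer; calls
anchored on shorter repeats should then be treated as tentative.

## Repeat search: algorithm and numerical choices

The repeat finder is seed-and-extend: exact 10-mer seeds
(`Biostrings::matchPDict`) are merged into maximal exact runs per
diagonal, runs of at least `min(min_len, 12)` bp are extended without
gaps under an X-drop rule (+1 match, −3 mismatch, X-drop 12), and
matches are trimmed to their maximal-scoring extent, which always ends
on a match.  Consequences worth knowing:

* Exact repeats of at least `min_len` bp are always found, and their
  reported coordinates are the maximal exact match.
* Detecting a *mutated* repeat requires an exact core of at least
  `min(min_len, 12)` bp; heavily fragmented repeats can be missed.
* The scoring (3 matches to pay for one mismatch) makes extension past
  a repeat boundary essentially impossible unless the flanking context
  itself continues to match, which is what "maximal repeat" means.
* N never matches anything, including another N, so draft-genome gaps
  cannot fabricate repeats.

Default parameters, chosen once for the scale of bacterial replicons:
anchor flank `W` = 10 kb (integrases sit within a few kb of *attL*);
maximum span `L` = 250 kb (covers the largest reported elements,
~208 kb, with headroom); minimum repeat length `m` = 14 bp with
identity >= 0.9 (the default trades the rare 10-bp site for noise
suppression; scans targeting the full observed geometry pass
`min_len = 10` and a companion genome); minimum element span 5 kb (the
GI definition's size floor).  Composition statistics (G+C, GC skew,
per-element deviation from the replicon) are computed and reported as
evidence but never gate a call — elements are defined by repeats and
integrases, not by composition.

Unequal annotated repeat lengths (an *attL* of 77 bp against an *attR*
of 46 bp, say) are modelled as an annotated attL that extends 5' beyond
the duplicated core.  The sequence-level, recoverable repeat is the
core, so the finder reports equal matched lengths and element extents
are measured from the core; the simulator's truth tables carry both the
core and the annotated attL span.

## The classifier's thresholds

"T4SS present" means at least 4 distinct mating-pair gene names
(virB1–virB11 or TrbB–TrbL).  Complete systems carry ~11; requiring 4
tolerates fragmentary annotation while still excluding IMEs, whose
relaxase/coupling pair must not count as a secretion system.  The
prophage rule needs 3 of {cI, cII, Cro, Xis, structural}; single
lysogeny-module genes are common on ICEs and must not relabel them.
Rules are ordered (prophage, ICE, IME, GI, unclassified), so every
element gets exactly one label, and adding mobility evidence can only
move an element "up" the order.  Elements sharing >= 25 kb of sequence
at >= 90% identity (assessed by mapping 5-kb chunks) form families;
when a family contains an ICE, T4SS-less members are promoted to the
family label with an explicit `by-family` flag — families of related
elements often include members whose secretion genes have decayed.
Toxin–antitoxin pairing is greedy nearest-neighbour within 2
intervening genes, which resolves interleaved systems and leaves lone
toxins as reported orphans.

## What the simulator emulates — and what it does not

The generator produces paired "strains": strain A carries the implants,
strain B the same backbone with empty integration sites (optionally
mutated at a configured divergence).  It emulates the features the
pipeline actually keys on: multi-replicon plans with configured G+C
(chromosome ~61%, plasmids lower), elements of 5–250 kb with ~57% G+C
cargo, repeat cores of 10–800 bp abutting the 3' end of generated tRNA
genes, an integrase CDS within 5 kb of *attL*, cargo products drawn
from the classifier's catalog (keeping simulator and classifier
contract-coupled), and proteome pairs with controlled ortholog
identities around the 95% cutoff.

Two deliberate idealizations matter for interpreting green tests.
First, background sequence is i.i.d. at the configured G+C, so the
background repeat structure of real genomes (rRNA operons, IS
expansions, REP elements) is absent; the false-positive measurements on
controls bound chance matches in random sequence, not repeat-driven
confusion in real chromosomes.  Second, the bases flanking each
implanted repeat copy are forced to mismatch, making ground-truth
repeats maximal exact matches — without this, "exact coordinates" would
be ill-posed, because the maximal repeat would extend past the
implanted one by chance (probability ~1/4 per boundary).  Codon usage,
realistic phylogenetic divergence and read-level sequencing are out of
scope.  Cargo CDS are random DNA, so their translations are
alignment-fodder rather than plausible proteins; this is irrelevant to
RBH behaviour, which the controlled-identity proteome generator probes
directly.

## Comparative statistics

**RBH orthologs.**  Local protein alignment uses BLOSUM62 with affine
gaps (open 11, extend 1); identity is identities over alignment
columns, gaps included — the convention of database search tools.  The
95% cutoff is applied to that quantity, with a raw-score floor of 50
standing in for a database E-value threshold (at 95% identity it is
almost never binding).  A shared-5-mer prefilter (>= 10 distinct shared
5-mers, relaxed for short proteins) keeps all-vs-all comparisons
tractable; it provably cannot drop a pair at >= 95% identity over
>= 50 aa, and tests compare the filtered path against the exhaustive
oracle.  Whether the published cutoff meant aligned-region or
full-length identity is not stated anywhere authoritative; this package
uses aligned-region identity and exposes `min_identity` for sensitivity
analysis.

**ANI.**  The query genome is cut into 1,020-bp fragments; each is
mapped by exact 13-mer seeding to its best diagonal window and aligned
locally; fragments at >= 30% identity over >= 70% of their length are
kept and ANI is their mean identity (the fragment-based convention with
30%/70% filters).  Fragments with more than 20% N are skipped.  Both
one-way values and the symmetric mean are reported; ANI(A, A) is
exactly 100 because self-fragments align perfectly.

**qPCR.**  Standard curves are ordinary least squares of Ct on log10
dilution; efficiency is `E = 10^(-1/slope) - 1` (slope −3.321928 means
E = 1); quantities are read off the curve as `10^((ct - intercept) /
slope)`; fold induction is the ratio of mean treated to mean control
*quantities* (not mean Cts — the curve is linear in log quantity, so
averaging quantities matches absolute quantification), with the spread
reported as the extreme replicate ratios.  No ΔΔCt shortcut is used.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise every geometry
while staying desk-scale: ten seeded strain pairs whose ~400-kb
backbones carry the full seven-element inventory (9.9–208 kb elements,
repeat cores 10–738 bp, ~970 kb per scanned genome), ten implant-free
1-Mb controls, 24-gene proteome plans straddling the identity cutoff
plus planted strain-specific genes, 60-kb clone pairs at 2% divergence
for ANI, and 5-point dilution series for the qPCR closed forms.  The
reference-genome comparison (deposited assemblies of the two sequenced
strains) is wired into the acceptance suite but requires the user to
place the downloaded FASTA/GFF3 files under `inst/extdata/acaldus/`;
it fails visibly, rather than silently passing, when they are absent.

## Known limitations

* Gapped repeat copies are matched ungapped; an indel inside a repeat
  splits it into two candidate matches, of which the better is used.
* Elements integrated in both compared strains cannot be corroborated
  by the empty-site test (neither strain shows *attB*); selection then
  rests on the priority ranking.
* Prophage detection is geometry-plus-cargo only; there is no
  sequence-homology phage finder, and CRISPR arrays are reported only
  if a precomputed annotation supplies them.
* Nested or overlapping elements are reported independently and
  flagged, not resolved into a hierarchy.
* The module catalog is keyword/COG-based; profile-HMM hits can be
  injected by editing the catalog table but are not computed here.
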