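mk_features <- function(products, ftype = "CDS", start0 = 0L, len = 900L) {
  n <- length(products)
  data.frame(feature_id = paste0("f", seq_len(n)), replicon_id = "chr",
             start = start0 + (seq_len(n) - 1L) * 1000L,
             end = start0 + (seq_len(n) - 1L) * 1000L + len,
             strand = "+", ftype = ftype, product = products,
             anticodon = NA_character_, cog = NA_character_)
}

test_that("keyword anchoring accepts integrases and rejects transposases", {
  ft <- mk_features(c("tyrosine recombinase/integrase", "IS5 family transposase",
                      "retron-type integrase", "hypothetical protein",
                      "phage integrase family site-specific recombinase"))
  ft$cog[4] <- "COG4974"  # unannotated product but COG qualifier
  gs <- genome_set("s", list(genome_record("chr", strrep("ACGT", 2000))), ft)
  anchors <- find_integrases(gs)
  expect_setequal(anchors$feature_id, c("f1", "f4", "f5"))
  expect_true(all(anchors$detection_mode == "keyword"))
  expect_error(find_integrases(gs, mode = "similarity"), "query")
})

test_that("similarity anchoring finds integrase-like CDS from query proteins", {
  set.seed(17)
  prot <- fx_random_protein(200)
  # back-translate the protein deterministically (one codon per aa)
  codons <- c(A="GCT",C="TGT",D="GAT",E="GAA",F="TTT",G="GGT",H="CAT",I="ATT",
              K="AAA",L="CTT",M="ATG",N="AAT",P="CCT",Q="CAA",R="CGT",S="TCT",
              T="ACT",V="GTT",W="TGG",Y="TAT")
  cds <- paste(codons[strsplit(prot, "")[[1]]], collapse = "")
  filler <- random_dna(600, 0.5)
  r <- genome_record("chr", paste0(cds, filler))
  ft <- data.frame(feature_id = c("candidate", "other"), replicon_id = "chr",
                   start = c(0L, nchar(cds)), end = c(nchar(cds), nchar(cds) + 600L),
                   strand = "+", ftype = "CDS",
                   product = "hypothetical protein",
                   anticodon = NA_character_, cog = NA_character_)
  gs <- genome_set("s", list(r), ft)
  hits <- find_integrases(gs, mode = "similarity", queries = c(q = prot))
  expect_equal(hits$feature_id, "candidate")
  expect_equal(hits$detection_mode, "similarity")
})

test_that("direct repeats around an anchor are found at exact coordinates", {
  sp <- fx_small_pair()
  t1 <- sp$truth[1, ]  # GI with 77/77 repeats
  anchors <- find_integrases(sp$A)
  a <- anchors[anchors$start > t1$start & anchors$end < t1$end, , drop = FALSE][1, ]
  pairs <- find_direct_repeats(sp$A$records$chr, a)
  hit <- pairs[pairs$left_start == t1$attL_start, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$left_end, t1$attL_end)
  expect_equal(hit$right_start, t1$attR_start)
  expect_equal(hit$right_end, t1$attR_end)
  expect_equal(hit$left_len, 77L)
  expect_identical(hit$identity, 1)
})

test_that("repeats below the minimum length are not reported", {
  set.seed(111)
  bg <- random_dna(30000, 0.55)
  rep10 <- random_dna(10, 0.5)
  seq <- paste0(substr(bg, 1, 8000), rep10, substr(bg, 8011, 22000), rep10,
                substr(bg, 22011, 30000))
  r <- genome_record("chr", seq)
  anchor <- data.frame(feature_id = "int1", replicon_id = "chr",
                       start = 9000L, end = 10200L, strand = "+",
                       product = "integrase", detection_mode = "keyword")
  covers <- function(p) p$left_start <= 8000L & p$left_end >= 8010L &
    p$right_start <= 22000L & p$right_end >= 22010L
  p14 <- find_direct_repeats(r, anchor, dr_params(min_len = 14))
  expect_false(any(covers(p14)))
  p10 <- find_direct_repeats(r, anchor, dr_params(min_len = 10))
  expect_true(any(covers(p10)))
})

test_that("a truncated right repeat is matched over its core length", {
  cfg <- sim_config(seed = 8, replicons = list(list(name = "chr", length = 80000L,
                                                    gc = 0.61)),
                    implants = list(implant_spec("ICE", 24000L, 77L, 46L, "Met-CAT",
                                                 modules = c("trb_t4ss", "parAB"))))
  sp <- simulate_strain_pair(cfg)
  sc <- scan_genome(sp$A, companion = sp$B)
  expect_equal(nrow(sc$report), 1L)
  expect_equal(sc$report$start, sp$truth$start)
  expect_equal(sc$report$end, sp$truth$end)
  expect_equal(sc$elements[[1]]$pair$right_len, 46L)
  expect_equal(sc$report$dr, "DR (46, 46)")
  expect_equal(sc$report$att_site, "Met-CAT")
})

test_that("tRNA association labels pairs by amino acid and anticodon", {
  ft <- data.frame(feature_id = "t1", replicon_id = "chr", start = 924L, end = 1000L,
                   strand = "+", ftype = "tRNA", product = "tRNA-Met",
                   anticodon = "CAT", cog = NA_character_)
  pairs <- data.frame(left_start = 950L, left_end = 1000L, right_start = 15000L,
                      right_end = 15050L, left_len = 50L, right_len = 50L,
                      identity = 1, nmatch = 50L, span = 14100L)
  lab <- associate_trna(pairs, ft, "chr")
  expect_equal(lab$att_label, "Met-CAT")
  expect_equal(lab$trna_id, "t1")
  far <- pairs; far$left_start <- 5000L; far$left_end <- 5050L
  expect_equal(associate_trna(far, ft, "chr")$att_label, "non-tRNA")
})

test_that("element selection prefers tRNA-associated, then longer, then tighter pairs", {
  sp <- fx_small_pair()
  gs <- sp$A
  anchor <- data.frame(feature_id = "x", replicon_id = "chr", start = 21000L,
                       end = 22200L, strand = "+", product = "integrase",
                       detection_mode = "keyword")
  pairs <- data.frame(left_start = c(20000L, 20100L, 20200L),
                      left_end = c(20050L, 20140L, 20250L),
                      right_start = c(40000L, 35000L, 30200L),
                      right_end = c(40050L, 35040L, 30250L),
                      left_len = c(50L, 40L, 50L), right_len = c(50L, 40L, 50L),
                      identity = 1, nmatch = c(50L, 40L, 50L),
                      span = c(20050L, 14940L, 10050L),
                      att_label = c("non-tRNA", "Met-CAT", "non-tRNA"),
                      trna_id = c(NA, "t1", NA))
  el <- select_element(pairs, anchor, gs)
  expect_equal(el$start, 20100L)  # the tRNA-associated pair wins despite lower score
  el2 <- select_element(pairs[c(1, 3), ], anchor, gs)
  expect_equal(el2$start, 20200L)  # equal length: smallest span wins
  expect_identical(select_element(pairs, anchor, gs)$start,
                   select_element(pairs, anchor, gs)$start)  # deterministic
  expect_null(select_element(pairs[0, ], anchor, gs))
})

test_that("junction sequences match hand-built strings on a toy locus", {
  set.seed(5)
  up <- random_dna(300, 0.5); core <- random_dna(20, 0.5)
  cargo <- random_dna(400, 0.5); down <- random_dna(300, 0.5)
  r <- genome_record("chr", paste0(up, core, cargo, core, down))
  s <- 300L; e <- 300L + 20L + 400L + 20L
  jx <- att_junctions(r, s, e, 20L, flank = 200L)
  expect_identical(jx$attB, paste0(substr(up, 101, 300), core, substr(down, 1, 200)))
  expect_identical(jx$attI, paste0(substr(cargo, 201, 400), core, substr(cargo, 1, 200)))
  expect_identical(jx$core, core)
  ex <- excise_element(r, s, e, 20L)
  expect_identical(ex$genome, paste0(up, core, down))
  expect_identical(ex$circle, paste0(cargo, core))
  # exactly one copy of the core remains in the excised chromosome
  expect_equal(length(Biostrings::matchPattern(core, ex$genome)), 1L)
  # short flanks at the replicon edge shorten with a warning
  expect_warning(att_junctions(r, s, e, 20L, flank = 400L), "truncated")
})

test_that("cross-strain presence distinguishes occupied, empty and missing sites", {
  sc <- fx_small_scan()
  sp <- fx_small_pair()
  el <- sc$elements[[1]]
  expect_equal(cross_strain_presence(el, sp$A), "present")
  expect_equal(cross_strain_presence(el, sp$B), "absent_with_empty_site")
  set.seed(6)
  stranger <- genome_set("x", list(genome_record("chr", random_dna(50000, 0.5))))
  expect_equal(cross_strain_presence(el, stranger), "no_site")
  expect_equal(presence_symbol("present"), "+")
  expect_equal(presence_symbol("absent_with_empty_site"), "-, s")
  expect_equal(presence_symbol("no_site"), "-")
})
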