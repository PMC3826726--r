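mk_cds <- function(products) {
  n <- length(products)
  data.frame(feature_id = paste0("c", seq_len(n)), replicon_id = "chr",
             start = (seq_len(n) - 1L) * 1000L, end = (seq_len(n) - 1L) * 1000L + 900L,
             strand = "+", ftype = "CDS", product = products,
             anticodon = NA_character_, cog = NA_character_)
}

test_that("module detection matches product keywords and COG ids", {
  ft <- mk_cds(c("TrbL mating pair protein", "VirB4 ATPase",
                 "VirD4 coupling protein", "hypothetical protein"))
  hits <- detect_modules(ft)
  expect_setequal(hits$tag[hits$feature_id == "c1"], "t4ss_mpf")
  expect_setequal(hits$tag[hits$feature_id == "c2"], "t4ss_mpf")
  expect_true("coupling" %in% hits$tag[hits$feature_id == "c3"])
  expect_false("c4" %in% hits$feature_id)
  ft2 <- mk_cds(c("MazF toxin", "MazE antitoxin", "uncharacterized protein"))
  ft2$cog[3] <- "COG4974"
  h2 <- detect_modules(ft2)
  expect_equal(h2$role[h2$tag == "mazF"], "toxin")
  expect_equal(h2$role[h2$tag == "mazE"], "antitoxin")
  expect_true("int" %in% h2$tag[h2$feature_id == "c3"])  # COG qualifier route
  expect_error(detect_modules(ft, catalog = NULL), "empty")
})

test_that("toxin-antitoxin pairing is greedy by gene distance", {
  ft <- mk_cds(c("VapC toxin", "Phd antitoxin", "hypothetical protein",
                 "HigB toxin"))
  hits <- detect_modules(ft)
  ta <- pair_toxin_antitoxin(hits, ft)
  expect_equal(nrow(ta$pairs), 1L)
  expect_equal(ta$pairs$toxin_tag, "vapC")
  expect_equal(ta$pairs$antitoxin_tag, "phd")
  expect_equal(ta$orphans$tag, "higB")  # lone toxin stays an orphan
  # two interleaved systems resolve to two pairs (T1 A1 T2 A2)
  ft2 <- mk_cds(c("MazF toxin", "MazE antitoxin", "HicA toxin", "HicB antitoxin"))
  ta2 <- pair_toxin_antitoxin(detect_modules(ft2), ft2)
  expect_equal(nrow(ta2$pairs), 2L)
  expect_setequal(paste(ta2$pairs$toxin_tag, ta2$pairs$antitoxin_tag),
                  c("mazF mazE", "hicA hicB"))
  # beyond two intervening genes, no pair forms
  ft3 <- mk_cds(c("MazF toxin", rep("hypothetical protein", 3), "MazE antitoxin"))
  ta3 <- pair_toxin_antitoxin(detect_modules(ft3), ft3)
  expect_equal(nrow(ta3$pairs), 0L)
  expect_equal(nrow(ta3$orphans), 2L)
})

test_that("classification rules reproduce the ICE / IME / GI / prophage assignments", {
  ice <- mk_cds(c("site-specific integrase",
                  paste0("conjugal transfer protein Trb", c("B", "C", "E", "G", "I", "L")),
                  "ParA partition protein", "MazF toxin", "MazE antitoxin"))
  cl <- classify_element(detect_modules(ice), 104341L, ice)
  expect_equal(cl$label, "ICE")
  expect_equal(nrow(cl$ta_pairs), 1L)
  ime <- mk_cds(c("site-specific integrase", "VirD2 relaxase",
                  "VirD4 coupling protein"))
  expect_equal(classify_element(detect_modules(ime), 80923L, ime)$label, "IME")
  gi <- mk_cds("site-specific integrase")
  expect_equal(classify_element(detect_modules(gi), 13644L, gi)$label, "GI")
  expect_equal(classify_element(detect_modules(gi), 4000L, gi)$label, "unclassified")
  pro <- mk_cds(c("site-specific integrase", "excisionase Xis",
                  "phage CI-family repressor", "phage Cro-family repressor",
                  "phage terminase large subunit"))
  expect_equal(classify_element(detect_modules(pro), 59363L, pro)$label, "prophage")
  # a full phage regulatory switch plus a T4SS is still an ICE (rule order)
  both <- rbind(pro, mk_cds(paste0("conjugal transfer protein Trb",
                                   c("B", "C", "E", "G"))))
  both$feature_id <- paste0("b", seq_len(nrow(both)))
  expect_equal(classify_element(detect_modules(both), 183318L, both)$label, "ICE")
})

test_that("classification is monotone in mobility evidence", {
  base <- mk_cds(c("site-specific integrase", "VapC toxin", "Phd antitoxin"))
  expect_equal(classify_element(detect_modules(base), 20000L, base)$label, "GI")
  more <- mk_cds(c("site-specific integrase", "VapC toxin", "Phd antitoxin",
                   paste0("conjugal transfer protein Trb", c("B", "C", "E", "G"))))
  expect_equal(classify_element(detect_modules(more), 20000L, more)$label, "ICE")
  # removing all mobility hits from a >= 5 kb element yields GI, never IME/ICE
  stripped <- mk_cds(c("site-specific integrase", "hypothetical protein"))
  expect_equal(classify_element(detect_modules(stripped), 8000L, stripped)$label, "GI")
})

test_that("family assignment groups elements sharing long backbones and promotes labels", {
  set.seed(44)
  backbone <- random_dna(56000, 0.57)
  e1 <- paste0(backbone, random_dna(20000, 0.57))
  e2 <- paste0(random_dna(15000, 0.57), islescan:::.mutate_dna(backbone, 1120))  # ~98%
  e3 <- random_dna(40000, 0.57)
  fam <- assign_families(c(ice1 = e1, gi1 = e2, other = e3),
                         c(ice1 = "ICE", gi1 = "GI", other = "GI"))
  expect_equal(fam$family[fam$element == "ice1"], fam$family[fam$element == "gi1"])
  expect_false(fam$family[fam$element == "other"] == fam$family[fam$element == "ice1"])
  expect_equal(fam$label[fam$element == "gi1"], "ICE")
  expect_true(fam$promoted[fam$element == "gi1"])
  expect_false(fam$promoted[fam$element == "ice1"])
  expect_equal(fam$label[fam$element == "other"], "GI")
})

test_that("element summaries render the report columns", {
  sc <- fx_small_scan()
  rep <- summarize_elements(sc$elements, sc$classifications, "TY")
  expect_equal(nrow(rep), 2L)
  expect_match(rep$mge_id[1], "^GITY\\.1$")
  expect_match(rep$dr, "^DR \\(\\d+, \\d+\\)")
  expect_true(all(rep$size_bp == rep$end - rep$start))
  expect_match(rep$ta_systems[rep$type == "GI"], "vapC/phd")
  empty <- summarize_elements(list(), list(), "TY")
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("mge_id", "type", "size_bp", "att_site", "dr") %in% names(empty)))
})
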