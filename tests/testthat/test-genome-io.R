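test_that("read_fasta folds case, converts U and preserves file order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "acgu", ">r2 some description", "GGCC", "AATT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(recs[[1]]$length, 4L)
  expect_equal(vapply(recs, `[[`, character(1), "replicon_id"), c("r1", "r2"))
  expect_equal(recs[[2]]$sequence, "GGCCAATT")
  expect_equal(recs[[1]]$topology, "linear")
  expect_equal(read_fasta(f, circular = "r2")[[2]]$topology, "circular")
})

test_that("read_fasta rejects bad alphabet, duplicates and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACXGT"), f)
  expect_error(read_fasta(f), "illegal character 'X'.*position 3")
  writeLines(c(">r1", "ACGT", ">r1", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "no such file")
})

test_that("GFF3 features convert to 0-based half-open and carry qualifiers", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t3\t.\t+\t.\tID=g1;product=site-specific integrase",
               "chr\tx\ttRNA\t10\t85\t.\t+\t.\tID=t1;product=tRNA-Lys-CTT",
               "chr\tx\ttRNA\t100\t175\t.\t-\t.\tID=t2;product=tRNA-Met (cat)"), f)
  ft <- read_features(f, "gff3")
  expect_equal(ft$start, c(0L, 9L, 99L))
  expect_equal(ft$end, c(3L, 85L, 175L))
  expect_equal(ft$product[1], "site-specific integrase")
  expect_equal(ft$anticodon[2], "CTT")
  expect_equal(ft$anticodon[3], "CAT")
  expect_equal(ft$ftype, c("CDS", "tRNA", "tRNA"))
})

test_that("malformed GFF3 errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t3\t.\t+\t.\tID=g1",
               "chr\tx\tCDS\t5"), f)
  expect_error(read_features(f, "gff3"), "line 3")
  writeLines(c("chr\tx\tCDS\t1\t3\t.\t%\t.\tID=g1"), f)
  expect_error(read_features(f, "gff3"), "strand")
})

test_that("extract_seq handles strands and circular wraparound", {
  r <- genome_record("r", "ACGTAC")
  expect_equal(extract_seq(r, 1, 4, "+"), "CGT")
  expect_equal(extract_seq(r, 1, 4, "-"), "ACG")
  circ <- genome_record("c", "ACGT", topology = "circular")
  expect_equal(extract_seq(circ, 3, 5), "TA")
  expect_error(extract_seq(r, 4, 8), "exceeds length")
  # rotate-string oracle for wraparound on a larger circular record
  set.seed(9)
  s <- random_dna(200, 0.5)
  rc <- genome_record("c2", s, topology = "circular")
  doubled <- paste0(s, s)
  for (st in c(150L, 180L, 199L)) {
    expect_equal(extract_seq(rc, st, st + 60L), substr(doubled, st + 1L, st + 60L))
  }
})

test_that("extraction is additive over adjacent intervals and revcomp is an involution", {
  set.seed(4)
  r <- genome_record("r", random_dna(500, 0.6))
  for (cut in c(10L, 250L, 499L)) {
    expect_equal(paste0(extract_seq(r, 0, cut), extract_seq(r, cut, 500)),
                 r$sequence)
  }
  s <- extract_seq(r, 20, 120)
  expect_equal(revcomp(revcomp(s)), s)
  expect_equal(extract_seq(r, 20, 120, "-"), revcomp(s))
})

test_that("interval writing round-trips through all three dialects", {
  iv <- data.frame(feature_id = c("e1", "e2"), replicon_id = "chr",
                   start = c(0L, 150L), end = c(100L, 275L),
                   strand = c("+", "-"), ftype = c("CDS", "CDS"),
                   product = c("site-specific integrase", "hypothetical protein"))
  for (fmt in c("bed", "gff3", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_intervals(iv, f, fmt)
    back <- read_features(f, fmt)
    expect_equal(back$start, iv$start, info = fmt)
    expect_equal(back$end, iv$end, info = fmt)
    expect_equal(back$feature_id, iv$feature_id, info = fmt)
    if (fmt != "bed") expect_equal(back$product, iv$product, info = fmt)
    expect_equal(back$strand, iv$strand, info = fmt)
  }
  # coordinate conventions on disk: BED half-open 0-based, GFF3 1-based inclusive
  fb <- withr::local_tempfile(); fg <- withr::local_tempfile()
  write_intervals(iv[1, ], fb, "bed")
  write_intervals(iv[1, ], fg, "gff3")
  expect_equal(strsplit(readLines(fb), "\t")[[1]][2:3], c("0", "100"))
  expect_equal(strsplit(readLines(fg)[2], "\t")[[1]][4:5], c("1", "100"))
})

test_that("genome_set validates feature coordinates and replicon ids", {
  r <- genome_record("chr", "ACGTACGTAC")
  bad <- data.frame(feature_id = "f", replicon_id = "chr", start = 5L, end = 12L,
                    strand = "+", ftype = "CDS", product = NA)
  expect_error(genome_set("s", list(r), bad), "outside")
  bad$end <- 4L
  expect_error(genome_set("s", list(r), bad), "outside")
  bad$replicon_id <- "nope"; bad$end <- 8L
  expect_error(genome_set("s", list(r), bad), "unknown replicons")
})

test_that("proteome translates CDS strand-aware", {
  # + strand ATGAAA -> MK; - strand: revcomp(TTTCAT) = ATGAAA -> MK
  r <- genome_record("chr", "ATGAAATTTCAT")
  ft <- data.frame(feature_id = c("p", "m"), replicon_id = "chr",
                   start = c(0L, 6L), end = c(6L, 12L), strand = c("+", "-"),
                   ftype = "CDS", product = NA)
  gs <- genome_set("s", list(r), ft)
  expect_equal(unname(proteome(gs)), c("MK", "MK"))
})
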