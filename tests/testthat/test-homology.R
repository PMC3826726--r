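test_that("protein alignment reports identity, coverage and score", {
  set.seed(21)
  p <- fx_random_protein(100)
  h <- align_protein_pair(p, p)
  expect_equal(h$identity, 1)
  expect_equal(h$coverage_shorter, 1)
  expect_equal(h$alignment_length, 100L)
  # containment: a protein vs its 50-aa prefix covers the shorter fully
  h2 <- align_protein_pair(p, substr(p, 1, 50))
  expect_equal(h2$coverage_shorter, 1)
  expect_equal(h2$identity, 1)
  expect_error(align_protein_pair("", p), "empty")
})

test_that("measured identity tracks the simulated substitution count", {
  pp <- simulate_proteome_pair(data.frame(length_aa = 300, identity = 0.90),
                               seed = 7)
  h <- align_protein_pair(pp$A[[1]], pp$B[[1]])
  expect_lt(abs(h$identity - 0.90), 0.02)
})

test_that("best_hits with prefilter equals the exhaustive all-vs-all oracle", {
  set.seed(33)
  mk <- function(n, prefix) {
    setNames(vapply(seq_len(n), function(i) fx_random_protein(150), character(1)),
             sprintf("%s%02d", prefix, seq_len(n)))
  }
  A <- mk(12, "a"); B <- mk(12, "b")
  # plant homologs at several identities straddling the cutoff
  for (i in 1:6) {
    nsub <- c(0L, 3L, 7L, 12L, 25L, 40L)[i]
    B[[i]] <- islescan:::.mutate_protein(A[[i]], nsub)
  }
  fast <- best_hits(A, B, min_identity = 0.9)
  slow <- best_hits(A, B, min_identity = 0.9, prefilter = FALSE)
  expect_equal(fast[order(fast$query), ], slow[order(slow$query), ],
               ignore_attr = TRUE)
  # prefilter never drops a >= 95% pair over >= 50 aa
  fast95 <- best_hits(A, B, min_identity = 0.95)
  expect_true(all(c("a01", "a02", "a03") %in% fast95$query))
})

test_that("reciprocal orthologs partition each proteome and are symmetric", {
  pp <- simulate_proteome_pair(
    data.frame(length_aa = rep(250, 12), identity = rep(c(1, 0.97, 0.9), 4)),
    n_unique_a = 3, n_unique_b = 5, seed = 19)
  ot <- reciprocal_orthologs(pp$A, pp$B)
  expect_setequal(c(ot$pairs$gene_a, ot$unique_a), names(pp$A))
  expect_setequal(c(ot$pairs$gene_b, ot$unique_b), names(pp$B))
  expect_equal(nrow(ot$pairs), sum(pp$truth$identity >= 0.95))
  expect_length(ot$unique_a, 3 + sum(pp$truth$identity < 0.95))
  expect_length(ot$unique_b, 5 + sum(pp$truth$identity < 0.95))
  # symmetry: swapping inputs swaps the unique sets and reverses pairs
  to <- reciprocal_orthologs(pp$B, pp$A)
  expect_setequal(to$unique_a, ot$unique_b)
  expect_setequal(to$unique_b, ot$unique_a)
  expect_setequal(paste(to$pairs$gene_b, to$pairs$gene_a),
                  paste(ot$pairs$gene_a, ot$pairs$gene_b))
  # monotonicity: lowering the cutoff never shrinks the pair set
  lo <- reciprocal_orthologs(pp$A, pp$B, min_identity = 0.85)
  expect_true(all(paste(ot$pairs$gene_a, ot$pairs$gene_b) %in%
                    paste(lo$pairs$gene_a, lo$pairs$gene_b)))
})

test_that("disjoint random proteomes share nothing", {
  set.seed(55)
  A <- setNames(vapply(1:5, function(i) fx_random_protein(200), character(1)),
                paste0("a", 1:5))
  B <- setNames(vapply(1:5, function(i) fx_random_protein(200), character(1)),
                paste0("b", 1:5))
  ot <- reciprocal_orthologs(A, B)
  expect_equal(nrow(ot$pairs), 0L)
  expect_setequal(ot$unique_a, names(A))
  expect_setequal(ot$unique_b, names(B))
})

test_that("paralog clusters match a brute-force transitive closure", {
  set.seed(77)
  base <- fx_random_protein(200)
  prot <- c(g1 = base, g2 = base,                        # identical duplicates
            g3 = islescan:::.mutate_protein(base, 4),    # ~98% copy
            g4 = fx_random_protein(200), g5 = fx_random_protein(200))
  pc <- paralog_clusters(prot)
  expect_equal(pc$non_redundant, 3L)
  expect_setequal(pc$clusters[[1]], c("g1", "g2", "g3"))
  # no duplicates: every gene its own cluster
  uniq <- setNames(vapply(1:4, function(i) fx_random_protein(150), character(1)),
                   paste0("u", 1:4))
  expect_equal(paralog_clusters(uniq)$non_redundant, 4L)
  # oracle: transitive closure over pairwise >= 95% identity decisions
  adj <- diag(length(prot)) > 0
  for (i in seq_along(prot)) for (j in seq_along(prot)) {
    if (i < j) {
      h <- align_protein_pair(prot[[i]], prot[[j]])
      adj[i, j] <- adj[j, i] <- h$identity >= 0.95 && h$score >= 50
    }
  }
  for (k in seq_along(prot)) adj <- adj | (adj[, k] %o% adj[k, ]) > 0
  oracle_clusters <- length(unique(apply(adj, 1, paste, collapse = "")))
  expect_equal(pc$non_redundant, oracle_clusters)
})

test_that("COG tallies exclude unannotated genes and match a hand count", {
  genes <- list(core = paste0("g", 1:6), flex = paste0("g", 7:10))
  mapping <- data.frame(gene_id = paste0("g", c(1:4, 7:9)),
                        category = c("L", "L", "K", "C", "V", "V", "L"))
  tal <- cog_tally(genes, mapping)
  core <- tal[tal$set == "core" & tal$n > 0, ]
  expect_equal(core$pct[core$category == "L"], 50)   # 2 of 4 annotated
  expect_equal(core$pct[core$category == "K"], 25)
  flex <- tal[tal$set == "flex" & tal$n > 0, ]
  expect_equal(flex$pct[flex$category == "V"], 200 / 3)
  expect_equal(sum(tal$pct[tal$set == "flex"]), 100)
  # all genes one category
  t1 <- cog_tally(list(s = "g1"), data.frame(gene_id = "g1", category = "P"))
  expect_equal(t1$pct[t1$category == "P"], 100)
  expect_warning(tal0 <- cog_tally(genes, data.frame(gene_id = character(),
                                                     category = character())),
                 "empty")
  expect_equal(nrow(tal0), 0L)
  expect_error(cog_tally(genes, data.frame(gene_id = "g1", category = "Z")),
               "unknown COG")
})
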