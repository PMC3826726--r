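# Proteome comparisons: pairwise local protein alignment, per-query best
# hits with a k-mer prefilter, reciprocal best hits at the 95% identity
# cutoff, paralog clustering, and COG-category tallies.

.as_proteome <- function(x) {
  if (inherits(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("proteome must be a named character vector", call. = FALSE)
  if (anyDuplicated(names(x))) stop("duplicate gene ids in proteome", call. = FALSE)
  if (any(!nzchar(x))) stop("empty protein sequence", call. = FALSE)
  x
}

#' Local alignment of two proteins
#'
#' Smith-Waterman with BLOSUM62 and affine gaps (open 11, extend 1).
#' Identity is identities / alignment length with gap columns counted in
#' the length (end overhangs excluded, as in local alignment).  Coverage
#' is the aligned span of the shorter sequence divided by its length.
#'
#' @param a,b protein strings (20-letter alphabet plus X and `*`).
#' @return list: `identity`, `alignment_length`, `coverage_shorter`,
#'   `score`.
#' @export
align_protein_pair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                       type = "local", substitutionMatrix = "BLOSUM62",
                                       gapOpening = 11, gapExtension = 1)
  alen <- Biostrings::nchar(aln)
  shorter <- min(nchar(a), nchar(b))
  span <- if (nchar(a) <= nchar(b)) Biostrings::width(Biostrings::pattern(aln)) else
    Biostrings::width(Biostrings::subject(aln))
  list(identity = if (alen > 0) Biostrings::nmatch(aln) / alen else 0,
       alignment_length = alen,
       coverage_shorter = if (alen > 0) span / shorter else 0,
       score = Biostrings::score(aln))
}

# distinct-k-mer sharing counts between two proteomes:
# data.table(query, subject, shared).  The prefilter must never drop a
# pair with true identity >= 95% over >= 50 aa; at k = 5 such a pair
# shares far more than `min_shared` 5-mers (tested against the oracle).
.kmer_prefilter <- function(qprot, sprot, k = 5L, min_shared = 10L) {
  kmers <- function(p) {
    n <- nchar(p)
    if (n < k) return(character())
    unique(substring(p, seq_len(n - k + 1L), k:n))
  }
  qk <- lapply(qprot, kmers)
  sk <- lapply(sprot, kmers)
  qdt <- data.table(query = rep(names(qprot), lengths(qk)),
                    kmer = unlist(qk, use.names = FALSE))
  sdt <- data.table(subject = rep(names(sprot), lengths(sk)),
                    kmer = unlist(sk, use.names = FALSE))
  if (!nrow(qdt) || !nrow(sdt)) return(data.table(query = character(),
                                                  subject = character()))
  j <- qdt[sdt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  pairs <- j[, .N, by = list(query, subject)]
  # short proteins cannot reach min_shared distinct k-mers: relax the floor
  qlen <- nchar(qprot); slen <- nchar(sprot)
  pairs[, floor_q := pmax(1L, pmin(min_shared, qlen[query] - 3L * k))]
  pairs[N >= floor_q, list(query, subject)]
}

#' Per-query best hits between two proteomes
#'
#' For every query protein, the highest-scoring subject whose alignment
#' passes the identity and raw-score thresholds.  Ties are broken by
#' higher identity, then lexicographic subject id.  Queries with no
#' passing hit are omitted.  A shared-5-mer prefilter keeps the search
#' tractable; set `prefilter = FALSE` for the exhaustive scan.
#'
#' @param proteomeA,proteomeB named character vectors of proteins.
#' @param min_identity identity cutoff (default 0.95).
#' @param min_score raw BLOSUM62 score floor, standing in for the
#'   E-value cutoff of database searches (default 50; at 95% identity it
#'   is almost never binding).
#' @param prefilter use the k-mer prefilter (default TRUE).
#' @return data frame: query, subject, identity, alignment_length,
#'   coverage_shorter, score.
#' @export
best_hits <- function(proteomeA, proteomeB, min_identity = 0.95, min_score = 50,
                      prefilter = TRUE) {
  A <- .as_proteome(proteomeA); B <- .as_proteome(proteomeB)
  cand <- if (prefilter) .kmer_prefilter(A, B) else
    data.table(expand.grid(query = names(A), subject = names(B),
                           stringsAsFactors = FALSE))
  if (!nrow(cand)) return(data.frame(query = character(), subject = character(),
                                     identity = numeric(), alignment_length = integer(),
                                     coverage_shorter = numeric(), score = numeric()))
  res <- lapply(seq_len(nrow(cand)), function(i) {
    h <- align_protein_pair(A[[cand$query[i]]], B[[cand$subject[i]]])
    data.frame(query = cand$query[i], subject = cand$subject[i],
               identity = h$identity, alignment_length = h$alignment_length,
               coverage_shorter = h$coverage_shorter, score = h$score,
               stringsAsFactors = FALSE)
  })
  dt <- as.data.table(do.call(rbind, res))
  dt <- dt[identity >= min_identity & score >= min_score]
  if (!nrow(dt)) return(data.frame(query = character(), subject = character(),
                                   identity = numeric(), alignment_length = integer(),
                                   coverage_shorter = numeric(), score = numeric()))
  setorder(dt, query, -score, -identity, subject)
  as.data.frame(dt[, .SD[1L], by = query])
}

#' Reciprocal-best-hit orthologs and strain-unique gene sets
#'
#' `(a, b)` is an ortholog pair iff a's best hit in B is b and b's best
#' hit in A is a, both passing the identity/score thresholds.  Genes
#' without a reciprocal partner form the strain-specific (unique) sets;
#' pairs plus `unique_A` partition proteome A exactly (likewise B).
#'
#' @inheritParams best_hits
#' @return object of class `ortholog_table`: list with `pairs` (data
#'   frame gene_a, gene_b, identity_ab, identity_ba), `unique_a`,
#'   `unique_b` (character vectors).
#' @export
reciprocal_orthologs <- function(proteomeA, proteomeB, min_identity = 0.95,
                                 min_score = 50, prefilter = TRUE) {
  A <- .as_proteome(proteomeA); B <- .as_proteome(proteomeB)
  ab <- best_hits(A, B, min_identity, min_score, prefilter)
  ba <- best_hits(B, A, min_identity, min_score, prefilter)
  ba_of <- setNames(ba$subject, ba$query)
  keep <- which(ba_of[ab$subject] == ab$query)
  pairs <- data.frame(gene_a = ab$query[keep], gene_b = ab$subject[keep],
                      identity_ab = ab$identity[keep],
                      identity_ba = ba$identity[match(ab$subject[keep], ba$query)],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 unique_a = setdiff(names(A), pairs$gene_a),
                 unique_b = setdiff(names(B), pairs$gene_b)),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("<ortholog_table> %d ortholog pairs; %d unique to A, %d unique to B\n",
              nrow(x$pairs), length(x$unique_a), length(x$unique_b)))
  invisible(x)
}

#' Write an ortholog table to TSV files
#'
#' @param ot an [reciprocal_orthologs()] result.
#' @param prefix path prefix; writes `<prefix>_pairs.tsv`,
#'   `<prefix>_unique_a.tsv`, `<prefix>_unique_b.tsv`.
#' @return the three paths, invisibly.
#' @export
write_orthologs <- function(ot, prefix) {
  paths <- paste0(prefix, c("_pairs.tsv", "_unique_a.tsv", "_unique_b.tsv"))
  write.table(ot$pairs, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("gene_id", ot$unique_a), paths[2])
  writeLines(c("gene_id", ot$unique_b), paths[3])
  invisible(paths)
}

#' Paralog clusters within one proteome
#'
#' Single-linkage clusters over self-hits at or above the identity
#' threshold (self-matches excluded).  The non-redundant gene count is
#' the number of clusters plus singletons.
#'
#' @inheritParams best_hits
#' @param proteome named character vector of proteins.
#' @return list: `clusters` (list of gene-id vectors, multi-member
#'   first), `non_redundant` (integer), `membership` (named vector).
#' @export
paralog_clusters <- function(proteome, min_identity = 0.95, min_score = 50,
                             prefilter = TRUE) {
  P <- .as_proteome(proteome)
  cand <- if (prefilter) .kmer_prefilter(P, P) else
    data.table(expand.grid(query = names(P), subject = names(P),
                           stringsAsFactors = FALSE))
  cand <- cand[query < subject]  # one alignment per unordered pair
  edges <- character(0)
  if (nrow(cand)) {
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      h <- align_protein_pair(P[[cand$query[i]]], P[[cand$subject[i]]])
      h$identity >= min_identity && h$score >= min_score
    }, logical(1))
    cand <- cand[keep]
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(cand)) cand else data.frame(query = character(), subject = character()),
    directed = FALSE, vertices = data.frame(name = names(P)))
  comp <- igraph::components(g)
  membership <- comp$membership
  clusters <- split(names(membership), membership)
  clusters <- clusters[order(-lengths(clusters))]
  names(clusters) <- NULL
  list(clusters = clusters, non_redundant = comp$no, membership = membership)
}

# canonical COG function classes used by the category tally
.COG_CLASSES <- c("L", "D", "K", "J", "O", "C", "G", "E", "I", "F", "H", "P",
                  "Q", "M", "N", "T", "U", "V")

#' COG-category percentage tally for gene sets
#'
#' Genes with no category in the mapping are excluded from the
#' denominator.  Categories are the 18 single-letter COG function
#' classes used for core/flexible genome comparisons (replication L,
#' cell cycle D, transcription K, translation J, posttranslational O,
#' energy C, carbohydrate G, amino acid E, lipid I, nucleotide F,
#' coenzyme H, inorganic ion P, secondary metabolites Q, cell wall M,
#' motility N, signal transduction T, trafficking/secretion U, defense V).
#'
#' @param gene_sets named list of gene-id vectors (e.g. core vs flexible).
#' @param mapping data frame with columns `gene_id`, `category`.
#' @return data frame: set, category, n, pct.
#' @export
cog_tally <- function(gene_sets, mapping) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (!all(c("gene_id", "category") %in% names(mapping)))
    stop("mapping needs columns gene_id, category", call. = FALSE)
  mapping <- mapping[!is.na(mapping$category) & nzchar(mapping$category), , drop = FALSE]
  bad <- setdiff(unique(mapping$category), .COG_CLASSES)
  if (length(bad)) stop("unknown COG category letter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!nrow(mapping)) {
    warning("empty gene-to-category mapping; nothing to tally")
    return(data.frame(set = character(), category = character(),
                      n = integer(), pct = numeric()))
  }
  cat_of <- setNames(mapping$category, mapping$gene_id)
  out <- lapply(names(gene_sets), function(nm) {
    cats <- cat_of[gene_sets[[nm]]]
    cats <- cats[!is.na(cats)]
    if (!length(cats)) return(NULL)
    tab <- table(factor(cats, levels = .COG_CLASSES))
    data.frame(set = nm, category = names(tab), n = as.integer(tab),
               pct = 100 * as.integer(tab) / length(cats),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(set = character(), category = character(),
                               n = integer(), pct = numeric()) else out
}
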