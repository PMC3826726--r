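# Cargo-module detection and element classification (prophage / ICE /
# IME / GI), toxin-antitoxin pairing, cross-element family assignment
# and Table-style report rendering.

#' Default cargo-module catalog
#'
#' Maps module tags to case-insensitive product-string patterns and
#' optional COG ids.  Tags cover the integration module (int, xis), the
#' lambda-like regulatory switch (cI, cII, Cro), phage structural genes,
#' mating-pair-formation T4SS components (virB1-virB11 / trb), the
#' relaxase (VirD2-type) and coupling protein (VirD4/TraD-type),
#' partition systems (ParAB, ParB-ThiF, PRTRC) and type II
#' toxin-antitoxin genes (toxins VapC, MazF, HigB, HicA, RelE, HipA;
#' antitoxins YefM, MazE, HigA, HicB, RelB, Phd, HipB).  The catalog is
#' an editable data frame, so hits from profile-based annotation can be
#' injected by adding rows.
#'
#' @return data frame: tag, pattern, cog, role (one of core, phage,
#'   mpf, relaxase, coupling, partition, toxin, antitoxin).
#' @export
module_catalog <- function() {
  rbind(
    data.frame(tag = "int", pattern = "integrase|site-specific recombinase",
               cog = "COG4974", role = "core"),
    data.frame(tag = "xis", pattern = "excisionase|\\bxis\\b",
               cog = "COG1257", role = "phage"),
    data.frame(tag = "cI", pattern = "\\bcI\\b.{0,15}repressor|phage repressor|CI-family",
               cog = "COG2932", role = "phage"),
    data.frame(tag = "cII", pattern = "\\bcII\\b|CII-family",
               cog = "pfam05269", role = "phage"),
    data.frame(tag = "cro", pattern = "\\bcro\\b|Cro-family",
               cog = "COG4197", role = "phage"),
    data.frame(tag = "phage_struct",
               pattern = "terminase|capsid|portal protein|tail protein|tail fiber|baseplate",
               cog = NA, role = "phage"),
    data.frame(tag = "t4ss_mpf",
               pattern = "\\btrb[B-L]\\b|\\bvirB(1[01]?|[2-9])\\b|mating[ -]pair",
               cog = NA, role = "mpf"),
    data.frame(tag = "relaxase", pattern = "\\bvirD2\\b|relaxase|\\bmobA\\b|\\btraI\\b",
               cog = NA, role = "relaxase"),
    data.frame(tag = "coupling",
               pattern = "\\bvirD4\\b|coupling protein|\\btraD\\b|\\btraG\\b",
               cog = NA, role = "coupling"),
    data.frame(tag = "parAB", pattern = "\\bparA\\b|\\bparB\\b|partition protein",
               cog = NA, role = "partition"),
    data.frame(tag = "parB_thiF", pattern = "parB-thiF|\\bthiF\\b.{0,20}partition",
               cog = NA, role = "partition"),
    data.frame(tag = "prtrc", pattern = "PRTRC", cog = NA, role = "partition"),
    data.frame(tag = "vapC", pattern = "\\bvapC\\b|PIN[ -]domain toxin", cog = NA, role = "toxin"),
    data.frame(tag = "mazF", pattern = "\\bmazF\\b", cog = NA, role = "toxin"),
    data.frame(tag = "higB", pattern = "\\bhigB\\b", cog = NA, role = "toxin"),
    data.frame(tag = "hicA", pattern = "\\bhicA\\b", cog = NA, role = "toxin"),
    data.frame(tag = "relE", pattern = "\\brelE\\b", cog = NA, role = "toxin"),
    data.frame(tag = "hipA", pattern = "\\bhipA\\b", cog = NA, role = "toxin"),
    data.frame(tag = "yefM", pattern = "\\byefM\\b", cog = NA, role = "antitoxin"),
    data.frame(tag = "mazE", pattern = "\\bmazE\\b", cog = NA, role = "antitoxin"),
    data.frame(tag = "higA", pattern = "\\bhigA\\b", cog = NA, role = "antitoxin"),
    data.frame(tag = "hicB", pattern = "\\bhicB\\b", cog = NA, role = "antitoxin"),
    data.frame(tag = "relB", pattern = "\\brelB\\b", cog = NA, role = "antitoxin"),
    data.frame(tag = "phd", pattern = "\\bphd\\b|prevent[ -]host[ -]death", cog = NA,
               role = "antitoxin"),
    data.frame(tag = "hipB", pattern = "\\bhipB\\b|\\bhipAB\\b", cog = NA, role = "antitoxin")
  )
}

#' Detect cargo modules among a set of CDS features
#'
#' Each CDS may match several tags; hits carry the feature id and, for
#' mating-pair genes, the matched gene token (so distinct T4SS
#' components can be counted).
#'
#' @param features CDS feature rows (e.g. those inside an element).
#' @param catalog module catalog, see [module_catalog()].
#' @return data frame: feature_id, tag, role, token, start.
#' @export
detect_modules <- function(features, catalog = module_catalog()) {
  if (is.null(catalog) || !nrow(catalog)) stop("empty module catalog", call. = FALSE)
  cds <- features[features$ftype == "CDS", , drop = FALSE]
  out <- list()
  prod <- ifelse(is.na(cds$product), "", cds$product)
  cogq <- ifelse(is.na(cds$cog), "", cds$cog)
  for (i in seq_len(nrow(catalog))) {
    hit <- grepl(catalog$pattern[i], prod, ignore.case = TRUE, perl = TRUE)
    if (!is.na(catalog$cog[i])) hit <- hit | cogq == catalog$cog[i]
    if (!any(hit)) next
    token <- rep(NA_character_, sum(hit))
    if (catalog$tag[i] == "t4ss_mpf") {
      m <- regmatches(prod[hit],
                      regexpr("trb[B-L]|virB(1[01]?|[2-9])", prod[hit], ignore.case = TRUE))
      token[seq_along(m)] <- toupper(m)
      token[!nzchar(token) | is.na(token)] <- "MPF"
    }
    out[[length(out) + 1L]] <- data.frame(feature_id = cds$feature_id[hit],
                                          tag = catalog$tag[i],
                                          role = catalog$role[i],
                                          token = token,
                                          start = cds$start[hit],
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(feature_id = character(), tag = character(),
                                      role = character(), token = character(),
                                      start = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$tag), ]
}

#' Pair toxin and antitoxin genes
#'
#' A toxin and an antitoxin CDS within `max_between` intervening genes
#' of each other form a pair; pairing is greedy by gene distance (ties
#' by position), so two interleaved systems resolve to two pairs.
#' Unpaired hits are reported as orphans.
#'
#' @param hits output of [detect_modules()].
#' @param features the CDS features the hits were called on (used for
#'   gene order).
#' @param max_between maximum intervening genes (default 2).
#' @return list: `pairs` (data frame toxin, antitoxin, toxin_tag,
#'   antitoxin_tag), `orphans` (data frame feature_id, tag, role).
#' @export
pair_toxin_antitoxin <- function(hits, features, max_between = 2L) {
  cds <- features[features$ftype == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), ]
  idx <- setNames(seq_len(nrow(cds)), cds$feature_id)
  tox <- hits[hits$role == "toxin", , drop = FALSE]
  ant <- hits[hits$role == "antitoxin", , drop = FALSE]
  pairs <- data.frame(toxin = character(), antitoxin = character(),
                      toxin_tag = character(), antitoxin_tag = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tox) && nrow(ant)) {
    cand <- expand.grid(ti = seq_len(nrow(tox)), ai = seq_len(nrow(ant)))
    cand$dist <- abs(idx[tox$feature_id[cand$ti]] - idx[ant$feature_id[cand$ai]]) - 1L
    cand <- cand[cand$dist >= 0L & cand$dist <= max_between, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$ti, cand$ai), , drop = FALSE]
    used_t <- logical(nrow(tox)); used_a <- logical(nrow(ant))
    for (r in seq_len(nrow(cand))) {
      ti <- cand$ti[r]; ai <- cand$ai[r]
      if (used_t[ti] || used_a[ai]) next
      used_t[ti] <- TRUE; used_a[ai] <- TRUE
      pairs <- rbind(pairs, data.frame(toxin = tox$feature_id[ti],
                                       antitoxin = ant$feature_id[ai],
                                       toxin_tag = tox$tag[ti],
                                       antitoxin_tag = ant$tag[ai],
                                       stringsAsFactors = FALSE))
    }
    orphans <- rbind(tox[!used_t, c("feature_id", "tag", "role")],
                     ant[!used_a, c("feature_id", "tag", "role")])
  } else {
    orphans <- rbind(tox[, c("feature_id", "tag", "role")],
                     ant[, c("feature_id", "tag", "role")])
  }
  rownames(orphans) <- NULL
  list(pairs = pairs, orphans = orphans)
}

# distinct mating-pair-formation gene count from module hits
.mpf_count <- function(hits) {
  tk <- hits$token[hits$tag == "t4ss_mpf"]
  tk[is.na(tk)] <- "MPF"
  length(unique(tk))
}

#' Classify an element from its module inventory
#'
#' Rules are applied in order, so every element gets exactly one label:
#' (1) three or more phage markers (cI, cII, Cro, Xis, structural genes)
#' without a mating-pair T4SS: prophage; (2) four or more distinct
#' mating-pair T4SS genes (virB/trb): ICE; (3) relaxase plus coupling
#' protein without the mating-pair set: IME; (4) at least `gi_min_size`
#' bp: GI; (5) otherwise unclassified.
#'
#' @param hits [detect_modules()] output for the element.
#' @param size_bp element size.
#' @param features element CDS features (for toxin-antitoxin pairing).
#' @param min_mpf distinct mating-pair genes that count as a T4SS
#'   (default 4).
#' @param min_phage distinct phage markers that count as a prophage
#'   signature (default 3).
#' @param gi_min_size GI size floor in bp (default 5000).
#' @return object of class `mge_classification`: list with `label`,
#'   `evidence` (tags found), `ta_pairs`, `ta_orphans`, `n_mpf`.
#' @export
classify_element <- function(hits, size_bp, features = NULL, min_mpf = 4L,
                             min_phage = 3L, gi_min_size = 5000L) {
  tags <- unique(hits$tag)
  n_mpf <- .mpf_count(hits)
  phage_tags <- intersect(tags, c("cI", "cII", "cro", "xis", "phage_struct"))
  has_t4ss <- n_mpf >= min_mpf
  label <- if (length(phage_tags) >= min_phage && !has_t4ss) "prophage"
  else if (has_t4ss) "ICE"
  else if (all(c("relaxase", "coupling") %in% tags)) "IME"
  else if (size_bp >= gi_min_size) "GI"
  else "unclassified"
  ta <- if (!is.null(features)) pair_toxin_antitoxin(hits, features) else
    list(pairs = NULL, orphans = NULL)
  structure(list(label = label, evidence = tags, ta_pairs = ta$pairs,
                 ta_orphans = ta$orphans, n_mpf = n_mpf),
            class = "mge_classification")
}

#' @export
print.mge_classification <- function(x, ...) {
  cat(sprintf("<mge_classification> %s (modules: %s; %d distinct MPF genes)\n",
              x$label, paste(x$evidence, collapse = ", "), x$n_mpf))
  invisible(x)
}

#' Group elements into families by shared sequence
#'
#' Elements share a family when local alignments at `min_identity` or
#' better cover at least `min_shared` bp of sequence between them
#' (assessed by mapping 5-kb chunks of the smaller element onto the
#' larger).  Families are connected components of that sharing graph.
#' When a family contains an ICE, members lacking the T4SS themselves
#' are promoted to the family label with a `by_family` flag.
#'
#' @param seqs named character vector of element sequences.
#' @param labels named character vector of classifier labels for the
#'   same elements.
#' @param min_shared shared-sequence threshold in bp (default 25000).
#' @param min_identity chunk identity threshold (default 0.9).
#' @param chunk chunk size in bp (default 5000).
#' @return data frame: element, family, label, promoted.
#' @export
assign_families <- function(seqs, labels, min_shared = 25000L, min_identity = 0.9,
                            chunk = 5000L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  labels <- labels[names(seqs)]
  n <- length(seqs)
  edges <- data.frame(a = character(), b = character())
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      la <- nchar(seqs[[i]]); lb <- nchar(seqs[[j]])
      if (min(la, lb) < min_shared) next
      qi <- if (la <= lb) i else j
      sj <- if (la <= lb) j else i
      q <- seqs[[qi]]; s <- seqs[[sj]]
      starts <- seq.int(1L, nchar(q), by = chunk)
      shared <- 0L
      for (st in starts) {
        fr <- substr(q, st, min(nchar(q), st + chunk - 1L))
        if (nchar(fr) < chunk / 2) next
        m <- find_local_matches(fr, s, seed_k = 13L, min_len = 500L,
                                min_identity = min_identity, xdrop = 20L,
                                max_matches = 50L)
        if (nrow(m)) {
          # non-overlapping query coverage of this chunk
          m <- m[order(-m$nmatch), , drop = FALSE]
          covered <- logical(nchar(fr))
          for (r in seq_len(nrow(m))) {
            span <- seq.int(m$qstart[r] + 1L, m$qend[r])
            covered[span] <- TRUE
          }
          shared <- shared + sum(covered)
        }
        if (shared >= min_shared) break
      }
      if (shared >= min_shared)
        edges <- rbind(edges, data.frame(a = names(seqs)[i], b = names(seqs)[j]))
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = names(seqs)))
  comp <- igraph::components(g)$membership
  fam <- paste0("F", comp[names(seqs)])
  out <- data.frame(element = names(seqs), family = fam,
                    label = unname(labels), promoted = FALSE,
                    stringsAsFactors = FALSE)
  for (f in unique(out$family)) {
    memb <- out$family == f
    if (sum(memb) > 1L && any(out$label[memb] == "ICE")) {
      promote <- memb & out$label != "ICE" & out$label != "prophage"
      out$label[promote] <- "ICE"
      out$promoted[promote] <- TRUE
    }
  }
  out
}

#' Render classified elements as a per-element summary table
#'
#' One row per element with an auto-generated id `<Type><strain>.<n>`,
#' size, ORF and G+C columns, the att-site label and the repeat pair
#' rendered `"DR (l, r)"`.
#'
#' @param elements list of `candidate_element` objects.
#' @param classifications list of [classify_element()] results, parallel
#'   to `elements`.
#' @param strain_id strain label used in the ids.
#' @return data frame with the report columns.
#' @export
summarize_elements <- function(elements, classifications, strain_id = "strain") {
  if (!length(elements)) {
    return(data.frame(mge_id = character(), type = character(),
                      replicon = character(), start = integer(), end = integer(),
                      size_bp = integer(), orf_count = integer(),
                      gc_percent = numeric(), gc_deviation = numeric(),
                      att_site = character(), dr = character(),
                      modules = character(), ta_systems = character(),
                      stringsAsFactors = FALSE))
  }
  counts <- integer(0)
  rows <- lapply(seq_along(elements), function(i) {
    el <- elements[[i]]; cl <- classifications[[i]]
    ty <- cl$label
    counts[ty] <<- (if (is.na(counts[ty])) 0L else counts[ty]) + 1L
    ta <- if (!is.null(cl$ta_pairs) && nrow(cl$ta_pairs))
      paste(paste0(cl$ta_pairs$toxin_tag, "/", cl$ta_pairs$antitoxin_tag),
            collapse = " ") else "-"
    data.frame(mge_id = sprintf("%s%s.%d", ty, strain_id, counts[[ty]]),
               type = ty, replicon = el$replicon_id,
               start = el$start, end = el$end, size_bp = el$size_bp,
               orf_count = el$orf_count, gc_percent = el$gc_percent,
               gc_deviation = round(el$gc_deviation, 2),
               att_site = el$att_label,
               dr = sprintf("DR (%d, %d)", el$pair$left_len, el$pair$right_len),
               modules = paste(cl$evidence, collapse = ","),
               ta_systems = ta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
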