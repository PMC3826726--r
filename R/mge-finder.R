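# Integrase-anchored element detection: anchors, flanking direct repeats
# (attL/attR), tRNA association, element selection, attB/attI junction
# reconstruction and cross-strain presence typing.

#' Find integrase anchors among annotated CDS
#'
#' Keyword mode matches product text against an integrase pattern while
#' excluding transposases and retrons, or accepts a COG4974 qualifier.
#' Similarity mode translates each CDS and keeps those aligning to any
#' query integrase at >= 30% identity over >= 50% of the query.
#'
#' @param gs a [genome_set()].
#' @param mode `"keyword"` or `"similarity"`.
#' @param queries named character vector of query integrase proteins
#'   (similarity mode only).
#' @param include_pattern,exclude_pattern regexes for keyword mode
#'   (case-insensitive).
#' @param min_identity,min_query_cov similarity-mode thresholds.
#' @return data frame of anchors: feature_id, replicon_id, start, end,
#'   strand, product, detection_mode.
#' @export
find_integrases <- function(gs, mode = c("keyword", "similarity"), queries = NULL,
                            include_pattern = "integrase|site-specific recombinase",
                            exclude_pattern = "transposase|retron",
                            min_identity = 0.3, min_query_cov = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(gs, "genome_set"))
  cds <- gs$features[gs$features$ftype == "CDS", , drop = FALSE]
  cols <- c("feature_id", "replicon_id", "start", "end", "strand", "product")
  if (!nrow(cds)) return(cbind(cds[, cols], detection_mode = character()))
  if (mode == "keyword") {
    prod <- ifelse(is.na(cds$product), "", cds$product)
    hit <- (grepl(include_pattern, prod, ignore.case = TRUE) &
              !grepl(exclude_pattern, prod, ignore.case = TRUE)) |
      (!is.na(cds$cog) & cds$cog == "COG4974")
  } else {
    if (is.null(queries) || !length(queries))
      stop("similarity mode requires query integrase proteins", call. = FALSE)
    prots <- proteome(gs)
    prots <- prots[cds$feature_id]
    hit <- vapply(prots, function(p) {
      if (is.na(p) || !nzchar(p)) return(FALSE)
      for (q in queries) {
        aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(q),
                                             Biostrings::AAString(p), type = "local",
                                             substitutionMatrix = "BLOSUM62",
                                             gapOpening = 11, gapExtension = 1)
        alen <- Biostrings::nchar(aln)
        if (alen > 0 &&
            Biostrings::nmatch(aln) / alen >= min_identity &&
            Biostrings::width(Biostrings::pattern(aln)) / nchar(q) >= min_query_cov)
          return(TRUE)
      }
      FALSE
    }, logical(1))
  }
  out <- cds[hit, cols, drop = FALSE]
  out$detection_mode <- rep(mode, nrow(out))
  rownames(out) <- NULL
  out
}

#' Default direct-repeat search parameters
#'
#' `flank`: window each side of the anchor whose sequence is searched
#' for re-occurrence; `max_span`: maximum attL-to-attR span (covers the
#' largest reported elements, ~208 kb, with headroom); `min_len`:
#' minimum repeat length; `min_identity`: minimum repeat identity;
#' `seed_k`: exact seed length; `min_span`: smallest reportable element.
#'
#' @return named list of parameters.
#' @export
dr_params <- function(flank = 10000L, max_span = 250000L, min_len = 14L,
                      min_identity = 0.9, seed_k = 10L, min_span = 5000L) {
  list(flank = as.integer(flank), max_span = as.integer(max_span),
       min_len = as.integer(min_len), min_identity = min_identity,
       seed_k = as.integer(seed_k), min_span = as.integer(min_span))
}

#' Direct-repeat (attL/attR) pairs around an integrase anchor
#'
#' The sequence flanking the anchor is compared against the replicon
#' within `max_span` of the anchor; every maximal same-orientation local
#' match of at least `min_len` bp at `min_identity` or better yields a
#' candidate pair, with attL/attR assigned by genomic order.  Only pairs
#' that bracket the anchor (left repeat ends before the anchor starts,
#' right repeat starts after it ends) are kept, since the element must
#' contain its integrase.  Pairs are sorted by match score.
#'
#' @param record the [genome_record()] carrying the anchor.
#' @param anchor one row of [find_integrases()] output.
#' @param params parameter list from [dr_params()].
#' @return data frame: left_start, left_end, right_start, right_end,
#'   left_len, right_len, identity, nmatch, span (0-based half-open).
#' @export
find_direct_repeats <- function(record, anchor, params = dr_params()) {
  stopifnot(inherits(record, "genome_record"))
  len <- record$length
  a_start <- anchor$start; a_end <- anchor$end
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      left_len = integer(), right_len = integer(),
                      identity = numeric(), nmatch = integer(), span = integer())
  flo <- max(0L, a_start - params$flank)
  fhi <- min(len, a_end + params$flank)
  if (fhi - flo < params$seed_k) {
    warning("anchor ", anchor$feature_id, " has no usable flank; empty result")
    return(empty)
  }
  mid <- (a_start + a_end) %/% 2L
  rlo <- max(0L, mid - params$max_span)
  rhi <- min(len, mid + params$max_span)
  flank_seq <- substr(record$sequence, flo + 1L, fhi)
  region_seq <- substr(record$sequence, rlo + 1L, rhi)
  m <- find_local_matches(flank_seq, region_seq, seed_k = params$seed_k,
                          min_len = params$min_len,
                          min_identity = params$min_identity,
                          max_matches = 100000L)
  if (!nrow(m)) return(empty)
  qa <- m$qstart + flo; qb <- m$qend + flo
  sa <- m$sstart + rlo; sb <- m$send + rlo
  self <- qa == sa
  left_start <- pmin(qa, sa); left_end <- pmin(qb, sb)
  right_start <- pmax(qa, sa); right_end <- pmax(qb, sb)
  dt <- data.table(left_start, left_end, right_start, right_end,
                   identity = m$identity, nmatch = m$nmatch,
                   length = m$length)[!self]
  dt <- unique(dt, by = c("left_start", "right_start", "length"))
  dt[, span := right_end - left_start]
  dt <- dt[left_end <= right_start &            # repeats must not overlap
             span <= params$max_span &
             left_end <= a_start & right_start >= a_end]  # bracket the anchor
  if (!nrow(dt)) return(empty)
  setorder(dt, -nmatch, span, left_start)
  data.frame(left_start = dt$left_start, left_end = dt$left_end,
             right_start = dt$right_start, right_end = dt$right_end,
             left_len = dt$length, right_len = dt$length,
             identity = dt$identity, nmatch = dt$nmatch, span = dt$span)
}

# amino-acid label from tRNA product text ("tRNA-Met ..." -> "Met")
.trna_aa <- function(product) {
  m <- regmatches(product, regexec("tRNA-([A-Za-z]{3})", product))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, character(1))
}

#' Label direct-repeat pairs with their associated tRNA
#'
#' A pair is tRNA-associated when a tRNA gene's 3' end lies within
#' `max_dist` bp of the left repeat (or, failing that, the right
#' repeat).  Labels are formatted `"AminoAcid-Anticodon"` (e.g.
#' `"Met-CAT"`); when two genes abut the repeat both labels are emitted,
#' comma-separated; pairs with no nearby tRNA are labeled `"non-tRNA"`.
#'
#' @param pairs output of [find_direct_repeats()].
#' @param features feature data frame of the genome set.
#' @param replicon_id replicon the pairs live on.
#' @param max_dist association distance in bp (default 100).
#' @return `pairs` with `att_label` and `trna_id` columns added.
#' @export
associate_trna <- function(pairs, features, replicon_id, max_dist = 100L) {
  trna <- features[features$ftype == "tRNA" & features$replicon_id == replicon_id, ,
                   drop = FALSE]
  n <- nrow(pairs)
  pairs$att_label <- rep("non-tRNA", n)
  pairs$trna_id <- rep(NA_character_, n)
  if (!nrow(trna) || !n) return(pairs)
  end3 <- ifelse(trna$strand == "-", trna$start, trna$end)
  aa <- .trna_aa(ifelse(is.na(trna$product), "", trna$product))
  lab <- ifelse(is.na(trna$anticodon), aa, paste0(aa, "-", trna$anticodon))
  lab[is.na(aa)] <- trna$feature_id[is.na(aa)]
  dist_to <- function(p3, lo, hi) ifelse(p3 >= lo & p3 <= hi, 0L,
                                         pmin(abs(p3 - lo), abs(p3 - hi)))
  for (i in seq_len(n)) {
    dl <- dist_to(end3, pairs$left_start[i], pairs$left_end[i])
    hit <- which(dl <= max_dist)
    if (!length(hit)) {
      dr <- dist_to(end3, pairs$right_start[i], pairs$right_end[i])
      hit <- which(dr <= max_dist)
    }
    if (length(hit)) {
      hit <- hit[order(pmin(dl, Inf)[hit])]
      pairs$att_label[i] <- paste(lab[hit], collapse = ", ")
      pairs$trna_id[i] <- paste(trna$feature_id[hit], collapse = ", ")
    }
  }
  pairs
}

#' Reconstruct attB and attI junction sequences
#'
#' For an element `[s, e)` whose repeat copies share an exact-core
#' length `c`:  attB (empty site after excision) is `flank` bp upstream
#' of attL, one repeat copy, and `flank` bp downstream of attR; attI
#' (circular-intermediate junction) is the last `flank` bp of the
#' excised circle, the right repeat copy, and the first `flank` bp of
#' the circle.  Flanks truncated at a replicon edge are shortened with a
#' warning.
#'
#' @param record the [genome_record()].
#' @param start,end element extent (attL start to attR end), 0-based
#'   half-open.
#' @param core_len length of the matched repeat core.
#' @param flank junction flank length (default 200 bp).
#' @return list: `attB`, `attI` (character), plus the `core` sequence.
#' @export
att_junctions <- function(record, start, end, core_len, flank = 200L) {
  seq <- record$sequence
  len <- record$length
  s <- start; e <- end; c <- core_len
  if (e - s <= 2L * c) stop("element shorter than two repeat cores", call. = FALSE)
  if (s - flank < 0L || e + flank > len)
    warning("junction flank truncated at replicon edge")
  up <- substr(seq, max(0L, s - flank) + 1L, s)
  down <- substr(seq, e + 1L, min(len, e + flank))
  core_left <- substr(seq, s + 1L, s + c)
  core_right <- substr(seq, e - c + 1L, e)
  circle <- substr(seq, s + c + 1L, e)    # excised circle, core at its 3' end
  nc <- nchar(circle)
  inside_end <- substr(circle, max(1L, nc - c - flank + 1L), nc - c)
  inside_start <- substr(circle, 1L, min(flank, nc - c))
  list(attB = paste0(up, core_left, down),
       attI = paste0(inside_end, core_right, inside_start),
       core = core_left)
}

#' Excise an element in silico
#'
#' Site-specific recombination between the two repeat cores leaves one
#' core in the chromosome and one on the excised circle: together the
#' two products contain every base of the original locus exactly once,
#' apart from the duplicated repeat core.
#'
#' @inheritParams att_junctions
#' @return list: `genome` (replicon sequence after excision), `circle`
#'   (excised circular intermediate, linearized at the attI junction so
#'   its 3' end is the repeat core).
#' @export
excise_element <- function(record, start, end, core_len) {
  seq <- record$sequence
  list(genome = paste0(substr(seq, 1L, start),
                       substr(seq, start + 1L, start + core_len),
                       substr(seq, end + 1L, record$length)),
       circle = substr(seq, start + core_len + 1L, end))
}

# presence status of an element's att junctions in another genome
.presence_status <- function(attL_j, attR_j, attB, other, min_identity = 0.9,
                             min_cov = 0.8) {
  if (.query_present(attL_j, other, min_identity, min_cov) &&
      .query_present(attR_j, other, min_identity, min_cov)) return("present")
  if (.query_present(attB, other, min_identity, min_cov))
    return("absent_with_empty_site")
  "no_site"
}

#' Pick the best direct-repeat pair for an anchor and build the element
#'
#' Candidate pairs are ranked by (1) tRNA association, (2) repeat
#' length, (3) smallest span, (4) leftmost start (a total order, so the
#' choice is deterministic).  When a companion genome is supplied the
#' ranking is refined the way a second sequenced strain is used in
#' comparative scans: walking down the ranked list, the first pair
#' whose reconstructed empty-site (attB) junction occurs contiguously
#' in the companion is selected; if none does, the top-ranked pair is
#' used.  A spurious repeat pair cannot pass this check: its attB
#' junction glues two loci that are not adjacent in any real genome,
#' whereas a true pair's attB is the companion's unoccupied
#' integration site.  (Occupied-site attL/attR windows are not used for
#' corroboration: around a spurious pair they are ordinary genomic
#' sequence and would be found trivially.)
#'
#' @param pairs labeled pairs from [associate_trna()].
#' @param anchor the anchor row.
#' @param gs the [genome_set()] being scanned.
#' @param companion optional second [genome_set()] for junction
#'   corroboration.
#' @param params list from [dr_params()] (uses `min_span`).
#' @param junction_flank flank used for junction reconstruction.
#' @param max_verify maximum candidates to test against the companion.
#' @return a `candidate_element` list, or `NULL` when no pair qualifies.
#' @export
select_element <- function(pairs, anchor, gs, companion = NULL,
                           params = dr_params(), junction_flank = 200L,
                           max_verify = 200L) {
  record <- gs$records[[anchor$replicon_id]]
  if (!nrow(pairs)) return(NULL)
  pairs <- pairs[pairs$span >= params$min_span &
                   pairs$span > 2L * pairs$right_len, , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  ord <- order(pairs$att_label == "non-tRNA",      # tRNA-associated first
               -pairs$left_len, pairs$span, pairs$left_start)
  pairs <- pairs[ord, , drop = FALSE]
  pick <- 1L
  verified <- NA
  if (!is.null(companion)) {
    verified <- FALSE
    for (i in seq_len(min(nrow(pairs), max_verify))) {
      jx <- suppressWarnings(att_junctions(record, pairs$left_start[i],
                                           pairs$right_end[i], pairs$right_len[i],
                                           flank = junction_flank))
      if (.query_present(jx$attB, companion)) { pick <- i; verified <- TRUE; break }
    }
  }
  p <- pairs[pick, , drop = FALSE]
  s <- p$left_start; e <- p$right_end
  jx <- suppressWarnings(att_junctions(record, s, e, p$right_len,
                                       flank = junction_flank))
  feats <- gs$features
  inside <- feats$replicon_id == anchor$replicon_id & feats$ftype == "CDS" &
    feats$start >= s & feats$end <= e
  el_seq_gc <- gc_content(substr(record$sequence, s + 1L, e))
  structure(list(replicon_id = anchor$replicon_id, start = s, end = e,
                 size_bp = e - s, anchor = anchor, pair = p,
                 att_label = p$att_label, trna_id = p$trna_id,
                 orf_count = sum(inside),
                 gc_percent = round(100 * el_seq_gc, 2),
                 gc_deviation = element_gc_deviation(record, s, e),
                 attB_seq = jx$attB, attI_seq = jx$attI, core_seq = jx$core,
                 attL_junction = extract_seq(record, max(0L, s - junction_flank),
                                             min(record$length, p$left_end + junction_flank)),
                 attR_junction = extract_seq(record, max(0L, p$right_start - junction_flank),
                                             min(record$length, e + junction_flank)),
                 companion_verified = verified),
            class = "candidate_element")
}

#' @export
print.candidate_element <- function(x, ...) {
  cat(sprintf("<candidate_element> %s:[%d, %d) %d bp, %d ORFs, G+C %.2f%%, att %s, DR (%d, %d)\n",
              x$replicon_id, x$start, x$end, x$size_bp, x$orf_count, x$gc_percent,
              x$att_label, x$pair$left_len, x$pair$right_len))
  invisible(x)
}

#' Presence of an element's integration site in another strain
#'
#' Searches the other genome for the element's attL and attR occupied-site
#' junction sequences (present, `+`), failing that for the attB
#' empty-site sequence (absent with empty site, `-, s`), else reports no
#' site (`-`).
#'
#' @param element a `candidate_element` from [select_element()].
#' @param other another [genome_set()].
#' @param min_identity,min_cov match thresholds (defaults 0.9 identity
#'   over 0.8 of the junction length).
#' @return one of `"present"`, `"absent_with_empty_site"`, `"no_site"`.
#' @export
cross_strain_presence <- function(element, other, min_identity = 0.9, min_cov = 0.8) {
  stopifnot(inherits(element, "candidate_element"))
  .presence_status(element$attL_junction, element$attR_junction, element$attB_seq,
                   other, min_identity, min_cov)
}

#' Table 4-style symbol for a presence call
#'
#' @param status a [cross_strain_presence()] value.
#' @return `"+"`, `"-, s"` or `"-"`.
#' @export
presence_symbol <- function(status) {
  c(present = "+", absent_with_empty_site = "-, s", no_site = "-")[[status]]
}
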