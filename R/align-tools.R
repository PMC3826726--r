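# Shared seed-and-extend machinery.
#
# Exact k-mer seeds (Biostrings::PDict/matchPDict) are merged into maximal
# exact runs per diagonal, then extended without gaps under an X-drop
# criterion with BLASTn-like scoring (+1 match, -3 mismatch).  N never
# matches anything, including another N.  All coordinates 0-based
# half-open; qpos/spos are positions in query/subject.

.bytes <- function(s) as.integer(charToRaw(s))

# scoring matrix for windowed nucleotide alignments: N is a mismatch
.NUCMAT <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5L, 5L, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -2
  m
})

# all exact k-mer matches between query and subject -> data.table(qpos, spos)
.kmer_seeds <- function(query, subject, k) {
  nq <- nchar(query)
  empty <- data.table(qpos = integer(), spos = integer())
  if (nq < k || nchar(subject) < k) return(empty)
  qk <- substring(query, seq_len(nq - k + 1L), k:nq)
  keep <- !grepl("N", qk, fixed = TRUE)
  if (!any(keep)) return(empty)
  qdt <- data.table(kmer = qk[keep], qpos = which(keep) - 1L)
  uk <- unique(qdt$kmer)
  m <- Biostrings::matchPDict(Biostrings::PDict(uk), Biostrings::DNAString(subject))
  st <- Biostrings::startIndex(m)
  ns <- lengths(st)
  if (sum(ns) == 0L) return(empty)
  sdt <- data.table(kmer = rep(uk, ns), spos = unlist(st, use.names = FALSE) - 1L)
  out <- sdt[qdt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  out[, list(qpos, spos)]
}

# merge seeds into maximal exact runs per diagonal
.exact_runs <- function(seeds, k) {
  if (!nrow(seeds)) {
    return(data.table(qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(), len = integer()))
  }
  seeds <- data.table::copy(seeds)
  seeds[, diag := spos - qpos]
  setorder(seeds, diag, qpos)
  seeds[, grp := cumsum(c(TRUE, diff(qpos) != 1L)), by = diag]
  runs <- seeds[, list(qstart = qpos[1L], qend = qpos[.N] + k,
                       sstart = spos[1L], send = spos[.N] + k),
                by = list(diag, grp)]
  runs[, len := qend - qstart]
  runs[, c("diag", "grp") := NULL]
  runs[]
}

# ungapped X-drop extension in one direction; qi/si are the first
# candidate positions (1-based indices into the byte vectors); dir +1/-1
.extend_dir <- function(qr, sr, qi, si, dir, xdrop, match, mism, chunk = 64L) {
  score <- 0L; steps <- 0L; matches <- 0L
  best_gain <- 0L; best_steps <- 0L; best_matches <- 0L
  nq <- length(qr); ns <- length(sr)
  repeat {
    if (dir > 0L) {
      avail <- min(nq - (qi + steps) + 1L, ns - (si + steps) + 1L, chunk)
    } else {
      avail <- min(qi - steps, si - steps, chunk)
    }
    if (avail <= 0L) break
    idx <- seq_len(avail) - 1L
    if (dir > 0L) {
      qb <- qr[qi + steps + idx]; sb <- sr[si + steps + idx]
    } else {
      qb <- qr[qi - steps - idx]; sb <- sr[si - steps - idx]
    }
    eq <- qb == sb & qb != 78L
    sc <- cumsum(ifelse(eq, match, mism))
    cand <- score + sc
    i_best <- which.max(cand)
    if (cand[i_best] > best_gain) {
      best_gain <- cand[i_best]
      best_steps <- steps + i_best
      best_matches <- matches + sum(eq[seq_len(i_best)])
    }
    score <- score + sc[avail]
    matches <- matches + sum(eq)
    steps <- steps + avail
    if (best_gain - score > xdrop) break
    if (avail < chunk) break
  }
  list(steps = best_steps, matches = best_matches)
}

# extend one exact run both ways; returns extended 0-based half-open coords
.extend_run <- function(qr, sr, qstart, qend, sstart, xdrop = 12L,
                        match = 1L, mism = -3L) {
  len0 <- qend - qstart
  rt <- .extend_dir(qr, sr, qend + 1L, sstart + len0 + 1L, +1L, xdrop, match, mism)
  lt <- .extend_dir(qr, sr, qstart, sstart, -1L, xdrop, match, mism)
  list(qstart = qstart - lt$steps, qend = qend + rt$steps,
       sstart = sstart - lt$steps, send = sstart + len0 + rt$steps,
       nmatch = len0 + lt$matches + rt$matches)
}

#' Maximal local matches between two sequences (same orientation)
#'
#' Seed-and-extend search for ungapped local matches: exact `seed_k`-mer
#' seeds are merged into maximal exact runs, runs at least
#' `min(min_len, 12)` bp long are extended under an X-drop rule, and
#' matches of at least `min_len` bp at `min_identity` or better are
#' returned.  Detection of a repeat therefore requires an exact core of
#' at least `min(min_len, 12)` bp; exact repeats of length `>= min_len`
#' are always found.
#'
#' @param query,subject DNA strings.
#' @param seed_k seed length (default 10).
#' @param min_len minimum reported match length.
#' @param min_identity minimum identity (matches / match length).
#' @param xdrop X-drop threshold for extension.
#' @param max_matches cap on reported matches (best-scoring kept).
#' @return data frame: qstart, qend, sstart, send, length, nmatch,
#'   identity (0-based half-open coordinates).
#' @export
find_local_matches <- function(query, subject, seed_k = 10L, min_len = 14L,
                               min_identity = 0.9, xdrop = 12L,
                               max_matches = 2000L) {
  seed_k <- as.integer(seed_k); min_len <- as.integer(min_len)
  xdrop <- as.integer(xdrop); max_matches <- as.integer(max_matches)
  seeds <- .kmer_seeds(query, subject, seed_k)
  runs <- .exact_runs(seeds, seed_k)
  gate <- min(min_len, 12L)
  runs <- runs[len >= gate]
  if (!nrow(runs)) {
    return(data.frame(qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), length = integer(), nmatch = integer(),
                      identity = numeric()))
  }
  if (nrow(runs) > max_matches) {
    setorder(runs, -len)
    runs <- runs[seq_len(max_matches)]
  }
  qr <- .bytes(query); sr <- .bytes(subject)
  ext <- lapply(seq_len(nrow(runs)), function(i) {
    .extend_run(qr, sr, runs$qstart[i], runs$qend[i], runs$sstart[i], xdrop)
  })
  dt <- data.table(qstart = vapply(ext, `[[`, integer(1), "qstart"),
                   qend = vapply(ext, `[[`, integer(1), "qend"),
                   sstart = vapply(ext, `[[`, integer(1), "sstart"),
                   send = vapply(ext, `[[`, integer(1), "send"),
                   nmatch = vapply(ext, `[[`, integer(1), "nmatch"))
  dt <- unique(dt, by = c("qstart", "qend", "sstart"))
  dt[, length := qend - qstart]
  dt[, identity := nmatch / length]
  dt <- dt[length >= min_len & identity >= min_identity]
  setorder(dt, -nmatch)
  as.data.frame(dt[, list(qstart, qend, sstart, send, length, nmatch, identity)])
}

# best single local hit of query in a (multi-record) subject genome set or
# character vector of sequences; returns NULL when nothing passes
.best_local_hit <- function(query, subjects, seed_k = 13L, min_len = 30L,
                            min_identity = 0.8, xdrop = 20L) {
  if (inherits(subjects, "genome_set")) {
    subjects <- vapply(subjects$records, `[[`, character(1), "sequence")
  }
  best <- NULL
  for (nm in seq_along(subjects)) {
    hits <- find_local_matches(query, subjects[[nm]], seed_k = seed_k,
                               min_len = min_len, min_identity = min_identity,
                               xdrop = xdrop, max_matches = 200L)
    if (nrow(hits)) {
      h <- hits[1L, ]
      h$subject <- if (!is.null(names(subjects))) names(subjects)[nm] else as.character(nm)
      if (is.null(best) || h$nmatch > best$nmatch) best <- h
    }
  }
  best
}

# does `query` occur in `subjects` at >= min_identity over >= min_cov of
# its length (single contiguous ungapped match)?
.query_present <- function(query, subjects, min_identity = 0.9, min_cov = 0.8) {
  hit <- .best_local_hit(query, subjects, min_identity = min_identity,
                         min_len = max(30L, floor(min_cov * nchar(query))))
  !is.null(hit) && hit$length >= min_cov * nchar(query) && hit$identity >= min_identity
}

# map one fragment onto a subject sequence: mode-diagonal window plus a
# local Needleman/Smith-Waterman refinement; returns identity/coverage
.map_fragment <- function(fragment, subject, seed_k = 13L, pad = 150L) {
  seeds <- .kmer_seeds(fragment, subject, seed_k)
  if (!nrow(seeds)) return(NULL)
  seeds[, diag := spos - qpos]
  d <- seeds[, .N, by = diag][order(-N)]$diag[1L]
  ns <- nchar(subject)
  lo <- max(0L, d - pad)
  hi <- min(ns, d + nchar(fragment) + pad)
  if (hi - lo < seed_k) return(NULL)
  window <- substr(subject, lo + 1L, hi)
  aln <- Biostrings::pairwiseAlignment(fragment, window, type = "local",
                                       substitutionMatrix = .NUCMAT,
                                       gapOpening = 5, gapExtension = 2)
  alen <- Biostrings::nchar(aln)
  if (alen == 0L) return(NULL)
  list(identity = Biostrings::nmatch(aln) / alen,
       coverage = Biostrings::width(Biostrings::pattern(aln)) / nchar(fragment),
       score = Biostrings::score(aln))
}
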