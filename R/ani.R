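#' Fragment-based average nucleotide identity between two genomes
#'
#' The query genome is cut into consecutive non-overlapping fragments
#' (1,020 bp by default).  Each fragment is mapped to the subject genome
#' (exact 13-mer seeding to locate the homologous window, then a local
#' alignment inside it) and kept when its identity is at least `min_id`
#' over at least `min_cov` of the fragment length.  ANI is the mean
#' identity of kept fragments, in percent.  Fragments with more than 20%
#' N are skipped (draft-genome gaps).  Both one-way values and their
#' symmetric mean are reported.
#'
#' @param genomeA,genomeB [genome_set()] objects (or lists of
#'   [genome_record()]).
#' @param fragment fragment length in bp.
#' @param min_id minimum fragment identity (fraction).
#' @param min_cov minimum aligned fraction of the fragment.
#' @return object of class `ani_result`: list with `ani` (symmetric mean,
#'   percent), `ani_ab`, `ani_ba`, `n_fragments_ab`, `n_fragments_ba`,
#'   `fragment_identities_ab`, `fragment_identities_ba`.
#' @export
ani <- function(genomeA, genomeB, fragment = 1020L, min_id = 0.3, min_cov = 0.7) {
  seqs <- function(g) {
    if (inherits(g, "genome_set")) g <- g$records
    vapply(g, `[[`, character(1), "sequence")
  }
  a <- seqs(genomeA); b <- seqs(genomeB)
  one_way <- function(qs, ss) {
    ids <- numeric(0)
    for (q in qs) {
      n <- nchar(q)
      starts <- seq.int(1L, n, by = fragment)
      for (st in starts) {
        fr <- substr(q, st, min(n, st + fragment - 1L))
        if (nchar(fr) < fragment / 2) next
        if (.base_counts(fr)[["N"]] > 0.2 * nchar(fr)) next
        best <- NULL
        for (s in ss) {
          m <- .map_fragment(fr, s)
          if (!is.null(m) && (is.null(best) || m$score > best$score)) best <- m
        }
        if (!is.null(best) && best$identity >= min_id && best$coverage >= min_cov)
          ids <- c(ids, best$identity)
      }
    }
    ids
  }
  id_ab <- one_way(a, b)
  id_ba <- one_way(b, a)
  if (!length(id_ab) && !length(id_ba))
    stop("no fragment passed the identity/coverage filters", call. = FALSE)
  ani_ab <- if (length(id_ab)) 100 * mean(id_ab) else NA_real_
  ani_ba <- if (length(id_ba)) 100 * mean(id_ba) else NA_real_
  structure(list(ani = mean(c(ani_ab, ani_ba), na.rm = TRUE),
                 ani_ab = ani_ab, ani_ba = ani_ba,
                 n_fragments_ab = length(id_ab), n_fragments_ba = length(id_ba),
                 fragment_identities_ab = id_ab, fragment_identities_ba = id_ba),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> ANI %.2f%% (A->B %.2f%% over %d fragments, B->A %.2f%% over %d)\n",
              x$ani, x$ani_ab, x$n_fragments_ab, x$ani_ba, x$n_fragments_ba))
  invisible(x)
}
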