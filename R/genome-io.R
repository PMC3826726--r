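#' One replicon: identifier, sequence, topology
#'
#' @param replicon_id replicon name, unique within a genome set.
#' @param sequence uppercase DNA text over A/C/G/T/N (lowercase and U are
#'   folded on input by [read_fasta()], not here).
#' @param topology `"linear"` (default) or `"circular"`.  Wraparound
#'   extraction is only allowed on circular replicons.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(replicon_id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L, nzchar(replicon_id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence for replicon ", replicon_id, call. = FALSE)
  .check_dna(sequence, replicon_id)
  structure(list(replicon_id = replicon_id, sequence = sequence,
                 topology = topology, length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s\n", x$replicon_id, x$length, x$topology))
  invisible(x)
}

# canonical empty feature table
empty_features <- function() {
  data.frame(feature_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             ftype = character(), product = character(),
             anticodon = character(), cog = character(),
             stringsAsFactors = FALSE)
}

.complete_features <- function(df) {
  tmpl <- empty_features()
  for (nm in names(tmpl)) {
    if (is.null(df[[nm]])) df[[nm]] <- rep(NA_character_, nrow(df))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  rownames(df) <- NULL
  df[, names(tmpl)]
}

#' A set of replicons plus their annotated features for one strain
#'
#' Features live in a single data frame with 0-based half-open `start`/
#' `end`, `strand` in `+`/`-`, `ftype` one of CDS/tRNA/rRNA/other, free
#' text `product`, and optional `anticodon` and `cog` qualifiers.
#'
#' @param strain_id strain label.
#' @param records list of [genome_record()] objects.
#' @param features feature data frame (see above); defaults to empty.
#' @return an object of class `genome_set`.
#' @export
genome_set <- function(strain_id, records, features = empty_features()) {
  stopifnot(is.list(records), length(records) > 0L)
  ids <- vapply(records, function(r) r$replicon_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate replicon ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "),
                               call. = FALSE)
  names(records) <- ids
  features <- .complete_features(as.data.frame(features))
  if (nrow(features)) {
    unknown <- setdiff(unique(features$replicon_id), ids)
    if (length(unknown)) stop("features reference unknown replicons: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    len <- vapply(records, `[[`, integer(1), "length")[features$replicon_id]
    bad <- which(!(features$start >= 0L & features$start < features$end &
                     features$end <= len))
    if (length(bad)) stop(sprintf(
      "feature %s has coordinates outside [0, replicon length): start=%d end=%d",
      features$feature_id[bad[1]], features$start[bad[1]], features$end[bad[1]]),
      call. = FALSE)
    need_strand <- features$ftype %in% c("CDS", "tRNA")
    if (any(need_strand & !(features$strand %in% c("+", "-"))))
      stop("CDS/tRNA features must have strand '+' or '-'", call. = FALSE)
  }
  structure(list(strain_id = strain_id, records = records, features = features),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> strain %s: %d replicon(s), %d feature(s)\n",
              x$strain_id, length(x$records), nrow(x$features)))
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' Sequences are uppercased and U is converted to T; any other character
#' outside A/C/G/T/N raises an error naming the offending position.
#'
#' @param path FASTA file.
#' @param circular character vector of record ids to mark circular;
#'   everything else is linear.
#' @return list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path, circular = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "),
                               call. = FALSE)
  lapply(seq_along(set), function(i) {
    s <- chartr("U", "T", toupper(as.character(set[[i]])))
    .check_dna(s, ids[i])
    genome_record(ids[i], s, topology = if (ids[i] %in% circular) "circular" else "linear")
  })
}

#' Write genome records to FASTA
#'
#' @param records list of [genome_record()] (or a [genome_set()]).
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_set")) records <- records$records
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "replicon_id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# parse an anticodon out of tRNA product text shaped like
# "tRNA-Lys-CTT" or "tRNA-Met (cat)"
.parse_anticodon <- function(product) {
  m <- regmatches(product,
                  regexec("tRNA-[A-Za-z]{3}[-_ ]*\\(?([ACGTUacgtu]{3})\\)?", product))
  vapply(m, function(g) if (length(g) == 2L) chartr("U", "T", toupper(g[2])) else NA_character_,
         character(1))
}

.validate_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_ln <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in data_ln) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop(sprintf("malformed GFF3 at line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)), call. = FALSE)
    if (is.na(suppressWarnings(as.integer(f[4]))) || is.na(suppressWarnings(as.integer(f[5]))))
      stop(sprintf("malformed GFF3 at line %d: non-numeric coordinates", i), call. = FALSE)
    if (!f[7] %in% c("+", "-", ".", "?"))
      stop(sprintf("malformed GFF3 at line %d: unknown strand symbol '%s'", i, f[7]),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read annotated features from GFF3, BED or TSV
#'
#' GFF3 coordinates (1-based inclusive) and BED coordinates (already
#' 0-based half-open) are converted to the internal 0-based half-open
#' convention.  The TSV dialect is this package's own report format and
#' is read back verbatim (columns `feature_id`, `replicon_id`, `start`,
#' `end`, `strand`, `ftype`, `product`, `anticodon`, `cog`; coordinates
#' 0-based half-open).  tRNA anticodons are pulled from an `anticodon`
#' attribute or parsed from product text like `"tRNA-Lys-CTT"`.
#'
#' @param path input file.
#' @param dialect `"gff3"`, `"tsv"` or `"bed"`.
#' @return feature data frame (see [genome_set()]).
#' @export
read_features <- function(path, dialect = c("gff3", "tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("feature_id", "replicon_id", "start", "end")
    if (!all(need %in% names(df)))
      stop("TSV feature table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    return(.complete_features(df))
  }
  if (dialect == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(feature_id = if (ncol(df) >= 4) as.character(df[[4]]) else
                        paste0("bed_", seq_len(nrow(df))),
                      replicon_id = as.character(df[[1]]),
                      start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                      strand = if (ncol(df) >= 6) as.character(df[[6]]) else NA_character_,
                      ftype = "other", product = NA_character_,
                      stringsAsFactors = FALSE)
    return(.complete_features(out))
  }
  .validate_gff3(path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  n <- nrow(df)
  ftype <- as.character(df$type)
  ftype[!ftype %in% c("CDS", "tRNA", "rRNA")] <- "other"
  ids <- if (!is.null(df$ID)) as.character(df$ID) else rep(NA_character_, n)
  ids[is.na(ids)] <- paste0("feat_", which(is.na(ids)))
  product <- if (!is.null(df$product)) as.character(df$product) else rep(NA_character_, n)
  anticodon <- if (!is.null(df$anticodon)) toupper(as.character(df$anticodon)) else
    rep(NA_character_, n)
  miss <- is.na(anticodon) & !is.na(product)
  anticodon[miss] <- .parse_anticodon(product[miss])
  strand <- as.character(df$strand)
  strand[strand == "*"] <- NA_character_
  if (any(is.na(strand) & ftype %in% c("CDS", "tRNA")))
    stop("unknown strand symbol for CDS/tRNA feature in ", path, call. = FALSE)
  out <- data.frame(feature_id = ids, replicon_id = as.character(df$seqnames),
                    start = as.integer(df$start) - 1L, end = as.integer(df$end),
                    strand = strand, ftype = ftype, product = product,
                    anticodon = anticodon,
                    cog = if (!is.null(df$cog)) as.character(df$cog) else NA_character_,
                    stringsAsFactors = FALSE)
  .complete_features(out)
}

#' Extract a subsequence from a record
#'
#' Intervals are 0-based half-open.  On circular records `end` may run
#' past the replicon length, in which case the extraction wraps around
#' the origin.  Strand `-` returns the reverse complement.
#'
#' @param record a [genome_record()].
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return subsequence as a character scalar.
#' @export
extract_seq <- function(record, start, end, strand = "+") {
  stopifnot(inherits(record, "genome_record"))
  len <- record$length
  if (start < 0L || end <= start) stop("invalid interval [", start, ", ", end, ")",
                                       call. = FALSE)
  if (end > len) {
    if (record$topology != "circular")
      stop(sprintf("interval [%d, %d) exceeds length %d of linear replicon %s",
                   start, end, len, record$replicon_id), call. = FALSE)
    if (end - start > len) stop("interval longer than circular replicon", call. = FALSE)
    s <- paste0(substr(record$sequence, start + 1L, len),
                substr(record$sequence, 1L, end - len))
  } else {
    s <- substr(record$sequence, start + 1L, end)
  }
  if (strand == "-") s <- revcomp(s)
  s
}

#' Write intervals to BED, GFF3 or TSV
#'
#' BED is written 0-based half-open, GFF3 1-based inclusive; both
#' round-trip through [read_features()] back to identical internal
#' coordinates.
#'
#' @param x data frame with at least `replicon_id`, `start`, `end`;
#'   `feature_id`, `strand`, `ftype`, `product`, `anticodon` are used
#'   when present.
#' @param path output file.
#' @param format `"bed"`, `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "gff3", "tsv")) {
  format <- match.arg(format)
  x <- .complete_features(as.data.frame(x))
  if (format == "tsv") {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  } else if (format == "bed") {
    bed <- data.frame(x$replicon_id, x$start, x$end, x$feature_id, 0L,
                      ifelse(is.na(x$strand), "+", x$strand))
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    attrs <- paste0("ID=", x$feature_id)
    has_p <- !is.na(x$product)
    attrs[has_p] <- paste0(attrs[has_p], ";product=", x$product[has_p])
    has_a <- !is.na(x$anticodon)
    attrs[has_a] <- paste0(attrs[has_a], ";anticodon=", x$anticodon[has_a])
    gff <- data.frame(x$replicon_id, "islescan",
                      ifelse(is.na(x$ftype), "region", x$ftype),
                      x$start + 1L, x$end, ".",
                      ifelse(is.na(x$strand), ".", x$strand), ".", attrs)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Translate the CDS features of a genome set
#'
#' Extracts each CDS (strand-aware), translates it with the standard
#' code and returns named protein strings.  Internal stops are kept as
#' `*` (BLOSUM62 scores them); fuzzy codons containing N become X.
#'
#' @param gs a [genome_set()].
#' @return named character vector of protein sequences, one per CDS.
#' @export
proteome <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  cds <- gs$features[gs$features$ftype == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(setNames(character(), character()))
  seqs <- vapply(seq_len(nrow(cds)), function(i) {
    s <- extract_seq(gs$records[[cds$replicon_id[i]]], cds$start[i], cds$end[i],
                     cds$strand[i])
    substr(s, 1L, 3L * (nchar(s) %/% 3L))
  }, character(1))
  aa <- suppressWarnings(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                               if.fuzzy.codon = "solve"))
  setNames(as.character(aa), cds$feature_id)
}
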