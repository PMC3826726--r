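# End-to-end orchestration: scan one genome for elements, compare two
# strains (pangenome, ANI, att-site presence), and file-based entry
# points used by the command-line script.

#' Scan an annotated genome for integrative mobile genetic elements
#'
#' Runs the full anchor -> direct repeats -> tRNA association -> element
#' selection -> junction reconstruction -> module detection ->
#' classification pipeline, optionally corroborating candidate repeat
#' pairs against a companion strain and grouping elements into families.
#'
#' @param gs a [genome_set()].
#' @param params repeat-search parameters from [dr_params()].
#' @param companion optional second [genome_set()] used to corroborate
#'   candidate att sites (occupied or empty site must be found there).
#' @param catalog module catalog for classification.
#' @param do_families assign cross-element families (default TRUE).
#' @param anchor_mode integrase detection mode, see [find_integrases()].
#' @return object of class `mge_scan`: list with `report` (one row per
#'   element), `elements` (list of `candidate_element`),
#'   `classifications`, `anchors`.
#' @export
scan_genome <- function(gs, params = dr_params(), companion = NULL,
                        catalog = module_catalog(), do_families = TRUE,
                        anchor_mode = "keyword") {
  stopifnot(inherits(gs, "genome_set"))
  anchors <- find_integrases(gs, mode = anchor_mode)
  elements <- list(); classifications <- list()
  for (i in seq_len(nrow(anchors))) {
    anchor <- anchors[i, , drop = FALSE]
    record <- gs$records[[anchor$replicon_id]]
    pairs <- find_direct_repeats(record, anchor, params)
    pairs <- associate_trna(pairs, gs$features, anchor$replicon_id)
    el <- select_element(pairs, anchor, gs, companion = companion, params = params)
    if (is.null(el)) next
    dup <- any(vapply(elements, function(e)
      e$replicon_id == el$replicon_id && e$start == el$start && e$end == el$end,
      logical(1)))
    if (dup) next
    feats <- gs$features[gs$features$replicon_id == el$replicon_id &
                           gs$features$start >= el$start &
                           gs$features$end <= el$end, , drop = FALSE]
    hits <- detect_modules(feats, catalog)
    cl <- classify_element(hits, el$size_bp, features = feats)
    elements[[length(elements) + 1L]] <- el
    classifications[[length(classifications) + 1L]] <- cl
  }
  report <- summarize_elements(elements, classifications, strain_id = gs$strain_id)
  if (length(elements)) {
    # nested/overlapping extents are reported, flagged
    ov <- vapply(seq_along(elements), function(i) {
      any(vapply(seq_along(elements), function(j) {
        if (i == j) return(FALSE)
        ei <- elements[[i]]; ej <- elements[[j]]
        ei$replicon_id == ej$replicon_id && ei$start < ej$end && ej$start < ei$end
      }, logical(1)))
    }, logical(1))
    report$nested <- ov
    report$companion_verified <- vapply(elements, function(e)
      isTRUE(e$companion_verified), logical(1))
    report$family <- NA_character_
    if (do_families && length(elements) >= 2L) {
      seqs <- setNames(vapply(seq_along(elements), function(i) {
        e <- elements[[i]]
        substr(gs$records[[e$replicon_id]]$sequence, e$start + 1L, e$end)
      }, character(1)), report$mge_id)
      fam <- assign_families(seqs, setNames(report$type, report$mge_id))
      report$family <- fam$family[match(report$mge_id, fam$element)]
      promoted <- fam$promoted[match(report$mge_id, fam$element)]
      report$type <- ifelse(promoted, paste0(fam$label[match(report$mge_id, fam$element)],
                                             " (by-family)"), report$type)
    }
  }
  structure(list(report = report, elements = elements,
                 classifications = classifications, anchors = anchors,
                 strain_id = gs$strain_id),
            class = "mge_scan")
}

#' @export
print.mge_scan <- function(x, ...) {
  cat(sprintf("<mge_scan> strain %s: %d anchor(s), %d element(s)\n",
              x$strain_id, nrow(x$anchors), length(x$elements)))
  if (nrow(x$report)) print(x$report[, c("mge_id", "type", "replicon", "start",
                                         "end", "size_bp", "att_site", "dr")])
  invisible(x)
}

#' Write a scan's outputs to files
#'
#' Writes the per-element report (TSV), element extents (GFF3 and BED)
#' and attB/attI junction sequences (FASTA) under a path prefix.
#'
#' @param scan an [scan_genome()] result.
#' @param prefix output path prefix.
#' @return the written paths, invisibly.
#' @export
write_scan <- function(scan, prefix) {
  paths <- paste0(prefix, c("_elements.tsv", "_elements.gff3", "_elements.bed",
                            "_junctions.fasta"))
  write.table(scan$report, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  iv <- data.frame(feature_id = scan$report$mge_id,
                   replicon_id = scan$report$replicon,
                   start = scan$report$start, end = scan$report$end,
                   strand = "+", ftype = "mobile_genetic_element",
                   product = scan$report$type)
  write_intervals(iv, paths[2], "gff3")
  write_intervals(iv, paths[3], "bed")
  if (length(scan$elements)) {
    jseq <- unlist(lapply(seq_along(scan$elements), function(i) {
      el <- scan$elements[[i]]
      setNames(c(el$attB_seq, el$attI_seq),
               paste0(scan$report$mge_id[i], c("_attB", "_attI")))
    }))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(jseq), paths[4])
  } else {
    file.create(paths[4])
  }
  invisible(paths)
}

#' Compare two strains: orthologs, ANI and att-site presence
#'
#' Translates both strains' CDS, computes reciprocal-best-hit orthologs
#' and strain-unique gene sets at the 95% identity cutoff, fragment ANI,
#' and (when scans are supplied or requested) the cross-strain presence
#' code of every detected element (`+` occupied site found, `-, s`
#' empty site found, `-` neither).
#'
#' @param A,B [genome_set()] objects.
#' @param scanA,scanB optional [scan_genome()] results for the two
#'   strains; set `scan = TRUE` to compute them here.
#' @param scan run element scans if not supplied (default FALSE).
#' @param min_identity ortholog identity cutoff.
#' @param do_ani compute fragment ANI (default TRUE).
#' @return object of class `strain_comparison`: list with `orthologs`,
#'   `ani`, `presence` (data frame element, from_strain, in_strain,
#'   status, symbol).
#' @export
compare_strains <- function(A, B, scanA = NULL, scanB = NULL, scan = FALSE,
                            min_identity = 0.95, do_ani = TRUE) {
  stopifnot(inherits(A, "genome_set"), inherits(B, "genome_set"))
  orth <- reciprocal_orthologs(proteome(A), proteome(B), min_identity = min_identity)
  ani_res <- if (do_ani) ani(A, B) else NULL
  if (scan && is.null(scanA)) scanA <- scan_genome(A, companion = B)
  if (scan && is.null(scanB)) scanB <- scan_genome(B, companion = A)
  presence <- list()
  add_presence <- function(sc, from, other, other_id) {
    for (i in seq_along(sc$elements)) {
      st <- cross_strain_presence(sc$elements[[i]], other)
      presence[[length(presence) + 1L]] <<-
        data.frame(element = sc$report$mge_id[i], from_strain = from,
                   in_strain = other_id, status = st,
                   symbol = presence_symbol(st), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(scanA)) add_presence(scanA, A$strain_id, B, B$strain_id)
  if (!is.null(scanB)) add_presence(scanB, B$strain_id, A, A$strain_id)
  structure(list(orthologs = orth, ani = ani_res,
                 presence = if (length(presence)) do.call(rbind, presence) else
                   data.frame()),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat("<strain_comparison>\n")
  print(x$orthologs)
  if (!is.null(x$ani)) print(x$ani)
  if (nrow(x$presence)) print(x$presence)
  invisible(x)
}

# ---- file-based entry points (used by inst/cli/islescan.R) ----------

#' Simulate a strain pair and write it to files
#'
#' Writes per-strain FASTA and GFF3 plus the ground-truth element table
#' (TSV) and extents (BED).
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @param config optional [sim_config()]; defaults to a ~1 Mb
#'   chromosome carrying the [study_implants()] set.
#' @return named vector of written paths, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, config = NULL) {
  if (is.null(config))
    config <- sim_config(seed = seed,
                         replicons = list(list(name = "chr", length = 450000L,
                                               gc = 0.61)),
                         implants = study_implants())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- simulate_strain_pair(config)
  paths <- c(A_fasta = file.path(out_dir, "strainA.fasta"),
             A_gff = file.path(out_dir, "strainA.gff3"),
             B_fasta = file.path(out_dir, "strainB.fasta"),
             B_gff = file.path(out_dir, "strainB.gff3"),
             truth = file.path(out_dir, "truth.tsv"),
             truth_bed = file.path(out_dir, "truth.bed"))
  write_fasta(sp$A, paths["A_fasta"])
  write_intervals(sp$A$features, paths["A_gff"], "gff3")
  write_fasta(sp$B, paths["B_fasta"])
  write_intervals(sp$B$features, paths["B_gff"], "gff3")
  write.table(sp$truth, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(sp$truth))
    write_intervals(data.frame(feature_id = sp$truth$element_id,
                               replicon_id = sp$truth$replicon,
                               start = sp$truth$start, end = sp$truth$end,
                               strand = "+", ftype = "mobile_genetic_element",
                               product = sp$truth$class),
                    paths["truth_bed"], "bed")
  invisible(paths)
}

#' Scan a genome given FASTA and feature files
#'
#' @param fasta genome FASTA path.
#' @param features feature file path.
#' @param out_prefix output path prefix for [write_scan()].
#' @param dialect feature-file dialect, see [read_features()].
#' @param companion_fasta,companion_features optional companion strain
#'   files for att-site corroboration.
#' @param params repeat-search parameters.
#' @param strain_id strain label (default: FASTA basename).
#' @return the [scan_genome()] result, invisibly.
#' @export
run_scan <- function(fasta, features, out_prefix, dialect = "gff3",
                     companion_fasta = NULL, companion_features = NULL,
                     params = dr_params(), strain_id = NULL) {
  gs <- genome_set(strain_id %||% sub("\\.[^.]*$", "", basename(fasta)),
                   read_fasta(fasta), read_features(features, dialect))
  companion <- NULL
  if (!is.null(companion_fasta))
    companion <- genome_set("companion", read_fasta(companion_fasta),
                            if (!is.null(companion_features))
                              read_features(companion_features, dialect) else
                                empty_features())
  sc <- scan_genome(gs, params = params, companion = companion)
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  write_scan(sc, out_prefix)
  invisible(sc)
}

#' Compare two strains given FASTA and feature files
#'
#' @param fastaA,featuresA,fastaB,featuresB input files for the two
#'   strains.
#' @param out_prefix output path prefix; writes ortholog tables, an ANI
#'   summary and the presence matrix.
#' @param dialect feature-file dialect.
#' @param scan also scan both strains and type element presence.
#' @return the [compare_strains()] result, invisibly.
#' @export
run_compare <- function(fastaA, featuresA, fastaB, featuresB, out_prefix,
                        dialect = "gff3", scan = TRUE) {
  A <- genome_set("A", read_fasta(fastaA), read_features(featuresA, dialect))
  B <- genome_set("B", read_fasta(fastaB), read_features(featuresB, dialect))
  cmp <- compare_strains(A, B, scan = scan)
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  write_orthologs(cmp$orthologs, out_prefix)
  if (!is.null(cmp$ani))
    write.table(data.frame(ani = cmp$ani$ani, ani_ab = cmp$ani$ani_ab,
                           ani_ba = cmp$ani$ani_ba,
                           fragments_ab = cmp$ani$n_fragments_ab,
                           fragments_ba = cmp$ani$n_fragments_ba),
                paste0(out_prefix, "_ani.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (nrow(cmp$presence))
    write.table(cmp$presence, paste0(out_prefix, "_presence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(cmp)
}

#' Read a run-configuration file
#'
#' Plain-text key-value format with bracketed per-module sections:
#' ```
#' [scan]
#' min_len = 14
#' ```
#' Unknown sections or keys are rejected so typos cannot silently
#' change a run.
#'
#' @param path config file.
#' @return nested named list (section -> key -> character value).
#' @export
read_run_config <- function(path) {
  known <- list(
    general = c("seed", "out", "log_level"),
    simulate = c("seed", "chromosome_length", "gc", "divergence"),
    scan = c("flank", "max_span", "min_len", "min_identity", "seed_k", "min_span"),
    compare = c("min_identity", "scan"),
    ani = c("fragment", "min_id", "min_cov"),
    qpcr = c("control"))
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  cfg <- list(); section <- "general"
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(known))
        stop("unknown config section [", section, "]", call. = FALSE)
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% known[[section]])
        stop("unknown key '", key, "' in section [", section, "]", call. = FALSE)
      cfg[[section]][[key]] <- val
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  cfg
}
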