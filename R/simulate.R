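# Seeded simulator: paired strains with implanted, ground-truthed
# integrative elements, controlled-identity proteome pairs, and qPCR
# dilution series / treatment tables.
#
# Background sequence is i.i.d. bases at the configured G+C (split
# evenly G/C and A/T).  Each implant is placed so the recombination
# core (the sequence duplicated by site-specific integration) is the 3'
# end of a generated tRNA gene: the attL copy stays in place and an
# exact copy closes the element's downstream boundary (attR), so in
# silico excision regenerates the empty site base for base.  The
# annotated attL may extend 5' beyond the core (unequal printed repeat
# lengths); the matched, recoverable repeat is the core.  An integrase
# CDS sits within 5 kb inside attL and cargo CDS products realize the
# requested module inventory.  The few bases flanking each repeat copy
# are forced to mismatch positionwise so ground-truth repeats are
# maximal exact matches and "exact coordinates" is well defined.

#' Random DNA at a given G+C content
#'
#' @param n length in bp.
#' @param gc G+C fraction.
#' @return DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute `n` random positions with a different base
.mutate_dna <- function(seq, n) {
  if (n == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(v), n)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

# product strings realizing each module tag (contract-coupled to the
# classifier's default catalog)
.MODULE_PRODUCTS <- list(
  xis = "excisionase Xis",
  cI = "phage CI-family repressor",
  cII = "phage CII-family regulatory protein",
  cro = "phage Cro-family repressor",
  phage_struct = c("phage terminase large subunit", "phage major capsid protein",
                   "phage portal protein"),
  trb_t4ss = c("conjugal transfer protein TrbB", "conjugal transfer protein TrbC",
               "conjugal transfer protein TrbE", "conjugal transfer protein TrbG",
               "conjugal transfer protein TrbI", "conjugal transfer protein TrbL"),
  virb_t4ss = c("VirB1 lytic transglycosylase", "VirB2 pilin", "VirB4 ATPase",
                "VirB5 minor pilin", "VirB6 channel protein", "VirB9 pore protein",
                "VirB10 channel protein", "VirB11 ATPase"),
  virD2 = "VirD2 relaxase",
  virD4 = "VirD4 coupling protein",
  traAU = c("conjugative transfer protein TraA", "conjugative transfer protein TraU"),
  parAB = c("ParA partition protein", "ParB partition protein"),
  prtrc = "PRTRC system protein",
  ta_vapC_phd = c("VapC toxin", "Phd antitoxin"),
  ta_mazF = c("MazF toxin", "MazE antitoxin"),
  ta_higB = c("HigB toxin", "HigA antitoxin"),
  ta_hicA = c("HicA toxin", "HicB antitoxin"),
  ta_hipA = c("HipA toxin", "HipB antitoxin"),
  ta_relE = c("RelE toxin", "RelB antitoxin"))

#' Specification of one implanted element
#'
#' @param element_class `"prophage"`, `"ICE"`, `"IME"` or `"GI"` (the
#'   intended truth label).
#' @param size_bp element size, attL start to attR end (>= 5000 here so
#'   every implant is reportable).
#' @param dr_left,dr_right annotated left/right repeat lengths in bp
#'   (10-800, right <= left).  `dr_right` is the recombination core:
#'   the 3'-suffix of the annotated attL that is duplicated at the
#'   element's downstream boundary.  Unequal pairs model att sites whose
#'   annotated attL extends beyond the duplicated core.
#' @param att_trna tRNA label `"AminoAcid-Anticodon"` (e.g. "Met-CAT")
#'   whose 3' end the attL overlaps.
#' @param cargo_gc cargo G+C fraction (default 0.57).
#' @param modules character vector of module tags from
#'   `names(islescan:::.MODULE_PRODUCTS)`; the integrase is always
#'   present.
#' @param replicon replicon name to insert into (default first).
#' @return an `implant_spec` list.
#' @export
implant_spec <- function(element_class, size_bp, dr_left, dr_right,
                         att_trna = "Met-CAT", cargo_gc = 0.57,
                         modules = character(), replicon = NULL) {
  stopifnot(element_class %in% c("prophage", "ICE", "IME", "GI"))
  size_bp <- as.integer(size_bp)
  dr_left <- as.integer(dr_left); dr_right <- as.integer(dr_right)
  if (size_bp < 5000L) stop("implant size_bp must be >= 5000", call. = FALSE)
  if (dr_left < 10L || dr_left > 800L || dr_right < 10L || dr_right > 800L)
    stop("repeat lengths must be in [10, 800] bp", call. = FALSE)
  if (dr_right > dr_left) stop("dr_right must be <= dr_left", call. = FALSE)
  unknown <- setdiff(modules, names(.MODULE_PRODUCTS))
  if (length(unknown)) stop("unknown module tag(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  structure(list(element_class = element_class, size_bp = size_bp,
                 dr_left = dr_left, dr_right = dr_right, att_trna = att_trna,
                 cargo_gc = cargo_gc, modules = modules, replicon = replicon),
            class = "implant_spec")
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; the same seed reproduces the output
#'   byte for byte.
#' @param replicons list of replicon plans: each a list with `name`,
#'   `length`, `gc`, and optional `topology`.
#' @param implants list of [implant_spec()] objects.
#' @param divergence per-base substitution rate applied to strain B's
#'   shared backbone (default 0: clonal pair).
#' @param gene_spacing,gene_length background/cargo filler-gene layout
#'   in bp (lengths are multiples of 3).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       replicons = list(list(name = "chr", length = 400000L,
                                             gc = 0.61, topology = "linear")),
                       implants = list(), divergence = 0,
                       gene_spacing = 1000L, gene_length = 600L) {
  for (im in implants) stopifnot(inherits(im, "implant_spec"))
  structure(list(seed = as.integer(seed), replicons = replicons,
                 implants = implants, divergence = divergence,
                 gene_spacing = as.integer(gene_spacing),
                 gene_length = as.integer(gene_length)),
            class = "sim_config")
}

# filler CDS rows tiled along [lo, hi), avoiding exclusion intervals
.tile_genes <- function(lo, hi, spacing, glen, exclude = NULL, prefix = "g",
                        replicon = "chr", product = "hypothetical protein") {
  starts <- seq.int(lo, max(lo, hi - glen), by = spacing)
  starts <- starts[starts + glen <= hi]
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- vapply(starts, function(s) {
      !any(s < exclude$hi & (s + glen) > exclude$lo)
    }, logical(1))
    starts <- starts[keep]
  }
  if (!length(starts)) return(empty_features())
  .complete_features(data.frame(
    feature_id = sprintf("%s_%07d", prefix, starts),
    replicon_id = replicon, start = starts, end = starts + glen,
    strand = rep_len(c("+", "-"), length(starts)), ftype = "CDS",
    product = product, stringsAsFactors = FALSE))
}

# force positionwise mismatches: returns `b` with any position equal to
# the corresponding position of `a` replaced by a different base
.force_mismatch <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  for (i in seq_along(bv)) {
    if (bv[i] == av[i]) bv[i] <- sample(setdiff(c("A", "C", "G", "T"), av[i]), 1L)
  }
  paste(bv, collapse = "")
}

#' Simulate a pair of strains with implanted, ground-truthed elements
#'
#' Strain A carries the implants; strain B shares the backbone (with
#' optional divergence) and therefore carries the empty integration
#' sites (attB).  The truth table records exact element extents, repeat
#' coordinates, class labels and cargo-gene counts.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_pair`: `A`, `B` ([genome_set()]s) and
#'   `truth` (data frame).
#' @export
simulate_strain_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rec_names <- vapply(config$replicons, `[[`, character(1), "name")
  recordsA <- list(); recordsB <- list()
  featsA <- list(); featsB <- list()
  truth <- list()
  trna_len <- 76L
  for (ri in seq_along(config$replicons)) {
    rp <- config$replicons[[ri]]
    implants <- Filter(function(im) (im$replicon %||% rec_names[1]) == rp$name,
                       config$implants)
    bg <- random_dna(rp$length, rp$gc)
    k <- length(implants)
    sites <- if (k) as.integer(round(rp$length * seq_len(k) / (k + 1L))) else integer()
    if (k) {
      dl <- vapply(implants, `[[`, integer(1), "dr_left")
      lo_need <- sites - dl - 1000L
      if (any(lo_need < 0L) || any(sites + 1000L > rp$length) ||
          (k > 1L && any(diff(sites) < head(dl, -1L) + dl[-1L] + 2000L)))
        stop("implants overlap or fall outside replicon ", rp$name, call. = FALSE)
    }
    # background features: tRNAs at the sites plus filler genes
    exclude <- if (k) data.frame(lo = sites - vapply(implants, `[[`, integer(1), "dr_left") - 900L,
                                 hi = sites + 900L) else NULL
    bg_genes <- .tile_genes(200L, rp$length - 200L, config$gene_spacing,
                            config$gene_length, exclude = exclude,
                            prefix = paste0("bg_", rp$name), replicon = rp$name)
    trna_rows <- if (k) .complete_features(data.frame(
      feature_id = sprintf("trna_%s_%d", rp$name, seq_len(k)),
      replicon_id = rp$name, start = sites - trna_len, end = sites,
      strand = "+", ftype = "tRNA",
      product = paste0("tRNA-", sub("-.*$", "", vapply(implants, `[[`, character(1), "att_trna"))),
      anticodon = sub("^.*-", "", vapply(implants, `[[`, character(1), "att_trna")),
      stringsAsFactors = FALSE)) else empty_features()
    # build strain A by splicing inserts at the sites
    segsA <- list(); cargo_featsA <- list()
    offset <- 0L
    prev <- 0L
    for (i in seq_len(k)) {
      im <- implants[[i]]; q <- sites[i]
      dl <- im$dr_left; dr <- im$dr_right
      # the recombination core is the 3'-suffix of the annotated attL,
      # ending at the tRNA 3' end; attR is its exact copy
      insert_len <- im$size_bp - dr
      cargo_len <- insert_len - dr
      core <- substr(bg, q - dr + 1L, q)
      cargo <- random_dna(cargo_len, im$cargo_gc)
      # repeat-flanking mismatches realized inside the cargo:
      # right context of attL is the cargo start (vs background after q);
      # left context of attR is the cargo tail (vs background before the core)
      substr(cargo, 1L, 4L) <- .force_mismatch(substr(bg, q + 1L, q + 4L),
                                               substr(cargo, 1L, 4L))
      substr(cargo, cargo_len - 3L, cargo_len) <-
        .force_mismatch(substr(bg, q - dr - 3L, q - dr),
                        substr(cargo, cargo_len - 3L, cargo_len))
      insert <- paste0(cargo, core)
      # cargo genes: integrase, module genes, fillers
      products <- unlist(.MODULE_PRODUCTS[im$modules], use.names = FALSE)
      if (1500L + length(products) * 1000L + 200L > cargo_len)
        stop("module inventory does not fit in cargo of ", im$element_class,
             " implant (", im$size_bp, " bp)", call. = FALSE)
      ins_at <- q + offset   # A-coordinate where the insert begins
      el_id <- sprintf("el_%s_%d", rp$name, i)
      gene_rows <- data.frame(
        feature_id = c(sprintf("%s_int", el_id),
                       if (length(products)) sprintf("%s_mod%02d", el_id, seq_along(products))),
        start = c(ins_at + 100L,
                  if (length(products)) ins_at + 1500L + (seq_along(products) - 1L) * 1000L),
        end = c(ins_at + 1300L,
                if (length(products)) ins_at + 1500L + (seq_along(products) - 1L) * 1000L + 900L),
        product = c("site-specific integrase", products),
        cog = c("COG4974", rep(NA_character_, length(products))),
        stringsAsFactors = FALSE)
      fill_lo <- max(gene_rows$end) + 100L - ins_at
      fillers <- .tile_genes(ins_at + fill_lo, ins_at + cargo_len - 700L,
                             config$gene_spacing, config$gene_length,
                             prefix = paste0(el_id, "_cg"), replicon = rp$name)
      cargo_featsA[[i]] <- rbind(
        .complete_features(cbind(gene_rows,
                                 replicon_id = rp$name, strand = "+", ftype = "CDS")),
        fillers)
      segsA[[length(segsA) + 1L]] <- substr(bg, prev + 1L, q)
      segsA[[length(segsA) + 1L]] <- insert
      truth[[length(truth) + 1L]] <- data.frame(
        element_id = el_id, class = im$element_class, replicon = rp$name,
        start = q - dr + offset, end = ins_at + insert_len,
        size_bp = im$size_bp,
        attL_start = q - dr + offset, attL_end = q + offset,
        attL_full_start = q - dl + offset,  # annotated attL 5' limit
        attR_start = ins_at + cargo_len, attR_end = ins_at + insert_len,
        dr_left = dl, dr_right = dr, core_len = dr,
        att_site = im$att_trna, trna_id = sprintf("trna_%s_%d", rp$name, i),
        attB_pos = q - dr,  # strain-B coordinate of the empty site
        modules = paste(im$modules, collapse = ","),
        n_cargo_genes = nrow(gene_rows) + nrow(fillers),
        stringsAsFactors = FALSE)
      prev <- q
      offset <- offset + insert_len
    }
    segsA[[length(segsA) + 1L]] <- substr(bg, prev + 1L, rp$length)
    seqA <- paste(unlist(segsA), collapse = "")
    # shift shared background features into A coordinates
    shift_of <- function(pos) {
      if (!k) return(rep(0L, length(pos)))
      vapply(pos, function(p) {
        sum(vapply(seq_len(k), function(i)
          if (p > sites[i]) nchar(segsA[[2L * i]]) else 0L, numeric(1)))
      }, numeric(1))
    }
    sharedA <- rbind(bg_genes, trna_rows)
    if (nrow(sharedA)) {
      sh <- as.integer(shift_of(sharedA$start))
      sharedA$start <- sharedA$start + sh
      sharedA$end <- sharedA$end + sh
    }
    featsA[[ri]] <- rbind(sharedA, do.call(rbind, cargo_featsA))
    seqB <- bg
    if (config$divergence > 0)
      seqB <- .mutate_dna(seqB, round(config$divergence * nchar(seqB)))
    featsB[[ri]] <- rbind(bg_genes, trna_rows)
    topo <- rp$topology %||% "linear"
    recordsA[[ri]] <- genome_record(rp$name, seqA, topo)
    recordsB[[ri]] <- genome_record(rp$name, seqB, topo)
  }
  fa <- do.call(rbind, featsA); fa <- fa[order(fa$replicon_id, fa$start), ]
  fb <- do.call(rbind, featsB); fb <- fb[order(fb$replicon_id, fb$start), ]
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  structure(list(A = genome_set("A", recordsA, fa),
                 B = genome_set("B", recordsB, fb),
                 truth = truth %||% data.frame()),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("<sim_pair> strain A: %d bp in %d replicon(s); %d implanted element(s)\n",
              sum(vapply(x$A$records, `[[`, integer(1), "length")),
              length(x$A$records), nrow(x$truth)))
  invisible(x)
}

#' The study-scale implant set spanning the observed element geometry
#'
#' Seven implants covering the reported size range (~10-208 kb), repeat
#' lengths from 10/10 to 738/738 bp including unequal pairs (77/46,
#' 89/18, 76/50, 77/45), ~57% G+C cargo, tRNA-anchored att sites and
#' class-defining module inventories for prophage, ICE (with and
#' without the full phage regulatory switch), IME and GI.
#'
#' @return list of [implant_spec()] objects.
#' @export
study_implants <- function() {
  list(
    implant_spec("prophage", 59363L, 10L, 10L, "Arg-TCT",
                 modules = c("xis", "cI", "cro", "phage_struct")),
    implant_spec("ICE", 104341L, 77L, 46L, "Met-CAT",
                 modules = c("trb_t4ss", "parAB", "ta_mazF")),
    implant_spec("ICE", 208271L, 76L, 50L, "Lys-CTT",
                 modules = c("xis", "cI", "cII", "cro", "trb_t4ss", "virD2",
                             "virD4", "parAB", "ta_hicA")),
    implant_spec("IME", 80923L, 89L, 18L, "Ser-CGA",
                 modules = c("virD2", "virD4")),
    implant_spec("GI", 13719L, 77L, 77L, "Arg-CCG",
                 modules = c("ta_vapC_phd")),
    implant_spec("GI", 9952L, 77L, 45L, "Arg-TCT", modules = character()),
    implant_spec("GI", 45079L, 76L, 45L, "Lys-CTT",
                 modules = c("ta_hipA", "ta_vapC_phd")))
}

#' Implant-free control genome
#'
#' A single-replicon genome with background genes and tRNAs but no
#' integrase and no repeats beyond chance: the element caller must
#' return nothing on it.
#'
#' @param seed RNG seed.
#' @param length replicon length (default 1 Mb).
#' @param gc background G+C.
#' @return a [genome_set()].
#' @export
simulate_control_genome <- function(seed, length = 1000000L, gc = 0.61) {
  cfg <- sim_config(seed = seed,
                    replicons = list(list(name = "chr", length = as.integer(length),
                                          gc = gc)))
  simulate_strain_pair(cfg)$A
}

# substitute n positions of a protein with different residues
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.mutate_protein <- function(p, n) {
  if (n == 0L) return(p)
  v <- strsplit(p, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(v), n)
  for (i in pos) v[i] <- sample(setdiff(.AA20, v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulate paired proteomes with controlled ortholog identities
#'
#' Each row of `plan` yields one gene pair: protein A is random, protein
#' B is A with `round((1 - identity) * length)` substitutions.  Unique
#' genes are independent random proteins with no counterpart.
#'
#' @param plan data frame with columns `length_aa`, `identity`.
#' @param n_unique_a,n_unique_b strain-specific gene counts.
#' @param unique_len length of unique genes in aa.
#' @param seed RNG seed.
#' @return list: `A`, `B` (named character vectors), `truth` (data
#'   frame gene_a, gene_b, identity, n_sub).
#' @export
simulate_proteome_pair <- function(plan, n_unique_a = 0L, n_unique_b = 0L,
                                   unique_len = 250L, seed = 1L) {
  set.seed(seed)
  stopifnot(all(c("length_aa", "identity") %in% names(plan)))
  A <- character(); B <- character(); rows <- list()
  for (i in seq_len(nrow(plan))) {
    len <- plan$length_aa[i]
    a <- paste(sample(.AA20, len, replace = TRUE), collapse = "")
    nsub <- round((1 - plan$identity[i]) * len)
    b <- .mutate_protein(a, nsub)
    na <- sprintf("A_%04d", i); nb <- sprintf("B_%04d", i)
    A[na] <- a; B[nb] <- b
    rows[[i]] <- data.frame(gene_a = na, gene_b = nb,
                            identity = plan$identity[i], n_sub = nsub)
  }
  for (i in seq_len(n_unique_a))
    A[sprintf("A_uniq_%03d", i)] <- paste(sample(.AA20, unique_len, TRUE), collapse = "")
  for (i in seq_len(n_unique_b))
    B[sprintf("B_uniq_%03d", i)] <- paste(sample(.AA20, unique_len, TRUE), collapse = "")
  list(A = A, B = B, truth = do.call(rbind, rows) %||% data.frame())
}

#' Simulate a qPCR dilution series
#'
#' Ct = intercept + slope * log10(dilution) with
#' slope = -1 / log10(1 + E), plus Gaussian noise.  The default series
#' is the 5-point 10-fold dilution design (relative factors 1 to 1e-4).
#'
#' @param efficiency reaction efficiency E in (0, 1].
#' @param intercept Ct at the reference dilution.
#' @param dilutions dilution factors (default `10^(0:-4)`).
#' @param n_replicates replicates per dilution.
#' @param noise_sd Ct noise standard deviation.
#' @param seed RNG seed.
#' @return data frame: dilution, log10_dilution, replicate, ct.
#' @export
simulate_dilution_series <- function(efficiency, intercept = 30, dilutions = 10^(0:-4),
                                     n_replicates = 1L, noise_sd = 0, seed = 1L) {
  if (any(efficiency <= 0) || any(efficiency > 1))
    stop("efficiency must be in (0, 1]", call. = FALSE)
  if (any(dilutions <= 0)) stop("non-positive dilution factor", call. = FALSE)
  set.seed(seed)
  slope <- -1 / log10(1 + efficiency)
  grid <- expand.grid(dilution = dilutions, replicate = seq_len(n_replicates))
  grid$log10_dilution <- log10(grid$dilution)
  grid$ct <- intercept + slope * grid$log10_dilution +
    rnorm(nrow(grid), sd = noise_sd)
  grid[, c("dilution", "log10_dilution", "replicate", "ct")]
}

#' Simulate a full excision qPCR experiment
#'
#' For each target (e.g. attR, attB, attI) a dilution series is
#' generated, plus control and treated sample Cts whose underlying
#' quantities differ by the requested fold induction.
#'
#' @param folds named numeric vector: fold induction per target (values
#'   must be > 0).
#' @param efficiency shared reaction efficiency.
#' @param control_quantity underlying control quantity (curve units).
#' @param conditions name(s) of the treated condition(s); each gets the
#'   same fold (a named list of per-condition folds is also accepted).
#' @param n_replicates replicates per condition.
#' @param noise_sd Ct noise standard deviation.
#' @param intercept Ct at the reference dilution.
#' @param seed RNG seed.
#' @return list: `series` (data frame target + dilution columns),
#'   `samples` (data frame target, condition, replicate, ct),
#'   `truth` (data frame target, condition, fold).
#' @export
simulate_qpcr_experiment <- function(folds, efficiency = 0.95,
                                     control_quantity = 0.01,
                                     conditions = "treated", n_replicates = 3L,
                                     noise_sd = 0.05, intercept = 30, seed = 1L) {
  stopifnot(!is.null(names(folds)), all(unlist(folds) > 0))
  if (control_quantity <= 0) stop("non-positive quantity", call. = FALSE)
  set.seed(seed)
  slope <- -1 / log10(1 + efficiency)
  series <- list(); samples <- list(); truth <- list()
  for (tg in names(folds)) {
    s <- simulate_dilution_series(efficiency, intercept = intercept,
                                  noise_sd = noise_sd,
                                  seed = .subseed(seed, length(series) + 1L))
    series[[tg]] <- cbind(target = tg, s)
    fold_of <- function(cond) if (is.list(folds[[tg]])) folds[[tg]][[cond]] else folds[[tg]]
    for (cond in c("control", conditions)) {
      qty <- control_quantity * if (cond == "control") 1 else fold_of(cond)
      ct <- intercept + slope * log10(qty) + rnorm(n_replicates, sd = noise_sd)
      samples[[length(samples) + 1L]] <-
        data.frame(target = tg, condition = cond,
                   replicate = seq_len(n_replicates), ct = ct)
      if (cond != "control")
        truth[[length(truth) + 1L]] <- data.frame(target = tg, condition = cond,
                                                  fold = fold_of(cond))
    }
  }
  list(series = do.call(rbind, c(series, make.row.names = FALSE)),
       samples = do.call(rbind, samples),
       truth = do.call(rbind, truth))
}
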