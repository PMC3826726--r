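#' G+C content of a sequence
#'
#' N bases are excluded from both numerator and denominator.
#'
#' @param seq DNA string (A/C/G/T/N).
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  cnt <- .base_counts(seq)
  denom <- sum(cnt[c("A", "C", "G", "T")])
  if (denom == 0L) stop("all-N (or empty) sequence has no defined G+C content",
                        call. = FALSE)
  unname((cnt["G"] + cnt["C"]) / denom)
}

#' GC skew of a sequence
#'
#' `(G - C) / (G + C)`, defined as 0 when the sequence contains no G or C.
#'
#' @param seq DNA string.
#' @return value in `[-1, 1]`.
#' @export
gc_skew <- function(seq) {
  cnt <- .base_counts(seq)
  gc <- cnt["G"] + cnt["C"]
  if (gc == 0L) return(0)
  unname((cnt["G"] - cnt["C"]) / gc)
}

#' Sliding-window composition profile of a replicon
#'
#' Windows tile `[0, length)`; a final partial window is kept when it is
#' at least half a window long.  Per-window G+C (N-excluded) and GC skew
#' are reported together with the whole-replicon mean G+C, plus flags
#' for windows deviating from the replicon mean by at least
#' `delta_threshold` percentage points or `z_threshold` standard
#' deviations of the window distribution.  The flags are evidence for
#' foreign origin; they never gate element calling.
#'
#' @param record a [genome_record()].
#' @param window window size in bp (>= 50).
#' @param step step in bp (>= 1).
#' @param delta_threshold,z_threshold anomaly flag thresholds.
#' @return object of class `composition_profile`: a list with `windows`
#'   (data frame: start, end, gc, skew, anomalous), `window`, `step`,
#'   `replicon_mean_gc`.
#' @export
composition_profile <- function(record, window = 1000L, step = 500L,
                                delta_threshold = 2, z_threshold = 2) {
  stopifnot(inherits(record, "genome_record"))
  len <- record$length
  if (window < 50L) stop("window must be >= 50 bp", call. = FALSE)
  if (window > len) stop("window exceeds replicon length", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  r <- as.integer(charToRaw(record$sequence))
  cg <- cumsum(r == .BYTE[["G"]])
  cc <- cumsum(r == .BYTE[["C"]])
  cn <- cumsum(r == .BYTE[["N"]])
  starts <- seq.int(0L, max(0L, len - window), by = step)
  # trailing partial window, kept when >= window/2
  last_end <- starts[length(starts)] + window
  if (last_end < len) {
    tail_start <- last_end  # continue the tiling at the next step multiple
    ts <- starts[length(starts)] + step
    if (len - ts >= window / 2) starts <- c(starts, ts)
  }
  ends <- pmin(starts + window, len)
  # 0-padded cumulative counts so a window starting at 0 indexes cleanly
  win_at <- function(cum, s, e) { cum0 <- c(0L, cum); cum0[e + 1L] - cum0[s + 1L] }
  g <- win_at(cg, starts, ends)
  c_ <- win_at(cc, starts, ends)
  n <- win_at(cn, starts, ends)
  wlen <- ends - starts
  denom <- wlen - n
  gc <- ifelse(denom > 0, (g + c_) / denom, NA_real_)
  skew <- ifelse(g + c_ > 0, (g - c_) / (g + c_), 0)
  mean_gc <- gc_content(record$sequence)
  sd_gc <- stats::sd(gc, na.rm = TRUE)
  z <- if (is.na(sd_gc) || sd_gc == 0) rep(0, length(gc)) else (gc - mean(gc, na.rm = TRUE)) / sd_gc
  anomalous <- (abs(gc - mean_gc) * 100 >= delta_threshold) | (abs(z) >= z_threshold)
  structure(list(windows = data.frame(start = starts, end = ends, gc = gc,
                                      skew = skew, z = z,
                                      anomalous = anomalous),
                 window = window, step = step, replicon_mean_gc = mean_gc,
                 replicon_id = record$replicon_id),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s: %d windows of %d bp (step %d), mean G+C %.3f\n",
              x$replicon_id, nrow(x$windows), x$window, x$step, x$replicon_mean_gc))
  invisible(x)
}

#' Write a composition profile as TSV
#'
#' @param profile a [composition_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- cbind(replicon = profile$replicon_id, profile$windows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Signed G+C deviation of an element from the rest of its replicon
#'
#' `100 * (gc(element) - gc(rest))`, where "rest" excludes the element
#' itself, in percentage points.
#'
#' @param record a [genome_record()].
#' @param start,end element interval, 0-based half-open.
#' @return signed percentage points.
#' @export
element_gc_deviation <- function(record, start, end) {
  stopifnot(inherits(record, "genome_record"))
  len <- record$length
  if (start < 0L || end > len || end <= start)
    stop("element interval outside replicon", call. = FALSE)
  if (start == 0L && end == len)
    stop("element covers the entire replicon; no background left", call. = FALSE)
  inner <- .base_counts(substr(record$sequence, start + 1L, end))
  total <- .base_counts(record$sequence)
  rest <- total - inner
  gc_in <- (inner[["G"]] + inner[["C"]]) / sum(inner[c("A", "C", "G", "T")])
  gc_out <- (rest[["G"]] + rest[["C"]]) / sum(rest[c("A", "C", "G", "T")])
  100 * (gc_in - gc_out)
}
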