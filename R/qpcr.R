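# Real-time PCR mathematics: dilution-series standard curves, reaction
# efficiency, absolute quantification and fold induction of integrated
# (attR) vs excised (attB, attI) element forms.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct against log10(dilution factor).  The
#' reaction efficiency is `E = 10^(-1/slope) - 1`, so a perfect
#' (doubling) reaction has slope -1/log10(2) = -3.321928 and E = 1.
#'
#' @param points data frame with columns `log10_dilution` (or
#'   `dilution`, which is log10-transformed) and `ct`.
#' @return object of class `standard_curve`: list with `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `points`.
#' @export
fit_standard_curve <- function(points) {
  points <- as.data.frame(points)
  if (!"log10_dilution" %in% names(points)) {
    if (!"dilution" %in% names(points))
      stop("points need a log10_dilution or dilution column", call. = FALSE)
    if (any(points$dilution <= 0)) stop("dilution factors must be positive", call. = FALSE)
    points$log10_dilution <- log10(points$dilution)
  }
  if (!"ct" %in% names(points)) stop("points need a ct column", call. = FALSE)
  if (length(unique(points$log10_dilution)) < 3L)
    stop("need at least 3 distinct dilutions for a standard curve", call. = FALSE)
  fit <- lm(ct ~ log10_dilution, data = points)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0)
    stop("positive slope: Ct must fall as dilution factor rises ",
         "(is the dilution axis inverted?)", call. = FALSE)
  structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 points = points[, c("log10_dilution", "ct")]),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.2f, E = %.3f, r2 = %.4f\n",
              x$slope, x$intercept, x$efficiency, x$r_squared))
  invisible(x)
}

#' Absolute quantity from a Ct value
#'
#' `amount = 10^((ct - intercept) / slope)`, in the units of the
#' dilution series (the reference dilution has amount 1).  Ct values
#' outside the calibrated range are extrapolated with a warning.
#'
#' @param ct Ct value(s).
#' @param curve a [fit_standard_curve()] result.
#' @return numeric amounts.
#' @export
quantify_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  rng <- range(curve$points$ct)
  if (any(ct < rng[1] - 1e-9 | ct > rng[2] + 1e-9))
    warning("Ct outside the calibrated range; value extrapolated")
  10^((ct - curve$intercept) / curve$slope)
}

#' Fold induction of a target between two conditions
#'
#' Replicate Cts are converted to absolute quantities on the standard
#' curve; the fold is the ratio of mean treated to mean control
#' quantity, with the spread given by the extreme ratios over all
#' replicate combinations.  Scale-invariant: multiplying all quantities
#' by a constant leaves folds unchanged.
#'
#' @param treated_ct,control_ct replicate Ct vectors (>= 1 each).
#' @param curve the target's [fit_standard_curve()].
#' @param target,condition labels carried into the result.
#' @return object of class `fold_induction`: list with `fold`,
#'   `spread` (min/max replicate ratio), `n_treated`, `n_control`,
#'   `target`, `condition`.
#' @export
fold_induction <- function(treated_ct, control_ct, curve, target = "target",
                           condition = "treated") {
  if (!length(treated_ct) || !length(control_ct))
    stop("need at least one replicate per condition", call. = FALSE)
  qt <- suppressWarnings(quantify_ct(treated_ct, curve))
  qc <- suppressWarnings(quantify_ct(control_ct, curve))
  if (any(qc <= 0)) stop("zero control quantity", call. = FALSE)
  ratios <- outer(qt, qc, "/")
  structure(list(fold = mean(qt) / mean(qc), spread = range(ratios),
                 n_treated = length(qt), n_control = length(qc),
                 target = target, condition = condition),
            class = "fold_induction")
}

#' @export
print.fold_induction <- function(x, ...) {
  cat(sprintf("<fold_induction> %s, %s: %.2f-fold (replicate ratios %.2f-%.2f)\n",
              x$target, x$condition, x$fold, x$spread[1], x$spread[2]))
  invisible(x)
}

#' Fold induction for every target/condition in a Ct table
#'
#' @param ct_table data frame: target, condition, replicate, ct; the
#'   control condition is named by `control`.
#' @param curves named list of [fit_standard_curve()] objects, one per
#'   target.
#' @param control name of the control condition (default "control").
#' @return data frame: target, condition, fold, spread_lo, spread_hi.
#' @export
fold_table <- function(ct_table, curves, control = "control") {
  stopifnot(all(c("target", "condition", "ct") %in% names(ct_table)))
  out <- list()
  for (tg in unique(ct_table$target)) {
    if (is.null(curves[[tg]])) stop("no standard curve for target ", tg, call. = FALSE)
    sub <- ct_table[ct_table$target == tg, ]
    ctrl <- sub$ct[sub$condition == control]
    for (cond in setdiff(unique(sub$condition), control)) {
      fi <- fold_induction(sub$ct[sub$condition == cond], ctrl, curves[[tg]],
                           target = tg, condition = cond)
      out[[length(out) + 1L]] <- data.frame(target = tg, condition = cond,
                                            fold = fi$fold,
                                            spread_lo = fi$spread[1],
                                            spread_hi = fi$spread[2])
    }
  }
  do.call(rbind, out)
}
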