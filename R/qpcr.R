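#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on the log10 template quantity
#' (concentration in ng/uL or cell density in CFU/mL), with Cq as the
#' response. Replicates enter individually, not as level means, by
#' default.
#'
#' @param points Data.frame with columns `x` (log10 quantity) and `cq`;
#'   an optional `replicate` column is ignored by the fit.
#' @param average_replicates Average Cq per level before fitting.
#' @return An object of class `standard_curve`: `slope` (cycles per log10
#'   unit), `intercept` (cycles), `r2`, `efficiency_pct`, `n_points`.
#' @export
fit_standard_curve <- function(points, average_replicates = FALSE) {
  stopifnot(is.data.frame(points), all(c("x", "cq") %in% names(points)))
  pts <- points[is.finite(points$x) & is.finite(points$cq), , drop = FALSE]
  if (average_replicates)
    pts <- stats::aggregate(cq ~ x, data = pts, FUN = mean)
  if (length(unique(pts$x)) < 3L)
    stop("standard curve needs at least 3 distinct x levels")
  fit <- stats::lm(cq ~ x, data = pts)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((pts$cq - mean(pts$cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 efficiency_pct = efficiency_from_slope(slope),
                 n_points = nrow(pts)),
            class = "standard_curve")
}

#' Construct a standard curve from known coefficients
#'
#' @param slope Slope in cycles per log10 unit (negative).
#' @param intercept Intercept in cycles.
#' @param r2 Optional coefficient of determination.
#' @return A `standard_curve` object.
#' @export
standard_curve <- function(slope, intercept, r2 = NA_real_) {
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 efficiency_pct = if (slope < 0) efficiency_from_slope(slope)
                                  else NA_real_,
                 n_points = NA_integer_),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> Cq = %.4f * x + %.4f  (R2 = %s, efficiency = %s%%)\n",
              x$slope, x$intercept,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2),
              if (is.na(x$efficiency_pct)) "NA"
              else sprintf("%.2f", x$efficiency_pct)))
  invisible(x)
}

#' Predicted Cq at a log10 quantity
#'
#' @param object A `standard_curve`.
#' @param x log10 quantity.
#' @param ... Unused.
#' @return Predicted Cq.
#' @export
predict.standard_curve <- function(object, x, ...) {
  object$intercept + object$slope * x
}

#' Amplification efficiency from a standard-curve slope
#'
#' E(%) = (10^(-1/slope) - 1) x 100. A slope of -3.32 cycles per log10
#' unit corresponds to perfect doubling (100%).
#'
#' @param slope Standard-curve slope (negative, cycles per log10 unit).
#' @param digits Decimals for the reported value.
#' @return Efficiency percentage, rounded to `digits` decimals.
#' @export
efficiency_from_slope <- function(slope, digits = 2L) {
  if (!is.finite(slope) || slope >= 0) stop("slope must be negative")
  round((10^(-1 / slope) - 1) * 100, digits)
}

#' Standard-curve slope implied by an amplification efficiency
#'
#' Inverse of [efficiency_from_slope()]: slope = -1 / log10(E/100 + 1).
#'
#' @param efficiency_pct Efficiency percentage (> 0).
#' @return The implied slope.
#' @export
slope_from_efficiency <- function(efficiency_pct) {
  if (!is.finite(efficiency_pct) || efficiency_pct <= 0)
    stop("efficiency_pct must be positive")
  -1 / log10(efficiency_pct / 100 + 1)
}

#' Positivity call for a Cq value
#'
#' A reaction is positive iff Cq is strictly below the threshold
#' (default 35 cycles). Undetermined or missing Cq values are negative.
#'
#' @param cq Cq value(s); `NA` for undetermined.
#' @param threshold Positivity threshold in cycles.
#' @return Logical vector.
#' @export
is_positive <- function(cq, threshold = 35) {
  !is.na(cq) & cq < threshold
}

#' Invert a standard curve: Cq to log10 quantity
#'
#' @param curve A `standard_curve` with negative slope.
#' @param cq Cq value(s).
#' @return x = (cq - intercept) / slope.
#' @export
cq_to_log_density <- function(curve, cq) {
  if (curve$slope >= 0) stop("curve slope must be negative")
  (cq - curve$intercept) / curve$slope
}

#' Viable-count content of a sample from a curve-inverted density
#'
#' M = 10^x x (A + B) / A x C, where x is the log10 density (CFU/mL) of
#' the measured suspension obtained by inverting the standard curve, A is
#' the sample mass (g), B the diluent volume (mL) and C the dilution
#' factor. Equivalence between genome copies of a single-copy marker gene
#' and CFU is assumed, and flagged in the result.
#'
#' @param x log10 density of the measured suspension (CFU/mL).
#' @param A Sample mass in g (> 0).
#' @param B Diluent volume in mL (>= 0).
#' @param C Dilution factor (>= 1).
#' @return A list: `x`, `density` (10^x CFU/mL), `M` (CFU/g), `log10_M`
#'   (2 decimals), `assumes_single_copy_equivalence`.
#' @export
cfu_per_gram <- function(x, A, B, C = 1) {
  if (!is.finite(A) || A <= 0) stop("sample mass A must be > 0")
  if (B < 0) stop("diluent volume B must be >= 0")
  if (C < 1) stop("dilution factor C must be >= 1")
  M <- 10^x * (A + B) / A * C
  list(x = x, density = 10^x, M = M, log10_M = round(log10(M), 2L),
       assumes_single_copy_equivalence = TRUE)
}

#' Replicate statistics across groups of Cq values
#'
#' Computes the per-group means, the grand mean, the sample standard
#' deviation (n-1) of the group means, the relative standard deviation
#' of the group means (computed on unrounded intermediates), and the
#' pooled within-group SD. With a single group the SD of group means is
#' undefined and flagged; the pooled SD then equals the sample SD.
#'
#' @param groups Named list of numeric Cq vectors (one per group, e.g.
#'   per passage generation, run, or platform).
#' @return A list: `group_means`, `grand_mean`, `sd_of_group_means`,
#'   `rsd_pct`, `pooled_sd`, `sd_undefined`.
#' @export
replicate_stats <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) stop("every group must be non-empty")
  gm <- vapply(groups, mean, numeric(1))
  grand <- mean(unlist(groups))
  k <- length(groups)
  if (k >= 2L) {
    sdm <- stats::sd(gm)
    rsd <- 100 * sdm / mean(gm)
    sd_undef <- FALSE
  } else {
    sdm <- NA_real_; rsd <- NA_real_; sd_undef <- TRUE
  }
  within_ss <- sum(vapply(seq_along(groups), function(i)
    sum((groups[[i]] - gm[i])^2), numeric(1)))
  df <- sum(sizes - 1L)
  pooled <- if (df > 0L) sqrt(within_ss / df) else 0
  if (k == 1L) pooled <- stats::sd(groups[[1]])
  list(group_means = gm, grand_mean = grand, sd_of_group_means = sdm,
       rsd_pct = rsd, pooled_sd = pooled, sd_undefined = sd_undef)
}

#' Limit of detection from a dilution-ladder positivity series
#'
#' The detection limit is the smallest level x such that its replicates
#' and those of every larger level are all positive (the monotone
#' positivity frontier). If a fully positive level exists below a level
#' with dropouts, the frontier stays at the conservative (larger) x and a
#' warning is raised.
#'
#' @param series Named list: names are the levels (log10 quantities),
#'   values are logical replicate positivity vectors (from
#'   [is_positive()]).
#' @return A list: `x_min` (NA with `defined = FALSE` when no level is
#'   fully positive), `defined`, `non_monotone`.
#' @export
detection_limit <- function(series) {
  x <- as.numeric(names(series))
  stopifnot(!anyNA(x))
  ord <- order(x)
  x <- x[ord]
  full <- vapply(series[ord], function(v) all(v) && length(v) > 0L, logical(1))
  if (!any(full)) return(list(x_min = NA_real_, defined = FALSE,
                              non_monotone = FALSE))
  # smallest x with every level >= x fully positive
  suffix_all <- rev(cumprod(rev(full))) > 0
  if (!any(suffix_all)) return(list(x_min = NA_real_, defined = FALSE,
                                    non_monotone = TRUE))
  x_min <- min(x[suffix_all])
  non_mono <- any(full & x < x_min)
  if (non_mono)
    warning(sprintf(paste0("non-monotone positivity ladder: level(s) below ",
                           "%.3g are fully positive; reporting the ",
                           "conservative frontier"), x_min))
  list(x_min = x_min, defined = TRUE, non_monotone = non_mono)
}

#' Read a Cq measurement table
#'
#' Expected CSV columns: `x` (log10 quantity) and `cq`; optional `sample`,
#' `group`, `replicate`, `A`, `B`, `C`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_cq_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "cq") %in% names(df)))
    stop("Cq table must have columns 'x' and 'cq'")
  df
}

#' Quantify a sample from replicate Cq values
#'
#' Inverts the standard curve at the mean Cq of the replicates and applies
#' the CFU/g formula.
#'
#' @param curve A `standard_curve`.
#' @param cq Replicate Cq values.
#' @param A,B,C See [cfu_per_gram()].
#' @param positivity_threshold Cq threshold for the positivity gate.
#' @return A list combining the [cfu_per_gram()] fields with `mean_cq`,
#'   `n_replicates`, `all_positive`.
#' @export
quantify_sample <- function(curve, cq, A, B, C = 1,
                            positivity_threshold = 35) {
  stopifnot(length(cq) >= 1L)
  pos <- is_positive(cq, positivity_threshold)
  x <- cq_to_log_density(curve, mean(cq, na.rm = TRUE))
  res <- cfu_per_gram(x, A, B, C)
  c(res, list(mean_cq = mean(cq, na.rm = TRUE), n_replicates = length(cq),
              all_positive = all(pos)))
}
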