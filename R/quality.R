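#' Normalize measured spacings by the target spacing
#'
#' Each measured spacing `d_i` is expressed as the ratio `S_i = d_i /
#' d_ref` to the planter's target spacing. Ratios are quantized at 1e-6
#' (far below the millimeter-level measurement precision) so that the
#' downstream quality report is exactly invariant to the unit in which
#' spacings and target are expressed.
#'
#' @param spacings Numeric vector of measured spacings (>= 0), meters.
#' @param target Target spacing `d_ref` (> 0), meters.
#' @return Numeric vector of normalized ratios, order preserved.
#' @export
normalize_ratios <- function(spacings, target) {
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0)
    stop("target spacing must be a single positive number", call. = FALSE)
  if (any(!is.finite(spacings)) || any(spacings < 0))
    stop("spacings must be finite and >= 0", call. = FALSE)
  round(spacings / target, 6)
}

#' Bin normalized spacing ratios into the ISO 7256 intervals
#'
#' Classifies each ratio into one of five intervals:
#' bin 1 = \[0, 0.5\] (multiples), bin 2 = (0.5, 1.5\] (qualified),
#' bin 3 = (1.5, 2.5\], bin 4 = (2.5, 3.5\], bin 5 = (3.5, Inf)
#' (increasing skip multiplicity). Every non-negative ratio lands in
#' exactly one bin; boundaries belong to the lower bin.
#'
#' @param ratios Numeric vector of normalized ratios (>= 0).
#' @return Named integer vector `c(n1p, n2p, n3p, n4p, n5p)` of interval
#'   counts, summing to `length(ratios)`.
#' @export
bin_ratios <- function(ratios) {
  if (any(!is.finite(ratios)) || any(ratios < 0))
    stop("ratios must be finite and >= 0", call. = FALSE)
  idx <- findInterval(ratios, c(0.5, 1.5, 2.5, 3.5), left.open = TRUE) + 1L
  counts <- tabulate(idx, nbins = 5L)
  names(counts) <- c("n1p", "n2p", "n3p", "n4p", "n5p")
  counts
}

#' Derive seeding event counts from interval counts
#'
#' Converts the five interval counts n'1..n'5 into the seeding event
#' counts: multiples `n2 = n'1`, misses `n0 = n'3 + 2 n'4 + 3 n'5` (each
#' interval of length ~k+1 targets hides k misses), total intervals
#' `N' = n'2 + 2 n'3 + 3 n'4 + 4 n'5`, and normal seedings
#' `n1 = (n'1 + ... + n'5) - 2 n2`. These satisfy `n1 + n2 + n0 = N'`,
#' which is what makes the three indices sum to 100%. `n1` can go negative
#' when short intervals dominate; it is reported as-is with `valid =
#' FALSE` downstream rather than clamped.
#'
#' @param bins Named integer vector from [bin_ratios()] (names `n1p`..`n5p`).
#' @return List with elements `n2`, `n1`, `n0`, `Np`.
#' @export
derive_counts <- function(bins) {
  need <- c("n1p", "n2p", "n3p", "n4p", "n5p")
  if (!all(need %in% names(bins)))
    stop("bins must carry names n1p..n5p", call. = FALSE)
  b <- as.integer(bins[need])
  if (any(b < 0)) stop("bin counts must be >= 0", call. = FALSE)
  n2 <- b[1L]
  n1 <- sum(b) - 2L * n2
  n0 <- b[3L] + 2L * b[4L] + 3L * b[5L]
  Np <- b[2L] + 2L * b[3L] + 3L * b[4L] + 4L * b[5L]
  list(n2 = n2, n1 = n1, n0 = n0, Np = Np)
}

#' Quality of feed, multiple and miss indices
#'
#' `QFI = 100 n1 / N'`, `MUL = 100 n2 / N'`, `MI = 100 n0 / N'` (percent).
#' With counts from [derive_counts()] the three always sum to 100.
#'
#' @param counts List with `n1`, `n2`, `n0`, `Np` (see [derive_counts()]).
#' @return Named numeric vector `c(qfi, mul, mi)` in percent.
#' @export
seeding_indices <- function(counts) {
  stopifnot(all(c("n1", "n2", "n0", "Np") %in% names(counts)))
  if (counts$Np <= 0) stop("no intervals: N' = 0", call. = FALSE)
  c(qfi = 100 * counts$n1 / counts$Np,
    mul = 100 * counts$n2 / counts$Np,
    mi  = 100 * counts$n0 / counts$Np)
}

#' Dispersion of the qualified spacings
#'
#' Restricts to the qualified ratios (bin 2, `0.5 < S <= 1.5`) and reports
#' their mean `S_bar`, standard deviation `sigma` and the coefficient of
#' variation `CV = 100 sigma` (percent). The default `sigma` is the
#' population standard deviation about the mean (divisor n'2).
#' `sigma_formula = "as_printed"` instead uses the raw second-moment form
#' `sqrt(sum(S^2)/n'2)` for auditing; being a second moment about zero it
#' sits near 1 for ratios near 1 (CV near 100%) and is not a dispersion
#' measure.
#' `cv_normalize_by_mean = TRUE` reports the classical `100 sigma / S_bar`;
#' the default follows the plain `100 sigma` convention, a second-order
#' difference since `S_bar` is close to 1 for normalized ratios.
#'
#' @param ratios Numeric vector of normalized ratios.
#' @param sigma_formula `"corrected"` (default) or `"as_printed"`.
#' @param cv_normalize_by_mean Divide the CV by `S_bar`? Default `FALSE`.
#' @return List `s_bar`, `sigma`, `cv` (percent), `n_qualified`; all `NA`
#'   with a warning attribute when no qualified ratio exists.
#' @export
qualified_stats <- function(ratios,
                            sigma_formula = c("corrected", "as_printed"),
                            cv_normalize_by_mean = FALSE) {
  sigma_formula <- match.arg(sigma_formula)
  q <- ratios[ratios > 0.5 & ratios <= 1.5]
  n <- length(q)
  if (n == 0L)
    return(list(s_bar = NA_real_, sigma = NA_real_, cv = NA_real_,
                n_qualified = 0L))
  s_bar <- mean(q)
  sigma <- if (sigma_formula == "corrected")
    sqrt(sum((q - s_bar)^2) / n)
  else
    sqrt(sum(q^2) / n)
  cv <- 100 * sigma / (if (cv_normalize_by_mean) s_bar else 1)
  list(s_bar = s_bar, sigma = sigma, cv = cv, n_qualified = n)
}

#' Evaluate sowing quality from a spacing series
#'
#' Full evaluation chain: normalize measured spacings by the target,
#' classify the ratios into the five ISO 7256 intervals, derive the
#' seeding event counts and compute the quality of feed index (QFI),
#' multiple index (MUL), miss index (MI) and the dispersion of the
#' qualified spacings (S_bar, sigma, CV).
#'
#' @param spacings Numeric vector of measured within-row spacings, meters
#'   (ordered or not: the indices are order-free).
#' @param target Target spacing in meters (> 0).
#' @inheritParams qualified_stats
#' @return An object of class `"sowing_quality"`: a list with `qfi`,
#'   `mul`, `mi` (percent), `s_bar`, `sigma`, `cv` (percent), `bins`,
#'   `counts`, `n_spacings`, `target`, `valid` and `warnings`.
#' @examples
#' evaluate_sowing(c(0.06, 0.16, 0.44, 0.20), target = 0.20)
#' @export
evaluate_sowing <- function(spacings, target,
                            sigma_formula = c("corrected", "as_printed"),
                            cv_normalize_by_mean = FALSE) {
  sigma_formula <- match.arg(sigma_formula)
  if (length(spacings) == 0L)
    stop("empty spacing series: nothing to evaluate", call. = FALSE)
  ratios <- normalize_ratios(spacings, target)
  bins <- bin_ratios(ratios)
  counts <- derive_counts(bins)
  if (counts$Np <= 0)
    stop("no intervals: all spacings fall in the multiples bin (N' = 0)",
         call. = FALSE)
  idx <- seeding_indices(counts)
  qs <- qualified_stats(ratios, sigma_formula, cv_normalize_by_mean)
  warnings <- character(0)
  valid <- TRUE
  if (counts$n1 < 0) {
    valid <- FALSE
    warnings <- c(warnings,
                  "n1 < 0: short intervals dominate; indices unreliable")
  }
  if (qs$n_qualified == 0L)
    warnings <- c(warnings, "no qualified spacings: S_bar/sigma/CV undefined")
  structure(list(qfi = unname(idx["qfi"]), mul = unname(idx["mul"]),
                 mi = unname(idx["mi"]),
                 s_bar = qs$s_bar, sigma = qs$sigma, cv = qs$cv,
                 bins = bins, counts = counts,
                 n_spacings = length(spacings), target = target,
                 sigma_formula = sigma_formula,
                 cv_normalize_by_mean = cv_normalize_by_mean,
                 valid = valid, warnings = warnings),
            class = "sowing_quality")
}

#' @export
print.sowing_quality <- function(x, digits = 2, ...) {
  cat("Sowing quality (ISO 7256/1-1984 indices)\n")
  cat(sprintf("  spacings: %d, target: %g m\n", x$n_spacings, x$target))
  cat(sprintf("  QFI %s%%  MUL %s%%  MI %s%%\n",
              format(round(x$qfi, digits), nsmall = digits),
              format(round(x$mul, digits), nsmall = digits),
              format(round(x$mi, digits), nsmall = digits)))
  if (is.na(x$cv)) cat("  CV undefined (no qualified spacings)\n")
  else cat(sprintf("  S_bar %.4f  sigma %.4f  CV %s%%\n",
                   x$s_bar, x$sigma, format(round(x$cv, digits),
                                            nsmall = digits)))
  cat(sprintf("  intervals N' = %d (n1 %d, n2 %d, n0 %d)\n",
              x$counts$Np, x$counts$n1, x$counts$n2, x$counts$n0))
  if (!x$valid) cat("  WARNING:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.sowing_quality <- function(object, ...) {
  data.frame(qfi_pct = object$qfi, mul_pct = object$mul, mi_pct = object$mi,
             s_bar = object$s_bar, sigma = object$sigma, cv_pct = object$cv,
             n_intervals = object$counts$Np, valid = object$valid)
}
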