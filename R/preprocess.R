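#' Standard Normal Variate (SNV) transform
#'
#' Centers each spectrum to mean 0 and scales it to unit sample
#' (n-1 denominator) standard deviation, removing additive offsets and
#' global multiplicative scatter per spectrum.
#'
#' @param x Numeric vector (one spectrum), matrix (rows = spectra) or
#'   [spectra_set()].
#' @return Object of the same shape with each spectrum transformed.
#' @export
#' @examples
#' snv(c(1, 2, 3)) # -1 0 1
snv <- function(x) UseMethod("snv")

#' @export
snv.default <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("snv: degenerate input (constant spectrum has zero variance)")
  (x - mean(x)) / s
}

#' @export
snv.matrix <- function(x) t(apply(x, 1L, snv.default))

#' @export
snv.spectra_set <- function(x) {
  x$spectra <- snv.matrix(x$spectra)
  x
}

#' Max-min (MMS) normalization onto \[0, 1\]
#'
#' @inheritParams snv
#' @return Same shape, each spectrum mapped linearly onto \[0, 1\].
#' @export
minmax <- function(x) UseMethod("minmax")

#' @export
minmax.default <- function(x) {
  x <- as.numeric(x)
  r <- range(x)
  if (r[1] == r[2])
    stop("minmax: degenerate input (constant spectrum)")
  (x - r[1]) / (r[2] - r[1])
}

#' @export
minmax.matrix <- function(x) t(apply(x, 1L, minmax.default))

#' @export
minmax.spectra_set <- function(x) {
  x$spectra <- minmax.matrix(x$spectra)
  x
}

#' Multiplicative Scatter Correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, `x = a * ref + b`, and returns `(x - b) / a`. The reference
#' defaults to the arithmetic mean spectrum of the set it is fitted on
#' and is attached to the result (attribute `"reference"`) so held-out
#' data can be corrected against the same reference.
#'
#' @param x Matrix (rows = spectra) or [spectra_set()].
#' @param reference Optional reference spectrum; default is the column
#'   mean of `x`.
#' @return Corrected object; attribute `"reference"` carries the
#'   reference spectrum used.
#' @export
msc <- function(x, reference = NULL) UseMethod("msc")

#' @export
msc.matrix <- function(x, reference = NULL) {
  if (nrow(x) < 1L) stop("msc: empty set")
  if (is.null(reference)) reference <- colMeans(x)
  if (length(reference) != ncol(x)) stop("msc: reference length mismatch")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0)
    stop("msc: degenerate input (reference spectrum has zero variance)")
  out <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    a <- sum((xi - mean(xi)) * rc) / denom
    b <- mean(xi) - a * mean(reference)
    if (a == 0) stop("msc: degenerate spectrum with zero slope on reference")
    out[i, ] <- (xi - b) / a
  }
  attr(out, "reference") <- reference
  out
}

#' @export
msc.spectra_set <- function(x, reference = NULL) {
  corrected <- msc.matrix(x$spectra, reference)
  x$spectra <- corrected
  attr(x$spectra, "reference") <- NULL
  attr(x, "reference") <- attr(corrected, "reference")
  x
}

#' Fit a per-wavelength standardization (column autoscaling)
#'
#' Learns column means and sample (n-1) standard deviations on a
#' training set; [standardize_apply()] reuses them unchanged on held-out
#' data.
#'
#' @param x Matrix (rows = spectra) or [spectra_set()] with >= 2 rows.
#' @return Object of class `standardize_fit` with `center` and `scale`.
#' @export
standardize_fit <- function(x) {
  m <- if (inherits(x, "spectra_set")) x$spectra else as.matrix(x)
  if (nrow(m) < 2L) stop("standardize_fit: need at least 2 spectra")
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  bad <- which(scale == 0)
  if (length(bad))
    stop("standardize_fit: zero-variance column(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  structure(list(center = center, scale = scale), class = "standardize_fit")
}

#' Apply a fitted standardization
#' @param fit A `standardize_fit`.
#' @param x Matrix or [spectra_set()] on the same band grid.
#' @return Transformed object of the same shape.
#' @export
standardize_apply <- function(fit, x) {
  stopifnot(inherits(fit, "standardize_fit"))
  set <- inherits(x, "spectra_set")
  m <- if (set) x$spectra else as.matrix(x)
  if (ncol(m) != length(fit$center))
    stop("standardize_apply: column count mismatch")
  m <- sweep(sweep(m, 2L, fit$center, "-"), 2L, fit$scale, "/")
  if (set) { x$spectra <- m; x } else m
}

#' Standardize a set (fit + apply in one step)
#' @inheritParams standardize_fit
#' @return Transformed object; attribute `"fit"` carries the
#'   `standardize_fit` for reuse on held-out data.
#' @export
standardize <- function(x) {
  fit <- standardize_fit(x)
  out <- standardize_apply(fit, x)
  attr(out, "fit") <- fit
  out
}

#' Resample a spectrum to a fixed length by linear interpolation
#'
#' Maps the intensity vector onto `L` evenly spaced points across the
#' same wavelength span (endpoints preserved). Used to adapt the
#' 701-band instrument grid to the network's canonical input length.
#'
#' @param x Numeric vector, matrix (rows = spectra) or [spectra_set()].
#' @param L Target length (>= 2).
#' @return Vector/matrix of width `L` (a `spectra_set` input returns a
#'   plain matrix, since the resampled axis is no longer the instrument
#'   grid).
#' @export
#' @examples
#' resample_to_length(c(0, 1), 3) # 0 0.5 1
resample_to_length <- function(x, L) {
  if (L < 2) stop("resample_to_length: L must be >= 2")
  if (inherits(x, "spectra_set")) x <- x$spectra
  f <- function(v) {
    if (length(v) == L) return(as.numeric(v))
    stats::approx(seq_along(v), v, n = L)$y
  }
  if (is.matrix(x)) t(apply(x, 1L, f)) else f(as.numeric(x))
}

#' Apply a named preprocessing method to a spectra matrix
#'
#' Dispatcher used by the pipeline/CLI. `"none"` returns the input
#' unchanged. Set-level methods (`"msc"`, `"standardize"`) return fitted
#' parameters as attributes for reuse on held-out data.
#'
#' @param x Matrix or [spectra_set()].
#' @param method One of `"none"`, `"minmax"`, `"snv"`, `"msc"`,
#'   `"standardize"`.
#' @return Preprocessed object.
#' @export
preprocess_spectra <- function(x, method = c("none", "minmax", "snv", "msc",
                                             "standardize")) {
  method <- match.arg(method)
  switch(method,
         none = x,
         minmax = minmax(x),
         snv = snv(x),
         msc = msc(x),
         standardize = standardize(x))
}
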