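#' Wavelength grid for Vis/NIR transmission spectra
#'
#' Builds the fixed wavelength axis on which all spectra in a
#' [spectra_set()] live. The default is 350--1050 nm sampled at 1 nm,
#' i.e. 701 bands, matching the working range of compact CCD
#' spectrometers used for fruit transmission measurements.
#'
#' @param from,to Range of the grid in nm. Must lie within 300--1100 nm.
#' @param n Number of bands (default 701).
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
#' @examples
#' grid <- wavelength_grid()
#' length(grid) # 701
wavelength_grid <- function(from = 350, to = 1050, n = 701) {
  if (!is.numeric(from) || !is.numeric(to) || from >= to)
    stop("wavelength_grid: 'from' must be < 'to'")
  if (from < 300 || to > 1100)
    stop("wavelength_grid: grid must lie within [300, 1100] nm")
  if (n < 2) stop("wavelength_grid: need at least 2 bands")
  seq(from, to, length.out = n)
}

assert_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2 || any(!is.finite(grid)))
    stop("invalid wavelength grid: non-finite or too short")
  if (any(diff(grid) <= 0))
    stop("invalid wavelength grid: must be strictly increasing")
  if (grid[1] < 300 || grid[length(grid)] > 1100)
    stop("invalid wavelength grid: outside [300, 1100] nm")
  invisible(grid)
}

#' Container for a set of spectra with optional grade annotation
#'
#' Rows of `spectra` are samples, columns are the bands of `wavelength`.
#' When both `labels` and `true_ratio` are given they must agree under
#' the grade thresholds of [grade_from_ratio()].
#'
#' @param spectra Numeric matrix, n samples x P bands.
#' @param wavelength Wavelength grid of length P (see [wavelength_grid()]).
#' @param labels Optional integer grades in 1..4.
#' @param true_ratio Optional watercore volume fractions in \[0, 1).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(spectra, wavelength, labels = NULL, true_ratio = NULL) {
  spectra <- as.matrix(spectra)
  assert_grid(wavelength)
  if (ncol(spectra) != length(wavelength))
    stop("spectra_set: ncol(spectra) != length(wavelength)")
  if (any(!is.finite(spectra)))
    stop("spectra_set: non-finite intensities")
  n <- nrow(spectra)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("spectra_set: labels length mismatch")
    if (any(is.na(labels)) || any(labels < 1L) || any(labels > 4L))
      stop("spectra_set: labels must be integers in 1..4")
  }
  if (!is.null(true_ratio)) {
    if (length(true_ratio) != n) stop("spectra_set: true_ratio length mismatch")
    if (any(!is.finite(true_ratio)) || any(true_ratio < 0) || any(true_ratio >= 1))
      stop("spectra_set: true_ratio must lie in [0, 1)")
    if (!is.null(labels) && any(grade_from_ratio(true_ratio) != labels))
      stop("spectra_set: labels disagree with true_ratio under grade thresholds")
  }
  structure(
    list(spectra = spectra, wavelength = as.numeric(wavelength),
         labels = labels, true_ratio = true_ratio),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d bands (%.0f-%.0f nm)\n",
              nrow(x$spectra), ncol(x$spectra),
              x$wavelength[1], x$wavelength[length(x$wavelength)]))
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = 1:4))
    cat("  grades:", paste(sprintf("L%s=%d", names(tab), as.integer(tab)),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$spectra)

#' @export
as.matrix.spectra_set <- function(x, ...) x$spectra

#' Subset a spectra_set by sample index
#' @param set A `spectra_set`.
#' @param i Integer sample indices.
#' @return A `spectra_set` with the selected samples.
#' @export
subset_spectra <- function(set, i) {
  stopifnot(inherits(set, "spectra_set"))
  spectra_set(set$spectra[i, , drop = FALSE], set$wavelength,
              labels = if (!is.null(set$labels)) set$labels[i],
              true_ratio = if (!is.null(set$true_ratio)) set$true_ratio[i])
}

# Deterministic number formatting used by all CSV writers so that identical
# configurations export byte-identical files across runs.
fmt_num <- function(x) sprintf("%.10g", x)

#' Write a spectra_set to plain-text CSV
#'
#' The spectra file has the wavelengths as its header row and one sample
#' per subsequent row. When the set carries labels or true ratios a
#' companion metadata CSV (columns `sample_id,label,true_ratio`) is
#' written next to it.
#'
#' @param set A `spectra_set`.
#' @param path Output CSV path for the spectra.
#' @param meta_path Optional path for the metadata CSV; default replaces
#'   the extension of `path` with `_meta.csv`.
#' @return Invisibly, the paths written.
#' @export
write_spectra_csv <- function(set, path, meta_path = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  header <- paste(fmt_num(set$wavelength), collapse = ",")
  rows <- apply(set$spectra, 1L, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(c(header, rows), path)
  paths <- path
  if (!is.null(set$labels) || !is.null(set$true_ratio)) {
    if (is.null(meta_path))
      meta_path <- sub("\\.csv$", "_meta.csv", path)
    n <- nrow(set$spectra)
    lab <- if (is.null(set$labels)) rep(NA_integer_, n) else set$labels
    tr <- if (is.null(set$true_ratio)) rep(NA_real_, n) else set$true_ratio
    lines <- c("sample_id,label,true_ratio",
               sprintf("%d,%s,%s", seq_len(n),
                       ifelse(is.na(lab), "", as.character(lab)),
                       ifelse(is.na(tr), "", fmt_num(tr))))
    writeLines(lines, meta_path)
    paths <- c(paths, meta_path)
  }
  invisible(paths)
}

#' Read a spectra_set written by [write_spectra_csv()]
#'
#' @param path Spectra CSV path.
#' @param meta_path Optional metadata CSV path; when `NULL` the
#'   `_meta.csv` sibling is used if it exists.
#' @return A `spectra_set`.
#' @export
read_spectra_csv <- function(path, meta_path = NULL) {
  m <- as.matrix(utils::read.csv(path, header = FALSE, colClasses = "numeric"))
  dimnames(m) <- NULL
  wl <- m[1L, ]
  sp <- m[-1L, , drop = FALSE]
  labels <- NULL; true_ratio <- NULL
  if (is.null(meta_path)) {
    cand <- sub("\\.csv$", "_meta.csv", path)
    if (file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path)
    if (!all(is.na(meta$label))) labels <- meta$label
    if (!all(is.na(meta$true_ratio))) true_ratio <- meta$true_ratio
  }
  spectra_set(sp, wl, labels = labels, true_ratio = true_ratio)
}
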