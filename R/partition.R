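new_split_result <- function(train, test, n) {
  train <- sort(as.integer(train)); test <- sort(as.integer(test))
  stopifnot(length(intersect(train, test)) == 0L,
            setequal(c(train, test), seq_len(n)))
  structure(list(train = train, test = test, n = n), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d test (n = %d)\n",
              length(x$train), length(x$test), x$n))
  invisible(x)
}

#' Stratified random train/test split
#'
#' Within every class, `round(train_fraction * n_class)` samples (round
#' half up) are drawn uniformly at random into the training set; the
#' remainder form the test set. The canonical grading protocol is a 3:1
#' split, e.g. 150 train / 50 test per class for 200-sample classes.
#'
#' @param labels Class label vector, or a [spectra_set()] with labels.
#' @param train_fraction Fraction in (0, 1), default 0.75.
#' @param seed RNG seed for the random selection.
#' @return A `split_result` with `$train` and `$test` index vectors.
#' @export
stratified_split <- function(labels, train_fraction = 0.75, seed = 1) {
  if (inherits(labels, "spectra_set")) {
    if (is.null(labels$labels)) stop("stratified_split: set has no labels")
    labels <- labels$labels
  }
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("stratified_split: train_fraction must lie in (0, 1)")
  n <- length(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2L))
    stop("stratified_split: every class needs >= 2 samples")
  set.seed(seed)
  train <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    k <- floor(train_fraction * length(idx) + 0.5)  # round half up
    k <- max(1L, min(length(idx) - 1L, k))
    train <- c(train, sample(idx, k))
  }
  new_split_result(train, setdiff(seq_len(n), train), n)
}

# Normalized joint predictor/response distance matrix used by SPXY.
# Degenerate components (all-zero distances) are dropped with a warning;
# both degenerate is an error.
spxy_distance <- function(X, y) {
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(as.numeric(y), as.numeric(y), "-"))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0)
    stop("spxy_split: all samples identical in both X and y")
  if (mx == 0) {
    warning("spxy_split: X distances all zero; using y distances only")
    return(dy / my)
  }
  if (my == 0) {
    warning("spxy_split: y distances all zero; using X distances only")
    return(dx / mx)
  }
  dx / mx + dy / my
}

#' SPXY calibration/validation partition
#'
#' Deterministic Kennard-Stone style selection on the joint
#' predictor-response distance `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)`
#' with Euclidean `dx` over spectra and `|yi - yj|` over the response
#' (grade labels are used ordinally, 1..4). The seed pair is the pair at
#' maximum joint distance; samples are then accreted by the max-min rule
#' until the training size is reached. Ties are broken by lowest index,
#' so the split is deterministic and involves no RNG.
#'
#' @param X Numeric matrix, rows = samples.
#' @param y Numeric/ordinal response vector.
#' @param train_fraction Fraction in (0, 1); training size is
#'   `round(n * train_fraction)` (round half up).
#' @return A `split_result`.
#' @export
spxy_split <- function(X, y, train_fraction = 0.75) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("spxy_split: need at least 3 samples")
  if (length(y) != n) stop("spxy_split: y length mismatch")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("spxy_split: train_fraction must lie in (0, 1)")
  d <- spxy_distance(X, y)
  n_train <- max(2L, min(n - 1L, floor(train_fraction * n + 0.5)))
  # seed pair: maximum joint distance; which.max scans column-major so
  # ties resolve to the lowest (j, i) pair deterministically
  flat <- which.max(d)
  i0 <- (flat - 1L) %% n + 1L
  j0 <- (flat - 1L) %/% n + 1L
  sel <- sort(c(i0, j0))
  # max-min accretion with incremental minimum-distance bookkeeping
  mind <- pmin(d[, sel[1L]], d[, sel[2L]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(mind)            # ties -> lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  new_split_result(sel, setdiff(seq_len(n), sel), n)
}
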