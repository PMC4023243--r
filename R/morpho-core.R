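#' Isometric size (isosize) of one or more specimens
#'
#' Isosize is the geometric mean of all measurements of a specimen.  On the
#' natural-log scale (the default) it is the mean of the logged
#' measurements, i.e. the coordinate of the specimen along the isometric
#' direction (1, ..., 1)/sqrt(p) up to scaling.
#'
#' @param values Positive numeric vector (one specimen) or matrix
#'   (specimens x characters).
#' @param geometric If `TRUE` return the geometric mean in the original
#'   units (micrometres) instead of the log-scale value.
#' @return Numeric scalar or per-specimen vector.
#' @export
#' @examples
#' isosize(c(a = 100, b = 400), geometric = TRUE)  # 200
isosize <- function(values, geometric = FALSE) {
  if (is.matrix(values)) {
    bad <- !is.finite(values) | values <= 0
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      nm <- colnames(values)[idx[2L]]
      if (is.null(nm)) nm <- paste0("column ", idx[2L])
      stop("nonpositive or missing measurement in character '", nm,
           "' (row ", idx[1L], ")")
    }
    s <- rowMeans(log(values))
  } else {
    bad <- !is.finite(values) | values <= 0
    if (any(bad)) {
      nm <- names(values)[which(bad)[1L]]
      if (is.null(nm) || !nzchar(nm)) nm <- paste0("entry ", which(bad)[1L])
      stop("nonpositive or missing measurement in character '", nm, "'")
    }
    s <- mean(log(values))
  }
  if (geometric) exp(s) else s
}

#' Size/shape decomposition of a measurement table
#'
#' Splits the logged data into an isometric size component and a log-shape
#' matrix: each row of `log_shape` is the logged measurement vector of one
#' specimen minus its own mean, so `log(values) = isosize + log_shape`
#' exactly and every log-shape row sums to zero.  Log-shape coordinates are
#' the log ratios of each character to the specimen's geometric mean, which
#' is why a PCA of this matrix is a PCA "in the space of all ratios".
#'
#' @param x A [measurement_table()] or positive numeric matrix.
#' @return A list of class `shape_decomposition` with elements `isosize`
#'   (per-specimen, natural-log scale), `log_shape` (specimens x p), and
#'   `characters`.
#' @export
log_shape_transform <- function(x) {
  vals <- if (inherits(x, "measurement_table")) x$values else as.matrix(x)
  if (ncol(vals) < 2L) stop("shape is undefined for fewer than 2 characters")
  iso <- isosize(vals)
  ls <- log(vals) - iso
  structure(list(isosize = iso, log_shape = ls, characters = colnames(vals)),
            class = "shape_decomposition")
}

# Project a loading vector onto the shape subspace (orthogonal complement of
# the isometric direction) and normalise; fixes the residual numerical
# component along (1,...,1).
project_to_shape_space <- function(v) {
  v <- v - mean(v)
  nv <- sqrt(sum(v^2))
  if (nv > 0) v / nv else v
}

# Deterministic sign convention: the coefficient of largest magnitude is
# positive (first index on ties).
fix_loading_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Shape principal component analysis
#'
#' Unsupervised PCA of the log-shape matrix (covariance based; the
#' variables share units and scale).  Equivalent to an eigendecomposition
#' of the log-data covariance restricted to the orthogonal complement of
#' the isometric direction, so at most p - 1 components carry variance.
#' Group labels are never used.
#'
#' @param x A [measurement_table()] or positive numeric matrix with at
#'   least 3 specimens.
#' @param allow_mixed_sex Set `TRUE` to analyse a mixed-sex table (the
#'   analyses are normally run per sex).
#' @return An object of class `shape_pca`: the `shape_decomposition` fields
#'   plus `loadings` (p x (p-1), columns unit-norm, zero-sum, sign-fixed),
#'   `scores` (n x (p-1), centred), `variance` (eigenvalues),
#'   `var_fraction`, and `degenerate` (`TRUE` when total shape variance is
#'   numerically zero, e.g. pure isometry).
#' @export
shape_pca <- function(x, allow_mixed_sex = FALSE) {
  if (inherits(x, "measurement_table")) check_single_sex(x, allow_mixed_sex)
  dec <- log_shape_transform(x)
  Z <- dec$log_shape
  n <- nrow(Z); p <- ncol(Z)
  if (n < 3L) stop("shape PCA needs at least 3 specimens")
  S <- stats::cov(Z)
  ee <- eigen(S, symmetric = TRUE)
  k <- p - 1L
  lam <- pmax(ee$values[seq_len(k)], 0)
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  V <- apply(V, 2L, project_to_shape_space)
  V <- apply(V, 2L, fix_loading_sign)
  dim(V) <- c(p, k)
  rownames(V) <- dec$characters
  colnames(V) <- paste0("PC", seq_len(k))
  scores <- sweep(Z, 2L, colMeans(Z)) %*% V
  rownames(scores) <- rownames(Z)
  tot <- sum(lam)
  degenerate <- tot <= max(1e-12, 1e-12 * p)
  vf <- if (degenerate) rep(NA_real_, k) else lam / tot
  out <- dec
  out$loadings <- V
  out$scores <- scores
  out$variance <- lam
  out$var_fraction <- vf
  out$degenerate <- degenerate
  class(out) <- c("shape_pca", "shape_decomposition")
  out
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(4L, length(x$variance))
  cat(sprintf("<shape_pca> %d specimens, %d characters\n",
              nrow(x$log_shape), ncol(x$log_shape)))
  if (x$degenerate) {
    cat("  total shape variance is zero (pure isometry)\n")
  } else {
    cat("  variance explained:",
        paste0(colnames(x$loadings)[seq_len(k)], " ",
               sprintf("%.1f%%", 100 * x$var_fraction[seq_len(k)]),
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scree table of a shape PCA
#'
#' @param decomp A `shape_pca` object.
#' @return A data frame with columns `component`, `variance`,
#'   `var_fraction`, `cumulative`, ordered by decreasing variance.
#' @export
scree <- function(decomp) {
  stopifnot(inherits(decomp, "shape_pca"))
  k <- length(decomp$variance)
  data.frame(
    component = colnames(decomp$loadings),
    variance = decomp$variance,
    var_fraction = decomp$var_fraction,
    cumulative = if (decomp$degenerate) rep(NA_real_, k)
                 else cumsum(decomp$var_fraction),
    row.names = NULL)
}

#' Correlation of size with a shape PC
#'
#' The Pearson correlation of isosize with the scores of one shape PC; a
#' large magnitude indicates allometry (shape changing with size).
#'
#' @param decomp A `shape_pca` object.
#' @param pc_index Which shape PC (1-based, at most p - 1).
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) if either
#'   variable has zero variance.
#' @export
size_shape_correlation <- function(decomp, pc_index = 1L) {
  stopifnot(inherits(decomp, "shape_pca"))
  k <- ncol(decomp$scores)
  if (pc_index < 1L || pc_index > k)
    stop("pc_index must be in 1..", k)
  s <- decomp$isosize
  y <- decomp$scores[, pc_index]
  if (stats::sd(s) == 0 || stats::sd(y) == 0) {
    warning("zero variance in isosize or PC scores; correlation undefined")
    return(NA_real_)
  }
  stats::cor(s, y)
}

# Shared bootstrap driver: resamples specimens with replacement (redrawing
# when fewer than 3 distinct specimens appear), applies `fun` to the value
# matrix of each replicate, and returns per-character 68% percentile bounds.
# The point estimate is pooled with the replicates so the interval always
# contains it.
boot_spectrum_ci <- function(vals, fun, point, n_boot, seed) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(vals)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = ncol(vals))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 3L) break
    }
    reps[b, ] <- fun(vals[idx, , drop = FALSE])
  }
  pool <- rbind(reps, point)
  list(low = apply(pool, 2L, stats::quantile, probs = 0.16, names = FALSE),
       high = apply(pool, 2L, stats::quantile, probs = 0.84, names = FALSE))
}

new_ratio_spectrum <- function(characters, position, low, high, kind, n_boot) {
  ord <- order(position, characters, decreasing = TRUE)
  df <- data.frame(character = characters[ord], position = position[ord],
                   ci_low = low[ord], ci_high = high[ord], row.names = NULL,
                   stringsAsFactors = FALSE)
  structure(df, kind = kind, n_boot = n_boot,
            class = c("ratio_spectrum", "data.frame"))
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat(sprintf("<ratio_spectrum> kind = %s, %d bootstrap replicates\n",
              attr(x, "kind"), attr(x, "n_boot")))
  print.data.frame(x, digits = 4)
  bp <- spectrum_best_pair(x)
  cat(sprintf("implied ratio: %s : %s\n", bp[1L], bp[2L]))
  invisible(x)
}

#' Character pair at the extremes of a ratio spectrum
#'
#' The ratio of the two characters at opposite ends of the spectrum axis is
#' the one best tracking the PC (PCA spectrum) or the most allometric one
#' (allometry spectrum).  Ties are broken by character name.
#'
#' @param spectrum A `ratio_spectrum`.
#' @return Character vector `c(top, bottom)`.
#' @export
spectrum_best_pair <- function(spectrum) {
  stopifnot(inherits(spectrum, "ratio_spectrum"))
  pos <- spectrum$position
  nm <- spectrum$character
  top <- nm[order(-pos, nm)][1L]
  bottom <- nm[order(pos, nm)][1L]
  c(top, bottom)
}

#' PCA ratio spectrum
#'
#' Displays the loading coefficients of one shape PC on a single axis with
#' 68% bootstrap percentile intervals.  Only ratios between characters at
#' opposite ends of the spectrum are relevant for that PC.  Bootstrap
#' replicates resample specimens with replacement, recompute the shape PCA
#' and are sign-aligned to the point estimate by dot product.
#'
#' @param x A [measurement_table()] (single sex) or matrix.
#' @param pc_index Which shape PC.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed (mandatory for reproducible output).
#' @param allow_mixed_sex Override the per-sex guard.
#' @return A `ratio_spectrum` data frame (`character`, `position`,
#'   `ci_low`, `ci_high`), rows sorted by decreasing position.
#' @export
pca_ratio_spectrum <- function(x, pc_index = 1L, n_boot = 1000L, seed = NULL,
                               allow_mixed_sex = FALSE) {
  if (inherits(x, "measurement_table")) check_single_sex(x, allow_mixed_sex)
  vals <- if (inherits(x, "measurement_table")) x$values else as.matrix(x)
  pca <- shape_pca(vals)
  if (pc_index < 1L || pc_index > ncol(pca$loadings))
    stop("pc_index must be in 1..", ncol(pca$loadings))
  point <- pca$loadings[, pc_index]
  one_rep <- function(v) {
    g <- shape_pca(v)$loadings[, pc_index]
    if (sum(g * point) < 0) g <- -g
    g
  }
  ci <- boot_spectrum_ci(vals, one_rep, point, n_boot, seed)
  new_ratio_spectrum(colnames(vals), point, ci$low, ci$high, "pca", n_boot)
}

# Per-character OLS slope of log(measurement) on isosize; slope 1 = isometry.
allometry_slopes <- function(vals) {
  s <- isosize(vals)
  vs <- stats::var(s)
  if (vs == 0) stop("isosize has zero variance; allometric slopes undefined")
  sc <- s - mean(s)
  L <- log(vals)
  drop(crossprod(sc, sweep(L, 2L, colMeans(L))) / ((length(s) - 1) * vs))
}

#' Allometry ratio spectrum
#'
#' Per-character slopes of log(measurement) regressed on isosize, displayed
#' on one axis with 68% bootstrap percentile intervals.  Under perfect
#' isometry every slope is 1; the ratio of the two characters with the most
#' extreme slope difference is the most allometric one.
#'
#' @inheritParams pca_ratio_spectrum
#' @return A `ratio_spectrum` with `kind = "allometry"`.
#' @export
allometry_ratio_spectrum <- function(x, n_boot = 1000L, seed = NULL,
                                     allow_mixed_sex = FALSE) {
  if (inherits(x, "measurement_table")) check_single_sex(x, allow_mixed_sex)
  vals <- if (inherits(x, "measurement_table")) x$values else as.matrix(x)
  point <- allometry_slopes(vals)
  ci <- boot_spectrum_ci(vals, allometry_slopes, point, n_boot, seed)
  new_ratio_spectrum(colnames(vals), point, ci$low, ci$high,
                     "allometry", n_boot)
}
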