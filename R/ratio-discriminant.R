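#' Pooled within-group covariance of log measurements
#'
#' Classical two-group pooled covariance
#' `W = ((n1 - 1) S1 + (n2 - 1) S2) / (n1 + n2 - 2)`.
#'
#' @param log_data Numeric matrix of logged measurements (specimens x p).
#' @param groups Vector of group labels with exactly two levels.
#' @return Symmetric p x p matrix.
#' @export
pooled_within_covariance <- function(log_data, groups) {
  log_data <- as.matrix(log_data)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("exactly two groups required, found ", length(lev))
  n1 <- sum(groups == lev[1L]); n2 <- sum(groups == lev[2L])
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 specimens (sizes ", n1, ", ", n2, ")")
  S1 <- stats::cov(log_data[groups == lev[1L], , drop = FALSE])
  S2 <- stats::cov(log_data[groups == lev[2L], , drop = FALSE])
  ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
}

# Group mean difference (lev[1] minus lev[2]) of log data.
group_mean_diff <- function(log_data, groups, lev) {
  m1 <- colMeans(log_data[groups == lev[1L], , drop = FALSE])
  m2 <- colMeans(log_data[groups == lev[2L], , drop = FALSE])
  m1 - m2
}

#' Standard distance along a direction
#'
#' The absolute group-mean separation along direction `r` divided by the
#' pooled within-group standard deviation along `r`:
#' `D(r) = |r' (mu1 - mu2)| / sqrt(r' W r)`.  Invariant to rescaling of
#' `r` and to a global rescaling of the measurement units.
#'
#' @param direction Nonzero numeric p-vector (in log space); e.g.
#'   `e_j - e_k` for the log ratio of characters j and k.
#' @param log_data Logged measurement matrix.
#' @param groups Two-level group vector.
#' @return Nonnegative scalar; `Inf` (with a warning) when the within-group
#'   variance along `r` is zero but the means differ.
#' @export
standard_distance <- function(direction, log_data, groups) {
  direction <- as.numeric(direction)
  if (all(direction == 0)) stop("direction must be nonzero")
  log_data <- as.matrix(log_data)
  groups <- as.character(groups)
  lev <- unique(groups)
  W <- pooled_within_covariance(log_data, groups)
  dm <- group_mean_diff(log_data, groups, lev)
  num <- abs(sum(direction * dm))
  den2 <- drop(crossprod(direction, W %*% direction))
  scale2 <- sum(direction^2) * max(diag(W), 1e-300)
  if (den2 <= 1e-14 * scale2) {
    if (num > 1e-10 * sqrt(sum(direction^2))) {
      warning("zero within-group variance along direction with nonzero ",
              "mean difference: infinite separation")
      return(Inf)
    }
    return(0)
  }
  num / sqrt(den2)
}

# Moore-Penrose pseudoinverse via symmetric eigendecomposition.
sym_pinv <- function(M, tol = 1e-10) {
  ee <- eigen(M, symmetric = TRUE)
  pos <- ee$values > tol * max(ee$values, 0)
  if (!any(pos)) return(matrix(0, nrow(M), ncol(M)))
  V <- ee$vectors[, pos, drop = FALSE]
  V %*% (t(V) / ee$values[pos])
}

#' Size-versus-shape discrimination measure delta
#'
#' `delta = D(u) / D(d_shape)` where `u = (1,...,1)/sqrt(p)` is the
#' isometric (size) axis and `d_shape` is the linear discriminant direction
#' restricted to shape space: `W_shape^+ (mu1 - mu2)_shape`, with the
#' isometric component projected out and a pseudo-inverse used because the
#' shape-space covariance has rank at most p - 1.  Values near zero mean
#' the groups are separated by shape rather than size; delta is exactly 0
#' when the group mean isosizes are equal, and is unchanged when group
#' labels are swapped.
#'
#' @inheritParams standard_distance
#' @return Nonnegative scalar, or `NA` (with a warning) when the shape
#'   discriminant separation is zero (pure size separation).
#' @export
delta_statistic <- function(log_data, groups) {
  log_data <- as.matrix(log_data)
  groups <- as.character(groups)
  lev <- unique(groups)
  p <- ncol(log_data)
  u <- rep(1 / sqrt(p), p)
  W <- pooled_within_covariance(log_data, groups)
  dm <- group_mean_diff(log_data, groups, lev)
  # shape-space projection P = I - 11'/p
  P <- diag(p) - matrix(1 / p, p, p)
  dm_shape <- drop(P %*% dm)
  W_shape <- P %*% W %*% P
  d_shape <- drop(sym_pinv(W_shape) %*% dm_shape)
  D_u <- standard_distance(u, log_data, groups)
  if (sqrt(sum(d_shape^2)) <= 1e-14 * max(1, sqrt(sum(dm^2)))) {
    warning("shape discriminant separation is zero; delta undefined ",
            "(pure-size separation)")
    return(NA_real_)
  }
  D_shape <- standard_distance(d_shape, log_data, groups)
  if (!is.finite(D_shape) || D_shape == 0) {
    warning("shape discriminant separation is zero; delta undefined")
    return(NA_real_)
  }
  D_u / D_shape
}

#' Range of a raw character ratio within a group
#'
#' @param table A [measurement_table()].
#' @param group OTU label (or vector of labels to pool).
#' @param pair Character vector `c(numerator, denominator)`.
#' @return Numeric `c(min, max)` of the raw (unlogged) ratio across the
#'   group's specimens.  Rounding happens only at the presentation layer.
#' @export
ratio_range <- function(table, group, pair) {
  stopifnot(inherits(table, "measurement_table"), length(pair) == 2L)
  missing_c <- setdiff(pair, colnames(table$values))
  if (length(missing_c))
    stop("unknown character(s): ", paste(missing_c, collapse = ", "))
  keep <- table$group %in% group
  if (!any(keep)) stop("group not present: ", paste(group, collapse = ", "))
  r <- table$values[keep, pair[1L]] / table$values[keep, pair[2L]]
  c(min(r), max(r))
}

#' Exhaustive best-ratio search (LDA ratio extractor)
#'
#' Finds the single character ratio that best discriminates two groups:
#' evaluates the standard distance along `e_j - e_k` (the log-ratio
#' direction) for all p(p-1)/2 unordered character pairs and returns the
#' maximising pair, with the raw-ratio range in each group, the standard
#' distance, and [delta_statistic()].  Ties are broken by character-name
#' order; the ratio is oriented so the pooled geometric-mean ratio is >= 1.
#'
#' @param table A [measurement_table()] containing exactly the specimens to
#'   compare.
#' @param group_1,group_2 OTU labels.  `group_2 = "rest"` pools every other
#'   group in the table into a single comparison group.
#' @param sex Optional sex to subset to (required unless the table already
#'   holds one sex).
#' @param allow_mixed_sex Override the per-sex guard.
#' @return An object of class `discriminant_report`: a list with
#'   `group_1`, `group_2`, `sex`, `best_pair`, `range_1`, `range_2`,
#'   `standard_distance`, `delta`, `n_1`, `n_2`, `overlap`, `separable`.
#' @export
best_ratio_search <- function(table, group_1, group_2, sex = NULL,
                              allow_mixed_sex = FALSE) {
  stopifnot(inherits(table, "measurement_table"))
  if (!is.null(sex)) table <- subset_table(table, sex = sex)
  check_single_sex(table, allow_mixed_sex)
  rest <- identical(group_2, "rest")
  g2_members <- if (rest) setdiff(unique(table$group), group_1) else group_2
  if (!length(g2_members)) stop("no specimens available for group_2")
  sub <- subset_table(table, groups = c(group_1, g2_members))
  grp <- ifelse(sub$group %in% group_1, "g1", "g2")
  if (sum(grp == "g1") < 2L || sum(grp == "g2") < 2L)
    stop("each comparison group needs at least 2 specimens")
  L <- log(sub$values)
  p <- ncol(L)
  chars <- colnames(L)
  W <- pooled_within_covariance(L, grp)
  dm <- group_mean_diff(L, grp, c("g1", "g2"))
  pooled_mean <- colMeans(L)

  best <- NULL
  best_D <- -Inf
  skipped <- character(0)
  ord <- order(chars)  # visit pairs in character-name order: ties keep the first
  for (jj in seq_len(p - 1L)) {
    for (kk in (jj + 1L):p) {
      j <- ord[jj]; k <- ord[kk]
      den2 <- W[j, j] + W[k, k] - 2 * W[j, k]
      if (den2 <= 1e-14 * max(W[j, j] + W[k, k], 1e-300)) {
        skipped <- c(skipped, paste0(chars[j], ":", chars[k]))
        next
      }
      D <- unname(abs(dm[j] - dm[k])) / sqrt(den2)
      if (D > best_D + 1e-12) {
        best_D <- D
        best <- c(j, k)
      }
    }
  }
  if (length(skipped))
    warning("skipped pair(s) with zero within-group ratio variance: ",
            paste(skipped, collapse = ", "))
  if (is.null(best)) stop("no usable character pair (degenerate covariance)")

  # orientation: numerator so that the pooled geometric-mean ratio >= 1
  pair <- if (pooled_mean[best[1L]] >= pooled_mean[best[2L]])
    chars[best] else chars[rev(best)]
  g2_label <- if (rest) "rest" else paste(group_2, collapse = "+")
  r1 <- ratio_range(sub, group_1, pair)
  r2 <- ratio_range(sub, g2_members, pair)
  overlap <- r1[1L] <= r2[2L] && r2[1L] <= r1[2L]
  structure(list(
    group_1 = paste(group_1, collapse = "+"), group_2 = g2_label,
    sex = paste(sort(unique(sub$sex)), collapse = "+"),
    best_pair = pair, range_1 = r1, range_2 = r2,
    standard_distance = best_D,
    delta = delta_statistic(L, grp),
    n_1 = sum(grp == "g1"), n_2 = sum(grp == "g2"),
    overlap = overlap,
    separable = best_D > 1e-8), class = "discriminant_report")
}

#' @export
print.discriminant_report <- function(x, ...) {
  cat(sprintf("<discriminant_report> %s vs %s (%s)\n",
              x$group_1, x$group_2, x$sex))
  if (!x$separable) cat("  groups are not separable (D = 0 for all ratios)\n")
  cat(sprintf("  best ratio %s : %s\n", x$best_pair[1L], x$best_pair[2L]))
  cat(sprintf("  range %s: %.4g-%.4g (n = %d)\n", x$group_1,
              x$range_1[1L], x$range_1[2L], x$n_1))
  cat(sprintf("  range %s: %.4g-%.4g (n = %d)\n", x$group_2,
              x$range_2[1L], x$range_2[2L], x$n_2))
  cat(sprintf("  standard distance %.3f, delta %.3f, overlap: %s\n",
              x$standard_distance, x$delta,
              if (x$overlap) "yes" else "no"))
  invisible(x)
}

#' @export
as.data.frame.discriminant_report <- function(x, ...) {
  data.frame(
    comparison = paste0(x$group_1, "-", x$group_2), sex = x$sex,
    best_ratio = paste0(x$best_pair[1L], ":", x$best_pair[2L]),
    range1_min = x$range_1[1L], range1_max = x$range_1[2L],
    range2_min = x$range_2[1L], range2_max = x$range_2[2L],
    standard_distance = x$standard_distance, delta = x$delta,
    n_1 = x$n_1, n_2 = x$n_2,
    overlap_flag = x$overlap, stringsAsFactors = FALSE)
}

#' Run a suite of two-group ratio extractions
#'
#' One [best_ratio_search()] per requested comparison, assembled into a
#' single report table.  A `group2` of `"rest"` pools all other OTUs of the
#' same sex present in the table.  The `overlap_flag` column marks
#' comparisons whose raw-ratio ranges intersect; non-overlapping ratios are
#' the ones eligible for identification keys.
#'
#' @param table A [measurement_table()].
#' @param comparisons Data frame with columns `sex`, `group1`, `group2`.
#' @return A data frame, one row per comparison, columns `comparison`,
#'   `sex`, `best_ratio`, `range1_min`, `range1_max`, `range2_min`,
#'   `range2_max`, `standard_distance`, `delta`, `n_1`, `n_2`,
#'   `overlap_flag`.
#' @export
comparison_suite <- function(table, comparisons) {
  stopifnot(inherits(table, "measurement_table"))
  comparisons <- as.data.frame(comparisons)
  need <- c("sex", "group1", "group2")
  if (!all(need %in% names(comparisons)))
    stop("'comparisons' needs columns ", paste(need, collapse = ", "))
  if (!nrow(comparisons)) stop("empty comparison set")
  known <- unique(table$group)
  bad <- setdiff(setdiff(unique(c(comparisons$group1, comparisons$group2)),
                         "rest"), known)
  if (length(bad))
    stop("comparison references unknown OTU label(s): ",
         paste(bad, collapse = ", "))
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    cc <- comparisons[i, ]
    as.data.frame(best_ratio_search(table, cc$group1, cc$group2,
                                    sex = cc$sex))
  })
  do.call(rbind, rows)
}
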