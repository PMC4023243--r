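#' Specification for the morphometric data generator
#'
#' The generator draws, per group, a latent log-size `s ~ N(size_mean,
#' size_sd)` and sets `log x_j = s * slope_j + offset_j + eps_j` with
#' `eps_j ~ N(0, resid_sd_j)`; measurements are `exp()` of that, giving
#' multi-group log-normal data with a common isometric size axis,
#' group-specific shape means, optional allometric slopes and independent
#' residual shape noise.  Shape offsets must sum to zero (they live in
#' shape space), so adding them never changes the expected isosize.
#'
#' @param groups List of group specs, each a list with elements `label`,
#'   `sex`, `n`, `size_mean` (mean latent log-size, natural log of
#'   micrometres), `size_sd`, `shape_offset` (length-p zero-sum vector, or
#'   a single 0), `slope` (length-p allometric slope vector, default all
#'   1 = isometry), `resid_sd` (scalar or length-p residual SD of log
#'   measurements).
#' @param characters Character names (default the 16-character set of
#'   [default_characters()]).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class `morpho_gen_spec`.
#' @export
morpho_gen_spec <- function(groups, characters = default_characters(),
                            seed = 1L) {
  p <- length(characters)
  groups <- lapply(groups, function(g) {
    stopifnot(!is.null(g$label), !is.null(g$n))
    if (g$n < 1L) stop("group size must be >= 1")
    g$sex <- if (is.null(g$sex)) "female" else g$sex
    if (is.null(g$size_sd)) g$size_sd <- 0
    if (is.null(g$shape_offset)) g$shape_offset <- rep(0, p)
    if (length(g$shape_offset) == 1L) g$shape_offset <- rep(g$shape_offset, p)
    if (length(g$shape_offset) != p)
      stop("shape_offset must have one entry per character")
    if (abs(sum(g$shape_offset)) > 1e-8)
      stop("shape_offset must sum to 0 (it lives in shape space); group ",
           g$label, " sums to ", sum(g$shape_offset))
    if (is.null(g$slope)) g$slope <- rep(1, p)
    if (length(g$slope) == 1L) g$slope <- rep(g$slope, p)
    if (is.null(g$resid_sd)) g$resid_sd <- 0.02
    if (length(g$resid_sd) == 1L) g$resid_sd <- rep(g$resid_sd, p)
    if (any(g$resid_sd < 0) || g$size_sd < 0) stop("SDs must be >= 0")
    g
  })
  structure(list(groups = groups, characters = characters,
                 seed = as.integer(seed)), class = "morpho_gen_spec")
}

#' Generate a synthetic measurement table
#'
#' @param spec A [morpho_gen_spec()].
#' @return A [measurement_table()], deterministic for a given spec
#'   (including its seed).
#' @export
gen_morpho <- function(spec) {
  stopifnot(inherits(spec, "morpho_gen_spec"))
  set.seed(spec$seed)
  p <- length(spec$characters)
  out <- lapply(spec$groups, function(g) {
    s <- stats::rnorm(g$n, g$size_mean, g$size_sd)
    eps <- matrix(stats::rnorm(g$n * p, 0, rep(g$resid_sd, each = g$n)),
                  nrow = g$n)
    logx <- outer(s, g$slope) + matrix(g$shape_offset, g$n, p, byrow = TRUE) +
      eps
    list(values = exp(logx), group = rep(g$label, g$n),
         sex = rep(g$sex, g$n))
  })
  vals <- do.call(rbind, lapply(out, `[[`, "values"))
  colnames(vals) <- spec$characters
  grp <- unlist(lapply(out, `[[`, "group"))
  sex <- unlist(lapply(out, `[[`, "sex"))
  ids <- paste0(grp, "_", sex, "_",
                unlist(lapply(out, function(o) seq_along(o$group))))
  measurement_table(vals, grp, sex, ids)
}

#' Load the bundled per-group measurement moments
#'
#' A long-format table of published per-group summary statistics (min, max,
#' mean, SD in micrometres, with sample sizes) for the five-OTU wasp group
#' that motivates the package, used to calibrate the synthetic generator to
#' realistic magnitudes.
#'
#' @return Data frame with columns `otu`, `sex`, `n`, `character`, `min`,
#'   `max`, `mean`, `sd`.
#' @export
measurement_moments <- function() {
  path <- system.file("extdata", "gallicus_group_measurement_moments.tsv",
                      package = "mratax", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Generator spec calibrated to per-group measurement moments
#'
#' Converts per-character means and SDs into the latent size/shape model of
#' [morpho_gen_spec()]: per character the log-scale variance is
#' `v_j = log(1 + (sd_j/mean_j)^2)` and the log-scale mean
#' `l_j = log(mean_j) - v_j/2` (exact log-normal moment matching, so the
#' arithmetic group means of generated data match the targets in
#' expectation).  The common size factor receives a share `size_share` of
#' the median log-variance; the remainder is per-character residual shape
#' noise.
#'
#' @param moments Moments table as from [measurement_moments()] (the
#'   default), optionally pre-filtered.
#' @param sex Which sex to build the spec for.
#' @param n Optional named vector overriding per-group sample sizes
#'   (defaults to the `n` recorded in the moments table).
#' @param size_share Fraction of the shared log-variance assigned to the
#'   latent size factor (default 0.6: size is the dominant shared factor in
#'   these data).
#' @param seed Seed stored in the spec.
#' @return A [morpho_gen_spec()].
#' @export
calibrated_morpho_spec <- function(moments = measurement_moments(),
                                   sex = "female", n = NULL,
                                   size_share = 0.6, seed = 1L) {
  m <- moments[moments$sex == sex, ]
  if (!nrow(m)) stop("no moments for sex ", sex)
  chars <- sort(unique(m$character))
  groups <- lapply(split(m, m$otu), function(g) {
    g <- g[match(chars, g$character), ]
    v <- log(1 + (g$sd / g$mean)^2)
    l <- log(g$mean) - v / 2
    size_sd2 <- size_share * stats::median(v)
    resid <- sqrt(pmax(v - size_sd2, 1e-8))
    ng <- if (!is.null(n)) unname(n[g$otu[1L]]) else g$n[1L]
    list(label = g$otu[1L], sex = sex, n = ng,
         size_mean = mean(l), size_sd = sqrt(size_sd2),
         shape_offset = l - mean(l), slope = rep(1, length(chars)),
         resid_sd = resid)
  })
  morpho_gen_spec(groups, characters = chars, seed = seed)
}

#' Two-group table with a planted discriminating ratio
#'
#' Convenience generator for parameter-recovery studies: two equally sized
#' groups with identical size distributions and a shape offset of
#' `+/- delta/2 * (e_j - e_k)` on a chosen character pair, calibrated so
#' the true standard distance along the planted log-ratio direction is
#' `d_true`: with iid residual SD `sigma` per character the within-group SD
#' of the log ratio is `sigma * sqrt(2)`, so the group mean log-ratio
#' difference is set to `d_true * sigma * sqrt(2)`.  Size distributions are
#' identical, so separation is pure shape and the delta statistic is 0 in
#' expectation.
#'
#' @param pair Character vector `c(j, k)` naming the planted pair.
#' @param d_true Target standard distance along `e_j - e_k`.
#' @param n Specimens per group.
#' @param sigma Residual SD of each log measurement (default 0.03, a
#'   realistic measurement-plus-individual CV of about 3%).
#' @param size_mean,size_sd Latent log-size distribution shared by both
#'   groups (defaults roughly matching wasp head/leg measurements).
#' @param characters Character set.
#' @param seed Seed.
#' @return A [measurement_table()] with groups `"A"` and `"B"`.
#' @export
planted_ratio_table <- function(pair, d_true, n = 30L, sigma = 0.03,
                                size_mean = log(800), size_sd = 0.05,
                                characters = default_characters(),
                                seed = 1L) {
  stopifnot(length(pair) == 2L, all(pair %in% characters))
  p <- length(characters)
  j <- match(pair[1L], characters); k <- match(pair[2L], characters)
  # r = e_j - e_k; Var(r'eps) = 2 sigma^2; want |r'(m1-m2)| = d_true*sqrt(2)*sigma.
  # Offsets are applied as +off to group A and -off to group B, so each group
  # carries a quarter of the total mean log-ratio difference.
  half <- d_true * sigma * sqrt(2) / 4
  off <- rep(0, p); off[j] <- half; off[k] <- -half
  spec <- morpho_gen_spec(list(
    list(label = "A", sex = "female", n = n, size_mean = size_mean,
         size_sd = size_sd, shape_offset = off, resid_sd = sigma),
    list(label = "B", sex = "female", n = n, size_mean = size_mean,
         size_sd = size_sd, shape_offset = -off, resid_sd = sigma)),
    characters = characters, seed = seed)
  gen_morpho(spec)
}

# ---------------------------------------------------------------------------
# sequence generation under GTR

#' GTR rate matrix
#'
#' Builds the general time-reversible generator `Q` from six
#' exchangeabilities (order AC, AG, AT, CG, CT, GT) and base frequencies,
#' normalised so the expected substitution rate is 1 (branch lengths are
#' then in substitutions/site).
#'
#' @param rates Positive 6-vector of exchangeabilities.
#' @param freqs Base frequencies in A,C,G,T order, summing to 1.
#' @return 4 x 4 rate matrix with zero row sums.
#' @export
gtr_rate_matrix <- function(rates = rep(1, 6), freqs = rep(0.25, 4)) {
  if (length(rates) != 6L || any(rates <= 0))
    stop("6 positive exchangeabilities required")
  if (length(freqs) != 4L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("4 positive base frequencies summing to 1 required")
  R <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  # exchangeabilities in the conventional AC, AG, AT, CG, CT, GT order
  R[1, 2] <- rates[1]; R[1, 3] <- rates[2]; R[1, 4] <- rates[3]
  R[2, 3] <- rates[4]; R[2, 4] <- rates[5]; R[3, 4] <- rates[6]
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  Q <- R * matrix(freqs, 4, 4, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Transition probability matrix exp(Q t) via the reversible symmetrisation.
gtr_transition_matrix <- function(Q, t, freqs) {
  sq <- sqrt(freqs)
  B <- Q * tcrossprod(sq, 1 / sq)
  B <- (B + t(B)) / 2
  ee <- eigen(B, symmetric = TRUE)
  P <- tcrossprod(1 / sq, sq) *
    (ee$vectors %*% (exp(ee$values * t) * t(ee$vectors)))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Evolve one sequence (integer-coded 1..4) along a branch of length t.
evolve_seq <- function(x, P) {
  y <- integer(length(x))
  for (b in 1:4) {
    ii <- which(x == b)
    if (length(ii)) y[ii] <- sample.int(4L, length(ii), replace = TRUE,
                                        prob = P[b, ])
  }
  y
}

#' Specification for the sequence-set generator
#'
#' Sequences are generated on a star-of-stars: a root sequence is drawn
#' from the base frequencies, each OTU ancestor evolves from the root along
#' a branch of length `(between - within)/2`, and each taxon evolves from
#' its OTU ancestor along `within/2`.  GTR distances are additive in
#' expectation, so the expected pairwise distance is `within` inside an OTU
#' and `between` across OTUs.  Indel events are inserted post hoc as shared
#' gap runs and do not affect distances (pairwise deletion).
#'
#' @param otus Data frame with columns `label` and `n` (taxa per OTU).
#' @param length Alignment length (columns) before gaps.
#' @param between Target between-OTU distance (substitutions/site).
#' @param within Target within-OTU distance; must not exceed `between`.
#' @param rates,freqs GTR exchangeabilities and base frequencies (defaults:
#'   equal rates, uniform frequencies).
#' @param indels Optional list of events `list(start =, end =, taxa =)`
#'   (taxa as indices or ids) carving shared gap runs.
#' @param seed Integer seed.
#' @return Object of class `seq_gen_spec`.
#' @export
seq_gen_spec <- function(otus, length = 600L, between = 0.026,
                         within = 0, rates = rep(1, 6),
                         freqs = rep(0.25, 4), indels = list(), seed = 1L) {
  otus <- as.data.frame(otus)
  stopifnot(all(c("label", "n") %in% names(otus)), all(otus$n >= 1))
  if (between < 0 || within < 0) stop("distances must be >= 0")
  if (within > between) stop("'within' must not exceed 'between'")
  gtr_rate_matrix(rates, freqs)  # validates
  structure(list(otus = otus, length = as.integer(length), between = between,
                 within = within, rates = rates, freqs = freqs,
                 indels = indels, seed = as.integer(seed)),
            class = "seq_gen_spec")
}

#' Generate a synthetic aligned sequence set
#'
#' @param spec A [seq_gen_spec()].
#' @return An [aligned_seq_set()], deterministic per seed.
#' @export
gen_alignment <- function(spec) {
  stopifnot(inherits(spec, "seq_gen_spec"))
  set.seed(spec$seed)
  Q <- gtr_rate_matrix(spec$rates, spec$freqs)
  t_b <- max(spec$between - spec$within, 0) / 2
  t_w <- spec$within / 2
  root <- sample.int(4L, spec$length, replace = TRUE, prob = spec$freqs)
  P_b <- gtr_transition_matrix(Q, t_b, spec$freqs)
  P_w <- gtr_transition_matrix(Q, t_w, spec$freqs)
  seqs <- list(); ids <- character(0); otu <- character(0)
  for (g in seq_len(nrow(spec$otus))) {
    anc <- if (t_b > 0) evolve_seq(root, P_b) else root
    for (i in seq_len(spec$otus$n[g])) {
      taxon <- if (t_w > 0) evolve_seq(anc, P_w) else anc
      seqs[[length(seqs) + 1L]] <- taxon
      ids <- c(ids, paste0(spec$otus$label[g], "_", i))
      otu <- c(otu, spec$otus$label[g])
    }
  }
  mat <- do.call(rbind, lapply(seqs, function(s) BASES[s]))
  rownames(mat) <- ids
  for (ev in spec$indels) {
    taxa <- ev$taxa
    if (is.character(taxa)) taxa <- match(taxa, ids)
    if (anyNA(taxa) || any(taxa < 1L) || any(taxa > nrow(mat)))
      stop("indel event references unknown taxa")
    if (ev$start < 1L || ev$end > ncol(mat) || ev$start > ev$end)
      stop("indel event span outside the alignment")
    mat[taxa, ev$start:ev$end] <- "-"
  }
  aligned_seq_set(mat, otu = otu, id = ids)
}
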