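test_that("isosize matches the geometric mean and a brute-force oracle", {
  expect_equal(isosize(c(100, 100, 100), geometric = TRUE), 100)
  expect_equal(isosize(c(100, 400), geometric = TRUE), 200)
  set.seed(42)
  x <- runif(16, 100, 3500)
  # independent accumulation, term by term
  acc <- 0
  for (xi in x) acc <- acc + log(xi)
  expect_equal(isosize(x, geometric = TRUE), exp(acc / 16),
               tolerance = 1e-12)
  expect_equal(isosize(x), acc / 16, tolerance = 1e-12)
})

test_that("isosize rejects bad entries naming the offending character", {
  expect_error(isosize(c(a = 100, b = -5)), "'b'")
  m <- matrix(c(100, 200, NA, 300), 2, dimnames = list(NULL, c("u", "v")))
  expect_error(isosize(m), "'v'")
})

test_that("log-shape transform decomposes log data exactly", {
  tab <- rand_table(n = 7, p = 5, seed = 3)
  dec <- log_shape_transform(tab)
  expect_lt(max(abs(rowSums(dec$log_shape))), 1e-10)
  recon <- dec$isosize + dec$log_shape
  expect_equal(recon, log(tab$values), tolerance = 1e-12)
  # direct recomputation on a 3-specimen toy
  toy <- matrix(c(100, 200, 50, 400, 800, 100), 3, 2,
                dimnames = list(NULL, c("a", "b")))
  d2 <- log_shape_transform(toy)
  expect_equal(d2$log_shape, log(toy) - rowMeans(log(toy)),
               tolerance = 1e-14)
  # all characters equal -> zero shape row
  expect_equal(unname(log_shape_transform(rbind(c(x = 7, y = 7, z = 7),
                                                c(x = 2, y = 2, z = 2)))$log_shape),
               matrix(0, 2, 3))
  expect_error(log_shape_transform(matrix(1, 3, 1)), "2 characters")
})

test_that("scale equivariance: times c shifts isosize by log c only", {
  tab <- rand_table(n = 6, p = 4, seed = 9)
  scaled <- tab$values * 3.7
  d1 <- log_shape_transform(tab$values)
  d2 <- log_shape_transform(scaled)
  expect_equal(d2$log_shape, d1$log_shape, tolerance = 1e-12)
  expect_equal(d2$isosize, d1$isosize + log(3.7), tolerance = 1e-12)
  p1 <- shape_pca(tab$values)
  p2 <- shape_pca(scaled)
  expect_equal(p2$loadings, p1$loadings, tolerance = 1e-9)
  expect_equal(p2$scores, p1$scores, tolerance = 1e-9)
  expect_equal(p2$variance, p1$variance, tolerance = 1e-12)
})

test_that("shape PCA equals brute-force eigenanalysis of projected covariance", {
  for (seed in 1:5) {
    p <- sample(3:4, 1)
    n <- sample(4:8, 1)
    tab <- rand_table(n = n, p = p, seed = 100 + seed)
    pca <- shape_pca(tab)
    # oracle: eigenvalues of P Cov(log X) P with P = I - 11'/p
    P <- diag(p) - matrix(1 / p, p, p)
    S <- P %*% cov(log(tab$values)) %*% P
    ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(pca$variance, ev[seq_len(p - 1)], tolerance = 1e-10)
    # structural invariants
    expect_lt(max(abs(colSums(pca$loadings))), 1e-10)
    expect_equal(crossprod(pca$loadings), diag(p - 1), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_lt(max(abs(colMeans(pca$scores))), 1e-10)
    expect_equal(sum(pca$var_fraction), 1, tolerance = 1e-10)
    # sign convention: largest-magnitude coefficient positive
    expect_true(all(apply(pca$loadings, 2,
                          function(v) v[which.max(abs(v))] > 0)))
  }
})

test_that("pure isometry gives zero shape variance, flagged not errored", {
  base <- c(a = 100, b = 250, c = 400)
  vals <- outer(c(1, 1.5, 2, 3), base)
  colnames(vals) <- names(base)
  pca <- shape_pca(vals)
  expect_true(pca$degenerate)
  expect_lt(sum(pca$variance), 1e-20)
  expect_true(all(is.na(pca$var_fraction)))
  expect_error(shape_pca(vals[1:2, ]), "at least 3")
})

test_that("a planted shape contrast is recovered by PC1", {
  tab <- shape_pair_table(n = 25, p = 6, delta = 0.3, sigma = 0.02,
                          seed = 5)
  pca <- shape_pca(tab)
  target <- c(1, -1, rep(0, 4)) / sqrt(2)
  alignment <- abs(sum(pca$loadings[, 1] * target))
  expect_gt(alignment, 0.97)  # within ~14 degrees
  s1 <- pca$scores[tab$group == "A", 1]
  s2 <- pca$scores[tab$group == "B", 1]
  expect_true(min(s1) > max(s2) || min(s2) > max(s1))
})

test_that("scree table is normalised and finds planted factors", {
  tab <- rand_table(n = 10, p = 5, seed = 2)
  sc <- scree(shape_pca(tab))
  expect_true(all(diff(sc$variance) <= 1e-12))
  expect_equal(sc$cumulative[nrow(sc)], 1, tolerance = 1e-10)
  # two planted shape factors above an iid noise floor
  chars <- paste0("c", 1:6)
  o1 <- c(0.2, -0.2, 0, 0, 0, 0); o2 <- c(0, 0, 0.15, -0.15, 0, 0)
  spec <- morpho_gen_spec(list(
    list(label = "A", n = 40, size_mean = log(500), size_sd = 0.03,
         shape_offset = o1, resid_sd = 0.01),
    list(label = "B", n = 40, size_mean = log(500), size_sd = 0.03,
         shape_offset = o2, resid_sd = 0.01),
    list(label = "C", n = 40, size_mean = log(500), size_sd = 0.03,
         shape_offset = -o1 - o2, resid_sd = 0.01)),
    characters = chars, seed = 8)
  sc2 <- scree(shape_pca(gen_morpho(spec)))
  noise_floor <- 5 * 0.01^2  # well above the iid residual variance scale
  expect_equal(sum(sc2$variance > noise_floor), 2)
})

test_that("size-shape correlation detects planted allometry", {
  chars <- paste0("c", 1:5)
  # isometric: size varies, shape is pure noise -> |cor| small
  iso_spec <- morpho_gen_spec(list(
    list(label = "A", n = 150, size_mean = log(500), size_sd = 0.15,
         resid_sd = 0.02)), characters = chars, seed = 3)
  pca_iso <- shape_pca(gen_morpho(iso_spec))
  expect_lt(abs(size_shape_correlation(pca_iso, 1)), 0.3)
  # planted allometric slope on one character
  slopes <- c(1.4, 1, 1, 1, 1)
  allo_spec <- morpho_gen_spec(list(
    list(label = "A", n = 150, size_mean = log(500), size_sd = 0.15,
         slope = slopes, resid_sd = 0.01)), characters = chars, seed = 4)
  pca_allo <- shape_pca(gen_morpho(allo_spec))
  expect_gt(abs(size_shape_correlation(pca_allo, 1)), 0.8)
  expect_error(size_shape_correlation(pca_allo, 10), "pc_index")
})

test_that("ratio spectra are deterministic given a seed and contain the point estimate", {
  tab <- shape_pair_table(n = 15, seed = 6)
  s1 <- pca_ratio_spectrum(tab, 1, n_boot = 50, seed = 99)
  s2 <- pca_ratio_spectrum(tab, 1, n_boot = 50, seed = 99)
  expect_identical(s1, s2)
  expect_true(all(s1$ci_low <= s1$position + 1e-12))
  expect_true(all(s1$ci_high >= s1$position - 1e-12))
  expect_true(all(diff(s1$position) <= 1e-12))  # sorted by position
  a1 <- allometry_ratio_spectrum(tab, n_boot = 50, seed = 7)
  a2 <- allometry_ratio_spectrum(tab, n_boot = 50, seed = 7)
  expect_identical(a1, a2)
})

test_that("PCA ratio spectrum puts the planted pair at the extremes", {
  hits <- vapply(1:20, function(seed) {
    tab <- planted_ratio_table(c("tib3.l", "msp.l"), d_true = 6, n = 30,
                               seed = seed)
    bp <- spectrum_best_pair(pca_ratio_spectrum(tab, 1, n_boot = 20,
                                                seed = seed))
    setequal(bp, c("tib3.l", "msp.l"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("allometry spectrum: isometry gives slope 1, planted slope recovered", {
  chars <- paste0("c", 1:5)
  iso <- gen_morpho(morpho_gen_spec(list(
    list(label = "A", n = 200, size_mean = log(500), size_sd = 0.2,
         resid_sd = 0.005)), characters = chars, seed = 12))
  sp <- allometry_ratio_spectrum(iso, n_boot = 30, seed = 1)
  expect_true(all(abs(sp$position - 1) < 0.05))
  b <- 1.35
  allo <- gen_morpho(morpho_gen_spec(list(
    list(label = "A", n = 200, size_mean = log(500), size_sd = 0.2,
         slope = c(b, 1, 1, 1, 1), resid_sd = 0.005)),
    characters = chars, seed = 13))
  sp2 <- allometry_ratio_spectrum(allo, n_boot = 100, seed = 2)
  expect_identical(sp2$character[1], "c1")  # extreme of the spectrum
  row <- sp2[sp2$character == "c1", ]
  # isosize itself contains the allometric character, so the observable
  # slope is the planted slope over the mean slope: b / mean(c(b, 1, 1, 1, 1))
  # (68% intervals miss ~1/3 of the time by design, so test the point
  # estimate against ~5 standard errors instead: SE ~ 0.005/(0.2*sqrt(199)))
  b_obs <- b / mean(c(b, 1, 1, 1, 1))
  expect_lt(abs(row$position - b_obs), 0.01)
  expect_lt(row$ci_high - row$ci_low, 0.02)
  # degenerate input: no size variation
  flat <- gen_morpho(morpho_gen_spec(list(
    list(label = "A", n = 10, size_mean = log(500), size_sd = 0,
         resid_sd = 0)), characters = chars, seed = 1))
  expect_error(allometry_ratio_spectrum(flat, n_boot = 5, seed = 1),
               "zero variance")
})
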