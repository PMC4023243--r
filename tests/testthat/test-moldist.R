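test_that("alignment construction validates and normalises", {
  expect_error(aln_from_strings(a = "ACGT", b = "ACG"), "ragged")
  expect_error(aligned_seq_set(c("ACGT", "ACGT")), "named")
  expect_error(aln_from_strings(a = "ACGT", a = "ACGT"), "duplicate")
  expect_error(aln_from_strings(a = "ACGT", b = "NN--"), "unambiguous")
  a <- aln_from_strings(a = "acgu", b = "ACGT")
  expect_identical(unname(a$seq[1, ]), c("A", "C", "G", "T"))
})

test_that("FASTA io round-trips and normalises case and U", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 otuA", "acgtu-acgt", ">s2 otuB", "ACGTTNACGT"), f)
  aln <- read_alignment(f)
  expect_equal(aln$length, 10)
  expect_identical(aln$otu, c("otuA", "otuB"))
  expect_identical(paste(aln$seq[1, ], collapse = ""), "ACGTT-ACGT")
  # ragged file rejected with a line reference
  writeLines(c(">s1", "ACGT", ">s2", "ACG"), f)
  expect_error(read_alignment(f), "ragged")
  # generator output round-trips bit-identically
  spec <- seq_gen_spec(data.frame(label = c("A", "B"), n = c(2, 3)),
                       length = 120, between = 0.05, within = 0.01,
                       seed = 42)
  aln2 <- gen_alignment(spec)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln2, f2)
  back <- read_alignment(f2)
  expect_identical(back$seq, aln2$seq)
  expect_identical(back$otu, aln2$otu)
})

test_that("OTU maps attach labels from TSV files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACGA"), f)
  mapf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tX", "s2\tY"), mapf)
  expect_identical(read_alignment(f, otu_map = mapf)$otu, c("X", "Y"))
  writeLines("s1\tX", mapf)
  expect_error(read_alignment(f, otu_map = mapf), "s2")
})

test_that("p-distance matches a hand count with pairwise deletion", {
  a <- strsplit("ACGTACGTAC", "")[[1]]
  b <- strsplit("ACGAACGTTC", "")[[1]]  # 2 differences over 10
  expect_equal(as.numeric(p_distance(a, b)), 0.2)
  c_ <- strsplit("AC-TACNTAC", "")[[1]]  # gap + N: 8 usable, 0 diffs vs a
  expect_equal(as.numeric(p_distance(a, c_)), 0)
  expect_equal(attr(p_distance(a, c_), "sites"), 8)
})

test_that("GTR distance is 0 for identical sequences and symmetric", {
  set.seed(9)
  a <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  expect_equal(as.numeric(gtr_distance(a, a)), 0, tolerance = 1e-12)
  b <- a; b[1:25] <- "A"
  expect_equal(as.numeric(gtr_distance(a, b)),
               as.numeric(gtr_distance(b, a)), tolerance = 1e-12)
  # invariance under a consistent column permutation
  perm <- sample(length(a))
  expect_equal(as.numeric(gtr_distance(a[perm], b[perm])),
               as.numeric(gtr_distance(a, b)), tolerance = 1e-12)
})

test_that("GTR reduces to the Jukes-Cantor closed form in the uniform limit", {
  # construct an exactly uniform divergence pattern: every ordered base
  # pair (i,j), i != j, occurs once; every identical pair 22 times
  bases <- c("A", "C", "G", "T")
  a <- character(0); b <- character(0)
  for (i in bases) for (j in bases) {
    k <- if (i == j) 22 else 1
    a <- c(a, rep(i, k)); b <- c(b, rep(j, k))
  }
  p <- 12 / 100
  expect_equal(as.numeric(gtr_distance(a, b)),
               -3 / 4 * log(1 - 4 * p / 3), tolerance = 1e-9)
})

test_that("GTR corrects multiple hits: >= p-distance, converging as p -> 0", {
  set.seed(10)
  a <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  for (ndiff in c(10, 100, 400)) {
    b <- a
    idx <- sample(2000, ndiff)
    b[idx] <- vapply(a[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    d_gtr <- as.numeric(gtr_distance(a, b))
    d_p <- as.numeric(p_distance(a, b))
    expect_gte(d_gtr, d_p - 1e-12)
    if (d_p <= 0.01) expect_lt(abs(d_gtr - d_p) / d_p, 0.05)
  }
})

test_that("saturated pairs are flagged unavailable, not mis-estimated", {
  a <- rep(c("A", "C"), 100)
  b <- rep(c("G", "T"), 100)  # transversion at every site
  expect_warning(d <- gtr_distance(a, b), "saturation")
  expect_true(is.na(d))
})

test_that("GTR simulation recovery at the study's headline divergence", {
  spec <- seq_gen_spec(data.frame(label = c("A", "B"), n = 1),
                       length = 10000, between = 0.05, within = 0,
                       seed = 77)
  aln <- gen_alignment(spec)
  d <- as.numeric(gtr_distance(aln$seq[1, ], aln$seq[2, ]))
  se <- sqrt(0.05 / 10000)  # rough Poisson scale
  expect_lt(abs(d - 0.05), 3.5 * se)
})

test_that("distance matrices are symmetric with zero diagonal", {
  spec <- seq_gen_spec(data.frame(label = c("A", "B"), n = c(3, 2)),
                       length = 800, between = 0.04, within = 0.005,
                       seed = 3)
  aln <- gen_alignment(spec)
  for (model in c("gtr", "p")) {
    dm <- distance_matrix(aln, model)
    expect_equal(dm$d, t(dm$d), tolerance = 1e-12)
    expect_equal(unname(diag(dm$d)), rep(0, 5))
    expect_true(all(dm$d >= 0))
    expect_true(all(dm$sites_used <= aln$length, na.rm = TRUE))
  }
  # n identical sequences -> zero matrix
  ident <- aligned_seq_set(matrix("A", 3, 10,
                                  dimnames = list(paste0("s", 1:3), NULL)),
                           otu = rep("X", 3))
  ident$seq[, 1:5] <- "C"
  expect_true(all(distance_matrix(ident, "p")$d == 0))
})

test_that("barcoding gap summary flags gaps and handles singletons", {
  # two OTUs, identical within, one substitution in 100 between
  m <- rbind(a1 = strsplit(strrep("ACGT", 25), "")[[1]],
             a2 = strsplit(strrep("ACGT", 25), "")[[1]],
             b1 = strsplit(strrep("ACGT", 25), "")[[1]])
  m["b1", 2] <- "G"
  aln <- aligned_seq_set(m, otu = c("A", "A", "B"))
  gs <- barcoding_gap_summary(distance_matrix(aln, "p"))
  a_row <- gs$per_otu[gs$per_otu$otu == "A", ]
  expect_equal(a_row$within_max, 0)
  expect_equal(a_row$between_min, 0.01)
  expect_true(a_row$gap_flag)
  b_row <- gs$per_otu[gs$per_otu$otu == "B", ]
  expect_true(is.na(b_row$within_max))  # singleton
  expect_true(is.na(b_row$gap_flag))
  expect_equal(gs$pairs$between_min, gs$pairs$between_max)
  expect_error(barcoding_gap_summary(
    distance_matrix(aligned_seq_set(m, otu = rep("A", 3)), "p")),
    "2 OTUs")
})

test_that("simple indel coding reproduces enumerated toy alignments", {
  # taxa 1-2 share gap 3-5; taxon 3 a single-column gap at 7
  m <- rbind(t1 = c("A", "C", "-", "-", "-", "G", "T", "A", "C", "G"),
             t2 = c("A", "C", "-", "-", "-", "G", "T", "A", "C", "G"),
             t3 = c("A", "C", "G", "T", "A", "G", "-", "A", "C", "G"),
             t4 = c("A", "C", "G", "T", "A", "G", "T", "A", "C", "G"))
  ic <- code_indels(aligned_seq_set(m))
  expect_equal(nrow(ic$characters), 2)
  expect_equal(ic$characters$start, c(3, 7))
  expect_equal(ic$characters$end, c(5, 7))
  expect_equal(ic$characters$class, c("parsimony-informative",
                                      "autapomorphic"))
  expect_equal(unname(ic$matrix[, 1]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(ic$matrix[, 2]), c(0L, 0L, 1L, 0L))
  # one taxon with a single 10-bp gap vs a gapless taxon -> 1 autapomorphy
  m2 <- rbind(u1 = strsplit(strrep("ACGTA", 6), "")[[1]],
              u2 = strsplit(strrep("ACGTA", 6), "")[[1]])
  m2["u2", 10:19] <- "-"
  ic2 <- code_indels(aligned_seq_set(m2))
  expect_equal(nrow(ic2$characters), 1)
  expect_equal(ic2$characters$class, "autapomorphic")
  # indel size is irrelevant: same count as a 1-bp version
  m3 <- m2; m3["u2", ] <- m2["u2", ]; m3["u2", 11:19] <- "A"
  expect_equal(nrow(code_indels(aligned_seq_set(m3))$characters), 1)
})

test_that("terminal overhangs are missing data, and subsumed spans are NA", {
  m <- rbind(v1 = c("-", "-", "A", "C", "G", "T", "A", "-", "-", "-"),
             v2 = c("A", "C", "A", "-", "-", "T", "A", "C", "G", "T"),
             v3 = c("A", "C", "-", "-", "-", "T", "A", "C", "G", "T"),
             v4 = c("A", "C", "A", "C", "G", "T", "A", "C", "G", "T"))
  ic <- code_indels(aligned_seq_set(m))
  # overhangs of v1 are not indel characters
  expect_equal(nrow(ic$characters), 2)
  expect_equal(ic$characters$start, c(3, 4))
  expect_equal(ic$characters$end, c(5, 5))
  # v2's 4-5 gap is subsumed by v3's 3-5 gap: v3 scored NA for char(4,5)
  ch45 <- which(ic$characters$start == 4)
  expect_true(is.na(ic$matrix["v3", ch45]))
  # gapless alignment -> empty set, not an error
  m0 <- rbind(w1 = c("A", "C"), w2 = c("A", "G"))
  expect_equal(nrow(code_indels(aligned_seq_set(m0))$characters), 0)
})

test_that("indel class counts sum and duplication never loses informativeness", {
  set.seed(33)
  for (rep_i in 1:10) {
    n <- sample(4:7, 1); L <- 40
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
    rownames(m) <- paste0("t", seq_len(n))
    for (i in seq_len(n)) {
      if (runif(1) < 0.8) {
        s <- sample(5:30, 1); e <- s + sample(0:5, 1)
        m[i, s:e] <- "-"
      }
    }
    ic <- code_indels(aligned_seq_set(m))
    expect_equal(sum(ic$counts), nrow(ic$characters))
    dup <- rbind(m, dup_taxon = m[1, ])
    ic_dup <- code_indels(aligned_seq_set(dup))
    expect_gte(ic_dup$counts[["parsimony-informative"]],
               ic$counts[["parsimony-informative"]])
  }
})
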