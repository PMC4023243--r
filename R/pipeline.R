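# Fixed-precision float serialisation keeps every output byte-reproducible.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA",
         ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                formatC(x, format = "g", digits = digits)))
}

write_tsv_fixed <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combined species-hypothesis verdict
#'
#' Pure function of the per-pair evidence flags.  `morpho` is the
#' morphometric non-overlap flag (best-ratio ranges disjoint), `gaps` a
#' logical vector with one barcoding-gap flag per evaluated marker
#' (length 0 when no molecular data were run); `NA` marks evidence not
#' evaluated.
#'
#' Truth table:
#' * `"distinct"` — morphometric non-overlap, or a barcoding gap on at
#'   least two markers (all evaluated markers gapped);
#' * `"cryptic-species candidate"` — no morphometric non-overlap (overlap
#'   observed or morphometrics not evaluated) but a gap on at least one
#'   marker, short of the two-marker rule above;
#' * `"not separable"` — some evidence evaluated, none positive;
#' * `"not evaluated"` — no evidence evaluated at all.
#'
#' @param morpho Logical scalar or `NA`.
#' @param gaps Logical vector (possibly with `NA`s) of per-marker gap
#'   flags.
#' @return One of the four verdict strings.
#' @export
species_verdict <- function(morpho, gaps = logical(0)) {
  gaps_eval <- gaps[!is.na(gaps)]
  n_eval <- length(gaps_eval)
  all_gap <- n_eval >= 2L && all(gaps_eval)
  any_gap <- n_eval >= 1L && any(gaps_eval)
  if (isTRUE(morpho) || all_gap) return("distinct")
  if (any_gap) return("cryptic-species candidate")
  if (!is.na(morpho) || n_eval > 0L) return("not separable")
  "not evaluated"
}

#' Build a pipeline configuration
#'
#' @param measurements Path to a measurement table (CSV/TSV) or a
#'   `measurement_table`; `NULL` for a molecular-only run.
#' @param alignments Named list of aligned FASTA paths (or
#'   `aligned_seq_set` objects), one per marker; empty for a morpho-only
#'   run.
#' @param otu_maps Optional named list (same names as `alignments`) of OTU
#'   map files or named vectors.
#' @param comparisons Data frame `sex`, `group1`, `group2` of morphometric
#'   comparisons; defaults to all OTU pairs per sex present.
#' @param sexes Sexes to analyse (default both, each separately).
#' @param pcs Number of shape PCs to report scores for.
#' @param n_boot Bootstrap replicates for the ratio spectra.
#' @param seed Integer seed; mandatory because spectra are stochastic.
#' @param model Distance model, `"gtr"` or `"p"`.
#' @param out Output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(measurements = NULL, alignments = list(),
                            otu_maps = NULL, comparisons = NULL,
                            sexes = c("female", "male"), pcs = 2L,
                            n_boot = 1000L, seed, model = "gtr",
                            out = ".") {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory (the spectra are stochastic)")
  if (is.null(measurements) && !length(alignments))
    stop("config needs at least one of measurements or alignments")
  for (nm in c(measurements[is.character(measurements)],
               unlist(alignments[vapply(alignments, is.character,
                                        logical(1))])))
    if (!file.exists(nm)) stop("input file not found: ", nm)
  structure(list(measurements = measurements, alignments = alignments,
                 otu_maps = otu_maps, comparisons = comparisons,
                 sexes = sexes, pcs = as.integer(pcs),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 model = model, out = out), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; `alignments` and
#' `otu_maps` are JSON objects mapping marker name to file path, and
#' `comparisons` an array of `{sex, group1, group2}` objects.  Relative
#' paths are resolved against the config file's directory.
#'
#' @param path Path to a JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(f) ifelse(grepl("^/", f), f, file.path(base, f))
  if (!is.null(cfg$measurements)) cfg$measurements <- rel(cfg$measurements)
  if (!is.null(cfg$alignments))
    cfg$alignments <- lapply(as.list(cfg$alignments), rel)
  if (!is.null(cfg$otu_maps)) cfg$otu_maps <- lapply(as.list(cfg$otu_maps), rel)
  if (!is.null(cfg$comparisons)) cfg$comparisons <- as.data.frame(cfg$comparisons)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

all_pairs_comparisons <- function(table, sexes) {
  do.call(rbind, lapply(intersect(sexes, unique(table$sex)), function(sx) {
    g <- sort(unique(table$group[table$sex == sx]))
    if (length(g) < 2L) return(NULL)
    cp <- t(utils::combn(g, 2L))
    data.frame(sex = sx, group1 = cp[, 1L], group2 = cp[, 2L],
               stringsAsFactors = FALSE)
  }))
}

#' Run the full delimitation pipeline
#'
#' Executes, per sex: shape PCA (score table + scree), PCA and allometry
#' ratio spectra, and the best-ratio comparison suite; per marker: the
#' pairwise distance matrix, barcoding-gap summary and indel characters;
#' then joins the morphometric non-overlap flag and per-marker gap flags
#' into a per-OTU-pair verdict table (see [species_verdict()]).  All
#' outputs are TSV with fixed column order and fixed float precision, so
#' an unchanged config reproduces every file byte for byte.  A run log
#' records package version, seed and input digests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `verdicts` (data frame), `suite`,
#'   `gap_summaries`, and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_lines <- c(
    paste0("mratax ", as.character(utils::packageVersion("mratax"))),
    paste0("seed ", config$seed),
    paste0("model ", config$model))

  emit <- function(df, name, digits = 6) {
    path <- file.path(config$out, name)
    write_tsv_fixed(df, path, digits = digits)
    files <<- c(files, path)
    path
  }

  # ---- morphometrics -------------------------------------------------------
  suite <- NULL
  morpho_pairs <- NULL
  if (!is.null(config$measurements)) {
    tab <- if (inherits(config$measurements, "measurement_table"))
      config$measurements else read_measurement_table(config$measurements)
    if (is.character(config$measurements))
      log_lines <- c(log_lines, paste0("measurements md5 ",
                                       tools::md5sum(config$measurements)[[1]]))
    comparisons <- config$comparisons
    if (is.null(comparisons))
      comparisons <- all_pairs_comparisons(tab, config$sexes)
    if (is.null(comparisons) || !nrow(comparisons))
      stop("no morphometric comparisons possible")
    for (sx in intersect(config$sexes, unique(tab$sex))) {
      sub <- subset_table(tab, sex = sx)
      pca <- shape_pca(sub)
      k <- min(config$pcs, ncol(pca$scores))
      scores <- data.frame(specimen_id = sub$specimen_id, otu = sub$group,
                           isosize = pca$isosize,
                           pca$scores[, seq_len(k), drop = FALSE],
                           check.names = FALSE)
      emit(scores, paste0("shape_scores_", sx, ".tsv"))
      emit(scree(pca), paste0("scree_", sx, ".tsv"))
      sp <- pca_ratio_spectrum(sub, 1L, n_boot = config$n_boot,
                               seed = config$seed)
      emit(as.data.frame(sp), paste0("pca_ratio_spectrum_", sx, ".tsv"))
      al <- allometry_ratio_spectrum(sub, n_boot = config$n_boot,
                                     seed = config$seed)
      emit(as.data.frame(al), paste0("allometry_ratio_spectrum_", sx, ".tsv"))
    }
    suite <- comparison_suite(tab, comparisons)
    emit(suite, "discriminant_suite.tsv")
    morpho_pairs <- data.frame(
      sex = suite$sex,
      otu_1 = comparisons$group1, otu_2 = comparisons$group2,
      nonoverlap = !suite$overlap_flag, stringsAsFactors = FALSE)
  }

  # ---- molecular -----------------------------------------------------------
  gap_summaries <- list()
  for (marker in names(config$alignments)) {
    a <- config$alignments[[marker]]
    if (is.character(a)) {
      log_lines <- c(log_lines, paste0(marker, " md5 ",
                                       tools::md5sum(a)[[1]]))
      a <- read_alignment(a, otu_map = config$otu_maps[[marker]])
    }
    dm <- distance_matrix(a, model = config$model)
    path <- file.path(config$out, paste0("distances_", marker, ".tsv"))
    write_distance_matrix(dm, path)
    files <- c(files, path)
    gs <- barcoding_gap_summary(dm)
    gap_summaries[[marker]] <- gs
    per <- gs$per_otu
    per$within_max_pct <- fmt_num(100 * per$within_max)
    per$between_min_pct <- fmt_num(100 * per$between_min)
    emit(per[, c("otu", "n", "within_max_pct", "nearest_otu",
                 "between_min_pct", "gap_flag")],
         paste0("gap_summary_", marker, ".tsv"))
    ic <- code_indels(a)
    emit(ic$characters, paste0("indels_", marker, ".tsv"))
  }

  # ---- combined verdict ----------------------------------------------------
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  keys <- character(0)
  if (!is.null(morpho_pairs))
    keys <- union(keys, pair_key(morpho_pairs$otu_1, morpho_pairs$otu_2))
  for (gs in gap_summaries)
    keys <- union(keys, pair_key(gs$pairs$otu_1, gs$pairs$otu_2))
  verdicts <- NULL
  if (length(keys)) {
    keys <- sort(keys)
    rows <- lapply(keys, function(kk) {
      ot <- strsplit(kk, "|", fixed = TRUE)[[1L]]
      morpho <- NA
      if (!is.null(morpho_pairs)) {
        hit <- morpho_pairs[pair_key(morpho_pairs$otu_1,
                                     morpho_pairs$otu_2) == kk, ]
        if (nrow(hit)) morpho <- any(hit$nonoverlap)
      }
      gaps <- vapply(names(gap_summaries), function(marker) {
        pr <- gap_summaries[[marker]]$pairs
        hit <- pr[pair_key(pr$otu_1, pr$otu_2) == kk, ]
        if (!nrow(hit)) return(NA)
        wm <- gap_summaries[[marker]]$per_otu
        wmax <- suppressWarnings(
          max(wm$within_max[wm$otu %in% ot], na.rm = TRUE))
        if (!is.finite(wmax)) wmax <- 0  # singletons: no within variation seen
        hit$between_min > wmax
      }, logical(1))
      row <- data.frame(otu_1 = ot[1L], otu_2 = ot[2L],
                        morpho_nonoverlap = morpho,
                        stringsAsFactors = FALSE, row.names = NULL)
      for (marker in names(gap_summaries))
        row[[paste0("gap_", marker)]] <- gaps[[marker]]
      row$verdict <- species_verdict(morpho, gaps)
      row
    })
    verdicts <- do.call(rbind, rows)
    emit(verdicts, "verdicts.tsv")
  }

  writeLines(log_lines, file.path(config$out, "run_log.txt"))
  files <- c(files, file.path(config$out, "run_log.txt"))
  invisible(list(verdicts = verdicts, suite = suite,
                 gap_summaries = gap_summaries, files = files))
}
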