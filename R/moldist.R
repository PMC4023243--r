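BASES <- c("A", "C", "G", "T")

#' Construct an aligned sequence set
#'
#' @param seqs Character matrix (taxa x alignment columns) over
#'   `A,C,G,T,-` and IUPAC ambiguity codes, or a named character vector of
#'   equal-length strings.
#' @param otu Optional OTU label per sequence (defaults to the sequence id).
#' @param id Sequence identifiers (defaults to names/rownames).
#' @return An object of class `aligned_seq_set`: list with `seq` (character
#'   matrix, uppercase, `U` mapped to `T`), `id`, `otu`, `length`.
#' @export
aligned_seq_set <- function(seqs, otu = NULL, id = NULL) {
  if (!is.matrix(seqs)) {
    if (is.null(id)) id <- names(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths ",
           paste(unique(lens), collapse = ", "))
    seqs <- do.call(rbind, strsplit(as.character(seqs), ""))
  } else if (is.null(id)) {
    id <- rownames(seqs)
  }
  if (is.null(id)) stop("sequences must be named")
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  seqs <- toupper(seqs)
  seqs[seqs == "U"] <- "T"
  if (!nrow(seqs) || !ncol(seqs)) stop("empty alignment")
  n_unamb <- rowSums(matrix(seqs %in% BASES, nrow = nrow(seqs)))
  if (any(n_unamb == 0L))
    stop("sequence(s) without any unambiguous base: ",
         paste(id[n_unamb == 0L], collapse = ", "))
  if (is.null(otu)) otu <- id
  otu <- as.character(otu)
  if (length(otu) != nrow(seqs)) stop("one OTU label per sequence required")
  rownames(seqs) <- id
  structure(list(seq = seqs, id = id, otu = otu, length = ncol(seqs)),
            class = "aligned_seq_set")
}

#' @export
print.aligned_seq_set <- function(x, ...) {
  cat(sprintf("<aligned_seq_set> %d sequences x %d columns, %d OTU(s)\n",
              nrow(x$seq), x$length, length(unique(x$otu))))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences are uppercased and `U` is normalised to `T`.  OTU labels come
#' from a two-column TSV map (`sequence_id`, `otu`) when given, otherwise
#' from the second whitespace-separated token of each FASTA header if
#' present, else from the id itself.
#'
#' @param path Path to an aligned FASTA file (equal sequence lengths).
#' @param otu_map Optional path to a 2-column TSV, or a named character
#'   vector mapping sequence id to OTU.
#' @return An [aligned_seq_set()].
#' @export
read_alignment <- function(path, otu_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- Biostrings::readBStringSet(path)
  if (!length(dna)) stop("empty FASTA file: ", path)
  lens <- Biostrings::width(dna)
  if (length(unique(lens)) != 1L) {
    hdr <- grep("^>", readLines(path))
    bad <- which(lens != stats::median(lens))
    stop("ragged alignment in ", path, ": record(s) starting at line ",
         paste(hdr[bad], collapse = ", "), " have deviating length")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(dna)), ""))
  full_ids <- names(dna)
  rownames(mat) <- full_ids
  ids <- sub("\\s.*$", "", full_ids)
  otu <- NULL
  if (!is.null(otu_map)) {
    if (is.character(otu_map) && length(otu_map) == 1L && file.exists(otu_map)) {
      mp <- utils::read.table(otu_map, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE,
                              col.names = c("sequence_id", "otu"))
      otu_map <- stats::setNames(mp$otu, mp$sequence_id)
    }
    if (!all(ids %in% names(otu_map)))
      stop("OTU map lacks entries for: ",
           paste(setdiff(ids, names(otu_map)), collapse = ", "))
    otu <- unname(otu_map[ids])
  } else {
    tok2 <- sub("^\\S+\\s+", "", full_ids)
    otu <- ifelse(tok2 != full_ids & nzchar(tok2), sub("\\s.*$", "", tok2), ids)
  }
  rownames(mat) <- ids
  aligned_seq_set(mat, otu = otu, id = ids)
}

#' Write an aligned sequence set as FASTA
#'
#' @param aln An `aligned_seq_set`.
#' @param path Output path.
#' @param with_otu Append the OTU label to the header after a space.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, with_otu = TRUE) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  hdr <- if (with_otu) paste(aln$id, aln$otu) else aln$id
  lines <- character(2L * nrow(aln$seq))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# Usable = unambiguous A/C/G/T; gaps and ambiguity codes are treated as
# missing and removed by pairwise deletion.
usable_mask <- function(chars) chars %in% BASES

#' Uncorrected p-distance between two aligned sequences
#'
#' @param a,b Character vectors (one per alignment column).
#' @return Scalar proportion of differing sites after pairwise deletion,
#'   with attribute `sites` (number of compared columns).
#' @export
p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in alignment length")
  use <- usable_mask(a) & usable_mask(b)
  n <- sum(use)
  if (n == 0L) stop("no usable (unambiguous, ungapped) columns in common")
  structure(sum(a[use] != b[use]) / n, sites = n)
}

#' Closed-form pairwise GTR distance
#'
#' General time-reversible distance computed from the symmetrised
#' divergence matrix: `d = -tr(Pi %*% logm(Pi^-1 %*% F))`, where `F` is the
#' matrix of site-pattern proportions symmetrised as `(F + t(F))/2` and
#' `Pi` the diagonal matrix of the averaged base frequencies of the two
#' sequences (per-pair by default).  Columns where either sequence has a
#' gap or ambiguity code are excluded (pairwise deletion).  Identical
#' sequences give 0.  Saturated pairs (non-positive eigenvalues, matrix
#' logarithm undefined) are returned as `NA` with a warning.
#'
#' @param a,b Character vectors over the alignment columns.
#' @param freqs `"pair"` (average empirical frequencies of the two
#'   sequences, the default) or a numeric 4-vector of global frequencies in
#'   A,C,G,T order.
#' @param min_sites Minimum usable columns below which a warning is issued.
#' @return Distance in substitutions/site with attribute `sites`;
#'   multiply by 100 for percent.
#' @export
gtr_distance <- function(a, b, freqs = "pair", min_sites = 50L) {
  if (length(a) != length(b)) stop("sequences differ in alignment length")
  use <- usable_mask(a) & usable_mask(b)
  n <- sum(use)
  if (n == 0L) stop("no usable (unambiguous, ungapped) columns in common")
  if (n < min_sites)
    warning("only ", n, " usable sites for a pair; distance is unstable")
  au <- factor(a[use], levels = BASES)
  bu <- factor(b[use], levels = BASES)
  Fhat <- unclass(table(au, bu)) / n
  Fhat <- (Fhat + t(Fhat)) / 2
  if (identical(freqs, "pair")) {
    pi_vec <- rowSums(Fhat)
  } else {
    pi_vec <- as.numeric(freqs)
    if (length(pi_vec) != 4L || any(pi_vec < 0) ||
        abs(sum(pi_vec) - 1) > 1e-8)
      stop("'freqs' must be \"pair\" or 4 nonnegative frequencies summing to 1")
  }
  keep <- pi_vec > 0
  Fk <- Fhat[keep, keep, drop = FALSE]
  pk <- pi_vec[keep]
  # tr(Pi log(Pi^-1 F)) via the symmetric similarity transform
  # S = Pi^-1/2 F Pi^-1/2 (F symmetric => S symmetric)
  isq <- 1 / sqrt(pk)
  S <- Fk * tcrossprod(isq)
  ee <- eigen(S, symmetric = TRUE)
  if (any(ee$values <= 0)) {
    warning("GTR distance undefined (saturation: matrix logarithm ",
            "has non-positive eigenvalues)")
    return(structure(NA_real_, sites = n))
  }
  logS <- ee$vectors %*% (log(ee$values) * t(ee$vectors))
  d <- -sum(pk * diag(logS))
  structure(max(d, 0), sites = n)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln An [aligned_seq_set()] with at least 2 sequences.
#' @param model `"gtr"` (closed-form GTR) or `"p"` (uncorrected
#'   p-distance).
#' @param ... Passed to [gtr_distance()].
#' @return An object of class `distance_matrix`: list with `d` (symmetric,
#'   zero diagonal, substitutions/site), `sites_used`, `labels`, `otu`,
#'   `model`.
#' @export
distance_matrix <- function(aln, model = c("gtr", "p"), ...) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  model <- match.arg(model)
  n <- nrow(aln$seq)
  if (n < 2L) stop("at least 2 sequences required")
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  sites <- matrix(aln$length, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- if (model == "gtr")
        gtr_distance(aln$seq[i, ], aln$seq[j, ], ...)
      else p_distance(aln$seq[i, ], aln$seq[j, ])
      d[i, j] <- d[j, i] <- as.numeric(dij)
      sites[i, j] <- sites[j, i] <- attr(dij, "sites")
    }
  }
  diag(sites) <- NA_integer_
  structure(list(d = d, sites_used = sites, labels = aln$id, otu = aln$otu,
                 model = model), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s model, %d sequences\n",
              toupper(x$model), nrow(x$d)))
  print(round(100 * x$d, 2))
  invisible(x)
}

#' Within/between-OTU distance summary (barcoding gap)
#'
#' For each OTU the maximum within-OTU distance (undefined for singletons),
#' its nearest neighbouring OTU, the minimum between-OTU distance, and a
#' gap flag set when the maximum within-OTU distance is smaller than the
#' minimum distance to any other OTU (the barcoding gap).  A pair table
#' reports min and max between-OTU distance for every OTU pair.
#'
#' @param dm A [distance_matrix()].
#' @return List of class `gap_summary` with data frames `per_otu`
#'   (`otu`, `n`, `within_max`, `nearest_otu`, `between_min`, `gap_flag`)
#'   and `pairs` (`otu_1`, `otu_2`, `between_min`, `between_max`).
#'   Distances are in substitutions/site.
#' @export
barcoding_gap_summary <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  otus <- unique(dm$otu)
  if (length(otus) < 2L) stop("at least 2 OTUs required")
  idx <- split(seq_along(dm$otu), dm$otu)[otus]

  pairs <- do.call(rbind, lapply(seq_along(otus)[-length(otus)], function(i) {
    do.call(rbind, lapply((i + 1L):length(otus), function(j) {
      block <- dm$d[idx[[i]], idx[[j]], drop = FALSE]
      data.frame(otu_1 = otus[i], otu_2 = otus[j],
                 between_min = min(block, na.rm = TRUE),
                 between_max = max(block, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))

  per_otu <- do.call(rbind, lapply(otus, function(o) {
    ii <- idx[[o]]
    wmax <- if (length(ii) < 2L) NA_real_ else {
      block <- dm$d[ii, ii]
      max(block[upper.tri(block)], na.rm = TRUE)
    }
    rel <- pairs[pairs$otu_1 == o | pairs$otu_2 == o, ]
    nn <- which.min(rel$between_min)
    nearest <- ifelse(rel$otu_1[nn] == o, rel$otu_2[nn], rel$otu_1[nn])
    bmin <- rel$between_min[nn]
    data.frame(otu = o, n = length(ii), within_max = wmax,
               nearest_otu = nearest, between_min = bmin,
               gap_flag = if (is.na(wmax)) NA else wmax < bmin,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_otu = per_otu, pairs = pairs), class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat("<gap_summary> per-OTU (distances in %):\n")
  df <- x$per_otu
  df$within_max <- round(100 * df$within_max, 2)
  df$between_min <- round(100 * df$between_min, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Simple indel coding of an alignment
#'
#' Each maximal internal gap run with identical start and end columns
#' becomes one binary presence/absence character, regardless of its length
#' (simple indel coding).  Runs with different boundaries are distinct
#' characters.  Terminal overhangs (leading/trailing gaps) are treated as
#' missing data, not indels; a taxon whose gap run strictly extends beyond
#' a character's span, or whose sequence is entirely missing across the
#' span, is scored as missing (`NA`) for that character.
#'
#' Characters are classified as `parsimony-informative` (both states in at
#' least 2 taxa each), `autapomorphic` (minority state in exactly one
#' taxon) or `constant`.
#'
#' @param aln An [aligned_seq_set()].
#' @return Object of class `indel_character_set`: list with `matrix`
#'   (taxa x characters, values 0/1/`NA`), `characters` (data frame
#'   `char`, `start`, `end`, `class`) and `counts` (named vector of class
#'   totals).  A gapless alignment yields zero characters.
#' @export
code_indels <- function(aln) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  n <- nrow(aln$seq); L <- aln$length
  is_gap <- aln$seq == "-"
  # terminal overhangs per taxon -> missing, not gaps
  missing_pos <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    g <- is_gap[i, ]
    if (g[1L]) {
      lead <- which(!g)[1L] - 1L
      missing_pos[i, seq_len(lead)] <- TRUE
    }
    if (g[L]) {
      trail <- max(which(!g))
      missing_pos[i, (trail + 1L):L] <- TRUE
    }
  }
  internal_gap <- is_gap & !missing_pos

  # maximal internal gap runs per taxon
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rle(internal_gap[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs[[i]] <- cbind(start = starts[r$values], end = ends[r$values])
  }
  all_runs <- unique(do.call(rbind, runs))
  if (is.null(all_runs) || !nrow(all_runs)) {
    return(structure(list(
      matrix = matrix(integer(0), nrow = n, ncol = 0,
                      dimnames = list(aln$id, NULL)),
      characters = data.frame(char = character(0), start = integer(0),
                              end = integer(0), class = character(0),
                              stringsAsFactors = FALSE),
      counts = c(`parsimony-informative` = 0L, autapomorphic = 0L,
                 constant = 0L)), class = "indel_character_set"))
  }
  all_runs <- all_runs[order(all_runs[, "start"], all_runs[, "end"]), ,
                       drop = FALSE]
  nc <- nrow(all_runs)
  M <- matrix(0L, n, nc, dimnames = list(aln$id, NULL))
  for (ch in seq_len(nc)) {
    s <- all_runs[ch, "start"]; e <- all_runs[ch, "end"]
    for (i in seq_len(n)) {
      has_exact <- any(runs[[i]][, "start"] == s & runs[[i]][, "end"] == e)
      if (has_exact) {
        M[i, ch] <- 1L
      } else if (all(missing_pos[i, s:e])) {
        M[i, ch] <- NA_integer_
      } else if (any(runs[[i]][, "start"] <= s & runs[[i]][, "end"] >= e)) {
        # subsumed by a longer gap: inapplicable
        M[i, ch] <- NA_integer_
      } else {
        M[i, ch] <- 0L
      }
    }
  }
  cls <- apply(M, 2L, function(col) {
    ones <- sum(col == 1L, na.rm = TRUE)
    zeros <- sum(col == 0L, na.rm = TRUE)
    if (ones >= 2L && zeros >= 2L) "parsimony-informative"
    else if (min(ones, zeros) == 1L) "autapomorphic"
    else "constant"
  })
  chars <- data.frame(char = paste0("indel_", seq_len(nc)),
                      start = all_runs[, "start"], end = all_runs[, "end"],
                      class = cls, row.names = NULL, stringsAsFactors = FALSE)
  colnames(M) <- chars$char
  counts <- c(`parsimony-informative` = sum(cls == "parsimony-informative"),
              autapomorphic = sum(cls == "autapomorphic"),
              constant = sum(cls == "constant"))
  structure(list(matrix = M, characters = chars, counts = counts),
            class = "indel_character_set")
}

#' @export
print.indel_character_set <- function(x, ...) {
  cat(sprintf("<indel_character_set> %d character(s): %d informative, %d autapomorphic, %d constant\n",
              nrow(x$characters), x$counts[["parsimony-informative"]],
              x$counts[["autapomorphic"]], x$counts[["constant"]]))
  if (nrow(x$characters)) print(x$characters, row.names = FALSE)
  invisible(x)
}

#' Write a distance matrix as TSV (and optional PHYLIP square format)
#'
#' @param dm A [distance_matrix()].
#' @param path Output TSV path.
#' @param phylip If `TRUE`, write a PHYLIP-style square matrix instead.
#' @param percent Report distances in percent (default) or raw.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, phylip = FALSE, percent = TRUE) {
  stopifnot(inherits(dm, "distance_matrix"))
  d <- if (percent) 100 * dm$d else dm$d
  d <- round(d, 6)
  if (phylip) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(formatC(dm$labels[i], width = -10),
                         formatC(d[i, ], format = "f", digits = 6)),
                       collapse = "  "), con)
  } else {
    df <- data.frame(id = dm$labels, otu = dm$otu, d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
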