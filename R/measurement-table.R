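#' The 16 linear measurement characters of the default character set
#'
#' Standard abbreviations for the head, antennal and hind-leg distance
#' measurements (in micrometres) used throughout the package as the default
#' character list for synthetic data generation.
#'
#' @return Character vector of 16 character abbreviations.
#' @export
#' @examples
#' default_characters()
default_characters <- function() {
  c("cly.b", "eye.d", "eye.h", "flgfirst.l", "flglast.b", "flglast.l",
    "hea.b", "hea.h", "lof.l", "msp.l", "ool.l", "pol.l",
    "scp.b", "scp.l", "tib3.b", "tib3.l")
}

#' Construct a labelled measurement table
#'
#' A `measurement_table` holds strictly positive linear measurements (in
#' micrometres) for a set of specimens, together with an OTU (group) label
#' and a sex label per specimen.  Specimens with any missing or nonpositive
#' measurement are dropped with a warning: multivariate ratio analysis
#' requires complete positive rows and no imputation is performed.
#'
#' @param values Numeric matrix, specimens in rows, named characters in
#'   columns (at least 2 columns).
#' @param group Character vector of OTU labels, one per specimen.
#' @param sex Character vector, each element `"female"` or `"male"`.
#' @param specimen_id Unique specimen identifiers; defaults to the row
#'   names of `values`, or `spec_1 ... spec_n` if absent.
#' @return An object of class `measurement_table`: a list with elements
#'   `values`, `group`, `sex`, `specimen_id`.
#' @export
measurement_table <- function(values, group, sex, specimen_id = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L)
    stop("a measurement table needs at least 2 characters (shape is undefined for p < 2)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique character (column) names")
  n <- nrow(values)
  if (is.null(specimen_id)) {
    specimen_id <- rownames(values)
    if (is.null(specimen_id)) specimen_id <- paste0("spec_", seq_len(n))
  }
  specimen_id <- as.character(specimen_id)
  group <- as.character(group)
  sex <- as.character(sex)
  if (length(group) != n || length(sex) != n || length(specimen_id) != n)
    stop("'group', 'sex' and 'specimen_id' must each have one entry per specimen")
  if (anyDuplicated(specimen_id))
    stop("duplicated specimen_id: ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "))
  bad_sex <- setdiff(unique(sex), c("female", "male"))
  if (length(bad_sex))
    stop("sex labels must be 'female' or 'male'; found: ",
         paste(bad_sex, collapse = ", "))

  bad <- !is.finite(values) | values <= 0
  if (any(bad)) {
    drop <- which(rowSums(bad) > 0L)
    warning(sprintf(
      "dropping %d specimen(s) with missing or nonpositive measurements: %s",
      length(drop), paste(specimen_id[drop], collapse = ", ")))
    keep <- setdiff(seq_len(n), drop)
    if (!length(keep)) stop("no complete positive specimen rows remain")
    values <- values[keep, , drop = FALSE]
    group <- group[keep]
    sex <- sex[keep]
    specimen_id <- specimen_id[keep]
  }
  rownames(values) <- specimen_id
  structure(
    list(values = values, group = group, sex = sex, specimen_id = specimen_id),
    class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> %d specimens x %d characters\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$group, x$sex)
  print(tab)
  invisible(x)
}

#' Number of specimens and characters
#' @param x A `measurement_table`.
#' @param ... Ignored.
#' @return Integer vector `c(specimens, characters)`.
#' @export
dim.measurement_table <- function(x) dim(x$values)

#' Subset a measurement table by group and/or sex
#'
#' @param x A `measurement_table`.
#' @param groups Optional character vector of OTU labels to keep.
#' @param sex Optional single sex (`"female"` or `"male"`).
#' @param specimens Optional specimen ids to keep.
#' @return A `measurement_table` restricted to the selection.
#' @export
subset_table <- function(x, groups = NULL, sex = NULL, specimens = NULL) {
  stopifnot(inherits(x, "measurement_table"))
  keep <- rep(TRUE, nrow(x$values))
  if (!is.null(groups)) {
    missing_g <- setdiff(groups, unique(x$group))
    if (length(missing_g))
      stop("unknown group label(s): ", paste(missing_g, collapse = ", "))
    keep <- keep & x$group %in% groups
  }
  if (!is.null(sex)) keep <- keep & x$sex %in% sex
  if (!is.null(specimens)) keep <- keep & x$specimen_id %in% specimens
  if (!any(keep)) stop("selection leaves no specimens")
  measurement_table(x$values[keep, , drop = FALSE], x$group[keep],
                    x$sex[keep], x$specimen_id[keep])
}

#' Read a measurement table from delimited text
#'
#' The file must have a header row with columns `specimen_id`, `otu`, `sex`
#' followed by one column per measurement character (values in micrometres).
#' The field separator (comma or tab) is auto-detected from the header line.
#'
#' @param path Path to a CSV or TSV file.
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("specimen_id", "otu", "sex")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  chars <- setdiff(names(df), need)
  vals <- as.matrix(df[, chars, drop = FALSE])
  measurement_table(vals, df$otu, df$sex, df$specimen_id)
}

#' Write a measurement table as delimited text
#'
#' @param x A `measurement_table`.
#' @param path Output path; a `.csv` extension selects comma separation,
#'   anything else tab separation.
#' @return Invisibly, `path`.
#' @export
write_measurement_table <- function(x, path) {
  stopifnot(inherits(x, "measurement_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(specimen_id = x$specimen_id, otu = x$group, sex = x$sex,
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Guard used by all MRA entry points: the analyses are defined per sex.
check_single_sex <- function(x, allow_mixed_sex = FALSE) {
  if (!allow_mixed_sex && length(unique(x$sex)) > 1L)
    stop("table mixes sexes; MRA is run per sex. Subset with subset_table(),",
         " or set allow_mixed_sex = TRUE to override.")
  invisible(TRUE)
}
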