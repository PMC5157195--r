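#' Read a quantitative interaction matrix from CSV
#'
#' The CSV dialect is UTF-8, comma-separated, first row bird names, first
#' column plant names, integer visit counts in the cells. Lines starting
#' with \code{#} are comments and may carry provenance metadata; they are
#' ignored on read (except a \code{# provenance:} line when reading a
#' probability matrix).
#'
#' @param path path to a CSV file.
#' @return An \code{\link{interaction_matrix}}.
#' @export
read_interaction_matrix <- function(path) {
  interaction_matrix(read_labelled_csv(path)$mat)
}

#' @rdname read_interaction_matrix
#' @export
read_probability_matrix <- function(path) {
  got <- read_labelled_csv(path)
  prov <- sub("^#\\s*provenance:\\s*", "",
              grep("^#\\s*provenance:", got$comments, value = TRUE))
  prov <- if (length(prov)) strsplit(prov[1L], "\\*")[[1L]] else "unknown"
  probability_matrix(got$mat, provenance = prov, normalize = FALSE)
}

read_labelled_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  comments <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("file has no data rows: ", path)
  # read.csv de-duplicates repeated header names, which would mask a
  # duplicate-label validation error: parse the header ourselves
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  colnames(mat) <- header[-1L]
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))) &
                   !is.na(mat), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("non-numeric cell [%s, %s] = \"%s\"",
                   labels[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]],
                   mat[bad[1L, , drop = FALSE]]))
    storage.mode(mat) <- "numeric"
  }
  rownames(mat) <- labels
  list(mat = mat, comments = comments)
}

#' Write an interaction or probability matrix to CSV
#'
#' Writes the package's CSV dialect (see
#' \code{\link{read_interaction_matrix}}). Counts round-trip exactly;
#' probabilities are written with 15 significant digits and carry their
#' provenance tag in a \code{# provenance:} comment line.
#'
#' @param m an \code{interaction_matrix} or \code{probability_matrix}.
#' @param path output path.
#' @param label header for the first (plant-name) column.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(m, path, label = "species") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  x <- unclass_matrix(m)
  if (inherits(m, "probability_matrix")) {
    writeLines(sprintf("# pollinet probability_matrix"), con)
    writeLines(sprintf("# provenance: %s", provenance_label(m)), con)
    cells <- format(x, digits = 15, scientific = TRUE, trim = TRUE)
  } else {
    writeLines("# pollinet interaction_matrix", con)
    cells <- format(x, trim = TRUE)
  }
  writeLines(paste(c(label, colnames(x)), collapse = ","), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(c(rownames(x)[i], cells[i, ]), collapse = ","), con)
  invisible(path)
}

#' Remove empty rows and columns
#'
#' Drops all-zero plant rows and bird columns (as arise after filtering
#' illegitimate visits), preserving label order otherwise. The total number
#' of interactions is unchanged.
#'
#' @param m an \code{\link{interaction_matrix}}.
#' @return An \code{interaction_matrix} with no empty margins.
#' @export
drop_empty_margins <- function(m) {
  x <- unclass_matrix(as_interaction_matrix(m))
  if (sum(x) == 0) stop("network is empty: every cell is zero")
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  interaction_matrix(x)
}

#' Remove illegitimate (non-pollinating) visits from a network
#'
#' Zeroes out every interaction of robber-annotated bird species (whole
#' columns; e.g. *Diglossa* flowerpiercers that pierce the corolla base)
#' plus an explicit list of species-pair exclusions for illegitimate visits
#' by otherwise legitimate birds, then drops emptied rows and columns. The
#' result is a pollination network rather than a visitation network.
#'
#' @param m an \code{\link{interaction_matrix}}.
#' @param traits optional \code{\link{trait_table}}; birds annotated
#'   \code{"robber"} are removed. Trait species absent from the network are
#'   ignored with a warning (the network defines the analysis universe).
#' @param robbers optional character vector of bird species to remove
#'   wholesale (in addition to any annotated in \code{traits}).
#' @param pair_exclusions optional two-column data.frame or matrix
#'   (\code{plant}, \code{bird}) of individual interactions to remove.
#' @param drop_empty drop emptied margins afterwards (default TRUE).
#' @return A filtered \code{interaction_matrix}.
#' @export
filter_illegitimate <- function(m, traits = NULL, robbers = character(),
                                pair_exclusions = NULL, drop_empty = TRUE) {
  m <- as_interaction_matrix(m)
  x <- unclass_matrix(m)
  if (!is.null(traits)) {
    tr <- traits$birds$species[traits$birds$legitimacy == "robber"]
    extra <- setdiff(tr, colnames(x))
    if (length(extra))
      warning("robber-annotated species not in the network ignored: ",
              paste(extra, collapse = ", "))
    robbers <- union(robbers, intersect(tr, colnames(x)))
  }
  unknown <- setdiff(robbers, colnames(x))
  if (length(unknown))
    stop("unknown bird species in robber list: ",
         paste(unknown, collapse = ", "))
  x[, colnames(x) %in% robbers] <- 0L
  if (!is.null(pair_exclusions)) {
    pe <- as.matrix(pair_exclusions)[, 1:2, drop = FALSE]
    badp <- setdiff(pe[, 1L], rownames(x))
    badb <- setdiff(pe[, 2L], colnames(x))
    if (length(badp) || length(badb))
      stop("unknown species in pair exclusions: ",
           paste(c(badp, badb), collapse = ", "))
    for (k in seq_len(nrow(pe))) x[pe[k, 1L], pe[k, 2L]] <- 0L
  }
  if (drop_empty) drop_empty_margins(x) else interaction_matrix(x)
}
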