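#' Quantitative interaction matrix
#'
#' Constructs a validated plant x flower-visitor count matrix: plants as
#' rows, birds (or other visitors) as columns, cells holding the number of
#' observed visits. This is the central container of the package; all
#' metrics, likelihoods and null models operate on it.
#'
#' @param counts numeric matrix of nonnegative integer visit counts with
#'   unique row (plant) and column (bird) names. A data.frame is accepted
#'   and coerced.
#' @param plants,birds optional character vectors overriding the dimnames.
#' @return An object of class \code{interaction_matrix}: an integer matrix
#'   with dimnames, plus attribute \code{N} (total visits).
#' @examples
#' m <- interaction_matrix(rbind(c(1, 0), c(0, 2)),
#'                         plants = c("p1", "p2"), birds = c("b1", "b2"))
#' total_interactions(m)  # 3
#' @export
interaction_matrix <- function(counts, plants = NULL, birds = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (!is.null(plants)) rownames(counts) <- plants
  if (!is.null(birds)) colnames(counts) <- birds
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("plant_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("bird_", seq_len(ncol(counts)))
  validate_interaction_matrix(counts)
  storage.mode(counts) <- "integer"
  structure(counts, N = sum(counts), class = c("interaction_matrix", "matrix"))
}

validate_interaction_matrix <- function(counts) {
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("interaction matrix needs at least one plant and one bird")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate plant labels: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate bird labels: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing count at [%s, %s]",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-9,
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "cell [%s, %s] = %s is not a nonnegative integer",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
      format(counts[bad[1L, , drop = FALSE]])))
  invisible(TRUE)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d plants x %d birds, N = %d visits, %d links\n",
              nrow(x), ncol(x), attr(x, "N"), sum(x > 0)))
  print(unclass_matrix(x))
  invisible(x)
}

# strip class/attrs for plain-matrix work
unclass_matrix <- function(x) {
  y <- as.matrix(x)
  attr(y, "N") <- NULL
  attr(y, "provenance") <- NULL
  attr(y, "epsilon_cells") <- NULL
  class(y) <- NULL
  dim(y) <- dim(x)
  dimnames(y) <- dimnames(x)
  y
}

#' @rdname interaction_matrix
#' @param m an \code{interaction_matrix}.
#' @export
total_interactions <- function(m) sum(unclass_matrix(m))

as_interaction_matrix <- function(m) {
  if (inherits(m, "interaction_matrix")) m else interaction_matrix(m)
}

#' Interaction probability matrix
#'
#' A matrix of cell probabilities \eqn{p_{ij}} over the same plant x bird
#' label space as an \code{\link{interaction_matrix}}, summing to one over
#' all cells. Each matrix carries a provenance tag naming the factors it
#' encodes: any subset of \code{Ab} (abundance), \code{Phen} (phenology),
#' \code{Mor} (morphology), or \code{Null} for the uniform matrix.
#'
#' @param probs nonnegative numeric matrix; normalized to sum to one if not
#'   already (a warning is raised if the sum is off by more than 1e-6 and
#'   \code{normalize = FALSE}).
#' @param provenance character vector of factor tags.
#' @param normalize divide by the total so cells sum to one (default TRUE).
#' @param epsilon_cells optional two-column integer matrix of (row, col)
#'   indices that received the forbidden-but-observed epsilon.
#' @return Object of class \code{probability_matrix}.
#' @seealso \code{\link{build_phen}}, \code{\link{build_ab}},
#'   \code{\link{build_mor}}, \code{\link{null_matrix}},
#'   \code{\link{combine_probs}}
#' @export
probability_matrix <- function(probs, provenance, normalize = TRUE,
                               epsilon_cells = NULL) {
  if (is.data.frame(probs)) probs <- as.matrix(probs)
  if (!is.matrix(probs) || !is.numeric(probs))
    stop("`probs` must be a numeric matrix")
  if (missing(provenance) || length(provenance) == 0L)
    stop("provenance must name at least one factor")
  if (anyNA(probs) || any(probs < 0)) stop("probabilities must be >= 0")
  tot <- sum(probs)
  if (tot <= 0) stop("probability matrix sums to zero")
  if (normalize) probs <- probs / tot
  else if (abs(tot - 1) > 1e-6)
    warning("probability matrix sum differs from 1 by ", format(tot - 1))
  if (is.null(rownames(probs)))
    rownames(probs) <- paste0("plant_", seq_len(nrow(probs)))
  if (is.null(colnames(probs)))
    colnames(probs) <- paste0("bird_", seq_len(ncol(probs)))
  structure(probs, provenance = provenance,
            epsilon_cells = epsilon_cells,
            class = c("probability_matrix", "matrix"))
}

#' @export
print.probability_matrix <- function(x, digits = 4, ...) {
  eps <- attr(x, "epsilon_cells")
  cat(sprintf("probability_matrix [%s]: %d x %d, sum = %s%s\n",
              provenance_label(x), nrow(x), ncol(x),
              format(sum(x)),
              if (!is.null(eps) && nrow(eps) > 0L)
                sprintf(", %d epsilon cell(s)", nrow(eps)) else ""))
  print(round(unclass_matrix(x), digits))
  invisible(x)
}

#' @rdname probability_matrix
#' @param x a \code{probability_matrix}.
#' @export
provenance_label <- function(x) {
  paste(attr(x, "provenance"), collapse = "*")
}

#' Community phenology and abundance tables
#'
#' Bundles the four species x month tables behind the phenology and
#' abundance probability matrices: monthly flowering / presence scores
#' (0/1) and monthly abundances (flowers per hectare for plants, captures
#' per 100 net-hours for birds). All four tables must share the month axis.
#'
#' @param plant_phenology,bird_phenology 0/1 matrices, species x months.
#' @param plant_abundance,bird_abundance nonnegative matrices, species x
#'   months, same dimensions as the corresponding phenology table.
#' @return Object of class \code{community_tables} with element \code{M},
#'   the number of months with simultaneous data.
#' @export
community_tables <- function(plant_phenology, bird_phenology,
                             plant_abundance = NULL, bird_abundance = NULL) {
  chk01 <- function(x, nm) {
    x <- as.matrix(x)
    if (!all(x %in% c(0, 1)))
      stop(nm, " entries must be 0/1")
    x
  }
  chkpos <- function(x, nm, template) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (anyNA(x) || any(x < 0)) stop(nm, " entries must be >= 0")
    if (!identical(dim(x), dim(template)))
      stop(nm, " must match the corresponding phenology table's dimensions")
    x
  }
  pp <- chk01(plant_phenology, "plant_phenology")
  bp <- chk01(bird_phenology, "bird_phenology")
  if (ncol(pp) != ncol(bp))
    stop("plant and bird tables must share the month axis")
  if (ncol(pp) < 1L) stop("need at least one month")
  structure(list(plant_phenology = pp, bird_phenology = bp,
                 plant_abundance = chkpos(plant_abundance,
                                          "plant_abundance", pp),
                 bird_abundance = chkpos(bird_abundance,
                                         "bird_abundance", bp),
                 M = ncol(pp)),
            class = "community_tables")
}

#' @export
print.community_tables <- function(x, ...) {
  cat(sprintf("community_tables: %d plants, %d birds, M = %d months%s\n",
              nrow(x$plant_phenology), nrow(x$bird_phenology), x$M,
              if (is.null(x$plant_abundance)) " (phenology only)" else ""))
  invisible(x)
}

#' Morphology and legitimacy trait table
#'
#' Bird bill-length ranges (with the tongue-reach correction fraction),
#' plant corolla dimensions, the wide-flower exception flag, and the
#' legitimacy annotation used by the nectar-robber filter.
#'
#' @param birds data.frame with columns \code{species}, \code{bill_lo},
#'   \code{bill_hi} (mm), optional \code{tongue_fraction} (default 1/3,
#'   the assumed tongue extension beyond the bill) and \code{legitimacy}
#'   (\code{"legitimate"}, \code{"robber"} or \code{"unknown"}; default
#'   legitimate).
#' @param plants data.frame with columns \code{species}, \code{corolla_lo},
#'   \code{corolla_hi} (mm), optional \code{corolla_width} (mm) and
#'   \code{wide_flower} (logical: corolla wide enough for any bird's head,
#'   e.g. *Puya*; default FALSE).
#' @return Object of class \code{trait_table}.
#' @export
trait_table <- function(birds, plants) {
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(nm, " is missing column(s): ",
                           paste(miss, collapse = ", "))
    df
  }
  birds <- need(as.data.frame(birds), c("species", "bill_lo", "bill_hi"),
                "birds")
  plants <- need(as.data.frame(plants),
                 c("species", "corolla_lo", "corolla_hi"), "plants")
  if (is.null(birds$tongue_fraction)) birds$tongue_fraction <- 1 / 3
  if (is.null(birds$legitimacy)) birds$legitimacy <- "legitimate"
  if (is.null(plants$wide_flower)) plants$wide_flower <- FALSE
  if (is.null(plants$corolla_width)) plants$corolla_width <- NA_real_
  if (any(birds$bill_lo > birds$bill_hi))
    stop("bill_lo > bill_hi for: ",
         paste(birds$species[birds$bill_lo > birds$bill_hi], collapse = ", "))
  if (any(plants$corolla_lo > plants$corolla_hi))
    stop("corolla_lo > corolla_hi for: ",
         paste(plants$species[plants$corolla_lo > plants$corolla_hi],
               collapse = ", "))
  if (any(birds$bill_lo <= 0) || any(plants$corolla_lo <= 0))
    stop("lengths must be > 0")
  if (any(birds$tongue_fraction < 0 | birds$tongue_fraction > 1))
    stop("tongue_fraction must lie in [0, 1]")
  if (!all(birds$legitimacy %in% c("legitimate", "robber", "unknown")))
    stop("legitimacy must be one of legitimate/robber/unknown")
  if (anyDuplicated(birds$species) || anyDuplicated(plants$species))
    stop("duplicate species in trait table")
  structure(list(birds = birds, plants = plants), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d birds (%d robber-annotated), %d plants (%d wide-flowered)\n",
              nrow(x$birds), sum(x$birds$legitimacy == "robber"),
              nrow(x$plants), sum(x$plants$wide_flower)))
  invisible(x)
}

#' Interaction incidence table for sampling-completeness estimation
#'
#' Detection (0/1) of each unique plant x bird interaction across sampling
#' units (days), the input to the Chao2 estimator.
#'
#' @param detections 0/1 matrix, unique interactions x sampling units; each
#'   interaction must be detected in at least one unit.
#' @return Object of class \code{incidence_table} with element \code{m},
#'   the number of sampling units.
#' @export
incidence_table <- function(detections) {
  detections <- as.matrix(detections)
  if (!all(detections %in% c(0, 1)))
    stop("detections must be 0/1")
  if (any(rowSums(detections) == 0))
    stop("every interaction must be detected in at least one sampling unit")
  if (is.null(rownames(detections)))
    rownames(detections) <- paste0("interaction_", seq_len(nrow(detections)))
  structure(list(detections = detections, m = ncol(detections)),
            class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("incidence_table: %d interactions over %d sampling units\n",
              nrow(x$detections), x$m))
  invisible(x)
}
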