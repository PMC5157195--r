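#' Phenology (temporal-overlap) interaction probability matrix
#'
#' Multiplies the plant and bird monthly presence tables (species x months,
#' 0/1) so that each cell counts the months in which both partners were
#' present, then normalizes the overlap matrix so all cells sum to one.
#' Encodes the phenological-constraint hypothesis: pairs that overlap
#' longer in time are proportionally more likely to interact.
#'
#' @param ct a \code{\link{community_tables}}.
#' @param observed optional \code{\link{interaction_matrix}}; cells with
#'   zero overlap but positive observed counts receive the forbidden-but-
#'   observed epsilon (see \code{\link{repair_epsilon}}).
#' @param epsilon epsilon value, default 1e-8.
#' @return A \code{\link{probability_matrix}} with provenance \code{Phen}.
#' @export
build_phen <- function(ct, observed = NULL, epsilon = 1e-8) {
  stopifnot(inherits(ct, "community_tables"))
  O <- ct$plant_phenology %*% t(ct$bird_phenology)
  if (sum(O) == 0)
    stop("no temporal co-occurrence between any plant and bird")
  finish_probability(O, "Phen", observed, epsilon)
}

#' Abundance (neutrality) interaction probability matrix
#'
#' For each month, the outer product of plant flower densities (flowers/ha)
#' and bird capture rates (captures per 100 net-hours) is accumulated, and
#' the summed matrix is normalized to one. Encodes the neutrality
#' hypothesis: interaction frequencies proportional to the product of
#' partner abundances while both are present. Setting
#' \code{monthly = FALSE} instead uses study-total abundances (aggregate
#' outer product) for sensitivity analysis.
#'
#' @inheritParams build_phen
#' @param monthly align abundances month by month (default) or use study
#'   totals.
#' @return A \code{\link{probability_matrix}} with provenance \code{Ab}.
#' @export
build_ab <- function(ct, observed = NULL, monthly = TRUE, epsilon = 1e-8) {
  stopifnot(inherits(ct, "community_tables"))
  if (is.null(ct$plant_abundance) || is.null(ct$bird_abundance))
    stop("community_tables lacks abundance tables")
  A <- if (monthly) ct$plant_abundance %*% t(ct$bird_abundance)
       else outer(rowSums(ct$plant_abundance), rowSums(ct$bird_abundance))
  dimnames(A) <- list(rownames(ct$plant_abundance),
                      rownames(ct$bird_abundance))
  if (sum(A) == 0) stop("abundance product is identically zero")
  if (any(colSums(A) == 0))
    warning("all-zero column(s) in abundance product (species never ",
            "captured/flowering): ",
            paste(colnames(A)[colSums(A) == 0], collapse = ", "))
  finish_probability(A, "Ab", observed, epsilon)
}

#' Morphology (size-matching) interaction probability matrix
#'
#' Scores each plant-bird pair by the overlap between the bird's corrected
#' bill-length range (bill range times \code{1 + tongue_fraction}, to
#' account for tongue reach) and the flower's corolla-length range. With
#' corrected bill range [b_lo, b_hi] and flower lower limit f_lo:
#' \itemize{
#'   \item \code{b_lo >= f_lo}: the interaction is fully possible, score 1;
#'   \item \code{b_hi < f_lo}: forbidden, score 0;
#'   \item otherwise (default \code{"lower-limit"} rule): the proportion of
#'     the bill range reaching past the flower's lower limit,
#'     \code{(b_hi - f_lo) / (b_hi - b_lo)};
#'   \item \code{"jaccard"} rule (sensitivity alternative): length of the
#'     intersection of the two ranges over the length of their union.
#' }
#' Wide-flowered plants (e.g. *Puya*, whose flowers admit a bird's whole
#' head) score 1 for every bird. Forbidden cells with positive observed
#' counts receive the epsilon (default 1e-8, less probable than any
#' realizable case) so the multinomial likelihood remains defined. The
#' matrix is then normalized to sum to one.
#'
#' @param traits a \code{\link{trait_table}}.
#' @param observed optional \code{\link{interaction_matrix}} providing the
#'   label space and the observed counts for epsilon repair. Without it the
#'   trait table's species order is used.
#' @param rule overlap interpolation rule, see above.
#' @param epsilon epsilon value, default 1e-8.
#' @return A \code{\link{probability_matrix}} with provenance \code{Mor}.
#' @export
build_mor <- function(traits, observed = NULL,
                      rule = c("lower-limit", "jaccard"), epsilon = 1e-8) {
  stopifnot(inherits(traits, "trait_table"))
  rule <- match.arg(rule)
  tb <- traits$birds
  tp <- traits$plants
  if (!is.null(observed)) {
    observed <- as_interaction_matrix(observed)
    missb <- setdiff(colnames(observed), tb$species)
    missp <- setdiff(rownames(observed), tp$species)
    if (length(missb) || length(missp))
      stop("network species missing from trait table: ",
           paste(c(missp, missb), collapse = ", "))
    extra <- c(setdiff(tp$species, rownames(observed)),
               setdiff(tb$species, colnames(observed)))
    if (length(extra))
      warning("trait species not in the network ignored: ",
              paste(extra, collapse = ", "))
    tb <- tb[match(colnames(observed), tb$species), ]
    tp <- tp[match(rownames(observed), tp$species), ]
  }
  b_lo <- tb$bill_lo * (1 + tb$tongue_fraction)
  b_hi <- tb$bill_hi * (1 + tb$tongue_fraction)
  f_lo <- tp$corolla_lo
  f_hi <- tp$corolla_hi
  M <- matrix(0, nrow(tp), nrow(tb),
              dimnames = list(tp$species, tb$species))
  for (j in seq_len(nrow(tb))) {
    v <- if (rule == "lower-limit") {
      ifelse(b_lo[j] >= f_lo, 1,
             ifelse(b_hi[j] < f_lo, 0,
                    (b_hi[j] - f_lo) / (b_hi[j] - b_lo[j])))
    } else {
      isect <- pmax(pmin(b_hi[j], f_hi) - pmax(b_lo[j], f_lo), 0)
      un <- pmax(b_hi[j], f_hi) - pmin(b_lo[j], f_lo)
      ifelse(un > 0, isect / un, 1)
    }
    M[, j] <- v
  }
  M[tp$wide_flower, ] <- 1
  if (sum(M) == 0) stop("morphology matrix is identically zero")
  finish_probability(M, "Mor", observed, epsilon)
}

#' Uniform null probability matrix
#'
#' Every pair of observed plant and bird species has the same interaction
#' probability 1/(I*J).
#'
#' @param I,J numbers of plant and bird species (or give \code{like}).
#' @param like optional matrix whose dimensions and labels to copy.
#' @return A \code{\link{probability_matrix}} with provenance \code{Null}.
#' @export
null_matrix <- function(I, J, like = NULL) {
  if (!is.null(like)) {
    I <- nrow(like); J <- ncol(like)
    dn <- dimnames(like)
  } else dn <- list(paste0("plant_", seq_len(I)), paste0("bird_", seq_len(J)))
  probability_matrix(matrix(1 / (I * J), I, J, dimnames = dn),
                     provenance = "Null", normalize = FALSE)
}

#' Combine probability matrices by elementwise product
#'
#' Multiplies the given matrices cell by cell and renormalizes, yielding
#' the joint hypothesis (e.g. abundance x phenology). Combining with the
#' uniform null matrix leaves a matrix unchanged. Provenance tags are
#' concatenated.
#'
#' @param ... two or more \code{\link{probability_matrix}} objects on the
#'   same label space (or a single list of them).
#' @param observed optional \code{\link{interaction_matrix}} for epsilon
#'   repair of cells zeroed by the product.
#' @param epsilon epsilon value, default 1e-8.
#' @return A combined \code{\link{probability_matrix}}.
#' @export
combine_probs <- function(..., observed = NULL, epsilon = 1e-8) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1L]]) && !is.matrix(ms[[1L]]))
    ms <- ms[[1L]]
  if (length(ms) < 2L) stop("need at least two matrices to combine")
  base <- ms[[1L]]
  prod <- unclass_matrix(base)
  prov <- attr(base, "provenance")
  for (m in ms[-1L]) {
    if (!identical(dimnames(m), dimnames(base)))
      stop("probability matrices must share an identical label space")
    prod <- prod * unclass_matrix(m)
    prov <- c(prov, attr(m, "provenance"))
  }
  prov <- setdiff(unique(prov), if (length(unique(prov)) > 1L) "Null")
  if (sum(prod) == 0) stop("combined matrix is identically zero")
  finish_probability(prod, prov, observed, epsilon)
}

#' Repair forbidden-but-observed zero cells
#'
#' Any cell with probability zero but a positive observed count makes the
#' multinomial likelihood undefined; such cells are set to a tiny epsilon
#' (default 1e-8, less probable than any realizable cell) and the matrix is
#' renormalized. The affected cells are recorded in the
#' \code{epsilon_cells} attribute and reported with a warning.
#'
#' @param pm a \code{\link{probability_matrix}}.
#' @param observed an \code{\link{interaction_matrix}} on the same labels.
#' @param epsilon replacement value before renormalization.
#' @return The repaired \code{\link{probability_matrix}}.
#' @export
repair_epsilon <- function(pm, observed, epsilon = 1e-8) {
  obs <- unclass_matrix(as_interaction_matrix(observed))
  x <- unclass_matrix(pm)
  if (!identical(dim(x), dim(obs)))
    stop("probability and observed matrices differ in shape")
  hit <- which(x == 0 & obs > 0, arr.ind = TRUE)
  if (nrow(hit) > 0L) {
    x[hit] <- epsilon
    warning(sprintf(
      "%d forbidden-but-observed cell(s) set to epsilon = %g: %s",
      nrow(hit), epsilon,
      paste(sprintf("[%s, %s]", rownames(x)[hit[, 1L]],
                    colnames(x)[hit[, 2L]]), collapse = "; ")))
  }
  probability_matrix(x, provenance = attr(pm, "provenance"),
                     normalize = TRUE,
                     epsilon_cells = if (nrow(hit)) hit else NULL)
}

finish_probability <- function(x, provenance, observed, epsilon) {
  pm <- probability_matrix(x, provenance = provenance, normalize = TRUE)
  if (!is.null(observed)) pm <- repair_epsilon(pm, observed, epsilon)
  pm
}
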