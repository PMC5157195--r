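#' Multinomial log-likelihood of an observed network under a probability
#' matrix
#'
#' Treats the N observed visits as one multinomial draw over the I*J
#' cells with cell probabilities \eqn{p_{ij}}:
#' \deqn{\ln L = \ln N! - \sum_{ij} \ln a_{ij}! + \sum_{ij} a_{ij} \ln p_{ij}.}
#' Log-factorials use \code{lgamma} so totals in the hundreds and beyond do
#' not overflow. A zero probability under a positive count is an error;
#' apply \code{\link{repair_epsilon}} first.
#'
#' @param obs an \code{\link{interaction_matrix}}.
#' @param pm a \code{\link{probability_matrix}} on the same label space.
#' @return The log-likelihood (0 for an empty network).
#' @export
multinomial_loglik <- function(obs, pm) {
  a <- unclass_matrix(as_interaction_matrix(obs))
  p <- unclass_matrix(pm)
  if (!identical(dim(a), dim(p)) ||
      !identical(rownames(a), rownames(p)) ||
      !identical(colnames(a), colnames(p)))
    stop("observed and probability matrices must share the same label space")
  if (any(p == 0 & a > 0))
    stop("zero probability under a positive count; apply repair_epsilon()")
  N <- sum(a)
  if (N == 0) return(0)
  pos <- a > 0
  lgamma(N + 1) - sum(lgamma(a + 1)) + sum(a[pos] * log(p[pos]))
}

#' Number of parameters charged to a model in AIC
#'
#' Two conventions: \code{"species"} charges (number of species, plants
#' plus birds) parameters per factor entering the probability matrix
#' (e.g. with 44 species: 44 for one factor, 88 for two, 132 for three);
#' \code{"factors"} charges simply the number of factors (1, 2 or 3). The
#' uniform null matrix counts as one factor under either convention.
#'
#' @param pm a \code{\link{probability_matrix}} (its provenance tag gives
#'   the factor count).
#' @param S total number of species, I + J.
#' @param convention \code{"species"} or \code{"factors"}.
#' @return Integer parameter count k.
#' @export
count_parameters <- function(pm, S, convention = c("species", "factors")) {
  convention <- match.arg(convention)
  nf <- max(length(attr(pm, "provenance")), 1L)
  if (convention == "species") as.integer(S) * nf else nf
}

#' Rank interaction-probability models by AIC
#'
#' Computes the multinomial log-likelihood of the observed network under
#' each candidate probability matrix, charges parameters per
#' \code{\link{count_parameters}}, and ranks by \eqn{AIC = -2 \ln L + 2k}
#' (or AICc with the small-sample correction if requested). Ties keep the
#' input order. By default, zero cells under positive observed counts are
#' epsilon-repaired automatically.
#'
#' @param obs an \code{\link{interaction_matrix}}.
#' @param pms list of \code{\link{probability_matrix}} objects (two or
#'   more); names default to the provenance labels.
#' @param convention parameter-counting convention, see
#'   \code{\link{count_parameters}}.
#' @param aicc use the small-sample corrected AICc (default plain AIC, as
#'   is conventional for this analysis).
#' @param repair apply \code{\link{repair_epsilon}} where needed (default
#'   TRUE).
#' @param epsilon epsilon for repair.
#' @return A \code{model_ranking} data.frame sorted by ascending AIC with
#'   columns \code{model}, \code{factors}, \code{lnL}, \code{k},
#'   \code{AIC}, \code{dAIC}.
#' @export
rank_models <- function(obs, pms, convention = c("species", "factors"),
                        aicc = FALSE, repair = TRUE, epsilon = 1e-8) {
  convention <- match.arg(convention)
  obs <- as_interaction_matrix(obs)
  if (!is.list(pms) || length(pms) < 2L)
    stop("supply a list of at least two candidate probability matrices")
  nms <- names(pms)
  labs <- vapply(pms, provenance_label, character(1L))
  if (is.null(nms)) nms <- labs else nms[!nzchar(nms)] <- labs[!nzchar(nms)]
  S <- nrow(obs) + ncol(obs)
  N <- attr(obs, "N")
  rows <- lapply(seq_along(pms), function(i) {
    pm <- pms[[i]]
    if (repair && any(unclass_matrix(pm) == 0 & unclass_matrix(obs) > 0))
      pm <- repair_epsilon(pm, obs, epsilon)
    lnL <- multinomial_loglik(obs, pm)
    k <- count_parameters(pm, S, convention)
    aic <- -2 * lnL + 2 * k
    if (aicc) {
      if (N - k - 1 <= 0)
        stop("AICc undefined: N - k - 1 <= 0 for model ", nms[i])
      aic <- aic + 2 * k * (k + 1) / (N - k - 1)
    }
    data.frame(model = nms[i],
               factors = length(attr(pm, "provenance")),
               lnL = lnL, k = k, AIC = aic)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC, seq_len(nrow(out))), , drop = FALSE]
  out$dAIC <- out$AIC - out$AIC[1L]
  rownames(out) <- NULL
  class(out) <- c("model_ranking", "data.frame")
  attr(out, "convention") <- convention
  out
}

#' @export
print.model_ranking <- function(x, digits = 2, ...) {
  cat(sprintf("multinomial AIC ranking (%s convention):\n",
              attr(x, "convention")))
  y <- as.data.frame(x)
  y$lnL <- round(y$lnL, digits)
  y$AIC <- round(y$AIC, digits)
  y$dAIC <- round(y$dAIC, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
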