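#' Draw a random network from a probability matrix with full species
#' coverage
#'
#' Probability-constrained randomization: generates an integer network
#' with the observed total N from cell probabilities \eqn{p_{ij}} while
#' guaranteeing that every species receives at least one interaction.
#' Two phases:
#' \enumerate{
#'   \item coverage - visit the plant rows in random order, drawing one
#'     partner per row with the row's within-row probabilities; then give
#'     each still-empty bird column one interaction, drawing its plant with
#'     the within-column probabilities;
#'   \item remainder - distribute the remaining interactions in one
#'     multinomial draw over the full matrix with probabilities
#'     \eqn{p_{ij}}.
#' }
#' The coverage phase biases cell frequencies slightly away from
#' \eqn{p_{ij}} (each row is forced one interaction regardless of its row
#' total probability); the bias shrinks as N grows past I + J.
#'
#' @param pm a \code{\link{probability_matrix}}; every row and column must
#'   have positive total probability.
#' @param N total interactions to assign; must be at least max(I, J), and
#'   in the worst case the coverage phase alone needs up to I + (number of
#'   columns not hit) interactions, so an error is raised if coverage
#'   exceeds N.
#' @param seed optional integer seed for reproducibility (the current RNG
#'   state is used when NULL).
#' @return An \code{\link{interaction_matrix}} with total N and no empty
#'   margins.
#' @export
sample_network <- function(pm, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- unclass_matrix(pm)
  I <- nrow(p); J <- ncol(p)
  if (N < max(I, J))
    stop(sprintf("N = %d cannot cover %d plants and %d birds", N, I, J))
  if (any(rowSums(p) == 0))
    stop("zero-probability plant row(s): coverage impossible for ",
         paste(rownames(p)[rowSums(p) == 0], collapse = ", "))
  if (any(colSums(p) == 0))
    stop("zero-probability bird column(s): coverage impossible for ",
         paste(colnames(p)[colSums(p) == 0], collapse = ", "))
  x <- matrix(0L, I, J, dimnames = dimnames(p))
  for (i in sample.int(I)) {
    j <- sample.int(J, 1L, prob = p[i, ])
    x[i, j] <- x[i, j] + 1L
  }
  for (j in which(colSums(x) == 0)) {
    i <- sample.int(I, 1L, prob = p[, j])
    x[i, j] <- x[i, j] + 1L
  }
  used <- sum(x)
  if (used > N)
    stop(sprintf(
      "N = %d too small: coverage phase alone needed %d interactions",
      N, used))
  if (N > used)
    x <- x + matrix(stats::rmultinom(1L, N - used, as.vector(p)), I, J)
  interaction_matrix(x)
}

#' Ensemble metric distribution under a probability-matrix null model
#'
#' Draws \code{reps} random networks from \code{pm} at total N via
#' \code{\link{sample_network}}, computes all
#' \code{\link{network_metrics}} on each, and summarizes each metric by
#' its mean and 95 percent percentile interval (2.5 and 97.5 percentiles).
#' Replicates on which a metric computation fails are rejected, logged and
#' resampled.
#'
#' @param pm a \code{\link{probability_matrix}}.
#' @param N total interactions per replicate.
#' @param reps number of replicates (default 1000).
#' @param seed optional integer seed; recorded in the result.
#' @param evenness_denominator passed to \code{\link{network_metrics}}.
#' @return An \code{ensemble_summary} data.frame (one row per metric:
#'   \code{mean}, \code{ci_low}, \code{ci_high}) with attributes
#'   \code{reps}, \code{seed}, \code{model} (provenance label),
#'   \code{rejected} and \code{values} (the reps x metrics draw matrix).
#' @export
ensemble_metrics <- function(pm, N, reps = 1000, seed = NULL,
                             evenness_denominator = "cells") {
  if (reps < 2L) stop("need at least 2 replicates")
  if (!is.null(seed)) set.seed(seed)
  metric_names <- c("connectance", "wnodf", "interaction_evenness",
                    "h2prime", "asymmetry_plants", "asymmetry_birds")
  vals <- matrix(NA_real_, reps, length(metric_names),
                 dimnames = list(NULL, metric_names))
  rejected <- 0L
  for (r in seq_len(reps)) {
    repeat {
      ms <- tryCatch(
        unlist(network_metrics(sample_network(pm, N),
                               evenness_denominator), use.names = FALSE),
        error = function(e) NULL)
      if (!is.null(ms)) break
      rejected <- rejected + 1L
      if (rejected > 100L * reps)
        stop("too many rejected replicates; metrics fail on this ensemble")
    }
    vals[r, ] <- ms
  }
  if (rejected > 0L)
    warning(rejected, " replicate(s) rejected and resampled")
  ci <- apply(vals, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(metric = metric_names, mean = colMeans(vals),
                    ci_low = ci[1L, ], ci_high = ci[2L, ],
                    row.names = NULL)
  structure(out, reps = reps, seed = seed,
            model = provenance_label(pm), rejected = rejected,
            values = vals,
            class = c("ensemble_summary", "data.frame"))
}

#' @export
print.ensemble_summary <- function(x, digits = 4, ...) {
  cat(sprintf("ensemble of %d networks under model %s%s:\n",
              attr(x, "reps"), attr(x, "model"),
              if (!is.null(attr(x, "seed")))
                sprintf(" (seed %d)", attr(x, "seed")) else ""))
  y <- as.data.frame(x)
  y[-1L] <- lapply(y[-1L], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Compare observed metrics with null-ensemble confidence intervals
#'
#' For each candidate model's ensemble, reports whether each observed
#' metric falls inside, below or above the ensemble's 95 percent interval
#' (closed interval: a value exactly on an endpoint is "inside"). A model
#' whose interval contains the observed value is consistent with that
#' metric of network structure.
#'
#' @param obs an \code{\link{interaction_matrix}}.
#' @param summaries one \code{ensemble_summary} or a (optionally named)
#'   list of them, e.g. one per probability model.
#' @param evenness_denominator passed to \code{\link{network_metrics}}.
#' @return A \code{verdict_table} data.frame with columns \code{model},
#'   \code{metric}, \code{observed}, \code{mean}, \code{ci_low},
#'   \code{ci_high}, \code{verdict}.
#' @export
compare_observed <- function(obs, summaries,
                             evenness_denominator = "cells") {
  if (inherits(summaries, "ensemble_summary")) summaries <- list(summaries)
  obs_m <- unlist(network_metrics(as_interaction_matrix(obs),
                                  evenness_denominator))
  nms <- names(summaries)
  if (is.null(nms)) nms <- vapply(summaries, attr, "", "model")
  out <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- as.data.frame(summaries[[i]])
    v <- obs_m[s$metric]
    data.frame(model = nms[i], metric = s$metric, observed = unname(v),
               mean = s$mean, ci_low = s$ci_low, ci_high = s$ci_high,
               verdict = ifelse(v < s$ci_low, "below",
                                ifelse(v > s$ci_high, "above", "inside")))
  }))
  rownames(out) <- NULL
  class(out) <- c("verdict_table", "data.frame")
  out
}

#' @export
print.verdict_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
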