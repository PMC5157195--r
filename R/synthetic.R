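#' Scenario configuration for the synthetic community generator
#'
#' Describes a synthetic bird-flowering-plant community: dimensions,
#' seasonal presence windows, abundance distributions, trait distributions
#' and the generative driver of observations. Defaults mirror the
#' dimensional envelope of a 15-month Andean elfin-forest study: 27 plants,
#' 17 birds, 278 observed visits, roughly 5/17 of birds annotated as
#' nectar robbers.
#'
#' @param I,J,M numbers of plant species, bird species and months.
#' @param N_obs total observed interactions to draw.
#' @param plant_window,bird_window integer length-2 ranges (months) for
#'   the contiguous (wrap-around) flowering / presence window widths.
#'   Plants flower for part of the year; birds are longer-resident.
#' @param plant_abund_meanlog,plant_abund_sdlog log-normal parameters for
#'   species-level flower density (flowers/ha): right-skewed, a few mass
#'   bloomers and many sparse species.
#' @param bird_abund_meanlog,bird_abund_sdlog log-normal parameters for
#'   bird capture rate (captures per 100 net-hours).
#' @param monthly_jitter_sdlog log-normal monthly noise on abundances.
#' @param bill_range,corolla_range ranges (mm) from which species' mean
#'   bill and corolla lengths are drawn uniformly.
#' @param range_halfwidth relative intraspecific half-width of each trait
#'   range (lo/hi = mean * (1 -/+ halfwidth)).
#' @param wide_flower_frac fraction of plants whose flowers admit any
#'   bird's head (*Puya*-like).
#' @param robber_frac fraction of birds annotated as nectar robbers.
#' @param driver which probability matrix generates observations:
#'   \code{"Phen"}, \code{"Ab"}, \code{"Mor"} or \code{"Null"}.
#' @param seed optional integer seed.
#' @return Object of class \code{scenario_config}.
#' @export
scenario_config <- function(I = 27, J = 17, M = 15, N_obs = 278,
                            plant_window = c(3, 10),
                            bird_window = c(6, 15),
                            plant_abund_meanlog = log(200),
                            plant_abund_sdlog = 1.5,
                            bird_abund_meanlog = log(1.5),
                            bird_abund_sdlog = 0.8,
                            monthly_jitter_sdlog = 0.3,
                            bill_range = c(9, 34),
                            corolla_range = c(8, 45),
                            range_halfwidth = 0.12,
                            wide_flower_frac = 0.05,
                            robber_frac = 5 / 17,
                            driver = c("Phen", "Ab", "Mor", "Null"),
                            seed = NULL) {
  driver <- match.arg(driver)
  stopifnot(I >= 2, J >= 2, M >= 1, N_obs >= 1,
            length(plant_window) == 2L, length(bird_window) == 2L)
  if (plant_window[2L] > M || bird_window[2L] > M)
    stop("presence-window width cannot exceed M months")
  if (plant_window[1L] < 1 || bird_window[1L] < 1)
    stop("presence-window width must be at least one month")
  structure(as.list(environment()), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "scenario_config: %d plants x %d birds, M = %d months, N_obs = %d, driver = %s\n",
    x$I, x$J, x$M, x$N_obs, x$driver))
  invisible(x)
}

# contiguous presence window of `width` months starting at `start`,
# wrapping around the M-month axis
presence_window <- function(start, width, M) {
  months <- ((start - 1L) + seq_len(width) - 1L) %% M + 1L
  out <- integer(M)
  out[months] <- 1L
  out
}

#' Generate a synthetic community (phenology, abundance, traits)
#'
#' Emulates the field tables of a visitation-network study: contiguous
#' (wrap-around) seasonal presence windows per species, log-normal
#' species-level abundances applied within the window with monthly
#' log-normal jitter and zero outside it, and bill/corolla trait ranges
#' whose overlap produces forbidden pairs at a rate set by the trait
#' distributions. Robber and wide-flower annotations are drawn at the
#' configured fractions (always rounding to at least one robber when
#' \code{robber_frac > 0}).
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @return List with elements \code{community}
#'   (\code{\link{community_tables}}) and \code{traits}
#'   (\code{\link{trait_table}}).
#' @export
generate_community <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  plants <- sprintf("plant_%02d", seq_len(cfg$I))
  birds <- sprintf("bird_%02d", seq_len(cfg$J))
  months <- sprintf("month_%02d", seq_len(cfg$M))
  win <- function(n, range) {
    # index into the width choices explicitly: sample(x, ...) with a
    # scalar x would sample from 1:x instead
    choices <- seq.int(range[1L], range[2L])
    widths <- choices[sample.int(length(choices), n, replace = TRUE)]
    starts <- sample.int(cfg$M, n, replace = TRUE)
    t(mapply(presence_window, starts, widths, MoreArgs = list(M = cfg$M)))
  }
  pp <- win(cfg$I, cfg$plant_window)
  bp <- win(cfg$J, cfg$bird_window)
  dimnames(pp) <- list(plants, months)
  dimnames(bp) <- list(birds, months)
  abund <- function(phen, meanlog, sdlog) {
    lvl <- stats::rlnorm(nrow(phen), meanlog, sdlog)
    jit <- matrix(stats::rlnorm(length(phen), 0, cfg$monthly_jitter_sdlog),
                  nrow(phen))
    phen * lvl * jit
  }
  pa <- abund(pp, cfg$plant_abund_meanlog, cfg$plant_abund_sdlog)
  ba <- abund(bp, cfg$bird_abund_meanlog, cfg$bird_abund_sdlog)
  ct <- community_tables(pp, bp, pa, ba)
  mk_range <- function(n, range) {
    mid <- stats::runif(n, range[1L], range[2L])
    cbind(lo = mid * (1 - cfg$range_halfwidth),
          hi = mid * (1 + cfg$range_halfwidth))
  }
  br <- mk_range(cfg$J, cfg$bill_range)
  cr <- mk_range(cfg$I, cfg$corolla_range)
  n_rob <- if (cfg$robber_frac > 0) max(1L, round(cfg$robber_frac * cfg$J))
           else 0L
  legit <- rep("legitimate", cfg$J)
  if (n_rob > 0L) legit[sample.int(cfg$J, n_rob)] <- "robber"
  n_wide <- round(cfg$wide_flower_frac * cfg$I)
  wide <- rep(FALSE, cfg$I)
  if (n_wide > 0L) wide[sample.int(cfg$I, n_wide)] <- TRUE
  tt <- trait_table(
    birds = data.frame(species = birds, bill_lo = br[, "lo"],
                       bill_hi = br[, "hi"], tongue_fraction = 1 / 3,
                       legitimacy = legit),
    plants = data.frame(species = plants, corolla_lo = cr[, "lo"],
                        corolla_hi = cr[, "hi"],
                        corolla_width = cr[, "lo"] / 4,
                        wide_flower = wide))
  list(community = ct, traits = tt)
}

#' Driver probability matrix for a synthetic scenario
#'
#' Convenience wrapper building the generating probability matrix named by
#' \code{cfg$driver} from generated community tables.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @param community,traits output of \code{\link{generate_community}}.
#' @return A \code{\link{probability_matrix}}.
#' @export
driver_matrix <- function(cfg, community, traits) {
  switch(cfg$driver,
         Phen = build_phen(community),
         Ab = build_ab(community),
         Mor = build_mor(traits),
         Null = null_matrix(cfg$I, cfg$J,
                            like = matrix(0, cfg$I, cfg$J,
                                          dimnames = list(
                                            traits$plants$species,
                                            traits$birds$species))))
}

#' Draw an observed network from a generative probability matrix
#'
#' One multinomial draw of \code{N_obs} visits over the cells - the raw
#' observation process. Unlike \code{\link{sample_network}} there is no
#' every-species-covered constraint (nature does not guarantee that every
#' species is seen); empty margins are allowed and handled downstream by
#' \code{\link{drop_empty_margins}}.
#'
#' @param pm a \code{\link{probability_matrix}}.
#' @param N_obs number of visits to draw.
#' @param seed optional integer seed.
#' @return An \code{\link{interaction_matrix}} (possibly with empty
#'   margins).
#' @export
generate_observations <- function(pm, N_obs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- unclass_matrix(pm)
  x <- matrix(stats::rmultinom(1L, N_obs, as.vector(p)),
              nrow(p), dimnames = dimnames(p))
  interaction_matrix(x)
}

#' Generate a per-day incidence table from an observed network
#'
#' Each realized interaction (nonzero cell) is independently detected on
#' each sampling day with probability \eqn{1 - (1 - q)^{a_{ij}}}, where
#' \eqn{q} is the per-visit daily detection probability - commoner
#' interactions are seen on more days. Interactions never detected are
#' dropped (as in real incidence data, which only contains what was seen).
#'
#' @param m an \code{\link{interaction_matrix}}.
#' @param n_days number of sampling days.
#' @param detection_prob per-visit daily detection probability in (0, 1].
#' @param seed optional integer seed.
#' @return An \code{\link{incidence_table}}.
#' @export
generate_incidence <- function(m, n_days, detection_prob, seed = NULL) {
  if (detection_prob <= 0 || detection_prob > 1)
    stop("detection_prob must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  x <- unclass_matrix(as_interaction_matrix(m))
  nz <- which(x > 0, arr.ind = TRUE)
  q <- 1 - (1 - detection_prob)^x[nz]
  det <- matrix(stats::rbinom(nrow(nz) * n_days, 1L, rep(q, n_days)),
                nrow(nz), n_days)
  rownames(det) <- paste(rownames(x)[nz[, 1L]], colnames(x)[nz[, 2L]],
                         sep = " x ")
  det <- det[rowSums(det) > 0, , drop = FALSE]
  if (nrow(det) == 0L)
    stop("no interaction detected on any day; raise detection_prob")
  incidence_table(det)
}
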