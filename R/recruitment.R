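#' Configure a webRDS recruitment simulation
#'
#' Parameters of the chain-referral process and of the fabricated submission
#' table. Defaults follow a web-based RDS design: 20 seeds, up to 4 electronic
#' invitations per participant, voluntary participation, sampling without
#' replacement.
#'
#' @param n_seeds Number of seeds (>= 1).
#' @param seed_selection \code{"uniform"} or \code{"by_trait"}; with
#'   \code{"by_trait"}, \code{seed_trait = list(name=, category=)} restricts
#'   seed draws to one category.
#' @param seed_trait See \code{seed_selection}.
#' @param coupons_per_participant Maximum invitations each participant may send
#'   (>= 0; default 4).
#' @param participation_probability Probability an individual is willing to
#'   participate if invited; willingness is drawn once per person, so a
#'   decliner stays out even when re-invited.
#' @param with_replacement If \code{FALSE} (default) no individual can be
#'   recruited twice.
#' @param max_waves Stop after this many waves (\code{Inf} = until die-out).
#' @param rng_seed Master integer seed for the simulation and fabrication.
#' @param invalid_injection List of rates in \[0, 1\]: \code{underage_rate},
#'   \code{duplicate_token_rate}, \code{shared_ip_rate},
#'   \code{fast_completion_rate}. Applied independently to non-seed records.
#' @param network_size_missing_rate Probability a participant declines the
#'   network-size question.
#' @param network_size_noise List with \code{fraction}: the reported 7-day
#'   network size is Poisson with mean \code{fraction * true_degree}.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_seeds = 20,
                              seed_selection = c("uniform", "by_trait"),
                              seed_trait = NULL,
                              coupons_per_participant = 4,
                              participation_probability = 0.35,
                              with_replacement = FALSE,
                              max_waves = Inf,
                              rng_seed = 1,
                              invalid_injection = list(underage_rate = 0.03,
                                                       duplicate_token_rate = 0.07,
                                                       shared_ip_rate = 0.10,
                                                       fast_completion_rate = 0.02),
                              network_size_missing_rate = 0.10,
                              network_size_noise = list(fraction = 0.7)) {
  if (n_seeds < 1) stopf("n_seeds must be >= 1")
  if (coupons_per_participant < 0) stopf("coupons_per_participant must be >= 0")
  assert_prob(participation_probability, "participation_probability")
  assert_prob(network_size_missing_rate, "network_size_missing_rate")
  for (r in names(invalid_injection)) assert_prob(invalid_injection[[r]], r)
  structure(list(n_seeds = as.integer(n_seeds),
                 seed_selection = match.arg(seed_selection),
                 seed_trait = seed_trait,
                 coupons_per_participant = as.integer(coupons_per_participant),
                 participation_probability = participation_probability,
                 with_replacement = isTRUE(with_replacement),
                 max_waves = max_waves,
                 rng_seed = as.integer(rng_seed),
                 invalid_injection = invalid_injection,
                 network_size_missing_rate = network_size_missing_rate,
                 network_size_noise = network_size_noise),
            class = "simulation_config")
}

#' Simulate webRDS chain-referral recruitment
#'
#' Recruitment runs in discrete waves. Each participant invites a uniform
#' random subset of its still-eligible graph neighbours, of size at most
#' \code{coupons_per_participant}. Participation is voluntary: each individual
#' is independently willing to participate with
#' \code{participation_probability}, drawn once per person, so someone who
#' declines an invitation does not join later through a different recruiter
#' (seeds are willing by construction). Without replacement, already-sampled
#' individuals are ineligible; together with per-person willingness this
#' reproduces the local-saturation die-out of real chain-referral samples:
#' chains stop because participants' neighbourhoods are exhausted even while
#' most of the population remains unsampled.
#' Submission timestamps (days from study start) increase along every chain.
#'
#' @param pop An \code{rds_population}.
#' @param config A [simulation_config()].
#' @return An object of class \code{rds_forest}: a data frame with one row per
#'   sampled participant and columns \code{id} (record id), \code{individual}
#'   (population id), \code{recruiter_id} (\code{NA} for seeds), \code{wave}
#'   (seeds are 0), \code{chain} (root record id) and \code{timestamp}.
#' @export
simulate_recruitment <- function(pop, config) {
  stopifnot(inherits(pop, "rds_population"), inherits(config, "simulation_config"))
  n <- nrow(pop$attributes)
  if (config$n_seeds > n) stopf("n_seeds exceeds population size")
  set.seed(derive_seed(config$rng_seed, 23L))
  adj <- lapply(igraph::as_adj_list(pop$graph), as.integer)

  candidates <- seq_len(n)
  if (config$seed_selection == "by_trait") {
    st <- config$seed_trait
    if (is.null(st)) stopf("seed_selection='by_trait' needs seed_trait")
    candidates <- which(pop$attributes[[st$name]] == st$category)
    if (length(candidates) < config$n_seeds)
      stopf("not enough individuals in seed trait category")
  }
  seeds <- resample(candidates, config$n_seeds)
  willing <- stats::runif(n) < config$participation_probability
  willing[seeds] <- TRUE

  individual <- seeds
  recruiter <- rep(NA_integer_, length(seeds))   # row index of recruiter
  wave <- rep(0L, length(seeds))
  timestamp <- sort(stats::runif(length(seeds), 0, 3))
  sampled <- rep(FALSE, n)
  sampled[seeds] <- TRUE
  frontier <- seq_along(seeds)                   # row indices of current wave
  w <- 0L
  while (length(frontier) > 0 && w < config$max_waves &&
         config$coupons_per_participant > 0) {
    w <- w + 1L
    new_frontier <- integer(0)
    for (row in resample(frontier)) {            # random order within a wave
      ind <- individual[row]
      nb <- adj[[ind]]
      if (!config$with_replacement) nb <- nb[!sampled[nb]]
      if (length(nb) == 0) next
      k <- min(config$coupons_per_participant, length(nb))
      invited <- resample(nb, k)
      joins <- invited[willing[invited]]
      for (j in joins) {
        if (!config$with_replacement && sampled[j]) next  # taken earlier this wave
        individual <- c(individual, j)
        recruiter <- c(recruiter, row)
        wave <- c(wave, w)
        timestamp <- c(timestamp, timestamp[row] + 0.25 + stats::rexp(1, 1 / 2))
        sampled[j] <- TRUE
        new_frontier <- c(new_frontier, length(individual))
      }
    }
    frontier <- new_frontier
  }

  id <- sprintf("r%04d", seq_along(individual))
  chain_row <- seq_along(individual)
  for (i in seq_along(individual))
    if (!is.na(recruiter[i])) chain_row[i] <- chain_row[recruiter[i]]
  forest <- data.frame(id = id,
                       individual = individual,
                       recruiter_id = ifelse(is.na(recruiter), NA_character_,
                                             id[recruiter]),
                       wave = wave,
                       chain = id[chain_row],
                       timestamp = timestamp,
                       stringsAsFactors = FALSE)
  class(forest) <- c("rds_forest", "data.frame")
  attr(forest, "n_population") <- n
  forest
}

#' @export
print.rds_forest <- function(x, ...) {
  cat(sprintf("Recruitment forest: %d participants, %d seeds, max wave %d\n",
              nrow(x), sum(is.na(x$recruiter_id)), max(x$wave)))
  invisible(x)
}

#' Plot recruitment chains as trees
#'
#' @param x An \code{rds_forest}.
#' @param ... Passed to \code{plot.igraph}.
#' @export
plot.rds_forest <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = x$recruiter_id[!is.na(x$recruiter_id)],
               to = x$id[!is.na(x$recruiter_id)]),
    vertices = data.frame(name = x$id))
  igraph::plot.igraph(g, layout = igraph::layout_as_tree(g,
                        root = which(is.na(x$recruiter_id))),
                      vertex.size = 2, vertex.label = NA,
                      edge.arrow.size = 0.2, ...)
  invisible(x)
}

# recompute wave numbers from a parent map given in record order
recompute_waves <- function(ids, parent_ids) {
  wave <- rep(NA_integer_, length(ids))
  idx <- match(parent_ids, ids)
  remaining <- seq_along(ids)
  wave[is.na(parent_ids)] <- 0L
  repeat {
    todo <- which(is.na(wave) & !is.na(wave[idx]))
    if (length(todo) == 0) break
    wave[todo] <- wave[idx[todo]] + 1L
  }
  if (anyNA(wave)) stopf("parent map is not a forest (cycle or missing root)")
  wave
}
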