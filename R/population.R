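#' Describe a synthetic hidden population
#'
#' Bundles the parameters of the synthetic social network over which webRDS
#' recruitment is simulated: its size, degree model, categorical traits with
#' optional homophily, and a geographic (province) structure with its own
#' homophily level.
#'
#' @param n_individuals Number of individuals (at least 2).
#' @param degree_model A list with element \code{model}, one of
#'   \code{"poisson"}, \code{"powerlaw"} or \code{"regular"}, plus its
#'   parameters: \code{lambda} (poisson), \code{exponent} and \code{max_degree}
#'   (powerlaw), \code{degree} (regular).
#' @param traits A list of trait specifications from [trait_spec()].
#' @param provinces Named numeric vector of province probabilities (sums to 1).
#' @param province_homophily Homophily coefficient in \[0, 1\] for the province
#'   attribute: 0 means ties ignore geography, values near 1 make cross-province
#'   ties rare.
#' @return An object of class \code{population_config}.
#' @seealso [generate_population()]
#' @export
population_config <- function(n_individuals,
                              degree_model = list(model = "poisson", lambda = 8),
                              traits = list(),
                              provinces = c(metropolitan = 0.5, other = 0.5),
                              province_homophily = 0) {
  if (!is.numeric(n_individuals) || n_individuals < 2)
    stopf("n_individuals must be at least 2")
  model <- match.arg(degree_model$model, c("poisson", "powerlaw", "regular"))
  if (is.null(names(provinces)) || abs(sum(provinces) - 1) > 1e-8)
    stopf("provinces must be a named probability vector summing to 1")
  assert_prob(province_homophily, "province_homophily")
  for (tr in traits) {
    if (!inherits(tr, "trait_spec")) stopf("traits must be built with trait_spec()")
  }
  degree_model$model <- model
  structure(list(n_individuals = as.integer(n_individuals),
                 degree_model = degree_model,
                 traits = traits,
                 provinces = provinces / sum(provinces),
                 province_homophily = province_homophily),
            class = "population_config")
}

#' Specify a categorical trait with homophily
#'
#' @param name Trait (column) name.
#' @param categories Character vector of category labels.
#' @param probs Marginal category probabilities (sums to 1).
#' @param homophily Coefficient in \[0, 1\]; 0 means edges ignore the trait,
#'   larger values make same-category ties increasingly over-represented.
#' @return An object of class \code{trait_spec}.
#' @export
trait_spec <- function(name, categories, probs, homophily = 0) {
  if (length(categories) != length(probs)) stopf("categories and probs differ in length")
  if (abs(sum(probs) - 1) > 1e-8) stopf("trait '%s': probs must sum to 1", name)
  assert_prob(homophily, sprintf("trait '%s' homophily", name))
  structure(list(name = name, categories = as.character(categories),
                 probs = probs / sum(probs), homophily = homophily),
            class = "trait_spec")
}

# draw a degree sequence for the configured model; sum forced even
draw_degrees <- function(dm, n) {
  degs <- switch(dm$model,
    poisson  = stats::rpois(n, dm$lambda %||% 8),
    powerlaw = {
      kmax <- min(n - 1L, dm$max_degree %||% 100L)
      k <- seq_len(kmax)
      sample(k, n, replace = TRUE, prob = k^-(dm$exponent %||% 2.5))
    },
    regular  = {
      k <- dm$degree
      if (is.null(k) || k >= n) stopf("regular degree must be given and smaller than n")
      if ((k * n) %% 2 == 1) stopf("regular model needs n * degree even")
      rep.int(as.integer(k), n)
    })
  degs <- pmin(degs, n - 1L)
  if (sum(degs) %% 2 == 1) {
    i <- which(degs < n - 1L)[1]
    degs[i] <- degs[i] + 1L
  }
  as.integer(degs)
}

# configuration-model stub matching; cross-category stub pairs for a trait with
# homophily h are accepted with probability (1 - h) during the early rounds,
# and unconditionally afterwards so the matching cannot deadlock
match_stubs <- function(degrees, trait_values, homophily,
                        hom_rounds = 60L, total_rounds = 90L) {
  stubs <- rep.int(seq_along(degrees), degrees)
  edge_env <- new.env(hash = TRUE, size = max(16L, length(stubs)))
  eu <- integer(0); ev <- integer(0)
  round <- 0L
  use_hom <- length(homophily) > 0 && any(homophily > 0)
  while (length(stubs) > 1L && round < total_rounds) {
    round <- round + 1L
    stubs <- sample(stubs)
    leftover <- integer(0)
    if (length(stubs) %% 2L == 1L) {
      leftover <- stubs[length(stubs)]
      stubs <- stubs[-length(stubs)]
    }
    u <- stubs[c(TRUE, FALSE)]
    v <- stubs[c(FALSE, TRUE)]
    key <- paste0(pmin(u, v), "_", pmax(u, v))
    seen <- vapply(key, exists, TRUE, envir = edge_env, inherits = FALSE,
                   USE.NAMES = FALSE)
    ok <- u != v & !seen & !duplicated(key)
    if (use_hom && round <= hom_rounds) {
      acc <- rep(1, length(u))
      for (t in seq_along(homophily)) {
        h <- homophily[[t]]
        if (h > 0) {
          tv <- trait_values[[t]]
          acc <- acc * ifelse(tv[u] != tv[v], 1 - h, 1)
        }
      }
      ok <- ok & stats::runif(length(u)) < acc
    }
    for (k in key[ok]) assign(k, TRUE, envir = edge_env)
    eu <- c(eu, u[ok]); ev <- c(ev, v[ok])
    stubs <- c(u[!ok], v[!ok], leftover)
  }
  # place any stubborn leftover stubs by degree-preserving edge swaps:
  # removing an existing edge (x, y) and adding (u, x), (v, y) realizes the
  # stubs u, v without changing any degree
  while (length(stubs) >= 2L && length(eu) > 0L) {
    u <- stubs[1L]; v <- stubs[2L]
    placed <- FALSE
    for (try in seq_len(500L)) {
      k <- sample.int(length(eu), 1L)
      x <- eu[k]; y <- ev[k]
      if (x == u || x == v || y == u || y == v) next
      k1 <- paste0(min(u, x), "_", max(u, x))
      k2 <- paste0(min(v, y), "_", max(v, y))
      if (k1 == k2 || exists(k1, envir = edge_env, inherits = FALSE) ||
          exists(k2, envir = edge_env, inherits = FALSE))
        next
      rm(list = paste0(min(x, y), "_", max(x, y)), envir = edge_env)
      assign(k1, TRUE, envir = edge_env)
      assign(k2, TRUE, envir = edge_env)
      eu[k] <- u; ev[k] <- x
      eu <- c(eu, v); ev <- c(ev, y)
      placed <- TRUE
      break
    }
    if (!placed) break  # give up; these stubs stay unrealized
    stubs <- stubs[-(1:2)]
  }
  cbind(eu, ev)
}

#' Generate a synthetic attributed social network
#'
#' Builds an undirected simple graph by configuration-model stub matching with
#' rejection of self-loops and multi-edges. Homophily is injected during the
#' matching: a proposed edge whose endpoints differ on a trait with homophily
#' coefficient \eqn{h} is accepted with probability \eqn{1 - h}, so the
#' same-category edge fraction grows monotonically with \eqn{h}. Provinces are
#' treated as one more categorical attribute with their own homophily level.
#' Each individual additionally receives an age (years), drawn on 18--40 and
#' centred near 22 to mimic a young, internet-using hidden population.
#'
#' @param config A [population_config()].
#' @param rng_seed Integer seed; output is deterministic given the seed.
#' @return An object of class \code{rds_population}: a list with \code{graph}
#'   (an \pkg{igraph} graph), \code{attributes} (a data frame with one row per
#'   individual: \code{id}, \code{province}, \code{age}, one column per trait,
#'   and \code{true_degree}), and the \code{config}.
#' @examples
#' cfg <- population_config(50, degree_model = list(model = "regular", degree = 4))
#' pop <- generate_population(cfg, rng_seed = 1)
#' table(igraph::degree(pop$graph))
#' @export
generate_population <- function(config, rng_seed = 1) {
  stopifnot(inherits(config, "population_config"))
  set.seed(derive_seed(rng_seed, 11L))
  n <- config$n_individuals
  degs <- draw_degrees(config$degree_model, n)

  attrs <- data.frame(id = seq_len(n))
  attrs$province <- sample(names(config$provinces), n, replace = TRUE,
                           prob = config$provinces)
  attrs$age <- pmin(40L, 18L + stats::rpois(n, 4))
  trait_values <- list()
  homophily <- numeric(0)
  for (tr in config$traits) {
    attrs[[tr$name]] <- sample(tr$categories, n, replace = TRUE, prob = tr$probs)
    trait_values <- c(trait_values, list(attrs[[tr$name]]))
    homophily <- c(homophily, tr$homophily)
  }
  if (config$province_homophily > 0) {
    trait_values <- c(trait_values, list(attrs$province))
    homophily <- c(homophily, config$province_homophily)
  }

  el <- match_stubs(degs, trait_values, homophily)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  attrs$true_degree <- igraph::degree(g)

  structure(list(graph = g, attributes = attrs, config = config),
            class = "rds_population")
}

#' @export
print.rds_population <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Synthetic population: %d individuals, %d ties (mean degree %.2f)\n",
              igraph::vcount(g), igraph::ecount(g), mean(igraph::degree(g))))
  tr <- vapply(x$config$traits, function(t) t$name, "")
  cat(sprintf("Traits: %s; provinces: %d; province homophily %.2f\n",
              if (length(tr)) paste(tr, collapse = ", ") else "(none)",
              length(x$config$provinces), x$config$province_homophily))
  invisible(x)
}

#' Fraction of edges joining same-category endpoints
#'
#' @param pop An \code{rds_population}.
#' @param attribute Name of a trait or \code{"province"}.
#' @return Fraction in \[0, 1\].
#' @export
same_category_edge_fraction <- function(pop, attribute) {
  el <- igraph::as_edgelist(pop$graph, names = FALSE)
  if (nrow(el) == 0) stopf("population has no edges")
  v <- pop$attributes[[attribute]]
  if (is.null(v)) stopf("unknown attribute '%s'", attribute)
  mean(v[el[, 1]] == v[el[, 2]])
}

#' Restrict a population to its largest connected component
#'
#' Random-walk sampling requires a connected graph; real hidden-population
#' networks are analysed on their giant component.
#'
#' @param pop An \code{rds_population}.
#' @return An \code{rds_population} on the largest component, with individual
#'   ids renumbered consecutively and \code{true_degree} recomputed.
#' @export
largest_component <- function(pop) {
  comp <- igraph::components(pop$graph)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(pop$graph, keep)
  attrs <- pop$attributes[keep, , drop = FALSE]
  attrs$id <- seq_len(nrow(attrs))
  attrs$true_degree <- igraph::degree(g)
  rownames(attrs) <- NULL
  structure(list(graph = g, attributes = attrs, config = pop$config),
            class = "rds_population")
}

#' Sample nodes by a simple random walk
#'
#' The stationary distribution of a simple random walk on a connected
#' undirected graph is proportional to degree, the inclusion regime in which
#' the RDS-II estimator is unbiased. This makes the walk a convenient oracle
#' for estimator tests: by default the start is drawn from the stationary
#' (degree-proportional) distribution so every draw is stationary.
#'
#' @param pop An \code{rds_population} with a connected graph.
#' @param n_draws Number of steps to record (>= 1).
#' @param rng_seed Integer seed.
#' @param start Starting node id, or \code{NULL} to draw the start from the
#'   degree-proportional stationary distribution.
#' @param burn_in Steps discarded before recording (default 0).
#' @return Integer vector of visited node ids, length \code{n_draws}.
#' @export
random_walk_sample <- function(pop, n_draws, rng_seed = 1, start = NULL,
                               burn_in = 0) {
  stopifnot(n_draws >= 1)
  g <- pop$graph
  comp <- igraph::components(g)
  if (comp$no > 1)
    stopf("graph is disconnected: %d components with sizes %s",
          comp$no, paste(comp$csize, collapse = ", "))
  set.seed(derive_seed(rng_seed, 13L))
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  deg <- lengths(adj)
  if (any(deg == 0)) stopf("graph has isolated nodes")
  cur <- if (is.null(start)) sample.int(length(adj), 1, prob = deg) else as.integer(start)
  total <- burn_in + n_draws
  out <- integer(total)
  for (i in seq_len(total)) {
    nb <- adj[[cur]]
    cur <- nb[sample.int(length(nb), 1L)]
    out[i] <- cur
  }
  out[(burn_in + 1L):total]
}

#' Overlay a degree-correlated binary trait
#'
#' Assigns a \code{"yes"}/\code{"no"} trait whose probability is proportional
#' to an individual's degree, scaled to a target overall prevalence. Useful for
#' demonstrating the degree bias of raw sample proportions under chain-referral
#' sampling: high-degree individuals are over-sampled, so an attribute
#' concentrated on them is over-represented unless inverse-degree weights are
#' applied.
#'
#' @param pop An \code{rds_population}.
#' @param prevalence Target population prevalence of the \code{"yes"} category.
#' @param name Column name for the new trait.
#' @param rng_seed Integer seed.
#' @return The population with the extra attribute column; the realized
#'   prevalence is stored in \code{attr(pop$attributes[[name]], "prevalence")}.
#' @export
degree_correlated_trait <- function(pop, prevalence = 0.3,
                                    name = "degree_trait", rng_seed = 1) {
  set.seed(derive_seed(rng_seed, 17L))
  d <- pop$attributes$true_degree
  p <- pmin(1, prevalence * d / mean(d))
  v <- ifelse(stats::runif(length(d)) < p, "yes", "no")
  attr(v, "prevalence") <- mean(v == "yes")
  pop$attributes[[name]] <- v
  pop
}
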