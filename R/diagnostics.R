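#' Recruiter-to-recruit transition matrix for a variable
#'
#' Counts recruitment events by the recruiter's and recruit's category and
#' row-normalizes to a stochastic matrix. The Markov state space is restricted
#' to categories observed at least once as a recruiter (rows cannot otherwise
#' be normalized); events leading into categories outside that state space are
#' dropped and the affected categories reported.
#'
#' @param forest An \code{rds_forest}.
#' @param records Submissions providing the category of every individual that
#'   appears in a recruitment event (recruiter or recruit).
#' @param variable Column of \code{records} to analyse.
#' @return An object of class \code{rds_transition}: \code{counts} (events
#'   matrix C), \code{P} (row-stochastic), \code{states}, \code{dropped}
#'   (categories excluded from the state space), \code{n_events}.
#' @export
estimate_transition_matrix <- function(forest, records, variable) {
  if (!variable %in% names(records)) stopf("variable '%s' not in records", variable)
  ev <- forest[!is.na(forest$recruiter_id), , drop = FALSE]
  if (nrow(ev) == 0) stopf("no recruitment events in forest")
  val <- records[[variable]]
  names(val) <- records$id
  if (!all(ev$recruiter_id %in% records$id))
    stopf("some recruiters are missing from records")
  from <- as.character(val[ev$recruiter_id])
  to <- as.character(val[ev$id])
  keep <- !is.na(from) & !is.na(to)
  from <- from[keep]; to <- to[keep]
  if (length(from) == 0) stopf("no recruitment events with observed categories")

  cats <- sort(unique(c(from, to)))
  C <- table(factor(from, cats), factor(to, cats))
  states <- rownames(C)[rowSums(C) > 0]
  dropped <- setdiff(cats, states)
  use <- from %in% states & to %in% states
  C2 <- table(factor(from[use], states), factor(to[use], states))
  C2 <- matrix(as.numeric(C2), nrow = length(states),
               dimnames = list(states, states))
  if (any(rowSums(C2) == 0))
    stopf("state(s) %s have no within-state outgoing events",
          paste(states[rowSums(C2) == 0], collapse = ", "))
  P <- C2 / rowSums(C2)
  structure(list(variable = variable, states = states, counts = C2, P = P,
                 dropped = dropped, n_events = sum(C2)),
            class = "rds_transition")
}

#' @export
print.rds_transition <- function(x, digits = 3, ...) {
  cat(sprintf("Recruitment transition matrix for '%s' (%d events)\n",
              x$variable, x$n_events))
  print(round(x$P, digits))
  if (length(x$dropped))
    cat("Categories never recruiting (excluded from chain):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

as_transition_matrix <- function(P) {
  if (inherits(P, "rds_transition")) P <- P$P
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stopf("transition matrix must be square")
  if (any(P < 0)) stopf("negative transition probabilities")
  if (any(abs(rowSums(P) - 1) > 1e-8)) stopf("rows of P must sum to 1")
  if (is.null(rownames(P))) dimnames(P) <- list(seq_len(nrow(P)), seq_len(nrow(P)))
  P
}

# period of an irreducible chain: gcd over edges (u,v) of level(u) + 1 - level(v)
chain_period <- function(P) {
  g <- igraph::graph_from_adjacency_matrix(1 * (P > 0), mode = "directed")
  lev <- as.integer(igraph::distances(g, v = 1, mode = "out"))
  el <- igraph::as_edgelist(g, names = FALSE)
  gcd_all(abs(lev[el[, 1]] + 1L - lev[el[, 2]]))
}

#' Stationary composition of a recruitment chain
#'
#' Solves \eqn{\pi P = \pi}, \eqn{\sum \pi = 1} for an irreducible aperiodic
#' transition matrix: the sample composition the recruitment process
#' approaches after infinitely many waves, independent of the seeds.
#'
#' @param P A row-stochastic matrix or an \code{rds_transition}.
#' @return Named probability vector \eqn{\pi} satisfying \eqn{\pi P = \pi}
#'   within 1e-10.
#' @export
stationary_distribution <- function(P) {
  P <- as_transition_matrix(P)
  g <- igraph::graph_from_adjacency_matrix(1 * (P > 0), mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1) {
    sizes <- table(comp$membership)
    small <- rownames(P)[comp$membership != as.integer(names(which.max(sizes)))]
    stopf("chain is reducible: states {%s} do not communicate with the rest",
          paste(utils::head(small, 5), collapse = ", "))
  }
  per <- chain_period(P)
  if (per > 1)
    stopf("chain is periodic (period %d) over states {%s}", per,
          paste(rownames(P), collapse = ", "))
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi <- Re(e$vectors[, i])
  pi <- pi / sum(pi)
  # polish with power iterations to push the residual below 1e-10
  for (k in 1:100) {
    pi2 <- as.numeric(pi %*% P)
    if (max(abs(pi2 - pi)) < 1e-14) { pi <- pi2; break }
    pi <- pi2
  }
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  if (max(abs(as.numeric(pi %*% P) - pi)) > 1e-10)
    stopf("stationary distribution did not converge")
  names(pi) <- rownames(P)
  pi
}

#' Waves needed to reach compositional equilibrium
#'
#' The classic RDS convergence diagnostic: the smallest number of waves
#' \eqn{n} after which a first-order Markov process on the recruitment
#' transition matrix is, for every category, within a 2\% relative difference
#' of its stationary value. By default the worst case over all degenerate
#' starting compositions (all mass on one category) is used, mirroring the
#' requirement that estimates be independent of how seeds were chosen; a
#' specific starting distribution (e.g. the seed composition) can be supplied
#' instead.
#'
#' @param P Row-stochastic matrix or \code{rds_transition}.
#' @param tolerance Relative tolerance (default 0.02).
#' @param start \code{"worst"} (default) or a probability vector over states.
#' @param max_waves Safety cap on the iteration.
#' @return Integer number of waves.
#' @examples
#' waves_to_equilibrium(rbind(c(0.8, 0.2), c(0.3, 0.7)))  # 7
#' @export
waves_to_equilibrium <- function(P, tolerance = 0.02, start = "worst",
                                 max_waves = 100000L) {
  P <- as_transition_matrix(P)
  if (!is.numeric(tolerance) || tolerance <= 0) stopf("tolerance must be positive")
  pi <- stationary_distribution(P)
  if (any(pi == 0)) stopf("stationary probability of 0: relative difference undefined")
  if (identical(start, "worst")) {
    M <- P
    for (n in seq_len(max_waves)) {
      reldiff <- abs(sweep(M, 2, pi)) / rep(pi, each = nrow(M))
      if (max(reldiff) < tolerance) return(n)
      M <- M %*% P
    }
  } else {
    v <- as.numeric(start)
    if (length(v) != nrow(P) || abs(sum(v) - 1) > 1e-8)
      stopf("start must be a probability vector over the states")
    for (n in seq_len(max_waves)) {
      v <- as.numeric(v %*% P)
      if (max(abs(v - pi) / pi) < tolerance) return(n)
    }
  }
  stopf("no convergence within %d waves", max_waves)
}

#' Equilibrium report across survey variables
#'
#' Runs [estimate_transition_matrix()], [stationary_distribution()] and
#' [waves_to_equilibrium()] for each variable, recording diagnostic failures
#' (reducible or periodic chains, zero stationary mass) instead of stopping.
#' Numeric variables must be binned into categories first (see
#' [bin_numeric()]).
#'
#' @param forest An \code{rds_forest}.
#' @param records Submissions table.
#' @param variables Character vector of categorical variables.
#' @param tolerance Relative equilibrium tolerance (default 0.02).
#' @param start Passed to [waves_to_equilibrium()].
#' @return Object of class \code{rds_equilibrium}: per-variable list with
#'   \code{pi}, \code{waves_needed} (NA on failure) and \code{note}; plus
#'   \code{max_waves} and \code{median_waves} over the diagnosable variables.
#' @export
equilibrium_report <- function(forest, records, variables, tolerance = 0.02,
                               start = "worst") {
  per <- lapply(variables, function(v) {
    res <- tryCatch({
      tm <- estimate_transition_matrix(forest, records, v)
      pi <- stationary_distribution(tm)
      w <- waves_to_equilibrium(tm, tolerance = tolerance, start = start)
      list(variable = v, pi = pi, waves_needed = w, dropped = tm$dropped,
           note = "ok")
    }, error = function(e) list(variable = v, pi = NULL,
                                waves_needed = NA_integer_, dropped = character(0),
                                note = conditionMessage(e)))
    res
  })
  names(per) <- variables
  waves <- vapply(per, function(x) as.numeric(x$waves_needed), 0)
  structure(list(variables = per, tolerance = tolerance,
                 max_waves = if (all(is.na(waves))) NA else max(waves, na.rm = TRUE),
                 median_waves = if (all(is.na(waves))) NA
                                else stats::median(waves, na.rm = TRUE)),
            class = "rds_equilibrium")
}

#' @export
print.rds_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium diagnostics (relative tolerance %.3g)\n", x$tolerance))
  for (v in x$variables)
    cat(sprintf("  %-24s waves = %-4s %s\n", v$variable,
                ifelse(is.na(v$waves_needed), "NA", v$waves_needed),
                if (v$note == "ok") "" else paste0("[", v$note, "]")))
  cat(sprintf("Max waves: %s; median: %s\n", x$max_waves, x$median_waves))
  invisible(x)
}

#' Bin a numeric variable for Markov diagnostics
#'
#' @param x Numeric vector.
#' @param breaks Cut points (passed to \code{cut}, right-closed, include
#'   lowest).
#' @return Character vector of bin labels; \code{NA} preserved.
#' @export
bin_numeric <- function(x, breaks) {
  as.character(cut(as.numeric(x), breaks = breaks, include.lowest = TRUE))
}

#' Sample composition as the sample accumulates
#'
#' Recomputes the raw sample proportion and the RDS-II estimate of each
#' category on the first \eqn{m} submissions (in time order) for
#' \eqn{m = step, 2\,step, \dots, n}; the final point always uses the full
#' sample. Flat curves towards the end indicate compositional stability.
#'
#' @param records Submissions (any order; sorted by timestamp, ties by id).
#' @param degrees Post-imputation network sizes aligned with \code{records}.
#' @param variable Column to track.
#' @param step Evaluation spacing (default 25).
#' @return Data frame of class \code{rds_composition}: \code{m},
#'   \code{category}, \code{sample_proportion}, \code{rdsii_estimate}.
#' @export
running_composition <- function(records, degrees, variable, step = 25) {
  n <- nrow(records)
  if (length(degrees) != n) stopf("degrees do not match records")
  ord <- order(records$timestamp, records$id)
  x <- as.character(records[[variable]])[ord]
  x[is.na(x) | x == ""] <- "(no answer)"
  d <- degrees[ord]
  cats <- sort(unique(x))
  ms <- unique(c(seq(min(step, n), n, by = step), n))
  rows <- lapply(ms, function(m) {
    est <- rdsii_proportion(factor(x[1:m], cats), d[1:m])
    data.frame(m = m, category = cats,
               sample_proportion = as.numeric(prop.table(table(factor(x[1:m], cats)))),
               rdsii_estimate = as.numeric(est), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "variable") <- variable
  class(out) <- c("rds_composition", "data.frame")
  out
}

#' @export
plot.rds_composition <- function(x, ...) {
  cats <- unique(x$category)
  wide <- matrix(x$rdsii_estimate, ncol = length(cats), byrow = TRUE,
                 dimnames = list(NULL, cats))
  graphics::matplot(unique(x$m), wide, type = "l", lty = 1,
                    xlab = "sample size", ylab = "RDS-II estimate",
                    main = attr(x, "variable"), ...)
  graphics::legend("topright", legend = cats, lty = 1,
                   col = seq_along(cats), bty = "n", cex = 0.8)
  invisible(x)
}

#' Full-sample vs last-k stability comparison
#'
#' For each variable, the maximum absolute difference between the RDS-II
#' estimate on the full sample and on the last \code{k} respondents (by
#' submission time). Categorical variables compare proportions per category;
#' numeric variables compare weighted means. Small differences indicate the
#' composition had stabilized before the sample was complete.
#'
#' @param records Submissions.
#' @param degrees Post-imputation network sizes aligned with \code{records}.
#' @param variables Variables to compare.
#' @param k Window size (default 200); requires \code{nrow(records) > k}.
#' @return Data frame: \code{variable}, \code{type}, \code{max_abs_diff}.
#' @export
last_k_comparison <- function(records, degrees, variables, k = 200) {
  n <- nrow(records)
  if (n <= k) stopf("need more than k = %d records (have %d)", k, n)
  ord <- order(records$timestamp, records$id)
  records <- records[ord, , drop = FALSE]
  degrees <- degrees[ord]
  tail_idx <- (n - k + 1):n
  rows <- lapply(variables, function(v) {
    x <- records[[v]]
    if (is.numeric(x)) {
      d <- abs(as.numeric(rdsii_mean(x, degrees)) -
               as.numeric(rdsii_mean(x[tail_idx], degrees[tail_idx])))
      data.frame(variable = v, type = "mean", max_abs_diff = d)
    } else {
      xc <- as.character(x)
      xc[is.na(xc) | xc == ""] <- "(no answer)"
      cats <- sort(unique(xc))
      full <- rdsii_proportion(factor(xc, cats), degrees)
      last <- rdsii_proportion(factor(xc[tail_idx], cats), degrees[tail_idx])
      data.frame(variable = v, type = "proportion",
                 max_abs_diff = max(abs(full - last)))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recruitment-structure summary statistics
#'
#' @param forest An \code{rds_forest}.
#' @param wave_threshold Chains whose depth exceeds this are counted
#'   (default 5).
#' @return Object of class \code{rds_wave_stats}: per-chain sizes and maximum
#'   waves, the overall maximum wave, the number of chains deeper than the
#'   threshold, and the cumulative submissions per day.
#' @export
wave_stats <- function(forest, wave_threshold = 5) {
  chains <- split(seq_len(nrow(forest)), forest$chain)
  per <- data.frame(chain = names(chains),
                    size = vapply(chains, length, 0L),
                    max_wave = vapply(chains, function(i) max(forest$wave[i]), 0L),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  day <- floor(forest$timestamp)
  ud <- sort(unique(day))
  cum <- data.frame(day = ud, cumulative = cumsum(tabulate(match(day, ud))))
  structure(list(chains = per, n_chains = nrow(per),
                 max_wave = max(forest$wave),
                 n_exceeding = sum(per$max_wave > wave_threshold),
                 wave_threshold = wave_threshold, cumulative = cum),
            class = "rds_wave_stats")
}

#' @export
print.rds_wave_stats <- function(x, ...) {
  cat(sprintf("%d chains; sizes %d-%d; waves up to %d; %d chains deeper than %d waves\n",
              x$n_chains, min(x$chains$size), max(x$chains$size), x$max_wave,
              x$n_exceeding, x$wave_threshold))
  invisible(x)
}

#' @export
plot.rds_wave_stats <- function(x, ...) {
  graphics::plot(x$cumulative$day, x$cumulative$cumulative, type = "s",
                 xlab = "day of study", ylab = "cumulative submissions",
                 main = "Cumulative survey submissions", ...)
  invisible(x)
}

#' Fraction of recruitment events crossing attribute categories
#'
#' Share of recruiter-to-recruit events whose endpoints differ on an
#' attribute, e.g. home province: frequent cross-province recruitment argues
#' against geographically isolated sub-networks biasing the sample.
#'
#' @param forest An \code{rds_forest}.
#' @param records Submissions providing the attribute for both endpoints of
#'   every event.
#' @param attribute Column of \code{records}.
#' @return Fraction in \[0, 1\].
#' @export
cross_group_recruitment_fraction <- function(forest, records, attribute) {
  ev <- forest[!is.na(forest$recruiter_id), , drop = FALSE]
  if (nrow(ev) == 0) stopf("no recruitment events")
  val <- records[[attribute]]
  if (is.null(val)) stopf("unknown attribute '%s'", attribute)
  names(val) <- records$id
  from <- val[ev$recruiter_id]
  to <- val[ev$id]
  if (anyNA(from) || anyNA(to))
    stopf("attribute '%s' missing for some recruitment events", attribute)
  mean(from != to)
}
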