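toy_forest <- function(parents, categories, ids = NULL) {
  ids <- ids %||% sprintf("n%d", seq_along(parents))
  root <- seq_along(parents)
  for (i in seq_along(parents)) {
    r <- i
    while (!is.na(parents[r])) r <- parents[r]
    root[i] <- r
  }
  f <- data.frame(id = ids, individual = seq_along(parents),
                  recruiter_id = ifelse(is.na(parents), NA_character_,
                                        ids[parents]),
                  wave = recompute_waves_for_test(parents),
                  chain = ids[root], timestamp = seq_along(parents),
                  stringsAsFactors = FALSE)
  class(f) <- c("rds_forest", "data.frame")
  rec <- data.frame(id = ids, cat = categories, stringsAsFactors = FALSE)
  list(forest = f, records = rec)
}

recompute_waves_for_test <- function(parents) {
  w <- ifelse(is.na(parents), 0L, NA_integer_)
  while (anyNA(w)) w <- ifelse(is.na(w), w[parents] + 1L, w)
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("transition counts are tabulated and row-normalized by hand-checkable rules", {
  # events A->A, A->B, B->A, B->A on a single chain
  tf <- toy_forest(c(NA, 1, 1, 3, 3), c("A", "A", "B", "A", "A"))
  tm <- estimate_transition_matrix(tf$forest, tf$records, "cat")
  expect_equal(unname(tm$counts), rbind(c(1, 1), c(2, 0)))
  expect_equal(unname(tm$P), rbind(c(0.5, 0.5), c(1, 0)))
  expect_equal(tm$n_events, 4)

  # perfect homophily: identity on observed states
  tf2 <- toy_forest(c(NA, 1, 2, NA, 4), c("A", "A", "A", "B", "B"))
  tm2 <- estimate_transition_matrix(tf2$forest, tf2$records, "cat")
  expect_equal(unname(tm2$P), diag(2))

  # categories never recruiting are dropped and reported
  tf3 <- toy_forest(c(NA, 1, 1), c("A", "A", "B"))
  tm3 <- estimate_transition_matrix(tf3$forest, tf3$records, "cat")
  expect_equal(tm3$states, "A")
  expect_equal(tm3$dropped, "B")
  expect_equal(unname(tm3$P), matrix(1))
  expect_error(
    estimate_transition_matrix(tf3$forest[1, ], tf3$records, "cat"),
    "no recruitment events")
})

test_that("independent recruitment gives rows near the marginal distribution", {
  set.seed(99)
  n <- 2000
  parents <- c(NA, seq_len(n - 1))            # one long chain
  cats <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.3, 0.7))
  tf <- toy_forest(parents, cats, ids = sprintf("n%04d", 1:n))
  tm <- estimate_transition_matrix(tf$forest, tf$records, "cat")
  expect_true(max(abs(tm$P - rep(c(0.3, 0.7), each = 2))) < 0.05)
})

test_that("stationary distributions solve piP = pi with diagnostic failures named", {
  r <- c(0.2, 0.5, 0.3)
  P <- rbind(r, r, r)
  expect_equal(unname(stationary_distribution(P)), r)

  pi <- stationary_distribution(rbind(c(0.8, 0.2), c(0.3, 0.7)))
  expect_equal(unname(pi), c(0.6, 0.4))

  S <- rbind(c(0.5, 0.3, 0.2), c(0.3, 0.4, 0.3), c(0.2, 0.3, 0.5))
  expect_equal(unname(stationary_distribution(S)), rep(1 / 3, 3))

  expect_error(stationary_distribution(diag(2)), "reducible")
  expect_error(stationary_distribution(rbind(c(0, 1), c(1, 0))), "periodic")
  expect_error(stationary_distribution(rbind(c(0.9, 0.2), c(0.3, 0.7))),
               "sum to 1")
})

test_that("waves to equilibrium: worked example, tolerance monotonicity, options", {
  P <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  expect_equal(waves_to_equilibrium(P), 7)
  expect_equal(waves_to_equilibrium(rbind(c(0.3, 0.7), c(0.3, 0.7))), 1)
  expect_error(waves_to_equilibrium(diag(2)), "reducible")

  tols <- c(0.005, 0.02, 0.1, 0.3)
  waves <- vapply(tols, function(t) waves_to_equilibrium(P, tolerance = t), 0L)
  expect_true(all(diff(waves) <= 0))

  # seed-composition start can only converge at least as fast as the worst case
  expect_lte(waves_to_equilibrium(P, start = c(0.5, 0.5)),
             waves_to_equilibrium(P))
})

test_that("two-state chains match the eigenvalue-decay closed form", {
  set.seed(7)
  for (i in 1:20) {
    P <- rbind(c(0, stats::runif(1, 0.05, 0.95)),
               c(stats::runif(1, 0.05, 0.95), 0))
    P[1, 1] <- 1 - P[1, 2]
    P[2, 2] <- 1 - P[2, 1]
    expect_equal(waves_to_equilibrium(P), two_state_waves_oracle(P),
                 info = paste("chain", i))
    pi <- stationary_distribution(P)
    expect_lt(max(abs(as.numeric(pi %*% P) - pi)), 1e-10)
  }
})

test_that("running composition tracks the stream and ends at the full-sample estimate", {
  n <- 60
  rec <- data.frame(id = sprintf("r%02d", 1:n), timestamp = 1:n,
                    grp = rep(c("A", "B"), each = n / 2),
                    stringsAsFactors = FALSE)
  deg <- rep(2, n)
  comp <- running_composition(rec, deg, "grp", step = 10)
  a <- comp[comp$category == "A", ]
  # all-A prefix, then the curve crosses 1/2 only after the midpoint
  expect_equal(a$rdsii_estimate[a$m <= 30], rep(1, 3))
  expect_true(all(a$rdsii_estimate[a$m > 30] < 1))
  expect_equal(a$rdsii_estimate[a$m == 60], 0.5)

  # constant-composition stream: flat curves
  rec2 <- rec; rec2$grp <- rep(c("A", "B"), n / 2)
  comp2 <- running_composition(rec2, deg, "grp", step = 10)
  expect_true(all(comp2$rdsii_estimate %in% c(0.5)))

  # final point equals the full-sample estimator exactly, uneven step included
  set.seed(5)
  deg3 <- stats::runif(n, 1, 9)
  rec3 <- rec; rec3$grp <- sample(c("A", "B", "C"), n, replace = TRUE)
  comp3 <- running_composition(rec3, deg3, "grp", step = 23)
  last <- comp3[comp3$m == n, ]
  full <- rdsii_proportion(rec3$grp, deg3)
  expect_identical(last$rdsii_estimate, as.numeric(full[last$category]))
})

test_that("last-k comparison matches hand-computed windows", {
  n <- 10
  rec <- data.frame(id = sprintf("r%02d", 1:n), timestamp = 1:n,
                    grp = c(rep("A", 5), rep("B", 5)),
                    age = c(rep(20, 5), rep(30, 5)), stringsAsFactors = FALSE)
  deg <- rep(1, n)
  out <- last_k_comparison(rec, deg, c("grp", "age"), k = 4)
  expect_equal(out$max_abs_diff[out$variable == "grp"], 0.5)  # 0.5 vs 1.0 B
  expect_equal(out$max_abs_diff[out$variable == "age"], 5)    # 25 vs 30
  expect_error(last_k_comparison(rec, deg, "grp", k = 10), "more than k")

  # a window that replicates the full composition and degrees differs by zero
  m <- 30
  rec2 <- data.frame(id = sprintf("r%02d", 1:m), timestamp = 1:m,
                     grp = rep(c("A", "A", "B"), m / 3), stringsAsFactors = FALSE)
  deg2 <- rep(c(1, 2, 4), m / 3)
  out2 <- last_k_comparison(rec2, deg2, "grp", k = 3)
  expect_equal(out2$max_abs_diff, 0)
})

test_that("wave statistics agree with a brute-force traversal", {
  seeds_only <- toy_forest(rep(NA, 20), rep("A", 20))
  ws <- wave_stats(seeds_only$forest, wave_threshold = 5)
  expect_equal(ws$max_wave, 0)
  expect_equal(ws$n_exceeding, 0)
  expect_equal(ws$chains$size, rep(1, 20))

  path25 <- toy_forest(c(NA, 1:24), rep("A", 25))
  expect_equal(wave_stats(path25$forest)$max_wave, 24)

  pop <- small_pop(seed = 14)
  f <- simulate_recruitment(pop, small_sim(seed = 14,
                                           participation_probability = 0.6))
  ws <- wave_stats(f, wave_threshold = 3)
  # brute force: depth by climbing parents
  depth <- function(id) {
    d <- 0
    p <- f$recruiter_id[f$id == id]
    while (!is.na(p)) { d <- d + 1; p <- f$recruiter_id[f$id == p] }
    d
  }
  depths <- vapply(f$id, depth, 0)
  expect_equal(ws$max_wave, max(depths))
  roots <- f$id[is.na(f$recruiter_id)]
  root_of <- function(id) {
    p <- id
    repeat {
      up <- f$recruiter_id[f$id == p]
      if (is.na(up)) return(p)
      p <- up
    }
  }
  sizes <- table(vapply(f$id, root_of, ""))
  expect_equal(sort(ws$chains$size), sort(as.integer(sizes)))
  expect_equal(ws$n_exceeding,
               sum(tapply(depths, vapply(f$id, root_of, ""), max) > 3))
  expect_equal(max(ws$cumulative$cumulative), nrow(f))
})

test_that("cross-group recruitment fractions count differing endpoints", {
  tf <- toy_forest(c(NA, 1, 2), c("X", "Y", "X"))
  names(tf$records)[2] <- "province"
  expect_equal(cross_group_recruitment_fraction(tf$forest, tf$records,
                                                "province"), 1.0)
  tf2 <- toy_forest(c(NA, 1, 2), c("X", "X", "X"))
  names(tf2$records)[2] <- "province"
  expect_equal(cross_group_recruitment_fraction(tf2$forest, tf2$records,
                                                "province"), 0)
  tf3 <- toy_forest(c(NA, rep(1, 10)), c("X", rep("X", 7), rep("Y", 3)))
  names(tf3$records)[2] <- "province"
  expect_equal(cross_group_recruitment_fraction(tf3$forest, tf3$records,
                                                "province"), 0.3)
  expect_error(cross_group_recruitment_fraction(tf$forest[1, ], tf$records,
                                                "province"), "no recruitment")
})

test_that("equilibrium reports summarize per-variable convergence", {
  pop <- small_pop(n = 500, seed = 15, homophily = 0.5)
  cfg <- small_sim(seed = 15, participation_probability = 0.6)
  f <- simulate_recruitment(pop, cfg)
  subs <- fabricate_submissions(f, pop, cfg)
  eq <- equilibrium_report(f, subs, c("grp", "province"))
  expect_s3_class(eq, "rds_equilibrium")
  waves <- vapply(eq$variables, function(v) as.numeric(v$waves_needed), 0)
  expect_true(all(is.finite(waves)))
  expect_equal(eq$max_waves, max(waves))
  expect_equal(eq$median_waves, stats::median(waves))
  for (v in eq$variables) {
    tm <- estimate_transition_matrix(f, subs, v$variable)
    expect_lt(max(abs(as.numeric(v$pi %*% tm$P) - v$pi)), 1e-10)
    expect_equal(unname(rowSums(tm$P)), rep(1, nrow(tm$P)))
  }
})

test_that("observed convergence slows as homophily grows", {
  waves_at <- function(h) {
    res <- numeric(0)
    for (s in 1:10) {
      pop <- small_pop(n = 500, seed = 300 + s, homophily = h)
      cfg <- small_sim(seed = 300 + s, participation_probability = 0.7)
      f <- simulate_recruitment(pop, cfg)
      subs <- fabricate_submissions(f, pop, cfg)
      eq <- equilibrium_report(f, subs, "grp")
      w <- eq$variables$grp$waves_needed
      if (!is.na(w)) res <- c(res, w)
    }
    mean(res)
  }
  expect_lt(waves_at(0.1), waves_at(0.85))
})
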