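# shared fixtures, built in code

# minimal hand-written submissions table; record 4 repeats record 1's phone,
# record 5 states age 17
toy_records <- function() {
  data.frame(
    id = sprintf("r%d", 1:5),
    recruiter_id = c(NA, "r1", "r1", "r2", "r3"),
    is_seed = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    timestamp = 1:5,
    completion_minutes = c(10, 12, 9, 11, 15),
    phone_token = c("+84 912345", "+84 900001", "+84 900002",
                    "(+84) 91-23-45", "+84 900004"),
    email_token = sprintf("u%d@x.vn", 1:5),
    chat_token = sprintf("c%d", 1:5),
    ip_token = sprintf("ip%d", 1:5),
    stated_age = c(25, 22, 30, 21, 17),
    education = c("university", "secondary", "primary", "university",
                  "high_school"),
    income = "middle",
    province = c("X", "Y", "X", "Y", "X"),
    partners_6mo = c(2, 0, 5, 1, 3),
    reported_network_size = c(4, 2, NA, 8, 5),
    stringsAsFactors = FALSE)
}

# small default-flavoured population for simulation tests
small_pop <- function(n = 300, seed = 1, lambda = 6, homophily = 0.4) {
  cfg <- population_config(
    n, degree_model = list(model = "poisson", lambda = lambda),
    traits = list(trait_spec("grp", c("a", "b"), c(0.3, 0.7),
                             homophily = homophily)),
    provinces = c(X = 0.6, Y = 0.4))
  generate_population(cfg, seed)
}

small_sim <- function(seed = 1, ...) {
  simulation_config(n_seeds = 5, rng_seed = seed, ...)
}

# closed form for two-state chains: P^n - Pi = lambda^n (I - Pi), so the
# worst relative deviation after n waves is |lambda|^n (1 - pi_min) / pi_min
two_state_waves_oracle <- function(P, tol = 0.02) {
  pi1 <- P[2, 1] / (P[1, 2] + P[2, 1])
  pim <- min(pi1, 1 - pi1)
  lam <- abs(P[1, 1] + P[2, 2] - 1)
  M <- (1 - pim) / pim
  n <- 1L
  while (lam^n * M >= tol) n <- n + 1L
  n
}

# deterministic 676-submission table with known composition: 20 seeds,
# 40 underage + 25 duplicated-contact records among the 656 others
study_count_fixture <- function() {
  n <- 676L
  seeds <- 1:20
  rec <- data.frame(
    id = sprintf("r%03d", 1:n),
    recruiter_id = c(rep(NA_character_, 20), sprintf("r%03d", ((21:n) %% 20) + 1)),
    is_seed = seq_len(n) %in% seeds,
    timestamp = seq_len(n),
    completion_minutes = 10,
    phone_token = sprintf("p%03d", 1:n),
    email_token = sprintf("e%03d@x.vn", 1:n),
    chat_token = sprintf("c%03d", 1:n),
    ip_token = sprintf("i%03d", 1:n),
    stated_age = 25L,
    education = "secondary",
    income = "middle",
    province = rep(c("X", "Y"), length.out = n),
    partners_6mo = 2L,
    reported_network_size = 5L,
    stringsAsFactors = FALSE)
  rec$stated_age[101:140] <- 17L                     # 40 underage
  rec$phone_token[201:225] <- rec$phone_token[21:45] # 25 duplicated contacts
  rec
}
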