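test_that("hand-checked example: a repeated phone and an underage record", {
  rec <- toy_records()  # record 4 repeats record 1's phone, record 5 is 17
  flags <- flag_invalid(rec)
  expect_equal(flags$id[flags$duplicate_contact], "r4")
  expect_equal(flags$id[flags$underage], "r5")
  expect_equal(sum(unlist(flags[, c("duplicate_ip", "fast_completion",
                                    "no_education", "extreme_partners")])), 0)
  expect_equal(flags$id[flags$any_invalid], c("r4", "r5"))
})

test_that("clean input yields zero flags and duplicate ids are refused", {
  rec <- toy_records()
  rec$phone_token[4] <- "+84 900003"
  rec$stated_age[5] <- 19
  flags <- flag_invalid(rec)
  expect_equal(sum(unlist(flags[, -1])), 0)
  rec$id[2] <- rec$id[1]
  expect_error(flag_invalid(rec), "duplicate submission ids")
})

test_that("token normalization is idempotent and canonical", {
  x <- c("  (+84) 91-23-45 ", "+84912345", NA, "")
  once <- normalize_token(x, "phone")
  expect_identical(normalize_token(once, "phone"), once)
  expect_equal(once[1], once[2])
  expect_equal(once[3:4], c("", ""))
  e <- normalize_token(c(" A.B@X.VN ", "a.b@x.vn"))
  expect_equal(e[1], e[2])
  expect_identical(normalize_token(e), e)
})

test_that("flags are independent of record storage order", {
  pop <- small_pop(seed = 11)
  cfg <- small_sim(seed = 11)
  subs <- fabricate_submissions(simulate_recruitment(pop, cfg), pop, cfg)
  flags <- flag_invalid(subs)
  perm <- sample(nrow(subs))
  flags_perm <- flag_invalid(subs[perm, ])
  expect_identical(flags_perm[match(flags$id, flags_perm$id), ]$duplicate_contact,
                   flags$duplicate_contact)
  expect_identical(flags_perm[match(flags$id, flags_perm$id), ]$any_invalid,
                   flags$any_invalid)
})

test_that("inclusion levels nest monotonically and honour their criteria", {
  rec <- toy_records()
  flags <- flag_invalid(rec)
  expect_equal(apply_inclusion(rec, flags, "L0")$id, c("r2", "r3", "r4"))
  expect_equal(apply_inclusion(rec, flags, "L1")$id, c("r2", "r3"))
  expect_error(apply_inclusion(rec, flags, "L9"))

  for (s in 1:3) {
    pop <- small_pop(n = 400, seed = s)
    cfg <- simulation_config(n_seeds = 5, rng_seed = s)
    subs <- fabricate_submissions(simulate_recruitment(pop, cfg), pop, cfg)
    fl <- flag_invalid(subs)
    sizes <- vapply(c("L0", "L1", "L2", "L3"),
                    function(l) nrow(apply_inclusion(subs, fl, l)), 0L)
    expect_true(all(diff(sizes) <= 0))
    ids <- lapply(c("L0", "L1", "L2", "L3"),
                  function(l) apply_inclusion(subs, fl, l)$id)
    expect_true(all(ids[[4]] %in% ids[[3]]) && all(ids[[3]] %in% ids[[2]]) &&
                  all(ids[[2]] %in% ids[[1]]))
    # level sizes agree with the generator's injection bookkeeping
    inj <- attr(subs, "injected")
    nonseed <- !subs$is_seed
    expect_equal(sum(nonseed & !inj$underage), length(ids[[1]]))
    expect_equal(sum(nonseed & !inj$underage & !inj$duplicate_contact),
                 length(ids[[2]]))
    expect_equal(sum(nonseed & !inj$underage & !inj$duplicate_contact &
                       !inj$duplicate_ip), length(ids[[3]]))
  }
})

test_that("orphan reattachment finds the nearest retained ancestor", {
  f <- data.frame(id = c("s", "a", "b"),
                  individual = 1:3,
                  recruiter_id = c(NA, "s", "a"),
                  wave = c(0L, 1L, 2L),
                  chain = "s",
                  timestamp = 1:3, stringsAsFactors = FALSE)
  class(f) <- c("rds_forest", "data.frame")
  # excluding the leaf changes nothing upstream
  g <- reattach_orphans(f, "b")
  expect_equal(g$id, c("s", "a"))
  expect_equal(g$wave, c(0L, 1L))
  # excluding the middle re-parents b to s at wave 1
  g <- reattach_orphans(f, "a")
  expect_equal(g$recruiter_id[g$id == "b"], "s")
  expect_equal(g$wave[g$id == "b"], 1L)
  # excluding the seed promotes a to pseudo-seed
  g <- reattach_orphans(f, "s")
  expect_true(is.na(g$recruiter_id[g$id == "a"]))
  expect_equal(g$wave, c(0L, 1L))
  expect_error(reattach_orphans(f, "zz"), "not all present")
})

test_that("reattachment never leaves an excluded parent (random forests)", {
  for (s in 1:3) {
    pop <- small_pop(n = 200, seed = s + 20)
    forest <- simulate_recruitment(pop, small_sim(seed = s + 20,
                                                  participation_probability = 0.7))
    excl <- sample(forest$id, min(10, nrow(forest) - 2))
    rep_f <- reattach_orphans(forest, excl)
    expect_false(any(rep_f$id %in% excl))
    expect_false(any(stats::na.omit(rep_f$recruiter_id) %in% excl))
    # new parent must be the nearest retained ancestor in the original forest
    orig_parent <- stats::setNames(forest$recruiter_id, forest$id)
    for (i in seq_len(nrow(rep_f))) {
      anc <- orig_parent[[rep_f$id[i]]]
      while (!is.na(anc) && anc %in% excl) anc <- orig_parent[[anc]]
      expect_identical(rep_f$recruiter_id[i], unname(anc))
    }
    # waves consistent with repaired parents
    nonseed <- !is.na(rep_f$recruiter_id)
    pw <- rep_f$wave[match(rep_f$recruiter_id[nonseed], rep_f$id)]
    expect_equal(rep_f$wave[nonseed], pw + 1L)
  }
})

test_that("sensitivity report recomputes estimates per level against L0", {
  rec <- toy_records()
  flags <- flag_invalid(rec)
  sens <- sensitivity_report(rec, flags, "province")
  expect_s3_class(sens, "rds_sensitivity")
  # L0 keeps r2 (Y, d=2), r3 (X, imputed), r4 (Y, d=8); L1 drops r4
  d3 <- impute_network_size(c(2, NA, 8))[2]
  l0x <- (1 / d3) / (1 / 2 + 1 / d3 + 1 / 8)
  expect_equal(sens$rdsii_estimate[sens$level == "L0" & sens$category == "X"],
               l0x, tolerance = 1e-12)
  d3b <- impute_network_size(c(2, NA))[2]
  l1x <- (1 / d3b) / (1 / 2 + 1 / d3b)
  expect_equal(sens$rdsii_estimate[sens$level == "L1" & sens$category == "X"],
               l1x, tolerance = 1e-12)
  expect_equal(sens$abs_diff_vs_L0[sens$level == "L0"], c(0, 0))
  expect_equal(max(sens$abs_diff_vs_L0), abs(l1x - l0x), tolerance = 1e-12)
  # identical records across levels: all differences zero
  clean <- rec
  clean$phone_token[4] <- "+84 900088"
  clean$stated_age[5] <- 20
  sens2 <- sensitivity_report(clean, flag_invalid(clean), "province")
  expect_equal(max(sens2$abs_diff_vs_L0), 0)
  expect_error(sensitivity_report(rec[rec$is_seed, ], flag_invalid(rec[rec$is_seed, ]),
                                  "province"), "L0")
})
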