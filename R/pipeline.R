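#' Default end-to-end pipeline configuration
#'
#' The packaged study conditions: a 2000-individual population with Poisson(8)
#' degrees, strong geographic clustering across eight provinces (two large
#' metropolitan areas holding 70\% of the population, province homophily 0.90
#' so that roughly 30\% of ties — and hence recruitment events — cross
#' provinces), a moderately homophilous binary partner-preference trait, 20
#' seeds, 4 invitations per participant and voluntary participation at 0.35,
#' which yields a few-hundred-participant sample that dies out by local
#' saturation. Reported network sizes are the 7-day internet-contact analogue:
#' Poisson noise around 0.7 of the true degree (mean about 5.6) with 10\%
#' refusal.
#'
#' @param rng_seed Master seed; every stage derives its own stream from it.
#' @return A list of class \code{pipeline_config} with components
#'   \code{population}, \code{simulation}, \code{level}, \code{variables},
#'   \code{binning}, \code{k}, \code{tolerance}, \code{composition_step},
#'   \code{rng_seed}.
#' @export
default_pipeline_config <- function(rng_seed = 1) {
  provinces <- c(hcmc = 0.35, hanoi = 0.35, haiphong = 0.06, danang = 0.06,
                 cantho = 0.06, hue = 0.04, nhatrang = 0.04, vinh = 0.04)
  pop <- population_config(
    n_individuals = 2000,
    degree_model = list(model = "poisson", lambda = 8),
    traits = list(
      trait_spec("partner_preference", c("men_only", "both"),
                 c(0.8, 0.2), homophily = 0.3),
      trait_spec("disclosure", c("open", "hidden"), c(0.35, 0.65),
                 homophily = 0.2)),
    provinces = provinces,
    province_homophily = 0.90)
  sim <- simulation_config(rng_seed = rng_seed)
  structure(list(population = pop, simulation = sim,
                 level = "L1",
                 variables = c("province", "partner_preference", "disclosure",
                               "education", "income", "age_group"),
                 binning = list(age_group = list(source = "stated_age",
                                                 breaks = c(18, 21, 24, 29, 40))),
                 k = 200, tolerance = 0.02, composition_step = 25,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

pipeline_log <- function(outdir, fmt, ...) {
  line <- sprintf("[%s] %s", "webrds", sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = file.path(outdir, "pipeline.log"),
      append = TRUE)
  if (isTRUE(getOption("webrds.verbose"))) message(line)
}

add_binned_columns <- function(records, binning) {
  for (nm in names(binning)) {
    b <- binning[[nm]]
    records[[nm]] <- bin_numeric(records[[b$source]], b$breaks)
  }
  records
}

#' Run the webRDS analysis pipeline
#'
#' Orchestrates the stages \code{simulate} (population, recruitment,
#' submission fabrication), \code{clean} (validity flags, inclusion levels),
#' \code{estimate} (RDS-II estimates and inclusion-level sensitivity),
#' \code{diagnose} (transition matrices, equilibrium, running composition,
#' last-k stability, chain statistics, cross-province recruitment) and
#' \code{report}. Each stage reads and writes plain-text artifacts (CSV/JSON)
#' in \code{outdir}, logs its input/output record counts, and the run ends by
#' writing a manifest with an MD5 hash per artifact. Identical configuration
#' and seed reproduce identical data artifacts.
#'
#' @param config A [default_pipeline_config()]-style configuration.
#' @param stages Subset of \code{c("simulate","clean","estimate","diagnose",
#'   "report")}; dependencies must be satisfied by earlier stages or existing
#'   files in \code{outdir}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with \code{status} (0 on success) and
#'   \code{manifest} (data frame of artifacts and hashes).
#' @export
run_rds_pipeline <- function(config = default_pipeline_config(),
                             stages = c("simulate", "clean", "estimate",
                                        "diagnose", "report"),
                             outdir = file.path(tempdir(), "webrds_run")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  need <- function(f, stage) {
    if (!file.exists(path(f)))
      stopf("stage '%s' needs %s; run its upstream stage first", stage, f)
    path(f)
  }

  if ("simulate" %in% stages) {
    pop <- generate_population(config$population, config$rng_seed)
    forest <- simulate_recruitment(pop, config$simulation)
    subs <- fabricate_submissions(forest, pop, config$simulation)
    write_submissions(subs, path("submissions.csv"))
    write_forest(forest, path("recruiter_edges.csv"))
    write_population_edges(pop, path("population_edges.csv"))
    yaml::write_yaml(list(rng_seed = config$rng_seed,
                          n_individuals = config$population$n_individuals,
                          n_seeds = config$simulation$n_seeds,
                          coupons = config$simulation$coupons_per_participant,
                          participation = config$simulation$participation_probability,
                          level = config$level),
                     path("config.yaml"))
    inj <- attr(subs, "injected")
    utils::write.csv(inj, path("injected_flags.csv"), row.names = FALSE)
    pipeline_log(outdir, "simulate: %d individuals in, %d submissions out (%d seeds)",
                 config$population$n_individuals, nrow(subs),
                 sum(subs$is_seed))
  }

  if ("clean" %in% stages) {
    subs <- read_submissions(need("submissions.csv", "clean"))
    flags <- flag_invalid(subs)
    utils::write.csv(flags, path("flags.csv"), row.names = FALSE)
    for (lev in c("L0", "L1", "L2", "L3")) {
      ids <- apply_inclusion(subs, flags, lev)$id
      writeLines(ids, path(sprintf("included_%s.txt", lev)))
    }
    cleaned <- apply_inclusion(subs, flags, config$level)
    write_submissions(cleaned, path("cleaned_submissions.csv"))
    pipeline_log(outdir,
                 "clean: %d in, %d excluded (seeds + %s criteria), %d out",
                 nrow(subs), nrow(subs) - nrow(cleaned), config$level,
                 nrow(cleaned))
  }

  if ("estimate" %in% stages) {
    cleaned <- read_submissions(need("cleaned_submissions.csv", "estimate"))
    cleaned <- add_binned_columns(cleaned, config$binning)
    fit <- rdsII(stats::reformulate(config$variables), data = cleaned)
    est <- summary(fit)$estimates
    est <- data.frame(level = config$level, est, stringsAsFactors = FALSE)
    utils::write.csv(est, path("estimates.csv"), row.names = FALSE)
    subs <- read_submissions(need("submissions.csv", "estimate"))
    subs <- add_binned_columns(subs, config$binning)
    sens <- sensitivity_report(subs, flag_invalid(subs),
                               setdiff(config$variables, names(config$binning)))
    utils::write.csv(sens, path("sensitivity.csv"), row.names = FALSE)
    pipeline_log(outdir, "estimate: %d records in, %d estimate rows out (mean degree %.2f)",
                 nrow(cleaned), nrow(est), fit$mean_degree)
  }

  if ("diagnose" %in% stages) {
    cleaned <- read_submissions(need("cleaned_submissions.csv", "diagnose"))
    cleaned <- add_binned_columns(cleaned, config$binning)
    forest <- read_forest(need("recruiter_edges.csv", "diagnose"))
    subs <- read_submissions(need("submissions.csv", "diagnose"))
    repaired <- reattach_orphans(forest, setdiff(forest$id, cleaned$id))
    degrees <- impute_network_size(cleaned$reported_network_size)

    allsubs <- add_binned_columns(subs, config$binning)
    eq <- equilibrium_report(repaired, allsubs, config$variables,
                             tolerance = config$tolerance)
    eq_json <- list(tolerance = eq$tolerance, max_waves = eq$max_waves,
                    median_waves = eq$median_waves,
                    variables = lapply(eq$variables, function(v)
                      list(variable = v$variable, waves_needed = v$waves_needed,
                           stationary = as.list(v$pi), note = v$note)))
    jsonlite::write_json(eq_json, path("equilibrium.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    comp <- lapply(config$variables, function(v)
      data.frame(variable = v,
                 running_composition(cleaned, degrees, v,
                                     step = config$composition_step)))
    utils::write.csv(do.call(rbind, comp), path("running_composition.csv"),
                     row.names = FALSE)

    ws <- wave_stats(forest)
    utils::write.csv(ws$chains, path("chain_stats.csv"), row.names = FALSE)
    utils::write.csv(ws$cumulative, path("cumulative_submissions.csv"),
                     row.names = FALSE)

    lastk <- last_k_comparison(cleaned, degrees,
                               c(config$variables, "stated_age",
                                 "partners_6mo"),
                               k = min(config$k, nrow(cleaned) - 1))
    cross <- cross_group_recruitment_fraction(repaired, cleaned, "province")
    diag <- list(max_wave = ws$max_wave, n_chains = ws$n_chains,
                 chains_deeper_than_threshold = ws$n_exceeding,
                 wave_threshold = ws$wave_threshold,
                 cross_province_fraction = cross,
                 estimated_mean_network_size = rdsii_mean_degree(degrees),
                 last_k = stats::setNames(as.list(lastk$max_abs_diff),
                                          lastk$variable),
                 k = min(config$k, nrow(cleaned) - 1))
    jsonlite::write_json(diag, path("diagnostics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    pipeline_log(outdir, "diagnose: %d records in, max wave %d, cross-province %.3f",
                 nrow(cleaned), ws$max_wave, cross)
  }

  if ("report" %in% stages) {
    build_report(outdir)
    pipeline_log(outdir, "report: written to report.txt")
  }

  files <- setdiff(list.files(outdir), c("manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, path("manifest.json"), pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest, outdir = outdir))
}

#' Assemble a human-readable report from pipeline artifacts
#'
#' Reads the estimate and diagnostic artifacts in \code{outdir} and writes
#' \code{report.txt} (cleaning summary, per-variable sample vs RDS-II
#' estimates, equilibrium table with max/median waves, chain statistics) plus
#' the four figure types: recruitment chains, cumulative submissions,
#' composition-stabilization curves and sample-vs-estimate bars.
#'
#' @param outdir Directory holding the pipeline artifacts.
#' @return Path to \code{report.txt}, invisibly.
#' @export
build_report <- function(outdir) {
  path <- function(f) file.path(outdir, f)
  for (f in c("estimates.csv", "equilibrium.json", "diagnostics.json"))
    if (!file.exists(path(f)))
      stopf("build_report needs %s; run the estimate/diagnose stages first", f)
  est <- utils::read.csv(path("estimates.csv"), stringsAsFactors = FALSE)
  eq <- jsonlite::read_json(path("equilibrium.json"))
  dg <- jsonlite::read_json(path("diagnostics.json"))
  subs <- read_submissions(path("submissions.csv"))
  flags <- utils::read.csv(path("flags.csv"))

  con <- file(path("report.txt"), "w")
  on.exit(close(con))
  w <- function(fmt, ...) cat(sprintf(fmt, ...), "\n", sep = "", file = con)
  w("webRDS pipeline report")
  w("======================")
  w("")
  w("Cleaning summary")
  w("  submissions: %d (%d seeds)", nrow(subs), sum(subs$is_seed))
  w("  invalid (underage or duplicate contact): %d (%.1f%% of submissions)",
    sum(flags$any_invalid), 100 * mean(flags$any_invalid))
  w("  excluded at L1 (seeds + invalid): %d (%.0f%% of submissions)",
    nrow(subs) - sum(!subs$is_seed & !flags$any_invalid),
    100 * (nrow(subs) - sum(!subs$is_seed & !flags$any_invalid)) / nrow(subs))
  w("")
  w("Estimates (level %s, n = %d)", est$level[1], est$n[1])
  for (v in unique(est$variable)) {
    w("  %s", v)
    ev <- est[est$variable == v, ]
    for (i in seq_len(nrow(ev)))
      w("    %-20s sample %.3f   RDS-II %.3f",
        ifelse(is.na(ev$category[i]), "(mean)", ev$category[i]),
        ev$sample_proportion[i], ev$rdsii_estimate[i])
  }
  w("")
  w("Equilibrium (relative tolerance %.3g)", eq$tolerance)
  for (v in eq$variables)
    w("  %-24s waves needed: %s%s", v$variable,
      ifelse(is.null(v$waves_needed) || is.na(v$waves_needed), "NA",
             v$waves_needed),
      ifelse(identical(v$note, "ok"), "", paste0("  [", v$note, "]")))
  w("  max waves: %s, median waves: %s", eq$max_waves, eq$median_waves)
  w("")
  w("Recruitment structure")
  w("  chains: %d, deepest wave: %d, chains deeper than %d waves: %d",
    dg$n_chains, dg$max_wave, dg$wave_threshold,
    dg$chains_deeper_than_threshold)
  w("  cross-province recruitment events: %.1f%%",
    100 * dg$cross_province_fraction)
  w("  estimated mean network size: %.2f", dg$estimated_mean_network_size)
  w("  last-%s max |difference| per variable:", dg$k)
  for (v in names(dg$last_k)) w("    %-24s %.4f", v, dg$last_k[[v]])

  # figures
  forest <- read_forest(path("recruiter_edges.csv"))
  grDevices::png(path("fig_chains.png"), 900, 700)
  plot(forest)
  grDevices::dev.off()
  grDevices::png(path("fig_cumulative.png"), 700, 500)
  plot(wave_stats(forest))
  grDevices::dev.off()
  comp <- utils::read.csv(path("running_composition.csv"),
                          stringsAsFactors = FALSE)
  v1 <- comp$variable[1]
  sub <- comp[comp$variable == v1, -1]
  attr(sub, "variable") <- v1
  class(sub) <- c("rds_composition", "data.frame")
  grDevices::png(path("fig_composition.png"), 700, 500)
  plot(sub)
  grDevices::dev.off()
  grDevices::png(path("fig_estimates.png"), 900, 700)
  cats <- est[est$type == "proportion", ]
  v2 <- unique(cats$variable)[1]
  ev <- cats[cats$variable == v2, ]
  m <- rbind(sample = ev$sample_proportion, `RDS-II` = ev$rdsii_estimate)
  colnames(m) <- ev$category
  graphics::barplot(m, beside = TRUE, main = v2, ylab = "proportion",
                    legend.text = TRUE, args.legend = list(bty = "n"))
  grDevices::dev.off()
  invisible(path("report.txt"))
}
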