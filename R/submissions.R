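#' Fabricate a survey submission table for a recruitment forest
#'
#' Produces one submission record per sampled participant, carrying identity
#' tokens (phone, e-mail, chat id), an IP token, timing, questionnaire answers
#' and the self-reported 7-day network size, and injects invalid records at the
#' configured rates: underage (stated age below 18), duplicated contact tokens
#' (copied from an earlier submission), shared IP addresses and implausibly
#' fast completions (under 3 minutes). Injection applies to non-seed records
#' only, and the exact injected flags are kept alongside the table as
#' bookkeeping so cleaning can be validated record by record.
#'
#' The reported network size emulates the "internet-using contacts in the past
#' 7 days" question: Poisson noise around \code{fraction * true_degree}, with
#' refusals at \code{network_size_missing_rate} stored as \code{NA}. A reported
#' value of 0 is possible and is treated as missing by the estimators.
#'
#' @param forest An \code{rds_forest} from [simulate_recruitment()].
#' @param pop The \code{rds_population} the forest was drawn from.
#' @param config The [simulation_config()] used for the simulation.
#' @return A data frame of submissions ordered by timestamp, with attribute
#'   \code{"injected"}: a data frame of the injected invalidity flags per id.
#' @export
fabricate_submissions <- function(forest, pop, config) {
  stopifnot(inherits(forest, "rds_forest"), inherits(pop, "rds_population"))
  if (!all(forest$individual %in% pop$attributes$id))
    stopf("forest references individuals outside the population")
  set.seed(derive_seed(config$rng_seed, 29L))

  ord <- order(forest$timestamp, forest$id)
  forest <- forest[ord, , drop = FALSE]
  n <- nrow(forest)
  at <- pop$attributes[match(forest$individual, pop$attributes$id), , drop = FALSE]

  subs <- data.frame(id = forest$id,
                     recruiter_id = forest$recruiter_id,
                     is_seed = is.na(forest$recruiter_id),
                     timestamp = forest$timestamp,
                     stringsAsFactors = FALSE)
  subs$completion_minutes <- round(pmax(4, stats::rlnorm(n, log(12), 0.4)), 1)
  subs$phone_token <- sprintf("+84 9%07d", seq_len(n))
  subs$email_token <- sprintf("user%05d@mail.example", seq_len(n))
  subs$chat_token <- sprintf("chat_%05d", seq_len(n))
  subs$ip_token <- sprintf("ip-%06d", seq_len(n))
  subs$stated_age <- at$age
  # honest submissions always state some education; a "none" answer is one of
  # the suspicion screens, so it only appears in hand-built or real data
  subs$education <- sample(c("primary", "secondary", "high_school",
                             "vocational", "university"),
                           n, replace = TRUE,
                           prob = c(0.08, 0.12, 0.25, 0.15, 0.40))
  subs$income <- sample(c("low", "middle", "high"), n, replace = TRUE,
                        prob = c(0.35, 0.45, 0.20))
  subs$province <- at$province
  subs$partners_6mo <- stats::rnbinom(n, size = 1.2, mu = 2.5)
  for (tr in pop$config$traits) subs[[tr$name]] <- at[[tr$name]]
  if ("degree_trait" %in% names(at)) subs$degree_trait <- at$degree_trait

  frac <- config$network_size_noise$fraction %||% 0.7
  subs$reported_network_size <- stats::rpois(n, frac * at$true_degree)
  miss <- stats::runif(n) < config$network_size_missing_rate
  subs$reported_network_size[miss] <- NA_integer_

  inj <- config$invalid_injection
  nonseed <- which(!subs$is_seed)
  injected <- data.frame(id = subs$id,
                         underage = FALSE, duplicate_contact = FALSE,
                         duplicate_ip = FALSE, fast_completion = FALSE,
                         stringsAsFactors = FALSE)

  pick <- function(rate) nonseed[stats::runif(length(nonseed)) < (rate %||% 0)]

  for (i in pick(inj$underage_rate)) {
    subs$stated_age[i] <- sample(16:17, 1)
    injected$underage[i] <- TRUE
  }
  for (i in pick(inj$duplicate_token_rate)) {
    src <- sample.int(i - 1L, 1)            # records are in time order
    col <- sample(c("phone_token", "email_token", "chat_token"), 1)
    subs[[col]][i] <- subs[[col]][src]
    injected$duplicate_contact[i] <- TRUE
  }
  for (i in pick(inj$shared_ip_rate)) {
    subs$ip_token[i] <- subs$ip_token[sample.int(i - 1L, 1)]
    injected$duplicate_ip[i] <- TRUE
  }
  for (i in pick(inj$fast_completion_rate)) {
    subs$completion_minutes[i] <- round(stats::runif(1, 0.5, 2.9), 1)
    injected$fast_completion[i] <- TRUE
  }

  rownames(subs) <- NULL
  attr(subs, "injected") <- injected
  subs
}

#' Write / read the pipeline's plain-text artifacts
#'
#' Submissions are stored as a one-header-row CSV; the recruitment forest as a
#' child/parent edge CSV plus wave and timestamp columns; the population's tie
#' structure as an edge-list CSV.
#'
#' @param subs,forest,pop Objects produced by the simulation stage.
#' @param path Output file path.
#' @return The path, invisibly (writers); the object (readers).
#' @name webrds_io
NULL

#' @rdname webrds_io
#' @export
write_submissions <- function(subs, path) {
  utils::write.csv(subs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname webrds_io
#' @export
read_submissions <- function(path) {
  subs <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character",
                                         recruiter_id = "character"))
  subs$recruiter_id[subs$recruiter_id == ""] <- NA_character_
  token_cols <- intersect(c("phone_token", "email_token", "chat_token",
                            "ip_token"), names(subs))
  for (col in token_cols) subs[[col]][is.na(subs[[col]])] <- ""
  subs$is_seed <- as.logical(subs$is_seed)
  subs
}

#' @rdname webrds_io
#' @export
write_forest <- function(forest, path) {
  out <- data.frame(child_id = forest$id, parent_id = forest$recruiter_id,
                    individual = forest$individual, wave = forest$wave,
                    chain = forest$chain, timestamp = forest$timestamp)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname webrds_io
#' @export
read_forest <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(child_id = "character",
                                      parent_id = "character",
                                      chain = "character"))
  x$parent_id[x$parent_id == ""] <- NA_character_
  forest <- data.frame(id = x$child_id, individual = x$individual,
                       recruiter_id = x$parent_id, wave = x$wave,
                       chain = x$chain, timestamp = x$timestamp,
                       stringsAsFactors = FALSE)
  class(forest) <- c("rds_forest", "data.frame")
  forest
}

#' @rdname webrds_io
#' @export
write_population_edges <- function(pop, path) {
  el <- igraph::as_edgelist(pop$graph, names = FALSE)
  utils::write.csv(data.frame(from = el[, 1], to = el[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}
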