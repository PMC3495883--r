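#' Normalize an identity token
#'
#' Canonicalizes contact tokens before duplicate detection: whitespace is
#' trimmed, letters lower-cased, and for phone numbers everything but digits is
#' stripped. Normalization is idempotent.
#'
#' @param x Character vector of tokens (\code{NA}/empty allowed).
#' @param type \code{"generic"} (e-mail, chat, IP) or \code{"phone"}.
#' @return Normalized character vector; \code{NA} and empty stay empty.
#' @export
normalize_token <- function(x, type = c("generic", "phone")) {
  type <- match.arg(type)
  x <- tolower(trimws(as.character(x)))
  if (type == "phone") x <- gsub("[^0-9]", "", x)
  x[is.na(x)] <- ""
  x
}

#' Flag invalid submissions
#'
#' Computes, from the record set alone, the validity flags used to screen a
#' webRDS sample: stated age below 18; a phone, e-mail or chat token already
#' registered by a chronologically earlier record; an IP token seen earlier;
#' completion under 3 minutes; no education; and more than 1,000 sexual
#' partners in six months. The earliest bearer of a token (by timestamp, ties
#' by id) is never flagged as a duplicate.
#'
#' @param records Data frame of submissions (see [fabricate_submissions()] for
#'   the column schema); \code{id} must be unique.
#' @return A data frame of class \code{rds_flags}, one row per record in the
#'   input order: \code{id}, \code{underage}, \code{duplicate_contact},
#'   \code{duplicate_ip}, \code{fast_completion}, \code{no_education},
#'   \code{extreme_partners}, and \code{any_invalid} (underage or duplicated
#'   contact token, the core invalidity screen for webRDS samples).
#' @export
flag_invalid <- function(records) {
  if (anyDuplicated(records$id)) stopf("duplicate submission ids")
  n <- nrow(records)
  ord <- order(records$timestamp, records$id)

  dup_earlier <- function(tokens) {
    # TRUE for every record whose token appeared on an earlier record
    out <- logical(n)
    tk <- tokens[ord]
    nonempty <- !is.na(tk) & tk != ""
    key <- ifelse(nonempty, tk, paste0("__empty", seq_len(n)))
    out[ord] <- nonempty & duplicated(key)
    out
  }

  dup_contact <- logical(n)
  for (spec in list(c("phone_token", "phone"), c("email_token", "generic"),
                    c("chat_token", "generic"))) {
    col <- spec[1]
    if (!col %in% names(records)) next
    dup_contact <- dup_contact |
      dup_earlier(normalize_token(records[[col]], spec[2]))
  }
  dup_ip <- if ("ip_token" %in% names(records))
    dup_earlier(normalize_token(records$ip_token)) else logical(n)

  col_or_false <- function(col, f) {
    if (!col %in% names(records)) return(logical(n))
    v <- f(records[[col]])
    v[is.na(v)] <- FALSE
    v
  }
  flags <- data.frame(
    id = records$id,
    underage = col_or_false("stated_age", function(a) a < 18),
    duplicate_contact = dup_contact,
    duplicate_ip = dup_ip,
    fast_completion = col_or_false("completion_minutes", function(m) m < 3),
    no_education = col_or_false("education", function(e) e == "none"),
    extreme_partners = col_or_false("partners_6mo", function(p) p > 1000),
    stringsAsFactors = FALSE)
  flags$any_invalid <- flags$underage | flags$duplicate_contact
  class(flags) <- c("rds_flags", "data.frame")
  flags
}

#' Inclusion levels for sensitivity analysis
#'
#' Progressively stricter inclusion criteria, cumulative by construction:
#' \describe{
#'   \item{L0}{non-seed submissions with valid (>= 18) stated age;}
#'   \item{L1}{L0 minus duplicated contact tokens (the "cleaned sample");}
#'   \item{L2}{L1 minus duplicated IP tokens;}
#'   \item{L3}{L2 minus fast completions, no-education answers and extreme
#'     partner counts.}
#' }
#' Seeds are always excluded, as is customary in RDS analysis.
#'
#' @param records Data frame of submissions.
#' @param flags The \code{rds_flags} computed from the same records.
#' @param level One of \code{"L0"}, \code{"L1"}, \code{"L2"}, \code{"L3"}.
#' @return The subset of \code{records} passing the level's criteria.
#' @export
apply_inclusion <- function(records, flags, level = c("L1", "L0", "L2", "L3")) {
  level <- match.arg(level)
  if (!identical(records$id, flags$id))
    flags <- flags[match(records$id, flags$id), , drop = FALSE]
  if (anyNA(flags$id)) stopf("flags were not computed from these records")
  seed <- if ("is_seed" %in% names(records)) records$is_seed
          else is.na(records$recruiter_id) | records$recruiter_id == ""
  keep <- !seed & !flags$underage
  if (level %in% c("L1", "L2", "L3")) keep <- keep & !flags$duplicate_contact
  if (level %in% c("L2", "L3")) keep <- keep & !flags$duplicate_ip
  if (level == "L3") keep <- keep & !flags$fast_completion &
    !flags$no_education & !flags$extreme_partners
  records[keep, , drop = FALSE]
}

#' Repair recruitment chains after exclusions
#'
#' Dropping invalid records orphans their retained descendants. Each retained
#' descendant of an excluded node is re-parented to its nearest retained
#' ancestor; if none exists it is promoted to a pseudo-seed (wave 0). Wave
#' numbers are recomputed from the repaired parent map. The repair is purely
#' diagnostic: RDS-II estimation ignores tree structure.
#'
#' @param forest An \code{rds_forest}.
#' @param excluded_ids Character vector of record ids to drop (must be forest
#'   nodes).
#' @return The repaired \code{rds_forest} over the retained nodes.
#' @export
reattach_orphans <- function(forest, excluded_ids) {
  if (!all(excluded_ids %in% forest$id))
    stopf("excluded ids not all present in forest")
  excluded <- forest$id %in% excluded_ids
  parent <- forest$recruiter_id
  idx <- match(parent, forest$id)
  # climb each retained node's ancestry to the nearest retained ancestor
  new_parent <- parent
  for (i in which(!excluded)) {
    j <- idx[i]
    while (!is.na(j) && excluded[j]) j <- idx[j]
    new_parent[i] <- if (is.na(j)) NA_character_ else forest$id[j]
  }
  out <- forest[!excluded, , drop = FALSE]
  out$recruiter_id <- new_parent[!excluded]
  out$wave <- recompute_waves(out$id, out$recruiter_id)
  root_idx <- match(out$recruiter_id, out$id)
  chain <- seq_len(nrow(out))
  for (i in seq_len(nrow(out))) if (!is.na(root_idx[i])) chain[i] <- chain[root_idx[i]]
  out$chain <- out$id[chain]
  rownames(out) <- NULL
  class(out) <- c("rds_forest", "data.frame")
  out
}

#' RDS-II estimates under progressively stricter inclusion
#'
#' Recomputes the RDS-II estimates of every requested variable at each
#' inclusion level and reports, per category, the absolute difference from the
#' L0 baseline. Small differences indicate that invalid submissions did not
#' bias the estimates.
#'
#' @param records Data frame of submissions.
#' @param flags \code{rds_flags} for the records.
#' @param variables Character vector of variable names to estimate.
#' @param network.size Column holding the reported network size.
#' @param levels Inclusion levels to compare (default all four).
#' @return A data frame of class \code{rds_sensitivity} with columns
#'   \code{level}, \code{variable}, \code{category}, \code{n},
#'   \code{sample_proportion}, \code{rdsii_estimate}, \code{abs_diff_vs_L0}.
#' @export
sensitivity_report <- function(records, flags, variables,
                               network.size = "reported_network_size",
                               levels = c("L0", "L1", "L2", "L3")) {
  rows <- list()
  baseline <- NULL
  for (lev in levels) {
    sub <- apply_inclusion(records, flags, lev)
    if (nrow(sub) == 0) stopf("inclusion level %s is empty", lev)
    fit <- rdsII(stats::reformulate(variables), data = sub,
                 network.size = network.size)
    tab <- summary(fit)$estimates
    tab <- tab[tab$type == "proportion", , drop = FALSE]
    tab <- data.frame(level = lev, tab[, c("variable", "category", "n",
                                           "sample_proportion",
                                           "rdsii_estimate")],
                      stringsAsFactors = FALSE)
    rows[[lev]] <- tab
    if (lev == levels[1]) baseline <- tab
  }
  out <- do.call(rbind, rows)
  key <- paste(out$variable, out$category)
  bkey <- paste(baseline$variable, baseline$category)
  out$abs_diff_vs_L0 <- abs(out$rdsii_estimate -
                              baseline$rdsii_estimate[match(key, bkey)])
  rownames(out) <- NULL
  class(out) <- c("rds_sensitivity", "data.frame")
  out
}

#' @export
print.rds_sensitivity <- function(x, digits = 3, ...) {
  cat("RDS-II sensitivity to inclusion criteria\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("Max |difference| vs baseline: %.4f\n",
              max(x$abs_diff_vs_L0, na.rm = TRUE)))
  invisible(x)
}
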