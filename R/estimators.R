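#' Impute missing network sizes with the RDS-II mean degree
#'
#' Missing (and zero, see Details) reported network sizes are replaced by the
#' RDS-II estimate of the population mean degree computed from the non-missing
#' values, \eqn{\hat d = n / \sum_i 1/d_i} — a harmonic mean, which under
#' degree-proportional inclusion estimates the population's arithmetic mean
#' degree.
#'
#' A reported size of 0 is treated as missing: a participant recruited through
#' the network has at least one contact by construction, and the inverse-degree
#' weight \eqn{1/d} is undefined at zero.
#'
#' @param degrees Numeric vector of reported network sizes, \code{NA} allowed.
#' @return Numeric vector with every missing/zero entry replaced by
#'   \eqn{\hat d}; non-missing positive entries are returned unchanged.
#' @examples
#' impute_network_size(c(1, 4, NA))  # 2 / (1 + 1/4) = 1.6
#' @export
impute_network_size <- function(degrees) {
  degrees <- as.numeric(degrees)
  valid <- !is.na(degrees) & degrees > 0
  if (!any(valid)) stopf("no positive non-missing network sizes to impute from")
  dhat <- sum(valid) / sum(1 / degrees[valid])
  degrees[!valid] <- dhat
  degrees
}

#' RDS-II harmonic-mean degree estimate
#'
#' @param degrees Positive reported network sizes (no missing values).
#' @return \eqn{\hat d = n / \sum 1/d_i}.
#' @export
rdsii_mean_degree <- function(degrees) {
  if (length(degrees) == 0) stopf("empty degree vector")
  if (anyNA(degrees) || any(degrees <= 0)) stopf("degrees must be positive; impute first")
  length(degrees) / sum(1 / degrees)
}

#' RDS-II estimated category proportions
#'
#' The Volz-Heckathorn RDS-II estimator weights each respondent by the
#' reciprocal of their personal network size, correcting for the
#' degree-proportional inclusion of chain-referral samples:
#' \deqn{\hat p_A = \frac{\sum_{i \in A} 1/d_i}{\sum_i 1/d_i}.}
#'
#' @param categories Vector (factor or character) of category answers; factor
#'   levels with no members receive estimate 0.
#' @param degrees Positive network sizes, one per respondent (impute first).
#' @return Named numeric vector of estimated proportions (sums to 1), with
#'   attribute \code{"n"} = sample size.
#' @examples
#' rdsii_proportion(c("A", "A", "B"), c(1, 2, 4))  # A: 6/7
#' @export
rdsii_proportion <- function(categories, degrees) {
  if (length(categories) == 0) stopf("empty sample")
  if (length(categories) != length(degrees)) stopf("lengths differ")
  if (anyNA(degrees) || any(degrees <= 0)) stopf("degrees must be positive; impute first")
  f <- if (is.factor(categories)) categories else factor(categories)
  w <- 1 / degrees
  num <- vapply(split(w, f), sum, 0)
  num[is.na(num)] <- 0
  est <- num / sum(w)
  attr(est, "n") <- length(categories)
  est
}

#' RDS-II estimated mean of a numeric variable
#'
#' Inverse-degree-weighted mean \eqn{\hat x = \sum x_i/d_i / \sum 1/d_i}.
#' Missing values are dropped pairwise (with their degrees).
#'
#' @param values Numeric answers.
#' @param degrees Positive network sizes.
#' @return The weighted mean, with attribute \code{"n"} = respondents used.
#' @export
rdsii_mean <- function(values, degrees) {
  if (length(values) == 0) stopf("empty sample")
  if (length(values) != length(degrees)) stopf("lengths differ")
  keep <- !is.na(values)
  if (!any(keep)) stopf("all values missing")
  if (anyNA(degrees[keep]) || any(degrees[keep] <= 0))
    stopf("degrees must be positive; impute first")
  est <- stats::weighted.mean(values[keep], 1 / degrees[keep])
  attr(est, "n") <- sum(keep)
  est
}

#' Fit RDS-II population estimates for survey variables
#'
#' The main fitting interface: estimates population proportions (for
#' categorical variables) and means (for numeric variables) from a cleaned
#' chain-referral sample by inverse network-size weighting. Missing network
#' sizes are imputed with the harmonic-mean estimate from the non-missing ones
#' before any estimation; refusals on categorical analysis variables form
#' their own \code{"(no answer)"} category, while refusals on numeric
#' variables are dropped pairwise.
#'
#' @param formula One-sided formula naming the variables to estimate, e.g.
#'   \code{~ province + age}.
#' @param data Data frame of included (cleaned, non-seed) submissions.
#' @param network.size Column name holding reported network sizes, or a
#'   numeric vector aligned with \code{data}.
#' @param impute Impute missing/zero network sizes first (default TRUE).
#' @return An object of class \code{rdsII} with methods \code{print},
#'   \code{summary}, \code{coef} and \code{plot}. Components include
#'   \code{estimates} (per variable: type, RDS-II and raw sample statistics),
#'   \code{degrees} (post-imputation) and \code{mean_degree}.
#' @examples
#' d <- data.frame(group = c("A", "A", "B"), size = c(1, 2, 4))
#' fit <- rdsII(~ group, d, network.size = "size")
#' coef(fit)
#' @export
rdsII <- function(formula, data, network.size = "reported_network_size",
                  impute = TRUE) {
  vars <- all.vars(formula)
  if (length(vars) == 0) stopf("formula names no variables")
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stopf("variables not in data: %s", paste(missing_vars, collapse = ", "))
  if (nrow(data) == 0) stopf("empty sample")

  degrees <- if (is.character(network.size)) {
    if (!network.size %in% names(data)) stopf("network.size column '%s' not in data", network.size)
    as.numeric(data[[network.size]])
  } else as.numeric(network.size)
  if (length(degrees) != nrow(data)) stopf("network sizes do not match data rows")
  if (impute) degrees <- impute_network_size(degrees)
  else if (anyNA(degrees) || any(degrees <= 0))
    stopf("degrees must be positive when impute = FALSE")

  estimates <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      list(variable = v, type = "mean",
           rdsii = as.numeric(rdsii_mean(x, degrees)),
           sample = mean(x, na.rm = TRUE),
           n = sum(!is.na(x)))
    } else {
      xc <- as.character(x)
      xc[is.na(xc) | xc == ""] <- "(no answer)"
      est <- rdsii_proportion(xc, degrees)
      list(variable = v, type = "proportion",
           rdsii = est, sample = prop.table(table(xc))[names(est)],
           n = length(xc))
    }
  })
  names(estimates) <- vars
  structure(list(call = match.call(), variables = vars, estimates = estimates,
                 degrees = degrees, mean_degree = rdsii_mean_degree(degrees),
                 n = nrow(data), estimator = "RDSII"),
            class = "rdsII")
}

#' @export
print.rdsII <- function(x, digits = 3, ...) {
  cat(sprintf("RDS-II estimates (n = %d, estimated mean network size %.2f)\n\n",
              x$n, x$mean_degree))
  for (e in x$estimates) {
    if (e$type == "mean") {
      cat(sprintf("%s (numeric): RDS-II mean %.*f, sample mean %.*f (n = %d)\n",
                  e$variable, digits, e$rdsii, digits, e$sample, e$n))
    } else {
      cat(sprintf("%s:\n", e$variable))
      m <- rbind(`sample proportion` = as.numeric(e$sample),
                 `RDS-II estimate` = as.numeric(e$rdsii))
      colnames(m) <- names(e$rdsii)
      print(round(m, digits))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.rdsII <- function(object, ...) {
  rows <- lapply(object$estimates, function(e) {
    if (e$type == "mean") {
      data.frame(variable = e$variable, category = NA_character_,
                 type = "mean", n = e$n,
                 sample_proportion = e$sample, rdsii_estimate = e$rdsii,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = e$variable, category = names(e$rdsii),
                 type = "proportion", n = e$n,
                 sample_proportion = as.numeric(e$sample),
                 rdsii_estimate = as.numeric(e$rdsii),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(estimates = out, n = object$n,
                 mean_degree = object$mean_degree, call = object$call),
            class = "summary.rdsII")
}

#' @export
print.summary.rdsII <- function(x, digits = 4, ...) {
  cat(sprintf("RDS-II fit: n = %d, estimated mean network size %.3f\n",
              x$n, x$mean_degree))
  print.data.frame(x$estimates, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.rdsII <- function(object, ...) {
  out <- numeric(0)
  for (e in object$estimates) {
    if (e$type == "mean") {
      v <- e$rdsii; names(v) <- e$variable
    } else {
      v <- as.numeric(e$rdsii)
      names(v) <- paste(e$variable, names(e$rdsii), sep = ":")
    }
    out <- c(out, v)
  }
  out
}

#' Compare raw sample and RDS-II estimated compositions
#'
#' @param x An \code{rdsII} fit.
#' @param variables Which variables to plot (default: all categorical).
#' @param ... Passed to \code{barplot}.
#' @export
plot.rdsII <- function(x, variables = NULL, ...) {
  cats <- Filter(function(e) e$type == "proportion", x$estimates)
  if (!is.null(variables)) cats <- cats[intersect(names(cats), variables)]
  if (length(cats) == 0) stopf("no categorical variables to plot")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(cats)))
  on.exit(graphics::par(old))
  for (e in cats) {
    m <- rbind(sample = as.numeric(e$sample), `RDS-II` = as.numeric(e$rdsii))
    colnames(m) <- names(e$rdsii)
    graphics::barplot(m, beside = TRUE, main = e$variable,
                      ylab = "proportion", legend.text = TRUE,
                      args.legend = list(bty = "n"), ...)
  }
  invisible(x)
}
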