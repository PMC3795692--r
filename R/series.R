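#' Per-generation summary of a per-animal statistic
#'
#' Groups a named per-animal statistic by generation (optionally also by
#' sex and/or line) and reports n, mean, SD, median and quartiles per
#' group, dropping missing values with a count. The returned table is the
#' machine-readable substrate for per-generation trajectory plots and for
#' [rate_per_generation()].
#'
#' @param ped a [pedigree()].
#' @param statistic numeric vector aligned with `ped` rows (or the name of
#'   a column of `ped`).
#' @param group_by character vector of grouping columns; must include
#'   `"generation"`. Default `"generation"`.
#' @return data frame of class `series_summary` with the group keys and
#'   columns `n`, `n_missing`, `mean`, `sd`, `median`, `q25`, `q75`.
#' @export
series_summary <- function(ped, statistic, group_by = "generation") {
  if (is.character(statistic) && length(statistic) == 1L) {
    if (!statistic %in% names(ped)) stop("no column '", statistic, "'")
    statistic <- ped[[statistic]]
  }
  stopifnot(length(statistic) == nrow(ped), "generation" %in% group_by)
  keys <- lapply(group_by, function(g) ped[[g]])
  names(keys) <- group_by
  grp <- interaction(keys, drop = TRUE, sep = "\r")
  empty <- tapply(statistic, grp, function(v) all(is.na(v)))
  if (any(empty))
    warning("omitting ", sum(empty), " group(s) with no non-missing values")
  rows <- lapply(levels(grp)[!empty], function(lv) {
    v <- statistic[grp == lv]
    keep <- !is.na(v)
    q <- stats::quantile(v[keep], c(0.25, 0.5, 0.75), names = FALSE)
    key <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    out <- as.data.frame(as.list(stats::setNames(key, group_by)),
                         stringsAsFactors = FALSE)
    out$n <- sum(keep)
    out$n_missing <- sum(!keep)
    out$mean <- mean(v[keep])
    out$sd <- if (sum(keep) > 1L) stats::sd(v[keep]) else 0
    out$median <- q[2]
    out$q25 <- q[1]
    out$q75 <- q[3]
    out
  })
  res <- do.call(rbind, rows)
  res$generation <- as.integer(res$generation)
  res <- res[order(res$generation), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("series_summary", "data.frame")
  res
}

#' Rate of change of a per-generation series
#'
#' Two reporting conventions are supported for the change of a
#' per-generation mean between two generations:
#' \describe{
#'   \item{`absolute_points`}{`(mean_last - mean_first) / n_steps * 100`,
#'     i.e. percentage points per generation. The natural convention for
#'     inbreeding coefficients.}
#'   \item{`relative`}{`(mean_first - mean_last) / mean_first / n_steps *
#'     100`, i.e. percent of the starting value lost per generation. The
#'     natural convention for heterozygosity decline.}
#'   \item{`slope`}{ordinary least-squares slope of the per-generation
#'     mean on generation over the span, x 100. Preferred for rotational
#'     inbreeding series, whose 6-generation first-cousin cycle makes
#'     endpoint-based rates depend on where the endpoints fall in the
#'     cycle; the regression slope is phase-robust.}
#' }
#'
#' @param series a [series_summary()] (or any data frame with `generation`
#'   and `mean` columns).
#' @param span length-2 integer vector of generation endpoints; default is
#'   the full observed span.
#' @param mode `"absolute_points"` or `"relative"`.
#' @return rate in percent per generation (scalar).
#' @export
rate_per_generation <- function(series, span = range(series$generation),
                                mode = c("absolute_points", "relative",
                                         "slope")) {
  mode <- match.arg(mode)
  stopifnot(length(span) == 2L, span[2] > span[1])
  i1 <- match(span[1], series$generation)
  i2 <- match(span[2], series$generation)
  if (is.na(i1) || is.na(i2))
    stop("span endpoints not present in series")
  if (mode == "slope") {
    keep <- series$generation >= span[1] & series$generation <= span[2]
    g <- series$generation[keep]
    return(unname(stats::coef(stats::lm(series$mean[keep] ~ g))[2]) * 100)
  }
  n_steps <- span[2] - span[1]
  m1 <- series$mean[i1]
  m2 <- series$mean[i2]
  if (mode == "absolute_points") {
    (m2 - m1) / n_steps * 100
  } else {
    if (m1 == 0) stop("relative rate undefined: first mean is zero")
    (m1 - m2) / m1 / n_steps * 100
  }
}
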