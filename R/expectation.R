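#' Per-generation effective breeder counts
#'
#' Helper constructing/validating a breeder-count table: one row per
#' generation with the numbers of male (`n_male`) and female (`n_female`)
#' effective breeders. These counts drive the random-mating expectations
#' for inbreeding and heterozygosity.
#'
#' @param generation integer vector of generation indices (0-based).
#' @param n_male,n_female positive integer vectors (recycled if scalar).
#' @return data frame of class `breeder_counts`.
#' @export
breeder_counts <- function(generation, n_male, n_female = n_male) {
  out <- data.frame(generation = as.integer(generation),
                    n_male = as.integer(n_male),
                    n_female = as.integer(n_female))
  if (any(out$n_male < 1L | out$n_female < 1L, na.rm = TRUE))
    stop("breeder counts must be >= 1")
  class(out) <- c("breeder_counts", "data.frame")
  out
}

#' Bundled per-generation breeder census of the HCR/LCR selection colony
#'
#' Returns the published per-generation census of the 28-generation
#' high/low-capacity-runner rat colony: number of phenotyped animals and
#' number of effective breeders by sex, for one line.
#'
#' @param line `"HCR"` or `"LCR"`.
#' @return data frame with columns `generation`, `n_phenotyped`,
#'   `n_breeders`, `n_male`, `n_female` (class `breeder_counts`). Breeder
#'   counts are `NA` for the final two generations (no subsequent
#'   breeding round was recorded).
#' @export
colony_breeder_counts <- function(line = c("HCR", "LCR")) {
  line <- match.arg(line)
  path <- system.file("extdata", "colony_breeder_counts.tsv",
                      package = "rotbreed", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$line == line,
             c("generation", "n_phenotyped", "n_breeders", "n_male",
               "n_female")]
  rownames(tab) <- NULL
  class(tab) <- c("breeder_counts", "data.frame")
  tab
}

## per-step increment c_n = (N_f + N_m) / (8 N_f N_m)
step_increment <- function(n_male, n_female) {
  (n_female + n_male) / (8 * n_female * n_male)
}

#' Expected inbreeding trajectory under random mating
#'
#' Iterates the classical recursion
#' `F_{n+1} = F_n + (1 - F_n) * (N_f + N_m) / (8 N_f N_m)`
#' from a starting value `F0`, using the breeder counts of each
#' generation. With constant counts this is
#' `F_n = 1 - (1 - c)^n` with `c = (N_f + N_m)/(8 N_f N_m)`.
#'
#' @param counts a [breeder_counts()] table, or a single integer for a
#'   constant equal number of male and female breeders.
#' @param F0 initial inbreeding coefficient (default 0).
#' @param n_steps number of generations to iterate; defaults to the number
#'   of count rows with non-missing counts.
#' @param start_generation generation label of `F0` (default 0).
#' @return data frame of class `expectation_series` with columns
#'   `generation`, `value` (expected F) and `increment` (per-step change).
#' @export
expected_F_random_series <- function(counts, F0 = 0, n_steps = NULL,
                                     start_generation = 0L) {
  cn <- resolve_counts(counts, n_steps, start_generation)
  stopifnot(F0 >= 0, F0 <= 1)
  f <- numeric(length(cn) + 1L)
  f[1] <- F0
  for (k in seq_along(cn)) f[k + 1L] <- f[k] + (1 - f[k]) * cn[k]
  structure(data.frame(generation = start_generation + 0:length(cn),
                       value = f,
                       increment = c(NA, diff(f))),
            class = c("expectation_series", "data.frame"),
            statistic = "F")
}

#' Expected heterozygosity trajectory under random mating
#'
#' Iterates `H_{n+1} = H_n * (1 - (N_f + N_m) / (8 N_f N_m))` from a
#' starting heterozygosity `H0`; the per-step relative decrease equals the
#' increment `c_n` of the inbreeding recursion, so `H_n / H_0 = 1 - F_n`
#' when both recursions start from `F0 = 0`.
#'
#' @inheritParams expected_F_random_series
#' @param H0 initial mean heterozygosity in `[0, 1]`.
#' @return data frame of class `expectation_series` with columns
#'   `generation`, `value` (expected H), `increment`, and
#'   `relative_decrease` (percent of the previous generation's H lost).
#' @export
expected_H_random_series <- function(counts, H0, n_steps = NULL,
                                     start_generation = 0L) {
  cn <- resolve_counts(counts, n_steps, start_generation)
  stopifnot(H0 >= 0, H0 <= 1)
  h <- H0 * cumprod(c(1, 1 - cn))
  structure(data.frame(generation = start_generation + 0:length(cn),
                       value = h,
                       increment = c(NA, diff(h)),
                       relative_decrease = c(NA, cn * 100)),
            class = c("expectation_series", "data.frame"),
            statistic = "H")
}

resolve_counts <- function(counts, n_steps, start_generation) {
  if (is.numeric(counts) && length(counts) == 1L) {
    if (is.null(n_steps)) stop("n_steps required with constant counts")
    return(rep(step_increment(counts, counts), n_steps))
  }
  stopifnot(is.data.frame(counts))
  tab <- counts[!is.na(counts$n_male) & !is.na(counts$n_female), ]
  gens <- start_generation + seq(0L, length.out = if (is.null(n_steps))
    nrow(tab) else n_steps)
  idx <- match(gens, tab$generation)
  if (anyNA(idx))
    stop("breeder counts missing for generation(s) ",
         paste(gens[is.na(idx)], collapse = ", "))
  step_increment(tab$n_male[idx], tab$n_female[idx])
}

#' Average per-generation rate of an expectation series
#'
#' For an F series, the mean per-step increase in percentage points over a
#' span; for an H series, the mean per-step relative decrease in percent.
#'
#' @param series an `expectation_series`.
#' @param span generation span (length-2); default full span.
#' @param mode `"absolute_points"` (mean of per-step increments x 100) or
#'   `"relative"` (mean of per-step relative changes x 100).
#' @return scalar rate in percent per generation.
#' @export
expectation_rate <- function(series, span = range(series$generation),
                             mode = c("absolute_points", "relative")) {
  mode <- match.arg(mode)
  keep <- series$generation > span[1] & series$generation <= span[2]
  if (!any(keep)) stop("empty span")
  if (mode == "absolute_points") {
    mean(series$increment[keep]) * 100
  } else {
    prev <- series$value[which(keep) - 1L]
    mean(-series$increment[keep] / prev) * 100
  }
}

#' Slowdown of rotational breeding relative to random mating
#'
#' Expresses how much slower one per-generation rate is than another:
#' `100 * (1 - rot_rate / rand_rate)`. Typically `rot_rate` is the mean-F
#' increase realized by a rotational pedigree and `rand_rate` the matched
#' random-mating expectation, computed under the same rate convention.
#'
#' @param rot_rate,rand_rate rates in the same units (e.g. percent per
#'   generation).
#' @return slowdown percentage.
#' @export
rotational_vs_random_comparison <- function(rot_rate, rand_rate) {
  if (rand_rate == 0) stop("random-mating rate is zero; comparison undefined")
  100 * (1 - rot_rate / rand_rate)
}
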