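#' Additive trait architecture
#'
#' Defines a polygenic trait on a marker panel: a set of QTL markers with
#' additive allele effects and an environmental variance, optionally
#' calibrated so that the founder-population narrow-sense heritability
#' hits a target.
#'
#' @param qtl integer indices of QTL markers on the map.
#' @param effects additive effect per reference-allele copy (recycled).
#' @param sigma_e environmental standard deviation; ignored when
#'   `h2_target` is given.
#' @param h2_target optional target founder h2 in `[0, 1]`; `sigma_e` is
#'   then set from the realized founder genetic variance at simulation
#'   time.
#' @return list of class `trait_architecture`.
#' @export
trait_architecture <- function(qtl, effects = 1, sigma_e = 1,
                               h2_target = NULL) {
  stopifnot(length(qtl) >= 1L)
  if (!is.null(h2_target)) stopifnot(h2_target >= 0, h2_target <= 1)
  structure(list(qtl = as.integer(qtl),
                 effects = rep_len(effects, length(qtl)),
                 sigma_e = sigma_e, h2_target = h2_target),
            class = "trait_architecture")
}

#' Simulate phenotypes from genotypes under an additive architecture
#'
#' `phenotype = sum(allele count x effect) + N(0, sigma_e^2)`. When the
#' architecture carries an `h2_target`, the environmental SD is
#' calibrated against the genetic variance realized in the founder rows
#' (`founder_rows`, default all animals) so the founder-population h2
#' matches the target.
#'
#' @param G a `genotype_matrix`.
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @param founder_rows rows defining the reference population for
#'   h2 calibration.
#' @return list: `phenotype` (named vector), `genetic_value`, `sigma_e`.
#' @export
simulate_phenotypes <- function(G, arch, seed = 1L,
                                founder_rows = seq_len(nrow(G$geno))) {
  if (max(arch$qtl) > ncol(G$geno)) stop("architecture QTL outside panel")
  gv <- drop(G$geno[, arch$qtl, drop = FALSE] %*% arch$effects)
  sigma_e <- arch$sigma_e
  if (!is.null(arch$h2_target)) {
    var_g <- stats::var(gv[founder_rows])
    if (var_g == 0 && arch$h2_target > 0)
      stop("zero genetic variance; cannot calibrate to positive h2")
    sigma_e <- if (arch$h2_target == 0) stats::sd(gv) + 1 else
      sqrt(var_g * (1 - arch$h2_target) / arch$h2_target)
  }
  set.seed(seed)
  y <- gv + stats::rnorm(length(gv), 0, sigma_e)
  names(y) <- rownames(G$geno)
  list(phenotype = y, genetic_value = gv, sigma_e = sigma_e)
}

#' Simulate additive breeding values through a pedigree
#'
#' Draws breeding values by the Mendelian-sampling recursion:
#' founders `u ~ N(0, sigma_a^2)`; otherwise
#' `u_i = (u_s + u_d)/2 + m_i` with
#' `m_i ~ N(0, sigma_a^2 (0.5 - 0.25 (F_s + F_d)))`. The resulting vector
#' has covariance `sigma_a^2 A`, the additive relationship structure the
#' animal model assumes.
#'
#' @param ped a [pedigree()].
#' @param sigma_a additive genetic SD.
#' @param seed integer seed.
#' @return named numeric vector of breeding values in pedigree row order.
#' @export
simulate_breeding_values <- function(ped, sigma_a = 1, seed = 1L) {
  set.seed(seed)
  f <- inbreeding_coefficients(ped)
  d <- mendelian_d(ped, f)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  u <- stats::setNames(numeric(nrow(ped)), ped$id)
  m <- stats::rnorm(nrow(ped), 0, sigma_a * sqrt(d))
  for (i in topological_order(ped)) {
    pa <- 0
    if (!is.na(si[i])) pa <- pa + u[si[i]] / 2
    if (!is.na(di[i])) pa <- pa + u[di[i]] / 2
    u[i] <- pa + m[i]
  }
  u
}

#' Mid-parent regression estimate of heritability
#'
#' Residualizes the phenotype on covariates, averages offspring residuals
#' within each full-sib family, and regresses the family mean on the
#' mid-parent residual; the slope estimates narrow-sense h2.
#'
#' @param ped a [pedigree()].
#' @param phenotype named numeric vector (names = animal ids).
#' @param covariates optional data frame of fixed covariates aligned with
#'   `ped` rows (residualized out by least squares).
#' @return list of class `heritability_estimate`: `h2`, `se`, `method`,
#'   `n_families`.
#' @export
heritability_midparent <- function(ped, phenotype, covariates = NULL) {
  y <- phenotype[ped$id]
  if (!is.null(covariates)) {
    fit <- stats::lm(y ~ ., data = as.data.frame(covariates),
                     na.action = stats::na.exclude)
    y <- stats::residuals(fit)
  }
  names(y) <- ped$id
  both <- !is.na(ped$sire) & !is.na(ped$dam)
  fam <- paste(ped$sire, ped$dam, sep = "\r")[both]
  off <- tapply(y[ped$id[both]], fam, mean, na.rm = TRUE)
  pair <- do.call(rbind, strsplit(names(off), "\r", fixed = TRUE))
  mid <- (y[pair[, 1]] + y[pair[, 2]]) / 2
  keep <- !is.na(off) & !is.na(mid)
  if (sum(keep) < 3L) stop("no usable mid-parent/offspring pairs")
  if (sum(keep) < 20L)
    warning("fewer than 20 mid-parent pairs; estimate will be noisy")
  fit <- stats::lm(off[keep] ~ mid[keep])
  structure(list(h2 = min(max(unname(stats::coef(fit)[2]), 0), 1),
                 se = summary(fit)$coefficients[2, 2],
                 method = "midparent", n_families = sum(keep)),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.3f +/- %.3f (%s)\n", x$h2, x$se, x$method))
  invisible(x)
}

#' Animal-model REML estimate of heritability
#'
#' Fits the mixed model `y = X beta + u + e` with `var(u) =
#' sigma_a^2 A` (A the pedigree numerator relationship matrix) and
#' `var(e) = sigma_e^2 I`, by restricted maximum likelihood. The
#' likelihood is profiled over `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`
#' with the residual scale maximized analytically; each profile point is
#' evaluated through the sparse mixed-model equations built from the
#' sparse `A^{-1}` ([ainverse()]), so colony-sized pedigrees are
#' tractable. The standard error comes from the curvature of the profile
#' deviance at the optimum.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `log(best_distance_m) ~ sex + factor(generation)`.
#' @param data data frame of phenotyped animals; must contain an `id`
#'   column matching pedigree ids plus all model variables. Rows with
#'   missing response or covariates are dropped.
#' @param ped the [pedigree()] providing the relationship structure (may
#'   contain unphenotyped relatives).
#' @param interval search interval for h2 (default `c(1e-4, 1 - 1e-4)`).
#' @return object of class `animal_model`: estimates (`h2`, `se_h2`,
#'   `sigma_a2`, `sigma_e2`), fixed effects (`beta`), breeding-value
#'   BLUPs (`u`), the profile deviance function, fit metadata.
#' @export
animal_model <- function(formula, data, ped,
                         interval = c(1e-4, 1 - 1e-4)) {
  stopifnot("id" %in% names(data))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  used <- as.integer(attr(mf, "na.action"))
  ids <- if (length(used)) data$id[-used] else data$id
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular fixed-effect design; aliased: ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  if (stats::sd(y) == 0) stop("constant response")
  ridx <- match(ids, ped$id)
  if (anyNA(ridx)) stop("phenotyped animals missing from pedigree")
  n <- length(y); p <- ncol(X); q <- nrow(ped)
  ainv <- ainverse(ped)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = ridx, x = 1,
                            dims = c(n, q))
  X <- Matrix::Matrix(X, sparse = TRUE)
  W <- cbind(X, Z)
  WtW <- Matrix::crossprod(W)
  Wty <- Matrix::crossprod(W, y)
  yty <- sum(y^2)
  pad <- Matrix::bdiag(Matrix::Matrix(0, p, p), ainv$Ainv)
  profile_dev <- function(h2) {
    gamma <- h2 / (1 - h2)
    M <- WtW + pad / gamma
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE,
                           perm = TRUE)
    sol <- Matrix::solve(ch, Wty)
    ssr <- max(yty - sum(sol * Wty), .Machine$double.eps)
    logdet_M <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
    sigma2 <- ssr / (n - p)
    (n - p) * (log(sigma2) + 1) + q * log(gamma) + ainv$logdet_A +
      as.numeric(logdet_M)
  }
  opt <- stats::optimize(profile_dev, interval = interval)
  h2 <- opt$minimum
  ## curvature -> SE; -2logL approx quadratic near optimum
  eps <- min(1e-3, h2 / 2, (1 - h2) / 2)
  d2 <- (profile_dev(h2 + eps) - 2 * opt$objective +
           profile_dev(h2 - eps)) / eps^2
  se_h2 <- if (d2 > 0) sqrt(2 / d2) else NA_real_
  gamma <- h2 / (1 - h2)
  M <- WtW + pad / gamma
  sol <- Matrix::solve(Matrix::forceSymmetric(M), Wty)
  ssr <- max(yty - sum(sol * Wty), .Machine$double.eps)
  sigma_e2 <- ssr / (n - p)
  beta <- stats::setNames(as.numeric(sol[seq_len(p)]), colnames(X))
  u <- stats::setNames(as.numeric(sol[-seq_len(p)]), ped$id)
  structure(list(h2 = h2, se_h2 = se_h2,
                 sigma_a2 = gamma * sigma_e2, sigma_e2 = sigma_e2,
                 beta = beta, u = u, n = n, p = p, q = q,
                 deviance = opt$objective, profile_dev = profile_dev,
                 call = match.call(), formula = formula),
            class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Animal-model REML fit\n")
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d records, %d pedigree animals\n", x$n, x$q))
  cat(sprintf("  h2 = %.3f +/- %.3f  (sigma_a2 = %.4g, sigma_e2 = %.4g)\n",
              x$h2, x$se_h2, x$sigma_a2, x$sigma_e2))
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$beta

#' @export
logLik.animal_model <- function(object, ...) {
  structure(-object$deviance / 2, df = object$p + 2, class = "logLik")
}

#' @export
summary.animal_model <- function(object, ...) {
  structure(list(fit = object), class = "summary.animal_model")
}

#' @export
print.summary.animal_model <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  print(round(x$fit$beta, 4))
  invisible(x)
}

#' Castle-Wright estimator of the effective number of QTL
#'
#' `n_E = (mean_P1 - mean_P2)^2 / (8 (var_F2 - var_F1))`: the classical
#' estimator from parental line divergence and the release of segregation
#' variance between the F1 and F2 of an intercross. Assumes unlinked,
#' additive loci of equal effect.
#'
#' @param mean_p1,mean_p2 parental line phenotype means.
#' @param var_f1,var_f2 F1 and F2 phenotype variances (`var_f2 > var_f1`).
#' @return list of class `castle_wright`: `n_e` plus inputs.
#' @export
castle_wright <- function(mean_p1, mean_p2, var_f1, var_f2) {
  if (var_f2 <= var_f1)
    stop("negative segregation variance (var_f2 <= var_f1); n_E undefined")
  n_e <- (mean_p1 - mean_p2)^2 / (8 * (var_f2 - var_f1))
  structure(list(n_e = n_e, mean_p1 = mean_p1, mean_p2 = mean_p2,
                 var_f1 = var_f1, var_f2 = var_f2),
            class = "castle_wright")
}

#' @export
print.castle_wright <- function(x, ...) {
  cat(sprintf("Castle-Wright effective QTL number: n_E = %.2f\n", x$n_e))
  invisible(x)
}

#' Vertical work of a treadmill run
#'
#' `work = distance x weight x sin(slope) x 9.8 / 1000` joules, for
#' distance in meters, body weight in grams and the treadmill slope in
#' degrees (default 15).
#'
#' @param distance_m running distance in meters (non-negative).
#' @param body_weight_g body weight in grams (non-negative).
#' @param slope_deg treadmill inclination in degrees.
#' @return work in joules.
#' @export
vertical_work <- function(distance_m, body_weight_g, slope_deg = 15) {
  if (any(distance_m < 0, na.rm = TRUE) ||
      any(body_weight_g < 0, na.rm = TRUE))
    stop("distance and weight must be non-negative")
  distance_m * body_weight_g * sin(slope_deg * pi / 180) * 9.8 / 1000
}

#' Cohort summary tables by line, generation and sex
#'
#' Per line x generation x sex counts, means and SDs of a phenotype
#' column — the standard colony reporting table.
#'
#' @param ped a [pedigree()] carrying phenotype columns.
#' @param trait phenotype column name (default `"best_distance_m"`).
#' @return data frame `line`, `generation`, `sex`, `n`, `mean`, `sd`.
#' @export
cohort_summary_tables <- function(ped, trait = "best_distance_m") {
  stopifnot(trait %in% names(ped))
  keep <- !is.na(ped[[trait]])
  d <- ped[keep, ]
  key <- paste(d$line, d$generation, d$sex, sep = "\r")
  lv <- unique(key)
  parts <- do.call(rbind, strsplit(lv, "\r", fixed = TRUE))
  out <- data.frame(line = parts[, 1],
                    generation = as.integer(parts[, 2]), sex = parts[, 3],
                    n = as.integer(table(key)[lv]),
                    mean = as.numeric(tapply(d[[trait]], key, mean)[lv]),
                    sd = as.numeric(tapply(d[[trait]], key, stats::sd)[lv]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$line, out$generation, out$sex), ]
  rownames(out) <- NULL
  out
}

#' Between-line divergence statistics from a cohort summary table
#'
#' From per-sex summary rows (n, mean, SD for each line at one
#' generation) computes (a) the fold change of sex-averaged means between
#' lines and (b) the between-line mean difference expressed in units of
#' the average combined-sex within-line SD, where each line's
#' combined-sex mean and SD come from the two-component mixture formula
#' `var = sum w_s (sd_s^2 + mean_s^2) - (sum w_s mean_s)^2` with
#' `w_s = n_s / n`.
#'
#' @param tbl data frame with columns `line`, `sex`, `n`, `mean`, `sd`
#'   (one generation; two lines, two sexes each).
#' @param high,low line labels of the numerator and denominator line
#'   (defaults: line with larger sex-averaged mean on top).
#' @return list: `fold_change`, `sd_units`, per-line `combined` mixture
#'   mean/SD.
#' @export
divergence_statistics <- function(tbl, high = NULL, low = NULL) {
  lines <- unique(tbl$line)
  stopifnot(length(lines) == 2L)
  mix <- lapply(lines, function(ln) {
    s <- tbl[tbl$line == ln, ]
    w <- s$n / sum(s$n)
    m <- sum(w * s$mean)
    v <- sum(w * (s$sd^2 + s$mean^2)) - m^2
    list(mean = m, sd = sqrt(v), sex_avg_mean = mean(s$mean))
  })
  names(mix) <- lines
  if (is.null(high)) {
    high <- lines[which.max(vapply(mix, `[[`, 1, "sex_avg_mean"))]
    low <- setdiff(lines, high)
  }
  fold <- mix[[high]]$sex_avg_mean / mix[[low]]$sex_avg_mean
  sd_units <- (mix[[high]]$mean - mix[[low]]$mean) /
    mean(c(mix[[high]]$sd, mix[[low]]$sd))
  list(fold_change = fold, sd_units = sd_units, combined = mix)
}

#' Spearman correlation of running distance and body weight
#'
#' Per-generation Spearman rank correlation (average ranks for ties)
#' between two phenotype columns within a line x sex stratum, averaged
#' over generations with its SD — the colony's standard summary of the
#' distance-weight association.
#'
#' @param ped a [pedigree()] with both phenotype columns.
#' @param line,sex stratum selectors.
#' @param trait_x,trait_y phenotype columns (defaults: best distance,
#'   body weight).
#' @param generations generation span to average (default 1 to max).
#' @return list: `mean_rho`, `sd_rho`, `per_generation` (data frame).
#' @export
spearman_distance_weight <- function(ped, line, sex,
                                     trait_x = "best_distance_m",
                                     trait_y = "body_weight_g",
                                     generations = NULL) {
  d <- ped[!is.na(ped$line) & ped$line == line & ped$sex == sex, ]
  if (is.null(generations))
    generations <- seq(max(1L, min(d$generation)), max(d$generation))
  rho <- vapply(generations, function(g) {
    s <- d[d$generation == g, ]
    x <- s[[trait_x]]; y <- s[[trait_y]]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3L || stats::sd(x[keep]) == 0 ||
        stats::sd(y[keep]) == 0) {
      warning("skipping generation ", g, " (too few or constant values)")
      return(NA_real_)
    }
    stats::cor(x[keep], y[keep], method = "spearman")
  }, numeric(1))
  per_gen <- data.frame(generation = generations, rho = rho)
  list(mean_rho = mean(rho, na.rm = TRUE),
       sd_rho = stats::sd(rho, na.rm = TRUE), per_generation = per_gen)
}
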