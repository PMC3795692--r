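test_that("phenotype simulation calibrates to the target heritability", {
  map <- small_map(120)
  fp <- simulate_founders(map, 200, K = 8, seed = 1)
  ped <- pedigree(data.frame(id = paste0("f", 1:200), sire = NA, dam = NA,
                             sex = rep(c("M", "F"), 100), generation = 0))
  G <- drop_genotypes(ped, fp, seed = 2)
  arch <- trait_architecture(qtl = seq(5, 100, by = 5), h2_target = 0.5)
  sim <- simulate_phenotypes(G, arch, seed = 3)
  h2_real <- stats::var(sim$genetic_value) / stats::var(sim$phenotype)
  expect_gt(h2_real, 0.4)
  expect_lt(h2_real, 0.6)
  ## zero effects: pure noise
  arch0 <- trait_architecture(qtl = 1:5, effects = 0, sigma_e = 1)
  sim0 <- simulate_phenotypes(G, arch0, seed = 4)
  expect_equal(unname(sim0$genetic_value), rep(0, 200))
  ## no environmental noise: phenotype determined by genotype
  archd <- trait_architecture(qtl = 1:10, sigma_e = 0)
  simd <- simulate_phenotypes(G, archd, seed = 5)
  expect_equal(simd$phenotype, stats::setNames(simd$genetic_value, ped$id))
  ## degenerate: no genetic variance but positive target
  archz <- trait_architecture(qtl = 1, effects = 0, h2_target = 0.5)
  expect_error(simulate_phenotypes(G, archz, seed = 6), "zero genetic")
})

test_that("mid-parent regression recovers trivial and simulated truths", {
  ped <- build_random_mating_pedigree(40, 8, seed = 3)
  u <- simulate_breeding_values(ped, sigma_a = 1, seed = 4)
  ## phenotype equal to the exact mid-parent average: slope 1
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  y <- u
  for (i in topological_order(ped))
    if (!is.na(si[i])) y[i] <- (y[si[i]] + y[di[i]]) / 2
  expect_equal(suppressWarnings(heritability_midparent(ped, y)$h2), 1,
               tolerance = 1e-8)
  ## pure noise: slope near zero
  set.seed(5)
  noise <- stats::setNames(stats::rnorm(nrow(ped)), ped$id)
  expect_lt(heritability_midparent(ped, noise)$h2, 0.2)
  ## simulated h2 = 0.5 at n >= 500
  set.seed(6)
  y2 <- u + stats::rnorm(nrow(ped), 0, 1)
  names(y2) <- ped$id
  est <- heritability_midparent(ped, y2)
  expect_gt(nrow(ped), 500)
  expect_gt(est$h2, 0.4)
  expect_lt(est$h2, 0.6)
})

test_that("REML animal model matches a dense-matrix REML oracle", {
  ped <- build_random_mating_pedigree(8, 4, seed = 5)
  u <- simulate_breeding_values(ped, 1, seed = 1)
  set.seed(2)
  y <- 1 + u + stats::rnorm(nrow(ped), 0, 1)
  dat <- data.frame(id = ped$id, y = y)
  fit <- animal_model(y ~ 1, dat, ped)
  A <- additive_relationship(ped)
  dense_dev <- function(h2) {
    g <- h2 / (1 - h2); n <- nrow(ped); X <- matrix(1, n, 1)
    V <- g * A + diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
    s2 <- drop(t(y) %*% P %*% y) / (n - 1)
    (n - 1) * (log(s2) + 1) + determinant(V)$modulus[1] +
      determinant(XtViX)$modulus[1]
  }
  for (h in c(0.15, 0.4, 0.7, 0.9))
    expect_equal(fit$profile_dev(h), dense_dev(h), tolerance = 1e-6)
  ## profile-search correctness: optimum beats a 21-point grid
  grid <- seq(0.02, 0.98, length.out = 21)
  expect_true(all(fit$deviance <= vapply(grid, fit$profile_dev,
                                         numeric(1)) + 1e-6))
})

test_that("REML recovers simulated heritability and detects its absence", {
  ped <- build_random_mating_pedigree(30, 9, seed = 42)
  u <- simulate_breeding_values(ped, sigma_a = 1, seed = 7)
  set.seed(8)
  y <- 2 + 0.5 * (ped$sex == "M") + u + stats::rnorm(nrow(ped), 0, 1)
  dat <- data.frame(id = ped$id, y = y, sex = ped$sex)
  fit <- animal_model(y ~ sex, dat, ped)
  expect_gt(nrow(ped), 500)
  expect_gt(fit$h2, 0.4)
  expect_lt(fit$h2, 0.6)
  ## agreement with the mid-parent route within joint uncertainty
  mp <- heritability_midparent(ped, stats::setNames(y, ped$id),
                               covariates = data.frame(sex = ped$sex))
  expect_lt(abs(fit$h2 - mp$h2), 2 * sqrt(fit$se_h2^2 + mp$se^2))
  ## pedigree-independent phenotype: h2 pinned near zero
  set.seed(9)
  dat$y <- stats::rnorm(nrow(ped))
  fit0 <- animal_model(y ~ sex, dat, ped)
  expect_lt(fit0$h2 + 2 * fit0$se_h2, 0.2)
  ## aliased fixed effect is named
  dat$dupsex <- dat$sex
  expect_error(animal_model(y ~ sex + dupsex, dat, ped), "aliased")
})

test_that("Castle-Wright estimator follows its closed form", {
  ## delta-mean^2 = 8 delta-var -> exactly one effective locus
  expect_equal(castle_wright(10, 2, 1, 9)$n_e, 1)
  expect_equal(castle_wright(5, 5, 1, 2)$n_e, 0)
  expect_error(castle_wright(10, 2, 3, 2), "segregation variance")
})

test_that("vertical work follows the treadmill equation", {
  expect_equal(vertical_work(0, 250), 0)
  expect_equal(vertical_work(1000, 250), 634.1, tolerance = 0.05)
  ## bilinear: doubling both inputs quadruples work
  expect_equal(vertical_work(2000, 500), 4 * vertical_work(1000, 250))
  expect_error(vertical_work(-1, 100), "non-negative")
})

test_that("published cohort tables reproduce the G28 divergence statistics", {
  tab <- rbind(colony_cohort_summary("HCR"), colony_cohort_summary("LCR"))
  g28 <- tab[tab$generation == 28, ]
  g28 <- data.frame(line = g28$line, sex = g28$sex, n = g28$n,
                    mean = g28$distance_mean, sd = g28$distance_sd)
  div <- divergence_statistics(g28)
  expect_equal(div$fold_change, 8.3, tolerance = 0.1)
  expect_equal(div$sd_units, 9, tolerance = 0.5)
  ## identical lines: fold change 1, zero SD units
  same <- g28; same$line <- rep(c("A", "B"), each = 2)
  same$mean <- 100; same$sd <- 10; same$n <- 50
  div0 <- divergence_statistics(same)
  expect_equal(div0$fold_change, 1)
  expect_equal(div0$sd_units, 0)
  ## inbred-strain reference range ~2.8-fold
  inbred <- inbred_strain_distances()
  expect_equal(max(inbred$best_distance_m) / min(inbred$best_distance_m),
               2.8, tolerance = 0.05)
})

test_that("cohort summaries recover a fixture with known moments", {
  ## regenerate the G28 male cohort from its published mean/SD
  n <- 112; target_mean <- 1810.4; target_sd <- 269.6
  set.seed(10)
  v <- stats::rnorm(n)
  v <- (v - mean(v)) / stats::sd(v) * target_sd + target_mean
  ped <- pedigree(data.frame(id = paste0("r", 1:n), sire = NA, dam = NA,
                             sex = "M", generation = 28, line = "HCR",
                             best_distance_m = v))
  tab <- cohort_summary_tables(ped)
  expect_equal(tab$mean, target_mean)
  expect_equal(tab$sd, target_sd)
  expect_equal(tab$n, n)
})

test_that("Spearman distance-weight summary behaves on monotone and independent data", {
  n <- 30
  mk <- function(dist, wt, gen) data.frame(
    id = paste0("g", gen, "_", seq_len(n)), sire = NA, dam = NA, sex = "M",
    generation = gen, line = "HCR", best_distance_m = dist,
    body_weight_g = wt)
  ## perfectly monotone decreasing relation: rho = -1 each generation
  rows <- do.call(rbind, lapply(1:3, function(g) {
    d <- stats::runif(n, 500, 1500)
    mk(d, 4000 / d, g)
  }))
  ped <- pedigree(rows)
  sp <- spearman_distance_weight(ped, "HCR", "M")
  expect_equal(sp$per_generation$rho, rep(-1, 3))
  expect_equal(sp$sd_rho, 0)
  ## independent values: mean near zero
  set.seed(11)
  rows2 <- do.call(rbind, lapply(1:20, function(g)
    mk(stats::rnorm(n, 1000, 100), stats::rnorm(n, 250, 20), g)))
  sp2 <- spearman_distance_weight(pedigree(rows2), "HCR", "M")
  expect_lt(abs(sp2$mean_rho), 0.1)
})
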