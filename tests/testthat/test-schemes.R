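test_that("rotational pairing rule reproduces the documented pairings", {
  expect_equal(rotation_sire_family(1, 6, 13), 7)
  expect_equal(rotation_sire_family(7, 6, 13), 13)
  expect_equal(rotation_sire_family(7, 7, 13), 1)
  ## 13th rotation (offset 0) is skipped and reuses the rotation-1 map
  expect_equal(rotation_sire_family(1:13, 13, 13),
               rotation_sire_family(1:13, 1, 13))
  expect_error(rotation_sire_family(1, 1, 2), ">= 3")
})

test_that("every rotation is a fixed-point-free bijection of families", {
  for (r in 1:12) {
    sf <- rotation_sire_family(1:13, r, 13)
    expect_equal(sort(sf), 1:13)
    expect_true(all(sf != 1:13))
  }
})

test_that("idealized rotational pedigree has the expected inbreeding structure", {
  ped <- build_idealized_rotational_pedigree(28)
  expect_identical(nrow(validate_pedigree(ped)), 0L)
  f <- inbreeding_coefficients(ped)
  ss <- series_summary(ped, unname(f))
  ## no inbreeding before the first repeat pairing; confirmed by the
  ## independent recursive-kinship oracle on the truncated pedigree
  early <- ped$generation <= 3
  expect_true(all(f[early] == 0))
  sub <- ped[ped$generation <= 4, ]
  class(sub) <- c("pedigree", "data.frame")
  expect_equal(unname(f[sub$id]), oracle_inbreeding(sub))
  ## first-cousin spike: G8 mean F >= 6%
  expect_gte(ss$mean[ss$generation == 8], 0.06)
  ## recurring spikes: the per-generation jump is locally maximal at
  ## G8, G14, G20, G26
  inc <- diff(ss$mean)
  for (g in c(8, 14, 20, 26))
    expect_true(inc[g] > inc[g - 1] && inc[g] > min(inc[g + 1], Inf,
                                                    na.rm = TRUE))
  ## never brother-sister mated
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  both <- !is.na(si)
  sib <- paste(ped$sire[si[both]], ped$dam[si[both]]) ==
    paste(ped$sire[di[both]], ped$dam[di[both]])
  sib[is.na(ped$sire[si[both]])] <- FALSE
  expect_false(any(sib, na.rm = TRUE))
})

test_that("generation-7 breeders of the idealized scheme are first cousins", {
  ped <- build_idealized_rotational_pedigree(8)
  A <- additive_relationship(ped)
  g8 <- ped[ped$generation == 8, ]
  rel <- A[cbind(g8$sire, g8$dam)]
  ## first cousins whose shared grandparents are non-inbred: A = 1/8 plus
  ## background accumulated by G7
  expect_true(all(rel >= 1 / 8 - 1e-9))
})

test_that("idealized scheme slows inbreeding by 30-45% relative to random mating", {
  ped <- build_idealized_rotational_pedigree(28)
  f <- inbreeding_coefficients(ped)
  ss <- series_summary(ped, unname(f))
  rot <- rate_per_generation(ss, span = c(1, 28), mode = "slope")
  rand <- expectation_rate(expected_F_random_series(13, 0, 28),
                           span = c(0, 27))
  slow <- rotational_vs_random_comparison(rot, rand)
  expect_gte(slow, 30)
  expect_lte(slow, 45)
})

test_that("repeated single-pair mating gives the classic full-sib F series", {
  ped <- build_random_mating_pedigree(1, 4, seed = 1)
  f <- tapply(inbreeding_coefficients(ped), ped$generation, mean)
  expect_equal(as.numeric(f[as.character(0:4)]), c(0, 0, 0.25, 0.375, 0.5))
})

test_that("random-mating builder is reproducible and tracks the recursion", {
  p1 <- build_random_mating_pedigree(13, 5, seed = 42)
  p2 <- build_random_mating_pedigree(13, 5, seed = 42)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  ## mean F trajectory matches the recursion with the one-generation
  ## inbreeding lag of separate sexes, within 3 Monte-Carlo SEM
  n_gen <- 8; n_seed <- 60
  mat <- sapply(seq_len(n_seed), function(s) {
    ped <- build_random_mating_pedigree(13, n_gen, seed = s)
    f <- inbreeding_coefficients(ped)
    vapply(0:n_gen, function(g) mean(f[ped$generation == g]), numeric(1))
  })
  obs <- rowMeans(mat)
  sem <- apply(mat, 1, stats::sd) / sqrt(n_seed)
  expct <- expected_F_random_series(13, 0, n_gen)$value
  for (g in 3:n_gen)  # pedigree F at g vs recursion at g-1
    expect_lt(abs(obs[g + 1] - expct[g]), 3 * sem[g + 1])
})

test_that("within-family truncation selection picks extremes with stable ties", {
  cand <- data.frame(id = c("m1", "m2", "f1", "f2"),
                     sex = c("M", "M", "F", "F"), family = 1,
                     trait = c(500, 700, 600, 400))
  hi <- select_breeders_within_family(cand, "trait", "highest")
  expect_equal(hi$breeders$sire, "m2")
  expect_equal(hi$breeders$dam, "f1")
  lo <- select_breeders_within_family(cand, "trait", "lowest")
  expect_equal(lo$breeders$sire, "m1")
  expect_equal(lo$breeders$dam, "f2")
  ## exact tie: lower id wins
  tie <- data.frame(id = c("b", "a", "f"), sex = c("M", "M", "F"),
                    family = 1, trait = c(700, 700, 1))
  expect_equal(select_breeders_within_family(tie, "trait",
                                             "highest")$breeders$sire, "a")
  ## missing sex flagged for substitution
  mis <- data.frame(id = "m", sex = "M", family = 1, trait = 5)
  out <- select_breeders_within_family(mis, "trait", "highest")
  expect_equal(out$missing$sex, "F")
})

test_that("intercross pedigree honors the published tier sizes and constraints", {
  f0 <- function(ln) data.frame(id = paste0(ln, 1:8),
                                sex = rep(c("M", "F"), 4))
  ## first-batch design: 8 F0 pairs -> 79 F1, 40 F1 breeders -> 154 F2
  ped <- build_intercross_pedigree(f0("h"), f0("l"), n_f0_pairs = 4,
                                   n_f1_offspring = 79, n_f1_pairs = 20,
                                   n_f2_offspring = 154, seed = 1)
  expect_equal(sum(ped$generation == 1), 79)
  expect_equal(sum(ped$generation == 2), 154)
  ## no F1 brother-sister pairs
  f1 <- ped[ped$generation == 1, ]
  f2 <- ped[ped$generation == 2, ]
  fam_of <- function(ids) f1$family[match(ids, f1$id)]
  expect_true(all(fam_of(f2$sire) != fam_of(f2$dam)))
  ## each F0 pair joins the two lines
  f0rows <- ped[ped$generation == 0, ]
  for (fam in unique(f0rows$family))
    expect_setequal(f0rows$line[f0rows$family == fam], c("L1", "L2"))
  ## a single F0 pair cannot produce a sib-free F1 pairing
  one <- function(ln, sx) data.frame(id = paste0(ln, sx), sex = sx)
  expect_error(build_intercross_pedigree(
    rbind(one("h", "M"), one("h", "F")), rbind(one("l", "M"), one("l", "F")),
    n_f0_pairs = 1, n_f1_offspring = 10, n_f1_pairs = 2,
    n_f2_offspring = 10, seed = 1), "sib mating")
  ## two batches together yield 645 F2 records
  b2 <- build_intercross_pedigree(f0("h"), f0("l"), n_f0_pairs = 4,
                                  n_f1_offspring = 97, n_f1_pairs = 40,
                                  n_f2_offspring = 491, seed = 2)
  expect_equal(sum(ped$generation == 2) + sum(b2$generation == 2), 645)
})
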