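test_that("HWE exact test matches a permutation oracle", {
  perm_oracle <- function(n_aa, n_ab, n_bb, n_perm = 4000, seed = 1) {
    set.seed(seed)
    n <- n_aa + n_ab + n_bb
    alleles <- rep(c(0L, 1L), c(2L * n_aa + n_ab, 2L * n_bb + n_ab))
    obs_p <- NA
    hets <- replicate(n_perm, {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n - 1, 2)] != a[seq(2, 2 * n, 2)])
    })
    tab <- table(hets) / n_perm
    p_obs <- tab[as.character(n_ab)]
    if (is.na(p_obs)) p_obs <- 0
    sum(tab[tab <= p_obs + 1e-9])
  }
  for (cfg in list(c(20, 10, 20), c(5, 10, 5), c(40, 12, 2))) {
    p_exact <- hwe_exact_test(cfg[1], cfg[2], cfg[3])
    p_perm <- perm_oracle(cfg[1], cfg[2], cfg[3])
    expect_lt(abs(p_exact - p_perm), 0.03)
  }
  ## perfect HWE proportions are not rejected
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
})

test_that("marker QC flags each defect class and keeps exact bookkeeping", {
  set.seed(42)
  n <- 60
  good <- function() stats::rbinom(n, 2, 0.5)
  geno <- cbind(g1 = good(), g2 = good(), g3 = good())
  geno <- cbind(geno, dup = geno[, "g1"])                    # duplicate
  missy <- good(); missy[1:7] <- NA                          # 11.7% missing
  geno <- cbind(geno, missy = missy)
  hwe_bad <- rep(c(0L, 2L), each = n / 2)                    # no hets
  geno <- cbind(geno, hwe_bad = hwe_bad)
  rare <- c(rep(0L, n - 2), 1L, 1L)                          # MAF < 5%
  geno <- cbind(geno, rare = rare)
  rownames(geno) <- paste0("a", 1:n)
  rep_ <- qc_marker_panel(geno)
  expect_equal(rep_$removed$duplicate, "dup")
  expect_equal(rep_$removed$missing, "missy")
  expect_true("hwe_bad" %in% rep_$removed$hwe)
  expect_true("rare" %in% rep_$removed$maf)
  ## bookkeeping: removed + surviving = input at both panel stages
  r <- rep_$removed
  expect_equal(length(r$duplicate) + length(r$missing) + length(r$hwe) +
                 length(rep_$panel1), ncol(geno))
  expect_equal(length(r$ld_pruned) + length(r$maf) + length(rep_$panel2),
               length(rep_$panel1))
})

test_that("LD pruning removes the later marker of a correlated pair", {
  set.seed(7)
  g <- stats::rbinom(80, 2, 0.5)
  geno <- cbind(a = g, b = stats::rbinom(80, 2, 0.5), c = g)
  geno[1, "c"] <- (g[1] + 1L) %% 3L  # near-duplicate, never identical
  rownames(geno) <- paste0("x", 1:80)
  rep_ <- qc_marker_panel(geno, min_maf = 0)
  expect_true("c" %in% rep_$removed$ld_pruned)
  expect_false("a" %in% rep_$removed$ld_pruned)
})

test_that("observed heterozygosity handles the degenerate and missing cases", {
  m <- rbind(allhet = rep(1L, 10), allhom = rep(c(0L, 2L), 5),
             onemiss = c(NA, rep(1L, 9)))
  h <- observed_heterozygosity(as_genotypes(m, small_map(10, 1)))
  expect_equal(unname(h["allhet"]), 1)
  expect_equal(unname(h["allhom"]), 0)
  expect_equal(unname(h["onemiss"]), 1)
  m2 <- rbind(ok = rep(1L, 4), gone = rep(NA_integer_, 4))
  expect_warning(h2 <- observed_heterozygosity(as_genotypes(m2,
                                                            small_map(4, 1))),
                 "excluding")
  expect_equal(names(h2), "ok")
})

test_that("ROH calls follow the marker-count and density rules exactly", {
  bp <- c(0.5, 1.0, 1.5, 2.0, 2.5) * 1e6
  map <- data.frame(marker = paste0("m", 1:5), chr = "chr1", bp = bp,
                    cM = bp / 2e6, is_x = FALSE)
  ## 3 consecutive homozygous markers: below min_markers
  g3 <- matrix(c(0L, 0L, 0L, 1L, 1L), 1)
  expect_equal(nrow(detect_roh(as_genotypes(g3, map))$segments), 0L)
  ## 5 homozygous spanning 2.0 Mb: density 1/400 kb, one ROH
  g5 <- matrix(rep(2L, 5), 1, dimnames = list("a", NULL))
  r5 <- detect_roh(as_genotypes(g5, map))
  expect_equal(nrow(r5$segments), 1L)
  expect_equal(r5$segments$length_bp, 2e6)
  expect_equal(unname(r5$genome_fraction["a"]), 2e6 / 2.75e9)
  ## 4 homozygous spanning 2.4 Mb: density 1/600 kb, rejected
  bp4 <- c(0, 0.8, 1.6, 2.4) * 1e6
  map4 <- data.frame(marker = paste0("m", 1:4), chr = "chr1", bp = bp4,
                     cM = bp4 / 2e6, is_x = FALSE)
  g4 <- matrix(rep(0L, 4), 1)
  expect_equal(nrow(detect_roh(as_genotypes(g4, map4))$segments), 0L)
  ## a heterozygous call interrupts a run
  g_int <- matrix(c(0L, 0L, 1L, 0L, 0L), 1)
  expect_equal(nrow(detect_roh(as_genotypes(g_int, map))$segments), 0L)
})

test_that("r-squared from EM equals hand computation and phased counting", {
  ## phased counts AB=40, Ab=10, aB=10, ab=40: D = 0.15, r2 = 0.36
  h1 <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  h2 <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(rotbreed:::haplotype_r2(h1, h2), 0.36)
  g1 <- h1[seq(1, 99, 2)] + h1[seq(2, 100, 2)]
  g2 <- h2[seq(1, 99, 2)] + h2[seq(2, 100, 2)]
  expect_equal(rotbreed:::genotype_r2(g1, g2), 0.36, tolerance = 0.02)
  ## EM equals direct counting when the data carry no double
  ## heterozygotes (phase unambiguous)
  set.seed(3)
  a1 <- rep(c(1, 0), 30); a2 <- a1
  b1 <- rep(c(1, 0, 0, 1), 15); b2 <- b1
  keep <- !(a1 + a2 == 1 & b1 + b2 == 1)
  expect_equal(rotbreed:::genotype_r2((a1 + a2)[keep], (b1 + b2)[keep]),
               rotbreed:::haplotype_r2(c(a1[keep], a2[keep]),
                                       c(b1[keep], b2[keep])),
               tolerance = 1e-8)
  ## duplicated marker: r2 = 1
  g <- stats::rbinom(50, 2, 0.4)
  expect_equal(rotbreed:::genotype_r2(g, g), 1, tolerance = 1e-6)
})

test_that("LD decay curve bins pairs and interpolates the crossing distance", {
  set.seed(9)
  map <- make_genetic_map(60, chr_lengths = c(chr1 = 3e7),
                          include_x = FALSE)
  ped <- build_random_mating_pedigree(10, 4, seed = 2)
  fp <- simulate_founders(map, 20, K = 2, switch_rate = 0.05, seed = 3)
  G <- drop_genotypes(ped, fp, seed = 4)
  ld <- ld_decay(G, max_dist = 2e7, bin_width = 2e6)
  expect_true(all(ld$bins$n_pairs >= 1))
  expect_true(!is.unsorted(ld$bins$bin_start))
  ## near pairs carry more LD than distant pairs in a low-switch pool
  expect_gt(ld$bins$mean_r2[1], ld$bins$mean_r2[nrow(ld$bins)])
  ## phased and EM curves agree closely on the same data
  ld_h <- ld_decay(G, max_dist = 2e7, bin_width = 2e6, use_haplotypes = TRUE)
  expect_lt(max(abs(ld$bins$mean_r2 - ld_h$bins$mean_r2)), 0.08)
})

test_that("AMOVA separates fixed groups, vanishes under panmixia, matches brute force", {
  ## fixed alternate alleles: everything among groups
  gm <- rbind(matrix(0L, 4, 12), matrix(2L, 4, 12))
  rownames(gm) <- paste0("a", 1:8)
  expect_equal(amova_two_groups(gm, rep(c("A", "B"), each = 4))$proportion, 1)
  ## arbitrary split of one panmictic pool: proportion near 0 over seeds
  props <- vapply(1:12, function(s) {
    set.seed(s)
    g <- matrix(stats::rbinom(40 * 50, 2, 0.5), 40, 50)
    rownames(g) <- paste0("x", 1:40)
    amova_two_groups(g, rep(c("A", "B"), each = 20))$proportion
  }, numeric(1))
  expect_lt(mean(props), 3 * stats::sd(props) / sqrt(length(props)) + 0.02)
  ## brute-force per-locus oracle (independent loops over animals)
  set.seed(5)
  g <- matrix(stats::rbinom(12 * 8, 2, 0.4), 12, 8)
  rownames(g) <- paste0("x", 1:12)
  grp <- rep(c("A", "B"), each = 6)
  am <- amova_two_groups(g, grp)
  sa <- sw <- 0
  for (j in 1:8) {
    alleles <- NULL; labels <- NULL
    for (i in 1:12) {
      alleles <- c(alleles, rep(1, g[i, j]), rep(0, 2 - g[i, j]))
      labels <- c(labels, rep(grp[i], 2))
    }
    if (length(unique(alleles)) < 2) next
    gm_ <- mean(alleles)
    ss_tot <- sum((alleles - gm_)^2)
    ss_am <- 0
    for (lv in unique(labels))
      ss_am <- ss_am + sum(labels == lv) * (mean(alleles[labels == lv]) - gm_)^2
    ms_am <- ss_am / 1
    ms_wi <- (ss_tot - ss_am) / (length(alleles) - 2)
    n0 <- (length(alleles) - sum(table(labels)^2) / length(alleles)) / 1
    sa <- sa + (ms_am - ms_wi) / n0
    sw <- sw + ms_wi
  }
  expect_equal(am$proportion, max(sa / (sa + sw), 0), tolerance = 1e-8)
})

test_that("IBS/MDS reproduces identical animals and embeddable distances", {
  m <- rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 1L, 2L, 1L),
             c = c(2L, 1L, 0L, 1L))
  res <- ibs_mds(as_genotypes(m, small_map(4, 1)), k = 1)
  expect_equal(res$ibs["a", "b"], 1)
  expect_equal(res$ibs["a", "a"], 1)
  ## 4 points on a line: classical MDS reproduces distances exactly
  x <- c(0, 1, 3, 6)
  D <- as.matrix(stats::dist(x))
  coords <- stats::cmdscale(D, k = 1)
  expect_lt(max(abs(as.matrix(stats::dist(coords)) - D)), 1e-8)
  ## the same double-centering oracle, written out by hand
  J <- diag(4) - 1 / 4
  B <- -0.5 * J %*% D^2 %*% J
  ev <- eigen(B, symmetric = TRUE)
  hand <- ev$vectors[, 1] * sqrt(ev$values[1])
  expect_lt(max(abs(as.matrix(stats::dist(hand)) - D)), 1e-8)
})

test_that("IBD sharing proportions recover the pedigree expectations", {
  map <- small_map(600, n_chr = 6)
  ## unrelated founder pair, their offspring (parent-offspring, sibs)
  n_off <- 4
  ped <- pedigree(data.frame(
    id = c("s", "d", paste0("o", 1:n_off), "hs", "h1"),
    sire = c(NA, NA, rep("s", n_off), "s", NA),
    dam = c(NA, NA, rep("d", n_off), "h1", NA),
    sex = c("M", "F", rep("M", n_off), "M", "F"),
    generation = c(0, 0, rep(1, n_off), 1, 0)))
  fp <- simulate_founders(map, 3, K = 8, switch_rate = 3, seed = 2)
  G <- drop_genotypes(ped, fp, seed = 3)
  ## allele frequencies from the wider strain pool for stability
  p <- colMeans(fp$strain_alleles)
  z <- ibd_z_proportions(G, allele_freq = p)
  po <- z[z$id1 == "s" & z$id2 == "o1", ]
  expect_lt(abs(po$z1 - 1), 0.1)
  sib <- z[z$id1 == "o1" & z$id2 == "o2", ]
  expect_lt(abs(sib$z0 - 0.25), 0.15)
  expect_lt(abs(sib$z1 - 0.5), 0.2)
  half <- z[z$id1 == "o1" & z$id2 == "hs", ]
  expect_lt(abs(half$z0 - 0.5), 0.15)
  expect_lt(half$z2, 0.1)
  ## duplicated sample: Z2 ~ 1
  G2 <- subset_genotypes(G, animals = c("o1", "o1", "s"))
  z2 <- ibd_z_proportions(G2, allele_freq = p)
  expect_gt(z2$z2[1], 0.9)
})

test_that("X heterozygosity separates the sexes in a colony-sized sample", {
  map <- make_genetic_map(160, chr_lengths = c(chr1 = 2e8, chrX = 8e7))
  ped <- build_idealized_rotational_pedigree(5)
  fp <- simulate_founders(map, 26, K = 8, seed = 6)
  G <- drop_genotypes(ped, fp, seed = 7)
  sx <- infer_sex_chrx(G)
  called <- !is.na(sx$inferred_sex)
  expect_gt(mean(called), 0.9)
  expect_true(all(sx$inferred_sex[called] ==
                    ped$sex[match(sx$id[called], ped$id)]))
  ## simulated males are exactly hemizygous
  expect_true(all(sx$x_het[ped$sex == "M"] == 0))
})
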