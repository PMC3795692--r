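#' Sire family under the rotational mate-pairing rule
#'
#' In an n-family rotational breeding scheme the female of family `i` is
#' paired, at rotation `r`, with the male of family
#' `((i - 1 + r) mod n) + 1`. Offsets that are multiples of `n` would pair
#' within a family and are skipped: when the scheme reaches such a
#' rotation it re-starts with the rotation-1 map. The map is a fixed-point
#' free bijection of families for every rotation, which is what defers
#' close inbreeding; with 13 families every pairing at the half cycle is a
#' first-cousin mating.
#'
#' @param dam_family family index of the dam, `1..n_families`.
#' @param rotation rotation index (positive integer).
#' @param n_families number of families (default 13; must be >= 3).
#' @return sire family index; never equal to `dam_family`.
#' @export
rotation_sire_family <- function(dam_family, rotation, n_families = 13L) {
  if (n_families < 3L) stop("rotational scheme requires >= 3 families")
  stopifnot(all(dam_family >= 1L), all(dam_family <= n_families),
            all(rotation >= 1L))
  offset <- rotation %% n_families
  offset[offset == 0L] <- 1L  # same-family rotation skipped, reuse rotation 1
  ((dam_family - 1L + offset) %% n_families) + 1L
}

## rotation used by the generation-g breeders (g >= 1): cycles 1..n-1
rotation_for_generation <- function(g, n_families = 13L) {
  ((g - 1L) %% (n_families - 1L)) + 1L
}

#' Idealized rotational-breeding pedigree
#'
#' Builds the deterministic pedigree of a colony maintained in perfect
#' adherence to the rotational scheme: generation 0 consists of
#' `n_families` unrelated founder pairs (the pair of family `i` founds
#' family `i`); every subsequent generation contains exactly one male and
#' one female offspring per family; offspring inherit the dam's family
#' index; and the generation-g breeders are paired under rotation
#' `((g - 1) mod (n_families - 1)) + 1`, so that e.g. with 13 families the
#' generation-7 pairs are first cousins and their offspring show the
#' characteristic inbreeding spike at generation 8, recurring every 6
#' generations.
#'
#' @param n_generations number of offspring generations to build (>= 1).
#' @param n_families number of families (default 13).
#' @return a [pedigree()]; ids are of the form `G<g>F<fam><M|F>`.
#' @export
build_idealized_rotational_pedigree <- function(n_generations,
                                                n_families = 13L) {
  stopifnot(n_generations >= 1L)
  fam <- seq_len(n_families)
  rows <- list(
    data.frame(id = sprintf("G0F%dM", fam), sire = NA_character_,
               dam = NA_character_, sex = "M", generation = 0L,
               family = fam, stringsAsFactors = FALSE),
    data.frame(id = sprintf("G0F%dF", fam), sire = NA_character_,
               dam = NA_character_, sex = "F", generation = 0L,
               family = fam, stringsAsFactors = FALSE))
  ## sire family of the pairing whose dam is family i, at generation g
  sire_family_at <- function(g, i) {
    if (g == 0L) i else rotation_sire_family(i, rotation_for_generation(g, n_families), n_families)
  }
  for (g in seq_len(n_generations)) {
    sf <- vapply(fam, function(i) sire_family_at(g - 1L, i), integer(1))
    sire <- sprintf("G%dF%dM", g - 1L, sf)
    dam <- sprintf("G%dF%dF", g - 1L, fam)
    rows[[length(rows) + 1L]] <-
      data.frame(id = sprintf("G%dF%dM", g, fam), sire = sire, dam = dam,
                 sex = "M", generation = g, family = fam,
                 stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(id = sprintf("G%dF%dF", g, fam), sire = sire, dam = dam,
                 sex = "F", generation = g, family = fam,
                 stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  ped <- ped[order(ped$generation, ped$family, ped$sex, method = "radix"), ]
  pedigree(ped)
}

#' Random-mating pedigree realization
#'
#' Simulates a closed population bred by random mating with the given
#' per-generation breeder counts: each generation the previous
#' generation's breeders are formed into monogamous male-female pairs
#' uniformly at random, and each offspring is assigned to a uniformly
#' random pair (multinomial family sizes, matching the variance
#' assumptions of the classical breeder-count recursions). Offspring sexes
#' are fixed so that the next generation contains exactly the requested
#' numbers of male and female breeders.
#'
#' @param counts a [breeder_counts()] table covering generations
#'   `0..n_generations`, or a single integer for constant counts.
#' @param n_generations number of offspring generations.
#' @param seed integer seed (the builder is deterministic given the seed).
#' @return a [pedigree()].
#' @export
build_random_mating_pedigree <- function(counts, n_generations, seed) {
  if (is.numeric(counts) && length(counts) == 1L)
    counts <- breeder_counts(0:n_generations, counts, counts)
  idx <- match(0:n_generations, counts$generation)
  if (anyNA(idx) || any(is.na(counts$n_male[idx])) ||
      any(is.na(counts$n_female[idx])))
    stop("breeder counts required for generations 0..", n_generations)
  nm <- counts$n_male[idx]; nf <- counts$n_female[idx]
  if (any(nm < 1L) || any(nf < 1L)) stop("breeder counts must be >= 1")
  set.seed(seed)
  males <- sprintf("G0M%d", seq_len(nm[1]))
  females <- sprintf("G0F%d", seq_len(nf[1]))
  rows <- list(data.frame(id = c(males, females), sire = NA_character_,
                          dam = NA_character_,
                          sex = rep(c("M", "F"), c(nm[1], nf[1])),
                          generation = 0L, stringsAsFactors = FALSE))
  for (g in seq_len(n_generations)) {
    n_pairs <- min(length(males), length(females))
    pm <- sample(males)[seq_len(n_pairs)]
    pf <- sample(females)[seq_len(n_pairs)]
    n_off_m <- nm[g + 1L]; n_off_f <- nf[g + 1L]
    pair_of <- sample.int(n_pairs, n_off_m + n_off_f, replace = TRUE)
    sex <- rep(c("M", "F"), c(n_off_m, n_off_f))
    within <- stats::ave(seq_along(sex), sex, FUN = seq_along)
    id <- sprintf("G%d%s%d", g, sex, within)
    rows[[length(rows) + 1L]] <-
      data.frame(id = id, sire = pm[pair_of], dam = pf[pair_of], sex = sex,
                 generation = g, stringsAsFactors = FALSE)
    males <- id[sex == "M"]; females <- id[sex == "F"]
  }
  pedigree(do.call(rbind, rows))
}

#' Within-family truncation selection of breeders
#'
#' From each family's phenotyped candidates, selects the male and the
#' female with the most extreme trait value in the requested direction
#' (highest or lowest); exact ties are broken by the smaller id. Families
#' missing candidates of a sex are flagged (the rotational protocol then
#' permits a substitute male from another family, at the caller's
#' discretion).
#'
#' @param candidates data frame with columns `id`, `sex`, `family` and the
#'   trait column; rows with missing trait values are not eligible.
#' @param trait name of the trait column.
#' @param direction `"highest"` or `"lowest"`.
#' @return list with `breeders` (data frame `family`, `sire`, `dam`;
#'   `NA` where a sex is missing) and `missing` (data frame of
#'   family/sex combinations needing substitution).
#' @export
select_breeders_within_family <- function(candidates, trait,
                                          direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  stopifnot(all(c("id", "sex", "family", trait) %in% names(candidates)))
  eligible <- candidates[!is.na(candidates[[trait]]), , drop = FALSE]
  fams <- sort(unique(candidates$family))
  pick <- function(fam, sex) {
    sub <- eligible[eligible$family == fam & eligible$sex == sex, ,
                    drop = FALSE]
    if (!nrow(sub)) return(NA_character_)
    v <- sub[[trait]]
    best <- if (direction == "highest") v == max(v) else v == min(v)
    sort(sub$id[best])[1L]  # stable tie-break: smallest id
  }
  sires <- vapply(fams, pick, character(1), sex = "M")
  dams <- vapply(fams, pick, character(1), sex = "F")
  missing <- data.frame(
    family = c(fams[is.na(sires)], fams[is.na(dams)]),
    sex = rep(c("M", "F"), c(sum(is.na(sires)), sum(is.na(dams)))),
    stringsAsFactors = FALSE)
  list(breeders = data.frame(family = fams, sire = sires, dam = dams,
                             stringsAsFactors = FALSE),
       missing = missing)
}

#' Line-intercross pedigree (F0 x F0 -> F1 -> F2)
#'
#' Builds the three-tier pedigree of an intercross between two diverged
#' lines: F0 pairs each combine one animal from each line with reciprocal
#' parentage balance (half the pairs have a line-1 sire, half a line-2
#' sire, as evenly as possible); F1 offspring are paired between different
#' F1 families (no brother-sister mating); each F1 pair contributes F2
#' offspring.
#'
#' @param f0_line1,f0_line2 data frames with columns `id`, `sex` (equal
#'   numbers of males and females per line are not required, but enough of
#'   each sex to form `n_f0_pairs`).
#' @param n_f0_pairs number of F0 couples.
#' @param n_f1_offspring total number of F1 animals to generate.
#' @param n_f1_pairs number of F1 breeding pairs.
#' @param n_f2_offspring total number of F2 animals.
#' @param seed integer seed.
#' @return a [pedigree()] with `line` set to `"F1"`/`"F2"` for the bred
#'   tiers (F0 animals keep their line labels) and `generation` 0/1/2.
#' @export
build_intercross_pedigree <- function(f0_line1, f0_line2, n_f0_pairs,
                                      n_f1_offspring, n_f1_pairs,
                                      n_f2_offspring, seed) {
  set.seed(seed)
  n_sires1 <- ceiling(n_f0_pairs / 2)  # reciprocal balance
  n_sires2 <- n_f0_pairs - n_sires1
  take <- function(pool, sex, k, label) {
    ids <- pool$id[pool$sex == sex]
    if (length(ids) < k)
      stop("not enough ", sex, " animals in ", label, " for the F0 design")
    sample(ids, k)
  }
  sires <- c(take(f0_line1, "M", n_sires1, "line 1"),
             take(f0_line2, "M", n_sires2, "line 2"))
  dams <- c(take(f0_line2, "F", n_sires1, "line 2"),
            take(f0_line1, "F", n_sires2, "line 1"))
  f0 <- rbind(
    data.frame(id = sires, sex = "M", stringsAsFactors = FALSE),
    data.frame(id = dams, sex = "F", stringsAsFactors = FALSE))
  f0$sire <- NA_character_; f0$dam <- NA_character_
  f0$generation <- 0L
  f0$line <- c(rep(c("L1", "L2"), c(n_sires1, n_sires2)),
               rep(c("L2", "L1"), c(n_sires1, n_sires2)))
  f0$family <- c(seq_len(n_f0_pairs), seq_len(n_f0_pairs))
  ## F1: offspring assigned round-robin across F0 pairs, alternating sex
  pair_of <- rep_len(seq_len(n_f0_pairs), n_f1_offspring)
  sex1 <- rep_len(c("M", "F"), n_f1_offspring)
  f1 <- data.frame(id = sprintf("F1_%03d", seq_len(n_f1_offspring)),
                   sire = sires[pair_of], dam = dams[pair_of], sex = sex1,
                   generation = 1L, line = "F1", family = pair_of,
                   stringsAsFactors = FALSE)
  ## F1 pairs between different F1 families
  m1 <- f1[f1$sex == "M", ]; fe1 <- f1[f1$sex == "F", ]
  if (n_f0_pairs < 2L)
    stop("F1 pairing without sib mating is infeasible with a single F0 pair")
  if (nrow(m1) < n_f1_pairs || nrow(fe1) < n_f1_pairs)
    stop("not enough F1 animals of each sex for ", n_f1_pairs, " pairs")
  msel <- sample(m1$id, n_f1_pairs)
  fpool <- fe1[sample.int(nrow(fe1)), ]
  fsel <- character(n_f1_pairs)
  used <- logical(nrow(fpool))
  for (k in seq_len(n_f1_pairs)) {
    ok <- which(!used & fpool$family != m1$family[match(msel[k], m1$id)])
    if (!length(ok))
      stop("F1 pairing without sib mating is infeasible with this design")
    fsel[k] <- fpool$id[ok[1L]]
    used[ok[1L]] <- TRUE
  }
  pair2 <- rep_len(seq_len(n_f1_pairs), n_f2_offspring)
  f2 <- data.frame(id = sprintf("F2_%03d", seq_len(n_f2_offspring)),
                   sire = msel[pair2], dam = fsel[pair2],
                   sex = rep_len(c("M", "F"), n_f2_offspring),
                   generation = 2L, line = "F2", family = pair2,
                   stringsAsFactors = FALSE)
  cols <- c("id", "sire", "dam", "sex", "generation", "line", "family")
  pedigree(rbind(f0[cols], f1[cols], f2[cols]))
}
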