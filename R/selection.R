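## internal: one recombinant gamete given parent haplotype rows and a
## prebuilt chromosome index (autosomal maps only)
gamete_from <- function(h1, h2, chr_index, cM) {
  recombine_gamete(h1, h2, chr_index, cM)
}

#' Run a divergent artificial-selection experiment
#'
#' End-to-end simulation of two selection lines maintained under the
#' rotational breeding scheme from a shared founder pool: each line
#' starts from `n_families` founder pairs drawn (disjointly) from the
#' pool; every generation each family produces a litter of phenotyped
#' candidates (genotypes by Mendelian gene drop, phenotypes additive QTL
#' values plus normal noise); within each family the extreme male and
#' female in the line's selection direction become breeders, and breeder
#' pairs follow the rotational mate-pairing rule.
#'
#' @param founders a [simulate_founders()] pool over an autosomal map,
#'   with at least `4 * n_families` animals.
#' @param arch a [trait_architecture()]; an `h2_target` is calibrated on
#'   the founder pool.
#' @param n_generations number of selected generations.
#' @param n_families families per line (default 13).
#' @param litter_per_sex candidates of each sex per family per generation
#'   (default 4).
#' @param directions selection direction per line (named character
#'   vector, default `c(HCR = "highest", LCR = "lowest")`).
#' @param seed integer seed.
#' @return object of class `selection_experiment`: `ped` (combined
#'   pedigree with `line` labels), `genotypes` (a `genotype_matrix` for
#'   all animals), `phenotype` (named vector), `sigma_e`, `summary`
#'   (per line x generation phenotype mean/SD of all candidates).
#' @export
run_selection_experiment <- function(founders, arch, n_generations,
                                     n_families = 13L, litter_per_sex = 4L,
                                     directions = c(HCR = "highest",
                                                    LCR = "lowest"),
                                     seed = 1L) {
  map <- founders$map
  if (any(map$is_x))
    stop("selection driver supports autosomal maps only")
  lines <- names(directions)
  n_pool <- nrow(founders$hap1)
  need <- 2L * n_families * length(lines)
  if (n_pool < need)
    stop("founder pool too small: need ", need, " animals")
  set.seed(seed)
  M <- ncol(founders$hap1)
  chr_index <- split(seq_len(M), map$chr)[unique(map$chr)]
  ## environmental SD calibrated on the founder pool
  gv_pool <- (founders$hap1 + founders$hap2)[, arch$qtl, drop = FALSE] %*%
    arch$effects
  sigma_e <- arch$sigma_e
  if (!is.null(arch$h2_target)) {
    vg <- stats::var(drop(gv_pool))
    if (vg == 0 && arch$h2_target > 0)
      stop("zero genetic variance in founder pool")
    sigma_e <- if (arch$h2_target == 0) max(stats::sd(drop(gv_pool)), 1)
      else sqrt(vg * (1 - arch$h2_target) / arch$h2_target)
  }
  males <- which(founders$sex == "M")
  females <- which(founders$sex == "F")
  if (length(males) < n_families * length(lines) ||
      length(females) < n_families * length(lines))
    stop("founder pool lacks enough animals of each sex")
  ped_rows <- list(); H1 <- list(); H2 <- list()
  phen <- numeric(0)
  idx_of <- integer(0)
  add_animal <- function(id, sire, dam, sex, gen, line, fam, h1, h2) {
    ped_rows[[length(ped_rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex, generation = gen,
      line = line, family = fam, stringsAsFactors = FALSE)
    H1[[length(H1) + 1L]] <<- h1
    H2[[length(H2) + 1L]] <<- h2
    idx_of[id] <<- length(ped_rows)
    g <- sum((h1[arch$qtl] + h2[arch$qtl]) * arch$effects)
    phen[id] <<- g + stats::rnorm(1L, 0, sigma_e)
  }
  state <- list()
  for (li in seq_along(lines)) {
    ln <- lines[li]
    fm <- males[seq_len(n_families) + (li - 1L) * n_families]
    ff <- females[seq_len(n_families) + (li - 1L) * n_families]
    sires <- dams <- character(n_families)
    for (k in seq_len(n_families)) {
      sid <- sprintf("%s_G0_F%d_M", ln, k)
      did <- sprintf("%s_G0_F%d_F", ln, k)
      add_animal(sid, NA_character_, NA_character_, "M", 0L, ln, k,
                 founders$hap1[fm[k], ], founders$hap2[fm[k], ])
      add_animal(did, NA_character_, NA_character_, "F", 0L, ln, k,
                 founders$hap1[ff[k], ], founders$hap2[ff[k], ])
      sires[k] <- sid; dams[k] <- did
    }
    state[[ln]] <- list(sires = sires, dams = dams)
  }
  id_index <- function(id) idx_of[[id]]
  for (g in seq_len(n_generations)) {
    for (ln in lines) {
      st <- state[[ln]]
      cand <- list()
      for (k in seq_len(n_families)) {
        si <- id_index(st$sires[k]); di <- id_index(st$dams[k])
        for (r in seq_len(2L * litter_per_sex)) {
          sex <- if (r <= litter_per_sex) "M" else "F"
          cid <- sprintf("%s_G%d_F%d_%s%d", ln, g, k, sex,
                         (r - 1L) %% litter_per_sex + 1L)
          h1 <- gamete_from(H1[[si]], H2[[si]], chr_index, map$cM)
          h2 <- gamete_from(H1[[di]], H2[[di]], chr_index, map$cM)
          add_animal(cid, st$sires[k], st$dams[k], sex, g, ln, k, h1, h2)
          cand[[length(cand) + 1L]] <- data.frame(
            id = cid, sex = sex, family = k, y = phen[cid],
            stringsAsFactors = FALSE)
        }
      }
      cand <- do.call(rbind, cand)
      names(cand)[names(cand) == "y"] <- "trait"
      sel <- select_breeders_within_family(cand, "trait",
                                           directions[[ln]])
      if (nrow(sel$missing))
        stop("family lost a sex; increase litter_per_sex")
      rot <- rotation_for_generation(g, n_families)
      sire_fam <- rotation_sire_family(seq_len(n_families), rot,
                                       n_families)
      state[[ln]] <- list(
        sires = sel$breeders$sire[match(sire_fam, sel$breeders$family)],
        dams = sel$breeders$dam)
    }
  }
  ped <- pedigree(do.call(rbind, ped_rows))
  H1m <- do.call(rbind, H1); H2m <- do.call(rbind, H2)
  geno <- H1m + H2m
  rownames(geno) <- ped$id
  colnames(geno) <- map$marker
  G <- structure(list(geno = geno, hap1 = H1m, hap2 = H2m, map = map,
                      ids = ped$id), class = "genotype_matrix")
  ped$best_distance_m <- unname(phen[ped$id])
  key <- paste(ped$line, ped$generation, sep = "\r")
  lv <- unique(key)
  parts <- do.call(rbind, strsplit(lv, "\r", fixed = TRUE))
  summ <- data.frame(line = parts[, 1], generation = as.integer(parts[, 2]),
                     n = as.integer(table(key)[lv]),
                     mean = as.numeric(tapply(ped$best_distance_m, key,
                                              mean)[lv]),
                     sd = as.numeric(tapply(ped$best_distance_m, key,
                                            stats::sd)[lv]),
                     stringsAsFactors = FALSE)
  summ <- summ[order(summ$line, summ$generation), ]
  rownames(summ) <- NULL
  structure(list(ped = ped, genotypes = G, phenotype = phen,
                 sigma_e = sigma_e, summary = summ, seed = seed,
                 directions = directions),
            class = "selection_experiment")
}

#' @export
print.selection_experiment <- function(x, ...) {
  gmax <- max(x$ped$generation)
  cat(sprintf(
    "Divergent selection experiment: %d animals over %d generations\n",
    nrow(x$ped), gmax))
  last <- x$summary[x$summary$generation == gmax, ]
  for (i in seq_len(nrow(last)))
    cat(sprintf("  %s G%d: mean %.2f (sd %.2f, n=%d)\n", last$line[i],
                gmax, last$mean[i], last$sd[i], last$n[i]))
  invisible(x)
}

#' Simulate an intercross of two diverged lines
#'
#' Takes final-generation animals of a [run_selection_experiment()]
#' result as the F0 tier, builds the F0 -> F1 -> F2 intercross pedigree
#' (reciprocal F0 pairs, no F1 sib mating), gene-drops the F0 haplotypes
#' through it and phenotypes every animal under the same architecture
#' and environmental SD as the selection run.
#'
#' @param sel a `selection_experiment`.
#' @param arch the same [trait_architecture()] used for the selection run.
#' @param n_f0_pairs,n_f1_offspring,n_f1_pairs,n_f2_offspring design
#'   sizes.
#' @param seed integer seed.
#' @return list of class `intercross_experiment`: `ped`, `genotypes`,
#'   `phenotype`, `parental_means` (final-generation line cohort means of
#'   the selection run), `var_f1`, `var_f2`.
#' @export
simulate_intercross <- function(sel, arch, n_f0_pairs = 8L,
                                n_f1_offspring = 80L, n_f1_pairs = 20L,
                                n_f2_offspring = 300L, seed = 1L) {
  gmax <- max(sel$ped$generation)
  lines <- names(sel$directions)
  last <- sel$ped[sel$ped$generation == gmax, ]
  pool1 <- last[last$line == lines[1], c("id", "sex")]
  pool2 <- last[last$line == lines[2], c("id", "sex")]
  xped <- build_intercross_pedigree(pool1, pool2, n_f0_pairs,
                                    n_f1_offspring, n_f1_pairs,
                                    n_f2_offspring, seed = seed)
  f0_ids <- xped$id[is_founder(xped)]
  rows <- match(f0_ids, rownames(sel$genotypes$geno))
  fpool <- structure(list(map = sel$genotypes$map,
                          hap1 = sel$genotypes$hap1[rows, , drop = FALSE],
                          hap2 = sel$genotypes$hap2[rows, , drop = FALSE],
                          sex = xped$sex[is_founder(xped)]),
                     class = "founder_pool")
  G <- drop_genotypes(xped, fpool, seed = seed + 1L)
  gv <- drop(G$geno[, arch$qtl, drop = FALSE] %*% arch$effects)
  set.seed(seed + 2L)
  y <- gv + stats::rnorm(length(gv), 0, sel$sigma_e)
  names(y) <- xped$id
  pm <- tapply(sel$ped$best_distance_m[sel$ped$generation == gmax],
               last$line, mean)
  structure(list(ped = xped, genotypes = G, phenotype = y,
                 parental_means = pm,
                 var_f1 = stats::var(y[xped$generation == 1L]),
                 var_f2 = stats::var(y[xped$generation == 2L])),
            class = "intercross_experiment")
}

#' @export
print.intercross_experiment <- function(x, ...) {
  cat(sprintf(
    "Intercross: %d F0 / %d F1 / %d F2 animals\n",
    sum(x$ped$generation == 0L), sum(x$ped$generation == 1L),
    sum(x$ped$generation == 2L)))
  cat(sprintf("  parental means: %s\n",
              paste(sprintf("%s=%.2f", names(x$parental_means),
                            x$parental_means), collapse = ", ")))
  cat(sprintf("  var(F1) = %.3f, var(F2) = %.3f\n", x$var_f1, x$var_f2))
  invisible(x)
}
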