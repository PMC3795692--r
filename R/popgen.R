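#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic marker: given the minor-allele
#' count, the number of heterozygotes follows the classical conditional
#' distribution; the p-value sums the probabilities of all heterozygote
#' counts no more probable than the observed one (no mid-p adjustment).
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @return two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  n_a <- 2L * n_aa + n_ab
  n_rare <- min(n_a, 2L * n - n_a)
  hets <- seq(n_rare %% 2L, n_rare, by = 2L)
  ## log P(n_het | n_rare, n) up to a constant
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Marker-panel quality control
#'
#' Applies the panel-construction filters in a fixed order: duplicated
#' marker columns (the later column of each identical pair is flagged),
#' missingness above threshold, Hardy-Weinberg exact-test failures
#' (yielding the "Panel-1" set), then a windowed LD prune and a
#' minor-allele-frequency filter (yielding the stricter "Panel-2" set used
#' for heterozygosity, AMOVA and IBD analyses). LD pruning slides a window
#' of `ld_window` SNPs in steps of `ld_step` and removes the later-indexed
#' marker of any pair with r-squared above `ld_r2`.
#'
#' @param G a `genotype_matrix` (or plain 0/1/2 matrix).
#' @param max_missing missingness threshold (default 0.10).
#' @param hwe_p HWE exact p-value threshold (default 1e-3).
#' @param ld_r2 LD pruning r-squared threshold (default 0.05).
#' @param ld_window,ld_step pruning window size and step (default 10, 2).
#' @param min_maf minor-allele-frequency threshold (default 0.05).
#' @return list of class `marker_qc_report`: per-stage removed marker
#'   names (`duplicate`, `missing`, `hwe`, `ld_pruned`, `maf`), the
#'   surviving `panel1` and `panel2` marker vectors, and a `counts`
#'   summary table.
#' @export
qc_marker_panel <- function(G, max_missing = 0.10, hwe_p = 1e-3,
                            ld_r2 = 0.05, ld_window = 10L, ld_step = 2L,
                            min_maf = 0.05) {
  geno <- if (inherits(G, "genotype_matrix")) G$geno else G
  if (!length(geno)) stop("empty genotype matrix")
  markers <- colnames(geno)
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(geno)))
  keep <- rep(TRUE, ncol(geno))
  removed <- list()
  ## 1. duplicates (identical genotype columns, missing pattern included)
  key <- apply(geno, 2L, paste, collapse = ",")
  dup <- duplicated(key)
  removed$duplicate <- markers[dup]
  keep[dup] <- FALSE
  ## 2. missingness
  miss <- colMeans(is.na(geno))
  bad <- keep & miss > max_missing
  removed$missing <- markers[bad]
  keep[bad] <- FALSE
  ## 3. HWE exact test
  hwe <- vapply(which(keep), function(j) {
    g <- geno[, j]
    hwe_exact_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                   sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  bad <- which(keep)[!is.na(hwe) & hwe < hwe_p]
  removed$hwe <- markers[bad]
  keep[bad] <- FALSE
  panel1 <- markers[keep]
  ## 4. windowed LD prune on panel-1 survivors
  idx <- which(keep)
  pruned <- logical(ncol(geno))
  if (length(idx) > 1L) {
    starts <- seq(1L, max(1L, length(idx) - 1L), by = ld_step)
    for (s in starts) {
      win <- idx[s:min(s + ld_window - 1L, length(idx))]
      win <- win[!pruned[win]]
      if (length(win) < 2L) next
      for (a in seq_len(length(win) - 1L)) {
        for (b in seq((a + 1L), length(win))) {
          if (pruned[win[b]]) next
          r2 <- genotype_r2(geno[, win[a]], geno[, win[b]])
          if (!is.na(r2) && r2 > ld_r2) pruned[win[b]] <- TRUE
        }
      }
    }
  }
  removed$ld_pruned <- markers[pruned]
  keep[pruned] <- FALSE
  ## 5. MAF
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad <- keep & (is.na(maf) | maf < min_maf)
  removed$maf <- markers[bad]
  keep[bad] <- FALSE
  panel2 <- markers[keep]
  counts <- data.frame(
    stage = c("input", "duplicate", "missing", "hwe", "panel1",
              "ld_pruned", "maf", "panel2"),
    n = c(ncol(geno), length(removed$duplicate), length(removed$missing),
          length(removed$hwe), length(panel1), length(removed$ld_pruned),
          length(removed$maf), length(panel2)))
  structure(list(removed = removed, panel1 = panel1, panel2 = panel2,
                 counts = counts),
            class = "marker_qc_report")
}

#' @export
print.marker_qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Observed per-animal heterozygosity
#'
#' Fraction of non-missing genotype calls that are heterozygous, per
#' animal, over a marker subset (typically the pruned panel).
#'
#' @param G a `genotype_matrix` or 0/1/2 matrix with animal rownames.
#' @param markers marker subset (names or indices; default all).
#' @return named numeric vector; animals with no non-missing calls are
#'   dropped with a warning.
#' @export
observed_heterozygosity <- function(G, markers = NULL) {
  geno <- if (inherits(G, "genotype_matrix")) G$geno else G
  if (!is.null(markers)) geno <- geno[, markers, drop = FALSE]
  n_called <- rowSums(!is.na(geno))
  h <- rowSums(geno == 1L, na.rm = TRUE) / n_called
  if (any(n_called == 0L)) {
    warning("excluding ", sum(n_called == 0L), " animal(s) with no calls")
    h <- h[n_called > 0L]
  }
  h
}

#' Runs of homozygosity
#'
#' Maximal runs of consecutive homozygous, non-missing genotype calls
#' along each chromosome, retained when they contain at least
#' `min_markers` markers and have a marker density of at least one marker
#' per `max_kb_per_marker` kb over the segment span. Segment length is the
#' bp span from the first to the last marker of the run (1-based
#' inclusive coordinates, `length = end - start`).
#'
#' @param G a `genotype_matrix`.
#' @param min_markers minimum markers per run (default 4).
#' @param max_kb_per_marker density threshold in kb per marker (default
#'   500, i.e. at least 1 SNP per 500 kb).
#' @param genome_size genome length in bp used for the genome fraction
#'   (default 2.75e9).
#' @return list with `segments` (data frame: `animal`, `chr`, `start_bp`,
#'   `end_bp`, `n_markers`, `length_bp`) and `genome_fraction` (named
#'   per-animal total ROH length divided by `genome_size`).
#' @export
detect_roh <- function(G, min_markers = 4L, max_kb_per_marker = 500,
                       genome_size = 2.75e9) {
  geno <- G$geno
  map <- G$map
  if (is.unsorted(order(map$chr)) &&
      any(tapply(map$bp, map$chr, is.unsorted)))
    stop("marker map must be sorted by position within chromosome")
  segs <- list()
  for (chr in unique(map$chr)) {
    idx <- which(map$chr == chr)
    if (is.unsorted(map$bp[idx])) stop("unsorted map on ", chr)
    for (a in seq_len(nrow(geno))) {
      hom <- !is.na(geno[a, idx]) & geno[a, idx] != 1L
      r <- rle(hom)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_markers)) {
        mk <- idx[starts[k]:ends[k]]
        len <- map$bp[mk[length(mk)]] - map$bp[mk[1]]
        if (len / length(mk) <= max_kb_per_marker * 1000) {
          segs[[length(segs) + 1L]] <- data.frame(
            animal = rownames(geno)[a], chr = chr,
            start_bp = map$bp[mk[1]], end_bp = map$bp[mk[length(mk)]],
            n_markers = length(mk), length_bp = len,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(animal = character(), chr = character(),
               start_bp = numeric(), end_bp = numeric(),
               n_markers = integer(), length_bp = numeric(),
               stringsAsFactors = FALSE)
  total <- stats::setNames(numeric(nrow(geno)), rownames(geno))
  if (nrow(segments)) {
    agg <- tapply(segments$length_bp, segments$animal, sum)
    total[names(agg)] <- agg
  }
  list(segments = segments, genome_fraction = total / genome_size)
}

## r-squared between two unphased genotype vectors, via two-locus EM
## haplotype frequencies (the double-heterozygote phase is latent)
genotype_r2 <- function(g1, g2, max_iter = 100L, tol = 1e-10) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n == 0L) return(NA_real_)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  ## haplotype counts AB, Ab, aB, ab; double hets are ambiguous
  n_dh <- sum(g1 == 1L & g2 == 1L)
  ## unambiguous haplotype contributions
  cAB <- sum((g1 == 2L) * (g2 == 2L) * 2 + (g1 == 2L) * (g2 == 1L) +
             (g1 == 1L) * (g2 == 2L))
  cAb <- sum((g1 == 2L) * (g2 == 0L) * 2 + (g1 == 2L) * (g2 == 1L) +
             (g1 == 1L) * (g2 == 0L))
  caB <- sum((g1 == 0L) * (g2 == 2L) * 2 + (g1 == 0L) * (g2 == 1L) +
             (g1 == 1L) * (g2 == 2L))
  cab <- sum((g1 == 0L) * (g2 == 0L) * 2 + (g1 == 0L) * (g2 == 1L) +
             (g1 == 1L) * (g2 == 0L))
  fAB <- pA * pB
  for (it in seq_len(max_iter)) {
    fAb <- pA - fAB; faB <- pB - fAB; fab <- 1 - pA - pB + fAB
    denom <- fAB * fab + fAb * faB
    w <- if (denom > 0) fAB * fab / denom else 0.5
    new_fAB <- (cAB + n_dh * w) / (2 * n)
    if (abs(new_fAB - fAB) < tol) { fAB <- new_fAB; break }
    fAB <- new_fAB
  }
  D <- fAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## r-squared from phased haplotype allele vectors
haplotype_r2 <- function(h1, h2) {
  pA <- mean(h1); pB <- mean(h2)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- mean(h1 * h2) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Linkage-disequilibrium decay curve
#'
#' Computes pairwise r-squared for marker pairs within `max_dist` bp on
#' one chromosome, bins pairs by inter-marker distance, and reports the
#' mean r-squared and pair count per bin, plus the distance at which the
#' binned curve first crosses a threshold (linear interpolation between
#' bin centers).
#'
#' For unphased genotypes r-squared is computed from EM-estimated
#' two-locus haplotype frequencies; with `use_haplotypes = TRUE` the
#' stored phased haplotypes are counted directly.
#'
#' @param G a `genotype_matrix`.
#' @param chr chromosome to analyse (default: the first in the map).
#' @param max_dist maximum pair distance in bp (default 5e6).
#' @param bin_width distance bin width in bp (default 5e5).
#' @param r2_threshold threshold for the crossing distance (default 0.3).
#' @param use_haplotypes count phased haplotypes instead of running EM.
#' @return list of class `ld_decay`: `bins` (data frame `bin_start`,
#'   `bin_mid`, `mean_r2`, `n_pairs`), `dist_at_threshold` (bp, `NA` if
#'   the curve never crosses), `chr`, `r2_threshold`.
#' @export
ld_decay <- function(G, chr = NULL, max_dist = 5e6, bin_width = 5e5,
                     r2_threshold = 0.3, use_haplotypes = FALSE) {
  map <- G$map
  if (is.null(chr)) chr <- map$chr[1]
  idx <- which(map$chr == chr)
  if (length(idx) < 2L) stop("need >= 2 markers on ", chr)
  pairs_d <- numeric(0); pairs_r2 <- numeric(0)
  for (a in seq_len(length(idx) - 1L)) {
    for (b in seq(a + 1L, length(idx))) {
      d <- map$bp[idx[b]] - map$bp[idx[a]]
      if (d > max_dist) break
      r2 <- if (use_haplotypes) {
        h1 <- c(G$hap1[, idx[a]], G$hap2[, idx[a]])
        h2 <- c(G$hap1[, idx[b]], G$hap2[, idx[b]])
        haplotype_r2(h1, h2)
      } else {
        genotype_r2(G$geno[, idx[a]], G$geno[, idx[b]])
      }
      if (!is.na(r2)) {
        pairs_d <- c(pairs_d, d)
        pairs_r2 <- c(pairs_r2, r2)
      }
    }
  }
  bin <- floor(pairs_d / bin_width)
  lv <- sort(unique(bin))
  bins <- data.frame(
    bin_start = lv * bin_width,
    bin_mid = lv * bin_width + bin_width / 2,
    mean_r2 = vapply(lv, function(b) mean(pairs_r2[bin == b]), numeric(1)),
    n_pairs = vapply(lv, function(b) sum(bin == b), numeric(1)))
  dist_at <- NA_real_
  below <- which(bins$mean_r2 < r2_threshold)
  if (length(below) && below[1] > 1L) {
    i <- below[1]
    x0 <- bins$bin_mid[i - 1L]; y0 <- bins$mean_r2[i - 1L]
    x1 <- bins$bin_mid[i]; y1 <- bins$mean_r2[i]
    dist_at <- x0 + (y0 - r2_threshold) / (y0 - y1) * (x1 - x0)
  } else if (length(below) && below[1] == 1L) {
    dist_at <- bins$bin_mid[1]
  }
  structure(list(bins = bins, dist_at_threshold = dist_at, chr = chr,
                 r2_threshold = r2_threshold),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("LD decay on %s: %d bins, r2 crosses %.2f at %s\n",
              x$chr, nrow(x$bins), x$r2_threshold,
              if (is.na(x$dist_at_threshold)) "no crossing" else
                sprintf("%.2f Mb", x$dist_at_threshold / 1e6)))
  invisible(x)
}

#' Two-group analysis of molecular variance
#'
#' Partitions allelic variance into among-group and within-group
#' components per locus (one-way AMOVA on allele indicator variables:
#' each diploid animal contributes two allele observations), and combines
#' loci as the ratio of summed variance components — a weighted average
#' over loci of the among-population proportion, analogous to FST.
#'
#' @param G a `genotype_matrix` or 0/1/2 matrix.
#' @param groups factor/character vector of length n animals, exactly two
#'   levels, each with at least 2 animals.
#' @param markers optional marker subset.
#' @return list with `proportion` (among-group variance proportion,
#'   clipped to `[0, 1]`), `sigma_among`, `sigma_within` (summed
#'   components), `n_loci`.
#' @export
amova_two_groups <- function(G, groups, markers = NULL) {
  geno <- if (inherits(G, "genotype_matrix")) G$geno else G
  if (!is.null(markers)) geno <- geno[, markers, drop = FALSE]
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 animals")
  sa_sum <- 0; sw_sum <- 0; n_loci <- 0L
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    keep <- !is.na(g)
    if (!any(keep)) next
    x <- g[keep] / 2           # per-animal allele frequency
    grp <- groups[keep]
    n_g <- tapply(rep(2, length(x)), grp, sum)   # allele copies per group
    if (any(is.na(n_g)) || any(n_g < 2)) next
    p_g <- tapply(g[keep], grp, sum) / n_g
    n_tot <- sum(n_g)
    p_tot <- sum(g[keep]) / n_tot
    if (p_tot %in% c(0, 1)) next                  # monomorphic locus
    ## allele-level sums of squares (each animal: 2 Bernoulli alleles)
    ss_total <- n_tot * p_tot * (1 - p_tot)
    ss_among <- sum(n_g * (p_g - p_tot)^2)
    ss_within <- ss_total - ss_among
    df_among <- 1
    df_within <- n_tot - 2
    ms_among <- ss_among / df_among
    ms_within <- ss_within / df_within
    n0 <- (n_tot - sum(n_g^2) / n_tot) / df_among
    sa_sum <- sa_sum + (ms_among - ms_within) / n0
    sw_sum <- sw_sum + ms_within
    n_loci <- n_loci + 1L
  }
  if (n_loci == 0L) stop("no polymorphic loci; AMOVA undefined")
  prop <- sa_sum / (sa_sum + sw_sum)
  list(proportion = min(max(prop, 0), 1), sigma_among = sa_sum,
       sigma_within = sw_sum, n_loci = n_loci)
}

#' Pairwise identity-by-state matrix and MDS projection
#'
#' IBS between two animals is the mean over shared non-missing markers of
#' `(2 - |g_i - g_j|) / 2`. Classical (Torgerson) multidimensional
#' scaling of the distance `1 - IBS` gives low-dimensional coordinates
#' (centered).
#'
#' @param G a `genotype_matrix` or 0/1/2 matrix.
#' @param k number of MDS dimensions (default 2).
#' @param markers optional marker subset.
#' @return list with `ibs` (n x n matrix), `coords` (n x k matrix; fewer
#'   columns with a warning when fewer positive eigenvalues exist).
#' @export
ibs_mds <- function(G, k = 2L, markers = NULL) {
  geno <- if (inherits(G, "genotype_matrix")) G$geno else G
  if (!is.null(markers)) geno <- geno[, markers, drop = FALSE]
  n <- nrow(geno)
  if (n < 3L) stop("need >= 3 animals")
  ibs <- matrix(1, n, n, dimnames = list(rownames(geno), rownames(geno)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- abs(geno[i, ] - geno[j, ])
      ibs[i, j] <- ibs[j, i] <- mean((2 - d) / 2, na.rm = TRUE)
    }
  }
  mds <- stats::cmdscale(stats::as.dist(1 - ibs), k = k, eig = TRUE)
  coords <- mds$points
  if (ncol(coords) < k)
    warning("only ", ncol(coords), " positive eigenvalue(s); returning ",
            ncol(coords), " dimension(s)")
  list(ibs = ibs, coords = coords)
}

#' Pairwise IBD sharing proportions (Z0, Z1, Z2)
#'
#' Method-of-moments estimates of the probabilities that a pair of
#' animals shares 0, 1 or 2 alleles identical by descent, from the counts
#' of markers at IBS state 0/1/2 and the panel allele frequencies
#' (estimated from the sample unless supplied). Estimates are projected
#' onto the probability simplex. No small-sample frequency correction is
#' applied.
#'
#' @param G a `genotype_matrix` or 0/1/2 matrix.
#' @param allele_freq optional per-marker reference-allele frequencies.
#' @param markers optional marker subset.
#' @return data frame with one row per animal pair: `id1`, `id2`, `z0`,
#'   `z1`, `z2`.
#' @export
ibd_z_proportions <- function(G, allele_freq = NULL, markers = NULL) {
  geno <- if (inherits(G, "genotype_matrix")) G$geno else G
  if (!is.null(markers)) geno <- geno[, markers, drop = FALSE]
  if (ncol(geno) < 50L)
    warning("fewer than 50 markers; IBD estimates will be noisy")
  if (is.null(allele_freq)) allele_freq <- colMeans(geno, na.rm = TRUE) / 2
  p <- allele_freq; q <- 1 - p
  poly <- p > 0 & p < 1
  ## expected per-marker IBS-state probabilities conditional on IBD state
  e0_i0 <- 2 * p^2 * q^2
  e1_i0 <- 4 * p^3 * q + 4 * p * q^3
  e1_i1 <- 2 * p * q
  e2_i0 <- 1 - e0_i0 - e1_i0
  e2_i1 <- 1 - e1_i1
  n <- nrow(geno)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      keep <- poly & !is.na(geno[i, ]) & !is.na(geno[j, ])
      ibs <- 2 - abs(geno[i, keep] - geno[j, keep])
      N0 <- sum(ibs == 0); N1 <- sum(ibs == 1)
      z0 <- N0 / sum(e0_i0[keep])
      z1 <- (N1 - z0 * sum(e1_i0[keep])) / sum(e1_i1[keep])
      z2 <- 1 - z0 - z1
      z <- pmax(c(z0, z1, z2), 0)
      z <- z / sum(z)
      out[[length(out) + 1L]] <- data.frame(
        id1 = rownames(geno)[i], id2 = rownames(geno)[j],
        z0 = z[1], z1 = z[2], z2 = z[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Infer sex from X-chromosome heterozygosity
#'
#' Per-animal mean heterozygosity over X-chromosome markers splits males
#' (hemizygous, coded homozygous, heterozygosity ~0) from females. The
#' two clusters are found by a 1-D two-means split; the decision
#' threshold is the midpoint of the cluster means, and animals within
#' `ambiguity` of the threshold are flagged.
#'
#' @param G a `genotype_matrix` containing X markers (`map$is_x`).
#' @param ambiguity half-width of the ambiguous band around the threshold
#'   (default 0.05).
#' @return data frame `id`, `x_het`, `inferred_sex` (`"M"`/`"F"`,
#'   `NA` when ambiguous), `ambiguous`.
#' @export
infer_sex_chrx <- function(G, ambiguity = 0.05) {
  x_idx <- which(G$map$is_x)
  if (length(x_idx) < 10L) stop("need >= 10 X-chromosome markers")
  h <- observed_heterozygosity(G, x_idx)
  ## deterministic 1-D two-means: initialize at extremes
  c1 <- min(h); c2 <- max(h)
  for (it in 1:100) {
    assign2 <- abs(h - c2) < abs(h - c1)
    if (!any(assign2) || all(assign2)) break
    n1 <- mean(h[!assign2]); n2 <- mean(h[assign2])
    if (n1 == c1 && n2 == c2) break
    c1 <- n1; c2 <- n2
  }
  if (!any(assign2) || all(assign2) || (c2 - c1) < 2 * ambiguity) {
    return(data.frame(id = names(h), x_het = unname(h),
                      inferred_sex = NA_character_, ambiguous = TRUE,
                      stringsAsFactors = FALSE))
  }
  thr <- (c1 + c2) / 2
  amb <- abs(h - thr) < ambiguity
  sex <- ifelse(h < thr, "M", "F")
  sex[amb] <- NA_character_
  data.frame(id = names(h), x_het = unname(h), inferred_sex = sex,
             ambiguous = amb, stringsAsFactors = FALSE)
}
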