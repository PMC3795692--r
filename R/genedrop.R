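#' Construct a marker map
#'
#' Builds a biallelic SNP-panel geometry: chromosomes with physical (bp)
#' and genetic (cM) coordinates. Defaults emulate a rat-sized genome of
#' 2.75 Gb over 20 autosomes plus X, with 1 cM per 2 Mb.
#'
#' @param n_markers total number of markers (allocated to chromosomes in
#'   proportion to length, at least 2 per chromosome).
#' @param chr_lengths named numeric vector of chromosome lengths in bp;
#'   default 21 chromosomes (`chr1..chr20`, `chrX`) of equal length
#'   totalling 2.75e9.
#' @param spacing `"uniform"` (evenly spaced) or `"random"` (uniform
#'   random positions).
#' @param cm_per_mb genetic map density (default 0.5 cM/Mb, i.e. 1 cM per
#'   2 Mb).
#' @param include_x whether the last chromosome is treated as X.
#' @param seed integer seed (used only for `spacing = "random"`).
#' @return data frame of class `genetic_map` with columns `marker`, `chr`,
#'   `bp`, `cM`, `is_x`; positions strictly increasing within chromosome.
#' @export
make_genetic_map <- function(n_markers, chr_lengths = NULL,
                             spacing = c("uniform", "random"),
                             cm_per_mb = 0.5, include_x = TRUE,
                             seed = 1L) {
  spacing <- match.arg(spacing)
  if (is.null(chr_lengths)) {
    n_chr <- 21L
    chr_lengths <- stats::setNames(rep(2.75e9 / n_chr, n_chr),
                                   c(paste0("chr", 1:20), "chrX"))
  }
  if (any(chr_lengths <= 0)) stop("zero-length chromosome")
  if (is.null(names(chr_lengths)))
    names(chr_lengths) <- paste0("chr", seq_along(chr_lengths))
  n_chr <- length(chr_lengths)
  if (n_markers < 2L * n_chr)
    stop("need at least 2 markers per chromosome")
  ## largest-remainder allocation so counts sum exactly to n_markers
  frac <- n_markers * chr_lengths / sum(chr_lengths)
  per_chr <- pmax(2L, floor(frac))
  short <- n_markers - sum(per_chr)
  if (short > 0) {
    extra <- order(frac - floor(frac), decreasing = TRUE)
    per_chr[extra[seq_len(short)]] <- per_chr[extra[seq_len(short)]] + 1L
  } else if (short < 0) {
    big <- order(per_chr, decreasing = TRUE)
    for (k in seq_len(-short)) {
      ci <- big[(k - 1L) %% n_chr + 1L]
      per_chr[ci] <- max(2L, per_chr[ci] - 1L)
    }
  }
  set.seed(seed)
  rows <- lapply(seq_len(n_chr), function(ci) {
    m <- per_chr[ci]
    L <- chr_lengths[ci]
    bp <- if (spacing == "uniform") {
      round(seq(0, L, length.out = m))
    } else {
      sort(round(stats::runif(m, 1, L)))
    }
    while (anyDuplicated(bp)) bp <- sort(bp + cumsum(duplicated(bp)))
    data.frame(chr = names(chr_lengths)[ci], bp = bp,
               cM = bp / 1e6 * cm_per_mb, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map <- data.frame(marker = sprintf("m%05d", seq_len(nrow(map))), map,
                    stringsAsFactors = FALSE)
  map$is_x <- include_x & map$chr == names(chr_lengths)[n_chr]
  attr(map, "chr_lengths") <- chr_lengths
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Simulate founder haplotypes as mosaics of inbred ancestral strains
#'
#' Emulates a heterogeneous-stock founder population: each of K ancestral
#' inbred strains carries a fixed haplotype over the marker panel, and
#' every founder haplotype is a mosaic of strain segments, with ancestry
#' switch points falling as a Poisson process along the genetic map. The
#' default switch rate of 0.3 per cM is an emulation knob yielding
#' sub-cM-to-multi-Mb blocks, in line with a stock mixed for a few dozen
#' generations before the colony was founded; it is not a measured value.
#'
#' @param map a [make_genetic_map()] map.
#' @param n_founders number of founder animals (half male, half female by
#'   default ordering M, F alternating).
#' @param K number of ancestral strains (default 8).
#' @param switch_rate expected ancestry switches per cM per haplotype.
#' @param strain_allele_freq probability that a strain carries the
#'   reference allele at a marker (strain haplotypes are drawn i.i.d.
#'   Bernoulli per marker).
#' @param strain_alleles optional explicit K x n_markers 0/1 matrix of
#'   strain haplotypes (overrides `strain_allele_freq`).
#' @param seed integer seed.
#' @return list of class `founder_pool`: `map`, `strain_alleles` (K x M
#'   0/1 matrix), `hap1`/`hap2` (n_founders x M 0/1 matrices), `sex`
#'   (alternating M/F), and `expected_het` (closed-form expected founder
#'   heterozygosity, `mean_m 2 p_m (1 - p_m)` with `p_m` the strain-pool
#'   frequency at marker m).
#' @export
simulate_founders <- function(map, n_founders, K = 8L, switch_rate = 0.3,
                              strain_allele_freq = 0.5,
                              strain_alleles = NULL, seed = 1L) {
  stopifnot(K >= 1L, n_founders >= 1L)
  set.seed(seed)
  M <- nrow(map)
  if (is.null(strain_alleles)) {
    strain_alleles <- matrix(stats::rbinom(K * M, 1L, strain_allele_freq),
                             nrow = K)
  } else {
    stopifnot(nrow(strain_alleles) == K, ncol(strain_alleles) == M)
  }
  mosaic <- function() {
    strain_at <- integer(M)
    for (chr in unique(map$chr)) {
      idx <- which(map$chr == chr)
      cm <- map$cM[idx]
      span <- max(cm) - min(cm)
      n_switch <- stats::rpois(1L, switch_rate * span)
      breaks <- sort(stats::runif(n_switch, min(cm), max(cm)))
      seg <- findInterval(cm, breaks) + 1L
      strains <- sample.int(K, n_switch + 1L, replace = TRUE)
      strain_at[idx] <- strains[seg]
    }
    strain_at
  }
  hap1 <- matrix(0L, n_founders, M)
  hap2 <- matrix(0L, n_founders, M)
  cols <- seq_len(M)
  for (i in seq_len(n_founders)) {
    hap1[i, ] <- strain_alleles[cbind(mosaic(), cols)]
    hap2[i, ] <- strain_alleles[cbind(mosaic(), cols)]
  }
  p <- colMeans(strain_alleles)
  structure(list(map = map, strain_alleles = strain_alleles,
                 hap1 = hap1, hap2 = hap2,
                 sex = rep_len(c("M", "F"), n_founders),
                 expected_het = mean(2 * p * (1 - p))),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf(
    "Founder pool: %d founders, %d markers, %d ancestral strains\n",
    nrow(x$hap1), ncol(x$hap1), nrow(x$strain_alleles)))
  cat(sprintf("Expected founder heterozygosity: %.4f\n", x$expected_het))
  invisible(x)
}

## one recombinant gamete from parent haplotypes h1, h2 (vectors) under
## the Haldane model: crossovers Poisson in map distance, no interference
recombine_gamete <- function(h1, h2, map_chr_index, map_cM) {
  out <- integer(length(h1))
  for (ci in seq_along(map_chr_index)) {
    idx <- map_chr_index[[ci]]
    cm <- map_cM[idx]
    span <- max(cm) - min(cm)
    n_x <- stats::rpois(1L, span / 100)
    phase <- rep(stats::rbinom(1L, 1L, 0.5), length(idx))
    if (n_x > 0L) {
      breaks <- sort(stats::runif(n_x, min(cm), max(cm)))
      phase <- (phase + findInterval(cm, breaks)) %% 2L
    }
    out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
  }
  out
}

#' Drop founder genotypes through a pedigree
#'
#' Mendelian gene-drop simulation: founder animals receive the pool's
#' haplotypes (in pedigree founder order); every other animal receives one
#' recombinant gamete from each parent, with crossover counts Poisson in
#' genetic map distance (Haldane model, no interference). On the X
#' chromosome males are hemizygous: a male carries his dam's gamete in
#' both haplotype slots (so his coded genotype is homozygous), and
#' transmits that single X to daughters; sires do not contribute an X to
#' sons.
#'
#' @param ped a [pedigree()] whose founder count matches the pool size.
#' @param founders a [simulate_founders()] pool.
#' @param seed integer seed.
#' @param missing_rate fraction of genotype calls set missing at random
#'   (default 0; available to exercise QC code).
#' @return object of class `genotype_matrix`: list with `geno` (animals x
#'   markers 0/1/2 integer matrix, NA = missing, rownames = animal ids),
#'   `hap1`, `hap2`, `map`, `ids`.
#' @export
drop_genotypes <- function(ped, founders, seed = 1L, missing_rate = 0) {
  map <- founders$map
  M <- nrow(map)
  fo <- which(is_founder(ped))
  if (length(fo) != nrow(founders$hap1))
    stop("pedigree has ", length(fo), " founders but pool has ",
         nrow(founders$hap1))
  set.seed(seed)
  n <- nrow(ped)
  chr_index <- split(seq_len(M), map$chr)[unique(map$chr)]
  auto_index <- chr_index[!vapply(chr_index, function(i) any(map$is_x[i]),
                                  logical(1))]
  x_idx <- which(map$is_x)
  H1 <- matrix(0L, n, M); H2 <- matrix(0L, n, M)
  H1[fo, ] <- founders$hap1
  H2[fo, ] <- founders$hap2
  ## founder male X: hemizygous, dam-derived slot duplicated
  if (length(x_idx)) {
    fm <- fo[ped$sex[fo] == "M"]
    H2[fm, x_idx] <- H1[fm, x_idx]
  }
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ord <- topological_order(ped)
  for (i in ord) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) next
    if (is.na(s) || is.na(d))
      stop("gene drop requires both parents known or both unknown (", ped$id[i], ")")
    pat <- recombine_gamete(H1[s, ], H2[s, ], auto_index, map$cM)
    mat <- recombine_gamete(H1[d, ], H2[d, ], auto_index, map$cM)
    if (length(x_idx)) {
      mat[x_idx] <- recombine_gamete(H1[d, ], H2[d, ], list(x_idx),
                                     map$cM)[x_idx]
      if (ped$sex[i] == "M") {
        pat[x_idx] <- mat[x_idx]       # hemizygous male X
      } else {
        pat[x_idx] <- H1[s, x_idx]     # sire's single X to daughters
      }
    }
    H1[i, ] <- pat
    H2[i, ] <- mat
  }
  geno <- H1 + H2
  if (missing_rate > 0) {
    drop <- stats::runif(length(geno)) < missing_rate
    geno[drop] <- NA_integer_
  }
  rownames(geno) <- ped$id
  colnames(geno) <- map$marker
  structure(list(geno = geno, hap1 = H1, hap2 = H2, map = map,
                 ids = ped$id),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d animals x %d markers (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param animals animal ids or row indices (default all).
#' @param markers marker names or column indices (default all).
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, animals = NULL, markers = NULL) {
  ai <- if (is.null(animals)) seq_len(nrow(x$geno)) else animals
  mi <- if (is.null(markers)) seq_len(ncol(x$geno)) else markers
  if (is.character(ai)) ai <- match(ai, rownames(x$geno))
  if (is.character(mi)) mi <- match(mi, colnames(x$geno))
  structure(list(geno = x$geno[ai, mi, drop = FALSE],
                 hap1 = x$hap1[ai, mi, drop = FALSE],
                 hap2 = x$hap2[ai, mi, drop = FALSE],
                 map = x$map[mi, , drop = FALSE],
                 ids = x$ids[ai]),
            class = "genotype_matrix")
}

#' Write genotypes in PLINK-style .ped/.map text format
#'
#' Column contract: the `.map` file has chromosome, marker id, cM, bp; the
#' `.ped` file has family (line or `0`), animal, sire, dam, sex (1=M,
#' 2=F), a phenotype placeholder `0`, then two allele columns per marker
#' coded `A`/`B` (`0` for missing). Bit-exact compatibility with binary
#' tools is not a goal; the format is for interchange and inspection.
#'
#' @param G a `genotype_matrix`.
#' @param ped the matching [pedigree()].
#' @param prefix output path prefix (writes `<prefix>.ped`,
#'   `<prefix>.map`).
#' @export
write_plink <- function(G, ped, prefix) {
  map_out <- data.frame(chr = sub("^chr", "", G$map$chr),
                        marker = G$map$marker,
                        cM = G$map$cM, bp = G$map$bp)
  utils::write.table(map_out, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  a1 <- ifelse(is.na(G$geno), "0", ifelse(G$hap1 == 1L, "A", "B"))
  a2 <- ifelse(is.na(G$geno), "0", ifelse(G$hap2 == 1L, "A", "B"))
  inter <- matrix("", nrow(a1), 2L * ncol(a1))
  inter[, seq(1L, 2L * ncol(a1), by = 2L)] <- a1
  inter[, seq(2L, 2L * ncol(a1), by = 2L)] <- a2
  lead <- cbind(ifelse(is.na(ped$line), "0", ped$line), ped$id,
                ifelse(is.na(ped$sire), "0", ped$sire),
                ifelse(is.na(ped$dam), "0", ped$dam),
                ifelse(ped$sex == "M", "1", "2"), "0")
  utils::write.table(cbind(lead, inter), paste0(prefix, ".ped"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
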