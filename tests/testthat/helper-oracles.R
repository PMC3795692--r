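## Independent oracles and fixture builders used across the suite.
## These deliberately avoid the package's own computational routines.

## Recursive-kinship oracle for inbreeding coefficients: F_i is the
## kinship of the parents, with kinship defined by the classical
## recursion (memoized). Independent of the tabular A-matrix route.
oracle_inbreeding <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  pos <- order(topological_order(ped)) # pos[i] = rank of row i
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      ## recurse on the later-ranked animal
      if (pos[i] < pos[j]) { tmp <- i; i <- j; j <- tmp }
      0.5 * (phi(si[i], j) + phi(di[i], j))
    }
    memo[[key]] <- val
    val
  }
  vapply(seq_len(nrow(ped)), function(i) {
    if (is.na(si[i]) || is.na(di[i])) 0 else phi(si[i], di[i])
  }, numeric(1))
}

## Monte-Carlo allele-drop oracle for pairwise kinship: drops unique
## founder allele labels through the pedigree n_rep times; kinship(i,j)
## is the probability that one random allele from each is identical by
## descent. Written independently of the package's gene-drop machinery.
oracle_kinship_drop <- function(ped, n_rep = 4000, seed = 99) {
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ord <- topological_order(ped)
  acc <- matrix(0, n, n)
  for (r in seq_len(n_rep)) {
    a1 <- integer(n); a2 <- integer(n)
    nxt <- 1L
    for (i in ord) {
      if (is.na(si[i])) {
        a1[i] <- nxt; a2[i] <- nxt + 1L; nxt <- nxt + 2L
      } else {
        a1[i] <- if (stats::runif(1) < 0.5) a1[si[i]] else a2[si[i]]
        a2[i] <- if (stats::runif(1) < 0.5) a1[di[i]] else a2[di[i]]
      }
    }
    ## P(IBD) of one random allele from each of i and j
    for (i in seq_len(n)) {
      m <- (outer(a1, a1[i], "==") + outer(a1, a2[i], "==") +
            outer(a2, a1[i], "==") + outer(a2, a2[i], "==")) / 4
      acc[, i] <- acc[, i] + m
    }
  }
  acc / n_rep
}

## trio fixture: founder pair + child
toy_trio <- function() {
  pedigree(data.frame(
    id = c("s1", "d1", "o1"), sire = c(NA, NA, "s1"),
    dam = c(NA, NA, "d1"), sex = c("M", "F", "M"),
    generation = c(0L, 0L, 1L), stringsAsFactors = FALSE))
}

## full-sib pair + their (inbred) offspring
toy_fullsib <- function() {
  pedigree(data.frame(
    id = c("s", "d", "a", "b", "x"),
    sire = c(NA, NA, "s", "s", "a"),
    dam = c(NA, NA, "d", "d", "b"),
    sex = c("M", "F", "M", "F", "M"),
    generation = c(0L, 0L, 1L, 1L, 2L), stringsAsFactors = FALSE))
}

## offspring of first cousins, all other ancestors unrelated
toy_cousins <- function() {
  pedigree(data.frame(
    id = c("g1", "g2", "u1", "u2", "p1", "p2", "c1", "c2", "o"),
    sire = c(NA, NA, NA, NA, "g1", "g1", "p1", "p2", "c1"),
    dam = c(NA, NA, NA, NA, "g2", "g2", "u1", "u2", "c2"),
    sex = c("M", "F", "F", "F", "M", "M", "M", "F", "F"),
    generation = c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 3L),
    stringsAsFactors = FALSE))
}

## small random pedigree generator (structured, deterministic per seed)
random_test_pedigree <- function(n_pairs, n_gens, seed) {
  build_random_mating_pedigree(n_pairs, n_gens, seed = seed)
}

## small autosomal map for genotype tests
small_map <- function(n_markers = 120, n_chr = 3, chr_len = 1e8) {
  make_genetic_map(n_markers,
                   chr_lengths = stats::setNames(rep(chr_len, n_chr),
                                                 paste0("chr", seq_len(n_chr))),
                   include_x = FALSE)
}

## build a genotype_matrix object directly from a plain matrix
as_genotypes <- function(geno, map) {
  rn <- rownames(geno)
  if (is.null(rn)) rn <- paste0("a", seq_len(nrow(geno)))
  rownames(geno) <- rn
  colnames(geno) <- map$marker
  structure(list(geno = geno, hap1 = NULL, hap2 = NULL, map = map,
                 ids = rn), class = "genotype_matrix")
}
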