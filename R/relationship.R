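#' Additive (numerator) relationship matrix by the tabular method
#'
#' Computes Wright's numerator relationship matrix A for every animal in
#' the pedigree by the standard tabular recursion: processing animals in
#' topological order, `A(i,j) = (A(j,s_i) + A(j,d_i))/2` for previously
#' processed `j`, and `A(i,i) = 1 + A(s_i,d_i)/2`. An unknown parent
#' contributes zero relationship; founders are treated as unrelated and
#' non-inbred (diagonal exactly 1).
#'
#' Memory is quadratic in pedigree size; for inbreeding coefficients alone
#' use [inbreeding_coefficients()], which restricts the tabular pass to the
#' ancestor-closed set of animals that appear as parents.
#'
#' @param ped a [pedigree()].
#' @return symmetric matrix with dimnames `ped$id`; diagonal `1 + F`.
#' @export
additive_relationship <- function(ped) {
  n <- nrow(ped)
  ord <- topological_order(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- si[i]; d <- di[i]
    if (k > 1L) {
      prev <- ord[seq_len(k - 1L)]
      as_ <- if (!is.na(s)) A[prev, s] else 0
      ad_ <- if (!is.na(d)) A[prev, d] else 0
      v <- (as_ + ad_) / 2
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  A
}

#' Pedigree inbreeding coefficients
#'
#' `F_i` is the probability that the two alleles of animal `i` at a locus
#' are identical by descent relative to the founder generation, i.e. the
#' diagonal of the additive relationship matrix minus one. Founders are
#' treated as unrelated and non-inbred (`F = 0` exactly).
#'
#' The tabular pass is run only over the ancestor-closed set of animals
#' that appear as a sire or dam (for colony pedigrees this is a small
#' fraction of all records); for every terminal animal
#' `F = A(sire, dam)/2`.
#'
#' @param ped a [pedigree()].
#' @return named numeric vector of inbreeding coefficients in `[0, 1]`,
#'   in pedigree row order.
#' @export
inbreeding_coefficients <- function(ped) {
  f <- stats::setNames(numeric(nrow(ped)), ped$id)
  parents <- unique(c(stats::na.omit(ped$sire), stats::na.omit(ped$dam)))
  if (length(parents)) {
    sub <- ped[ped$id %in% parents, , drop = FALSE]
    A <- additive_relationship(sub)
    f[sub$id] <- diag(A) - 1
    terminal <- !(ped$id %in% parents)
    both <- terminal & !is.na(ped$sire) & !is.na(ped$dam)
    if (any(both))
      f[ped$id[both]] <- A[cbind(ped$sire[both], ped$dam[both])] / 2
  }
  f
}

## Mendelian-sampling variance scale d_i of the A = T D T' decomposition.
## Founders 1; one known parent p: 3/4 - F_p/4; both: 1/2 - (F_s + F_d)/4.
mendelian_d <- function(ped, f = inbreeding_coefficients(ped)) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  d <- rep(1, nrow(ped))
  one <- xor(is.na(si), is.na(di))
  p <- ifelse(is.na(si), di, si)
  d[one] <- 0.75 - 0.25 * f[p[one]]
  both <- !is.na(si) & !is.na(di)
  d[both] <- 0.5 - 0.25 * (f[si[both]] + f[di[both]])
  d
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds `A^{-1}` directly from the pedigree by Henderson's rules with
#' Quaas's adjustment for inbred parents, without ever forming A. The
#' result is sparse (non-zeros only between mates, parents and offspring),
#' which is what makes animal-model REML tractable on colony-sized
#' pedigrees.
#'
#' @param ped a [pedigree()].
#' @param f optional precomputed inbreeding coefficients.
#' @return list with `Ainv` (a `dgCMatrix` with dimnames `ped$id`) and
#'   `logdet_A` (`log|A| = sum(log d_i)` from the `A = T D T'`
#'   factorization).
#' @export
ainverse <- function(ped, f = inbreeding_coefficients(ped)) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  alpha <- 1 / mendelian_d(ped, f)
  ii <- seq_len(n)
  I <- ii; J <- ii; X <- alpha
  push <- function(i, j, x) {
    I <<- c(I, i); J <<- c(J, j); X <<- c(X, x)
  }
  for (pcol in list(si, di)) {
    has <- !is.na(pcol)
    push(ii[has], pcol[has], -alpha[has] / 2)
    push(pcol[has], ii[has], -alpha[has] / 2)
    push(pcol[has], pcol[has], alpha[has] / 4)
  }
  both <- !is.na(si) & !is.na(di)
  push(si[both], di[both], alpha[both] / 4)
  push(di[both], si[both], alpha[both] / 4)
  Ainv <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  list(Ainv = Ainv, logdet_A = sum(log(mendelian_d(ped, f))))
}
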