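#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes each animal's inbreeding coefficient F — the probability that the
#' two alleles at a locus are identical by descent given the recorded
#' ancestry — with the Meuwissen & Luo algorithm, which accumulates the
#' within-animal diagonal of the additive relationship matrix A over the
#' animal's ancestor list without ever forming A. Founders and animals with
#' an unknown parent have F = 0; unknown parents contribute no relationship.
#'
#' @param ped a [Pedigree-class] object.
#' @return Named numeric vector of F, one entry per animal.
#' @examples
#' ped <- simPedigree(n_founders = 10, n_generations = 3, seed = 1)$pedigree
#' summary(inbreedingCoef(ped))
#' @export
inbreedingCoef <- function(ped) {
  px <- .pedIndex(ped)
  n <- px$n
  ord <- px$topo
  # recode so that parents precede offspring
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]  # in recoded ids, NA for unknown
  di <- pos[px$di][ord]
  F <- numeric(n)
  D <- numeric(n)  # Mendelian sampling variance, filled as we go
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    # unknown-parent F contributes -1 to D (yields 1 / 0.75 / 0.5 pattern)
    fs <- if (is.na(s)) -1 else F[s]
    fd <- if (is.na(d)) -1 else F[d]
    D[i] <- 0.5 - 0.25 * (fs + fd)
    if (is.na(s) || is.na(d)) {
      F[i] <- 0
      next
    }
    # trace the ancestor list of i, accumulating a_ii = sum L_j^2 D_j
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      aii <- aii + lj * lj * D[j]
      sj <- si[j]; dj <- di[j]
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * lj
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * lj
      L[j] <- 0
    }
    F[i] <- aii - 1
  }
  out <- numeric(n)
  out[ord] <- F
  names(out) <- ped@id
  out
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' Builds the full Wright numerator relationship matrix A with the tabular
#' recursion a_ij = (a_i,sire(j) + a_i,dam(j)) / 2 and
#' a_jj = 1 + a_sire(j),dam(j) / 2. Quadratic in memory; intended for
#' moderate pedigrees (cross-checks, AR oracles, mate-selection tables).
#'
#' @param ped a [Pedigree-class] object.
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
additiveRelationshipMatrix <- function(ped) {
  px <- .pedIndex(ped)
  n <- px$n
  ord <- px$topo
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      ii <- seq_len(j - 1L)
      as_ <- if (is.na(s)) 0 else A[ii, s]
      ad_ <- if (is.na(d)) 0 else A[ii, d]
      A[ii, j] <- A[j, ii] <- (as_ + ad_) / 2
    }
    A[j, j] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  out <- A[pos, pos, drop = FALSE]
  dimnames(out) <- list(ped@id, ped@id)
  out
}

#' Relatedness coefficient AR
#'
#' The relatedness coefficient of animal i is the probability that an allele
#' drawn at random from the whole pedigree belongs to i: the mean additive
#' relationship of i to every pedigree member divided by two,
#' AR_i = (1/(2n)) * sum_j a_ij. Computed in linear time through the
#' A = T D T' decomposition (two triangular sweeps over the pedigree) rather
#' than by forming A.
#'
#' @param ped a [Pedigree-class] object.
#' @param F optional precomputed [inbreedingCoef()] vector (recomputed when
#'   missing).
#' @return Named numeric vector of AR values in `[0, 1]`.
#' @export
relatednessAR <- function(ped, F = NULL) {
  if (is.null(F)) F <- inbreedingCoef(ped)
  px <- .pedIndex(ped)
  n <- px$n
  ord <- px$topo
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  Fo <- unname(F)[ord]
  fs <- ifelse(is.na(si), -1, Fo[si])
  fd <- ifelse(is.na(di), -1, Fo[di])
  D <- 0.5 - 0.25 * (fs + fd)
  # row sums of A: A 1 = T D (T' 1); T = (I - P/2)^{-1} with P the
  # parent-indicator matrix
  w <- rep(1, n)                       # w = T' 1, reverse sweep
  for (i in n:1) {
    s <- si[i]; d <- di[i]
    if (!is.na(s)) w[s] <- w[s] + 0.5 * w[i]
    if (!is.na(d)) w[d] <- w[d] + 0.5 * w[i]
  }
  z <- D * w                           # z = T (D w), forward sweep
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (!is.na(s)) z[i] <- z[i] + 0.5 * z[s]
    if (!is.na(d)) z[i] <- z[i] + 0.5 * z[d]
  }
  out <- numeric(n)
  out[ord] <- z / (2 * n)
  names(out) <- ped@id
  out
}
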