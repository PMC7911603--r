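#' Effective number of founders
#'
#' Expected proportional genetic contribution q_k of every founder to a
#' reference population, obtained by passing each reference animal's genome
#' weight (1/n each) half to each parent line up the pedigree. Founders are
#' animals with both parents unknown; each unknown single-parent slot
#' becomes a distinct phantom founder (named `"phantom:<slot>:<animal>"`).
#' The effective number of founders is fe = 1 / sum(q_k^2); contributions
#' sum to one.
#'
#' @param ped a [Pedigree-class] object.
#' @param ref character vector of reference-population animal ids (see
#'   [referencePopulation()]); default: every animal in the pedigree.
#' @return List with `q` (named contributions, founders then phantoms) and
#'   `fe`.
#' @export
effectiveFounders <- function(ped, ref = animalIds(ped)) {
  stopifnot(length(ref) > 0)
  px <- .pedIndex(ped)
  n <- px$n
  ord <- px$topo
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  refi <- pos[match(ref, ped@id)]
  if (anyNA(refi)) stop("reference animal not in pedigree")
  w <- numeric(n)
  w[refi] <- 1 / length(refi)
  phS <- numeric(n)  # weight landing on the phantom sire of animal i
  phD <- numeric(n)
  for (i in n:1) {
    wi <- w[i]
    if (wi == 0) next
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) next       # founder keeps its weight
    if (is.na(s)) phS[i] <- phS[i] + wi / 2 else w[s] <- w[s] + wi / 2
    if (is.na(d)) phD[i] <- phD[i] + wi / 2 else w[d] <- w[d] + wi / 2
    w[i] <- 0
  }
  idso <- ped@id[ord]
  isFounder <- is.na(si) & is.na(di)
  iS <- which(phS > 0)
  iD <- which(phD > 0)
  q <- c(setNames(w[isFounder], idso[isFounder]),
         setNames(phS[iS], sprintf("phantom:sire:%s", idso[iS])),
         setNames(phD[iD], sprintf("phantom:dam:%s", idso[iD])))
  q <- q[q > 0]
  list(q = q, fe = 1 / sum(q ^ 2))
}

# one upward sweep of genome weights with the parent links of `si`/`di`
# (already cut for selected ancestors); returns the weight arriving at (and
# possibly flowing through) every animal
.geneFlowArrival <- function(n, si, di, init) {
  w <- init
  arrival <- init
  for (i in n:1) {
    wi <- w[i]
    if (wi == 0) next
    s <- si[i]; d <- di[i]
    if (!is.na(s)) { w[s] <- w[s] + wi / 2; arrival[s] <- arrival[s] + wi / 2 }
    if (!is.na(d)) { w[d] <- w[d] + wi / 2; arrival[d] <- arrival[d] + wi / 2 }
  }
  arrival
}

#' Effective number of ancestors (marginal contributions)
#'
#' Iterative marginal-contribution algorithm: at each round the candidate
#' with the largest expected genetic contribution to the reference
#' population *not yet explained* by previously selected ancestors is
#' chosen, and its parent links are cut so that genome weight flowing
#' through it is absorbed and never counted again. Contributions are genome
#' weights arriving at an animal when each reference animal contributes
#' 1/n and passes weight half per parent line; weight on an unknown-parent
#' slot stays with the animal carrying it. A candidate's arriving weight is
#' further discounted by the expected fraction of its own genome already
#' explained by the selected ancestors (a descendant of a chosen ancestor
#' only adds the unexplained side of its genome). Candidates are animals
#' with progeny, plus reference animals with an unknown parent slot (whose
#' genome nobody else can explain). The effective number of ancestors is
#' fa = 1 / sum(p_k^2) over the marginal contributions p_k, and fa <= fe.
#'
#' @param ped a [Pedigree-class] object.
#' @param ref reference-population animal ids; default all animals.
#' @param tol smallest marginal contribution still selected.
#' @return List with `p` (named marginal contributions in selection order),
#'   `fa`, `n_ancestors_50pct` (smallest number of top ancestors jointly
#'   explaining half the genetic pool) and `explained` (cumulative sums).
#' @export
effectiveAncestors <- function(ped, ref = animalIds(ped), tol = 1e-12) {
  stopifnot(length(ref) > 0)
  px <- .pedIndex(ped)
  n <- px$n
  ord <- px$topo
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  refi <- pos[match(ref, ped@id)]
  if (anyNA(refi)) stop("reference animal not in pedigree")
  init <- numeric(n)
  init[refi] <- 1 / length(refi)
  idso <- ped@id[ord]
  # candidate ancestors: animals with progeny, plus reference animals with
  # an unknown parent slot (their unexplainable genome half makes them
  # their own gene origin, as in the founder accounting)
  isParent <- tabulate(c(si[!is.na(si)], di[!is.na(di)]), nbins = n) > 0L
  candidate <- isParent | (init > 0 & (is.na(si) | is.na(di)))
  selected <- logical(n)
  p <- numeric(0)
  repeat {
    arrival <- .geneFlowArrival(n, si, di, init)
    # fraction of each animal's own genome already explained by the
    # selected ancestors (downward pass; forced to 1 on selected animals)
    x <- numeric(n)
    for (i in seq_len(n)) {
      if (selected[i]) { x[i] <- 1; next }
      s <- si[i]; d <- di[i]
      x[i] <- ((if (is.na(s)) 0 else x[s]) + (if (is.na(d)) 0 else x[d])) / 2
    }
    marginal <- arrival * (1 - x)
    marginal[selected | !candidate] <- -Inf
    morig <- numeric(n)
    morig[ord] <- marginal             # ties broken by record order
    k <- pos[which.max(morig)]
    if (marginal[k] <= tol) break
    p <- c(p, setNames(marginal[k], idso[k]))
    selected[k] <- TRUE
    si[k] <- NA_integer_   # cut: genes through k are now explained by k
    di[k] <- NA_integer_
  }
  cum <- cumsum(p)
  list(p = p, fa = 1 / sum(p ^ 2),
       n_ancestors_50pct = if (any(cum >= 0.5)) which(cum >= 0.5)[1L]
                           else NA_integer_,
       explained = cum)
}
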