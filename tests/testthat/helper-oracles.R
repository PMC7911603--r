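# Independent oracles used to cross-check the package implementations.
# Each one recomputes a quantity by a different mechanism (explicit
# recursion, enumeration, brute-force window scans, Monte Carlo) so that a
# shared bug with the implementation under test is unlikely.

# random valid pedigree: each animal takes each parent with prob. p_parent
# from the animals already generated
randomPedigree <- function(n, seed, p_parent = 0.8) {
  set.seed(seed)
  id <- sprintf("A%04d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) && runif(1) < p_parent)
      sire[i] <- id[sample(rep(males, 2L), 1L)]
    if (length(females) && runif(1) < p_parent)
      dam[i] <- id[sample(rep(females, 2L), 1L)]
  }
  Pedigree(id, sire, dam, birth_year = 2000L + seq_len(n) %/% 10L,
           sex = sex)
}

# recursive-kinship oracle: phi(i, j) by the classic coancestry recursion,
# memoised; A = 2 * phi, F_i = phi(sire, dam)
oracleKinship <- function(ped) {
  tb <- pedigreeTable(ped)
  n <- nrow(tb)
  si <- match(tb$sire, tb$id)
  di <- match(tb$dam, tb$id)
  depth <- integer(n)  # to know which of i, j is "younger": use topo rank
  topo <- ped@topo
  rank <- integer(n); rank[topo] <- seq_len(n)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 + 0.5 * phi(si[i], di[i])
    } else {
      y <- if (rank[i] > rank[j]) i else j   # younger animal
      o <- if (y == i) j else i
      0.5 * (phi(si[y], o) + phi(di[y], o))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(tb$id, tb$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# explicit path-descent oracle for equivalent complete generations
oracleEqG <- function(tb, i, depth = 1L) {
  tot <- 0
  for (p in c(tb$sire[i], tb$dam[i]))
    if (!is.na(p)) {
      j <- match(p, tb$id)
      tot <- tot + 0.5 ^ depth + oracleEqG(tb, j, depth + 1L)
    }
  tot
}

# explicit slot-count oracle for pedigree completeness: number of known
# ancestors (path-counted) of animal i at each depth 1..maxd
oracleAncestorSlots <- function(tb, i, maxd) {
  counts <- numeric(maxd)
  recurse <- function(i, depth) {
    if (depth > maxd) return()
    for (p in c(tb$sire[i], tb$dam[i]))
      if (!is.na(p)) {
        counts[depth] <<- counts[depth] + 1
        recurse(match(p, tb$id), depth + 1L)
      }
  }
  recurse(i, 1L)
  counts
}

# brute-force ROH oracle: enumerate every window of consecutive markers
# that is entirely homozygous, has no gap above max_gap, and satisfies the
# count/span thresholds; report the maximal ones
oracleRohWindows <- function(g, pos, cfg) {
  L <- length(g)
  hom <- !is.na(g) & g != 1L
  okgap <- c(diff(pos) <= cfg$max_gap_bp, TRUE)
  wins <- list()
  for (i in seq_len(L)) {
    if (!hom[i]) next
    j <- i
    while (j < L && hom[j + 1L] && okgap[j]) j <- j + 1L
    # [i, j] is the widest homozygous gap-free window starting at i
    if (j - i + 1L >= cfg$min_snp && pos[j] - pos[i] >= cfg$min_len_bp)
      wins[[length(wins) + 1L]] <- c(i, j)
  }
  if (!length(wins)) return(matrix(integer(0), 0, 2))
  w <- do.call(rbind, wins)
  # maximality: drop windows contained in another qualifying window
  keep <- vapply(seq_len(nrow(w)), function(k)
    !any(w[, 1L] <= w[k, 1L] & w[, 2L] >= w[k, 2L] &
           (w[, 1L] != w[k, 1L] | w[, 2L] != w[k, 2L])), logical(1))
  w[keep, , drop = FALSE]
}

# independent re-implementation of the ROHet greedy scan with naive
# recounting of interior states at every step
oracleRohetRuns <- function(g, pos, cfg) {
  het <- which(!is.na(g) & g == 1L)
  runs <- list()
  if (!length(het)) return(runs)
  st <- 1L
  k <- 1L
  while (k <= length(het)) {
    # extend the run starting at het[st] as far as possible
    e <- k
    while (e < length(het)) {
      span <- g[het[st]:het[e + 1L]]
      inner_hom <- sum(!is.na(span) & span != 1L)
      inner_mis <- sum(is.na(span))
      gaps <- diff(pos[seq(het[st], het[e + 1L])])
      if (any(gaps > cfg$max_gap_bp) ||
          inner_hom > cfg$max_hom_inside ||
          inner_mis > cfg$max_missing_inside) break
      e <- e + 1L
    }
    s <- het[st]; en <- het[e]
    if (en - s + 1L >= cfg$min_snp && pos[en] - pos[s] >= cfg$min_len_bp)
      runs[[length(runs) + 1L]] <- c(s, en)
    st <- e + 1L
    k <- e + 1L
  }
  runs
}

# exact-enumeration oracle for the HWE test: probability of each possible
# heterozygote count given the allele counts, via choose()
oracleHweEnum <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na_ <- 2 * naa + nab
  rare <- min(na_, 2 * n - na_)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - aa - h
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nab, hets)] + 1e-12])
}

# single-locus Monte-Carlo gene dropping for founder contributions:
# fraction of reference-population alleles originating from each founder
oracleFounderContrib <- function(ped, ref, n_rep, seed) {
  set.seed(seed)
  px <- herddiv:::.pedIndex(ped)
  n <- px$n
  ord <- px$topo
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  # origin labels: founder alleles 2i-1, 2i; phantom labels negative
  O1 <- matrix(0L, n, n_rep)
  O2 <- matrix(0L, n, n_rep)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s)) {
      O1[i, ] <- if (is.na(d)) 2L * i - 1L else -(2L * i - 1L)
    } else {
      pick <- runif(n_rep) < 0.5
      O1[i, ] <- ifelse(pick, O1[s, ], O2[s, ])
    }
    if (is.na(d)) {
      O2[i, ] <- if (is.na(s)) 2L * i else -(2L * i)
    } else {
      pick <- runif(n_rep) < 0.5
      O2[i, ] <- ifelse(pick, O1[d, ], O2[d, ])
    }
  }
  refi <- pos[match(ref, animalIds(ped))]
  lab <- c(O1[refi, , drop = FALSE], O2[refi, , drop = FALSE])
  tab <- table(lab) / length(lab)
  idso <- animalIds(ped)[ord]
  nm <- vapply(as.integer(names(tab)), function(code) {
    i <- as.integer(ceiling(abs(code) / 2))
    slot <- if (abs(code) %% 2L == 1L) "sire" else "dam"
    if (code > 0) idso[i] else paste0("phantom:", slot, ":", idso[i])
  }, "")
  # merge a founder's two allele labels (they share the founder id)
  q <- tapply(as.numeric(tab), nm, sum)
  setNames(as.numeric(q), names(q))
}
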