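#' Equivalent complete generations
#'
#' EqG_i = sum over all known ancestors of (1/2)^n, with n the number of
#' generations between animal and ancestor; an ancestor reachable through
#' several paths contributes once per path. Equals 1 when both parents (and
#' nothing deeper) are known, 2 when parents and all four grandparents are
#' known. Computed by the recursion EqG_i = sum over known parents p of
#' (1 + EqG_p) / 2.
#'
#' @param ped a [Pedigree-class] object.
#' @return Named numeric vector of EqG values (founders have 0).
#' @export
equivalentGenerations <- function(ped) {
  px <- .pedIndex(ped)
  n <- px$n
  ord <- px$topo
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  eq <- numeric(n)
  for (i in seq_len(n)) {
    v <- 0
    if (!is.na(si[i])) v <- v + 0.5 * (1 + eq[si[i]])
    if (!is.na(di[i])) v <- v + 0.5 * (1 + eq[di[i]])
    eq[i] <- v
  }
  out <- numeric(n)
  out[ord] <- eq
  names(out) <- ped@id
  out
}

#' Pedigree completeness index by ancestral generation
#'
#' For each generation depth d = 1..`max_depth`, the proportion of the 2^d
#' ancestor slots at that depth that are filled by a known animal, averaged
#' over the population (or a subset): completeness 1.0 at depth 2 when all
#' four grandparents are known, 0.75 when three are known.
#'
#' @param ped a [Pedigree-class] object.
#' @param max_depth deepest generation evaluated (default 10).
#' @param subset optional character vector of animal ids to average over.
#' @return Named numeric vector of length `max_depth` of mean proportions.
#' @export
pedigreeCompleteness <- function(ped, max_depth = 10L, subset = NULL) {
  stopifnot(max_depth >= 1L)
  px <- .pedIndex(ped)
  n <- px$n
  ord <- px$topo
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  # K[i, d] = number of known ancestors of i at depth d (path-counted)
  K <- matrix(0, n, max_depth)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    K[i, 1L] <- (!is.na(s)) + (!is.na(d))
    if (max_depth >= 2L) {
      for (g in 2:max_depth) {
        v <- 0
        if (!is.na(s)) v <- v + K[s, g - 1L]
        if (!is.na(d)) v <- v + K[d, g - 1L]
        K[i, g] <- v
      }
    }
  }
  K <- K[pos, , drop = FALSE]
  rows <- if (is.null(subset)) seq_len(n) else match(subset, ped@id)
  stopifnot(!anyNA(rows))
  pci <- colMeans(K[rows, , drop = FALSE]) / (2 ^ seq_len(max_depth))
  names(pci) <- paste0("gen", seq_len(max_depth))
  pci
}

#' Generation intervals by selection path
#'
#' A record is a parent's age (in years) at the birth of an offspring that
#' was itself kept for reproduction (i.e. has progeny in the pedigree).
#' Records are assigned to the four selection paths by the parental slot and
#' the offspring's sex (sire-sire, sire-dam, dam-sire, dam-dam); offspring
#' of unknown sex are excluded and counted. The pooled interval is the
#' record-level mean, which equals the count-weighted mean of the path
#' means.
#'
#' @param ped a [Pedigree-class] object.
#' @param subset optional character vector of animal ids; when given, only
#'   records whose offspring is in the subset are counted (e.g. a reference
#'   population).
#' @return A `data.frame` with rows `sire-sire`, `sire-dam`, `dam-sire`,
#'   `dam-dam`, `pooled` and columns `n`, `mean_y`, `se`; the number of
#'   records dropped for unknown offspring sex is in
#'   `attr(, "excluded_unknown_sex")`.
#' @export
generationIntervals <- function(ped, subset = NULL) {
  tb <- pedigreeTable(ped)
  hasProgeny <- tb$id %in% c(tb$sire, tb$dam)
  keepOff <- hasProgeny & !is.na(tb$birth_year)
  if (!is.null(subset)) keepOff <- keepOff & tb$id %in% subset
  off <- tb[keepOff, , drop = FALSE]
  recs <- list()
  excluded <- 0L
  for (slot in c("sire", "dam")) {
    pid <- off[[slot]]
    ok <- !is.na(pid)
    pyear <- tb$birth_year[match(pid[ok], tb$id)]
    oyear <- off$birth_year[ok]
    osex <- off$sex[ok]
    good <- !is.na(pyear)
    age <- (oyear - pyear)[good]
    osex <- osex[good]
    excluded <- excluded + sum(is.na(osex))
    use <- which(!is.na(osex))
    role <- c(M = "sire", F = "dam")[osex[use]]
    recs[[slot]] <- data.frame(
      path = if (length(use)) paste0(slot, "-", role) else character(0),
      age = age[use], stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  paths <- c("sire-sire", "sire-dam", "dam-sire", "dam-dam")
  cell <- function(x) {
    if (!length(x)) return(c(n = 0, mean_y = NA, se = NA))
    c(n = length(x), mean_y = mean(x),
      se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA)
  }
  tab <- t(vapply(paths, function(p) cell(rec$age[rec$path == p]),
                  numeric(3)))
  pooled <- cell(rec$age)
  out <- as.data.frame(rbind(tab, pooled = pooled))
  out$n <- as.integer(out$n)
  attr(out, "excluded_unknown_sex") <- excluded
  out
}

#' Pool path-level generation intervals
#'
#' Count-weighted (record-level) pooling of per-path generation-interval
#' means, the same rule [generationIntervals()] applies to its own records.
#' Useful for pooling published path tables.
#'
#' @param means numeric vector of path means (years).
#' @param counts integer vector of record counts per path.
#' @return The pooled mean in years.
#' @examples
#' poolGenerationIntervals(c(6.21, 6.12, 7.09, 6.71), c(459, 557, 470, 544))
#' @export
poolGenerationIntervals <- function(means, counts) {
  stopifnot(length(means) == length(counts), all(counts >= 0))
  sum(means * counts) / sum(counts)
}

#' Reference population by birth-year window
#'
#' Animals born inside a birth-year window. When no window is given, the
#' window is the last `ceiling(GI)` years of the pedigree, with GI the
#' pooled generation interval — i.e. the animals born within the most recent
#' generation.
#'
#' @param ped a [Pedigree-class] object.
#' @param start,end first and last birth year of the window (inclusive);
#'   both `NULL` for the automatic last-generation window.
#' @return Character vector of member animal ids, with the window in
#'   `attr(, "window")`.
#' @export
referencePopulation <- function(ped, start = NULL, end = NULL) {
  yr <- ped@birthYear
  if (is.null(end)) end <- max(yr, na.rm = TRUE)
  if (is.null(start)) {
    gi <- generationIntervals(ped)["pooled", "mean_y"]
    if (is.na(gi)) stop("cannot derive a window: no generation-interval ",
                        "records; give start/end explicitly")
    start <- end - ceiling(gi) + 1L
  }
  ids <- ped@id[!is.na(yr) & yr >= start & yr <= end]
  if (!length(ids)) stop("empty reference population for window ",
                         start, "-", end)
  structure(ids, window = c(start = start, end = end))
}

#' Individual rate of inbreeding
#'
#' dF_i = 1 - (1 - F_i)^(1 / (EqG_i - 1)); animals with EqG <= 1 have an
#' undefined exponent and return `NA`.
#'
#' @param F inbreeding coefficients (fractions).
#' @param eqg equivalent complete generations ([equivalentGenerations()]).
#' @return Numeric vector of per-generation inbreeding rates.
#' @export
inbreedingRate <- function(F, eqg) {
  stopifnot(length(F) == length(eqg))
  ifelse(eqg > 1, 1 - (1 - F) ^ (1 / (eqg - 1)), NA_real_)
}

#' Realized effective population size from the pedigree
#'
#' Ne = 1 / (2 * mean(dF_i)) over animals with defined individual inbreeding
#' rates (EqG > 1). The standard error is obtained by the delta method from
#' the standard error of mean dF: SE(Ne) = SD(dF)/sqrt(N) / (2 * mean(dF)^2),
#' and the confidence interval is Ne +/- z * SE.
#'
#' @param F inbreeding coefficients, or a [Pedigree-class] object (then
#'   `eqg` is ignored and both inputs are computed internally).
#' @param eqg equivalent complete generations matching `F`.
#' @param level confidence level (default 0.95).
#' @return List with `ne`, `se`, `ci` (lower/upper), `mean_dF`, `n_used`,
#'   `n_excluded` and the `dF` vector.
#' @export
realizedNe <- function(F, eqg = NULL, level = 0.95) {
  if (is(F, "Pedigree")) {
    ped <- F
    F <- inbreedingCoef(ped)
    eqg <- equivalentGenerations(ped)
  }
  dF <- inbreedingRate(F, eqg)
  used <- !is.na(dF)
  x <- dF[used]
  m <- mean(x)
  if (m <= 0) {
    warning("mean inbreeding rate is zero; Ne is infinite")
    return(list(ne = Inf, se = NA, ci = c(lower = NA, upper = NA),
                mean_dF = m, n_used = sum(used),
                n_excluded = sum(!used), dF = dF))
  }
  ne <- 1 / (2 * m)
  se_m <- sd(x) / sqrt(length(x))
  se <- se_m / (2 * m ^ 2)
  list(ne = ne, se = se, ci = neConfidenceInterval(ne, se, level),
       mean_dF = m, n_used = sum(used), n_excluded = sum(!used), dF = dF)
}

#' Symmetric confidence interval for an effective population size
#'
#' @param ne point estimate.
#' @param se standard error.
#' @param level confidence level (default 0.95).
#' @return Named vector `c(lower, upper)` = `ne -/+ z * se`.
#' @examples
#' neConfidenceInterval(86.44, 14.6)
#' @export
neConfidenceInterval <- function(ne, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = ne - z * se, upper = ne + z * se)
}
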