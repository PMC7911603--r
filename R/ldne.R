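#' LD / effective-population-size configuration
#'
#' @param min_dist_bp,max_dist_bp distance window for marker pairs
#'   (defaults 100 kb and 35 Mb: short distances inform distant
#'   generations, long distances recent ones).
#' @param n_bins number of distance bins, equally spaced in log10 distance.
#' @param beta sample-size adjustment constant in
#'   `r2_adj = r2 - 1/(beta * n)`; 1 for unphased genotype data.
#' @param alpha mutation correction in the Ne formula (2 accounts for
#'   mutation).
#' @param mb_per_cm map scaling, Mb per cM (1 assumes 1 cM = 1 Mb).
#' @param mapping distance-to-recombination mapping: `"sved_feldman"`
#'   (c = d(1 - d/2)), `"haldane"` (c = (1 - exp(-2d))/2) or `"linear"`
#'   (c = d), with d in Morgans.
#' @return Named list of class `"LDConfig"`.
#' @export
ldConfig <- function(min_dist_bp = 1e5, max_dist_bp = 35e6, n_bins = 30L,
                     beta = 1, alpha = 2, mb_per_cm = 1,
                     mapping = c("sved_feldman", "haldane", "linear")) {
  stopifnot(min_dist_bp < max_dist_bp, n_bins >= 1, beta > 0,
            mb_per_cm > 0)
  structure(list(min_dist_bp = min_dist_bp, max_dist_bp = max_dist_bp,
                 n_bins = as.integer(n_bins), beta = beta, alpha = alpha,
                 mb_per_cm = mb_per_cm, mapping = match.arg(mapping)),
            class = "LDConfig")
}

#' Pairwise linkage disequilibrium binned by distance
#'
#' r2 is the squared Pearson correlation of the dosage vectors of two loci
#' on the same chromosome, computed over animals with non-missing calls at
#' both loci (pairwise deletion). Pairs are restricted to the configured
#' distance window and averaged within distance bins equally spaced on a
#' log10 scale. Pairs whose complete-case subset leaves a monomorphic locus
#' have an undefined correlation and are skipped (counted in `n_skipped`).
#'
#' @param gd a [GenotypeData-class] object (QC'd).
#' @param config an [ldConfig()] list.
#' @return `data.frame` with one row per non-empty bin: `bin`, `d_bp`
#'   (mean pair distance), `n_pairs`, `r2`; attributes `n_animals` and
#'   `n_skipped`.
#' @export
pairwiseR2 <- function(gd, config = ldConfig()) {
  stopifnot(is(gd, "GenotypeData"), inherits(config, "LDConfig"))
  d <- dosages(gd)
  map <- markerMap(gd)
  edges <- 10 ^ seq(log10(config$min_dist_bp), log10(config$max_dist_bp),
                    length.out = config$n_bins + 1L)
  dist_all <- r2_all <- list()
  skipped <- 0L
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    if (length(i) < 2L) next
    pos <- map$pos_bp[i]
    M <- t(d[i, , drop = FALSE]) * 1  # animals x loci, numeric
    cc <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dd <- pos[pr[, 2L]] - pos[pr[, 1L]]
    keep <- dd >= config$min_dist_bp & dd <= config$max_dist_bp
    r2 <- cc[pr][keep] ^ 2
    dd <- dd[keep]
    bad <- is.na(r2)
    skipped <- skipped + sum(bad)
    dist_all[[length(dist_all) + 1L]] <- dd[!bad]
    r2_all[[length(r2_all) + 1L]] <- r2[!bad]
  }
  dd <- unlist(dist_all)
  r2 <- unlist(r2_all)
  if (!length(dd)) stop("no marker pairs inside the distance window")
  bin <- findInterval(dd, edges, rightmost.closed = TRUE)
  out <- data.frame(
    bin = sort(unique(bin)),
    d_bp = as.numeric(tapply(dd, bin, mean)),
    n_pairs = as.integer(table(bin)),
    r2 = as.numeric(tapply(r2, bin, mean)))
  attr(out, "n_animals") <- ncol(d)
  attr(out, "n_skipped") <- skipped
  out
}

#' Sampling-bias adjustment of r2
#'
#' Subtracts the finite-sample expectation 1/(beta * n) from mean r2
#' values; bins whose adjusted value is not positive are unusable for Ne
#' estimation and are flagged.
#'
#' @param r2 numeric vector (or the `data.frame` from [pairwiseR2()], whose
#'   `r2` column is then adjusted in place as column `r2_adj`).
#' @param n_animals number of animals the correlations were computed on.
#' @param config an [ldConfig()] list (supplies `beta`).
#' @return Adjusted vector, or the input `data.frame` with columns
#'   `r2_adj` and `usable` added.
#' @export
adjustR2 <- function(r2, n_animals, config = ldConfig()) {
  stopifnot(n_animals > 1)
  corr <- 1 / (config$beta * n_animals)
  if (is.data.frame(r2)) {
    r2$r2_adj <- r2$r2 - corr
    r2$usable <- r2$r2_adj > 0
    return(r2)
  }
  r2 - corr
}

#' Historical effective population size from LD decay
#'
#' For every usable distance bin, the mean pair distance is converted to
#' Morgans (via `mb_per_cm`), mapped to a recombination rate c by the
#' configured mapping (Sved-Feldman c = d(1 - d/2) by default), dated
#' t = 1/(2c) generations ago, and inverted to
#' Ne(t) = (1/r2_adj - alpha) / (4c). Bins with `1/r2_adj <= alpha` would
#' give a non-positive Ne and are dropped with a warning.
#'
#' @param binned `data.frame` from [pairwiseR2()] passed through
#'   [adjustR2()] (needs columns `d_bp` and `r2_adj`).
#' @param config an [ldConfig()] list.
#' @return `data.frame` sorted by increasing t: `d_bp`, `d_morgan`, `c`,
#'   `t` (raw), `t_gen` (rounded), `n_pairs`, `r2`, `r2_adj`, `ne`.
#' @export
neTrajectory <- function(binned, config = ldConfig()) {
  stopifnot(all(c("d_bp", "r2_adj") %in% names(binned)))
  b <- binned[!is.na(binned$r2_adj) & binned$r2_adj > 0, , drop = FALSE]
  if (!nrow(b)) stop("no usable bins (all adjusted r2 non-positive)")
  d_m <- b$d_bp / 1e6 / config$mb_per_cm / 100   # bp -> Mb -> cM -> Morgan
  c <- switch(config$mapping,
              sved_feldman = d_m * (1 - d_m / 2),
              haldane = (1 - exp(-2 * d_m)) / 2,
              linear = d_m)
  ne <- (1 / b$r2_adj - config$alpha) / (4 * c)
  drop <- ne <= 0
  if (any(drop))
    warning(sum(drop), " bins dropped (adjusted r2 implies non-positive Ne)")
  out <- data.frame(d_bp = b$d_bp, d_morgan = d_m, c = c,
                    t = 1 / (2 * c), t_gen = round(1 / (2 * c)),
                    n_pairs = if (is.null(b$n_pairs)) NA else b$n_pairs,
                    r2 = if (is.null(b$r2)) NA else b$r2,
                    r2_adj = b$r2_adj, ne = ne)[!drop, , drop = FALSE]
  out[order(out$t), , drop = FALSE]
}

#' One-call LD-based Ne trajectory
#'
#' Convenience wrapper: [pairwiseR2()] then [adjustR2()] then
#' [neTrajectory()].
#'
#' @inheritParams pairwiseR2
#' @return The [neTrajectory()] data.frame.
#' @export
ldNe <- function(gd, config = ldConfig()) {
  b <- pairwiseR2(gd, config)
  b <- adjustR2(b, attr(b, "n_animals"), config)
  neTrajectory(b, config)
}
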