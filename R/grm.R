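#' VanRaden genomic relationship matrix and genomic inbreeding
#'
#' G = Z Z' / (2 * sum p_i (1 - p_i)), with Z the dosage matrix centred by
#' twice the allele frequency per locus and missing dosages imputed to the
#' centring value (contributing zero). Genomic inbreeding is
#' FGRM = diag(G) - 1, which can be negative for animals less homozygous
#' than expected. With `freq = "fixed_half"` (the default, appropriate when
#' too few animals are genotyped to estimate frequencies) every p_i = 0.5
#' and, for complete genotypes, FGRM reduces exactly to
#' 1 - 2 * (heterozygous fraction).
#'
#' @param gd a [GenotypeData-class] object (normally after [qcGenotypes()]).
#' @param freq `"fixed_half"`, `"observed"`, or a numeric vector of allele
#'   frequencies, one per marker.
#' @return List with `G` (dense symmetric matrix, animal ids as dimnames),
#'   `fgrm` (named vector, diag(G) - 1), `p` (frequencies used) and
#'   `n_markers`.
#' @examples
#' gd <- simWrightFisher(N = 30, n_generations = 5, n_chromosomes = 2,
#'                       snp_per_chrom = 50, sample_n = 10, seed = 1)
#' res <- buildGRM(gd)
#' range(res$fgrm)
#' @export
buildGRM <- function(gd, freq = c("fixed_half", "observed")) {
  stopifnot(is(gd, "GenotypeData"))
  d <- dosages(gd)                 # markers x animals
  if (ncol(d) < 2L) stop("need at least two animals")
  if (is.numeric(freq)) {
    p <- freq
    stopifnot(length(p) == nrow(d))
  } else {
    freq <- match.arg(freq)
    p <- if (freq == "fixed_half") rep(0.5, nrow(d))
         else rowMeans(d, na.rm = TRUE) / 2
  }
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic loci dropped from the GRM")
    d <- d[!mono, , drop = FALSE]
    p <- p[!mono]
  }
  if (!nrow(d)) stop("no polymorphic loci left")
  Z <- d - 2 * p
  Z[is.na(Z)] <- 0                # missing imputed to 2p
  denom <- 2 * sum(p * (1 - p))
  G <- crossprod(Z) / denom
  dimnames(G) <- list(colnames(d), colnames(d))
  fgrm <- diag(G) - 1
  list(G = G, fgrm = fgrm, p = p, n_markers = nrow(d))
}
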