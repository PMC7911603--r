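#' Marker and animal quality-control thresholds
#'
#' Defaults follow common chip QC practice for small herds: 95% call rate on
#' both animals and markers, MAF strictly greater than 1%, Hardy-Weinberg
#' exact-test p-value above 1e-6, autosomes only (chromosomes 1-29 for
#' cattle; anything else, including sentinel codes for unmapped contigs, is
#' treated as non-autosomal).
#'
#' @param min_call_rate minimum call-rate fraction for markers and animals.
#' @param min_maf markers with minor allele frequency `<= min_maf` are
#'   removed (strictly-greater-than rule).
#' @param hwe_alpha markers with HWE exact p `<= hwe_alpha` are removed.
#' @param autosomes_only drop markers outside chromosomes `1..n_autosomes`.
#' @param n_autosomes number of autosomes (29 for cattle).
#' @return A named list of class `"QCThresholds"`.
#' @export
qcThresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                         hwe_alpha = 1e-6, autosomes_only = TRUE,
                         n_autosomes = 29L) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1, hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, autosomes_only = autosomes_only,
                 n_autosomes = as.integer(n_autosomes)),
            class = "QCThresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact test of Hardy-Weinberg equilibrium for a biallelic marker
#' (Wigginton-style, no mid-p): the p-value is the summed probability of all
#' heterozygote counts, conditional on the allele counts, whose probability
#' does not exceed that of the observed count.
#'
#' @param n_aa,n_ab,n_bb observed genotype counts.
#' @return p-value in `[0, 1]`.
#' @examples
#' hweExactTest(5, 0, 5)   # extreme heterozygote deficit at n = 10
#' @export
hweExactTest <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_a <- 2L * n_aa + n_ab        # copies of the A allele
  rare <- min(n_a, 2L * n - n_a) # rare-allele copies
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het = h | allele counts): multinomial over genotypes / binomial
  # over alleles; computed via lgamma for stability, then normalised
  logp <- vapply(hets, function(h) {
    haa <- (rare - h) %/% 2L
    hbb <- n - haa - h
    lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) - lgamma(hbb + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pobs <- p[match(n_ab, hets)]  # het count is invariant to allele labelling
  if (is.na(pobs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= pobs + 1e-12]))
}

#' Genotype quality control
#'
#' Applies filters in a fixed order: (1) autosome filter, (2) animal
#' call rate, (3) marker call rate, (4) minor allele frequency (strictly
#' greater than the threshold to be retained), (5) Hardy-Weinberg exact
#' test. The operation is idempotent: a second application removes nothing.
#'
#' @param gd a [GenotypeData-class] object.
#' @param thresholds a [qcThresholds()] list.
#' @return A list with elements `genotypes` (filtered [GenotypeData-class])
#'   and `report` (named list counting removals per criterion plus the
#'   retained dimensions).
#' @export
qcGenotypes <- function(gd, thresholds = qcThresholds()) {
  stopifnot(is(gd, "GenotypeData"), inherits(thresholds, "QCThresholds"))
  th <- thresholds
  d <- dosages(gd)           # markers x animals
  map <- markerMap(gd)
  report <- list(
    input_markers = nrow(d), input_animals = ncol(d),
    removed_non_autosomal = 0L, removed_animal_call_rate = 0L,
    removed_marker_call_rate = 0L, removed_maf = 0L, removed_hwe = 0L
  )
  if (th$autosomes_only) {
    keep <- map$chrom >= 1L & map$chrom <= th$n_autosomes
    report$removed_non_autosomal <- sum(!keep)
    d <- d[keep, , drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("all markers removed by QC (autosome filter)")
  acr <- colMeans(!is.na(d))
  keepA <- acr >= th$min_call_rate
  report$removed_animal_call_rate <- sum(!keepA)
  d <- d[, keepA, drop = FALSE]
  if (ncol(d) == 0L) stop("all animals removed by QC (call rate)")
  mcr <- rowMeans(!is.na(d))
  keep <- mcr >= th$min_call_rate
  report$removed_marker_call_rate <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  map <- map[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("all markers removed by QC (call rate)")
  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > th$min_maf
  report$removed_maf <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  map <- map[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("all markers removed by QC (MAF)")
  hwe_p <- vapply(seq_len(nrow(d)), function(i) {
    g <- d[i, ]
    hweExactTest(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                 sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  keep <- hwe_p > th$hwe_alpha
  report$removed_hwe <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  map <- map[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("all markers removed by QC (HWE)")
  report$retained_markers <- nrow(d)
  report$retained_animals <- ncol(d)
  list(genotypes = GenotypeData(t(d), map, animal_ids = colnames(d)),
       report = report)
}
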