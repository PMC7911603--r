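#' Simulate a multi-generation livestock pedigree
#'
#' Discrete generations: founders in generation 0, then each generation a
#' limited share of the previous generation's males is used as sires (the
#' usage skew typical of cattle herds) on the full set of available dams.
#' Three mating schemes are available: `"random"` pairing, `"assortative"`
#' (each sire is mated to the most related of a few candidate dams,
#' raising inbreeding), and `"full_sib_lines"` (founders form fixed
#' couples; from the second generation on, full sibs within each family
#' line are mated, driving F to 0.25 and beyond). True inbreeding
#' coefficients are computed on the complete pedigree by the tabular
#' method *before* parent records are masked, so true and
#' observed-pedigree inbreeding can be compared.
#'
#' @param n_founders founders in generation 0 (half male, half female).
#' @param n_generations number of offspring generations.
#' @param n_offspring offspring born per generation.
#' @param prop_sires fraction of candidate males actually used as sires
#'   each generation (default 0.25).
#' @param mating `"random"`, `"assortative"` or `"full_sib_lines"`.
#' @param missing_sire,missing_dam probability that a recorded parent is
#'   masked to unknown in the released pedigree (the truth keeps it).
#' @param birth_year_start year of the founder generation; one generation
#'   per `years_per_generation` years.
#' @param years_per_generation default 1.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return List with `pedigree` (masked [Pedigree-class]), `true_pedigree`
#'   (unmasked), and `truth` — a `data.frame` of `id`, true `sire`/`dam`,
#'   `generation` and tabular-method `F_true`.
#' @export
simPedigree <- function(n_founders = 60L, n_generations = 5L,
                        n_offspring = 80L, prop_sires = 0.25,
                        mating = c("random", "assortative",
                                   "full_sib_lines"),
                        missing_sire = 0, missing_dam = 0,
                        birth_year_start = 2000L,
                        years_per_generation = 1L, seed) {
  mating <- match.arg(mating)
  stopifnot(n_founders >= 2L, n_generations >= 1L, n_offspring >= 1L,
            missing_sire >= 0, missing_sire <= 1,
            missing_dam >= 0, missing_dam <= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  nm <- ceiling(n_founders / 2)
  id <- paste0("F", seq_len(n_founders))
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  sex <- rep(c("M", "F"), c(nm, n_founders - nm))
  gen <- rep(0L, n_founders)
  family <- seq_len(n_founders)        # founder couple line (full-sib scheme)
  if (mating == "full_sib_lines") {
    nc <- min(nm, n_founders - nm)
    family <- rep(NA_integer_, n_founders)
    family[seq_len(nc)] <- seq_len(nc)               # males 1..nc
    family[nm + seq_len(nc)] <- seq_len(nc)          # females 1..nc
  }
  for (g in seq_len(n_generations)) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("no candidates of one sex in generation ", g - 1L)
    A <- NULL
    if (mating == "assortative")
      A <- additiveRelationshipMatrix(
        Pedigree(id, sire, dam, birth_year_start + gen, sex))
    nsire <- max(1L, round(prop_sires * length(males)))
    sires <- sample(males, nsire)
    newsex <- sample(c("M", "F"), n_offspring, replace = TRUE)
    ns <- nd <- integer(n_offspring)
    for (k in seq_len(n_offspring)) {
      if (mating == "full_sib_lines") {
        fams <- unique(na.omit(family[c(males, females)]))
        fams <- fams[fams %in% family[males] & fams %in% family[females]]
        if (!length(fams)) stop("no complete family line left")
        fam <- sample(fams, 1L)
        ns[k] <- sample(rep(males[family[males] %in% fam], 2L), 1L)
        nd[k] <- sample(rep(females[family[females] %in% fam], 2L), 1L)
      } else {
        ns[k] <- sample(rep(sires, 2L), 1L)
        if (mating == "assortative") {
          cand <- sample(rep(females, 2L), min(5L, length(females)))
          nd[k] <- cand[which.max(A[ns[k], cand])]
        } else {
          nd[k] <- sample(rep(females, 2L), 1L)
        }
      }
    }
    newid <- paste0("G", g, "_", seq_len(n_offspring))
    id <- c(id, newid)
    sire <- c(sire, id[ns])
    dam <- c(dam, id[nd])
    sex <- c(sex, newsex)
    gen <- c(gen, rep(g, n_offspring))
    family <- c(family, family[ns])
  }
  years <- birth_year_start + gen * years_per_generation
  trueped <- Pedigree(id, sire, dam, years, sex)
  F_true <- diag(additiveRelationshipMatrix(trueped))[id] - 1
  truth <- data.frame(id = id, sire = sire, dam = dam, generation = gen,
                      F_true = unname(F_true), stringsAsFactors = FALSE)
  ms <- !is.na(sire) & runif(length(sire)) < missing_sire
  md <- !is.na(dam) & runif(length(dam)) < missing_dam
  masked <- Pedigree(id, replace(sire, ms, NA), replace(dam, md, NA),
                     years, sex)
  list(pedigree = masked, true_pedigree = trueped, truth = truth)
}

# recode each marker so that dosage counts the observed minor allele
# (ties kept as drawn); matches the PLINK reader convention so written
# genotypes round-trip
.minorRecode <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  G[, flip] <- 2L - G[, flip]
  G
}

# genome layout helper: marker map plus Morgan positions and 0-based
# chromosome block bounds for the C++ kernels
.simMap <- function(n_chromosomes, snp_per_chrom, chrom_length_mb,
                    mb_per_cm = 1) {
  pos <- lapply(seq_len(n_chromosomes), function(ch)
    sort(as.integer(runif(snp_per_chrom, 1, chrom_length_mb * 1e6))))
  # regenerate ties (vanishingly rare at chip density)
  pos <- lapply(pos, function(p) {
    while (anyDuplicated(p))
      p <- sort(c(p[!duplicated(p)],
                  as.integer(runif(sum(duplicated(p)), 1,
                                   chrom_length_mb * 1e6))))
    p
  })
  map <- data.frame(
    snp_id = paste0("snp", seq_len(n_chromosomes * snp_per_chrom)),
    chrom = rep(seq_len(n_chromosomes), each = snp_per_chrom),
    pos_bp = unlist(pos))
  first <- match(unique(map$chrom), map$chrom)
  list(map = map,
       posM = map$pos_bp / 1e6 / mb_per_cm / 100,
       chromStart = first - 1L,
       chromEnd = c(first[-1L] - 1L, nrow(map)) - 1L)
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founders receive two labelled haplotypes; every descendant receives one
#' recombinant gamete from each parent under the Haldane crossover model
#' (1 cM = 1 Mb by default). Founder haplotype alleles are then drawn per
#' locus at the founder allele frequency, so pedigree inbreeding and
#' genomic homozygosity agree in expectation. Identity-by-descent is
#' recorded exactly from the haplotype labels.
#'
#' @param sim output of [simPedigree()] (the *true* pedigree is used), or a
#'   [Pedigree-class] whose non-founders all have both parents known.
#' @param n_chromosomes,snp_per_chrom,chrom_length_mb genome layout
#'   (cattle-like default: 29 autosomes).
#' @param founder_freq founder allele frequency: a single value (default
#'   0.5), or a length-2 range from which per-locus frequencies are drawn
#'   uniformly.
#' @param genotyping_error_rate probability a called genotype is replaced
#'   by a random other dosage.
#' @param missing_rate probability a call is set missing.
#' @param mb_per_cm map scaling (1 cM = 1 Mb default).
#' @param seed RNG seed.
#' @return List with `genotypes` ([GenotypeData-class]), `ibd`
#'   (`data.frame` of per-animal genome-wide IBD fraction — the realised
#'   autozygosity), and `founder_origin` (2n x L matrix of founder
#'   haplotype labels).
#' @export
simGenotypes <- function(sim, n_chromosomes = 29L, snp_per_chrom = 100L,
                         chrom_length_mb = 100, founder_freq = 0.5,
                         genotyping_error_rate = 0, missing_rate = 0,
                         mb_per_cm = 1, seed) {
  if (missing(seed)) stop("a seed is required")
  ped <- if (is(sim, "Pedigree")) sim else sim$true_pedigree
  set.seed(seed)
  px <- .pedIndex(ped)
  ord <- px$topo
  n <- px$n
  pos <- integer(n); pos[ord] <- seq_len(n)
  si <- pos[px$si][ord]
  di <- pos[px$di][ord]
  lay <- .simMap(n_chromosomes, snp_per_chrom, chrom_length_mb, mb_per_cm)
  L <- nrow(lay$map)
  H <- cpp_gene_drop(ifelse(is.na(si), -1L, si - 1L),
                     ifelse(is.na(di), -1L, di - 1L),
                     lay$posM, lay$chromStart, lay$chromEnd)
  p <- if (length(founder_freq) == 1L) rep(founder_freq, L)
       else runif(L, founder_freq[1L], founder_freq[2L])
  # allele state of every founder haplotype at every locus
  S <- matrix(rbinom(2L * n * L, 1L, rep(p, each = 2L * n)), 2L * n, L)
  li <- seq_len(L)
  G <- matrix(0L, n, L)
  ibd <- numeric(n)
  for (i in seq_len(n)) {
    h1 <- H[2L * i - 1L, ] + 1L
    h2 <- H[2L * i, ] + 1L
    G[i, ] <- S[cbind(h1, li)] + S[cbind(h2, li)]
    ibd[i] <- mean(h1 == h2)
  }
  if (genotyping_error_rate > 0) {
    err <- which(runif(length(G)) < genotyping_error_rate)
    G[err] <- (G[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
  }
  if (missing_rate > 0)
    G[runif(length(G)) < missing_rate] <- NA_integer_
  G <- .minorRecode(G)
  ids <- ped@id[ord]
  rownames(G) <- ids
  list(genotypes = GenotypeData(G, lay$map),
       ibd = data.frame(id = ids, ibd_fraction = ibd,
                        stringsAsFactors = FALSE),
       founder_origin = H)
}

#' Wright-Fisher forward simulation with recombination
#'
#' Constant-size random-mating diploid population evolved for a number of
#' discrete generations; a sample of the final generation is returned as
#' genotypes. The expected LD at a given recombination distance reflects
#' the (constant) census size, which makes this the recovery benchmark for
#' [ldNe()].
#'
#' @param N census (= effective) number of diploids.
#' @param n_generations generations of drift after initialisation.
#' @param n_chromosomes,snp_per_chrom,chrom_length_mb genome layout.
#' @param init_freq range of initial allele frequencies (per-locus uniform
#'   draw).
#' @param sample_n animals sampled from the final generation (default all).
#' @param mb_per_cm map scaling.
#' @param seed RNG seed.
#' @return A [GenotypeData-class] of the sampled animals.
#' @export
simWrightFisher <- function(N = 100L, n_generations = 200L,
                            n_chromosomes = 20L, snp_per_chrom = 200L,
                            chrom_length_mb = 100, init_freq = c(0.1, 0.9),
                            sample_n = N, mb_per_cm = 1, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(N >= 2L, sample_n <= N)
  set.seed(seed)
  lay <- .simMap(n_chromosomes, snp_per_chrom, chrom_length_mb, mb_per_cm)
  L <- nrow(lay$map)
  p <- if (length(init_freq) == 1L) rep(init_freq, L)
       else runif(L, init_freq[1L], init_freq[2L])
  H0 <- matrix(rbinom(2L * N * L, 1L, rep(p, each = 2L * N)), 2L * N, L)
  H <- cpp_wright_fisher(H0, as.integer(n_generations), lay$posM,
                         lay$chromStart, lay$chromEnd)
  take <- sort(sample(N, sample_n))
  G <- H[2L * take - 1L, , drop = FALSE] + H[2L * take, , drop = FALSE]
  G <- .minorRecode(G)
  rownames(G) <- paste0("wf", take)
  GenotypeData(G, lay$map)
}

#' Simulate growth phenotypes with an inbreeding effect
#'
#' y = mu + sex + year + beta1 * (100 F) + e, with sex and birth-year
#' effects and a linear inbreeding-depression slope in kg per 1%
#' inbreeding. Weaning ages are drawn uniformly in a window around 240 d.
#' Defaults mirror a tropical beef herd: birth weight around 27 kg,
#' weaning weight around 144 kg, males heavier, depression slopes of
#' -0.103 and -0.685 kg per 1%.
#'
#' @param ped a [Pedigree-class] supplying sex and birth year.
#' @param F named inbreeding coefficients (fractions) per animal.
#' @param traits traits to generate.
#' @param mu,sex_effect,beta1,residual_sd named numeric vectors per trait
#'   (`sex_effect` is added for males).
#' @param year_sd SD of the independent normal year effects per trait.
#' @param age_range weaning-age window in days.
#' @param ids animals to phenotype (default: all with known sex and year).
#' @param seed RNG seed.
#' @return Phenotype `data.frame` in the [readPhenotypes()] layout, with
#'   the true year effects in `attr(, "year_effects")`.
#' @export
simPhenotypes <- function(ped, F,
                          traits = c("birth_weight", "weaning_weight"),
                          mu = c(birth_weight = 27.1,
                                 weaning_weight = 144.3),
                          sex_effect = c(birth_weight = 1.3,
                                         weaning_weight = 8),
                          beta1 = c(birth_weight = -0.103,
                                    weaning_weight = -0.685),
                          residual_sd = c(birth_weight = 4,
                                          weaning_weight = 20),
                          year_sd = c(birth_weight = 1,
                                      weaning_weight = 4),
                          age_range = c(200, 280), ids = NULL, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  tb <- pedigreeTable(ped)
  if (is.null(ids))
    ids <- tb$id[!is.na(tb$sex) & !is.na(tb$birth_year)]
  ix <- match(ids, tb$id)
  stopifnot(!anyNA(ix))
  sex <- tb$sex[ix]
  year <- tb$birth_year[ix]
  f <- as.numeric(F[ids])
  stopifnot(!anyNA(f))
  years <- sort(unique(year))
  out <- list()
  yeff_all <- list()
  for (tr in traits) {
    yeff <- setNames(rnorm(length(years), 0, year_sd[[tr]]), years)
    y <- mu[[tr]] + ifelse(sex == "M", sex_effect[[tr]], 0) +
      yeff[as.character(year)] + beta1[[tr]] * 100 * f +
      rnorm(length(ids), 0, residual_sd[[tr]])
    out[[tr]] <- data.frame(
      animal_id = ids, trait = tr, value = unname(y),
      age_d = if (tr == "weaning_weight")
        round(runif(length(ids), age_range[1L], age_range[2L])) else NA,
      sex = sex, birth_year = year, stringsAsFactors = FALSE)
    yeff_all[[tr]] <- yeff
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "year_effects") <- yeff_all
  res
}
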