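# build a single-animal, single-chromosome GenotypeData from a dosage
# vector and positions
gd1 <- function(g, pos, chrom = 1L) {
  dos <- matrix(as.integer(g), nrow = 1)
  rownames(dos) <- "a1"
  GenotypeData(dos, data.frame(snp_id = paste0("s", seq_along(g)),
                               chrom = chrom, pos_bp = as.integer(pos)))
}

test_that("homozygosity runs obey the count, span and gap rules", {
  cfg <- rohConfig()
  # all-heterozygous chromosome: nothing
  expect_length(detectROH(gd1(rep(1, 40), (1:40) * 1e5), cfg), 0)
  # 20 homozygous SNP spanning 1.5 Mb flanked by heterozygotes
  g <- c(1, rep(0, 20), 1)
  pos <- c(5e4, seq(1e6, 2.5e6, length.out = 20), 2.6e6)
  segs <- detectROH(gd1(g, pos), cfg)
  expect_length(segs, 1)
  expect_equal(segs$n_snp, 20L)
  expect_equal(GenomicRanges::start(segs), 1e6)
  expect_equal(GenomicRanges::end(segs), 2.5e6)
  # 14 homozygous SNP spanning 2 Mb: fails the SNP-count threshold
  g <- rep(2, 14)
  pos <- seq(1e6, 3e6, length.out = 14)
  expect_length(detectROH(gd1(g, pos), cfg), 0)
  # a missing call breaks a run just like a heterozygote
  g <- c(rep(0, 10), NA, rep(0, 10))
  pos <- seq(1e6, 3.2e6, length.out = 21)
  expect_length(detectROH(gd1(g, pos), cfg), 0)
  # 30 homozygous SNP with one interior gap of 1.2 Mb: split; each side
  # emitted only if it independently satisfies both thresholds
  pos <- c(seq(1e6, 2.9e6, length.out = 20), seq(4.1e6, 5.0e6, length.out = 10))
  segs <- detectROH(gd1(rep(0, 30), pos), cfg)
  expect_length(segs, 1)           # right side: 10 SNP < 15 -> dropped
  expect_equal(segs$n_snp, 20L)
  pos2 <- c(seq(1e6, 2.9e6, length.out = 15), seq(4.1e6, 6.0e6, length.out = 15))
  segs2 <- detectROH(gd1(rep(0, 30), pos2), cfg)
  expect_length(segs2, 2)
})

test_that("the consecutive scanner equals brute-force window enumeration on random fixtures", {
  cfg <- rohConfig(min_snp = 8, min_len_bp = 4e5)
  set.seed(77)
  for (rep in 1:30) {
    L <- 250
    pos <- sort(sample.int(2e7, L))
    g <- sample(c(0L, 1L, 2L, NA), L, replace = TRUE,
                prob = c(0.42, 0.12, 0.42, 0.04))
    segs <- detectROH(gd1(g, pos), cfg)
    got <- cbind(GenomicRanges::start(segs), GenomicRanges::end(segs))
    ora <- oracleRohWindows(g, pos, cfg)
    expect_equal(nrow(got), nrow(ora))
    if (nrow(ora)) {
      expect_equal(got[order(got[, 1]), , drop = FALSE],
                   cbind(pos[ora[, 1]], pos[ora[, 2]]))
    }
  }
})

test_that("summaries bin lengths half-open and FROH uses the length threshold", {
  map <- data.frame(snp_id = c("a", "b"), chrom = c(1L, 2L),
                    pos_bp = c(1L, 2L))
  # one animal, one 25.0777 Mb segment, LAUT fixed -> FROH = 0.01 exactly
  seg <- GenomicRanges::GRanges("1", IRanges::IRanges(1e6, 1e6 + 25.0777e6),
                                animal_id = "a1", n_snp = 100L,
                                length_mb = 25.0777)
  s <- summarizeROH(seg, map, laut_bp = 2507.77e6, animal_ids = "a1")
  expect_equal(s$per_animal$froh_1, 0.01)
  expect_equal(s$per_animal$froh_16, 0.01)
  # class bins: lower edge inclusive (a 2.000 Mb segment is in 2-4 Mb)
  segs <- GenomicRanges::GRanges(
    rep("1", 4), IRanges::IRanges(c(1, 1, 1, 1) * 1e6,
                                  width = c(1, 2, 4.5, 17) * 1e6 + 1),
    animal_id = "a1", n_snp = 20L,
    length_mb = c(1, 2, 4.5, 17))
  s2 <- summarizeROH(segs, map, laut_bp = 100e6, animal_ids = "a1")
  expect_equal(unname(s2$class_counts),
               c(1L, 1L, 1L, 0L, 1L))
  # FROH thresholds are monotone decreasing
  pa <- s2$per_animal
  expect_true(pa$froh_1 >= pa$froh_2 && pa$froh_2 >= pa$froh_4 &&
                pa$froh_4 >= pa$froh_8 && pa$froh_8 >= pa$froh_16)
  expect_equal(pa$froh_1, (1 + 2 + 4.5 + 17) / 100)
  expect_equal(pa$froh_4, (4.5 + 17) / 100)
})

test_that("raising thresholds never increases the number or mass of runs", {
  sim <- simPedigree(n_founders = 16, n_generations = 4, n_offspring = 30,
                     mating = "assortative", seed = 41)
  sg <- simGenotypes(sim, n_chromosomes = 4, snp_per_chrom = 700,
                     chrom_length_mb = 80, seed = 42)
  base <- summarizeROH(detectROH(sg$genotypes, rohConfig()), sg$genotypes)
  for (cfg in list(rohConfig(min_snp = 25), rohConfig(min_len_bp = 2e6),
                   rohConfig(min_snp = 30, min_len_bp = 4e6))) {
    s <- summarizeROH(detectROH(sg$genotypes, cfg), sg$genotypes)
    expect_lte(sum(s$per_animal$n_roh), sum(base$per_animal$n_roh))
    expect_lte(sum(s$per_animal$s_roh_mb), sum(base$per_animal$s_roh_mb))
    expect_true(all(s$per_animal$froh_1 <= base$per_animal$froh_1 + 1e-12))
  }
})

test_that("run count and total run length are strongly correlated across animals", {
  sim <- simPedigree(n_founders = 14, n_generations = 5, n_offspring = 40,
                     mating = "assortative", seed = 43)
  sg <- simGenotypes(sim, n_chromosomes = 6, snp_per_chrom = 600,
                     chrom_length_mb = 70, founder_freq = c(0.2, 0.8),
                     seed = 44)
  s <- summarizeROH(detectROH(sg$genotypes), sg$genotypes)
  pa <- s$per_animal
  expect_gt(cor(pa$n_roh, pa$s_roh_mb), 0.8)
})

test_that("inbred animals carry significantly more ROH than outbred ones", {
  pvals <- vapply(1:3, function(seed) {
    sim <- simPedigree(n_founders = 24, n_generations = 3, n_offspring = 50,
                       mating = "full_sib_lines", seed = seed)
    sg <- simGenotypes(sim, n_chromosomes = 5, snp_per_chrom = 600,
                       chrom_length_mb = 70, seed = seed + 100)
    s <- summarizeROH(detectROH(sg$genotypes), sg$genotypes)
    froh <- setNames(s$per_animal$froh_1, s$per_animal$animal_id)
    f <- setNames(sim$truth$F_true, sim$truth$id)
    sib <- names(f)[abs(f - 0.25) < 1e-9]
    out <- names(f)[f == 0]
    t.test(froh[sib], froh[out], alternative = "greater")$p.value
  }, numeric(1))
  expect_true(all(pvals < 0.01))
})

test_that("specific ROH are grouped by exact coordinates only", {
  seg <- function(an, s, e) GenomicRanges::GRanges(
    "3", IRanges::IRanges(s, e), animal_id = an, n_snp = 20L,
    length_mb = (e - s) / 1e6)
  segs <- c(seg("a1", 1e6, 3e6), seg("a2", 1e6, 3e6), seg("a3", 1e6, 3e6),
            seg("a4", 1.01e6, 3e6))
  sh <- sharedROH(segs)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$n_carriers, 3L)
  expect_equal(sh$start_bp, 1e6)
})

test_that("an IBD haplotype dropped to several carriers surfaces as the top shared region", {
  # one founder couple and many offspring: all offspring share founder
  # haplotypes; force a fully homozygous founder region by making the
  # genotypes of a whole chromosome segment homozygous in all carriers
  sim <- simPedigree(n_founders = 6, n_generations = 2, n_offspring = 40,
                     mating = "full_sib_lines", seed = 51)
  sg <- simGenotypes(sim, n_chromosomes = 3, snp_per_chrom = 500,
                     chrom_length_mb = 60, seed = 52)
  d <- t(dosages(sg$genotypes))
  map <- markerMap(sg$genotypes)
  idx <- which(map$chrom == 2)[100:160]
  carriers <- rownames(d)[10:18]
  d[carriers, idx] <- 0L
  # heterozygous flanks so every carrier's run has identical bounds
  d[carriers, c(idx[1] - 1L, idx[length(idx)] + 1L)] <- 1L
  gd <- GenotypeData(d, map)
  sh <- sharedROH(detectROH(gd))
  expect_gt(nrow(sh), 0)
  top <- sh[1, ]
  expect_equal(top$n_carriers, 9L)
  expect_equal(top$start_bp, map$pos_bp[idx[1]])
})
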