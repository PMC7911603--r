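test_that("inbreeding matches classical closed forms", {
  # founders are non-inbred
  ped <- Pedigree(c("S", "D", "C"), c(NA, NA, "S"), c(NA, NA, "D"))
  expect_equal(unname(inbreedingCoef(ped)), c(0, 0, 0))
  # offspring of two full sibs: F = 0.25
  p2 <- Pedigree(c("A", "B", "X", "Y", "Z"),
                 sire = c(NA, NA, "A", "A", "X"),
                 dam = c(NA, NA, "B", "B", "Y"))
  expect_equal(inbreedingCoef(p2)[["Z"]], 0.25)
  # sire-daughter mating: F = 0.25; half sibs: F = 0.125
  p3 <- Pedigree(c("A", "B", "X", "Z"), sire = c(NA, NA, "A", "A"),
                 dam = c(NA, NA, "B", "X"))
  expect_equal(inbreedingCoef(p3)[["Z"]], 0.25)
})

test_that("Meuwissen-Luo F and fast AR equal full-matrix constructions on random pedigrees", {
  for (seed in 1:6) {
    ped <- randomPedigree(120, seed)
    A <- additiveRelationshipMatrix(ped)        # tabular recursion
    F <- inbreedingCoef(ped)                    # ancestor-list algorithm
    ar <- relatednessAR(ped, F)                 # triangular-sweep algorithm
    expect_lt(max(abs(F - (diag(A) - 1))), 1e-12)
    expect_lt(max(abs(ar - rowMeans(A) / 2)), 1e-12)
  }
  # and both agree with the memoised coancestry recursion on a small one
  ped <- randomPedigree(45, 99)
  K <- oracleKinship(ped)
  expect_lt(max(abs(additiveRelationshipMatrix(ped) - K)), 1e-12)
  expect_lt(max(abs(inbreedingCoef(ped) - (diag(K) - 1))), 1e-12)
})

test_that("AR has the textbook values in tiny populations", {
  # two unrelated founders: AR = 1/(2*2) * rowsum(A) = 0.25 each
  p <- Pedigree(c("A", "B"), c(NA, NA), c(NA, NA))
  expect_equal(unname(relatednessAR(p)), c(0.25, 0.25))
  # trio: AR_S = (1 + 0 + 0.5) / 6 = 0.25, AR_C = 2/6
  p <- Pedigree(c("S", "D", "C"), c(NA, NA, "S"), c(NA, NA, "D"))
  expect_equal(unname(relatednessAR(p)), c(0.25, 0.25, 1 / 3))
})

test_that("equivalent generations follow the per-path (1/2)^n sum", {
  ped <- Pedigree(c("GS", "GD", "S", "D", "C"),
                  sire = c(NA, NA, "GS", NA, "S"),
                  dam = c(NA, NA, "GD", NA, "D"))
  eq <- equivalentGenerations(ped)
  expect_equal(eq[["D"]], 0)
  expect_equal(eq[["S"]], 1)        # both parents known, nothing deeper
  expect_equal(eq[["C"]], 1 + 0.5)  # parents + two known grandparents
  # parents + all four grandparents -> 2
  p4 <- Pedigree(c("a", "b", "c", "d", "S", "D", "C"),
                 sire = c(NA, NA, NA, NA, "a", "c", "S"),
                 dam = c(NA, NA, NA, NA, "b", "d", "D"))
  expect_equal(equivalentGenerations(p4)[["C"]], 2)
  # random pedigrees vs recursive path descent
  for (seed in 7:9) {
    ped <- randomPedigree(60, seed)
    tb <- pedigreeTable(ped)
    eq <- equivalentGenerations(ped)
    ora <- vapply(seq_len(nrow(tb)), function(i) oracleEqG(tb, i),
                  numeric(1))
    expect_equal(unname(eq), ora, tolerance = 1e-12)
  }
})

test_that("pedigree completeness counts known ancestor slots per generation", {
  # 3 of 4 grandparents known -> generation-2 completeness 0.75
  ped <- Pedigree(c("a", "b", "c", "S", "D", "C"),
                  sire = c(NA, NA, NA, "a", "c", "S"),
                  dam = c(NA, NA, NA, "b", NA, "D"))
  pci <- pedigreeCompleteness(ped, max_depth = 3, subset = "C")
  expect_equal(unname(pci[1:2]), c(1, 0.75))
  # fully recorded pedigree to depth 5 saturates at 1
  sim <- simPedigree(n_founders = 32, n_generations = 5, n_offspring = 32,
                     seed = 1)
  top <- pedigreeTable(sim$true_pedigree)
  last <- top$id[grepl("^G5_", top$id)]
  pciF <- pedigreeCompleteness(sim$true_pedigree, 5, subset = last)
  expect_equal(unname(pciF), rep(1, 5))
  # explicit slot-count oracle on a masked pedigree
  sim2 <- simPedigree(n_founders = 20, n_generations = 3, n_offspring = 30,
                      missing_dam = 0.3, seed = 4)
  tb <- pedigreeTable(sim2$pedigree)
  pci2 <- pedigreeCompleteness(sim2$pedigree, 4)
  ora <- rowMeans(vapply(seq_len(nrow(tb)), function(i)
    oracleAncestorSlots(tb, i, 4), numeric(4))) / 2 ^ (1:4)
  expect_equal(unname(pci2), unname(ora), tolerance = 1e-12)
})

test_that("discovering an ancestor never decreases EqG or completeness", {
  sim <- simPedigree(n_founders = 20, n_generations = 4, n_offspring = 40,
                     missing_sire = 0.25, missing_dam = 0.25, seed = 21)
  tb <- pedigreeTable(sim$pedigree)
  truth <- sim$truth
  # fill one masked slot at a time and compare
  masked <- which(is.na(tb$sire) & !is.na(truth$sire[match(tb$id, truth$id)]))
  eq0 <- equivalentGenerations(sim$pedigree)
  pci0 <- pedigreeCompleteness(sim$pedigree, 5)
  for (i in head(masked, 5)) {
    tb2 <- tb
    tb2$sire[i] <- truth$sire[match(tb2$id[i], truth$id)]
    ped2 <- Pedigree(tb2$id, tb2$sire, tb2$dam, tb2$birth_year, tb2$sex)
    eq1 <- equivalentGenerations(ped2)[names(eq0)]
    expect_true(all(eq1 - eq0 >= -1e-12))
    pci1 <- pedigreeCompleteness(ped2, 5)
    expect_true(all(pci1 - pci0 >= -1e-12))
  }
})

test_that("generation intervals are assigned by path and pooled at record level", {
  # single record: sire born 2000, reproducing son born 2006
  ped <- Pedigree(id = c("S", "D", "X", "DX", "Y"),
                  sire = c(NA, NA, "S", NA, "X"),
                  dam = c(NA, NA, "D", NA, "DX"),
                  birth_year = c(2000, 2001, 2006, 2005, 2012),
                  sex = c("M", "F", "M", "F", "M"))
  gi <- generationIntervals(ped)
  expect_equal(gi["sire-sire", "mean_y"], 6)
  expect_equal(gi["sire-sire", "n"], 1L)
  # pooled mean equals record-level mean = count-weighted path mean
  sim <- simPedigree(n_founders = 30, n_generations = 4, n_offspring = 60,
                     seed = 31)
  g <- generationIntervals(sim$true_pedigree)
  paths <- g[rownames(g) != "pooled", ]
  expect_equal(g["pooled", "n"], sum(paths$n))
  expect_equal(g["pooled", "mean_y"],
               poolGenerationIntervals(paths$mean_y, paths$n),
               tolerance = 1e-12)
  # record-level brute force
  tb <- pedigreeTable(sim$true_pedigree)
  ages <- c()
  parents <- unique(c(tb$sire, tb$dam))
  for (i in seq_len(nrow(tb))) {
    if (!(tb$id[i] %in% parents)) next
    for (p in c(tb$sire[i], tb$dam[i]))
      if (!is.na(p))
        ages <- c(ages, tb$birth_year[i] - tb$birth_year[match(p, tb$id)])
  }
  expect_equal(g["pooled", "mean_y"], mean(ages), tolerance = 1e-12)
})

test_that("realized Ne follows the rate-of-inbreeding arithmetic", {
  expect_equal(inbreedingRate(0, 5), 0)
  expect_equal(inbreedingRate(0.25, 2), 0.25)          # exponent 1
  expect_true(is.na(inbreedingRate(0.1, 1)))           # excluded
  # mean dF = 0.01 -> Ne = 50 (the usual minimum-diversity threshold)
  r <- realizedNe(F = rep(0.01, 100), eqg = rep(2, 100))
  expect_equal(r$ne, 50)
  expect_equal(r$se, 0)
  # animals with EqG <= 1 are excluded and counted
  r2 <- realizedNe(F = c(0.01, 0.01, 0.5), eqg = c(2, 2, 1))
  expect_equal(r2$n_excluded, 1L)
  expect_equal(r2$ne, 50)
  # all-zero rates: infinite Ne with a warning
  expect_warning(r3 <- realizedNe(F = rep(0, 5), eqg = rep(3, 5)),
                 "infinite")
  expect_equal(r3$ne, Inf)
})
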