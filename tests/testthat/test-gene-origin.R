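test_that("effective founders has its closed forms", {
  # k equally contributing founders -> fe = k
  ped <- Pedigree(c("A", "B", "C", "D", "X", "Y"),
                  sire = c(NA, NA, NA, NA, "A", "C"),
                  dam = c(NA, NA, NA, NA, "B", "D"))
  r <- effectiveFounders(ped, ref = c("X", "Y"))
  expect_equal(unname(r$q[c("A", "B", "C", "D")]), rep(0.25, 4))
  expect_equal(r$fe, 4)
  # contributions (0.75, 0.25) -> fe = 1.6
  expect_equal(1 / sum(c(0.75, 0.25) ^ 2), 1.6)
  p2 <- Pedigree(c("A", "B", "X", "Z"),
                 sire = c(NA, NA, "A", "A"),
                 dam = c(NA, NA, "B", "X"))
  r2 <- effectiveFounders(p2, ref = "Z")  # A contributes 3/4, B 1/4
  expect_equal(unname(r2$q[c("A", "B")]), c(0.75, 0.25))
  expect_equal(r2$fe, 1.6)
  # unknown single-parent slots become phantom founders and q sums to 1
  p3 <- Pedigree(c("A", "X", "Z"), sire = c(NA, "A", "X"),
                 dam = c(NA, NA, NA))
  r3 <- effectiveFounders(p3, ref = "Z")
  expect_equal(sum(r3$q), 1)
  expect_true(any(grepl("^phantom:", names(r3$q))))
})

test_that("founder contributions match 100k-replicate gene dropping", {
  sim <- simPedigree(n_founders = 16, n_generations = 4, n_offspring = 30,
                     missing_dam = 0.1, seed = 13)
  ped <- sim$pedigree
  ref <- pedigreeTable(ped)$id[sim$truth$generation == 4]
  r <- effectiveFounders(ped, ref)
  mc <- oracleFounderContrib(ped, ref, n_rep = 1e5, seed = 14)
  common <- intersect(names(r$q), names(mc))
  expect_setequal(names(r$q), names(mc))
  expect_lt(max(abs(r$q[common] - mc[common])), 0.01)
})

test_that("effective ancestors explains bottlenecks and never exceeds fe", {
  # one founder parent of every lineage -> fa = 1
  ped <- Pedigree(c("S", "D1", "D2", "X", "Y"),
                  sire = c(NA, NA, NA, "S", "S"),
                  dam = c(NA, NA, NA, "D1", "D2"))
  ra <- effectiveAncestors(ped, ref = c("X", "Y"))
  # S explains 1/2; selecting X and Y (their own unknown-side halves)
  expect_equal(unname(ra$p["S"]), 0.5)
  # a popular non-founder ancestor is picked before its own parents
  p2 <- Pedigree(c("A", "B", "M"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"))
  tbl <- pedigreeTable(p2)
  kids <- paste0("k", 1:8)
  mates <- paste0("m", 1:8)
  p2 <- Pedigree(c(tbl$id, mates, kids),
                 sire = c(tbl$sire, rep(NA, 8), rep("M", 8)),
                 dam = c(tbl$dam, rep(NA, 8), mates))
  ra2 <- effectiveAncestors(p2, ref = kids)
  expect_equal(names(ra2$p)[1], "M")
  expect_equal(unname(ra2$p["M"]), 0.5)
  # after M is chosen, its parents A and B have zero marginal contribution
  expect_false(any(c("A", "B") %in% names(ra2$p)))
  # fa <= fe on random and simulated pedigrees
  for (seed in 1:5) {
    ped <- randomPedigree(80, seed)
    fe <- effectiveFounders(ped)$fe
    fa <- effectiveAncestors(ped)$fa
    expect_lte(fa, fe + 1e-9)
  }
  # fa = fe when every ancestor is a founder with non-overlapping descent
  flat <- Pedigree(c("A", "B", "C", "D", "X", "Y"),
                   sire = c(NA, NA, NA, NA, "A", "C"),
                   dam = c(NA, NA, NA, NA, "B", "D"))
  expect_equal(effectiveAncestors(flat, ref = c("X", "Y"))$fa,
               effectiveFounders(flat, ref = c("X", "Y"))$fe)
})

test_that("marginal contributions match exhaustive path enumeration on small pedigrees", {
  # independent mechanism: explicit enumeration of ancestry paths that do
  # not pass through previously selected ancestors
  pathContrib <- function(tb, ref, blocked) {
    contrib <- setNames(numeric(nrow(tb)), tb$id)
    descend <- function(id, w) {
      contrib[id] <<- contrib[id] + w
      if (id %in% blocked) return()
      i <- match(id, tb$id)
      for (p in c(tb$sire[i], tb$dam[i]))
        if (!is.na(p)) descend(p, w / 2)
    }
    for (r in ref) descend(r, 1 / length(ref))
    # discount each candidate by the explained share of its own genome
    explained <- function(id) {
      if (id %in% blocked) return(1)
      i <- match(id, tb$id)
      vals <- vapply(c(tb$sire[i], tb$dam[i]), function(p)
        if (is.na(p)) 0 else explained(p), numeric(1))
      mean(vals)
    }
    contrib * (1 - vapply(tb$id, explained, numeric(1)))
  }
  for (seed in c(3, 8, 15)) {
    ped <- randomPedigree(12, seed)
    tb <- pedigreeTable(ped)
    ref <- tb$id[7:12]
    candidates <- tb$id %in% c(tb$sire, tb$dam) |
      (tb$id %in% ref & (is.na(tb$sire) | is.na(tb$dam)))
    got <- effectiveAncestors(ped, ref)
    blocked <- character(0)
    expected <- numeric(0)
    repeat {
      ctr <- pathContrib(tb, ref, blocked)
      ctr[blocked] <- -Inf
      ctr[!candidates] <- -Inf
      k <- which.max(ctr)
      if (ctr[k] <= 1e-12) break
      expected <- c(expected, ctr[k])
      names(expected)[length(expected)] <- names(ctr)[k]
      blocked <- c(blocked, names(ctr)[k])
    }
    expect_equal(got$p, expected, tolerance = 1e-12)
    expect_equal(got$fa, 1 / sum(expected ^ 2), tolerance = 1e-12)
  }
})

test_that("half the gene pool is explained by the reported top ancestors", {
  sim <- simPedigree(n_founders = 12, n_generations = 4, n_offspring = 40,
                     prop_sires = 0.2, seed = 17)
  ra <- effectiveAncestors(sim$pedigree)
  m <- ra$n_ancestors_50pct
  expect_gte(sum(ra$p[seq_len(m)]), 0.5)
  if (m > 1) expect_lt(sum(ra$p[seq_len(m - 1L)]), 0.5)
})
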