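#' Phenotype quality control
#'
#' Trait-wise cleaning for growth records. Weaning weights are first
#' restricted to ages inside `240 +/- age_window` days, then adjusted to a
#' constant 240 d by the linear-gain rule
#' `WW240 = BW + 240 * (WW - BW) / age` when the animal has a birth-weight
#' record, else `WW240 = WW * 240 / age`. Each trait is then filtered once
#' to the range mean +/- 3 SD, with mean and SD computed before filtering
#' (single pass, no iteration); for weaning weight the filter acts on the
#' adjusted values.
#'
#' @param pt phenotype `data.frame` (see [readPhenotypes()]).
#' @param sd_limit the outlier cut in standard deviations (default 3).
#' @param target_age_d,age_window weaning-age target and half-window in
#'   days (defaults 240 and 45, i.e. the window [195, 285]).
#' @return Filtered `data.frame`; for weaning weight `value` holds the
#'   age-adjusted weight. Removal counts are in `attr(, "qc_log")`.
#' @export
qcPhenotypes <- function(pt, sd_limit = 3, target_age_d = 240,
                         age_window = 45) {
  stopifnot(all(c("animal_id", "trait", "value") %in% names(pt)))
  log <- list(age_window = 0L, sd_filter = 0L,
              adjustment = "linear-gain to 240 d")
  bw <- pt[pt$trait == "birth_weight", , drop = FALSE]
  out <- list()
  for (tr in unique(pt$trait)) {
    x <- pt[pt$trait == tr, , drop = FALSE]
    if (tr == "weaning_weight") {
      if (any(is.na(x$age_d)))
        stop("weaning-weight records require age_d")
      ok <- abs(x$age_d - target_age_d) <= age_window
      log$age_window <- log$age_window + sum(!ok)
      x <- x[ok, , drop = FALSE]
      bwv <- bw$value[match(x$animal_id, bw$animal_id)]
      x$value <- ifelse(is.na(bwv),
                        x$value * target_age_d / x$age_d,
                        bwv + (x$value - bwv) / x$age_d * target_age_d)
    }
    m <- mean(x$value)
    s <- sd(x$value)
    keep <- abs(x$value - m) <= sd_limit * s
    keep[is.na(keep)] <- TRUE        # zero-variance trait: keep all
    log$sd_filter <- log$sd_filter + sum(!keep)
    out[[tr]] <- x[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!nrow(res)) stop("no phenotype records survive QC")
  attr(res, "qc_log") <- log
  res
}

#' Inbreeding-depression regression
#'
#' Ordinary least-squares fit of a trait on an inbreeding coefficient with
#' sex and birth-year as categorical fixed effects:
#' `y = mu + sex + year + b1 * F + e`. The inbreeding covariate enters as a
#' fraction; the reported coefficient `beta1` is rescaled to kg per 1%
#' inbreeding (coefficient / 100), the unit depression estimates are
#' quoted in. Birth-year classes left rank-deficient (e.g. a single record
#' collinear with another effect) are merged into a pooled level and the
#' action is logged.
#'
#' @param pt QC'd phenotype `data.frame` for a single trait (see
#'   [qcPhenotypes()]); needs `sex` and `birth_year`.
#' @param F named vector of inbreeding coefficients (fractions), indexed by
#'   animal id — e.g. [inbreedingCoef()], `buildGRM()$fgrm` or a
#'   `froh_` column of [summarizeROH()].
#' @param measure_name label stored in the result (e.g. `"FPED"`).
#' @return List of class `"DepressionFit"`: `trait`, `measure`, `beta1`
#'   (kg per 1% inbreeding), `se` (same scale), `p_value`, `n`,
#'   `fixed_effects` (sex/year estimates), `pooled_years`, and the fitted
#'   `lm` object as `fit`.
#' @export
fitDepression <- function(pt, F, measure_name = "F") {
  stopifnot(length(unique(pt$trait)) == 1L)
  dat <- data.frame(y = pt$value,
                    sex = factor(pt$sex),
                    year = factor(pt$birth_year),
                    F = as.numeric(F[pt$animal_id]))
  if (anyNA(dat$F)) stop("missing inbreeding coefficient for ",
                         sum(is.na(dat$F)), " records")
  if (anyNA(dat$sex) || anyNA(dat$year))
    stop("records with missing sex or birth year")
  pooled <- character(0)
  fit <- lm(y ~ sex + year + F, data = dat)
  co <- coef(fit)
  bad <- is.na(co) & grepl("^year", names(co))
  if (any(bad)) {
    lv <- sub("^year", "", names(co)[bad])
    pooled <- lv
    levels(dat$year)[levels(dat$year) %in% lv] <- "pooled"
    fit <- lm(y ~ sex + year + F, data = dat)
  }
  sm <- summary(fit)$coefficients
  if (!"F" %in% rownames(sm))
    stop("inbreeding covariate dropped: no variation in F")
  structure(list(
    trait = pt$trait[1L], measure = measure_name,
    beta1 = unname(sm["F", "Estimate"]) / 100,
    se = unname(sm["F", "Std. Error"]) / 100,
    p_value = unname(sm["F", "Pr(>|t|)"]),
    n = nrow(dat),
    fixed_effects = coef(fit)[grepl("^(\\(Inter|sex|year)", names(coef(fit)))],
    pooled_years = pooled,
    fit = fit), class = "DepressionFit")
}

#' @export
print.DepressionFit <- function(x, ...) {
  cat(sprintf("Inbreeding depression: %s on %s\n", x$trait, x$measure))
  cat(sprintf("  beta1 = %.4f +/- %.4f kg per 1%% inbreeding (p = %.3g, n = %d)\n",
              x$beta1, x$se, x$p_value, x$n))
  invisible(x)
}
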