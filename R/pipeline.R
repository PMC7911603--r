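#' Run the full diversity analysis pipeline
#'
#' Orchestrates the stages in dependency order — simulate (optional) or
#' read inputs, genotype QC, pedigree metrics, GRM inbreeding, ROH/ROHet
#' detection and summaries, islands, LD-based Ne, inbreeding-depression
#' regressions — writing each table as CSV/TSV/JSON under `out_dir`
#' together with a run manifest (software version, seed registry, input
#' and output digests, per-stage timings). Reruns with the same seed are
#' byte-identical in every numeric output.
#'
#' @param out_dir output directory (created).
#' @param seed integer seed governing every stochastic stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "qc", "pedigree", "grm", "roh", "rohet", "islands",
#'   "ldne", "depression")`; upstream objects must exist (from a previous
#'   stage or the input files).
#' @param pedigree_file,ped_file,map_file,pheno_file input paths used when
#'   `"simulate"` is not among the stages.
#' @param sim_args list of overrides for the simulator preset (arguments
#'   of [simPedigree()], plus `snp_per_chrom`, `n_chromosomes`,
#'   `missing_rate`).
#' @param qc a [qcThresholds()] list.
#' @param roh_cfg,rohet_cfg run-detection configurations.
#' @param ld_cfg an [ldConfig()] list.
#' @param ref_window length-2 birth-year window for the reference
#'   population, or `NULL` for the automatic last-generation window.
#' @param islands_percentile incidence percentile for island calls.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(out_dir, seed,
                        stages = c("simulate", "qc", "pedigree", "grm",
                                   "roh", "rohet", "islands", "ldne",
                                   "depression"),
                        pedigree_file = NULL, ped_file = NULL,
                        map_file = NULL, pheno_file = NULL,
                        sim_args = list(), qc = qcThresholds(),
                        roh_cfg = rohConfig(), rohet_cfg = rohetConfig(),
                        ld_cfg = ldConfig(min_dist_bp = 1e5,
                                          max_dist_bp = 35e6),
                        ref_window = NULL, islands_percentile = 99.9) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  outputs <- character(0)
  clock <- function(stage, expr) {
    s <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - s, 3)
    r
  }
  emit <- function(obj, file, ...) {
    path <- file.path(out_dir, file)
    if (is.data.frame(obj) || is.matrix(obj))
      write.table(obj, path, sep = if (grepl("\\.tsv$", file)) "\t" else ",",
                  quote = FALSE, row.names = FALSE, ...)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE)
    outputs <<- c(outputs, path)
    path
  }
  ped <- gd <- pheno <- truth <- NULL

  if ("simulate" %in% stages) {
    sa <- sim_args
    get <- function(name, default) if (is.null(sa[[name]])) default
                                   else sa[[name]]
    sim <- clock("simulate_pedigree", simPedigree(
      n_founders = get("n_founders", 60L),
      n_generations = get("n_generations", 5L),
      n_offspring = get("n_offspring", 80L),
      prop_sires = get("prop_sires", 0.25),
      mating = get("mating", "random"),
      missing_sire = get("missing_sire", 0.1),
      missing_dam = get("missing_dam", 0.15),
      seed = seed))
    ped <- sim$pedigree
    truth <- sim$truth
    sg <- clock("simulate_genotypes", simGenotypes(
      sim, n_chromosomes = get("n_chromosomes", 10L),
      snp_per_chrom = get("snp_per_chrom", 120L),
      missing_rate = get("missing_rate", 0.01),
      seed = seed + 1L))
    gd <- sg$genotypes
    Ftrue <- setNames(truth$F_true, truth$id)
    pheno <- clock("simulate_phenotypes",
                   simPhenotypes(ped, Ftrue, seed = seed + 2L))
    writePedigree(ped, file.path(out_dir, "pedigree.csv"))
    writePlinkPedMap(gd, file.path(out_dir, "genotypes.ped"),
                     file.path(out_dir, "genotypes.map"), ped = ped)
    writePhenotypes(pheno, file.path(out_dir, "phenotypes.csv"))
    emit(truth, "sim_truth.csv")
    outputs <- c(outputs, file.path(out_dir, c("pedigree.csv",
                 "genotypes.ped", "genotypes.map", "phenotypes.csv")))
  } else {
    if (!is.null(pedigree_file)) ped <- readPedigree(pedigree_file)
    if (!is.null(ped_file)) gd <- readPlinkPedMap(ped_file, map_file)
    if (!is.null(pheno_file)) pheno <- readPhenotypes(pheno_file)
  }

  if ("qc" %in% stages) {
    if (is.null(gd)) stop("stage 'qc' needs genotypes (simulate stage or ",
                          "--ped/--map inputs)")
    res <- clock("qc", qcGenotypes(gd, qc))
    gd <- res$genotypes
    emit(res$report, "qc_report.json")
  }

  metrics <- NULL
  if ("pedigree" %in% stages) {
    if (is.null(ped)) stop("stage 'pedigree' needs a pedigree")
    metrics <- clock("pedigree", {
      F <- inbreedingCoef(ped)
      ar <- relatednessAR(ped, F)
      eqg <- equivalentGenerations(ped)
      dF <- inbreedingRate(F, eqg)
      ref <- if (is.null(ref_window)) referencePopulation(ped)
             else referencePopulation(ped, ref_window[1L], ref_window[2L])
      ne <- realizedNe(F, eqg)
      gi <- generationIntervals(ped)
      gi_ref <- generationIntervals(ped, subset = ref)
      fe <- effectiveFounders(ped, ref)
      fa <- effectiveAncestors(ped, ref)
      fe_tot <- effectiveFounders(ped)
      fa_tot <- effectiveAncestors(ped)
      list(F = F, ar = ar, eqg = eqg, dF = dF, ref = ref, ne = ne,
           gi = gi, gi_ref = gi_ref, fe = fe, fa = fa,
           fe_tot = fe_tot, fa_tot = fa_tot)
    })
    emit(data.frame(animal_id = animalIds(ped), F = metrics$F,
                    AR = metrics$ar, EqG = metrics$eqg, dF = metrics$dF),
         "pedigree_metrics.csv")
    emit(cbind(path = rownames(metrics$gi), metrics$gi),
         "generation_intervals.csv")
    emit(cbind(path = rownames(metrics$gi_ref), metrics$gi_ref),
         "generation_intervals_reference.csv")
    emit(data.frame(gen = seq_along(pedigreeCompleteness(ped)),
                    pci_total = pedigreeCompleteness(ped),
                    pci_reference = pedigreeCompleteness(
                      ped, subset = metrics$ref)), "pci.csv")
    emit(list(
      ne = metrics$ne$ne, se = metrics$ne$se, ci = as.list(metrics$ne$ci),
      mean_dF = metrics$ne$mean_dF, n_used = metrics$ne$n_used,
      fe_reference = metrics$fe$fe, fa_reference = metrics$fa$fa,
      fa_fe_reference = metrics$fa$fa / metrics$fe$fe,
      fe_total = metrics$fe_tot$fe, fa_total = metrics$fa_tot$fa,
      fa_fe_total = metrics$fa_tot$fa / metrics$fe_tot$fe,
      n_ancestors_50pct_reference = metrics$fa$n_ancestors_50pct,
      reference_window = as.list(attr(metrics$ref, "window")),
      reference_size = length(metrics$ref)), "population_summary.json")
  }

  grm <- NULL
  if ("grm" %in% stages) {
    if (is.null(gd)) stop("stage 'grm' needs genotypes")
    grm <- clock("grm", buildGRM(gd, freq = "fixed_half"))
    emit(data.frame(animal_id = names(grm$fgrm), fgrm = grm$fgrm),
         "fgrm.csv")
  }

  segs <- NULL
  if ("roh" %in% stages) {
    if (is.null(gd)) stop("stage 'roh' needs genotypes")
    segs <- clock("roh", detectROH(gd, roh_cfg))
    rs <- summarizeROH(segs, gd)
    emit(.segmentsToDf(segs), "roh_segments.tsv")
    emit(rs$per_animal, "roh_per_animal.csv")
    emit(data.frame(class = names(rs$class_counts),
                    count = rs$class_counts,
                    share_pct = rs$class_shares), "roh_classes.csv")
    emit(sharedROH(segs), "roh_shared.tsv")
  }

  hets <- NULL
  if ("rohet" %in% stages) {
    if (is.null(gd)) stop("stage 'rohet' needs genotypes")
    hets <- clock("rohet", detectROHet(gd, rohet_cfg))
    emit(.segmentsToDf(hets), "rohet_segments.tsv")
  }

  if ("islands" %in% stages) {
    if (is.null(segs)) stop("stage 'islands' needs the roh stage")
    isl <- clock("islands", findIslands(segs, gd,
                                        percentile = islands_percentile))
    emit(isl$incidence, "roh_incidence.tsv")
    emit(isl$islands, "roh_islands.tsv")
    if (!is.null(hets)) {
      isl2 <- findIslands(hets, gd, percentile = islands_percentile)
      emit(isl2$incidence, "rohet_incidence.tsv")
      emit(isl2$islands, "rohet_islands.tsv")
    }
  }

  if ("ldne" %in% stages) {
    if (is.null(gd)) stop("stage 'ldne' needs genotypes")
    traj <- clock("ldne", ldNe(gd, ld_cfg))
    emit(traj, "ne_trajectory.tsv")
  }

  if ("depression" %in% stages) {
    if (is.null(pheno) || is.null(ped))
      stop("stage 'depression' needs phenotypes and a pedigree")
    fits <- clock("depression", {
      ptq <- qcPhenotypes(pheno)
      F <- inbreedingCoef(ped)
      measures <- list(FPED = F)
      if (!is.null(grm)) measures$FGRM <- grm$fgrm
      if (!is.null(segs) && !is.null(gd)) {
        rs <- summarizeROH(segs, gd)
        measures$FROH <- setNames(rs$per_animal$froh_1,
                                  rs$per_animal$animal_id)
      }
      rows <- list()
      for (tr in unique(ptq$trait)) {
        pt <- ptq[ptq$trait == tr, , drop = FALSE]
        for (mn in names(measures)) {
          Fm <- measures[[mn]]
          sub <- pt[pt$animal_id %in% names(Fm)[!is.na(Fm)], , drop = FALSE]
          if (nrow(sub) < 10L) next
          ft <- fitDepression(sub, Fm, mn)
          rows[[paste(tr, mn)]] <- data.frame(
            trait = tr, measure = mn, beta1_kg_per_pct = ft$beta1,
            se = ft$se, p_value = ft$p_value, n = ft$n)
        }
      }
      do.call(rbind, rows)
    })
    emit(fits, "depression.csv")
  }

  manifest <- list(
    package = "herddiv", version = as.character(packageVersion("herddiv")),
    seed = seed, stages = stages,
    timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t0, 3),
    outputs = lapply(setNames(nm = basename(unique(outputs))), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# BED-like table for run segments (1-based closed coordinates)
.segmentsToDf <- function(segments) {
  data.frame(chrom = as.integer(as.character(
               GenomicRanges::seqnames(segments))),
             start_bp = GenomicRanges::start(segments),
             end_bp = GenomicRanges::end(segments),
             animal_id = segments$animal_id,
             n_snp = segments$n_snp,
             length_mb = segments$length_mb,
             stringsAsFactors = FALSE)
}
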