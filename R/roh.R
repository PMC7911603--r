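#' Run-detection configuration
#'
#' Parameters of the consecutive-scan run detectors. The homozygosity
#' defaults are the conservative cattle-chip settings: at least 15
#' consecutive homozygous SNP spanning at least 1 Mb, no heterozygous or
#' missing call inside a run, and no gap between consecutive markers above
#' 1 Mb. The heterozygosity-run defaults relax the span to 250 kb and
#' tolerate up to 3 homozygous and 2 missing calls inside a run.
#'
#' @param min_snp minimum number of SNP in a run.
#' @param min_len_bp minimum run span in bp (first to last SNP).
#' @param max_gap_bp maximum distance between consecutive markers inside a
#'   run.
#' @param max_hom_inside,max_missing_inside tolerated interior calls of the
#'   opposite/missing state (0 for strict homozygosity runs).
#' @return Named list of class `"RunConfig"`.
#' @export
rohConfig <- function(min_snp = 15L, min_len_bp = 1e6, max_gap_bp = 1e6,
                      max_hom_inside = 0L, max_missing_inside = 0L) {
  stopifnot(min_snp >= 1, min_len_bp >= 0, max_gap_bp > 0,
            max_hom_inside >= 0, max_missing_inside >= 0)
  structure(list(min_snp = as.integer(min_snp), min_len_bp = min_len_bp,
                 max_gap_bp = max_gap_bp,
                 max_hom_inside = as.integer(max_hom_inside),
                 max_missing_inside = as.integer(max_missing_inside)),
            class = "RunConfig")
}

#' @rdname rohConfig
#' @export
rohetConfig <- function(min_snp = 15L, min_len_bp = 250000, max_gap_bp = 1e6,
                        max_hom_inside = 3L, max_missing_inside = 2L) {
  rohConfig(min_snp = min_snp, min_len_bp = min_len_bp,
            max_gap_bp = max_gap_bp, max_hom_inside = max_hom_inside,
            max_missing_inside = max_missing_inside)
}

.newSegments <- function(chrom, start, end, animal, n_snp) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start, end = end),
    animal_id = animal, n_snp = as.integer(n_snp),
    length_mb = (end - start) / 1e6)
  gr
}

.emptySegments <- function()
  .newSegments(integer(0), integer(0), integer(0), character(0), integer(0))

.bindSegments <- function(out) {
  if (!length(out)) return(.emptySegments())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$animal), , drop = FALSE]
  .newSegments(df$chrom, df$start, df$end, df$animal, df$n_snp)
}

#' Detect runs of homozygosity
#'
#' Consecutive scan per animal and chromosome: a run of homozygous calls
#' breaks at any heterozygote, any missing call, and any inter-marker gap
#' above `max_gap_bp`; it is emitted when it contains at least `min_snp`
#' SNP *and* spans at least `min_len_bp`. Run coordinates are the bp
#' positions of the first and last SNP (1-based, closed).
#'
#' @param gd a [GenotypeData-class] object (QC'd genotypes).
#' @param config a [rohConfig()] list.
#' @return A `GRanges` of segments with metadata columns `animal_id`,
#'   `n_snp` and `length_mb`.
#' @export
detectROH <- function(gd, config = rohConfig()) {
  stopifnot(is(gd, "GenotypeData"), inherits(config, "RunConfig"))
  d <- dosages(gd)
  map <- markerMap(gd)
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_bp[idx]
    L <- length(idx)
    blk <- cumsum(c(0L, as.integer(diff(pos) > config$max_gap_bp)))
    for (a in colnames(d)) {
      g <- d[idx, a]
      hom <- !is.na(g) & g != 1L
      if (!any(hom)) next
      change <- c(TRUE, blk[-1L] != blk[-L] | hom[-1L] != hom[-L])
      starts <- which(change)
      ends <- c(starts[-1L] - 1L, L)
      isrun <- hom[starts]
      nsnp <- ends - starts + 1L
      span <- pos[ends] - pos[starts]
      keep <- isrun & nsnp >= config$min_snp & span >= config$min_len_bp
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos[starts[keep]], end = pos[ends[keep]],
          animal = a, n_snp = nsnp[keep])
    }
  }
  .bindSegments(out)
}

#' Detect runs of heterozygosity
#'
#' Same consecutive scan over heterozygous calls, tolerating a bounded
#' number of interior homozygous and missing calls
#' (`max_hom_inside` / `max_missing_inside` in the configuration). A run
#' starts and ends on a heterozygous SNP; when extending to the next
#' heterozygote would exceed a tolerance or cross a gap above
#' `max_gap_bp`, the run is closed at the last heterozygote and a new
#' candidate starts at the next one. The SNP count of a run includes the
#' tolerated interior calls.
#'
#' @inheritParams detectROH
#' @param config a [rohetConfig()] list.
#' @return A `GRanges` of heterozygosity runs, as in [detectROH()].
#' @export
detectROHet <- function(gd, config = rohetConfig()) {
  stopifnot(is(gd, "GenotypeData"), inherits(config, "RunConfig"))
  d <- dosages(gd)
  map <- markerMap(gd)
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_bp[idx]
    L <- length(idx)
    bad <- if (L > 1L) as.integer(diff(pos) > config$max_gap_bp) else integer(0)
    cumbad <- c(0L, cumsum(bad))        # cumbad[i+1] = bad gaps among first i
    for (a in colnames(d)) {
      g <- d[idx, a]
      het <- which(!is.na(g) & g == 1L)
      if (!length(het)) next
      hom <- cumsum(!is.na(g) & g != 1L)
      mis <- cumsum(is.na(g))
      st <- het[1L]; last <- het[1L]; chom <- 0L; cmis <- 0L
      close <- function(s, e) {
        nsnp <- e - s + 1L
        if (nsnp >= config$min_snp &&
            pos[e] - pos[s] >= config$min_len_bp)
          out[[length(out) + 1L]] <<- data.frame(
            chrom = ch, start = pos[s], end = pos[e], animal = a,
            n_snp = nsnp)
      }
      for (h in het[-1L]) {
        addh <- hom[h - 1L] - hom[last]
        addm <- mis[h - 1L] - mis[last]
        gapbad <- (cumbad[h] - cumbad[last]) > 0L
        if (!gapbad && chom + addh <= config$max_hom_inside &&
            cmis + addm <= config$max_missing_inside) {
          chom <- chom + addh; cmis <- cmis + addm; last <- h
        } else {
          close(st, last)
          st <- h; last <- h; chom <- 0L; cmis <- 0L
        }
      }
      close(st, last)
    }
  }
  .bindSegments(out)
}

#' Summarise runs of homozygosity
#'
#' Per-animal accounting (number of runs, total and mean length, genomic
#' inbreeding FROH at increasing minimum-length thresholds, per-chromosome
#' FROHCHR) and population length-class counts. FROH at threshold x uses
#' only segments at least x Mb long, divided by the autosomal length LAUT;
#' FROHCHR divides by the chromosome length LCHR. Length classes are
#' half-open with inclusive lower edge: [1,2), [2,4), [4,8), [8,16),
#' [16, Inf) Mb.
#'
#' @param segments `GRanges` from [detectROH()].
#' @param x the [GenotypeData-class] object (or marker-map `data.frame`)
#'   the runs were detected on; supplies marker extents and animal ids.
#' @param laut_bp autosome length in bp; default the map extents
#'   (sum of per-chromosome first-to-last SNP distances). Pass a constant
#'   (e.g. `2507.77e6`) to replicate published accounting.
#' @param animal_ids animals to report (zero rows for animals without
#'   runs); defaults to the animals of `x` when `x` is a
#'   [GenotypeData-class], else to the carriers in `segments`.
#' @param thresholds_mb minimum-length thresholds for FROH columns.
#' @return List with `per_animal` (data.frame), `froh_chr` (animals x
#'   chromosomes matrix), `class_counts`, `class_shares` (percent),
#'   `laut_mb` and `lchr_mb`.
#' @export
summarizeROH <- function(segments, x, laut_bp = NULL, animal_ids = NULL,
                         thresholds_mb = c(1, 2, 4, 8, 16)) {
  cl <- chromosomeLengths(x)
  if (is.null(laut_bp)) laut_bp <- cl$laut_bp
  if (is.null(animal_ids))
    animal_ids <- if (is(x, "GenotypeData")) animalIds(x)
                  else unique(segments$animal_id)
  laut_mb <- laut_bp / 1e6
  len <- segments$length_mb
  an <- factor(segments$animal_id, levels = animal_ids)
  per <- data.frame(
    animal_id = animal_ids,
    n_roh = as.integer(tabulate(an, nbins = length(animal_ids))),
    s_roh_mb = as.numeric(tapply(len, an, sum, default = 0)),
    mean_len_mb = as.numeric(tapply(len, an, mean, default = NA)),
    stringsAsFactors = FALSE)
  for (t in thresholds_mb)
    per[[sprintf("froh_%g", t)]] <- as.numeric(
      tapply(ifelse(len >= t, len, 0), an, sum, default = 0)) / laut_mb
  chroms <- names(cl$lchr_bp)
  fchr <- matrix(0, length(animal_ids), length(chroms),
                 dimnames = list(animal_ids, chroms))
  if (length(segments)) {
    sl <- tapply(len, list(an, factor(as.character(
      GenomicRanges::seqnames(segments)), levels = chroms)), sum,
      default = 0)
    fchr <- sweep(sl, 2L, cl$lchr_bp / 1e6, "/")
    fchr[is.na(fchr)] <- 0
  }
  breaks <- c(1, 2, 4, 8, 16, Inf)
  labs <- c("1-2Mb", "2-4Mb", "4-8Mb", "8-16Mb", ">16Mb")
  counts <- setNames(as.integer(table(cut(len, breaks, right = FALSE,
                                          labels = labs))), labs)
  shares <- if (sum(counts) > 0) rohClassShares(counts)
            else setNames(rep(0, length(counts)), names(counts))
  list(per_animal = per, froh_chr = fchr, class_counts = counts,
       class_shares = shares, laut_mb = laut_mb,
       lchr_mb = cl$lchr_bp / 1e6)
}

#' Percentage shares of ROH length classes
#'
#' @param counts vector of segment counts per length class.
#' @return Percentages summing to 100.
#' @examples
#' rohClassShares(c(1907, 1098, 640, 250, 48))
#' @export
rohClassShares <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  100 * counts / sum(counts)
}

#' Specific (exactly shared) runs of homozygosity
#'
#' Groups segments that start and end at precisely the same bp positions on
#' the same chromosome and reports regions carried by at least two animals,
#' sorted by decreasing carrier count.
#'
#' @param segments `GRanges` from [detectROH()].
#' @return `data.frame` with `chrom`, `start_bp`, `end_bp`, `n_carriers`
#'   and a comma-separated `carriers` column.
#' @export
sharedROH <- function(segments) {
  if (!length(segments))
    return(data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_carriers = integer(0),
                      carriers = character(0)))
  key <- paste(GenomicRanges::seqnames(segments),
               GenomicRanges::start(segments),
               GenomicRanges::end(segments), sep = ":")
  grp <- split(segments$animal_id, key)
  grp <- lapply(grp, unique)
  nc <- lengths(grp)
  keep <- nc >= 2L
  if (!any(keep))
    return(data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_carriers = integer(0),
                      carriers = character(0)))
  parts <- strsplit(names(grp)[keep], ":", fixed = TRUE)
  out <- data.frame(
    chrom = as.integer(vapply(parts, `[`, "", 1L)),
    start_bp = as.integer(vapply(parts, `[`, "", 2L)),
    end_bp = as.integer(vapply(parts, `[`, "", 3L)),
    n_carriers = as.integer(nc[keep]),
    carriers = vapply(grp[keep], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  out[order(-out$n_carriers, out$chrom, out$start_bp), , drop = FALSE]
}

#' Run incidence islands (selection signatures)
#'
#' Per-SNP incidence is the fraction of animals whose runs cover the SNP.
#' The threshold is the given percentile of the incidence distribution over
#' all SNP, and islands are maximal stretches of consecutive SNP at or
#' above the threshold that do not span an inter-marker gap larger than
#' `max_gap_bp`.
#'
#' @param runs `GRanges` from [detectROH()] or [detectROHet()].
#' @param gd the [GenotypeData-class] the runs were detected on.
#' @param percentile incidence percentile defining the threshold
#'   (default 99.9).
#' @param max_gap_bp island contiguity limit.
#' @return List with `incidence` (`data.frame`: snp_id, chrom, pos_bp,
#'   incidence), `threshold`, and `islands` (`data.frame`: chrom, start_bp,
#'   end_bp, n_snp, max_incidence).
#' @export
findIslands <- function(runs, gd, percentile = 99.9, max_gap_bp = 1e6) {
  stopifnot(is(gd, "GenotypeData"))
  map <- markerMap(gd)
  snps <- GenomicRanges::GRanges(as.character(map$chrom),
                                 IRanges::IRanges(map$pos_bp, width = 1L))
  inc <- GenomicRanges::countOverlaps(snps, runs) / nAnimals(gd)
  incidence <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                          pos_bp = map$pos_bp, incidence = inc)
  emptyIsl <- data.frame(chrom = integer(0), start_bp = integer(0),
                         end_bp = integer(0), n_snp = integer(0),
                         max_incidence = numeric(0))
  if (all(inc == 0)) {
    warning("no SNP is covered by any run; no islands")
    return(list(incidence = incidence, threshold = NA_real_,
                islands = emptyIsl))
  }
  threshold <- as.numeric(quantile(inc, percentile / 100))
  isl <- list()
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    pos <- map$pos_bp[i]
    ok <- inc[i] >= threshold & inc[i] > 0
    if (!any(ok)) next
    L <- length(i)
    blk <- cumsum(c(0L, as.integer(diff(pos) > max_gap_bp)))
    change <- c(TRUE, blk[-1L] != blk[-L] | ok[-1L] != ok[-L])
    starts <- which(change)
    ends <- c(starts[-1L] - 1L, L)
    keep <- ok[starts]
    if (any(keep))
      isl[[length(isl) + 1L]] <- data.frame(
        chrom = ch, start_bp = pos[starts[keep]], end_bp = pos[ends[keep]],
        n_snp = ends[keep] - starts[keep] + 1L,
        max_incidence = vapply(which(keep), function(k)
          max(inc[i][starts[k]:ends[k]]), numeric(1)))
  }
  islands <- if (length(isl)) do.call(rbind, isl) else emptyIsl
  list(incidence = incidence, threshold = threshold, islands = islands)
}
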