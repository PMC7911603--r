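#' @include AllGenerics.R
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats coef cor lm na.omit qnorm quantile
#'   rbinom rnorm runif sd setNames
#' @importFrom utils head read.table write.table packageVersion
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Pedigree of a livestock population
#'
#' Directed acyclic parent map with birth years and sexes. Unknown parents,
#' birth years and sexes are `NA`. Parents that are named but have no record
#' of their own are auto-promoted to founder records by the constructor. A
#' topological order (parents before offspring) is computed on construction
#' and cycles are a hard error.
#'
#' @slot id character, unique animal identifiers.
#' @slot sire character, sire id or `NA`.
#' @slot dam character, dam id or `NA`.
#' @slot birthYear integer, birth year or `NA`.
#' @slot sex character, `"M"`, `"F"` or `NA`.
#' @slot topo integer, permutation of `seq_along(id)` placing every parent
#'   before its offspring.
#'
#' @seealso [readPedigree()], [inbreedingCoef()], [simPedigree()]
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    sire = "character",
    dam = "character",
    birthYear = "integer",
    sex = "character",
    topo = "integer"
  )
)

.topoSortPedigree <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  # Kahn's algorithm over the parent -> offspring DAG
  indeg <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (j in seq_len(n)) {
    if (!is.na(si[j])) kids[[si[j]]] <- c(kids[[si[j]]], j)
    if (!is.na(di[j])) kids[[di[j]]] <- c(kids[[di[j]]], j)
  }
  order <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    k <- k + 1L
    order[k] <- v
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (k < n) {
    cyc <- id[indeg > 0L]
    stop("pedigree contains a cycle involving: ",
         paste(head(cyc, 10L), collapse = ", "))
  }
  order
}

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@birthYear) != n || length(object@sex) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@id))
    return(paste("duplicate animal id:",
                 object@id[duplicated(object@id)][1L]))
  bad <- !is.na(object@sire) & !(object@sire %in% object@id)
  if (any(bad)) return("sire without a pedigree record (promotion missed)")
  bad <- !is.na(object@dam) & !(object@dam %in% object@id)
  if (any(bad)) return("dam without a pedigree record (promotion missed)")
  if (any(object@sire == object@id, na.rm = TRUE) ||
      any(object@dam == object@id, na.rm = TRUE))
    return("animal recorded as its own parent")
  if (!is.na(s <- setdiff(unique(object@sex), c("M", "F", NA))[1L]))
    return(paste("invalid sex code:", s))
  TRUE
})

#' Construct a Pedigree
#'
#' @param id character vector of unique animal ids.
#' @param sire,dam character vectors of parent ids; `NA` = unknown. Parents
#'   without a row of their own are appended as founders (sex inferred from
#'   the parental role).
#' @param birth_year integer vector of birth years (`NA` allowed).
#' @param sex character vector, `"M"`/`"F"`/`NA`.
#' @return A validated [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(id = c("S", "D", "C"), sire = c(NA, NA, "S"),
#'                 dam = c(NA, NA, "D"), birth_year = c(2000, 2001, 2005),
#'                 sex = c("M", "F", "F"))
#' founders(ped)
#' @export
Pedigree <- function(id, sire = NA, dam = NA, birth_year = NA, sex = NA) {
  id <- as.character(id)
  n <- length(id)
  sire <- rep_len(as.character(sire), n)
  dam <- rep_len(as.character(dam), n)
  birth_year <- rep_len(as.integer(birth_year), n)
  sex <- rep_len(as.character(sex), n)
  # promote named-but-unrecorded parents to founders
  newS <- setdiff(sire[!is.na(sire)], id)
  newD <- setdiff(dam[!is.na(dam)], id)
  newD <- setdiff(newD, newS)
  if (length(newS) || length(newD)) {
    extra <- c(newS, newD)
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    birth_year <- c(birth_year, rep(NA_integer_, length(extra)))
    sex <- c(sex, rep(c("M", "F"), c(length(newS), length(newD))))
  }
  if (anyDuplicated(id))
    stop("duplicate animal id: ", id[duplicated(id)][1L])
  if (any(sire == id, na.rm = TRUE) || any(dam == id, na.rm = TRUE))
    stop("animal recorded as its own parent")
  topo <- .topoSortPedigree(id, sire, dam)
  new("Pedigree", id = id, sire = sire, dam = dam,
      birthYear = birth_year, sex = sex, topo = topo)
}

#' @describeIn Pedigree ids of all animals
#' @param x a `Pedigree`.
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)

#' @describeIn Pedigree number of animals
#' @export
setMethod("nAnimals", "Pedigree", function(x) length(x@id))

#' @describeIn Pedigree ids of animals with both parents unknown
#' @export
setMethod("founders", "Pedigree", function(x)
  x@id[is.na(x@sire) & is.na(x@dam)])

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  cat("Pedigree with", n, "animals |", length(founders(object)), "founders\n")
  yr <- object@birthYear
  if (any(!is.na(yr)))
    cat("  birth years:", min(yr, na.rm = TRUE), "-", max(yr, na.rm = TRUE),
        "\n")
  cat("  missing sire:", sum(is.na(object@sire)),
      "| missing dam:", sum(is.na(object@dam)), "\n")
})

#' Pedigree as a data.frame
#'
#' @param ped a [Pedigree-class] object.
#' @return `data.frame` with columns `id`, `sire`, `dam`, `birth_year`, `sex`.
#' @export
pedigreeTable <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  data.frame(id = ped@id, sire = ped@sire, dam = ped@dam,
             birth_year = ped@birthYear, sex = ped@sex,
             stringsAsFactors = FALSE)
}

#' Parent indices of a pedigree
#'
#' Integer indices of each animal's sire and dam (`NA` = unknown), plus the
#' topological order. Internal workhorse representation used by the metric
#' functions.
#' @noRd
.pedIndex <- function(ped) {
  list(si = match(ped@sire, ped@id), di = match(ped@dam, ped@id),
       topo = ped@topo, n = length(ped@id))
}

#' SNP genotypes with a marker map
#'
#' A [RangedSummarizedExperiment][SummarizedExperiment::RangedSummarizedExperiment-class]
#' holding a single `"dosage"` assay with markers in rows (a `GRanges` of SNP
#' positions, seqnames = chromosome numbers) and animals in columns. Dosages
#' count copies of the per-marker minor allele: 0/1/2 with `NA` for missing
#' calls. Markers are sorted by chromosome then position on construction.
#'
#' @seealso [readPlinkPedMap()], [qcGenotypes()], [detectROH()], [buildGRM()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!identical(SummarizedExperiment::assayNames(object), "dosage"))
    return("GenotypeData must carry exactly one assay named 'dosage'")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!all(d %in% c(0L, 1L, 2L, NA)))
    return("dosages must be 0, 1, 2 or NA")
  TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage matrix of 0/1/2 dosages (`NA` = missing) with animals in
#'   rows and markers in columns (the natural orientation of a PLINK PED
#'   file); it is stored transposed, markers x animals.
#' @param map `data.frame` with columns `snp_id`, `chrom` (integer),
#'   `pos_bp` (integer), one row per marker, matching `ncol(dosage)`.
#' @param animal_ids character vector of animal ids; defaults to
#'   `rownames(dosage)`.
#' @return A [GenotypeData-class] object with markers sorted by chromosome
#'   and position.
#' @examples
#' map <- data.frame(snp_id = c("s1", "s2"), chrom = 1L,
#'                   pos_bp = c(100L, 200L))
#' gd <- GenotypeData(rbind(a1 = c(0, 1), a2 = c(2, NA)), map)
#' dosages(gd)
#' @export
GenotypeData <- function(dosage, map, animal_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == nrow(map),
            all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
  if (is.null(animal_ids))
    animal_ids <- paste0("animal", seq_len(nrow(dosage)))
  map$chrom <- as.integer(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  o <- order(map$chrom, map$pos_bp)
  map <- map[o, , drop = FALSE]
  dup <- duplicated(map[, c("chrom", "pos_bp")])
  if (any(dup))
    stop("duplicate marker position on chromosome ", map$chrom[dup][1L])
  d <- t(dosage[, o, drop = FALSE])
  storage.mode(d) <- "integer"
  dimnames(d) <- list(map$snp_id, animal_ids)
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(map$chrom),
    ranges = IRanges::IRanges(start = map$pos_bp, width = 1L),
    snp_id = map$snp_id
  )
  names(rr) <- map$snp_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = d), rowRanges = rr,
    colData = S4Vectors::DataFrame(animal_id = animal_ids,
                                   row.names = animal_ids)
  )
  new("GenotypeData", se)
}

#' @describeIn GenotypeData animal ids (column names)
#' @param x a `GenotypeData`.
#' @export
setMethod("animalIds", "GenotypeData", function(x) colnames(x))

#' @describeIn GenotypeData number of animals
#' @export
setMethod("nAnimals", "GenotypeData", function(x) ncol(x))

#' @describeIn GenotypeData marker map as a data.frame
#' @export
setMethod("markerMap", "GenotypeData", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(snp_id = rr$snp_id,
             chrom = as.integer(as.character(GenomicRanges::seqnames(rr))),
             pos_bp = GenomicRanges::start(rr),
             stringsAsFactors = FALSE)
})

#' @describeIn GenotypeData dosage matrix, markers x animals
#' @export
setMethod("dosages", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

setMethod("show", "GenotypeData", function(object) {
  d <- dosages(object)
  cat("GenotypeData:", ncol(d), "animals x", nrow(d), "markers on",
      length(unique(markerMap(object)$chrom)), "chromosomes\n")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(d))), "\n")
})

#' Chromosome lengths from a marker map
#'
#' Length of each chromosome measured between the first and the last mapped
#' SNP, and the total autosomal length.
#'
#' @param x a [GenotypeData-class] object or a marker-map `data.frame` with
#'   `chrom` and `pos_bp` columns.
#' @return Named list: `lchr_bp`, a named vector of per-chromosome lengths in
#'   bp, and `laut_bp`, their sum.
#' @export
chromosomeLengths <- function(x) {
  map <- if (is(x, "GenotypeData")) markerMap(x) else x
  sp <- split(map$pos_bp, map$chrom)
  lchr <- vapply(sp, function(p) diff(range(p)), numeric(1))
  list(lchr_bp = lchr, laut_bp = sum(lchr))
}
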