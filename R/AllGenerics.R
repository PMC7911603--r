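#' @import methods
NULL

#' Animal identifiers of an object
#'
#' @param x a [Pedigree] or [GenotypeData] object.
#' @return Character vector of animal ids.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' Number of animals in an object
#'
#' @param x a [Pedigree] or [GenotypeData] object.
#' @return Integer scalar.
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' Marker map of a genotype object
#'
#' @param x a [GenotypeData] object.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos_bp`, sorted by
#'   chromosome and position.
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' Dosage matrix of a genotype object
#'
#' @param x a [GenotypeData] object.
#' @return Integer matrix of allele dosages (0/1/2, `NA` = missing call) with
#'   markers in rows and animals in columns.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Founder animals of a pedigree
#'
#' Founders are animals with both parents unknown.
#'
#' @param x a [Pedigree] object.
#' @return Character vector of founder animal ids.
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))
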