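#' Read a pedigree file
#'
#' Reads a CSV/TSV pedigree with columns animal, sire, dam and optionally
#' birth year and sex (matched by header name, or positionally when
#' `header = FALSE`). Unknown-parent tokens are normalised to `NA`, and named
#' parents without a record of their own are promoted to founders. Cycles and
#' duplicated ids are hard errors.
#'
#' @param path file path.
#' @param sep field separator; default `","`.
#' @param header logical; default `TRUE`.
#' @param unknown tokens denoting an unknown parent (default
#'   `c("0", "", "NA")`).
#' @param columns named character vector mapping the roles `id`, `sire`,
#'   `dam`, `birth_year`, `sex` to column names (or positions when there is
#'   no header). Defaults recognise common headers.
#' @return A [Pedigree-class] object.
#' @export
readPedigree <- function(path, sep = ",", header = TRUE,
                         unknown = c("0", "", "NA"),
                         columns = NULL) {
  stopifnot(file.exists(path))
  df <- read.table(path, sep = sep, header = header,
                   colClasses = "character", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = NULL)
  pick <- function(role, candidates, pos) {
    if (!is.null(columns) && role %in% names(columns))
      return(df[[columns[[role]]]])
    hit <- intersect(candidates, tolower(names(df)))
    if (length(hit)) return(df[[match(hit[1L], tolower(names(df)))]])
    if (!header && pos <= ncol(df)) return(df[[pos]])
    NULL
  }
  id <- pick("id", c("id", "animal", "animal_id"), 1L)
  sire <- pick("sire", c("sire", "sire_id", "father"), 2L)
  dam <- pick("dam", c("dam", "dam_id", "mother"), 3L)
  if (is.null(id) || is.null(sire) || is.null(dam))
    stop("could not identify animal/sire/dam columns in ", path)
  by <- pick("birth_year", c("birth_year", "year", "yob"), 4L)
  sex <- pick("sex", c("sex"), 5L)
  norm <- function(x) {
    x <- trimws(x)
    x[x %in% unknown] <- NA
    x
  }
  sexn <- if (is.null(sex)) NA_character_ else {
    s <- toupper(trimws(sex))
    s[s %in% c("1", "M", "MALE")] <- "M"
    s[s %in% c("2", "F", "FEMALE")] <- "F"
    s[!(s %in% c("M", "F"))] <- NA
    s
  }
  Pedigree(id = trimws(id), sire = norm(sire), dam = norm(dam),
           birth_year = if (is.null(by)) NA else
             suppressWarnings(as.integer(norm(by))),
           sex = sexn)
}

#' Write a pedigree to CSV
#'
#' Inverse of [readPedigree()]; unknown parents/years/sexes are written as
#' `"0"` so the file round-trips.
#'
#' @param ped a [Pedigree-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  df <- pedigreeTable(ped)
  for (cl in names(df)) df[[cl]][is.na(df[[cl]])] <- "0"
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PLINK text PED/MAP genotypes
#'
#' Parses the whitespace-delimited PLINK text dialect: the MAP file has
#' columns chromosome, SNP id, genetic position (cM) and bp position; the PED
#' file has six leading columns (FID, IID, sire, dam, sex, phenotype)
#' followed by two allele columns per SNP. Allele pairs are converted to
#' dosages by counting copies of the per-marker minor allele (observed
#' post-missing frequency; ties at 0.5 broken by allele lexical order);
#' `0 0` becomes a missing call.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [GenotypeData-class] object.
#' @export
readPlinkPedMap <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("MAP file must have 4 columns: ", map_path)
  names(map)[1:4] <- c("chrom", "snp_id", "cm", "pos_bp")
  nsnp <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nsnp
  nf <- lengths(toks)
  if (any(nf != want))
    stop("PED line ", which(nf != want)[1L], " has ", nf[nf != want][1L],
         " fields, expected ", want)
  m <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  ids <- m[, 2L]
  a1 <- m[, 6L + 2L * seq_len(nsnp) - 1L, drop = FALSE]
  a2 <- m[, 6L + 2L * seq_len(nsnp), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA
  a2[miss] <- NA
  dos <- matrix(NA_integer_, nrow(m), nsnp)
  for (j in seq_len(nsnp)) {
    al <- sort(unique(c(a1[, j], a2[, j])))  # drops NA
    if (!length(al)) next
    counts <- vapply(al, function(a)
      sum(a1[, j] == a, na.rm = TRUE) + sum(a2[, j] == a, na.rm = TRUE),
      numeric(1))
    # minor allele: lowest count; ties broken by lexical order (sort above)
    minor <- al[which.min(counts)]
    dos[, j] <- (a1[, j] == minor) + (a2[, j] == minor)
  }
  rownames(dos) <- ids
  GenotypeData(dos, data.frame(snp_id = as.character(map$snp_id),
                               chrom = map$chrom, pos_bp = map$pos_bp))
}

#' Write genotypes as PLINK text PED/MAP
#'
#' Dosages are written as allele pairs with `A` the minor allele (dosage
#' counts A) and `B` the major allele; missing calls become `0 0`. Reading
#' the files back with [readPlinkPedMap()] reproduces the dosage matrix
#' whenever the minor allele stays minor (always true for simulated data
#' with MAF < 0.5; at exactly 0.5 the lexical tie-break keeps `A`).
#'
#' @param gd a [GenotypeData-class] object.
#' @param ped_path,map_path output paths.
#' @param ped optional [Pedigree-class] supplying sire/dam/sex columns.
#' @return `ped_path`, invisibly.
#' @export
writePlinkPedMap <- function(gd, ped_path, map_path, ped = NULL) {
  map <- markerMap(gd)
  write.table(data.frame(map$chrom, map$snp_id, 0, map$pos_bp),
              map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  d <- t(dosages(gd))  # animals x markers
  ids <- rownames(d)
  code1 <- matrix("B", nrow(d), ncol(d))
  code2 <- matrix("B", nrow(d), ncol(d))
  code1[d >= 1] <- "A"
  code2[d == 2] <- "A"
  code1[is.na(d)] <- "0"
  code2[is.na(d)] <- "0"
  inter <- matrix("", nrow(d), 2L * ncol(d))
  inter[, seq(1L, 2L * ncol(d), 2L)] <- code1
  inter[, seq(2L, 2L * ncol(d), 2L)] <- code2
  lead <- if (is.null(ped)) {
    cbind("FAM", ids, "0", "0", "0", "-9")
  } else {
    tb <- pedigreeTable(ped)
    ix <- match(ids, tb$id)
    sx <- c(M = "1", F = "2")[tb$sex[ix]]
    cbind("FAM", ids,
          ifelse(is.na(tb$sire[ix]), "0", tb$sire[ix]),
          ifelse(is.na(tb$dam[ix]), "0", tb$dam[ix]),
          ifelse(is.na(sx), "0", sx), "-9")
  }
  writeLines(apply(cbind(lead, inter), 1L, paste, collapse = " "), ped_path)
  invisible(ped_path)
}

#' Read a phenotype table
#'
#' CSV with header columns `animal_id`, `trait`, `value` and optionally
#' `age_d`, `sex`, `birth_year`. Traits are free-form strings; the
#' depression analysis recognises `"birth_weight"` and `"weaning_weight"`.
#'
#' @param path file path.
#' @return A `data.frame` with the columns above (`age_d`, `sex`,
#'   `birth_year` filled with `NA` when absent).
#' @export
readPhenotypes <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("animal_id", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  for (cl in c("age_d", "sex", "birth_year"))
    if (is.null(df[[cl]])) df[[cl]] <- NA
  df$animal_id <- as.character(df$animal_id)
  df$value <- as.numeric(df$value)
  if (any(df$value <= 0, na.rm = TRUE))
    stop("non-positive phenotype value in ", path)
  df[, c("animal_id", "trait", "value", "age_d", "sex", "birth_year")]
}

#' Write a phenotype table
#'
#' @param pt phenotype `data.frame` as returned by [readPhenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(pt, path) {
  write.table(pt, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
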