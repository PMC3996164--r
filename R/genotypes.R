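# Genotype containers, validation, readers/writers and half-sib family grouping.
#
# Genotypes are stored as plain integer matrices (individuals x markers) with
# values 0/1/2 (count of the alternate allele) and NA for missing; rownames
# are individual ids, colnames marker names. Text formats encode missing as 9.

GENO_MISSING_TEXT <- 9L

#' Validate a genotype matrix
#'
#' Checks that `G` is an individuals-by-markers matrix of biallelic SNP
#' genotype codes: every cell is 0, 1, 2 or `NA`, there is at least one
#' individual and one marker, and row/column names are present and unique.
#'
#' @param G An integer matrix, individuals in rows, markers in columns.
#' @return `G`, invisibly, with storage mode integer.
#' @export
validate_genotypes <- function(G) {
  if (!is.matrix(G)) stop("genotypes must be a matrix (individuals x markers)")
  if (nrow(G) < 1L || ncol(G) < 1L) {
    stop("genotype matrix needs at least 1 individual and 1 marker")
  }
  storage.mode(G) <- "integer"
  bad <- !(G %in% c(0L, 1L, 2L)) & !is.na(G)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf(
      "invalid genotype code %s at individual %d, marker %d (allowed: 0, 1, 2, NA)",
      G[idx], (idx - 1L) %% nrow(G) + 1L, (idx - 1L) %/% nrow(G) + 1L
    ))
  }
  if (is.null(rownames(G))) rownames(G) <- paste0("ind", seq_len(nrow(G)))
  if (is.null(colnames(G))) colnames(G) <- paste0("m", seq_len(ncol(G)))
  if (anyDuplicated(rownames(G))) stop("duplicated individual ids in genotype matrix")
  if (anyDuplicated(colnames(G))) stop("duplicated marker names in genotype matrix")
  invisible(G)
}

#' Read a genotype matrix from a delimited text file
#'
#' The expected dialect is a header row of marker names and one row per
#' individual, first field the individual id, remaining fields genotype codes
#' 0/1/2 with 9 (or `NA`) for missing. Field separator is sniffed from the
#' header line (tab or comma) unless given.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma.
#' @param missing_code Code used for missing genotypes in the file.
#' @return A validated integer genotype matrix.
#' @export
read_genotype_matrix <- function(path, sep = NULL, missing_code = GENO_MISSING_TEXT) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("parse error: empty genotype file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  G <- suppressWarnings(vapply(raw, as.integer, integer(nrow(raw))))
  if (nrow(raw) == 1L) G <- matrix(G, nrow = 1L, dimnames = list(NULL, names(raw)))
  rownames(G) <- rownames(raw)
  nonnum <- is.na(G) & !(raw == "NA" | raw == as.character(missing_code) | is.na(as.matrix(raw)))
  if (any(nonnum)) {
    ln <- (which(nonnum)[1L] - 1L) %% nrow(G) + 1L
    stop(sprintf("parse error: non-numeric genotype on data line %d of %s", ln, path))
  }
  G[G == missing_code] <- NA_integer_
  validate_genotypes(G)
  G
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [read_genotype_matrix()]: missing genotypes are written as
#' `missing_code`.
#'
#' @param G Genotype matrix.
#' @param path Output path.
#' @param sep Field separator (`"\t"` or `","`).
#' @param missing_code Code written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(G, path, sep = "\t", missing_code = GENO_MISSING_TEXT) {
  G <- validate_genotypes(G)
  out <- G
  out[is.na(out)] <- as.integer(missing_code)
  df <- data.frame(id = rownames(G), out, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker map
#'
#' A delimited file with a header and columns `marker`, `chr`, and at least
#' one of `cm` (genetic position, centimorgan) and `bp` (physical position).
#' Positions must be non-decreasing within a chromosome.
#'
#' @param path Path to a TSV/CSV map file.
#' @return A tibble with columns `marker`, `chr`, `cm` and/or `bp`.
#' @export
read_marker_map <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  validate_marker_map(tibble::as_tibble(df))
}

#' Validate a marker map
#'
#' @param map A data frame with columns `marker`, `chr` and `cm` and/or `bp`.
#' @param markers Optional marker names that must appear exactly once, in order.
#' @return The map as a tibble, invisibly usable.
#' @export
validate_marker_map <- function(map, markers = NULL) {
  map <- tibble::as_tibble(map)
  if (!all(c("marker", "chr") %in% names(map)) || !any(c("cm", "bp") %in% names(map))) {
    stop("marker map needs columns 'marker', 'chr' and 'cm' and/or 'bp'")
  }
  if (anyDuplicated(map$marker)) stop("duplicated marker names in map")
  for (pos in intersect(c("cm", "bp"), names(map))) {
    ok <- tapply(map[[pos]], map$chr, function(x) !is.unsorted(x))
    if (!all(ok)) stop("map positions ('", pos, "') must be non-decreasing within a chromosome")
  }
  if (!is.null(markers)) {
    if (!identical(as.character(map$marker), as.character(markers))) {
      stop("map markers do not match genotype matrix markers (same set, same order required)")
    }
  }
  map
}

#' Read a pedigree table
#'
#' A delimited file with header columns `id`, `sire`, `dam`; unknown parents
#' are `0`, `NA` or empty.
#'
#' @param path Path to a TSV/CSV pedigree file.
#' @return A tibble with character columns `id`, `sire`, `dam` (`NA` unknown).
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  validate_pedigree(tibble::as_tibble(df))
}

#' Validate a pedigree table
#'
#' Individual ids must be unique and no individual may be its own ancestor.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam`.
#' @return The pedigree as a tibble with `"0"`/empty parents recoded to `NA`.
#' @export
validate_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  if (!all(c("id", "sire", "dam") %in% names(ped))) {
    stop("pedigree needs columns 'id', 'sire', 'dam'")
  }
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[ped$sire %in% c("0", "") | is.na(ped$sire)] <- NA_character_
  ped$dam[ped$dam %in% c("0", "") | is.na(ped$dam)] <- NA_character_
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  # cycle check: walk sire/dam links from each id
  parent <- rbind(
    data.frame(id = ped$id, par = ped$sire),
    data.frame(id = ped$id, par = ped$dam)
  )
  parent <- parent[!is.na(parent$par), , drop = FALSE]
  if (nrow(parent) > 0L) {
    anc <- split(parent$par, parent$id)
    for (start in names(anc)) {
      seen <- character(); frontier <- anc[[start]]
      while (length(frontier) > 0L) {
        if (start %in% frontier) stop("pedigree cycle: individual '", start, "' is its own ancestor")
        seen <- union(seen, frontier)
        frontier <- setdiff(unique(unlist(anc[frontier[frontier %in% names(anc)]])), seen)
      }
    }
  }
  ped
}

#' Construct a half-sib family
#'
#' @param sire Sire id (character scalar).
#' @param genotypes Genotype matrix restricted to that sire's offspring.
#' @return An object of class `hs_family`: a list with `sire` and `genotypes`.
#' @export
hs_family <- function(sire, genotypes) {
  genotypes <- validate_genotypes(genotypes)
  structure(list(sire = as.character(sire), genotypes = genotypes),
            class = "hs_family")
}

#' @export
print.hs_family <- function(x, ...) {
  cat(sprintf("<hs_family> sire %s: %d offspring x %d markers\n",
              x$sire, nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

# Accept either an hs_family or a bare genotype matrix in algorithm functions.
family_genotypes <- function(fam) {
  if (inherits(fam, "hs_family")) fam$genotypes else validate_genotypes(fam)
}

#' Group genotyped individuals into half-sib families
#'
#' One family is formed per distinct known sire with at least one genotyped
#' offspring. Genotyped individuals whose sire is unknown (or absent from the
#' pedigree) are excluded and reported via a message and the `"excluded"`
#' attribute.
#'
#' @param G Genotype matrix for all individuals.
#' @param ped Pedigree table (`id`, `sire`, `dam`).
#' @param min_offspring Families smaller than this are dropped (default 1).
#' @return A named list of [hs_family()] objects, named by sire id, with
#'   attribute `"excluded"` (ids of genotyped individuals with unknown sire).
#' @export
group_half_sib_families <- function(G, ped, min_offspring = 1L) {
  G <- validate_genotypes(G)
  ped <- validate_pedigree(ped)
  ids <- rownames(G)
  miss <- setdiff(ids, ped$id)
  if (length(miss) > 0L) {
    stop("genotyped individuals missing from pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  sire_of <- stats::setNames(ped$sire, ped$id)[ids]
  excluded <- ids[is.na(sire_of)]
  if (length(excluded) > 0L) {
    message(length(excluded), " genotyped individual(s) with unknown sire excluded from half-sib grouping")
  }
  keep <- ids[!is.na(sire_of)]
  fams <- split(keep, sire_of[keep])
  fams <- fams[vapply(fams, length, 1L) >= min_offspring]
  if (length(fams) == 0L) warning("no half-sib families could be formed")
  out <- lapply(names(fams), function(s) hs_family(s, G[fams[[s]], , drop = FALSE]))
  names(out) <- names(fams)
  attr(out, "excluded") <- excluded
  out
}

#' Read PLINK text PED/MAP genotypes
#'
#' Allele pairs are collapsed to 0/1/2 counts of the alternate allele. By
#' default the alternate allele at a marker is the lexicographically larger of
#' the (at most two) alleles observed there; a named character vector
#' `alt_alleles` (names = marker ids) overrides this. The PLINK missing
#' genotype `0 0` maps to `NA`; half-missing pairs are also treated as
#' missing. Markers with more than two observed alleles are an error.
#'
#' @param ped_path Path to a whitespace-delimited PED file
#'   (FID IID SIRE DAM SEX PHENO allele pairs ...).
#' @param map_path Path to the matching 4-column MAP file
#'   (chr, marker, cm, bp).
#' @param alt_alleles Optional named character vector of alternate alleles.
#' @return A list with `genotypes` (integer matrix), `map` (tibble) and
#'   `pedigree` (tibble `id`, `sire`, `dam`).
#' @export
read_plink <- function(ped_path, map_path, alt_alleles = NULL) {
  map_raw <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map_raw) < 4L) stop("MAP file must have 4 columns: chr, marker, cm, bp")
  map <- tibble::tibble(marker = as.character(map_raw[[2L]]),
                        chr = as.character(map_raw[[1L]]),
                        cm = as.numeric(map_raw[[3L]]),
                        bp = as.numeric(map_raw[[4L]]))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: empty PED file: ", ped_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  len <- vapply(fields, length, 1L)
  if (any(len != want)) {
    stop(sprintf("parse error: PED line %d has %d fields, expected %d",
                 which(len != want)[1L], len[len != want][1L], want))
  }
  ped_mat <- do.call(rbind, fields)
  ids <- ped_mat[, 2L]
  a1 <- ped_mat[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped_mat[, 6L + 2L * seq_len(m), drop = FALSE]
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  G <- matrix(NA_integer_, nrow = length(ids), ncol = m,
              dimnames = list(ids, map$marker))
  for (j in seq_len(m)) {
    obs <- unique(stats::na.omit(c(a1[, j], a2[, j])))
    if (length(obs) > 2L) {
      stop("non-biallelic marker '", map$marker[j], "': alleles ",
           paste(sort(obs), collapse = "/"))
    }
    alt <- if (!is.null(alt_alleles) && map$marker[j] %in% names(alt_alleles)) {
      alt_alleles[[map$marker[j]]]
    } else if (length(obs) > 0L) {
      max(obs)  # lexicographically larger observed allele
    } else {
      NA_character_
    }
    cnt <- (a1[, j] == alt) + (a2[, j] == alt)
    cnt[is.na(a1[, j]) | is.na(a2[, j])] <- NA_integer_
    G[, j] <- as.integer(cnt)
  }
  pedigree <- tibble::tibble(id = ids, sire = ped_mat[, 3L], dam = ped_mat[, 4L])
  list(genotypes = validate_genotypes(G),
       map = validate_marker_map(map),
       pedigree = validate_pedigree(pedigree))
}

#' Read genotypes from any supported format
#'
#' Convenience front end: `format = "matrix"` reads a delimited genotype
#' matrix ([read_genotype_matrix()]); `format = "ped"` reads a PLINK PED/MAP
#' pair ([read_plink()]) and returns just the genotype matrix with the map and
#' pedigree attached as attributes `"map"` and `"pedigree"`. `"auto"` picks
#' `"ped"` for `.ped` paths.
#'
#' @param path Path to the genotype file (PED file for `format = "ped"`).
#' @param format One of `"auto"`, `"matrix"`, `"ped"`.
#' @param map_path MAP file path (defaults to `path` with a `.map` extension).
#' @param ... Passed to the format-specific reader.
#' @return A validated integer genotype matrix.
#' @export
read_genotypes <- function(path, format = c("auto", "matrix", "ped"),
                           map_path = NULL, ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ped$", path, ignore.case = TRUE)) "ped" else "matrix"
  }
  if (format == "matrix") return(read_genotype_matrix(path, ...))
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path, ignore.case = TRUE)
  pl <- read_plink(path, map_path, ...)
  G <- pl$genotypes
  attr(G, "map") <- pl$map
  attr(G, "pedigree") <- pl$pedigree
  G
}
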