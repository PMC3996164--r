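# Writers/readers for phased haplotypes (TSV, VCF), block matrices and
# recombination events.

#' Write phased haplotypes
#'
#' Two dialects:
#'
#' * `"tsv"`: a header of marker names, then two rows per individual
#'   (`<id> paternal ...` and `<id> maternal ...`) with alleles 0/1 and `"."`
#'   for unphased.
#' * `"vcf"`: VCFv4.2 with one sample column per individual and a phased GT
#'   (`paternal|maternal`), `"."` for an unphased allele. Synthetic REF/ALT
#'   alleles A/B are written unless the `map` carries `ref`/`alt` columns;
#'   positions come from `map$bp` (or the marker index).
#'
#' Both dialects round-trip exactly through [read_phased_tsv()] /
#' [read_phased_vcf()].
#'
#' @param phased An `hs_phased` object (or `hs_phase_result`).
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param map Optional marker map (used for VCF CHROM/POS).
#' @return `path`, invisibly.
#' @export
write_phased_output <- function(phased, path, format = c("tsv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (inherits(phased, "hs_phase_result")) phased <- phased$phased
  if (!inherits(phased, "hs_phased")) stop("`phased` must come from phase_family() or hs_phase()")
  pat <- phased$paternal
  mat <- phased$maternal
  ids <- rownames(pat)
  markers <- colnames(pat)
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("id", "haplotype", markers), collapse = "\t"), con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], "paternal", dot(pat[i, ])), collapse = "\t"), con)
      writeLines(paste(c(ids[i], "maternal", dot(mat[i, ])), collapse = "\t"), con)
    }
    return(invisible(path))
  }
  # VCF
  if (!is.null(map)) map <- validate_marker_map(map, markers = markers)
  chrom <- if (!is.null(map)) as.character(map$chr) else rep("1", length(markers))
  posn <- if (!is.null(map) && "bp" %in% names(map)) as.integer(map$bp) else seq_along(markers)
  ref <- if (!is.null(map) && "ref" %in% names(map)) map$ref else rep("A", length(markers))
  alt <- if (!is.null(map) && "alt" %in% names(map)) map$alt else rep("B", length(markers))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sibphase",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype (paternal|maternal)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  for (j in seq_along(markers)) {
    gt <- paste0(dot(pat[, j]), "|", dot(mat[, j]))
    writeLines(paste(c(chrom[j], posn[j], markers[j], ref[j], alt[j], ".", ".",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read phased haplotypes written by [write_phased_output()]
#'
#' @param path Path to the TSV or VCF file.
#' @return An `hs_phased` object (`paternal`, `maternal` allele matrices).
#' @export
read_phased_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (!identical(names(df)[1:2], c("id", "haplotype"))) {
    stop("not a phased-haplotype TSV: expected columns 'id', 'haplotype', markers...")
  }
  markers <- names(df)[-(1:2)]
  ids <- unique(df$id)
  parse_rows <- function(which_hap) {
    sub <- df[df$haplotype == which_hap, , drop = FALSE]
    A <- as.matrix(sub[, -(1:2), drop = FALSE])
    A[A == "."] <- NA_character_
    out <- matrix(as.integer(A), nrow(sub), length(markers),
                  dimnames = list(sub$id, markers))
    out[ids, , drop = FALSE]
  }
  structure(list(paternal = parse_rows("paternal"),
                 maternal = parse_rows("maternal"),
                 inconsistent = tibble::tibble(offspring = character(),
                                               marker_index = integer(),
                                               marker = character())),
            class = "hs_phased")
}

#' @rdname read_phased_tsv
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  recs <- strsplit(body, "\t", fixed = TRUE)
  markers <- vapply(recs, `[[`, "", 3L)
  parse_allele <- function(x) {
    x[x == "."] <- NA_character_
    as.integer(x)
  }
  pat <- matrix(NA_integer_, length(ids), length(markers),
                dimnames = list(ids, markers))
  mat <- pat
  for (j in seq_along(recs)) {
    gt <- recs[[j]][-(1:9)]
    parts <- strsplit(gt, "|", fixed = TRUE)
    pat[, j] <- parse_allele(vapply(parts, `[[`, "", 1L))
    mat[, j] <- parse_allele(vapply(parts, `[[`, "", 2L))
  }
  structure(list(paternal = pat, maternal = mat,
                 inconsistent = tibble::tibble(offspring = character(),
                                               marker_index = integer(),
                                               marker = character())),
            class = "hs_phased")
}

#' Write a block matrix as CSV (codes P/M/U)
#'
#' @param B Integer block matrix or `hs_blocks` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_matrix <- function(B, path) {
  if (inherits(B, "hs_blocks")) B <- B$blocks
  chr <- block_codes_to_char(B)
  df <- data.frame(id = rownames(B), chr, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a block matrix CSV written by [write_block_matrix()]
#'
#' @param path Path to the CSV.
#' @return Integer block matrix (0 = U, 1 = P, 2 = M).
#' @export
read_block_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", row.names = 1L,
                          check.names = FALSE, colClasses = "character")
  block_codes_to_int(as.matrix(df))
}

#' Write recombination events as BED-like TSV
#'
#' Half-open intervals between the flanking informative markers:
#' columns chrom, start, end, offspring, change (e.g. `P>M`). With a map the
#' start/end are the flanking markers' bp (or cM) positions; otherwise marker
#' indices are used.
#'
#' @param events Events tibble from [block_partition()].
#' @param path Output path.
#' @param map Optional marker map.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, map = NULL) {
  if (inherits(events, "hs_blocks")) events <- events$events
  if (is.null(map)) {
    chrom <- rep("1", nrow(events))
    start <- events$left
    end <- events$right
  } else {
    map <- validate_marker_map(map)
    poscol <- if ("bp" %in% names(map)) "bp" else "cm"
    idx <- match(events$left_marker, map$marker)
    jdx <- match(events$right_marker, map$marker)
    chrom <- as.character(map$chr[idx])
    start <- map[[poscol]][idx]
    end <- map[[poscol]][jdx]
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   offspring = events$offspring,
                   change = paste0(events$from, ">", events$to))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
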