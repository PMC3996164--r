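# Sire haplotype/genotype imputation from the block structure, and phasing of
# the half-sib offspring by subtraction.

#' Impute the sire's haplotypes and genotype from offspring blocks
#'
#' For each marker and each sire strand, the offspring assigned to that strand
#' vote for the strand's allele. Two voting rules are available:
#'
#' * `method = "hom"` (default): only offspring *homozygous* at the marker
#'   vote — their paternal allele is their genotype divided by two, with no
#'   ambiguity. The allele is the rounded mean of these votes.
#' * `method = "mean"`: the raw genotype codes of all non-missing offspring on
#'   the strand are averaged; the allele is 0 when the mean is below 0.5 and 1
#'   when above (means above 1 therefore clip to 1).
#'
#' Under either rule a strand's allele is missing when no offspring on the
#' strand can vote or the vote ties exactly; the default rule is robust to the
#' maternal allele frequency, while `"mean"` follows the simple
#' genotype-averaging description literally (see the methods vignette for why
#' the default differs). Loci where offspring on one strand carry both
#' homozygote codes are reported in `low_confidence`. Loci that the opposing-
#' homozygote rule proves sire-heterozygous but where both imputed alleles
#' agree are reported in `conflicts` and set missing. The sire genotype is the
#' sum of the two strand alleles where both are known.
#'
#' @param fam An [hs_family()] or genotype matrix.
#' @param B Block matrix from [block_partition()] (an `hs_blocks` object or
#'   its integer matrix).
#' @param method Voting rule, `"hom"` or `"mean"`.
#' @return An object of class `hs_sire`: list with `hapP`, `hapM` (0/1/NA
#'   allele vectors over markers), `genotype` (0/1/2/NA), `support` (2 x
#'   markers matrix of contributing-offspring counts), `low_confidence` and
#'   `conflicts` (tibbles of markers).
#' @export
impute_sire <- function(fam, B, method = c("hom", "mean")) {
  method <- match.arg(method)
  G <- family_genotypes(fam)
  if (inherits(B, "hs_blocks")) B <- B$blocks
  if (!identical(dim(G), dim(B))) stop("genotype and block matrices must have the same shape")
  m <- ncol(G)
  markers <- colnames(G)

  hom <- !is.na(G) & G != 1L
  allele_of <- function(sel) {
    # sel: logical matrix of offspring cells voting for one strand
    if (method == "hom") {
      vote <- sel & hom
      val <- G / 2
    } else {
      vote <- sel & !is.na(G)
      val <- G
    }
    val0 <- val; val0[!vote] <- 0
    nvote <- colSums(vote)
    s <- colSums(val0 * vote)
    mu <- ifelse(nvote > 0L, s / nvote, NA_real_)
    allele <- ifelse(is.na(mu) | mu == 0.5, NA_integer_,
                     ifelse(mu < 0.5, 0L, 1L))
    # contradiction: both homozygote codes among this strand's offspring
    contra <- colSums(sel & !is.na(G) & G == 0L) > 0L &
      colSums(sel & !is.na(G) & G == 2L) > 0L
    list(allele = as.integer(allele), n = nvote, contra = contra)
  }

  aP <- allele_of(B == 1L)
  aM <- allele_of(B == 2L)
  hapP <- aP$allele; hapM <- aM$allele
  names(hapP) <- names(hapM) <- markers

  het <- find_sire_het_loci(G)
  conflict <- het & !is.na(hapP) & !is.na(hapM) & hapP == hapM
  hapP[conflict] <- NA_integer_
  hapM[conflict] <- NA_integer_

  genotype <- hapP + hapM
  support <- rbind(P = aP$n, M = aM$n)
  colnames(support) <- markers
  low_conf <- which(aP$contra | aM$contra)

  structure(list(
    hapP = hapP, hapM = hapM, genotype = genotype, support = support,
    low_confidence = tibble::tibble(marker_index = unname(low_conf),
                                    marker = markers[low_conf]),
    conflicts = tibble::tibble(marker_index = unname(which(conflict)),
                               marker = markers[conflict]),
    method = method
  ), class = "hs_sire")
}

#' @export
print.hs_sire <- function(x, ...) {
  cat(sprintf("<hs_sire> %d markers; %.1f%% imputed (method '%s'); %d conflict(s), %d low-confidence locus/loci\n",
              length(x$genotype), 100 * percent_imputed(x), x$method,
              nrow(x$conflicts), nrow(x$low_confidence)))
  invisible(x)
}

#' Fraction of markers with an imputed sire genotype
#'
#' @param s An `hs_sire` object from [impute_sire()].
#' @return Fraction in `[0, 1]` of loci with a non-missing imputed genotype.
#' @export
percent_imputed <- function(s) {
  g <- if (inherits(s, "hs_sire")) s$genotype else s
  if (length(g) == 0L) return(0)
  mean(!is.na(g))
}

#' Phase a half-sib family from its blocks and imputed sire
#'
#' The block code of each offspring cell is replaced by the corresponding sire
#' strand allele, giving the paternal haplotype; the maternal haplotype is the
#' genotype minus the paternal allele. Cells where the difference is not a
#' valid allele (0/1) indicate a genotyping error or wrong block and are left
#' missing and recorded in `inconsistent`.
#'
#' @param fam An [hs_family()] or genotype matrix.
#' @param B Block matrix, normally passed through [fill_uncertain_codes()]
#'   first (an `hs_blocks` object is filled automatically with defaults).
#' @param sire An `hs_sire` object from [impute_sire()].
#' @return An object of class `hs_phased`: list with `paternal` and `maternal`
#'   (offspring x marker allele matrices, 0/1/NA) and `inconsistent` (tibble
#'   of cells where genotype minus paternal allele was not 0/1).
#' @export
phase_family <- function(fam, B, sire) {
  G <- family_genotypes(fam)
  if (inherits(B, "hs_blocks")) B <- fill_uncertain_codes(B)
  if (!identical(dim(G), dim(B))) stop("genotype and block matrices must have the same shape")
  if (!inherits(sire, "hs_sire")) stop("`sire` must come from impute_sire()")
  if (length(sire$hapP) != ncol(G)) stop("sire haplotypes and genotypes disagree on marker count")

  jj <- col(B)
  pat <- matrix(NA_integer_, nrow(G), ncol(G), dimnames = dimnames(G))
  selP <- B == 1L
  selM <- B == 2L
  pat[selP] <- sire$hapP[jj[selP]]
  pat[selM] <- sire$hapM[jj[selM]]

  mat <- G - pat
  bad <- !is.na(mat) & (mat < 0L | mat > 1L)
  mat[bad] <- NA_integer_
  badidx <- which(bad, arr.ind = TRUE)
  inconsistent <- tibble::tibble(
    offspring = rownames(G)[badidx[, 1L]],
    marker_index = unname(badidx[, 2L]),
    marker = colnames(G)[badidx[, 2L]]
  )
  structure(list(paternal = pat, maternal = mat, inconsistent = inconsistent),
            class = "hs_phased")
}

#' @export
print.hs_phased <- function(x, ...) {
  cat(sprintf("<hs_phased> %d offspring x %d markers; %.1f%% of paternal alleles phased; %d inconsistent cell(s)\n",
              nrow(x$paternal), ncol(x$paternal),
              100 * mean(!is.na(x$paternal)), nrow(x$inconsistent)))
  invisible(x)
}

#' Run the full half-sib phasing pipeline on one family
#'
#' Convenience wrapper: block partitioning, gap filling, sire imputation and
#' offspring phasing in one call. With a multi-chromosome `map`, each
#' chromosome is processed independently and the results are stitched back
#' together in marker order.
#'
#' @param fam An [hs_family()] or genotype matrix.
#' @param map Optional marker map (tibble with `marker`, `chr`); `NULL` treats
#'   all markers as one chromosome.
#' @inheritParams block_partition
#' @inheritParams impute_sire
#' @param end_fill Passed to [fill_uncertain_codes()].
#' @return An object of class `hs_phase_result`: list with `blocks`
#'   (`hs_blocks`), `filled` (filled block matrix), `sire` (`hs_sire`),
#'   `phased` (`hs_phased`) and `family`.
#' @export
hs_phase <- function(fam, map = NULL, window = 30L, confirm = 3L,
                     method = c("hom", "mean"), end_fill = TRUE) {
  method <- match.arg(method)
  G <- family_genotypes(fam)
  sire_id <- if (inherits(fam, "hs_family")) fam$sire else NA_character_
  chrs <- if (is.null(map)) {
    rep("1", ncol(G))
  } else {
    map <- validate_marker_map(map, markers = colnames(G))
    as.character(map$chr)
  }
  pieces <- lapply(unique(chrs), function(ch) {
    Gc <- G[, chrs == ch, drop = FALSE]
    b <- block_partition(Gc, window = window, confirm = confirm)
    filled <- fill_uncertain_codes(b$blocks, end_fill = end_fill)
    s <- impute_sire(Gc, b$blocks, method = method)
    p <- phase_family(Gc, filled, s)
    list(b = b, filled = filled, s = s, p = p, chr = ch)
  })
  if (length(pieces) == 1L) {
    pc <- pieces[[1L]]
    res <- list(blocks = pc$b, filled = pc$filled, sire = pc$s,
                phased = pc$p, family = fam)
  } else {
    blocks <- do.call(cbind, lapply(pieces, function(pc) pc$b$blocks))
    filled <- do.call(cbind, lapply(pieces, function(pc) pc$filled))
    # restore original marker order
    ord <- match(colnames(G), colnames(blocks))
    comb_blocks <- structure(list(
      blocks = blocks[, ord, drop = FALSE],
      events = dplyr::bind_rows(lapply(pieces, function(pc) {
        dplyr::mutate(pc$b$events, chr = pc$chr)
      })),
      flagged = dplyr::bind_rows(lapply(pieces, function(pc) {
        dplyr::mutate(pc$b$flagged, chr = pc$chr)
      })),
      informative = unlist(lapply(pieces, function(pc) pc$b$informative))[ord]
    ), class = "hs_blocks")
    sire <- structure(list(
      hapP = unlist(lapply(pieces, function(pc) pc$s$hapP))[ord],
      hapM = unlist(lapply(pieces, function(pc) pc$s$hapM))[ord],
      genotype = unlist(lapply(pieces, function(pc) pc$s$genotype))[ord],
      support = do.call(cbind, lapply(pieces, function(pc) pc$s$support))[, ord, drop = FALSE],
      low_confidence = dplyr::bind_rows(lapply(pieces, function(pc) pc$s$low_confidence)),
      conflicts = dplyr::bind_rows(lapply(pieces, function(pc) pc$s$conflicts)),
      method = method
    ), class = "hs_sire")
    pat <- do.call(cbind, lapply(pieces, function(pc) pc$p$paternal))[, ord, drop = FALSE]
    mat <- do.call(cbind, lapply(pieces, function(pc) pc$p$maternal))[, ord, drop = FALSE]
    phased <- structure(list(
      paternal = pat, maternal = mat,
      inconsistent = dplyr::bind_rows(lapply(pieces, function(pc) pc$p$inconsistent))
    ), class = "hs_phased")
    res <- list(blocks = comb_blocks, filled = filled[, ord, drop = FALSE],
                sire = sire, phased = phased, family = fam)
  }
  res$sire_id <- sire_id
  class(res) <- "hs_phase_result"
  res
}

#' @export
print.hs_phase_result <- function(x, ...) {
  cat("<hs_phase_result>\n")
  print(x$blocks)
  print(x$sire)
  print(x$phased)
  invisible(x)
}
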