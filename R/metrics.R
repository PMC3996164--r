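# Evaluation statistics: orientation-matched R-squared, switch error rate,
# block accuracy, imputation yield and the random-phasing baseline.

#' Orientation-matched haplotype R-squared
#'
#' Squared product-moment correlation between a predicted haplotype pair and
#' the true pair for one individual, maximised over the two possible pairings
#' of the arbitrarily labelled strands. The two haplotypes are concatenated
#' into a single allele vector; positions missing in the prediction (or the
#' truth) are omitted first.
#'
#' @param pred_p,pred_m Predicted paternal/maternal allele vectors (0/1/NA).
#' @param true_p,true_m True allele vectors.
#' @return The maximal squared correlation, or `NA` if fewer than two usable
#'   positions remain or the retained predicted alleles are constant.
#' @export
r2_haplotypes <- function(pred_p, pred_m, true_p, true_m) {
  if (length(pred_p) != length(true_p) || length(pred_m) != length(true_m)) {
    stop("predicted and true haplotypes must have equal length")
  }
  pred <- c(pred_p, pred_m)
  t1 <- c(true_p, true_m)
  t2 <- c(true_m, true_p)
  r2_pair <- function(truth) {
    keep <- !is.na(pred) & !is.na(truth)
    if (sum(keep) < 2L) return(NA_real_)
    x <- pred[keep]; y <- truth[keep]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }
  r <- c(r2_pair(t1), r2_pair(t2))
  if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
}

#' Switch error rate of a phased individual
#'
#' Computed over loci heterozygous in the truth and phased heterozygous in the
#' prediction: the number of adjacent pairs of such loci whose relative phase
#' flips between prediction and truth, divided by (number of such loci - 1).
#' Counting flips makes the statistic invariant to a global strand swap.
#'
#' @inheritParams r2_haplotypes
#' @return Switch error rate in `[0, 1]`, or `NA` with fewer than 2 usable loci.
#' @export
switch_error_rate <- function(pred_p, pred_m, true_p, true_m) {
  use <- !is.na(true_p) & !is.na(true_m) & true_p != true_m &
    !is.na(pred_p) & !is.na(pred_m) & pred_p != pred_m
  if (sum(use) < 2L) return(NA_real_)
  agree <- pred_p[use] == true_p[use]
  sum(diff(agree) != 0L) / (sum(use) - 1L)
}

#' Fraction of truth-heterozygous loci with a phased paternal allele
#'
#' @inheritParams r2_haplotypes
#' @return Fraction in `[0, 1]`, or `NA` if the truth has no heterozygous loci.
#' @export
percent_het_phased <- function(pred_p, true_p, true_m) {
  het <- !is.na(true_p) & !is.na(true_m) & true_p != true_m
  if (!any(het)) return(NA_real_)
  mean(!is.na(pred_p[het]))
}

#' Fraction of phased heterozygous loci phased correctly
#'
#' Per-site concordance at loci heterozygous in the truth and phased
#' heterozygous in the prediction, after matching the individual's strand
#' orientation (the labelling of P/M is arbitrary, so the orientation giving
#' the higher concordance is taken).
#'
#' @inheritParams r2_haplotypes
#' @return Fraction in `[0.5, 1]` typically, or `NA` with no usable loci.
#' @export
percent_het_correct <- function(pred_p, pred_m, true_p, true_m) {
  use <- !is.na(true_p) & !is.na(true_m) & true_p != true_m &
    !is.na(pred_p) & !is.na(pred_m) & pred_p != pred_m
  if (!any(use)) return(NA_real_)
  agree <- mean(pred_p[use] == true_p[use])
  max(agree, 1 - agree)
}

#' Block-detection R-squared against the true strand matrix
#'
#' Strand codes are encoded 0/1 (P/M); unknown cells in the predicted matrix
#' are omitted; the squared product-moment correlation over all retained cells
#' of the family is maximised over a global P/M relabelling of the prediction
#' (a family shares one sire orientation).
#'
#' @param B Predicted integer block matrix (0 = U, 1 = P, 2 = M) or an
#'   `hs_blocks` object.
#' @param truthB True strand-origin matrix, same shape and coding.
#' @return Squared correlation, or `NA` with fewer than two retained cells or
#'   constant retained codes.
#' @export
block_r2 <- function(B, truthB) {
  if (inherits(B, "hs_blocks")) B <- B$blocks
  if (!identical(dim(B), dim(truthB))) stop("block matrices must have the same shape")
  keep <- B != 0L & truthB != 0L
  if (sum(keep) < 2L) return(NA_real_)
  x <- as.numeric(B[keep]) - 1
  y <- as.numeric(truthB[keep]) - 1
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  r2 <- stats::cor(x, y)^2
  # global relabelling flips the sign of the correlation, so the squared
  # value is already orientation-matched
  r2
}

#' Random-phasing baseline R-squared
#'
#' Phases every heterozygous genotype by a fair coin (homozygotes are
#' deterministic) and computes the mean orientation-matched haplotype
#' R-squared against the truth, averaged over individuals and repeats. This is
#' the floor any real phasing method must beat.
#'
#' @param G Genotype matrix (offspring x markers).
#' @param true_p,true_m True paternal/maternal allele matrices, same shape.
#' @param repeats Number of random phasings to average over.
#' @return Mean R-squared across repeats.
#' @export
random_phase_baseline <- function(G, true_p, true_m, repeats = 100L) {
  G <- family_genotypes(G)
  if (repeats < 1L) stop("repeats must be >= 1")
  n <- nrow(G)
  het <- !is.na(G) & G == 1L
  base_p <- G / 2L
  base_p[het] <- NA_real_
  vapply(seq_len(repeats), function(rep) {
    pat <- base_p
    pat[het] <- stats::rbinom(sum(het), 1L, 0.5)
    mat <- G - pat
    mean(vapply(seq_len(n), function(i) {
      r2_haplotypes(pat[i, ], mat[i, ], true_p[i, ], true_m[i, ])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1)) |> mean(na.rm = TRUE)
}

#' Evaluate a phased family against simulator truth
#'
#' Computes the family-level accuracy statistics used throughout the package:
#' block R-squared and assignment rate, sire-imputation R-squared and yield,
#' mean offspring haplotype R-squared, mean switch error rate, and the
#' fraction of heterozygous sites phased / phased correctly.
#'
#' @param result An `hs_phase_result` from [hs_phase()].
#' @param truth A list with elements `origin` (true strand matrix, codes 1/2),
#'   `paternal`, `maternal` (true offspring allele matrices) and
#'   `sire_genotype` (true sire genotype vector), as produced per family by
#'   [sim_population()].
#' @return A one-row tibble with columns `block_r2`, `pct_assigned`,
#'   `sire_r2`, `pct_imputed`, `phase_r2`, `swr`, `pct_het_phased`,
#'   `pct_het_correct`, `n_offspring`, `n_events`.
#' @export
evaluate_phasing <- function(result, truth) {
  if (!inherits(result, "hs_phase_result")) stop("`result` must come from hs_phase()")
  B <- result$blocks$blocks
  n <- nrow(B)
  pat <- result$phased$paternal
  mat <- result$phased$maternal
  per_ind <- function(f) {
    vapply(seq_len(n), function(i) {
      f(pat[i, ], mat[i, ], truth$paternal[i, ], truth$maternal[i, ])
    }, numeric(1))
  }
  imp <- !is.na(result$sire$genotype)
  sire_r2 <- if (sum(imp) >= 2L &&
                 stats::var(result$sire$genotype[imp]) > 0 &&
                 stats::var(truth$sire_genotype[imp]) > 0) {
    stats::cor(result$sire$genotype[imp], truth$sire_genotype[imp])^2
  } else {
    NA_real_
  }
  tibble::tibble(
    block_r2 = block_r2(B, truth$origin),
    pct_assigned = mean(B != 0L),
    sire_r2 = sire_r2,
    sire_hap_r2 = r2_haplotypes(result$sire$hapP, result$sire$hapM,
                                truth$sire_hap1, truth$sire_hap2),
    pct_imputed = percent_imputed(result$sire),
    phase_r2 = mean(per_ind(r2_haplotypes), na.rm = TRUE),
    swr = mean(per_ind(switch_error_rate), na.rm = TRUE),
    pct_het_phased = mean(vapply(seq_len(n), function(i) {
      percent_het_phased(pat[i, ], truth$paternal[i, ], truth$maternal[i, ])
    }, numeric(1)), na.rm = TRUE),
    pct_het_correct = mean(per_ind(percent_het_correct), na.rm = TRUE),
    n_offspring = n,
    n_events = nrow(result$blocks$events)
  )
}
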