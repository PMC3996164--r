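# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a block partition
#'
#' Returns the recombination events, one row per accepted event.
#'
#' @param x An `hs_blocks` object.
#' @param ... Unused.
#' @return A tibble (see [block_partition()]).
#' @method tidy hs_blocks
#' @export
tidy.hs_blocks <- function(x, ...) x$events

#' @rdname tidy.hs_blocks
#' @method glance hs_blocks
#' @export
glance.hs_blocks <- function(x, ...) {
  tibble::tibble(
    n_offspring = nrow(x$blocks),
    n_markers = ncol(x$blocks),
    n_informative = sum(x$informative),
    n_events = nrow(x$events),
    n_flagged = nrow(x$flagged),
    pct_assigned = mean(x$blocks != 0L)
  )
}

#' Tidy an imputed sire
#'
#' One row per marker with the imputed strand alleles, genotype and the number
#' of offspring supporting each strand.
#'
#' @param x An `hs_sire` object.
#' @param ... Unused.
#' @return A tibble with columns `marker`, `hapP`, `hapM`, `genotype`,
#'   `support_P`, `support_M`.
#' @method tidy hs_sire
#' @export
tidy.hs_sire <- function(x, ...) {
  tibble::tibble(
    marker = names(x$genotype),
    hapP = unname(x$hapP),
    hapM = unname(x$hapM),
    genotype = unname(x$genotype),
    support_P = unname(x$support["P", ]),
    support_M = unname(x$support["M", ])
  )
}

#' @rdname tidy.hs_sire
#' @method glance hs_sire
#' @export
glance.hs_sire <- function(x, ...) {
  tibble::tibble(
    n_markers = length(x$genotype),
    pct_imputed = percent_imputed(x),
    n_conflicts = nrow(x$conflicts),
    n_low_confidence = nrow(x$low_confidence),
    method = x$method
  )
}

#' Tidy a full phasing result
#'
#' One row per offspring with its recombination count and phasing yield.
#'
#' @param x An `hs_phase_result` from [hs_phase()].
#' @param ... Unused.
#' @return A tibble with columns `offspring`, `n_recombinations`,
#'   `pct_assigned`, `pct_phased`.
#' @method tidy hs_phase_result
#' @export
tidy.hs_phase_result <- function(x, ...) {
  B <- x$blocks$blocks
  tibble::tibble(
    offspring = rownames(B),
    n_recombinations = unname(recombination_counts(B)),
    pct_assigned = rowMeans(B != 0L),
    pct_phased = rowMeans(!is.na(x$phased$paternal))
  )
}

#' @rdname tidy.hs_phase_result
#' @method glance hs_phase_result
#' @export
glance.hs_phase_result <- function(x, ...) {
  tibble::tibble(
    sire = x$sire_id,
    n_offspring = nrow(x$blocks$blocks),
    n_markers = ncol(x$blocks$blocks),
    n_events = nrow(x$blocks$events),
    n_flagged = nrow(x$blocks$flagged),
    pct_assigned = mean(x$blocks$blocks != 0L),
    pct_imputed = percent_imputed(x$sire),
    pct_phased = mean(!is.na(x$phased$paternal))
  )
}
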