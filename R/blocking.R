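# Sire-strand block partitioning via the forward memory vector (FMV) walk.
#
# Strand codes are stored as integers: 0 = U (unknown), 1 = P, 2 = M. The P/M
# labels are arbitrary per chromosome; they distinguish the sire's two strands,
# not grand-parental origin.

BLOCK_CODES <- c(U = 0L, P = 1L, M = 2L)

#' Convert between integer and character strand codes
#'
#' Block matrices are integer matrices with 0 = unknown, 1/2 = the two sire
#' strands. `block_codes_to_char()` maps them to `"U"`, `"P"`, `"M"` (text
#' export); `block_codes_to_int()` is the inverse.
#'
#' @param B Integer (or character) block matrix.
#' @return A matrix of the other representation.
#' @export
block_codes_to_char <- function(B) {
  out <- matrix(c("U", "P", "M")[as.integer(B) + 1L], nrow(B), ncol(B),
                dimnames = dimnames(B))
  out
}

#' @rdname block_codes_to_char
#' @export
block_codes_to_int <- function(B) {
  out <- matrix(match(B, c("U", "P", "M")) - 1L, nrow(B), ncol(B),
                dimnames = dimnames(B))
  storage.mode(out) <- "integer"
  out
}

#' Find loci where the sire must be heterozygous
#'
#' A marker is informative for a half-sib family when both homozygote codes
#' (0 and 2) occur among the non-missing offspring genotypes: the two opposing
#' homozygotes must have received different paternal alleles, so the sire is
#' heterozygous there.
#'
#' @param fam An [hs_family()] or a genotype matrix.
#' @return Logical vector over markers, `TRUE` at sire-heterozygous loci.
#' @export
find_sire_het_loci <- function(fam) {
  G <- family_genotypes(fam)
  has0 <- colSums(!is.na(G) & G == 0L) > 0L
  has2 <- colSums(!is.na(G) & G == 2L) > 0L
  stats::setNames(has0 & has2, colnames(G))
}

#' Opposing-homozygote recombination test for a pair of half-sibs
#'
#' At two sire-heterozygous loci, a recombination between the loci in one of
#' two half-sibs is implied exactly when the sum of the four homozygous
#' genotype codes is 2 or 6 — i.e. the pair opposes at exactly one of the two
#' loci.
#'
#' @param gA,gB Length-2 genotype vectors (codes 0 or 2) for the two
#'   half-sibs at the two loci.
#' @return `TRUE` if the genotypes imply a recombination between the loci.
#' @export
pair_recombination <- function(gA, gB) {
  g <- c(gA, gB)
  if (length(g) != 4L || anyNA(g) || !all(g %in% c(0L, 2L))) {
    stop("pair_recombination needs four homozygous genotypes (codes 0 or 2)")
  }
  sum(g) %in% c(2L, 6L)
}

#' Count strand switches between two strand-code vectors
#'
#' Positions where either vector is unknown are ignored.
#'
#' @param fmv,v Strand-code vectors (integer 0/1/2 or character U/P/M) of
#'   equal length.
#' @return Integer count of positions where both codes are known and differ.
#' @export
count_strand_switches <- function(fmv, v) {
  if (is.character(fmv)) fmv <- match(fmv, c("U", "P", "M")) - 1L
  if (is.character(v)) v <- match(v, c("U", "P", "M")) - 1L
  if (length(fmv) != length(v)) stop("strand-code vectors must have equal length")
  sum(fmv != 0L & v != 0L & fmv != v)
}

# internal: switches between two integer code vectors (no coercion)
n_switches <- function(a, b) sum(a != 0L & b != 0L & a != b)

# internal: greedy switch cost of continuing the walk with candidate `v`
# applied, over the next `depth` informative loci.
lookahead_cost <- function(v, j, fmv, isP, isM, k, depth = 10L) {
  f <- fmv
  f[v != 0L] <- v[v != 0L]
  total <- 0L
  end <- min(j + depth, k)
  jj <- j
  while (jj < end) {
    jj <- jj + 1L
    v1 <- integer(length(f))
    v1[isP[, jj]] <- 1L; v1[isM[, jj]] <- 2L
    v2 <- 3L - v1; v2[v1 == 0L] <- 0L
    s1 <- n_switches(f, v1); s2 <- n_switches(f, v2)
    if (s1 <= s2) {
      total <- total + s1
      f[v1 != 0L] <- v1[v1 != 0L]
    } else {
      total <- total + s2
      f[v2 != 0L] <- v2[v2 != 0L]
    }
  }
  total
}

# internal: forward validation of a candidate switch for individual `i` at
# informative locus `j` (old -> new). Walks a temporary FMV across subsequent
# informative loci, counting those at which `i` is homozygous; TRUE once
# `confirm` of them assign `i` the new strand, FALSE once `confirm` assign the
# old strand or the window / chromosome is exhausted. The focal individual is
# excluded from each locus's orientation choice — its pending switch must not
# vote for itself — so each scanned locus compares `i`'s genotype against the
# orientation implied by its unswitched sibs (the pairwise opposing-homozygote
# test, pooled over the family).
validate_switch <- function(i, j, newcode, start_fmv, isP, isM, hom,
                            window, confirm, k) {
  f <- start_fmv
  f[i] <- 0L
  support <- 0L; oppose <- 0L; scanned <- 0L
  jj <- j
  while (scanned < window && jj < k) {
    jj <- jj + 1L
    v1 <- integer(length(f))
    v1[isP[, jj]] <- 1L; v1[isM[, jj]] <- 2L
    v2 <- 3L - v1; v2[v1 == 0L] <- 0L
    s1 <- n_switches(f, v1); s2 <- n_switches(f, v2)
    if (hom[i, jj] && s1 != s2) {
      scanned <- scanned + 1L
      v <- if (s1 < s2) v1 else v2
      if (v[i] == newcode) support <- support + 1L else oppose <- oppose + 1L
      if (support >= confirm) return(TRUE)
      if (oppose >= confirm) return(FALSE)
    }
    # labels in the temporary FMV are only ever filled in, never overwritten:
    # overwriting would smuggle other, unvalidated switches into the scan
    v <- if (s1 <= s2) v1 else v2
    fill <- v != 0L & f == 0L
    fill[i] <- FALSE
    f[fill] <- v[fill]
  }
  FALSE
}

#' Partition a half-sib family into sire-strand blocks
#'
#' Implements the forward-memory-vector walk over the family's sire-
#' heterozygous (informative) loci. At the first informative locus,
#' homozygous-0 offspring are seeded `P` and homozygous-2 offspring `M`
#' (heterozygous/missing offspring unknown). Stepping forward, each
#' informative locus offers two complementary strand assignments for its
#' homozygous offspring; the one requiring fewer switches is kept, where each
#' candidate's cost is its switches against the FMV plus the switches a greedy
#' continuation would be forced into over the next `lookahead` informative
#' loci (a purely local count, `lookahead = 0`, can take a locally free
#' orientation that strands the walk on the wrong side of a crossover).
#' Remaining ties go to the candidate agreeing with the most recently updated
#' FMV entry, then to the orientation assigning `P` to 0-homozygotes.
#' Non-informative loci inherit the FMV.
#'
#' Every implied switch is validated against up to `window` downstream
#' informative loci at which the switching offspring is homozygous: accepted
#' once `confirm` of them support the new strand, rejected (and the discordant
#' genotype flagged as a suspected genotyping error) once `confirm` support
#' the old strand or the scan is exhausted. An accepted switch whose *old*
#' strand had fewer than `confirm` supporting loci since the offspring's
#' previous block boundary is reclassified: the old supporting cells are
#' flagged as suspected errors and the block is rewritten instead of recording
#' a recombination. Setting `window = 0` disables validation entirely (every
#' implied switch is accepted).
#'
#' Markers before the first informative locus are back-filled with the seed
#' assignment. Markers strictly between an accepted event's flanking
#' informative loci are unknown (`U`): the crossover cannot be localised
#' inside that interval.
#'
#' @param fam An [hs_family()] or genotype matrix (single chromosome, markers
#'   in map order).
#' @param window Number of downstream informative loci scanned to validate a
#'   switch (default 30; 0 disables validation).
#' @param confirm Number of confirming loci required (default 3).
#' @param lookahead Number of downstream informative loci included in each
#'   candidate orientation's switch cost (default 10; 0 restricts the choice
#'   to the current locus).
#' @return An object of class `hs_blocks`: list with
#'   \item{blocks}{integer block matrix (0 = U, 1 = P, 2 = M), offspring x markers}
#'   \item{events}{tibble of accepted recombination events: `offspring`,
#'     `left`/`right` (marker indices of the flanking informative loci,
#'     half-open interval), `left_marker`/`right_marker`, `from`, `to`}
#'   \item{flagged}{tibble of suspected genotyping-error cells: `offspring`,
#'     `marker_index`, `marker`}
#'   \item{informative}{logical vector of sire-heterozygous loci}
#' @export
block_partition <- function(fam, window = 30L, confirm = 3L, lookahead = 10L) {
  G <- family_genotypes(fam)
  n <- nrow(G); m <- ncol(G)
  if (n < 2L) stop("block partitioning needs a family of at least 2 offspring")
  if (n < 4L) warning("family of size ", n, ": block detection is unreliable below 4 offspring")
  window <- as.integer(window); confirm <- as.integer(confirm)
  lookahead <- as.integer(lookahead)
  if (lookahead < 0L) stop("lookahead must be >= 0")
  if (window < 0L || confirm < 1L || (window > 0L && window < confirm)) {
    stop("need window >= confirm >= 1 (or window = 0 to disable validation)")
  }
  ids <- rownames(G)
  het <- find_sire_het_loci(G)
  # error guard for the walk: in families large enough to afford it, demand at
  # least two offspring in each homozygote class — a single opposing
  # homozygote among many sibs is more likely a genotyping error than proof of
  # sire heterozygosity, and such false loci mislabel half the family at once
  if (n >= 10L) {
    n0 <- colSums(!is.na(G) & G == 0L)
    n2 <- colSums(!is.na(G) & G == 2L)
    walk_loci <- het & n0 >= 2L & n2 >= 2L
  } else {
    walk_loci <- het
  }
  H <- which(walk_loci)
  k <- length(H)
  empty_events <- tibble::tibble(offspring = character(), left = integer(),
                                 right = integer(), left_marker = character(),
                                 right_marker = character(), from = character(),
                                 to = character())
  empty_flags <- tibble::tibble(offspring = character(), marker_index = integer(),
                                marker = character())
  if (k == 0L) {
    warning("no sire-heterozygous loci: family is uninformative, returning all-unknown blocks")
    B <- matrix(0L, n, m, dimnames = dimnames(G))
    return(structure(list(blocks = B, events = empty_events,
                          flagged = empty_flags, informative = het),
                     class = "hs_blocks"))
  }

  GH <- G[, H, drop = FALSE]
  isP <- !is.na(GH) & GH == 0L
  isM <- !is.na(GH) & GH == 2L
  hom <- isP | isM

  fmv <- integer(n)
  hist <- matrix(0L, n, k)
  last_upd <- integer(n)   # informative index of last genotype-consistent assignment
  prev_code <- integer(n)  # last known (non-U) strand code, survives FMV resets
  boundary <- rep(1L, n)   # informative index where the current block started
  consec <- integer(n)     # hom loci supporting the current strand since boundary

  fmv[isP[, 1L]] <- 1L
  fmv[isM[, 1L]] <- 2L
  hist[, 1L] <- fmv
  prev_code <- fmv
  last_upd[hom[, 1L]] <- 1L
  consec[hom[, 1L]] <- 1L

  ev_off <- integer(0); ev_l <- integer(0); ev_r <- integer(0)
  ev_from <- integer(0); ev_to <- integer(0)
  fl_off <- integer(0); fl_j <- integer(0)

  for (j in seq_len(k)[-1L]) {
    v1 <- integer(n)
    v1[isP[, j]] <- 1L; v1[isM[, j]] <- 2L
    v2 <- 3L - v1; v2[v1 == 0L] <- 0L
    s1 <- n_switches(fmv, v1); s2 <- n_switches(fmv, v2)
    if (lookahead > 0L) {
      s1 <- s1 + lookahead_cost(v1, j, fmv, isP, isM, k, depth = lookahead)
      s2 <- s2 + lookahead_cost(v2, j, fmv, isP, isM, k, depth = lookahead)
    }
    if (s1 != s2) {
      v <- if (s1 < s2) v1 else v2
    } else {
      a1 <- fmv != 0L & v1 != 0L & fmv == v1
      a2 <- fmv != 0L & v2 != 0L & fmv == v2
      r1 <- if (any(a1)) max(last_upd[a1]) else 0L
      r2 <- if (any(a2)) max(last_upd[a2]) else 0L
      v <- if (r2 > r1) v2 else v1
    }

    # strand changes needing validation: an ordinary switch against the FMV,
    # or a re-anchor onto the opposite strand after a rejected switch left the
    # offspring unknown
    switched <- which((fmv != 0L & v != 0L & v != fmv) |
                        (fmv == 0L & v != 0L & prev_code != 0L & v != prev_code))
    just_set <- logical(n)
    rejected <- integer(0)
    if (length(switched) > 0L) {
      start_fmv <- fmv
      start_fmv[v != 0L] <- v[v != 0L]
      newfmv <- start_fmv
      for (i in switched) {
        oldcode <- prev_code[i]; newcode <- v[i]
        ok <- window == 0L ||
          validate_switch(i, j, newcode, start_fmv, isP, isM, hom,
                          window, confirm, k)
        if (!ok) {
          # suspected genotyping error: the cell keeps the old code in the
          # block matrix, but the running assignment becomes unknown so the
          # discordant call cannot vote in later decisions
          newfmv[i] <- if (window == 0L) oldcode else 0L
          rejected <- c(rejected, i)
          fl_off <- c(fl_off, i); fl_j <- c(fl_j, j)
        } else if (window > 0L && consec[i] < confirm) {
          # too little support for the old strand: the old cells, not this
          # one, look like genotyping errors; absorb instead of recording an
          # event (Figure-2-style correction at a block anchor)
          rng <- boundary[i]:(j - 1L)
          old_cells <- rng[hist[i, rng] == oldcode & hom[i, rng]]
          fl_off <- c(fl_off, rep(i, length(old_cells)))
          fl_j <- c(fl_j, old_cells)
          hist[i, rng[hist[i, rng] == oldcode]] <- newcode
          consec[i] <- 1L
          just_set[i] <- TRUE
        } else {
          ev_off <- c(ev_off, i)
          ev_l <- c(ev_l, last_upd[i]); ev_r <- c(ev_r, j)
          ev_from <- c(ev_from, oldcode); ev_to <- c(ev_to, newcode)
          boundary[i] <- j
          consec[i] <- 1L
          just_set[i] <- TRUE
        }
      }
      fmv <- newfmv
    } else {
      fmv[v != 0L] <- v[v != 0L]
    }
    hist[, j] <- fmv
    # flagged cells display the previous code (the discordant genotype is
    # treated as an error, not a strand change)
    if (length(rejected) > 0L) hist[rejected, j] <- prev_code[rejected]

    consistent <- hom[, j] & v != 0L & fmv == v
    first_time <- consistent & last_upd == 0L & prev_code == 0L
    boundary[first_time] <- j
    consec[consistent & !just_set] <- consec[consistent & !just_set] + 1L
    last_upd[consistent] <- j
    prev_code[fmv != 0L] <- fmv[fmv != 0L]
  }

  # expand the informative-locus history to all markers; markers before the
  # first informative locus take the seed assignment
  fidx <- findInterval(seq_len(m), H)
  fidx[fidx == 0L] <- 1L
  B <- hist[, fidx, drop = FALSE]
  dimnames(B) <- dimnames(G)

  # recombination intervals cannot be localised between their flanks
  if (length(ev_off) > 0L) {
    for (e in seq_along(ev_off)) {
      lm <- H[ev_l[e]]; rm <- H[ev_r[e]]
      if (rm > lm + 1L) B[ev_off[e], (lm + 1L):(rm - 1L)] <- 0L
    }
  }

  code_chr <- c("U", "P", "M")
  events <- tibble::tibble(
    offspring = ids[ev_off],
    left = unname(H[ev_l]), right = unname(H[ev_r]),
    left_marker = colnames(G)[H[ev_l]], right_marker = colnames(G)[H[ev_r]],
    from = code_chr[ev_from + 1L], to = code_chr[ev_to + 1L]
  )
  flagged <- tibble::tibble(
    offspring = ids[fl_off],
    marker_index = unname(H[fl_j]),
    marker = colnames(G)[H[fl_j]]
  )
  structure(list(blocks = B, events = events, flagged = flagged,
                 informative = het),
            class = "hs_blocks")
}

#' @export
print.hs_blocks <- function(x, ...) {
  cat(sprintf(
    "<hs_blocks> %d offspring x %d markers; %d informative loci; %d recombination event(s); %d flagged cell(s); %.1f%% assigned\n",
    nrow(x$blocks), ncol(x$blocks), sum(x$informative), nrow(x$events),
    nrow(x$flagged), 100 * mean(x$blocks != 0L)))
  invisible(x)
}

#' Fill unknown strand codes from flanking blocks
#'
#' Runs of `U` whose flanking known codes (within the same offspring) agree
#' are filled with that code. Runs whose flanks disagree — recombination gaps —
#' stay unknown. Runs touching a chromosome end have a single flank and are
#' filled from it when `end_fill = TRUE` (the default); rows that are entirely
#' unknown always stay unknown.
#'
#' @param B Integer block matrix (e.g. `block_partition(fam)$blocks`) or an
#'   `hs_blocks` object.
#' @param end_fill Fill single-flank runs at chromosome ends?
#' @return The filled integer block matrix.
#' @export
fill_uncertain_codes <- function(B, end_fill = TRUE) {
  if (inherits(B, "hs_blocks")) B <- B$blocks
  for (i in seq_len(nrow(B))) {
    row <- B[i, ]
    if (!any(row == 0L) || all(row == 0L)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values == 0L)) {
      left <- if (q > 1L) r$values[q - 1L] else NA_integer_
      right <- if (q < length(r$values)) r$values[q + 1L] else NA_integer_
      fill <- if (!is.na(left) && !is.na(right)) {
        if (left == right) left else NA_integer_
      } else if (end_fill) {
        if (!is.na(left)) left else right
      } else {
        NA_integer_
      }
      if (!is.na(fill)) B[i, starts[q]:ends[q]] <- fill
    }
  }
  B
}
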