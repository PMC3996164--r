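# Truth-tracked forward-in-time simulator for livestock-style half-sib
# designs: founders with U(0,1) allele frequencies, discrete generations of
# random mating, Poisson (Haldane) or bounded-uniform crossover counts, and
# uniform random genotyping errors.

#' Simulation configuration
#'
#' Bundles and validates the parameters of [sim_population()]. Defaults mirror
#' a commercial-livestock design: one 500 cM chromosome, founder allele
#' frequencies uniform on (0, 1), 20 sires and 400 dams per generation, 10
#' generations of random mating, Poisson crossover counts with mean equal to
#' the map length in Morgans (no interference).
#'
#' @param n_markers Number of evenly spaced markers on the chromosome.
#' @param chr_length_cm Map length in centimorgan.
#' @param n_generations Generations of random mating after the founders.
#' @param hist_generations Historical burn-in: generations of random mating in
#'   a small constant-size population (`hist_size` individuals, half male)
#'   run before the recorded pedigree, building linkage disequilibrium and
#'   drift comparable to a long-bred livestock population. 0 disables.
#' @param hist_size Historical population size (even number).
#' @param n_sires,n_dams Males/females per generation.
#' @param offspring_per_sire Half-sib family size in the final generation.
#'   Each final-generation sire is mated to this many distinct dams (one
#'   offspring each), so `n_sires * offspring_per_sire <= n_dams` is required.
#' @param crossover Crossover-count model: `"poisson"` (mean = map length in
#'   Morgans, Haldane) or `"uniform"` (uniform on `0:max_crossovers`).
#' @param max_crossovers Upper bound for the `"uniform"` model.
#' @param error_rate Fraction of genotype cells rewritten to a random
#'   different code, in `[0, 1)`.
#' @param founder_freqs Optional vector of founder allele frequencies (one per
#'   marker); default drawn from U(0, 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 10000L, chr_length_cm = 500,
                       n_generations = 10L, n_sires = 20L, n_dams = 400L,
                       offspring_per_sire = 20L,
                       crossover = c("poisson", "uniform"),
                       max_crossovers = 6L, error_rate = 0,
                       founder_freqs = NULL,
                       hist_generations = 0L, hist_size = 100L) {
  crossover <- match.arg(crossover)
  stopifnot(n_markers >= 1L, chr_length_cm > 0, n_generations >= 1L,
            n_sires >= 1L, n_dams >= 1L, offspring_per_sire >= 1L,
            max_crossovers >= 0L, error_rate >= 0, error_rate < 1,
            hist_generations >= 0L, hist_size >= 4L)
  if (n_sires * offspring_per_sire > n_dams) {
    stop("infeasible config: n_sires * offspring_per_sire exceeds n_dams ",
         "(each final-generation dam is mated once)")
  }
  if (!is.null(founder_freqs) && length(founder_freqs) != n_markers) {
    stop("founder_freqs must have one frequency per marker")
  }
  structure(list(
    n_markers = as.integer(n_markers), chr_length_cm = chr_length_cm,
    n_generations = as.integer(n_generations), n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    offspring_per_sire = as.integer(offspring_per_sire),
    crossover = crossover, max_crossovers = as.integer(max_crossovers),
    error_rate = error_rate, founder_freqs = founder_freqs,
    hist_generations = as.integer(hist_generations),
    hist_size = as.integer(hist_size)
  ), class = "sim_config")
}

#' Draw founder haplotypes
#'
#' Each haplotype carries allele 1 at marker `j` independently with
#' probability `freqs[j]` (frequencies shared across founders).
#'
#' @param n_haplotypes Number of haplotypes to draw.
#' @param freqs Allele-1 frequency per marker.
#' @return Integer matrix, haplotypes in rows, markers in columns.
#' @export
sim_founder_haplotypes <- function(n_haplotypes, freqs) {
  m <- length(freqs)
  matrix(as.integer(stats::runif(n_haplotypes * m) < rep(freqs, each = n_haplotypes)),
         nrow = n_haplotypes, ncol = m)
}

#' Simulate one gamete from a parent's haplotype pair
#'
#' The crossover count is drawn from the configured model, crossover positions
#' i.i.d. uniform on (0, L), and the gamete copies alternating parental
#' strands between crossovers starting from a fair-coin strand.
#'
#' @param hap1,hap2 Parent allele vectors.
#' @param pos_cm Marker positions in cM.
#' @param chr_length_cm Map length L in cM.
#' @param crossover `"poisson"` or `"uniform"` crossover-count model.
#' @param max_crossovers Bound for the uniform model.
#' @return List with `gamete` (allele vector), `origin` (1/2 per marker: which
#'   parental strand it came from), `crossovers` (positions in cM) and
#'   `start` (strand at the chromosome start).
#' @export
sim_gamete <- function(hap1, hap2, pos_cm, chr_length_cm,
                       crossover = c("poisson", "uniform"),
                       max_crossovers = 6L) {
  crossover <- match.arg(crossover)
  n_xo <- if (crossover == "poisson") {
    stats::rpois(1L, chr_length_cm / 100)
  } else {
    sample.int(max_crossovers + 1L, 1L) - 1L
  }
  xo <- sort(stats::runif(n_xo, 0, chr_length_cm))
  start <- sample.int(2L, 1L)
  origin <- ((start - 1L + findInterval(pos_cm, xo)) %% 2L) + 1L
  gamete <- hap1
  take2 <- origin == 2L
  gamete[take2] <- hap2[take2]
  list(gamete = gamete, origin = origin, crossovers = xo, start = start)
}

#' Inject uniform random genotyping errors
#'
#' `floor(rate * #non-missing cells)` distinct non-missing cells are selected
#' uniformly and each rewritten to a uniformly chosen *different* code in
#' {0, 1, 2}.
#'
#' @param G Genotype matrix.
#' @param rate Error rate in `[0, 1)`.
#' @return List with `genotypes` (corrupted matrix) and `errors` (tibble of
#'   `offspring`, `marker_index`, `original`, `observed`).
#' @export
inject_errors <- function(G, rate) {
  G <- family_genotypes(G)
  if (rate < 0 || rate >= 1) stop("error rate must be in [0, 1)")
  cells <- which(!is.na(G))
  n_err <- floor(rate * length(cells))
  if (n_err == 0L) {
    return(list(genotypes = G,
                errors = tibble::tibble(offspring = character(),
                                        marker_index = integer(),
                                        original = integer(),
                                        observed = integer())))
  }
  hit <- sample(cells, n_err)
  old <- G[hit]
  # uniform over the two codes different from the original
  shift <- sample.int(2L, n_err, replace = TRUE)
  new <- (old + shift) %% 3L
  G[hit] <- as.integer(new)
  rc <- arrayInd(hit, dim(G))
  list(genotypes = G,
       errors = tibble::tibble(offspring = rownames(G)[rc[, 1L]],
                               marker_index = rc[, 2L],
                               original = as.integer(old),
                               observed = as.integer(new)))
}

#' Simulate a multi-generation half-sib population with full truth
#'
#' Founders (`n_sires + n_dams` individuals) are drawn from the founder
#' haplotype pool; each subsequent generation is produced by random mating
#' (sires drawn uniformly, dams without replacement while they last). In the
#' final generation each sire is mated to `offspring_per_sire` distinct dams,
#' one offspring each, giving half-sib families of exactly that size. Truth —
#' offspring haplotypes with parental labels, paternal strand-of-origin
#' matrices, crossover positions and the true sire haplotypes/genotypes — is
#' recorded for the final generation.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `hs_sim`: list with
#'   \item{genotypes}{offspring x markers genotype matrix (with errors if
#'     `error_rate > 0`)}
#'   \item{map}{marker map tibble (`marker`, `chr`, `cm`, `bp`)}
#'   \item{pedigree}{tibble `id`, `sire`, `dam` for the final generation}
#'   \item{families}{named list: sire id -> offspring ids}
#'   \item{truth}{list with `paternal`, `maternal` (allele matrices), `origin`
#'     (1/2 strand-of-origin matrix for the paternal gamete), `crossovers`
#'     (tibble `offspring`, `pos_cm`), `sire_hap1`, `sire_hap2`,
#'     `sire_genotype` (matrices, sires in rows)}
#'   \item{errors}{tibble of injected genotyping errors}
#'   \item{freqs, config}{founder frequencies and the configuration}
#' @export
sim_population <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must come from sim_config()")
  m <- cfg$n_markers
  L <- cfg$chr_length_cm
  freqs <- cfg$founder_freqs
  if (is.null(freqs)) freqs <- stats::runif(m)
  pos <- (seq_len(m) - 0.5) * L / m
  markers <- paste0("M", seq_len(m))
  map <- tibble::tibble(marker = markers, chr = "1", cm = pos,
                        bp = round(pos * 1e6))

  n_par <- cfg$n_sires + cfg$n_dams

  breed <- function(hapA, hapB, sire_idx, dam_idx, track = FALSE) {
    n_off <- length(sire_idx)
    offA <- matrix(0L, n_off, m)  # paternal gamete
    offB <- matrix(0L, n_off, m)  # maternal gamete
    origin <- if (track) matrix(0L, n_off, m) else NULL
    xo_list <- if (track) vector("list", n_off) else NULL
    for (c_ in seq_len(n_off)) {
      gp <- sim_gamete(hapA[sire_idx[c_], ], hapB[sire_idx[c_], ], pos, L,
                       crossover = cfg$crossover,
                       max_crossovers = cfg$max_crossovers)
      gm <- sim_gamete(hapA[dam_idx[c_], ], hapB[dam_idx[c_], ], pos, L,
                       crossover = cfg$crossover,
                       max_crossovers = cfg$max_crossovers)
      offA[c_, ] <- gp$gamete
      offB[c_, ] <- gm$gamete
      if (track) {
        origin[c_, ] <- gp$origin
        xo_list[[c_]] <- gp$crossovers
      }
    }
    list(hapA = offA, hapB = offB, origin = origin, crossovers = xo_list)
  }

  # historical burn-in: constant-size random-mating population (first half
  # male), building LD and background homozygosity before the recorded pedigree
  if (cfg$hist_generations > 0L) {
    nh <- cfg$hist_size
    hapA <- sim_founder_haplotypes(nh, freqs)
    hapB <- sim_founder_haplotypes(nh, freqs)
    nm <- nh %/% 2L
    for (g in seq_len(cfg$hist_generations)) {
      sires <- sample.int(nm, nh, replace = TRUE)
      dams <- nm + sample.int(nh - nm, nh, replace = TRUE)
      nxt <- breed(hapA, hapB, sires, dams)
      hapA <- nxt$hapA
      hapB <- nxt$hapB
    }
    # recorded-pedigree founders drawn from the historical population
    idx <- sample.int(nh, n_par, replace = n_par > nh)
    hapA <- hapA[idx, , drop = FALSE]
    hapB <- hapB[idx, , drop = FALSE]
  } else {
    hapA <- sim_founder_haplotypes(n_par, freqs)
    hapB <- sim_founder_haplotypes(n_par, freqs)
  }

  # intermediate generations: males are the first n_sires indices of the
  # current generation, females the rest
  for (g in seq_len(cfg$n_generations - 1L)) {
    sires <- sample.int(cfg$n_sires, n_par, replace = TRUE)
    extra <- n_par - cfg$n_dams
    dams <- cfg$n_sires + c(sample.int(cfg$n_dams),
                            if (extra > 0L) sample.int(cfg$n_dams, extra, replace = TRUE))
    nxt <- breed(hapA, hapB, sires, dams)
    hapA <- nxt$hapA
    hapB <- nxt$hapB
  }

  # final generation: structured half-sib families
  fam_size <- cfg$offspring_per_sire
  n_fam <- cfg$n_sires
  n_off <- n_fam * fam_size
  sire_idx <- rep(seq_len(n_fam), each = fam_size)
  dam_idx <- cfg$n_sires + sample.int(cfg$n_dams, n_off)
  off <- breed(hapA, hapB, sire_idx, dam_idx, track = TRUE)

  sire_ids <- paste0("S", seq_len(n_fam))
  dam_ids <- paste0("D", dam_idx - cfg$n_sires)
  off_ids <- paste0("O", seq_len(n_off))
  G <- off$hapA + off$hapB
  dimnames(G) <- list(off_ids, markers)
  dimnames(off$hapA) <- dimnames(off$hapB) <- dimnames(off$origin) <- dimnames(G)

  sire_hap1 <- hapA[seq_len(n_fam), , drop = FALSE]
  sire_hap2 <- hapB[seq_len(n_fam), , drop = FALSE]
  dimnames(sire_hap1) <- dimnames(sire_hap2) <- list(sire_ids, markers)

  errs <- inject_errors(G, cfg$error_rate)

  xo <- tibble::tibble(
    offspring = rep(off_ids, vapply(off$crossovers, length, 1L)),
    pos_cm = unlist(off$crossovers)
  )
  structure(list(
    genotypes = errs$genotypes,
    map = map,
    pedigree = tibble::tibble(id = off_ids, sire = sire_ids[sire_idx],
                              dam = dam_ids),
    families = split(off_ids, sire_ids[sire_idx])[sire_ids],
    truth = list(paternal = off$hapA, maternal = off$hapB,
                 origin = off$origin, crossovers = xo,
                 sire_hap1 = sire_hap1, sire_hap2 = sire_hap2,
                 sire_genotype = sire_hap1 + sire_hap2),
    errors = errs$errors,
    freqs = freqs,
    config = cfg
  ), class = "hs_sim")
}

#' @export
print.hs_sim <- function(x, ...) {
  cat(sprintf("<hs_sim> %d half-sib families of %d offspring; %d markers on %g cM; %d generation(s); %d injected error(s)\n",
              length(x$families), x$config$offspring_per_sire,
              x$config$n_markers, x$config$chr_length_cm,
              x$config$n_generations, nrow(x$errors)))
  invisible(x)
}

#' Extract one simulated family and its truth
#'
#' @param sim An `hs_sim` from [sim_population()].
#' @param sire Sire id (e.g. `"S1"`) or family index.
#' @return List with `family` (an [hs_family()]) and `truth` (list with
#'   `origin`, `paternal`, `maternal`, `sire_genotype`, `sire_hap1`,
#'   `sire_hap2` restricted to the family), ready for [hs_phase()] and
#'   [evaluate_phasing()].
#' @export
sim_family_truth <- function(sim, sire) {
  if (!inherits(sim, "hs_sim")) stop("`sim` must come from sim_population()")
  if (is.numeric(sire)) sire <- names(sim$families)[sire]
  ids <- sim$families[[sire]]
  if (is.null(ids)) stop("unknown sire: ", sire)
  list(
    family = hs_family(sire, sim$genotypes[ids, , drop = FALSE]),
    truth = list(
      origin = sim$truth$origin[ids, , drop = FALSE],
      paternal = sim$truth$paternal[ids, , drop = FALSE],
      maternal = sim$truth$maternal[ids, , drop = FALSE],
      sire_hap1 = sim$truth$sire_hap1[sire, ],
      sire_hap2 = sim$truth$sire_hap2[sire, ],
      sire_genotype = sim$truth$sire_genotype[sire, ],
      crossovers = sim$truth$crossovers[sim$truth$crossovers$offspring %in% ids, ]
    )
  )
}

#' Simulate a single half-sib family (unrelated dams)
#'
#' Lightweight generator for tests and examples: a sire haplotype pair is
#' drawn from the founder pool (or supplied), each offspring receives a
#' recombined paternal gamete from the sire and an independent maternal
#' haplotype drawn at the founder frequencies (each dam unrelated, used once).
#'
#' @param n_offspring Family size.
#' @param n_markers Marker count.
#' @param chr_length_cm Map length in cM.
#' @param freqs Optional allele frequencies (default U(0, 1)).
#' @param sire_haps Optional list of two sire allele vectors.
#' @param crossover,max_crossovers Crossover model, as in [sim_config()].
#' @param error_rate Genotyping error rate.
#' @return List with `family` (an [hs_family()]), `truth` (as in
#'   [sim_family_truth()]), `map`, `freqs` and `errors`.
#' @export
sim_half_sib_family <- function(n_offspring, n_markers, chr_length_cm = 100,
                                freqs = NULL, sire_haps = NULL,
                                crossover = c("poisson", "uniform"),
                                max_crossovers = 6L, error_rate = 0) {
  crossover <- match.arg(crossover)
  if (is.null(freqs)) freqs <- stats::runif(n_markers)
  pos <- (seq_len(n_markers) - 0.5) * chr_length_cm / n_markers
  markers <- paste0("M", seq_len(n_markers))
  if (is.null(sire_haps)) {
    sire_haps <- list(drop(sim_founder_haplotypes(1L, freqs)),
                      drop(sim_founder_haplotypes(1L, freqs)))
  }
  pat <- matrix(0L, n_offspring, n_markers)
  origin <- matrix(0L, n_offspring, n_markers)
  xo <- vector("list", n_offspring)
  for (i in seq_len(n_offspring)) {
    g <- sim_gamete(sire_haps[[1L]], sire_haps[[2L]], pos, chr_length_cm,
                    crossover = crossover, max_crossovers = max_crossovers)
    pat[i, ] <- g$gamete
    origin[i, ] <- g$origin
    xo[[i]] <- g$crossovers
  }
  mat <- sim_founder_haplotypes(n_offspring, freqs)
  ids <- paste0("O", seq_len(n_offspring))
  G <- pat + mat
  dimnames(G) <- dimnames(pat) <- dimnames(mat) <- dimnames(origin) <-
    list(ids, markers)
  errs <- inject_errors(G, error_rate)
  list(
    family = hs_family("S1", errs$genotypes),
    truth = list(origin = origin, paternal = pat, maternal = mat,
                 sire_hap1 = sire_haps[[1L]], sire_hap2 = sire_haps[[2L]],
                 sire_genotype = sire_haps[[1L]] + sire_haps[[2L]],
                 crossovers = xo),
    map = tibble::tibble(marker = markers, chr = "1", cm = pos,
                         bp = round(pos * 1e6)),
    freqs = freqs,
    errors = errs$errors
  )
}
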