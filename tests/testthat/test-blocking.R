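# Opposing-homozygote rules and the FMV block partition.

test_that("sire-heterozygous loci are exactly those with opposing homozygotes", {
  G <- rbind(c(0L, 1L, 0L, NA, 2L),
             c(2L, 1L, 9L, NA, 2L),
             c(1L, 1L, 0L, 0L, 2L))
  G[G == 9L] <- NA_integer_
  rownames(G) <- paste0("i", 1:3); colnames(G) <- paste0("m", 1:5)
  expect_identical(unname(find_sire_het_loci(G)),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("the sum-2-or-6 pair rule equals 'opposes at exactly one locus'", {
  codes <- c(0L, 2L)
  for (a1 in codes) for (a2 in codes) for (b1 in codes) for (b2 in codes) {
    want <- xor(a1 != b1, a2 != b2)  # independent oracle
    expect_identical(pair_recombination(c(a1, a2), c(b1, b2)), want)
  }
  expect_true(pair_recombination(c(2L, 2L), c(0L, 2L)))   # sum 6
  expect_false(pair_recombination(c(0L, 0L), c(0L, 0L)))  # sum 0
  expect_false(pair_recombination(c(0L, 2L), c(2L, 0L)))  # sum 4, opposes twice
  expect_error(pair_recombination(c(1L, 2L), c(0L, 2L)), "homozygous")
  expect_error(pair_recombination(c(NA, 2L), c(0L, 2L)), "homozygous")
})

test_that("strand-switch counting ignores unknowns", {
  expect_identical(count_strand_switches(c("P", "M", "U"), c("P", "P", "M")), 1L)
  expect_identical(count_strand_switches(c("P", "M"), c("P", "M")), 0L)
  expect_identical(count_strand_switches(c("U", "U", "U"), c("P", "M", "P")), 0L)
  expect_error(count_strand_switches(c("P"), c("P", "M")), "equal length")
})

test_that("a crossover-free family gets constant codes and no events", {
  set.seed(5)
  fs <- sim_half_sib_family(6, 80, chr_length_cm = 50,
                            crossover = "uniform", max_crossovers = 0)
  b <- block_partition(fs$family)
  expect_identical(nrow(b$events), 0L)
  per_row <- apply(b$blocks, 1L, function(r) length(unique(r[r != 0L])))
  expect_true(all(per_row <= 1L))
  expect_equal(block_r2(b, fs$truth$origin), 1)
})

test_that("a single mid-chromosome crossover yields one flanked event", {
  set.seed(9)
  found <- 0L
  for (rep in 1:20) {
    fs <- sim_half_sib_family(6, 150, chr_length_cm = 40,
                              crossover = "uniform", max_crossovers = 0)
    tr <- fs$truth
    # inject one true crossover mid-chromosome into offspring 1's gamete
    cut <- 75L
    m <- 150L
    pat <- tr$paternal; origin <- tr$origin
    pat[1, (cut + 1):m] <- ifelse(origin[1, (cut + 1):m] == 1L,
                                  tr$sire_hap2[(cut + 1):m],
                                  tr$sire_hap1[(cut + 1):m])
    origin[1, (cut + 1):m] <- 3L - origin[1, (cut + 1):m]
    G <- pat + tr$maternal
    dimnames(G) <- dimnames(fs$family$genotypes)
    b <- block_partition(G)
    if (nrow(b$events) == 1L) {
      found <- found + 1L
      expect_identical(b$events$offspring, rownames(G)[1L])
      expect_lte(b$events$left, cut)
      expect_gt(b$events$right, cut)
      # flanks are sire-het loci
      expect_true(all(b$events$left %in% which(b$informative)))
      expect_true(all(b$events$right %in% which(b$informative)))
      expect_gte(block_r2(b, origin), 0.95)
    }
  }
  # the crossover is detectable in the clear majority of random families
  expect_gte(found, 15L)
})

test_that("an isolated discordant homozygote is flagged, not an event", {
  set.seed(13)
  hits <- 0L
  for (rep in 1:25) {
    fs <- sim_half_sib_family(8, 250, chr_length_cm = 100,
                              crossover = "uniform", max_crossovers = 0)
    G <- fs$family$genotypes
    H <- which(find_sire_het_loci(G))
    if (length(H) < 40L) next
    j <- sample(H, 1L)
    homs <- which(G[, j] %in% c(0L, 2L))
    i <- if (length(homs) == 1L) homs else sample(homs, 1L)
    G[i, j] <- 2L - G[i, j]
    b <- block_partition(G)
    expect_identical(nrow(b$events), 0L)
    if (nrow(b$flagged) > 0L) {
      hits <- hits + 1L
      expect_true(any(b$flagged$marker_index == j &
                        b$flagged$offspring == rownames(G)[i]))
    }
  }
  expect_gte(hits, 10L)
})

test_that("uninformative families return all-unknown blocks with a warning", {
  G <- matrix(1L, 3, 5, dimnames = list(paste0("i", 1:3), paste0("m", 1:5)))
  expect_warning(b <- block_partition(G), "uninformative")
  expect_true(all(b$blocks == 0L))
  expect_identical(nrow(b$events), 0L)
})

test_that("relabeling the genotype codes mirrors the block matrix", {
  set.seed(21)
  for (rep in 1:10) {
    fs <- sim_half_sib_family(5, 60, chr_length_cm = 80)
    G <- fs$family$genotypes
    b1 <- suppressWarnings(block_partition(G))$blocks
    b2 <- suppressWarnings(block_partition(swap_geno_codes(G)))$blocks
    swapped <- b1
    swapped[b1 == 1L] <- 2L
    swapped[b1 == 2L] <- 1L
    expect_identical(b2, swapped)
  }
})

test_that("greedy partition attains the exhaustive minimum switch count", {
  set.seed(31)
  tried <- 0L
  while (tried < 60L) {
    fs <- sim_half_sib_family(sample(3:6, 1L), 20, chr_length_cm = 60)
    k <- sum(find_sire_het_loci(fs$family))
    if (k == 0L || k > 14L) next
    tried <- tried + 1L
    b <- suppressWarnings(block_partition(fs$family, window = 0L))
    expect_identical(sum(recombination_counts(b)),
                     as.integer(min_switches_oracle(fs$family$genotypes)))
  }
})

test_that("accepted events carve an unknown gap between their flanks", {
  set.seed(41)
  fs <- sim_half_sib_family(8, 300, chr_length_cm = 120)
  b <- block_partition(fs$family)
  ev <- b$events
  if (nrow(ev) > 0L) {
    for (e in seq_len(nrow(ev))) {
      i <- match(ev$offspring[e], rownames(b$blocks))
      gap <- (ev$left[e] + 1L):(ev$right[e] - 1L)
      if (ev$left[e] + 1L <= ev$right[e] - 1L) {
        expect_true(all(b$blocks[i, gap] == 0L))
      }
    }
  }
  expect_gt(nrow(ev), 0L)
})

test_that("fill_uncertain_codes fills agreeing runs, keeps gaps and respects end_fill", {
  B <- rbind(c(1L, 0L, 0L, 1L),
             c(1L, 0L, 2L, 2L),
             c(0L, 0L, 2L, 2L),
             c(0L, 0L, 0L, 0L))
  filled <- fill_uncertain_codes(B)
  expect_identical(filled[1, ], c(1L, 1L, 1L, 1L))   # agreeing flanks
  expect_identical(filled[2, ], c(1L, 0L, 2L, 2L))   # disagreeing flanks stay U
  expect_identical(filled[3, ], c(2L, 2L, 2L, 2L))   # leading run, single right flank
  expect_identical(filled[4, ], rep(0L, 4))          # all-unknown row stays
  strict <- fill_uncertain_codes(B, end_fill = FALSE)
  expect_identical(strict[3, ], c(0L, 0L, 2L, 2L))
})

test_that("window/confirm arguments are validated", {
  G <- rbind(i1 = c(0L, 2L), i2 = c(2L, 0L))
  colnames(G) <- c("m1", "m2")
  expect_error(block_partition(G, window = 2, confirm = 3), "window >= confirm")
  expect_error(block_partition(G, confirm = 0), "confirm")
})
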