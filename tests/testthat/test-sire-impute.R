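# Sire haplotype/genotype imputation and offspring phasing.

test_that("homozygous-vote rule imputes from unambiguous offspring only", {
  # one locus, strand P offspring hom 0 -> allele 0; strand M offspring (2,2) -> 1
  G <- rbind(c(0L), c(0L), c(2L), c(2L))
  rownames(G) <- paste0("i", 1:4); colnames(G) <- "m1"
  B <- matrix(c(1L, 1L, 2L, 2L), 4, 1, dimnames = dimnames(G))
  s <- impute_sire(G, B)
  expect_identical(unname(s$hapP), 0L)
  expect_identical(unname(s$hapM), 1L)
  expect_identical(unname(s$genotype), 1L)
  # het offspring carry no vote under the default rule
  G2 <- rbind(c(1L), c(1L), c(2L), c(2L))
  dimnames(G2) <- dimnames(G)
  s2 <- impute_sire(G2, B)
  expect_identical(unname(s2$hapP), NA_integer_)
  expect_identical(unname(s2$genotype), NA_integer_)
})

test_that("genotype-mean rule follows the literal averaging description", {
  # strand M offspring genotypes (1,1,0): mean 0.67 -> allele 1
  G <- rbind(c(0L), c(1L), c(1L), c(0L))
  rownames(G) <- paste0("i", 1:4); colnames(G) <- "m1"
  B <- matrix(c(1L, 2L, 2L, 2L), 4, 1, dimnames = dimnames(G))
  s <- impute_sire(G, B, method = "mean")
  expect_identical(unname(s$hapM), 1L)
  expect_identical(unname(s$hapP), 0L)
  # strand P offspring (0,2): mean 1 -> allele 1 (clipped), contradiction flagged
  G3 <- rbind(c(0L), c(2L), c(0L), c(0L))
  dimnames(G3) <- dimnames(G)
  B3 <- matrix(c(1L, 1L, 2L, 2L), 4, 1, dimnames = dimnames(G))
  s3 <- impute_sire(G3, B3, method = "mean")
  expect_identical(unname(s3$hapP), 1L)
  expect_identical(nrow(s3$low_confidence), 1L)
  # exact 0.5 mean -> missing
  G4 <- rbind(c(0L), c(1L), c(2L), c(2L))
  dimnames(G4) <- dimnames(G)
  s4 <- impute_sire(G4, B3, method = "mean")
  expect_identical(unname(s4$hapP), NA_integer_)
})

test_that("sire-heterozygosity conflicts are reported and blanked", {
  # opposing homozygotes prove the sire het, but both strand votes say allele 1
  G <- rbind(c(2L), c(2L), c(0L), c(2L))
  rownames(G) <- paste0("i", 1:4); colnames(G) <- "m1"
  B <- matrix(c(1L, 1L, 0L, 2L), 4, 1, dimnames = dimnames(G))
  s <- impute_sire(G, B)
  expect_identical(nrow(s$conflicts), 1L)
  expect_identical(unname(s$genotype), NA_integer_)
})

test_that("percent_imputed counts non-missing imputed genotypes", {
  s <- structure(list(genotype = c(0L, NA, 2L, 1L, NA)), class = "hs_sire")
  expect_equal(percent_imputed(s), 0.6)
  expect_equal(percent_imputed(structure(list(genotype = integer()), class = "hs_sire")), 0)
})

test_that("phasing subtracts the paternal allele and flags impossible cells", {
  G <- rbind(c(2L, 0L, 1L), c(1L, 1L, 2L))
  rownames(G) <- c("a", "b"); colnames(G) <- paste0("m", 1:3)
  B <- matrix(c(1L, 2L, 1L, 2L, 1L, 2L), 2, 3, dimnames = dimnames(G))
  s <- structure(list(hapP = c(1L, 1L, 0L), hapM = c(0L, 0L, 1L),
                      genotype = c(1L, 1L, 1L)), class = "hs_sire")
  names(s$hapP) <- names(s$hapM) <- names(s$genotype) <- colnames(G)
  p <- phase_family(G, B, s)
  # genotype 2, paternal 1 -> maternal 1
  expect_identical(p$maternal["a", "m1"], 1L)
  # genotype 0, paternal 1 -> impossible, flagged
  expect_true(is.na(p$maternal["a", "m2"]))
  expect_identical(nrow(p$inconsistent), 1L)
  expect_identical(p$inconsistent$marker, "m2")
  # conservation wherever both alleles known
  known <- !is.na(p$paternal) & !is.na(p$maternal)
  expect_identical((p$paternal + p$maternal)[known], G[known])
})

test_that("error-free families of 20 recover the true sire (near-)exactly", {
  set.seed(19)
  for (rep in 1:3) {
    # without crossovers the block structure is exact, and so is the sire
    fs0 <- sim_half_sib_family(20, 300, chr_length_cm = 100,
                               crossover = "uniform", max_crossovers = 0)
    res0 <- hs_phase(fs0$family)
    imp0 <- !is.na(res0$sire$genotype)
    expect_gt(mean(imp0), 0.9)
    expect_identical(unname(res0$sire$genotype[imp0]),
                     unname(fs0$truth$sire_genotype[imp0]))
    # with crossovers, rare block-boundary cells can cast a wrong vote at
    # low-support loci; the imputed genotype is still almost everywhere exact
    fs <- sim_half_sib_family(20, 600, chr_length_cm = 100)
    res <- hs_phase(fs$family)
    imp <- !is.na(res$sire$genotype)
    expect_gt(mean(imp), 0.9)
    agree <- mean(res$sire$genotype[imp] == fs$truth$sire_genotype[imp])
    expect_gte(agree, 0.995)
    # conservation across the phased family
    p <- res$phased
    known <- !is.na(p$paternal) & !is.na(p$maternal)
    expect_identical((p$paternal + p$maternal)[known],
                     fs$family$genotypes[known])
  }
})

test_that("imputation yield is non-decreasing in family size (in expectation)", {
  set.seed(23)
  sizes <- c(4L, 10L, 24L)
  yields <- sapply(sizes, function(n) {
    mean(replicate(20, {
      fs <- sim_half_sib_family(n, 150, chr_length_cm = 60)
      res <- hs_phase(fs$family)
      percent_imputed(res$sire)
    }))
  })
  expect_true(all(diff(yields) > 0))
})

test_that("hs_phase stitches multi-chromosome maps back in marker order", {
  set.seed(29)
  fs1 <- sim_half_sib_family(6, 60, chr_length_cm = 40)
  fs2 <- sim_half_sib_family(6, 40, chr_length_cm = 30,
                             sire_haps = NULL)
  G <- cbind(fs1$family$genotypes,
             `colnames<-`(fs2$family$genotypes, paste0("c2_", 1:40)))
  map <- tibble::tibble(marker = colnames(G),
                        chr = rep(c("1", "2"), c(60, 40)),
                        cm = c(fs1$map$cm, fs2$map$cm))
  res <- hs_phase(G, map = map)
  expect_identical(colnames(res$blocks$blocks), colnames(G))
  expect_identical(dim(res$phased$paternal), dim(G))
  # each chromosome phased like its standalone run
  r1 <- hs_phase(fs1$family$genotypes)
  expect_identical(res$phased$paternal[, 1:60], r1$phased$paternal)
})
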