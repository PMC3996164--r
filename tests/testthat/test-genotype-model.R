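# Genotype containers, file formats and half-sib family grouping.

make_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  G <- matrix(sample(c(0:2, NA), n * m, replace = TRUE, prob = c(.3, .3, .3, .1)),
              n, m, dimnames = list(paste0("i", 1:n), paste0("m", 1:m)))
  storage.mode(G) <- "integer"
  G
}

test_that("genotype matrix validation accepts legal codes and rejects the rest", {
  G <- make_geno(4, 6)
  expect_silent(validate_genotypes(G))
  bad <- G; bad[2, 3] <- 5L
  expect_error(validate_genotypes(bad), "invalid genotype code")
  expect_error(validate_genotypes(G[0, , drop = FALSE]), "at least 1")
  dup <- G; rownames(dup) <- rep("a", 4)
  expect_error(validate_genotypes(dup), "duplicated individual")
})

test_that("genotype matrix TSV/CSV round-trips, with 9 as missing", {
  for (sep in c("\t", ",")) {
    G <- make_geno(5, 8, seed = sep == ",")
    path <- withr::local_tempfile(fileext = ".txt")
    write_genotype_matrix(G, path, sep = sep)
    expect_identical(read_genotype_matrix(path), G)
  }
  # a 3 x 8 matrix of the worked-example shape reads with the right dims
  G <- make_geno(3, 8, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(G, path)
  got <- read_genotype_matrix(path)
  expect_equal(dim(got), c(3L, 8L))
  raw <- readLines(path)
  expect_true(any(grepl("\t9", raw, fixed = TRUE)))  # missing written as 9
})

test_that("empty or malformed genotype files raise parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path)
  expect_error(read_genotype_matrix(path), "empty|parse")
  writeLines(c("id\tm1\tm2", "a\t0\tx"), path)
  expect_error(read_genotype_matrix(path), "parse error")
})

test_that("PLINK PED/MAP collapses allele pairs to alternate-allele counts", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 snp1 0 10", "1 snp2 0 20"), map)
  writeLines("F1 A 0 0 1 -9 A A A B", ped)
  pl <- read_plink(ped, map)
  # alternate = lexicographically larger observed allele; at the monomorphic
  # snp1 the single observed allele is the alternate, so A A counts 2
  expect_identical(unname(pl$genotypes["A", ]), c(2L, 1L))
  # an explicit allele key overrides the default, even for unobserved alleles
  pl2 <- read_plink(ped, map, alt_alleles = c(snp1 = "B"))
  expect_identical(unname(pl2$genotypes["A", ]), c(0L, 1L))
})

test_that("PLINK missing and malformed inputs are handled", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 snp1 0 10", "1 snp2 0 20"), map)
  writeLines(c("F1 A 0 0 1 -9 0 0 A B", "F1 B 0 0 2 -9 A A B B"), ped)
  pl <- read_plink(ped, map)
  expect_identical(unname(pl$genotypes["A", 1L]), NA_integer_)
  writeLines("F1 A 0 0 1 -9 A A", ped)  # wrong field count
  expect_error(read_plink(ped, map), "parse error")
  writeLines(c("F1 A 0 0 1 -9 A B C C",
               "F1 C 0 0 1 -9 A A G T"), ped)  # three alleles at snp2
  expect_error(read_plink(ped, map), "non-biallelic marker 'snp2'")
})

test_that("half-sib grouping partitions genotyped offspring by known sire", {
  G <- make_geno(6, 4)
  ped <- tibble::tibble(id = rownames(G),
                        sire = c("s1", "s1", "s1", "s2", "s2", "s2"),
                        dam = NA_character_)
  fams <- group_half_sib_families(G, ped)
  expect_named(fams, c("s1", "s2"))
  expect_equal(vapply(fams, function(f) nrow(f$genotypes), 1L),
               c(s1 = 3L, s2 = 3L))
  # partition property: every offspring in exactly one family
  all_ids <- unlist(lapply(fams, function(f) rownames(f$genotypes)))
  expect_setequal(all_ids, rownames(G))
  expect_false(anyDuplicated(all_ids) > 0L)
})

test_that("unknown sires are excluded with a message; all-unknown warns", {
  G <- make_geno(4, 4)
  ped <- tibble::tibble(id = rownames(G), sire = c("s1", "s1", NA, "0"),
                        dam = NA_character_)
  expect_message(fams <- group_half_sib_families(G, ped), "unknown sire")
  expect_named(fams, "s1")
  expect_setequal(attr(fams, "excluded"), c("i3", "i4"))
  ped$sire <- NA_character_
  expect_warning(
    expect_message(fams0 <- group_half_sib_families(G, ped), "unknown sire"),
    "no half-sib families")
  expect_length(fams0, 0L)
})

test_that("a sire genotyped as offspring of another sire appears in both roles", {
  G <- make_geno(5, 4)
  # i5 is sire of i1..i2 and itself an offspring of s0
  ped <- tibble::tibble(id = c(rownames(G), "s0"),
                        sire = c("i5", "i5", "s0", "s0", "s0", NA),
                        dam = NA_character_)
  fams <- group_half_sib_families(G, ped)
  expect_setequal(names(fams), c("i5", "s0"))
  expect_true("i5" %in% rownames(fams[["s0"]]$genotypes))
})

test_that("pedigree validation catches duplicates and cycles", {
  expect_error(validate_pedigree(tibble::tibble(id = c("a", "a"), sire = NA, dam = NA)),
               "duplicated")
  expect_error(validate_pedigree(tibble::tibble(id = c("a", "b"),
                                                sire = c("b", "a"), dam = NA)),
               "cycle")
})

test_that("marker maps validate ordering and matching", {
  map <- tibble::tibble(marker = c("a", "b"), chr = "1", cm = c(2, 1))
  expect_error(validate_marker_map(map), "non-decreasing")
  map$cm <- c(1, 2)
  expect_error(validate_marker_map(map, markers = c("b", "a")), "order")
  expect_silent(validate_marker_map(map, markers = c("a", "b")))
})
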