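test_that("kinship recursion gives textbook coefficients", {
  # grandparents 1x2 -> sibs 3,4; spouses 5,6 -> cousins 7,8
  ped <- gdt_pedigree(
    family = rep("f", 8), id = as.character(1:8),
    father = c(NA, NA, "1", "1", NA, NA, "3", "4"),
    mother = c(NA, NA, "2", "2", NA, NA, "5", "6"))
  phi <- compute_kinship(ped)[["f"]]
  expect_equal(phi["1", "2"], 0)            # unrelated founders
  expect_equal(phi["1", "3"], 0.25)         # parent-offspring
  expect_equal(phi["3", "4"], 0.25)         # full sibs
  expect_equal(phi["7", "8"], 0.0625)       # first cousins
  expect_equal(unname(diag(phi)), rep(0.5, 8))  # no inbreeding here
  expect_equal(phi, t(phi))
})

test_that("kinship matrices are PSD and 2*phi lies in the unit range", {
  set.seed(11)
  for (r in 1:20) {
    ped <- random_pedigree(sample(3:10, 1))
    phi <- compute_kinship(ped)[[1L]]
    expect_gte(min(eigen(phi, symmetric = TRUE)$values), -1e-10)
    off <- 2 * phi[upper.tri(phi)]
    expect_true(all(off >= 0 & off <= 1))
    expect_true(all(2 * diag(phi) >= 1 & 2 * diag(phi) <= 2))
  }
})

test_that("pedigree validation catches structural errors", {
  expect_error(gdt_pedigree("f", c("1", "1"), c(NA, NA), c(NA, NA)),
               "duplicated")
  expect_error(gdt_pedigree("f", c("1", "2"), c(NA, "9"), c(NA, "1")),
               "unknown father")
  expect_error(gdt_pedigree("f", "1", "2", NA), "one parent")
  # cycle: 1 and 2 each other's parents (with dummy co-parents)
  expect_error(gdt_pedigree("f", c("1", "2", "3"),
                            c("2", "3", "1"), c("3", "1", "2")),
               "cycle|unknown")
})

write_fixture_files <- function(dir) {
  ped <- c("f1 1 0 0 1  1 2  1 2  0 0",
           "f1 2 0 0 2  2 1  1 1  1 2",
           "f1 3 1 2 1  2 2  1 2  2 2",
           "f2 1 0 0 1  1 x  2 2  1 1",
           "f2 2 0 0 2  2 1  1 2  1 2",
           "f2 3 1 2 2  2 2  2 2  1 2")
  dat <- c("A disease", "A endo", "M snpA", "M snpB")
  pp <- file.path(dir, "fix.ped"); dp <- file.path(dir, "fix.dat")
  writeLines(ped, pp); writeLines(dat, dp)
  list(ped = pp, dat = dp)
}

test_that("Merlin/QTDT reading maps codes and alleles correctly", {
  fx <- write_fixture_files(withr::local_tempdir())
  pd <- read_pedigree(fx$ped, fx$dat)
  expect_s3_class(pd$pedigree, "gdt_pedigree")
  expect_equal(names(pd$markers), c("snpA", "snpB"))
  expect_equal(pd$traits$disease, c(0L, 1L, 1L, 0L, 1L, 1L))
  expect_equal(pd$traits$endo, c(1L, 0L, 1L, NA, 0L, 1L))
  # a child with genotype "1 2" has allele-1 proportion 0.5
  expect_equal(allele_proportion(pd$markers$snpA, "1")[3L], 0.5)
  # "0 0" genotype is missing
  expect_true(is.na(allele_proportion(pd$markers$snpB, "1")[1L]))
})

test_that("write/read round-trip is lossless", {
  fx <- write_fixture_files(withr::local_tempdir())
  pd <- read_pedigree(fx$ped, fx$dat)
  d <- withr::local_tempdir()
  write_pedigree(pd, file.path(d, "rt.ped"), file.path(d, "rt.dat"),
                 file.path(d, "rt.map"))
  pd2 <- read_pedigree(file.path(d, "rt.ped"), file.path(d, "rt.dat"))
  expect_equal(pd2$pedigree, pd$pedigree)
  expect_equal(pd2$traits, pd$traits)
  expect_equal(unname(pd2$markers), unname(pd$markers))
})

test_that("malformed pedigree files raise parse errors", {
  d <- withr::local_tempdir()
  writeLines(c("A t", "M m"), file.path(d, "a.dat"))
  writeLines("f1 1 0 0 1 2 1", file.path(d, "a.ped"))  # odd allele count
  expect_error(read_pedigree(file.path(d, "a.ped"), file.path(d, "a.dat")),
               "columns")
  writeLines("f1 1 9 9 1 2 1 1", file.path(d, "b.ped"))
  expect_error(read_pedigree(file.path(d, "b.ped"), file.path(d, "a.dat")),
               "unknown father")
})

test_that("IBD files convert probabilities to sharing proportions", {
  ped <- gdt_pedigree("f", c("1", "2", "3"), c(NA, NA, "1"),
                      c(NA, NA, "2"))
  kin <- compute_kinship(ped)
  d <- withr::local_tempdir()
  f <- file.path(d, "x.ibd")
  writeLines(c("FAMILY ID1 ID2 MARKER P0 P1 P2",
               "f 1 2 m1 1 0 0",
               "f 1 3 m1 0 0.25 0.75",
               "f 1 1 m1 0 0 1",
               "f 2 2 m1 0 0 1"), f)
  # pair (2, 3) absent from the file: falls back to 2*kinship = 0.5
  expect_warning(pim <- read_ibd(f, "m1", kin), "absent")
  expect_equal(pim$f["1", "2"], 0)
  expect_equal(pim$f["1", "3"], 0.875)   # 0.25/2 + 0.75
  expect_equal(pim$f["2", "3"], 0.5)     # 2*phi fallback
  expect_equal(pim$f["3", "3"], 1)       # diagonal always 1
  expect_equal(pim$f, t(pim$f))
  writeLines(c("FAMILY ID1 ID2 MARKER P0 P1 P2",
               "f 1 2 m1 0.5 0.2 0.2"), f)
  expect_error(read_ibd(f, "m1", kin), "sum to 1")
})

test_that("family samples order members, count categories, flag
           non-informative families and drop missing data", {
  fx <- write_fixture_files(withr::local_tempdir())
  pd <- read_pedigree(fx$ped, fx$dat)
  smp <- build_family_samples(pd, list(Y1 = "endo", Y2 = "disease"),
                              loci = c(X2 = "snpA"))
  f1 <- smp$f1
  # f1: member1 (endo only) cat 1, member2 (disease only) cat 2,
  # member3 both cat 3
  expect_equal(f1$nk, c(1L, 1L, 1L, 0L))
  expect_true(f1$informative)
  expect_true(!is.unsorted(f1$Y))
  # f2: member1 has missing endo -> excluded
  expect_equal(smp$f2$n, 2L)
  expect_false("1" %in% smp$f2$ids)
  # all retained members in one category -> non-informative, zero score
  one_cat <- family_sample(Y = c(4L, 4L), X2 = c(0, 1),
                           phi = diag(0.5, 2), K = 4L)
  expect_false(one_cat$informative)
  expect_equal(unname(family_score(one_cat, design_one_locus(4L))),
               c(0, 0, 0))
  expect_error(family_sample(Y = c(1, 2), phi = diag(0.5, 2), K = 1),
               "K must be")
})

test_that("map files round-trip", {
  fx <- write_fixture_files(withr::local_tempdir())
  pd <- read_pedigree(fx$ped, fx$dat)
  d <- withr::local_tempdir()
  write_pedigree(pd, file.path(d, "m.ped"), file.path(d, "m.dat"),
                 file.path(d, "m.map"))
  map <- read_map(file.path(d, "m.map"))
  expect_equal(map$marker, names(pd$markers))
  expect_equal(map$pos, seq_along(pd$markers))
})
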