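test_that("pedigree loading validates structure and normalizes unknown parents", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,birth_year,sex,family_id,litter_id,genotyped,is_bp",
               "A,0,,2000,M,,,1,1",
               "B,0,0,2000,F,,,1,1",
               "C,A,B,2002,M,fam1,L1,1,0"), tmp)
  ped <- load_pedigree(tmp)
  expect_s3_class(ped, "pedigree_table")
  expect_equal(sum(is_founder(ped)), 2L)
  expect_true(all(is.na(ped$sire[ped$id %in% c("A", "B")])))
  expect_identical(ped$sire[ped$id == "C"], "A")

  expect_error(pedigree_table(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
               "duplicate")
  expect_error(pedigree_table(data.frame(id = "A", sire = "Z", dam = NA)),
               "unresolved")
  # A is its own grandparent: A -> B -> A
  expect_error(pedigree_table(data.frame(id = c("A", "B"),
                                         sire = c("B", "A"), dam = NA)),
               "cycle")
})

test_that("Meuwissen-Luo reproduces classical closed-form inbreeding values", {
  ped <- pedigree_table(data.frame(
    id = c("A", "B", "C", "D", "E", "X", "Y", "H"),
    sire = c(NA, NA, "A", "A", "C", NA, NA, "C"),
    dam = c(NA, NA, "B", "B", "D", NA, NA, "X")))
  F <- inbreeding_meuwissen_luo(ped)
  expect_equal(unname(F["C"]), 0)        # offspring of unrelated founders
  expect_equal(unname(F["E"]), 0.25)     # full-sib mating
  expect_equal(unname(F["H"]), 0)        # outbred line
  # half sibs: shared sire, unrelated founder dams
  ped2 <- pedigree_table(data.frame(
    id = c("S", "D1", "D2", "H1", "H2", "O"),
    sire = c(NA, NA, NA, "S", "S", "H1"),
    dam = c(NA, NA, NA, "D1", "D2", "H2")))
  expect_equal(unname(inbreeding_meuwissen_luo(ped2)["O"]), 0.125)
})

test_that("Meuwissen-Luo equals the recursive tabular oracle on random pedigrees", {
  for (seed in 1:12) {
    ped <- random_pedigree(sample(10:50, 1), seed = seed)
    expect_equal(inbreeding_meuwissen_luo(ped), oracle_inbreeding(ped),
                 tolerance = 1e-12)
  }
})

test_that("equivalent generations follow the (1/2)^n ancestor sum and G the full-trace depth", {
  ped <- pedigree_table(data.frame(
    id = c("A", "B", "C", "D", "E", "F1", "G1"),
    sire = c(NA, NA, "A", "A", "C", NA, "F1"),
    dam = c(NA, NA, "B", "B", "D", NA, "C")))
  eg <- equivalent_generations(ped)
  rownames(eg) <- eg$id
  expect_equal(eg["A", c("G", "t")], data.frame(G = 0L, t = 0, row.names = "A"))
  expect_equal(eg["C", c("G", "t")], data.frame(G = 1L, t = 1, row.names = "C"))
  # both parents known, all four grandparents known founders
  expect_equal(eg["E", c("G", "t")], data.frame(G = 2L, t = 2, row.names = "E"))
  # one founder parent, other parent with two founder parents
  expect_equal(eg["G1", c("G", "t")], data.frame(G = 1L, t = 1.5, row.names = "G1"))
})

test_that("t is monotone non-decreasing when ancestors are added", {
  before <- pedigree_table(data.frame(id = c("P", "X"), sire = c(NA, "P"),
                                      dam = c(NA, NA)))
  after <- pedigree_table(data.frame(id = c("G1", "G2", "P", "X"),
                                     sire = c(NA, NA, "G1", "P"),
                                     dam = c(NA, NA, "G2", NA)))
  t_before <- equivalent_generations(before)
  t_after <- equivalent_generations(after)
  expect_gt(t_after$t[t_after$id == "X"], t_before$t[t_before$id == "X"])
})

test_that("individual increase in inbreeding matches its closed form and monotonicities", {
  expect_equal(delta_F_individual(0, 3), 0)
  expect_equal(delta_F_individual(0.25, 2), 0.25)
  expect_equal(delta_F_individual(0.19, 3), 0.1)
  expect_true(is.na(delta_F_individual(0.2, 1)))
  # strictly increasing in F for fixed t, strictly decreasing in t for fixed F
  Fs <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(delta_F_individual(Fs, 2.5)) > 0))
  ts <- seq(1.5, 6, by = 0.25)
  expect_true(all(diff(delta_F_individual(0.3, ts)) < 0))
})

test_that("coancestry equals tabular kinship, self-coancestry is (1+F)/2", {
  ped <- pedigree_table(data.frame(
    id = c("A", "B", "C", "D", "E"),
    sire = c(NA, NA, "A", "A", "C"),
    dam = c(NA, NA, "B", "B", "D")))
  co <- coancestry(ped, data.frame(i = c("A", "C", "A"), j = c("B", "D", "C")))
  expect_equal(co$C, c(0, 0.25, 0.25))   # unrelated / full sibs / parent-offspring
  A <- relationship_matrix(ped)
  F <- inbreeding_meuwissen_luo(ped)
  expect_equal(diag(A) / 2, (1 + F) / 2)
  # against gene-dropping Monte-Carlo on the full-sib pair
  mc <- oracle_kinship_mc(ped, "C", "D", nrep = 20000, seed = 99)
  expect_lt(abs(mc - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
})

test_that("increase in pairwise coancestry matches its closed form", {
  expect_equal(delta_C_pairwise(0, 2, 2), 0)
  expect_equal(delta_C_pairwise(0.25, 1, 1), 0.25)
  expect_equal(delta_C_pairwise(0.19, 2, 2), 0.1)
  expect_true(is.na(delta_C_pairwise(0.1, 0, 0)))
})

test_that("cohort definition groups by year (with merges), by G, and by t threshold", {
  ped <- pedigree_table(data.frame(
    id = c("A", "B", "C", "D", "E", "F1"),
    sire = c(NA, NA, "A", "A", "C", "C"),
    dam = c(NA, NA, "B", "B", "D", "D"),
    birth_year = c(2000, 2000, 2002, 2002, 2009, 2010),
    genotyped = TRUE))
  yr <- define_cohorts(ped, "year", merge_years = c("2010" = "2009"))
  expect_setequal(names(yr), c("C2000", "C2002", "C2009"))
  expect_equal(yr$C2009$n, 2L)         # 2010-born absorbed
  cg <- define_cohorts(ped, "complete_generations")
  expect_equal(cg$CG2$member_ids, c("E", "F1"))
  ts <- define_cohorts(ped, "t_threshold", t_threshold = 2)
  expect_setequal(ts$`t-subset`$member_ids, c("E", "F1"))
  founders_only <- pedigree_table(data.frame(id = c("X", "Y"), sire = NA,
                                             dam = NA, genotyped = TRUE))
  expect_warning(empty <- define_cohorts(founders_only, "t_threshold"),
                 "no individuals")
  expect_length(empty, 0)
})

test_that("genealogical Ne inverts the mean rates; founder cohorts are undefined", {
  # cohort with known mean dF: full-sib offspring all have F=0.25, t=2
  ped <- pedigree_table(data.frame(
    id = c("A", "B", "C", "D", paste0("E", 1:4)),
    sire = c(NA, NA, "A", "A", rep("C", 4)),
    dam = c(NA, NA, "B", "B", rep("D", 4)),
    genotyped = TRUE))
  co <- list(label = "test", member_ids = paste0("E", 1:4), n = 4, mean_t = 2)
  ne <- ne_genealogical(ped, co)
  expect_equal(ne$Ne_Fi, 1 / (2 * 0.25))
  # all within-cohort pairs are full sibs of inbred parents: C = 0.375, t = 2
  expect_equal(ne$Ne_Cij, 1 / (2 * delta_C_pairwise(0.375, 2, 2)))
  expect_equal(ne$n_pairs, 6L)
  founders <- list(label = "f", member_ids = c("A", "B"), n = 2, mean_t = 0)
  nef <- ne_genealogical(ped, founders)
  expect_true(is.na(nef$Ne_Fi))
})
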