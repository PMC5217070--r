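test_that("delimited pedigrees parse, with configurable missing codes", {
  f <- write_temp_csv(c("id,dam,sire", "A,NA,NA", "B,0,*", "C,A,B"))
  ped <- read_pedigree(f)
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$dam[1:2])))
  expect_equal(ped$dam[ped$id == "C"], "A")
  expect_equal(ped$sire[ped$id == "C"], "B")

  # tab-separated, custom missing code, column mapping
  f2 <- write_temp_csv(c("animal\tmother\tfather", "A\t-\t-", "C\tA\t-"))
  ped2 <- read_pedigree(f2, missing_codes = "-",
                        col_map = c(id = "animal", dam = "mother", sire = "father"))
  expect_equal(ped2$dam, c(NA, "A"))
})

test_that("referenced-but-absent parents are appended as founders", {
  f <- write_temp_csv(c("id,dam,sire", "A,NA,NA", "B,NA,NA", "C,A,B", "D,E,F"))
  expect_warning(ped <- read_pedigree(f), "appended as founders")
  expect_equal(nrow(ped), 6)
  expect_setequal(ped$id, c("A", "B", "C", "D", "E", "F"))
  expect_true(all(is.na(ped$dam[ped$id %in% c("E", "F")])))
})

test_that("duplicate ids and malformed rows are rejected with context", {
  f <- write_temp_csv(c("id,dam,sire", "A,NA,NA", "A,NA,NA"))
  expect_error(read_pedigree(f), "duplicate id A")
  expect_error(as_pedigree(data.frame(id = "A", dam = "A", sire = NA)),
               "own parent")
})

test_that("ordering is topological, stable and idempotent", {
  ped <- tibble::tibble(id = c("C", "A", "B"), dam = c("A", NA, NA),
                        sire = c("B", NA, NA))
  ord <- order_pedigree(ped)
  expect_equal(ord$id, c("A", "B", "C"))
  expect_identical(order_pedigree(ord), ord)
  expect_setequal(ord$id, ped$id)

  # an already-valid non-canonical order is preserved (stability)
  ped2 <- tibble::tibble(id = c("A", "C", "B"), dam = c(NA, "A", NA),
                         sire = c(NA, NA, NA))
  expect_identical(order_pedigree(ped2)$id, ped2$id)
})

test_that("cyclic parentage is detected and reported", {
  ped <- tibble::tibble(id = c("A", "C"), dam = c("C", "A"),
                        sire = c(NA, NA))
  expect_error(order_pedigree(ped), "cycle")
})

test_that("missingness summary counts unknown parents correctly", {
  full <- trio_ped()
  ms <- missingness_summary(full)
  expect_equal(ms$pct_unknown_dam, 100 * 2 / 3)
  ped <- tibble::tibble(id = letters[1:10],
                        dam = c(rep(NA, 3), rep("a", 7)),
                        sire = c(NA, NA, NA, rep("b", 7)))
  ped$dam[4:6] <- NA  # 6 unknown dams total, 3 founders
  ms2 <- missingness_summary(order_pedigree(ped))
  expect_equal(ms2$n_unknown_dam, 6)
  expect_equal(ms2$pct_unknown_dam, 60)
  expect_equal(ms2$pct_unknown_sire, 30)
  expect_equal(ms2$n_founders, 3)
  expect_equal(ms2$n_nonfounder_unknown, 3)
})

test_that("write -> read round-trips a pedigree identically", {
  ped <- sim_random_pedigree(40, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  back$cohort <- as.integer(back$cohort)
  back$immigrant <- as.logical(back$immigrant)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ped))
})

test_that("group assignment covers every phantom slot, by each rule", {
  ped <- sim_random_pedigree(60, seed = 11)
  ms <- missingness_summary(ped)

  g1 <- assign_groups(ped, rule = "single")
  expect_equal(length(group_labels(g1)), 1)
  expect_equal(nrow(phantom_slots(g1)), ms$n_unknown_dam + ms$n_unknown_sire)
  expect_true(all(phantom_slots(g1)$g1 == 1))

  g2 <- assign_groups(ped, rule = "flag")
  expect_equal(group_labels(g2), c("founder", "immigrant"))
  expect_equal(reference_group(g2), "founder")
  sl <- phantom_slots(g2)
  imm_ids <- ped$id[!is.na(ped$immigrant) & ped$immigrant]
  expect_true(all(sl$immigrant[sl$id %in% imm_ids] == 1))
  expect_true(all(sl$founder[!sl$id %in% imm_ids] == 1))

  g3 <- assign_groups(ped, rule = "cohort")
  expect_equal(nrow(phantom_slots(g3)), nrow(sl))

  # explicit table must cover every slot
  unk <- ped$id[is.na(ped$dam) | is.na(ped$sire)]
  tab <- tibble::tibble(id = unk[-1], group = "gA")
  expect_error(assign_groups(ped, rule = "table", table = tab),
               "not covered")
  tab_full <- tibble::tibble(id = unk, group = "gA")
  g4 <- assign_groups(ped, rule = "table", table = tab_full)
  expect_equal(group_labels(g4), "gA")
})

test_that("fuzzy memberships validate and store probability vectors", {
  ped <- order_pedigree(tibble::tibble(id = c("A", "B", "C"),
                                       dam = c(NA, NA, "A"),
                                       sire = c(NA, NA, "B")))
  gp <- assign_groups(ped, rule = "table",
                      table = tibble::tibble(id = c("A", "B"), group = "g1"),
                      labels = c("g1", "g2"))
  tab <- tibble::tibble(id = "A", slot = "dam", g1 = 0.3, g2 = 0.7)
  gp2 <- fuzzy_memberships(gp, tab)
  sl <- phantom_slots(gp2)
  expect_equal(sl$g2[sl$id == "A" & sl$slot == "dam"], 0.7)

  expect_error(fuzzy_memberships(gp, tibble::tibble(id = "A", g1 = 0.3, g2 = 0.3)),
               "sum to 1")
  expect_error(fuzzy_memberships(gp, tibble::tibble(id = "A", g1 = 0, g2 = 0)),
               "sums to 0")
  expect_error(fuzzy_memberships(gp, tibble::tibble(id = "C", slot = "dam",
                                                    g1 = 1, g2 = 0)),
               "known")
})
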