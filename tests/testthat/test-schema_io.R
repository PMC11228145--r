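test_that("canonical schema has the seven-group panel structure", {
  sch <- canonical_schema()
  grp <- table(sch$attributes$group_id)
  expect_equal(as.integer(grp[c("A", "B", "C", "D", "E", "F", "G")]),
               c(2L, 8L, 3L, 4L, 5L, 12L, 5L))
  expect_equal(nrow(sch$attributes), 39L)
  expect_equal(sum(sch$attributes$kind == "categorical"), 1L)
  expect_equal(sch$attributes$attribute_id[sch$attributes$kind == "categorical"],
               "A2")
  expect_false(sch$target_name %in% sch$attributes$name)
})

test_that("schema constructor rejects malformed catalogues", {
  att <- canonical_schema()$attributes
  expect_error(feature_schema(att[, 1:2]), "columns")
  expect_error(feature_schema(rbind(att, att[1, ])), "unique")
  expect_error(feature_schema(att, target_name = "age"), "target")
})

test_that("load/write round-trips values, mask and target", {
  fix <- simulate_worked_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(fix, path)
  back <- load_table(path)
  expect_identical(back$observed, fix$observed)
  expect_equal(back$values, fix$values, tolerance = 1e-12)
  expect_equal(back$target, fix$target, tolerance = 1e-12)
  expect_identical(back$ids, fix$ids)
  # blank cells on disk are exactly the unobserved entries
  raw <- utils::read.csv(path, colClasses = "character")
  expect_equal(sum(raw == "", na.rm = TRUE) +
                 sum(is.na(raw)), sum(!fix$observed))
})

test_that("loader validates headers, numeric tokens and gender codes", {
  fix <- simulate_worked_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(fix, path)

  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  bad1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw[, setdiff(names(raw), "age")], bad1, row.names = FALSE)
  expect_error(load_table(bad1), "age")

  raw2 <- raw
  raw2$ALT[2] <- "not-a-number"
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw2, bad2, row.names = FALSE, na = "")
  expect_error(load_table(bad2), "row 2")

  raw3 <- raw
  raw3$gender[1] <- ""
  bad3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw3, bad3, row.names = FALSE, na = "")
  expect_error(load_table(bad3), "gender")

  # text-coded gender is accepted and recoded male=1/female=0
  raw4 <- raw
  raw4$gender <- ifelse(raw4$gender == "1", "male", "female")
  ok4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw4, ok4, row.names = FALSE, na = "")
  expect_equal(load_table(ok4)$values[, "A2"], fix$values[, "A2"])
})

test_that("missingness summary counts cells and whole-panel skips", {
  fix <- simulate_worked_fixture()
  ms <- missingness_summary(fix)
  expect_equal(sum(ms$per_attribute$missing_count), sum(!fix$observed))
  expect_equal(unname(ms$group_all_missing[c("D", "E")]), c(1L, 1L))
  expect_equal(unname(ms$group_all_missing[c("A", "F", "G")]), c(0L, 0L, 0L))

  full <- simulate_table(simulation_config(n_patients = 30,
                                           group_missing_prob = 0,
                                           cell_missing_prob = 0,
                                           seed = 2L))$table
  ms2 <- missingness_summary(full)
  expect_true(all(ms2$per_attribute$missing_count == 0))
  expect_true(all(ms2$group_all_missing == 0))
})

test_that("whole-panel skip counts match the generating probability", {
  # group-missing probability 0.3 at n = 1000: count within the central
  # 99% binomial interval [qbinom(.005), qbinom(.995)] = [263, 338]
  sim <- simulate_table(simulation_config(n_patients = 1000,
                                          group_missing_prob = 0.3,
                                          cell_missing_prob = 0,
                                          seed = 31L))
  ms <- missingness_summary(sim$table)
  lo <- qbinom(0.005, 1000, 0.3)
  hi <- qbinom(0.995, 1000, 0.3)
  for (g in c("B", "C", "D", "E")) {
    expect_gte(ms$group_all_missing[[g]], lo)
    expect_lte(ms$group_all_missing[[g]], hi)
  }
})
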