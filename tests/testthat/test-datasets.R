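test_that("the false-identification split rounds half up", {
  expect_identical(split_false_identifications(107, 6),
                   c(suspect = 18L, filler = 89L))
  expect_identical(split_false_identifications(9, 6),
                   c(suspect = 2L, filler = 7L))  # 1.5 rounds up
  expect_identical(split_false_identifications(0, 6),
                   c(suspect = 0L, filler = 0L))
  expect_error(split_false_identifications(-1, 6), ">= 0")
})

test_that("the split rule reproduces every reconstructed suspect/filler pair", {
  for (name in fixture_names()) {
    fx <- lineup_fixture(name)
    if (!all(fx$data$reconstructed_ca)) next
    for (i in seq_len(nrow(fx$data))) {
      total_false <- fx$data$ca_suspect[i] + fx$data$ca_filler[i]
      sp <- split_false_identifications(total_false, fx$data$lineup_size[i])
      expect_identical(unname(sp["suspect"]), as.integer(fx$data$ca_suspect[i]),
                       info = paste(name, fx$data$condition[i]))
      expect_identical(unname(sp["filler"]), as.integer(fx$data$ca_filler[i]))
    }
  }
})

test_that("equal cell counts divide balanced samples and refuse unbalanced ones", {
  expect_identical(equal_cell_counts(84, 4), 21L)
  expect_identical(equal_cell_counts(80, 4), 20L)
  expect_identical(equal_cell_counts(12, 3), 4L)
  expect_error(equal_cell_counts(10, 3), "not divisible")
})

test_that("fixture frequencies carry the source participant totals", {
  memon <- lineup_fixture("memon2003")$data
  cnt <- as.matrix(memon[lineup2ht:::count_cols])
  expect_true(all(rowSums(cnt[, 1:3]) == c(21, 21, 20, 20)))
  expect_true(all(rowSums(cnt[, 4:6]) == c(21, 21, 20, 20)))

  colloff <- lineup_fixture("colloff")$data
  unfair <- colloff[colloff$condition == "unfair", ]
  expect_identical(as.integer(unfair[c("cp_culprit", "cp_filler", "cp_reject")]),
                   c(629L, 206L, 275L))

  wb <- lineup_fixture("wilcock_bull")$data
  practice <- wb[wb$condition == "practice", ]
  expect_identical(as.integer(practice[c("ca_suspect", "ca_filler", "ca_reject")]),
                   c(2L, 12L, 36L))

  md <- lineup_fixture("malpass_devine")$data
  expect_identical(unique(md$lineup_size), 5L)
  expect_equal(sum(as.matrix(md[lineup2ht:::count_cols])), 100)

  kz <- lineup_fixture("karageorge_zajac")$data
  ctrl <- kz[kz$condition == "control", ]
  expect_identical(sum(as.integer(ctrl[c("cp_culprit", "cp_filler", "cp_reject")])), 53L)

  smith <- lineup_fixture("smith2014")$data
  expect_equal(sum(as.matrix(smith[lineup2ht:::count_cols])), 615)
})

test_that("every comparison-standard specification yields the published df", {
  published_df <- c(memon2003 = 10L, smith2014 = 2L, wetmore = 9L, colloff = 9L,
                    malpass_devine = 2L, lampinen = 6L, karageorge_zajac = 1L,
                    wilcock_bull = 1L)
  for (name in fixture_names()) {
    fx <- lineup_fixture(name)
    expect_identical(degrees_of_freedom(fx$comparison, fx$data),
                     published_df[[name]], info = name)
    for (r in fx$restrictions)
      expect_true(is_nested(r, fx$comparison), info = name)
  }
})

test_that("unknown fixture names raise a lookup error listing the registry", {
  expect_error(lineup_fixture("nosuch"), "memon2003")
  expect_error(lineup_fixture("nosuch"), "wilcock_bull")
})

test_that("fixtures export to the delimited data and JSON spec formats", {
  dir <- withr::local_tempdir()
  files <- export_fixture("karageorge_zajac", dir)
  expect_true(all(file.exists(file.path(dir, c(
    "karageorge_zajac_data.csv", "karageorge_zajac_comparison.json",
    "karageorge_zajac_restricted_dA.json")))))
  back <- read_lineup_data(file.path(dir, "karageorge_zajac_data.csv"))
  fx <- lineup_fixture("karageorge_zajac")
  expect_equal(as.data.frame(back), as.data.frame(fx$data))
  spec <- read_spec(file.path(dir, "karageorge_zajac_comparison.json"))
  expect_identical(degrees_of_freedom(spec, back), 1L)
})

test_that("data files with missing columns are refused by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  fx <- lineup_fixture("wilcock_bull")
  d <- as.data.frame(fx$data)
  d$ca_reject <- NULL
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_lineup_data(path), "ca_reject")
})
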