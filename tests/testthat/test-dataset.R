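test_that("packaged dataset has the experiment's cardinalities", {
  d <- fixture_data()
  expect_s3_class(d, "growth_dataset")
  expect_equal(nrow(d), 66)
  expect_equal(nrow(unique(as.data.frame(d)[, growth_inputs()[1:4]])), 22)
  expect_equal(sum(d$n), 264)
  expect_setequal(unique(d$sucrose), c(1, 3, 6))
  expect_false(any(duplicated(as.data.frame(d)[, growth_inputs()])))
})

test_that("named treatment records carry their transcribed values", {
  d <- as.data.frame(fixture_data())
  rec <- function(b, r, w, fr, s) {
    d[d$blue == b & d$red == r & d$white == w & d$far_red == fr &
        d$sucrose == s, ]
  }
  # best shoot length: 25 W + 25 Fr at 3 % sucrose
  expect_equal(rec(0, 0, 25, 25, 3)$mean_shoot_length, 154.68)
  expect_equal(rec(0, 0, 25, 25, 3)$se_shoot_length, 51.228)
  # rootless treatments
  expect_equal(rec(100, 0, 0, 0, 1)$mean_root_length, 0)
  expect_equal(rec(0, 0, 50, 50, 1)$mean_root_length, 0)
  # 27.70 +/- 2.311 mm shoot belongs to the 100 W + 1 % treatment
  expect_equal(rec(0, 0, 100, 0, 1)$mean_shoot_length, 27.70)
  expect_equal(rec(0, 0, 100, 0, 1)$se_shoot_length, 2.311)
})

test_that("trait_matrix gives fixed-order design matrices", {
  d <- fixture_data()
  tm <- trait_matrix(d, "shoot_length")
  expect_equal(dim(tm$X), c(66, 5))
  expect_equal(colnames(tm$X), growth_inputs())
  expect_length(tm$y, 66)
  # largest canopy at 50 B + 50 R + 3 % sucrose
  ca <- trait_matrix(d, "canopy_area")
  i <- which.max(ca$y)
  expect_equal(unname(ca$X[i, ]), c(50, 50, 0, 0, 3))
  # root length contains exact zeros
  expect_true(any(trait_matrix(d, "root_length")$y == 0))
  expect_error(trait_matrix(d, "leaf_count"), "valid traits")
})

test_that("trait_extremes reports the dataset's extrema", {
  ex <- trait_extremes(fixture_data())
  get <- function(tr, col) ex[ex$trait == tr, col]
  expect_equal(get("shoot_length", "max"), 154.68)
  expect_equal(get("shoot_length", "min"), 22.95)
  expect_equal(get("root_length", "max"), 477.10)
  expect_equal(get("root_length", "min"), 0)
  expect_equal(get("node_number", "max"), 11.50)
  expect_equal(get("node_number", "min"), 5.75)
  expect_equal(get("canopy_area", "max"), 13061.97)
  expect_equal(get("canopy_area", "min"), 493.01)
  # maximizing treatments
  expect_equal(unlist(get("node_number", paste0("max_", growth_inputs())),
                      use.names = FALSE), c(33.33, 33.33, 0, 33.33, 3))
  # single-record dataset: max equals min
  one <- validate_growth_dataset(as.data.frame(fixture_data())[1, ])
  ex1 <- trait_extremes(one)
  expect_equal(ex1$max, ex1$min)
})

test_that("CSV round-trips are lossless in both layouts", {
  d <- fixture_data()
  for (fmt in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_growth_csv(d, path, format = fmt)
    back <- read_growth_csv(path)
    expect_equal(as.data.frame(back), as.data.frame(d),
                 ignore_attr = TRUE)
  }
})

test_that("validation rejects malformed datasets with row numbers", {
  d <- as.data.frame(fixture_data())
  bad <- d
  bad$sucrose[3] <- -1
  expect_error(validate_growth_dataset(bad), "row 3")
  expect_error(validate_growth_dataset(d[, -4]), "far_red")
  bad <- d
  bad$mean_root_length[7] <- -5
  expect_error(validate_growth_dataset(bad), "row 7")
  bad <- d
  bad[2, growth_inputs()] <- bad[1, growth_inputs()]
  expect_error(validate_growth_dataset(bad), "duplicate")
})
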