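test_that("sampled inputs stay inside the ranges and are unique", {
  n <- 2000
  x <- sample_inputs(n, seed = 5)
  rg <- scenario_ranges()
  for (nm in names(rg)) {
    expect_true(all(x[[nm]] >= rg[[nm]][1] & x[[nm]] <= rg[[nm]][2]),
                label = paste("range of", nm))
  }
  expect_equal(nrow(unique(x)), n)
  # determinism contract
  expect_identical(sample_inputs(50, seed = 9), sample_inputs(50, seed = 9))
  expect_false(identical(sample_inputs(50, seed = 9), sample_inputs(50, seed = 10)))
})

test_that("retained records respect the saturation band and schema", {
  ds <- small_dataset()
  rec <- ds$records
  expect_true(all(rec$sao2 >= 0.87 & rec$sao2 <= 0.98))
  expect_true(all(rec$fio2 >= 0.21 & rec$fio2 <= 0.99))
  # the ten features, in fixed order, come first
  expect_identical(names(rec)[1:10],
                   c("fio2", "hb", "sao2", "ph", "pao2", "paco2",
                     "mean_paco2", "co", "vco2", "r"))
  expect_true(all(c("shunt", "venad", "low_vq", "log_sd", "mean_vq") %in% names(rec)))
  expect_true(all(is.finite(as.matrix(rec[, 1:10]))))
})

test_that("labels are consistent: rerunning the model reproduces the features", {
  rec <- small_dataset()$records
  for (i in c(3, 17, 41)) {
    row <- rec[i, ]
    inp <- lung_inputs(row$shunt / 100, row$log_sd, row$mean_vq,
                       metabolic_state(row$vco2, row$r, row$co),
                       blood_params(row$hb, row$p50st, row$be))
    f <- run_forward(inp, fio2 = row$fio2)
    expect_equal(f$sao2, row$sao2, tolerance = 1e-6)
    expect_equal(f$pao2, row$pao2, tolerance = 1e-5)
    expect_equal(f$paco2, row$paco2, tolerance = 1e-5)
    expect_equal(f$mean_paco2, row$mean_paco2, tolerance = 1e-5)
    expect_equal(100 * f$venad, row$venad, tolerance = 1e-4)
  }
})

test_that("dataset generation is reproducible from the seed", {
  a <- build_dataset(40, seed = 77, quiet = TRUE)
  b <- build_dataset(40, seed = 77, quiet = TRUE)
  expect_identical(a$records, b$records)
})

test_that("randomized split is disjoint, sized, and distributionally balanced", {
  ds <- small_dataset()
  rec <- ds$records
  expect_equal(sum(rec$split == "test"), 50)
  expect_equal(sum(rec$split == "train"), nrow(rec) - 50)
  # same record cannot be in both splits
  expect_equal(length(intersect(which(rec$split == "test"),
                                which(rec$split == "train"))), 0)
  ks <- suppressWarnings(stats::ks.test(rec$shunt[rec$split == "train"],
                                        rec$shunt[rec$split == "test"]))
  expect_gt(ks$p.value, 0.01)
  expect_error(randomize_split(ds, n_test = nrow(rec)), "smaller")
})

test_that("datasets round-trip through CSV", {
  ds <- small_dataset()
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$records$sao2, ds$records$sao2, tolerance = 1e-12)
  expect_equal(back$records$split, ds$records$split)
  unlink(path)
  # missing feature columns are reported by name
  bad <- ds$records[, setdiff(names(ds$records), "mean_paco2")]
  path2 <- tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_dataset(path2), "mean_paco2")
  unlink(path2)
})
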