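test_that("the binomial fixture matches the reference pmf", {
  b <- fixture_binomial(8, 0.4)
  expect_equal(b$probs, dbinom(0:8, 8, 0.4), tolerance = 1e-14)
  expect_equal(b$probs[9], 0.4^8)
  expect_equal(sum(b$probs), 1, tolerance = 1e-12)
  expect_equal(round(1 / b$probs[9], 2), 1525.88)
  expect_equal(fixture_binomial(1, 0.5)$probs, c(0.5, 0.5))
  expect_error(fixture_binomial(0, 0.5), "positive integer")
  expect_error(fixture_binomial(8, 1.2), "0, 1")
})

test_that("the exponential fixture has the closed-form diversity", {
  e1 <- fixture_exponential(1)
  expect_equal(part_summary(e1, NULL)$diversity, exp(1), tolerance = 1e-12)
  e2 <- fixture_exponential(2)
  expect_equal(mass_on(e2, interval_union(0, 0.5)), 1 - exp(-1))
  expect_error(fixture_exponential(-1), "positive")
})

test_that("incidence fixtures are unimodal, deterministic and split binary", {
  d <- fixture_incidence(20, 4, 0.8, seed = 7)
  expect_length(d$probs, 20)
  expect_equal(which.max(d$probs), 5)   # zero-based peak_bin 4
  expect_identical(d$labels[1], "0-4")
  expect_identical(d$labels[20], "95-99")
  # unimodal: increasing up to the mode, decreasing after
  expect_true(all(diff(d$probs[1:5]) > 0))
  expect_true(all(diff(d$probs[5:20]) < 0))
  expect_identical(fixture_incidence(20, 4, 0.8, seed = 7), d)
  expect_false(identical(fixture_incidence(20, 4, 0.8, seed = 8), d))

  # no ties: every split in the tree is binary (empty Z)
  for (seed in c(7, 21)) {
    tr <- build_tree(fixture_incidence(20, 4, 0.8, seed = seed))
    roles <- vapply(tr$nodes, `[[`, "", "role")
    expect_false(any(roles == "Z"))
  }
})

test_that("monotone load fixtures increase strictly and split binary", {
  d <- fixture_monotone_load(21, seed = 3)
  expect_length(d$probs, 21)
  expect_true(all(diff(d$probs) > 0))
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  expect_identical(fixture_monotone_load(21, seed = 3), d)
  roles <- vapply(build_tree(d)$nodes, `[[`, "", "role")
  expect_false(any(roles == "Z"))
})

test_that("histogram files round-trip in CSV and TSV, probs and counts", {
  d <- fixture_null_example()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_histogram(d, csv)
  expect_equal(read_histogram(csv)$probs, d$probs)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tcount", paste(letters[1:4], c(1, 1, 2, 4), sep = "\t")),
             tsv)
  d2 <- read_histogram(tsv)
  expect_equal(d2$probs, c(1, 1, 2, 4) / 8)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "a,0.5"), bad)
  expect_error(read_histogram(bad), "label")
  expect_error(read_histogram("no/such/file.csv"), "not found")
})

test_that("density specifications round-trip through JSON and CSV", {
  e <- exponential_density(2)
  j <- withr::local_tempfile(fileext = ".json")
  write_density(e, j)
  e2 <- read_density(j)
  expect_identical(e2$family, "exponential")
  expect_equal(e2$params$rate, 2)

  pw <- piecewise_density(c(0, 4, 10, 11), c(0.05, 0.1, 0.2))
  j2 <- withr::local_tempfile(fileext = ".json")
  write_density(pw, j2)
  pw2 <- read_density(j2)
  expect_equal(pw2$params$breaks, pw$params$breaks)
  expect_equal(pw2$params$heights, pw$params$heights)

  csvd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("break,height", "0,0.05", "4,0.1", "10,0.2", "11,"), csvd)
  pw3 <- read_density(csvd)
  expect_equal(pw3$params$heights, c(0.05, 0.1, 0.2))
  expect_error(read_density(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("tree JSON export round-trips bit-identically", {
  for (src in list(fixture_binomial(8, 0.4), exponential_density(2))) {
    tr <- build_tree(src)
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    write_tree(tr, f1)
    tr2 <- read_tree(f1)
    write_tree(tr2, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(tree_depth(tr2), tree_depth(tr))
    for (i in seq_along(tr$nodes)) {
      expect_equal(tr2$nodes[[i]]$summary$dou, tr$nodes[[i]]$summary$dou)
      expect_identical(tr2$nodes[[i]]$role, tr$nodes[[i]]$role)
      expect_identical(tr2$nodes[[i]]$children, tr$nodes[[i]]$children)
    }
    # infinite endpoints survive the round trip
    if (!tr$discrete)
      expect_true(is.infinite(unclass(tr2$nodes[[1]]$part)[, "hi"]))
  }
})

test_that("the command-line interface decomposes, designs and audits", {
  cli <- system.file("cli", "ineqtree.R", package = "ineqtree")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))

  hist <- withr::local_tempfile(fileext = ".csv")
  write_histogram(fixture_null_example(), hist)
  out <- withr::local_tempfile(fileext = ".json")
  res <- system2(rscript, c(cli, "decompose", "--input", hist, "--out", out),
                 stdout = TRUE, stderr = TRUE, env = env)
  expect_null(attr(res, "status"))
  expect_true(file.exists(out))
  expect_equal(level_view(read_tree(out), 1)$dou, c(20, 10, 5))

  res2 <- system2(rscript, c(cli, "null-design", "--cz", "0.6", "--eta1", "2",
                             "--eta2", "0.5", "--D", "10", "--discrete"),
                  stdout = TRUE, stderr = TRUE, env = env)
  expect_null(attr(res2, "status"))
  expect_true(any(grepl("cP = 0.2", res2)))

  res3 <- system2(rscript, c(cli, "audit", "--input", hist,
                             "--samples", "40", "--seed", "1"),
                  stdout = TRUE, stderr = TRUE, env = env)
  expect_null(attr(res3, "status"))
  expect_true(any(grepl("violations: 0", res3)))

  res4 <- suppressWarnings(
    system2(rscript, c(cli, "decompose", "--input", "missing.csv"),
            stdout = TRUE, stderr = TRUE, env = env))
  expect_identical(attr(res4, "status"), 1L)
})
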