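test_that("the designed null example yields a depth-1 ternary tree", {
  tr <- build_tree(fixture_null_example())
  expect_equal(tree_depth(tr), 1)
  lv <- level_view(tr, 1)
  expect_equal(lv$dou, c(20, 10, 5))
  expect_identical(lv$terminal_reason[2], "null_set")
  expect_identical(tr$nodes[[which(vapply(tr$nodes, `[[`, "", "role") == "Z")]]$terminal_reason,
                   "null_set")
  # the uniform positive part terminates as "uniform", not "null_set"
  expect_identical(lv$terminal_reason[1], "uniform")
})

test_that("the binomial tree refines to singleton leaves with known values", {
  b <- fixture_binomial(8, 0.4)
  tr <- build_tree(b)
  leaves <- Filter(function(n) length(n$children) == 0, tr$nodes)
  expect_true(all(vapply(leaves, function(n) length(n$part), integer(1)) == 1))
  expect_true(all(vapply(leaves, `[[`, "", "terminal_reason") == "singleton"))
  # leaf parts partition the support and masses add to 1
  leaf_labels <- unlist(lapply(leaves, `[[`, "part"))
  expect_setequal(leaf_labels, b$labels)
  expect_equal(sum(vapply(leaves, function(n) n$summary$mass, numeric(1))),
               1, tolerance = 1e-10)

  lv2 <- level_view(tr, 2)
  expect_identical(lv2$part,
                   c("{0,6,7,8}", "{1,5}", "{2,4}", "{3}"))
  expect_equal(round(lv2$dou[4], 2), 3.59)

  # dou of named parts anywhere in the tree matches direct recomputation
  find_part <- function(tree, labs) {
    for (n in tree$nodes)
      if (setequal(n$part, labs)) return(n)
    NULL
  }
  expect_equal(round(find_part(tr, c("7", "8"))$summary$dou, 2), 153.94)
  expect_equal(round(find_part(tr, "0")$summary$dou, 2), 59.54)
  expect_equal(round(find_part(tr, "8")$summary$dou, 2), 1525.88)
})

test_that("every level view is strictly decreasing in dou", {
  set.seed(31)
  sources <- list(fixture_binomial(8, 0.4), fixture_null_example(),
                  random_dist(15), fixture_incidence(20, 4, 0.8, seed = 7),
                  carryover_dist())
  for (src in sources) {
    tr <- build_tree(src)
    for (k in seq_len(tree_depth(tr))) {
      dou <- level_view(tr, k)$dou
      expect_true(all(diff(dou) < 0))
    }
  }
  expect_error(level_view(build_tree(fixture_binomial(8, 0.4)), 99),
               "between")
})

test_that("null sets are carried over into deeper levels at their position", {
  d <- carryover_dist()
  tr <- build_tree(d)
  expect_gte(tree_depth(tr), 2)
  lv1 <- level_view(tr, 1)
  expect_identical(lv1$terminal_reason[2], "null_set")
  expect_equal(lv1$dou[2], 10, tolerance = 1e-9)
  lv2 <- level_view(tr, 2)
  # the positive part split again; Z sits between the P-descendants and N
  zrow <- which(lv2$terminal_reason == "null_set")
  expect_equal(lv2$dou[zrow], 10, tolerance = 1e-9)
  expect_true(all(lv2$dou[seq_len(zrow - 1)] > 10))
  expect_true(all(lv2$dou[-seq_len(zrow)] < 10))

  # continuous analogue
  pw <- carryover_density()
  trc <- build_tree(pw)
  lv2c <- level_view(trc, 2)
  zc <- which(lv2c$terminal_reason == "null_set")
  expect_equal(lv2c$dou[zc], 10, tolerance = 1e-9)
  expect_true(all(diff(lv2c$dou) < 0))
})

test_that("parent-child ordering and geometric-mean conservation hold nodewise", {
  set.seed(77)
  for (src in list(fixture_binomial(8, 0.4), random_dist(12),
                   carryover_density())) {
    tr <- build_tree(src)
    for (n in tr$nodes) {
      if (!length(n$children)) next
      kids <- lapply(n$children, function(id) tr$nodes[[id]])
      roles <- vapply(kids, `[[`, "", "role")
      dous <- vapply(kids, function(k) k$summary$dou, numeric(1))
      if ("P" %in% roles) expect_gt(dous[roles == "P"], n$summary$dou)
      if ("N" %in% roles) expect_lt(dous[roles == "N"], n$summary$dou)
      if ("Z" %in% roles)
        expect_equal(dous[roles == "Z"], n$summary$dou, tolerance = 1e-9)
      # conservation: c*log(dou) of the node equals the sum over children
      lhs <- n$summary$mass * log(n$summary$dou)
      rhs <- sum(vapply(kids, function(k)
        k$summary$mass * log(k$summary$dou), numeric(1)))
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("the exponential tree reproduces the known breakpoints", {
  e <- exponential_density(2)
  tr2 <- build_tree(e, max_depth = 2)
  expect_equal(round(level_breakpoints(tr2, 2), 2), c(0.21, 0.5, 1))
  expect_equal(level_breakpoints(tr2, 1), 0.5, tolerance = 1e-9)
  expect_equal(min(level_breakpoints(tr2, 2)), 0.2090116, tolerance = 1e-6)

  tr3 <- build_tree(e, max_depth = 3)
  bp3 <- level_breakpoints(tr3, 3)
  expect_length(bp3, 7)
  expect_equal(max(bp3), 1.5, tolerance = 1e-9)
  expect_equal(round(min(bp3), 2), 0.1)
})

test_that("construction is deterministic and respects depth/mass guards", {
  b <- fixture_binomial(8, 0.4)
  t1 <- build_tree(b); t2 <- build_tree(b)
  expect_identical(t1, t2)

  t3 <- build_tree(b, max_depth = 1)
  expect_equal(tree_depth(t3), 1)
  expect_true(all(vapply(Filter(function(n) n$created_level == 1, t3$nodes),
                         `[[`, "", "terminal_reason") == "max_depth"))
  t4 <- build_tree(b, min_mass = 0.5)
  expect_lte(tree_depth(t4), 2)
  expect_true(any(vapply(t4$nodes, `[[`, "", "terminal_reason") == "min_mass"))

  # a tree can be rooted at any sub-part, not only the full support
  t5 <- build_tree(b, part = c("0", "6", "7", "8"))
  expect_setequal(t5$nodes[[1]]$part, c("0", "6", "7", "8"))
  expect_gte(tree_depth(t5), 1)
})

test_that("ratio reports are reciprocal with unit diagonal", {
  tr <- build_tree(fixture_null_example())
  r <- ratio_report(tr, 1)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r * t(r), matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(r[1, 2], 2)   # 20 / 10
  expect_equal(r[1, 3], 4)   # 20 / 5
  expect_equal(r[2, 3], 2)   # 10 / 5

  b <- fixture_binomial(8, 0.4)
  trb <- build_tree(b)
  rb <- ratio_report(trb, 2)
  expect_equal(rb[1, 4],
               part_summary(b, c(0, 6, 7, 8))$dou / part_summary(b, 3)$dou)
})

test_that("the monotonicity audit passes on standard trees", {
  b <- fixture_binomial(8, 0.4)
  rep_b <- monotonicity_audit(build_tree(b), b, n_samples = 200, seed = 1)
  expect_equal(rep_b$violations, 0)
  expect_equal(rep_b$n_pairs, 200)

  z <- fixture_null_example()
  rep_z <- monotonicity_audit(build_tree(z), z, n_samples = 100, seed = 2)
  expect_equal(rep_z$violations, 0)

  e <- exponential_density(2)
  rep_e <- monotonicity_audit(build_tree(e), e, n_samples = 60, seed = 3)
  expect_equal(rep_e$violations, 0)

  # single-node tree: empty report
  u <- discrete_distribution(1:3, rep(1 / 3, 3))
  rep_u <- monotonicity_audit(build_tree(u), u)
  expect_true(rep_u$trivial)
  expect_equal(rep_u$n_pairs, 0)
})
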