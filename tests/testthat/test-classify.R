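test_that("the two-group boundary sits at the midpoint of the means", {
  X <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
  grp <- rep(c("a", "b"), each = 3)
  model <- train_lda(X, grp, var_retain = 1)
  expect_equal(as.character(classify(model, matrix(0.999))$assigned), "a")
  expect_equal(as.character(classify(model, matrix(1.001))$assigned), "b")
  # score difference vanishes exactly at the midpoint
  sc <- suppressWarnings(classify(model, matrix(1))$scores)
  expect_equal(unname(sc[1, "a"]), unname(sc[1, "b"]), tolerance = 1e-10)
})

test_that("specimens at a group mean are assigned to that group", {
  set.seed(41)
  sim <- make_groups(20, list(a = c(0, 0, 0), b = c(8, 0, 0), c = c(0, 8, 0)))
  model <- train_lda(sim$X, sim$groups)
  for (lev in levels(sim$groups)) {
    m <- colMeans(sim$X[sim$groups == lev, ])
    expect_equal(as.character(classify(model, t(m))$assigned), lev)
  }
})

test_that("duplicated groups score identically and tie lexicographically", {
  set.seed(42)
  base <- matrix(rnorm(30), 10, 3)
  X <- rbind(base, base, base + 50)
  grp <- c(rep("dup2", 10), rep("dup1", 10), rep("far", 10))
  model <- train_lda(X, grp, var_retain = 1)
  sc <- suppressWarnings(classify(model, base))
  expect_lt(max(abs(sc$scores[, "dup1"] - sc$scores[, "dup2"])), 1e-10)
  expect_warning(res <- classify(model, base), "tie")
  expect_true(all(res$assigned == "dup1"))  # lexicographically first
})

test_that("assignments agree with MASS::lda on separable data", {
  skip_if_not_installed("MASS")
  set.seed(43)
  sim <- make_groups(25, list(a = c(0, 0, 0, 0), b = c(3, 0, 1, 0),
                              c = c(0, 3, 0, -1), d = c(-2, -2, 2, 0)))
  model <- train_lda(sim$X, sim$groups, var_retain = 1)
  mine <- classify(model, sim$X)$assigned
  ref <- MASS::lda(sim$X, sim$groups, prior = rep(1 / 4, 4))
  theirs <- stats::predict(ref, sim$X)$class
  expect_equal(as.character(mine), as.character(theirs))
})

test_that("classification is invariant to a constant shift of all data", {
  set.seed(44)
  sim <- make_groups(15, list(a = c(0, 0), b = c(4, 1)))
  m1 <- train_lda(sim$X, sim$groups, var_retain = 1)
  shift <- sweep(sim$X, 2, c(100, -50), "+")
  m2 <- train_lda(shift, sim$groups, var_retain = 1)
  q <- matrix(c(1.2, 0.3), ncol = 2)
  expect_equal(as.character(classify(m1, q)$assigned),
               as.character(classify(m2, sweep(q, 2, c(100, -50), "+"))$assigned))
})

test_that("NA-labelled rows train nothing but remain classifiable", {
  set.seed(45)
  sim <- make_groups(10, list(a = c(0, 0), b = c(6, 0)))
  X <- rbind(sim$X, matrix(rnorm(10) + c(6, 0), 5, 2, byrow = FALSE))
  grp <- c(as.character(sim$groups), rep(NA, 5))
  model <- train_lda(X, grp)
  expect_equal(model$n_train, 20)
  res <- classify(model, X[21:25, , drop = FALSE])
  expect_s3_class(res, "wing_classification")
})

test_that("provenance check blocks mixing separate superimpositions", {
  set.seed(46)
  ds1 <- concentrated_dataset(12, 8)
  ds2 <- concentrated_dataset(12, 8)
  g1 <- gpa_align(ds1); g2 <- gpa_align(ds2)
  model <- train_lda(g1, rep(c("a", "b"), each = 6))
  expect_error(classify(model, g2), "provenance")
  expect_silent(classify(model, g1))
})

test_that("accuracy metrics behave on separated and permuted labels", {
  set.seed(47)
  sim <- make_groups(12, list(a = c(0, 0, 0), b = c(9, 0, 0),
                              c = c(0, 9, 0), d = c(0, 0, 9)))
  expect_equal(resubstitution_accuracy(sim$X, sim$groups), 1)
  expect_equal(loocv_accuracy(sim$X, sim$groups), 1)
  # determinism
  expect_identical(loocv_accuracy(sim$X, sim$groups),
                   loocv_accuracy(sim$X, sim$groups))
  expect_error(loocv_accuracy(sim$X[c(1, 2, 13, 14), ],
                              sim$groups[c(1, 2, 13, 14)]), ">= 3")
})

test_that("frequency tables are percentages with conserved marginals", {
  assigned <- factor(c(rep("A", 18), rep("B", 2)), levels = c("A", "B"))
  pop <- rep("apiary1", 20)
  tab <- frequency_report(assigned, pop)
  expect_equal(unname(tab["apiary1", "A"]), 90)
  expect_equal(unname(rowSums(tab)), 100)
  expect_equal(unname(attr(tab, "n")), 20)
  expect_error(frequency_report(assigned, pop[-1]), "same length")

  set.seed(48)
  assigned <- factor(sample(c("x", "y", "z"), 60, replace = TRUE))
  pop <- rep(c("p1", "p2", "p3"), each = 20)
  tab <- frequency_report(assigned, pop)
  expect_equal(unname(rowSums(tab)), rep(100, 3), tolerance = 1e-9)
  counts <- sweep(tab, 1, attr(tab, "n") / 100, "*")
  expect_equal(colSums(counts), as.vector(table(assigned)),
               ignore_attr = TRUE)
})

test_that("Africanization table splits floors into two morphotype rows", {
  assigned <- c(rep("scutellata", 9), "carnica", rep("ligustica", 5),
                rep("AB", 5))
  floors <- c(rep("2600-2800", 10), rep("2801-3000", 5), rep("3001-3274", 5))
  tab <- africanization_table(assigned, floors)
  expect_equal(dim(tab), c(2, 3))
  expect_equal(unname(colSums(tab)), rep(100, 3))
  expect_equal(unname(tab["Africanized", ]), c(90, 0, 100))
  expect_error(africanization_table(assigned, rep(NA, 20)), "floor")
})
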