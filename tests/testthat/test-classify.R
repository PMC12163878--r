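test_that("separable classes are classified perfectly in training", {
  set.seed(31)
  X <- rbind(matrix(rnorm(30 * 5, 0), 30), matrix(rnorm(30 * 5, 6), 30))
  labels <- rep(c("lo", "hi"), each = 30)
  m <- fit_plsda(X, labels, n_lv = 2)
  expect_identical(predict(m, X), labels)
  expect_equal(classification_metrics(labels, predict(m, X))$accuracy, 1)
})

test_that("binary model on the study grouping trains on the default cohort", {
  s <- generate_cohort(cohort_design(seed = 32))
  labels <- regroup_classes(s$meta$class,
                            c(`250` = "iron", `500` = "iron", `1000` = "iron"),
                            keep_unmapped = TRUE)
  expect_setequal(unique(labels), c("control", "iron"))
  pp <- fit_pipeline(pp_pipeline(pp_step("truncate", low = 900, high = 1800), pp_step("snv")),
                     s$absorbance, s$wavenumbers)
  m <- fit_plsda(pp$X, labels, n_lv = 3)
  expect_s3_class(m$core, "pls_model")
  expect_gt(classification_metrics(labels, predict(m, pp$X))$accuracy, 0.9)
})

test_that("randomly permuted labels train near chance on noise data", {
  set.seed(33)
  X <- matrix(rnorm(500 * 5), 500)
  labels <- sample(rep(c("a", "b"), 250))
  m <- fit_plsda(X, labels, n_lv = 2)
  acc <- classification_metrics(labels, predict(m, X))$accuracy
  # 0.5 plus a generous binomial margin (3 * sqrt(.25/500) ~ 0.067)
  expect_lt(acc, 0.6)
})

test_that("assign_class applies argmax, documented tie-breaks and thresholds", {
  sc <- diag(3); colnames(sc) <- c("x", "y", "z")
  expect_identical(assign_class(sc), c("x", "y", "z"))
  expect_identical(assign_class(rbind(c(0.4, 0.4)), classes = c("x", "y")), "x")
  # brute-force per-row maximum oracle
  set.seed(34)
  S <- matrix(rnorm(200 * 4), 200); colnames(S) <- letters[1:4]
  oracle <- apply(S, 1, function(r) colnames(S)[which.max(r)])
  expect_identical(assign_class(S), oracle)
  # threshold rule leaves ambiguous rows unassigned
  thr <- assign_class(rbind(c(0.9, 0.1), c(0.3, 0.2), c(0.7, 0.8)),
                      rule = "threshold", classes = c("x", "y"))
  expect_identical(thr, c("x", "unassigned", "unassigned"))
})

test_that("dummy coding is one-hot with rows summing to one", {
  Y <- dummy_code(c("a", "b", "a", "c"))
  expect_equal(rowSums(Y), rep(1, 4))
  expect_equal(colnames(Y), c("a", "b", "c"))
  expect_error(dummy_code(c("a", "q"), classes = c("a", "b")), "outside")
})

test_that("regrouping builds the three-class task with 10/27/15 animals", {
  s <- generate_cohort(cohort_design(seed = 35))
  three <- regroup_classes(s$meta$class, c(`250` = "mid", `500` = "mid"),
                           keep_unmapped = TRUE)
  counts <- table(three[s$meta$replicate == 1])
  expect_equal(unname(c(counts[c("control", "mid", "1000")])), c(10, 27, 15))
  # identity mapping changes nothing
  expect_identical(regroup_classes(c("a", "b"), c(a = "a", b = "b")), c("a", "b"))
  expect_error(regroup_classes(c("a", "b"), c(a = "x")), "unmapped")
  # collapsing everything to one class breaks the downstream fit
  one <- regroup_classes(s$meta$class,
                         c(control = "all", `250` = "all", `500` = "all", `1000` = "all"))
  expect_error(fit_plsda(s$absorbance, one, n_lv = 2), "2 classes")
})

test_that("classification metrics match hand counts and their identities", {
  got <- classification_metrics(c("+", "+", "-", "-"), c("+", "-", "-", "-"),
                                classes = c("+", "-"))
  row <- got$per_class[got$per_class$class == "+", ]
  expect_equal(row$sens, 0.5)
  expect_equal(row$spec, 1.0)
  expect_equal(row$acc, 0.75)
  expect_equal(row$fpr, 0)
  expect_equal(row$fnr, 0.5)
  # FPR = 1 - spec, FNR = 1 - sens, exactly, for every class
  set.seed(36)
  yt <- sample(letters[1:3], 200, replace = TRUE)
  yp <- sample(letters[1:3], 200, replace = TRUE)
  m <- classification_metrics(yt, yp)
  expect_equal(m$per_class$fpr, 1 - m$per_class$spec)
  expect_equal(m$per_class$fnr, 1 - m$per_class$sens)
  # confusion row sums equal class supports; order permutation invariant
  expect_equal(unname(rowSums(m$confusion)), unname(c(table(factor(yt, letters[1:3])))))
  o <- sample(200)
  m2 <- classification_metrics(yt[o], yp[o])
  expect_equal(m2$per_class, m$per_class)
  # all-majority predictor: minority sens 0, spec 1
  maj <- classification_metrics(c("a", "a", "a", "b"), rep("a", 4))
  expect_equal(maj$per_class$sens[maj$per_class$class == "b"], 0)
  expect_equal(maj$per_class$spec[maj$per_class$class == "b"], 1)
  expect_error(classification_metrics(c("a"), c("z"), classes = "a"), "outside")
})
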