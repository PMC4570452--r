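test_that("kernel evaluation follows the stated forms", {
  expect_identical(kernel_eval("linear", c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_eval("rbf", c(1, 2), c(1, 2), g = 0.7), 1)
  # squared distance equal to 2 g^2 gives exp(-1)
  g <- 1.3
  x <- c(0, 0); xp <- c(sqrt(2) * g, 0)
  expect_equal(kernel_eval("rbf", x, xp, g = g), exp(-1), tolerance = 1e-12)
  expect_error(kernel_eval("linear", 1:2, 1:3), "dimension mismatch")
  expect_error(kernel_eval("rbf", 1:2, 1:2, g = 0), "g must be")
})

test_that("training contracts: separability, single class, label coding", {
  x <- matrix(c(-2, 2), ncol = 1)
  m <- train_svm(x, c(-1L, 1L), "linear", C = 1, scale = FALSE)
  expect_identical(predict(m, x), c(-1L, 1L))
  expect_error(train_svm(x, c(1L, 1L), "linear"), "both classes")
  expect_error(train_svm(x, c(0L, 1L), "linear"), "-1/\\+1")
})

test_that("zero decision value maps to the drowsy class (+1)", {
  m <- train_svm(matrix(c(-1, 1)), c(-1L, 1L), "linear", C = 1,
                 scale = FALSE)
  expect_equal(predict(m, matrix(0), type = "decision"), 0,
               tolerance = 1e-12)
  expect_identical(predict(m, matrix(0)), 1L)
})

test_that("predict agrees with an explicit kernel-sum decision oracle", {
  set.seed(21)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  y <- ifelse(x[, 1] + x[, 2] + rnorm(40, 0, 0.5) > 0, 1L, -1L)
  for (kern in c("linear", "rbf")) {
    m <- train_svm(x, y, kern, C = 2, g = 0.8)
    xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
    oracle <- vapply(seq_len(nrow(xs)), function(i) {
      sum(vapply(seq_len(m$n_sv), function(j)
        m$coef[j] * kernel_eval(kern, m$sv[j, ], xs[i, ], g = m$g), 0)) + m$b
    }, 0)
    expect_equal(predict(m, x, type = "decision"), oracle,
                 tolerance = 1e-10)
    expect_identical(predict(m, x), ifelse(oracle >= 0, 1L, -1L))
  }
})

test_that("solver reproduces an independent SVM implementation", {
  # reference values frozen from scikit-learn SVC on the identical dataset
  # (linear: C = 1; rbf: C = 2, gamma = 1/(2 g^2) with g = 0.5)
  set.seed(7)
  n <- 60
  x <- cbind(rnorm(n), rnorm(n))
  y <- ifelse(x[, 1] + 0.7 * x[, 2] + rnorm(n, 0, 0.8) > 0, 1L, -1L)

  m_lin <- train_svm(x, y, "linear", C = 1, scale = FALSE, tol = 1e-4)
  expect_equal(m_lin$b, 0.30299004, tolerance = 1e-4)
  expect_equal(predict(m_lin, x, type = "decision")[1:5],
               c(3.23817012, -1.13418716, -0.30723283, 0.12979329,
                 -0.76862696),
               tolerance = 1e-4)

  m_rbf <- train_svm(x, y, "rbf", C = 2, g = 0.5, scale = FALSE, tol = 1e-4)
  expect_equal(predict(m_rbf, x, type = "decision")[1:5],
               c(0.99999637, -0.57032676, -0.56879177, 0.09355022,
                 -0.83091184),
               tolerance = 1e-2)
  # sklearn training accuracy on this dataset: 49/60
  expect_equal(mean(predict(m_rbf, x) == y), 49 / 60)
})

test_that("feature scaling is encapsulated inside the model", {
  set.seed(5)
  x <- cbind(rnorm(30, 40, 3), rnorm(30, 120, 40))
  y <- rep(c(-1L, 1L), 15)
  m <- train_svm(x, y, "rbf", C = 1, g = 1, scale = TRUE)
  xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  m0 <- train_svm(xs, y, "rbf", C = 1, g = 1, scale = FALSE)
  expect_equal(predict(m, x, type = "decision"),
               predict(m0, xs, type = "decision"), tolerance = 1e-8)
  expect_error(predict(m, matrix(1, 1, 3)), "expected 2 features")
})

test_that("JSON model persistence is bit-reproducible", {
  set.seed(13)
  x <- matrix(rnorm(30 * 2), ncol = 2)
  y <- rep(c(-1L, 1L), 15)
  m <- train_svm(x, y, "rbf", C = 3, g = 0.9)
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(predict(m2, x, type = "decision"),
                   predict(m, x, type = "decision"))
  expect_identical(m2$kernel, "rbf")
  expect_identical(m2$b, m$b)
})
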