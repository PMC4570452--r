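test_that("metrics follow the Acc/Sens/Spec definitions", {
  m <- svm_metrics(list(tp = 191, tn = 65, fp = 3, fn = 7))
  expect_equal(round(unname(m), 2), c(96.24, 96.46, 95.59))

  expect_equal(unname(svm_metrics(list(tp = 5, tn = 3, fp = 0, fn = 0))),
               c(100, 100, 100))
  expect_equal(unname(svm_metrics(list(tp = 4, tn = 6, fp = 6, fn = 4)))[2:3],
               c(50, 50))
  expect_warning(m0 <- svm_metrics(list(tp = 2, tn = 0, fp = 0, fn = 1)),
                 "undefined")
  expect_true(is.na(m0["spec"]))
})

test_that("confusion reconstruction inverts printed sensitivity/specificity", {
  cm <- reconstruct_confusion(96.46, 95.59, 198, 68)
  expect_identical(c(cm$tp, cm$tn, cm$fp, cm$fn), c(191, 65, 3, 7))

  cm2 <- reconstruct_confusion(95.45, 45.59, 198, 68)
  expect_identical(c(cm2$tp, cm2$tn), c(189, 31))

  cm3 <- reconstruct_confusion(100, 0, 198, 68)
  expect_identical(c(cm3$tp, cm3$tn), c(198, 0))

  # no exact integer pre-image at the printed precision
  expect_warning(reconstruct_confusion(50, 50, 3, 68), "0.005")

  # round trip to 2 dp whenever a pre-image exists
  set.seed(2)
  for (i in 1:50) {
    P <- sample(50:250, 1); N <- sample(30:100, 1)
    tp <- sample(0:P, 1); tn <- sample(0:N, 1)
    s <- round(100 * tp / P, 2); p <- round(100 * tn / N, 2)
    cm <- reconstruct_confusion(s, p, P, N)
    m <- svm_metrics(cm)
    expect_equal(round(unname(m[2:3]), 2), c(s, p))
  }
})

test_that("a constant drowsy classifier reproduces the degenerate row", {
  truth <- c(rep(1L, 198), rep(-1L, 68))
  m <- svm_metrics(confusion_matrix(truth, rep(1L, 266)))
  expect_equal(unname(m["sens"]), 100)
  expect_equal(unname(m["spec"]), 0)
  expect_equal(unname(m["acc"]), 100 * 198 / 266, tolerance = 1e-12)
  expect_equal(round(unname(m["acc"]), 1), 74.4)
})

test_that("LOSO runs one round per subject with pooled counting", {
  w <- separable_windows(n_subjects = 6)
  cv <- loso_crossval(w, "mp", "linear", C = 1)
  expect_identical(nrow(cv$rounds), 6L)
  expect_identical(sum(cv$rounds$n), nrow(w))
  expect_identical(cv$cm$tp + cv$cm$tn + cv$cm$fp + cv$cm$fn, nrow(w))
  # MP fully determines the label here: pooled accuracy 100%
  expect_equal(unname(cv$metrics["acc"]), 100)

  expect_error(loso_crossval(w[w$subject == "S1", ], "mp", "linear"),
               ">= 2 subjects")

  w_bad <- w
  w_bad$label[w_bad$subject != "S1"] <- 1L
  expect_error(loso_crossval(w_bad, "mp", "linear"), "single class")
})

test_that("grid optimisation is exhaustive with deterministic tie-breaking", {
  w <- separable_windows(n_subjects = 4)

  single <- grid_optimize(w, "mp", "linear", C_grid = 0.5)
  expect_equal(single$best_C, 0.5)

  # separable instance: many points reach 100%; smallest C (then g) wins
  opt <- grid_optimize(w, "mp", "rbf", C_grid = c(10, 1, 0.1),
                       g_grid = c(2, 0.5))
  expect_equal(max(opt$grid$acc), unname(opt$best$metrics["acc"]))
  winners <- opt$grid[opt$grid$acc == max(opt$grid$acc), ]
  expect_equal(opt$best_C, min(winners$C))
  expect_equal(opt$best_g,
               min(winners$g[winners$C == opt$best_C]))

  # every grid point's accuracy is <= the winner's (re-evaluated)
  for (i in seq_len(nrow(opt$grid))) {
    cv_i <- loso_crossval(w, "mp", "rbf", C = opt$grid$C[i],
                          g = opt$grid$g[i])
    expect_equal(unname(cv_i$metrics["acc"]), opt$grid$acc[i])
    expect_lte(opt$grid$acc[i], unname(opt$best$metrics["acc"]))
  }

  expect_error(grid_optimize(w, "mp", "rbf", C_grid = numeric()),
               "empty grid")
})

test_that("the published sweep has 1000 points per axis", {
  expect_identical(length(published_grid()), 1000L)
  expect_equal(min(published_grid()), 0.01)
  expect_equal(max(published_grid()), 10)
})
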