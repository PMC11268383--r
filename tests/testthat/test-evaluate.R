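test_that("classification metrics reproduce hand-computed confusion arithmetic", {
  # TP=2, FP=1, FN=1, TN=6 on 10 samples
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  p <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  m <- classification_metrics(y, p)
  expect_equal(m$accuracy, 0.8, tolerance = 1e-9)
  expect_equal(unname(m$per_class_f1["cancer"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(m$per_class_f1["normal"]), 6 / 7, tolerance = 1e-9)
  expect_equal(m$weighted_f1, (3 * 2 / 3 + 7 * 6 / 7) / 10, tolerance = 1e-9)
  expect_equal(m$weighted_f1, 0.8, tolerance = 1e-9)
  expect_equal(m$sensitivity, 2 / 3, tolerance = 1e-9)
})

test_that("perfect and anti-perfect scores bracket the AU-ROC", {
  y <- c(0, 0, 1, 1)
  m1 <- classification_metrics(y, y, scores = c(.1, .2, .8, .9))
  expect_equal(unlist(m1[c("accuracy", "weighted_f1", "sensitivity",
                           "auroc")]),
               c(accuracy = 1, weighted_f1 = 1, sensitivity = 1, auroc = 1))
  m0 <- classification_metrics(y, y, scores = c(.9, .8, .2, .1))
  expect_equal(m0$auroc, 0)
})

test_that("AU-ROC is a rank statistic: monotone-invariant, tie-averaged", {
  set.seed(8)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(40)
  a <- classification_metrics(y, y, scores = s)$auroc
  expect_equal(classification_metrics(y, y, scores = exp(s))$auroc, a)
  expect_equal(classification_metrics(y, y, scores = 5 * s - 2)$auroc, a)
  # cross-check against the ROC package on the same scores
  expect_equal(a, as.numeric(suppressMessages(
    pROC::auc(y, s, direction = "<", levels = c(0, 1)))),
    tolerance = 1e-12)
  # ties handled by midranks
  expect_equal(classification_metrics(c(0, 1), c(0, 1),
                                      scores = c(1, 1))$auroc, 0.5)
  expect_warning(m <- classification_metrics(c(1, 1), c(1, 1),
                                             scores = c(.1, .2)), "single-class")
  expect_true(is.na(m$auroc))
})

test_that("slide masks assemble from patch predictions", {
  pr <- data.frame(grid_row = c(0, 0, 1, 1), grid_col = c(0, 1, 0, 1),
                   pred = c(1, 0, 0, 1))
  m <- assemble_slide_mask(pr)
  expect_equal(m$grid, matrix(c(1, 0, 0, 1), 2, 2))
  empty <- assemble_slide_mask(data.frame(grid_row = integer(),
                                          grid_col = integer(),
                                          pred = integer()),
                               n_rows = 3, n_cols = 3)
  expect_equal(empty$grid, matrix(0, 3, 3))
  expect_error(assemble_slide_mask(rbind(pr, pr[1, ])), "duplicate")
  expect_error(assemble_slide_mask(pr, n_rows = 1, n_cols = 2), "outside")
})

test_that("morphological opening removes specks, keeps blocks, is idempotent", {
  g <- matrix(0, 9, 9)
  g[2, 2] <- 1                 # isolated cell
  g[4:8, 4:8] <- 1             # solid 5x5 block
  m <- slide_mask(g)
  cl <- clean_mask(m, 1)
  expect_equal(cl$grid[2, 2], 0)
  expect_equal(cl$grid[4:8, 4:8], matrix(1, 5, 5))
  expect_identical(clean_mask(m, 0), m)
  expect_equal(clean_mask(cl, 1)$grid, cl$grid)
})

test_that("the Jaccard index counts cells like a brute-force loop", {
  A <- slide_mask(matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3))
  shift <- slide_mask(matrix(c(0, 1, 1, 0, 1, 1, 0, 0, 0), 3, 3))
  expect_equal(jaccard(A, A), 1)
  expect_equal(jaccard(A, shift), 2 / 6)
  B <- slide_mask(matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 0), 3, 3))
  expect_equal(jaccard(A, B), 0)
  expect_equal(jaccard(slide_mask(matrix(0, 2, 2)),
                       slide_mask(matrix(0, 2, 2))), 1)
  expect_error(jaccard(A, slide_mask(matrix(0, 2, 2))), "mismatch")
})

test_that("Hausdorff distances follow geometry and the brute-force oracle", {
  one <- function(r, c, n = 5, pitch = 1) {
    g <- matrix(0, n, n); g[r, c] <- 1; slide_mask(g, pitch)
  }
  expect_equal(hausdorff_mm(one(1, 1), one(1, 1)), 0)
  expect_equal(hausdorff_mm(one(1, 1), one(4, 5)), 5)   # 3-4-5 triangle
  brute <- function(A, B) {
    pa <- which(A$grid == 1, arr.ind = TRUE)
    pb <- which(B$grid == 1, arr.ind = TRUE)
    dir <- function(P, Q) {
      worst <- 0
      for (i in seq_len(nrow(P))) {
        best <- Inf
        for (j in seq_len(nrow(Q)))
          best <- min(best, sqrt(sum((P[i, ] - Q[j, ])^2)))
        worst <- max(worst, best)
      }
      worst
    }
    max(dir(pa, pb), dir(pb, pa)) * A$cell_pitch_mm
  }
  set.seed(10)
  for (i in 1:15) {
    A <- slide_mask(matrix(rbinom(100, 1, 0.2), 10, 10), 0.139)
    B <- slide_mask(matrix(rbinom(100, 1, 0.2), 10, 10), 0.139)
    if (sum(A$grid) == 0 || sum(B$grid) == 0) next
    expect_identical(hausdorff_mm(A, B), brute(A, B))
    expect_identical(hausdorff_mm(A, B), hausdorff_mm(B, A))
  }
  expect_error(hausdorff_mm(one(1, 1), slide_mask(matrix(0, 5, 5), 1)),
               "empty")
  expect_error(hausdorff_mm(one(1, 1, pitch = 1), one(1, 1, pitch = 2)),
               "pitch")
})

test_that("margin assessment combines opening with both scores", {
  g <- matrix(0, 6, 6)
  g[2:4, 2:4] <- 1       # block large enough to survive opening
  truth <- slide_mask(g)
  pred <- truth
  pred$grid[1, 6] <- 1   # speck that opening removes
  r <- margin_assessment(pred, truth, open_radius = 1)
  expect_equal(r$jaccard, 1)
  expect_equal(r$hausdorff_mm, 0)
})

test_that("masks round-trip through 8-bit PNG", {
  m <- slide_mask(matrix(rbinom(36, 1, 0.4), 6, 6))
  p <- tempfile(fileext = ".png")
  write_mask_png(m, p)
  back <- read_mask_png(p)
  expect_equal(back$grid, m$grid)
})
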