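test_that("whitening, eigenvalue order and constants behave as specified", {
  withr::with_seed(31, {
    des <- full_design()[-1, ]     # 14 chips, Cont n = 2
    X <- matrix(rnorm(14 * 9), 14, 9,
                dimnames = list(des$sample_id, paste0("g", 1:9)))
    shift <- matrix(0, 14, 9)
    shift[des$group == "Drago", 1:3] <- 3
    shift[des$group == "Salam", 4:6] <- -3
    X <- X + shift
    fit <- fit_cda(X, des$group)
  })
  q <- length(fit$eigenvalues)
  expect_equal(q, 4)
  expect_true(all(diff(fit$eigenvalues) <= 1e-10))
  expect_true(all(fit$eigenvalues >= 0))
  # pooled within-group covariance of the training scores is the identity
  g <- factor(des$group, levels = unique(des$group))
  cen_by_sample <- fit$centroids[as.character(des$group), , drop = FALSE]
  sc_c <- fit$scores - cen_by_sample
  expect_equal(crossprod(sc_c) / (14 - 5), diag(q), ignore_attr = TRUE,
               tolerance = 1e-8)
  # size-weighted mean of training scores is the origin
  expect_lt(max(abs(colMeans(fit$scores))), 1e-8)
  # grand mean projects to the origin; group means project to centroids
  expect_lt(max(abs(project_cda(fit, matrix(fit$grand_means, 1,
                                            dimnames = list(NULL, fit$variables))))),
            1e-8)
  for (grp in unique(des$group)) {
    sc <- project_cda(fit, X[des$group == grp, , drop = FALSE])
    expect_equal(colMeans(sc), fit$centroids[grp, ], tolerance = 1e-8)
  }
  # orientation: control (first) group centroid non-negative on CF1
  expect_gte(fit$centroids["Cont", 1], 0)
  expect_equal(percent_discrimination(fit, q), 100)
})

test_that("more variables than N - g raises the singularity error", {
  withr::with_seed(32, {
    des <- full_design()[-1, ]
    X10 <- matrix(rnorm(14 * 10), 14, 10, dimnames = list(des$sample_id, NULL))
  })
  expect_error(fit_cda(X10, des$group), "singular.*10 variables.*9")
  expect_equal(max_usable_variables(14, 5), 9)
})

test_that("one-variable two-group fit gives a single symmetric function", {
  withr::with_seed(33, {
    x <- matrix(c(rnorm(3, 0, 0.1), rnorm(3, 1, 0.1)), ncol = 1,
                dimnames = list(NULL, "v"))
  })
  fit <- fit_cda(x, rep(c("a", "b"), each = 3))
  expect_length(fit$eigenvalues, 1)
  expect_gt(fit$eigenvalues[1], 0)
  expect_equal(sum(fit$centroids[, 1] * 3), 0, tolerance = 1e-10)
  expect_equal(percent_discrimination(fit, 1), 100)
})

test_that("percent discrimination is plain arithmetic on the eigenvalues", {
  fake <- structure(list(eigenvalues = c(9, 3, 0.5, 0.5)), class = "cda")
  expect_equal(percent_discrimination(fake, 2), 100 * 12 / 13)
  expect_equal(percent_discrimination(fake, 4), 100)
  expect_error(percent_discrimination(fake, 5), "between 1 and 4")
  degenerate <- structure(list(eigenvalues = c(0, 0)), class = "cda")
  expect_error(percent_discrimination(degenerate, 1), "undefined")
})

test_that("nearest-centroid rule equals the original-space Mahalanobis rule", {
  withr::with_seed(34, {
    for (rep in 1:50) {
      p <- sample(2:4, 1)
      n_g <- sample(4:7, 3, replace = TRUE)
      g <- factor(rep(letters[1:3], n_g))
      mu <- matrix(rnorm(3 * p, sd = 3), 3, p)
      X <- mu[as.integer(g), , drop = FALSE] + matrix(rnorm(sum(n_g) * p), sum(n_g), p)
      colnames(X) <- paste0("v", 1:p)
      fit <- fit_cda(X, g)
      newX <- matrix(rnorm(20 * p), 20, p, dimnames = list(NULL, paste0("v", 1:p)))
      expect_identical(as.character(classify_cda(fit, newX)),
                       as.character(oracle_mahalanobis_classify(X, g, newX)))
    }
  })
})

test_that("classification is invariant under invertible affine maps of the input", {
  withr::with_seed(35, {
    des <- full_design()
    X <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(NULL, paste0("v", 1:4)))
    X[des$group == "Drago", 1] <- X[des$group == "Drago", 1] + 4
    X[des$group == "Cont", 2] <- X[des$group == "Cont", 2] - 4
    A <- matrix(rnorm(16), 4, 4) + 4 * diag(4)
    b <- rnorm(4)
    Xt <- sweep(X %*% A, 2, b, "+")
    colnames(Xt) <- colnames(X)
    newX <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("v", 1:4)))
    newXt <- sweep(newX %*% A, 2, b, "+")
    colnames(newXt) <- colnames(X)
  })
  f1 <- fit_cda(X, des$group)
  f2 <- fit_cda(Xt, des$group)
  expect_identical(as.character(classify_cda(f1, newX)),
                   as.character(classify_cda(f2, newXt)))
})

test_that("fit agrees with MASS::lda on subspace and classification", {
  withr::with_seed(36, {
    g <- factor(rep(c("a", "b", "c"), each = 8))
    mu <- matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE)
    X <- mu[as.integer(g), ] + matrix(rnorm(48), 24, 2)
    colnames(X) <- c("v1", "v2")
    newX <- matrix(rnorm(60, sd = 3), 30, 2, dimnames = list(NULL, c("v1", "v2")))
  })
  fit <- fit_cda(X, g)
  ld <- MASS::lda(X, g, prior = rep(1 / 3, 3))
  expect_identical(as.character(classify_cda(fit, newX)),
                   as.character(predict(ld, newX)$class))
})

test_that("boundary lines are perpendicular bisectors of centroid pairs", {
  # worked example from the published centroids of groups 2 and 5
  b <- boundary_line(c(-3.883, -2.388), c(-49.253, -3.269))
  expect_equal(b$slope, -51.488, tolerance = 0.05 / 51.488)
  expect_equal(b$intercept, -1370.757, tolerance = 1.0 / 1370.757)

  # vertical case: slope view unavailable
  v <- boundary_line(c(-1, 0), c(1, 0))
  expect_true(is.na(v$slope))
  expect_equal(v$b, 0)
  expect_equal(v$c / v$a, 0)

  # property: sampled points on the line are equidistant from both centroids
  withr::with_seed(37, {
    for (rep in 1:20) {
      ci <- rnorm(2, sd = 10); cj <- rnorm(2, sd = 10)
      bl <- boundary_line(ci, cj)
      for (x0 in c(-5, 0, 7)) {
        pt <- if (bl$b != 0) c(x0, (bl$c - bl$a * x0) / bl$b)
              else c(bl$c / bl$a, x0)
        expect_equal(sum((pt - ci)^2), sum((pt - cj)^2), tolerance = 1e-9)
      }
    }
  })
  expect_error(boundary_line(c(1, 1), c(1, 1)), "coincident")
})

test_that("tidy/glance/autoplot expose the fit in tabular and graphic form", {
  withr::with_seed(38, {
    des <- full_design()
    X <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, paste0("v", 1:3)))
    X[, 1] <- X[, 1] + 6 * (des$group %in% c("Drago", "MinusDrago"))
    X[, 2] <- X[, 2] + 6 * (des$group %in% c("Salam", "Cont"))
  })
  fit <- fit_cda(X, des$group)
  td <- tidy(fit)
  expect_equal(nrow(td), (3 + 1) * length(fit$eigenvalues))
  expect_true("(constant)" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_functions, 3)
  expect_gte(gl$percent_first_two, 50)
  expect_true(gl$training_accuracy >= 0 && gl$training_accuracy <= 1)
  bl <- boundary_lines(fit)
  expect_equal(nrow(bl), choose(5, 2))
  expect_s3_class(autoplot(fit), "ggplot")
})
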