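test_that("the dense head has the published layout and parameter count", {
  for (nc in c(2L, 3L)) {
    hd <- build_head(nc, feature_width = 64L)
    types <- vapply(hd$layers, `[[`, character(1), "type")
    expect_identical(types, c("global_average_pooling", "dense", "dropout",
                              "dense", "dropout", "dense"))
    units <- vapply(hd$layers[c(2, 4, 6)], `[[`, numeric(1), "units")
    expect_equal(units, c(256, 128, nc))
    rates <- vapply(hd$layers[c(3, 5)], `[[`, numeric(1), "rate")
    expect_equal(rates, c(0.4, 0.4))
    expect_equal(hd$n_params,
                 64 * 256 + 256 + 256 * 128 + 128 + 128 * nc + nc)
  }
  expect_error(build_head(4L), class = "semg_validation_error")
})

test_that("scratch head parameters match the closed form", {
  h <- head_spec(output_units = 3L)
  par <- init_scratch_params(3L, h)
  actual <- length(par$wd1) + length(par$bd1) + length(par$wd2) +
    length(par$bd2) + length(par$wo) + length(par$bo)
  expect_equal(actual, build_head(3L, h, 64L)$n_params)
})

test_that("the scratch CNN separates trivially separable images", {
  n <- 60
  imgs <- array(0, c(16, 16, 3, n))
  imgs[, , , 1:(n / 2)] <- 0.2
  imgs[, , , (n / 2 + 1):n] <- 0.8
  y <- factor(rep(c("NoFatigue", "Fatigue"), each = n / 2),
              levels = c("NoFatigue", "Fatigue"), ordered = TRUE)
  m <- train_image_model(imgs, y, train_spec(epochs = 6, batch_size = 16,
                                             seed = 3))
  p <- predict(m, imgs)
  expect_gte(mean(as.character(p$class) == as.character(y)), 0.99)
  expect_equal(rowSums(p$prob), rep(1, n), tolerance = 1e-9)
  expect_equal(nrow(m$history), 6)
  # dropout inactive at inference: repeated passes identical
  expect_identical(predict(m, imgs)$prob, p$prob)
})

test_that("image training validates inputs and backbone availability", {
  imgs <- array(runif(16 * 16 * 3 * 10), c(16, 16, 3, 10))
  y1 <- factor(rep("A", 10))
  expect_error(train_image_model(imgs, y1, train_spec(epochs = 1)),
               class = "semg_validation_error")
  y2 <- factor(rep(c("A", "B"), 5))
  expect_error(
    train_image_model(imgs, y2, train_spec(backbone_id = "resnet50")),
    class = "semg_backbone_unavailable")
  expect_error(train_spec(backbone_id = "vgg16"),
               class = "semg_validation_error")
  m1 <- train_image_model(imgs, y2, train_spec(epochs = 1, batch_size = 4,
                                               seed = 1))
  expect_equal(nrow(m1$history), 1)
})

test_that("seeded CNN training is reproducible", {
  set.seed(99)
  imgs <- array(runif(16 * 16 * 3 * 24), c(16, 16, 3, 24))
  y <- factor(rep(c("A", "B"), 12))
  m1 <- train_image_model(imgs, y, train_spec(epochs = 2, batch_size = 8,
                                              seed = 7))
  m2 <- train_image_model(imgs, y, train_spec(epochs = 2, batch_size = 8,
                                              seed = 7))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("baseline specs carry the published parameters verbatim", {
  rf2 <- baseline_spec("random_forest", "binary")
  expect_equal(rf2$params,
               list(max_depth = 15, n_estimators = 12, criterion = "gini"))
  knn3 <- baseline_spec("knn", "threeclass")
  expect_equal(knn3$params$n_neighbors, 8)
  expect_equal(knn3$params$metric, "minkowski")
  lr3 <- baseline_spec("logistic_regression", "threeclass")
  expect_equal(lr3$params$C, 0.003)
  expect_equal(lr3$params$max_iter, 65)
  svm2 <- baseline_spec("svm", "binary")
  expect_equal(svm2$params$C, 0.3)
  expect_equal(svm2$params$max_iter, 80)
  dt3 <- baseline_spec("decision_tree", "threeclass")
  expect_equal(dt3$params$max_depth, 16)
  expect_error(baseline_spec("random_forest", "binary",
                             params = list(gamma = 1)),
               class = "semg_validation_error")
})

test_that("baseline specs round-trip through the fitted model", {
  set.seed(20)
  x <- matrix(rnorm(120), 60, 2)
  y <- factor(rep(c("a", "b"), 30))
  for (fam in c("random_forest", "decision_tree", "knn",
                "logistic_regression", "svm")) {
    spec <- baseline_spec(fam, "binary")
    m <- suppressMessages(train_baseline(x, y, spec))
    expect_identical(m$spec$params, spec$params)
  }
})

test_that("every baseline separates a linearly separable toy problem", {
  set.seed(21)
  x <- rbind(matrix(rnorm(120, 0, 0.5), 60, 2),
             matrix(rnorm(120, 5, 0.5), 60, 2))
  y <- factor(rep(c("a", "b"), each = 60))
  for (fam in c("svm", "random_forest", "decision_tree", "knn")) {
    m <- suppressMessages(
      train_baseline(x, y, baseline_spec(fam, "binary")))
    p <- predict(m, x)
    acc <- mean(as.character(p$class) == as.character(y))
    if (fam == "svm") expect_equal(acc, 1.0) else expect_gte(acc, 0.99)
    expect_equal(rowSums(p$prob), rep(1, 120), tolerance = 1e-9)
  }
})

test_that("prediction breaks probability ties toward the lower class", {
  # a depth-0 tree is a single leaf carrying the class prior: with a
  # balanced prior every prediction ties and must resolve to class 1
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("lo", "hi"), 10), levels = c("lo", "hi"))
  m <- train_baseline(x, y, baseline_spec("decision_tree", "binary",
                                          params = list(max_depth = 0)))
  p <- predict(m, x)
  expect_true(all(p$prob == 0.5))
  expect_true(all(as.character(p$class) == "lo"))
  # argmax of probabilities always equals the predicted label
  set.seed(22)
  m2 <- train_baseline(matrix(rnorm(200), 100, 2),
                       factor(sample(c("a", "b", "c"), 100, TRUE)),
                       baseline_spec("knn", "threeclass"))
  xn <- matrix(rnorm(60), 30, 2)
  p2 <- predict(m2, xn)
  expect_identical(as.integer(p2$class), max.col(p2$prob, "first"))
})

test_that("training validates labels and missing values", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(train_baseline(x, factor(rep("a", 20)),
                              baseline_spec("knn", "binary")),
               class = "semg_validation_error")
  x[3, 1] <- NA
  expect_error(train_baseline(x, factor(rep(c("a", "b"), 10)),
                              baseline_spec("knn", "binary")),
               class = "semg_validation_error")
})
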