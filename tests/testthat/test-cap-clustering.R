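test_that("correlation distance matches its definition", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  expect_equal(correlation_distance(x, y), 1 - 9 / sqrt(84),
               tolerance = 1e-12)
  z <- rnorm(50)
  expect_equal(correlation_distance(z, z), 0)
  expect_equal(correlation_distance(z, -z), 2)
  # invariance to positive affine transforms
  expect_equal(correlation_distance(2 * x + 5, y),
               correlation_distance(x, y))
  expect_error(correlation_distance(rep(1, 5), rnorm(5)),
               "zero-variance")
  expect_error(correlation_distance(1:3, 1:4), "length")
})

test_that("standardized squared Euclidean distance halved equals 1 - r", {
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(40); y <- rnorm(40)
    sx <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
    sy <- (y - mean(y)) / sqrt(sum((y - mean(y))^2))
    expect_equal(sum((sx - sy)^2) / 2, correlation_distance(x, y),
                 tolerance = 1e-10)
  }
})

test_that("two planted orthogonal patterns are perfectly separated", {
  set.seed(32)
  m <- 60
  p1 <- c(rep(1, 30), rep(0, 30))
  p2 <- c(rep(0, 30), rep(1, 30))
  x <- rbind(t(replicate(10, p1 + rnorm(m, sd = 0.1))),
             t(replicate(10, p2 + rnorm(m, sd = 0.1))))
  fit <- kmeans_frames(x, k = 2, seed = 5)
  truth <- rep(1:2, each = 10)
  expect_equal(recovery_score(truth, fit$labels)$accuracy, 1)
})

test_that("n = k gives each frame its own cluster with J = 0", {
  set.seed(33)
  x <- matrix(rnorm(5 * 12), 5, 12)
  fit <- kmeans_frames(x, k = 5, seed = 2)
  expect_equal(sort(fit$labels), 1:5)
  expect_equal(fit$J, 0, tolerance = 1e-12)
})

test_that("kmeans_frames attains the exhaustive minimum on tiny instances", {
  set.seed(34)
  for (rep in 1:3) {
    x <- matrix(rnorm(6 * 8), 6, 8)
    # enumerate every 2-cluster assignment with both clusters nonempty
    best <- Inf
    for (code in 1:(2^6 - 2)) {
      labels <- as.integer(intToBits(code))[1:6] + 1L
      if (length(unique(labels)) < 2L) next
      best <- min(best, oracle_J(x, labels, 2))
    }
    fit <- kmeans_frames(x, k = 2, seed = rep, n_restarts = 10)
    expect_equal(fit$J, best, tolerance = 1e-8)
  }
})

test_that("J is non-increasing across Lloyd iterations", {
  set.seed(35)
  for (rep in 1:20) {
    x <- matrix(rnorm(30 * 15), 30, 15)
    fit <- kmeans_frames(x, k = 3, seed = rep, n_restarts = 1)
    expect_true(all(diff(fit$J_trace) <= 1e-10))
  }
})

test_that("reported J matches the definitional objective", {
  set.seed(36)
  x <- matrix(rnorm(40 * 25), 40, 25)
  fit <- kmeans_frames(x, k = 4, seed = 9)
  expect_equal(fit$J, oracle_J(x, fit$labels, 4), tolerance = 1e-10)
})

test_that("centroids are the means of standardized member vectors", {
  set.seed(37)
  x <- matrix(rnorm(30 * 20), 30, 20)
  fit <- kmeans_frames(x, k = 3, seed = 4)
  xs <- x - rowMeans(x)
  xs <- xs / sqrt(rowSums(xs^2))
  for (i in 1:3) {
    memb <- which(fit$labels == i)
    expect_equal(fit$centroids[i, ],
                 colMeans(xs[memb, , drop = FALSE]), tolerance = 1e-12)
  }
})

test_that("well-separated data give the same partition after frame reordering", {
  set.seed(38)
  m <- 50
  pats <- diag(3)[, c(1, 2, 3)] %x% matrix(1, 1, 16)  # 3 x 48
  pats <- cbind(pats, 0, 0)
  x <- pats[rep(1:3, each = 12), ] + matrix(rnorm(36 * m, sd = 0.05), 36, m)
  fit1 <- kmeans_frames(x, k = 3, seed = 7)
  perm <- sample(36)
  fit2 <- kmeans_frames(x[perm, ], k = 3, seed = 7)
  expect_equal(recovery_score(fit1$labels[perm], fit2$labels)$accuracy, 1)
})

test_that("cross-check: matches stats::kmeans on row-standardized data", {
  # on standardized rows the correlation distance is monotone in squared
  # Euclidean distance, so both optimizers should find partitions with
  # equal objective on well-separated data
  set.seed(39)
  m <- 30
  p1 <- rnorm(m); p2 <- rnorm(m)
  x <- rbind(t(replicate(15, p1 + rnorm(m, sd = 0.2))),
             t(replicate(15, p2 + rnorm(m, sd = 0.2))))
  xs <- x - rowMeans(x)
  xs <- xs / sqrt(rowSums(xs^2))
  ref <- stats::kmeans(xs, centers = 2, nstart = 10)
  fit <- kmeans_frames(x, k = 2, seed = 3)
  expect_equal(recovery_score(ref$cluster, fit$labels)$accuracy, 1)
})

test_that("degenerate inputs are rejected", {
  expect_error(kmeans_frames(matrix(rnorm(6), 2, 3), k = 5), "at least")
  x <- matrix(rnorm(30), 10, 3)
  x[4, ] <- 2
  expect_error(kmeans_frames(x, k = 2), "zero-variance")
})

test_that("clustering TSV output is complete and reproducible", {
  set.seed(40)
  x <- matrix(rnorm(20 * 10), 20, 10)
  fit <- kmeans_frames(x, k = 3, seed = 11)
  d1 <- tempfile(); d2 <- tempfile()
  write_clustering(fit, x, d1)
  write_clustering(fit, x, d2)
  tab <- read.table(file.path(d1, "labels.tsv"), header = TRUE)
  expect_equal(nrow(tab), 20L)
  expect_true(all(tab$label %in% 1:3))
  expect_true(all(tab$distance >= -1e-12))
  expect_identical(readLines(file.path(d1, "labels.tsv")),
                   readLines(file.path(d2, "labels.tsv")))
  meta <- jsonlite::read_json(file.path(d1, "clustering.json"))
  expect_equal(meta$k, 3L)
})
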