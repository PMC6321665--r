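# training dynamics, reduction cases, reproducibility, serialization

test_that("prototypes are attracted to their class and repulsed by the other", {
  x <- matrix(c(-1, 1), ncol = 1)
  labs <- c("EARLY", "LATE")
  cfg <- train_config(epochs = 20, data_ratio = 1, sigma_interval = c(1, 1),
                      prototype_lr = 0.5, learn_matrix = FALSE, seed = 1)
  model <- gmlvq_train(x, labs, cfg, cost_spec("CA"), standardize = FALSE)
  w_early <- model$prototypes[model$prototype_labels == "EARLY", 1]
  w_late <- model$prototypes[model$prototype_labels == "LATE", 1]
  expect_lt(w_early, w_late)
  expect_lt(abs(w_early - (-1)), 0.6)   # moved toward its data point
  expect_lt(abs(w_late - 1), 0.6)
  pred <- predict(model, x)
  expect_identical(pred$label, labs)
})

test_that("well-separated Gaussian classes are classified almost perfectly", {
  g <- make_gaussian_xy(n = 400, d = 2, mean_shift = 2, sd = 0.5, seed = 5)
  model <- gmlvq_train(g$x, g$labels, train_config(epochs = 60, seed = 2),
                       cost_spec("CA"))
  h <- training_history(model)
  expect_equal(nrow(h), 60)
  expect_gte(tail(h$accuracy, 1), 0.99)
  # nearest-centroid reference achieves the same on separable data
  mu_e <- colMeans(g$x[g$labels == "EARLY", ])
  mu_l <- colMeans(g$x[g$labels == "LATE", ])
  centroid_lab <- ifelse(
    rowSums(sweep(g$x, 2, mu_e)^2) < rowSums(sweep(g$x, 2, mu_l)^2),
    "EARLY", "LATE")
  expect_gte(mean(centroid_lab == g$labels), 0.99)
  pred <- predict(model, g$x)
  expect_gte(mean(pred$label == centroid_lab), 0.99)
})

test_that("with matrix learning off GMLVQ reduces to GLVQ (scaled identity)", {
  g <- make_gaussian_xy(n = 200, seed = 9)
  cfg <- train_config(epochs = 15, learn_matrix = FALSE, seed = 3)
  model <- gmlvq_train(g$x, g$labels, cfg, cost_spec("CA"))
  D <- ncol(g$x)
  expect_equal(model$omega, diag(D) / sqrt(D), tolerance = 1e-12)
  # mapped distance is squared Euclidean / D
  set.seed(4)
  for (rep in 1:10) {
    v <- rnorm(D); w <- rnorm(D)
    expect_equal(mapped_distance(v, w, model$omega),
                 sum((v - w)^2) / D, tolerance = 1e-12)
  }
})

test_that("omega trace normalization holds after training and every epoch", {
  g <- make_gaussian_xy(n = 200, seed = 12)
  for (kind in c("CA", "WCA", "F_BETA", "PR_WEIGHTED")) {
    model <- gmlvq_train(g$x, g$labels, train_config(epochs = 10, seed = 5),
                         cost_spec(kind))
    expect_equal(sum(diag(crossprod(model$omega))), 1, tolerance = 1e-9)
  }
})

test_that("training is bitwise reproducible for a fixed seed", {
  g <- make_gaussian_xy(n = 150, seed = 20)
  cfg <- train_config(epochs = 12, seed = 99)
  m1 <- gmlvq_train(g$x, g$labels, cfg, cost_spec("WCA"))
  m2 <- gmlvq_train(g$x, g$labels, cfg, cost_spec("WCA"))
  expect_identical(m1$prototypes, m2$prototypes)
  expect_identical(m1$omega, m2$omega)
  expect_identical(training_history(m1), training_history(m2))
  m3 <- gmlvq_train(g$x, g$labels, train_config(epochs = 12, seed = 100),
                    cost_spec("WCA"))
  expect_false(identical(m1$prototypes, m3$prototypes))
})

test_that("training does not disturb the caller's RNG stream", {
  g <- make_gaussian_xy(n = 100, seed = 2)
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(gmlvq_train(g$x, g$labels, train_config(epochs = 3, seed = 1)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("parameter recovery: prototypes land on class means, informative feature dominates", {
  # two classes separated on dimension 1 only, D = 5
  set.seed(31)
  n <- 2000; d <- 5
  half <- n / 2
  x <- matrix(rnorm(n * d), ncol = d)
  x[seq_len(half), 1] <- x[seq_len(half), 1] + 2
  x[(half + 1):n, 1] <- x[(half + 1):n, 1] - 2
  labs <- rep(c("EARLY", "LATE"), each = half)
  model <- gmlvq_train(x, labs, train_config(seed = 8), cost_spec("CA"))
  # prototypes live in standardized space; compare against the
  # standardized class means there
  mean_e <- (mean(x[seq_len(half), 1]) - model$center[1]) / model$scale[1]
  mean_l <- (mean(x[(half + 1):n, 1]) - model$center[1]) / model$scale[1]
  w_e <- model$prototypes[model$prototype_labels == "EARLY", ]
  w_l <- model$prototypes[model$prototype_labels == "LATE", ]
  expect_lt(abs(w_e[1] - mean_e), 0.2)
  expect_lt(abs(w_l[1] - mean_l), 0.2)
  infl <- diag(ccm(model))
  expect_gte(infl[1], 0.5)
  expect_equal(feature_influence(model)$feature[1],
               model$feature_names[1])
})

test_that("epoch subsampling honours the configured data ratio", {
  g <- make_gaussian_xy(n = 100, seed = 6)
  model <- gmlvq_train(g$x, g$labels,
                       train_config(epochs = 5, data_ratio = 0.5, seed = 4))
  h <- training_history(model)
  expect_equal(h$sigma, seq(1, 50, length.out = 5))
  expect_equal(h$prototype_lr, 1 * (1 - (0:4) / 5))
})

test_that("model JSON round trip preserves structure and numbers", {
  g <- make_gaussian_xy(n = 120, seed = 14)
  model <- gmlvq_train(g$x, g$labels, train_config(epochs = 8, seed = 7),
                       cost_spec("F_BETA", beta = 2))
  path <- tempfile(fileext = ".json")
  write_gmlvq_model(model, path)
  back <- read_gmlvq_model(path)
  expect_identical(back$prototype_labels, model$prototype_labels)
  expect_identical(back$feature_names, model$feature_names)
  expect_equal(back$prototypes, model$prototypes, tolerance = 1e-12)
  expect_equal(back$omega, model$omega, tolerance = 1e-12)
  expect_equal(back$sigma, model$sigma, tolerance = 1e-12)
  expect_equal(back$center, model$center, tolerance = 1e-12)
  expect_equal(back$scale, model$scale, tolerance = 1e-12)
  cfg <- attr(back, "config")
  expect_equal(cfg$epochs, 8L)
  expect_identical(attr(back, "cost_spec")$kind, "F_BETA")
  # predictions identical through the round trip
  p1 <- predict(model, g$x); p2 <- predict(back, g$x)
  expect_identical(p1$label, p2$label)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
})

test_that("prediction scores are monotone in the negated relative score", {
  set.seed(17)
  model <- gmlvq_model(matrix(rnorm(8), 4, 2),
                       c("EARLY", "LATE", "EARLY", "LATE"),
                       matrix(rnorm(4), 2, 2), sigma = 3)
  x <- matrix(rnorm(100), ncol = 2)
  pred <- predict(model, x)
  mu_pos <- apply(x, 1, relative_score, model = model, label = "EARLY")
  expect_identical(order(pred$score), order(-mu_pos))
  # equidistant point scores exactly 0.5 and takes the majority label
  m0 <- gmlvq_model(rbind(c(-1, 0), c(1, 0)), c("EARLY", "LATE"), diag(2))
  p0 <- predict(m0, rbind(c(0, 3)))
  expect_equal(p0$score, 0.5)
  expect_identical(p0$label, "LATE")
  # coincident with an EARLY prototype: confident positive
  m5 <- gmlvq_model(rbind(c(-1, 0), c(1, 0)), c("EARLY", "LATE"), diag(2),
                    sigma = 5)
  p1 <- predict(m5, rbind(c(-1, 0)))
  expect_identical(p1$label, "EARLY")
  expect_gt(p1$score, 0.99)
})

test_that("predict validates feature names", {
  g <- make_gaussian_xy(n = 100, seed = 3)
  colnames(g$x) <- c("a", "b")
  model <- gmlvq_train(g$x, g$labels, train_config(epochs = 3, seed = 1))
  bad <- data.frame(a = 1:3, wrong = 1:3)
  expect_error(predict(model, bad), "missing feature")
})

test_that("analytic training gradients agree with numerical cost gradients", {
  # finite-difference check of the full-batch update direction
  set.seed(41)
  n <- 30; d <- 3
  x <- matrix(rnorm(n * d), ncol = d)
  labs <- sample(c("EARLY", "LATE"), n, replace = TRUE, prob = c(0.5, 0.5))
  labs[1:2] <- c("EARLY", "LATE")
  for (kind in c("CA", "F_BETA", "WCA")) {
    spec <- cost_spec(kind)
    W <- matrix(rnorm(2 * d), 2, d)
    omega <- matrix(rnorm(d * d), d, d)
    omega <- omega / sqrt(sum(omega^2))
    sigma <- 2
    build <- function(W, omega) gmlvq_model(W, c("EARLY", "LATE"), omega,
                                            sigma = sigma)
    cost_at <- function(W, omega)
      gmlvq_cost(build(W, omega), x, labs, spec)
    # analytic gradient via one full-batch epoch internals
    model <- build(W, omega)
    np <- lvqfold:::.nearest_pair(x, labs, model)
    s <- np$d_plus + np$d_minus
    mu <- lvqfold:::.mu_from_d(np$d_plus, np$d_minus)
    cc <- sigmoid_transfer(-mu, sigma)
    pos <- labs == "EARLY"
    cd <- lvqfold:::.cost_from_soft_cm(sum(cc[pos]), sum(cc[!pos]),
                                       sum(pos), sum(!pos), spec)
    dCdc <- ifelse(pos, cd$dtp, cd$dtn)
    g <- dCdc * (-sigma * cc * (1 - cc))
    a_plus <- g * 2 * np$d_minus / s^2
    a_minus <- -g * 2 * np$d_plus / s^2
    lambda <- crossprod(omega)
    eps <- 1e-6
    # numerical gradient wrt one prototype coordinate and one omega entry
    for (k in 1:2) {
      grad_k <- -2 * as.numeric(
        lambda %*% colSums((ifelse(np$idx_plus == k, a_plus, 0) +
                              ifelse(np$idx_minus == k, a_minus, 0)) *
                             sweep(x, 2, W[k, ])))
      Wp <- W; Wp[k, 1] <- Wp[k, 1] + eps
      Wm <- W; Wm[k, 1] <- Wm[k, 1] - eps
      num <- (cost_at(Wp, omega) - cost_at(Wm, omega)) / (2 * eps)
      expect_equal(grad_k[1], num, tolerance = 1e-4)
    }
    U_plus <- x - W[np$idx_plus, , drop = FALSE]
    U_minus <- x - W[np$idx_minus, , drop = FALSE]
    gradO <- 2 * omega %*% (crossprod(U_plus, a_plus * U_plus) +
                              crossprod(U_minus, a_minus * U_minus))
    Op <- omega; Op[1, 2] <- Op[1, 2] + eps
    Om <- omega; Om[1, 2] <- Om[1, 2] - eps
    num_o <- (cost_at(W, Op) - cost_at(W, Om)) / (2 * eps)
    expect_equal(gradO[1, 2], num_o, tolerance = 1e-4)
  }
})
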