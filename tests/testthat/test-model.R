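test_that("architecture shapes, scaling and deterministic initialization", {
  arch <- model_config(input_length = 1000L, output_length = 500L,
                       scale_factor = 1)
  expect_equal(arch$n_filters1, 64L)
  expect_equal(arch$n_filters2, 128L)
  expect_equal(arch$n_filters_tower, 64L)
  quarter <- model_config(input_length = 1000L, output_length = 500L,
                          scale_factor = 0.25)
  expect_equal(quarter$n_filters1, 16L)
  expect_equal(quarter$n_filters2, 32L)
  expect_equal(quarter$n_filters_tower, 16L)
  expect_error(model_config(input_length = 100L, output_length = 200L),
               "output_length")
  m1 <- build_model(tiny_arch(), seed = 7)
  m2 <- build_model(tiny_arch(), seed = 7)
  expect_identical(m1$params, m2$params)
  # profile output length = 2 * output_length, quantity is scalar per input
  arch <- tiny_arch()
  m <- build_model(arch, seed = 1)
  x <- two_hot_encode(paste0(sample(c("A", "C", "G", "T"), arch$input_length,
                                    replace = TRUE), collapse = ""))
  pred <- predict(m, x)
  expect_equal(ncol(pred$profile), 2L * arch$output_length)
  expect_length(pred$quantity, 1L)
})

test_that("multiscale loss: analytic limits and the arithmetic oracle", {
  p <- c(1, 2, 3, 4)
  # perfect prediction: cosine 1, quantity term 0 -> loss exactly -1
  expect_equal(multiscale_loss(p, p, sum(p)), -1, tolerance = 1e-12)
  # orthogonal profile with matched quantity -> loss 0
  a <- c(1, 0, 0, 0)
  b <- c(0, 1, 0, 0)
  expect_equal(multiscale_loss(a, b, sum(a)), 0, tolerance = 1e-12)
  # worked scalar case: p_obs = (3,4), y_profile = (4,3), y_quantity = 1
  expected <- -(24 / 25) + (1 / 500) * (log(7 + 1e-6) - log(1 + 1e-6))^2
  expect_equal(multiscale_loss(c(3, 4), c(4, 3), 1), expected,
               tolerance = 1e-12)
  # random-input agreement with the independent scalar oracle
  set.seed(21)
  for (i in 1:50) {
    po <- rexp(30)
    yp <- rexp(30)
    yq <- rexp(1) * 10
    expect_equal(multiscale_loss(po, yp, yq), oracle_loss(po, yp, yq),
                 tolerance = 1e-10)
  }
  expect_error(multiscale_loss(c(1, 2), c(1, 2, 3), 1), "identical dimensions")
})

test_that("loss properties: lower bound and cosine scale invariance", {
  set.seed(31)
  for (i in 1:50) {
    po <- rexp(20)
    yp <- rexp(20)
    yq <- rexp(1)
    l <- multiscale_loss(po, yp, yq)
    expect_gte(l, -1)
    # cosine term invariant to positive rescaling of either vector
    l1 <- multiscale_loss(po, yp * runif(1, 0.1, 10), sum(po))
    l2 <- multiscale_loss(po, yp, sum(po))
    expect_equal(l1, l2, tolerance = 1e-10)
  }
  # zero-norm profile: cosine term defined as 0
  expect_equal(multiscale_loss(c(1, 1), c(0, 0), 2), 0, tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  arch <- model_config(input_length = 16L, output_length = 8L,
                       scale_factor = 0.03, n_tower = 3L)
  m <- build_model(arch, seed = 42)
  set.seed(7)
  B <- 3L
  X <- array(sample(0:2, B * 16 * 4, TRUE), dim = c(B, 16L, 4L)) * 1.0
  xc <- aperm(X, c(3, 2, 1))
  Pobs <- matrix(rexp(B * 16), nrow = B)
  res <- dipcap:::nn_loss_grad_cpp(m$params, unclass(arch), xc, Pobs,
                                   1 / 500, 1e-6)
  loss_at <- function(params) {
    out <- dipcap:::nn_forward_cpp(params, unclass(arch), xc, TRUE)
    dipcap:::multiscale_loss_cpp(Pobs, out$profile, as.numeric(out$quantity),
                                 1 / 500, 1e-6)
  }
  # the engine computes in single precision: use a wide central-difference
  # step and a 2% relative tolerance (a wrong gradient is off by orders of
  # magnitude, not percent)
  eps <- 1e-3
  set.seed(99)
  for (nm in dipcap:::trainable_names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- res$grads[[nm]][i]
      ok <- abs(num - ana) < 1e-4 ||
        abs(num - ana) / max(abs(num), abs(ana)) < 2e-2
      expect_true(ok, label = sprintf("gradient of %s[%d] (num %.3g ana %.3g)",
                                      nm, i, num, ana))
    }
  }
})

test_that("a small gradient step decreases the batch loss", {
  arch <- tiny_arch()
  m <- build_model(arch, seed = 5)
  set.seed(8)
  B <- 4L
  X <- array(sample(0:2, B * arch$input_length * 4, TRUE),
             dim = c(B, arch$input_length, 4L)) * 1.0
  xc <- aperm(X, c(3, 2, 1))
  Pobs <- matrix(rexp(B * 2 * arch$output_length), nrow = B)
  res <- dipcap:::nn_loss_grad_cpp(m$params, unclass(arch), xc, Pobs,
                                   1 / 500, 1e-6)
  lr <- 1e-3
  for (nm in dipcap:::trainable_names(m$params)) {
    m$params[[nm]] <- m$params[[nm]] - lr * res$grads[[nm]]
  }
  res2 <- dipcap:::nn_loss_grad_cpp(m$params, unclass(arch), xc, Pobs,
                                    1 / 500, 1e-6)
  expect_lt(res2$loss, res$loss)
})

test_that("prediction is deterministic, nonnegative and batch-consistent", {
  arch <- tiny_arch()
  m <- build_model(arch, seed = 2)
  set.seed(14)
  B <- 5L
  X <- array(sample(0:2, B * arch$input_length * 4, TRUE),
             dim = c(B, arch$input_length, 4L)) * 1.0
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1$profile, p2$profile)      # bitwise deterministic
  expect_identical(p1$quantity, p2$quantity)
  expect_true(all(is.finite(p1$profile)) && all(p1$profile >= 0))
  expect_true(all(is.finite(p1$quantity)) && all(p1$quantity >= 0))
  # batch prediction equals per-item prediction (inference-mode batch norm)
  for (i in seq_len(B)) {
    single <- predict(m, X[i, , ])
    expect_equal(single$profile[1, ], p1$profile[i, ], tolerance = 1e-12)
    expect_equal(single$quantity, p1$quantity[i], tolerance = 1e-12)
  }
  expect_error(predict(m, X[, 1:10, ]), "length")
})

test_that("predicted_track combines the heads and is scale invariant", {
  pred <- list(profile = matrix(c(1, 1, 2), nrow = 1), quantity = 8)
  expect_equal(predicted_track(pred)[1, ], c(2, 2, 4))
  # conservation: rows sum to quantity
  set.seed(6)
  pr <- matrix(rexp(30), nrow = 3)
  q <- c(2, 5, 11)
  tr <- predicted_track(list(profile = pr, quantity = q))
  expect_equal(rowSums(tr), q, tolerance = 1e-12)
  # invariance under positive rescaling of the raw profile
  tr2 <- predicted_track(list(profile = pr * 7.3, quantity = q))
  expect_equal(tr, tr2, tolerance = 1e-12)
  # all-zero profile falls back to uniform
  tr3 <- predicted_track(list(profile = matrix(0, 1, 4), quantity = 4))
  expect_equal(tr3[1, ], rep(1, 4))
})

test_that("the desk-scale model can memorize 50 examples (capacity check)", {
  # scale 0.25, input 500: overfit 50 synthetic examples to loss < -0.95
  arch <- model_config(input_length = 500L, output_length = 250L,
                       scale_factor = 0.25)
  m <- build_model(arch, seed = 3)
  set.seed(33)
  B <- 50L
  X <- array(sample(0:2, B * 500 * 4, TRUE), dim = c(B, 500L, 4L)) * 1.0
  xc <- aperm(X, c(3, 2, 1))
  # smooth two-bump profiles like real initiation tracks
  P <- 2L * arch$output_length
  Pobs <- t(vapply(seq_len(B), function(i) {
    mu1 <- sample(50:200, 1)
    mu2 <- sample(300:450, 1)
    amp <- runif(1, 50, 500)
    amp * (dnorm(seq_len(P), mu1, 15) + dnorm(seq_len(P), mu2, 15))
  }, numeric(P)))
  # start the quantity head at the data scale; minibatches of 10
  m$params$bnq_beta <- mean(rowSums(Pobs))
  m$params$bnq_gamma <- max(sd(rowSums(Pobs)), 1e-3)
  tn <- dipcap:::trainable_names(m$params)
  opt <- dipcap:::adam_init(m$params, tn)
  reached <- FALSE
  ep_loss <- Inf
  for (epoch in 1:200) {
    ord <- sample(B)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, B, by = 10L)) {
      b <- ord[s:min(s + 9L, B)]
      res <- dipcap:::nn_loss_grad_cpp(
        m$params, unclass(arch), xc[, , b, drop = FALSE],
        Pobs[b, , drop = FALSE], 1 / 500, 1e-6)
      for (nm in names(res$state)) m$params[[nm]] <- res$state[[nm]]
      upd <- dipcap:::adam_step(m$params, res$grads, opt, 0.002, tn)
      m$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + res$loss
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    if (ep_loss < -0.95) {
      reached <- TRUE
      break
    }
  }
  expect_true(reached, label = sprintf(
    "memorization reached loss %.3f by epoch %d", ep_loss, epoch))
})

test_that("model checkpoints round-trip", {
  m <- build_model(tiny_arch(), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  unlink(c(path, paste0(path, ".json")))
})
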