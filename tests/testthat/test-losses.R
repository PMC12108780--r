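test_that("cross-entropy matches closed forms and clips", {
  onehot <- diag(4)[c(1, 3), ]
  expect_equal(cross_entropy(onehot, c(0, 2)), 0)
  unif <- matrix(0.25, 2, 4)
  expect_equal(cross_entropy(unif, c(1, 3)), log(4))
  # zero probability on the true class stays finite via clipping
  p <- matrix(c(0, 1, 0, 0), 1)
  v <- cross_entropy(p, 0L)
  expect_true(is.finite(v))
  expect_equal(v, -log(1e-12))
  expect_error(cross_entropy(unif, c(0, 4)), "out of range")
})

test_that("mse matches hand values and is symmetric", {
  expect_equal(mse_loss(c(0, 2), c(0, 0)), 2)
  expect_equal(mse_loss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  a <- rand_array(c(3, 4), 1); b <- rand_array(c(3, 4), 2)
  expect_equal(mse_loss(a, b), mse_loss(b, a))
  expect_error(mse_loss(a, rand_array(c(4, 3), 2)), "shape")
})

test_that("covariance matches the hand-evaluated example and an oracle", {
  expect_equal(feat_covariance(rbind(c(1, 0), c(0, 1))),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  expect_equal(feat_covariance(matrix(3, 4, 2)), matrix(0, 2, 2))
  expect_error(feat_covariance(matrix(1, 1, 3)), "at least 2")
  # brute-force center-then-crossproduct oracle on random matrices
  for (s in 1:5) {
    X <- rand_array(c(5 + s, 3), seed = s)
    Xc <- sweep(X, 2, colMeans(X))
    oracle <- t(Xc) %*% Xc / (nrow(X) - 1)
    expect_lt(max(abs(feat_covariance(X) - oracle)), 1e-10)
    ev <- eigen(feat_covariance(X), symmetric = TRUE, only.values = TRUE)
    expect_true(all(ev$values > -1e-10))   # positive semi-definite
  }
})

test_that("coral alignment matches a double-loop oracle", {
  coral_oracle <- function(fs) {
    N <- length(fs)
    covs <- lapply(fs, function(X) {
      Xc <- sweep(X, 2, colMeans(X)); t(Xc) %*% Xc / (nrow(X) - 1)
    })
    tot <- 0
    for (i in 1:N) for (j in 1:N) if (i != j)
      tot <- tot + sum((covs[[i]] - covs[[j]])^2)
    2 * tot / (N * (N - 1))
  }
  X <- rand_array(c(6, 3), 1)
  expect_equal(coral_align(list(X, X, X)), 0)
  A <- rand_array(c(5, 3), 2); B <- rand_array(c(7, 3), 3)
  cA <- feat_covariance(A); cB <- feat_covariance(B)
  expect_equal(coral_align(list(A, B)), 2 * sum((cA - cB)^2))
  for (s in 1:4) {
    fs <- lapply(1:(2 + s %% 3), function(i) rand_array(c(4 + i, 4), s * 10 + i))
    expect_lt(abs(coral_align(fs) - coral_oracle(fs)), 1e-10)
  }
  # permutation invariance
  fs3 <- list(rand_array(c(5, 2), 7), rand_array(c(6, 2), 8),
              rand_array(c(4, 2), 9))
  expect_equal(coral_align(fs3), coral_align(rev(fs3)))
  # shift invariance: adding a constant row vector to one subdomain
  shifted <- fs3
  shifted[[2]] <- sweep(shifted[[2]], 2, c(100, -40), `+`)
  expect_equal(coral_align(shifted), coral_align(fs3), tolerance = 1e-8)
  expect_error(coral_align(list(rand_array(c(4, 2), 1))), "at least 2")
})

test_that("divergence is the negated mean squared pair distance", {
  z <- rand_array(c(4, 3), 1)
  expect_equal(divergence(z, z), 0)
  expect_equal(divergence(c(1, 0), c(0, 1)), -2)
  for (s in 1:4) {
    z1 <- rand_array(c(5, 3), s); z2 <- rand_array(c(5, 3), s + 50)
    expect_lte(divergence(z1, z2), 0)
    expect_equal(divergence(z1, z2), -mean(rowSums((z1 - z2)^2)))
  }
  expect_error(divergence(z, rand_array(c(3, 4), 2)), "shape")
})

test_that("total student loss is an affine combination of its components", {
  set.seed(1)
  probs <- matrix(stats::runif(8), 2); probs <- probs / rowSums(probs)
  labels <- c(0L, 2L)
  z1 <- rand_array(c(2, 5), 1); tf <- rand_array(c(2, 5), 2)
  sub <- list(rand_array(c(3, 5), 3), rand_array(c(3, 5), 4))
  z2 <- do.call(rbind, sub)[1:2, ]
  base <- student_total_loss(probs, labels, z1, tf, sub, loss_weights(0, 0, 0),
                             z2 = z2)
  expect_equal(base$total, base$components[["cls"]])
  expect_equal(base$components[["cls"]], cross_entropy(probs, labels))
  for (lam in c(0.5, 2)) {
    r1 <- student_total_loss(probs, labels, z1, tf, sub,
                             loss_weights(lam, 0, 0), z2 = z2)
    expect_equal(r1$total - base$total, lam * r1$components[["mse"]])
    r2 <- student_total_loss(probs, labels, z1, tf, sub,
                             loss_weights(0, lam, 0), z2 = z2)
    expect_equal(r2$total - base$total, lam * r2$components[["align"]])
    r3 <- student_total_loss(probs, labels, z1, tf, sub,
                             loss_weights(0, 0, lam), z2 = z2)
    expect_equal(r3$total - base$total, lam * r3$components[["div"]])
  }
  expect_named(base$components, c("cls", "mse", "align", "div"))
})

test_that("loss gradients w.r.t. z1 combine the distillation pull and the
           divergence push", {
  # finite-difference check of d(total)/dz1 at the feature level
  set.seed(2)
  n <- 4; d <- 3
  z1 <- rand_array(c(d, n), 1); z2 <- rand_array(c(d, n), 2)
  tf <- rand_array(c(d, n), 3)
  w <- loss_weights(0.7, 0, 0.3)
  total_of <- function(z1m) {
    w$lambda1 * mse_loss(z1m, tf) + w$lambda3 * divergence(t(z1m), t(z2))
  }
  g <- w$lambda1 * 2 * (z1 - tf) / (d * n) - w$lambda3 * 2 * (z1 - z2) / n
  for (k in 1:5) {
    ii <- sample(length(z1), 1); eps <- 1e-6
    zp <- z1; zp[[ii]] <- z1[[ii]] + eps
    zm <- z1; zm[[ii]] <- z1[[ii]] - eps
    fd <- (total_of(zp) - total_of(zm)) / (2 * eps)
    expect_equal(fd, g[[ii]], tolerance = 1e-6)
  }
  # both terms contribute: zeroing either weight changes the gradient
  g_nopull <- -w$lambda3 * 2 * (z1 - z2) / n
  g_nopush <- w$lambda1 * 2 * (z1 - tf) / (d * n)
  expect_false(isTRUE(all.equal(g, g_nopull)))
  expect_false(isTRUE(all.equal(g, g_nopush)))
})

test_that("coral gradient matches finite differences", {
  set.seed(3)
  fs <- list(rand_array(c(4, 3), 11), rand_array(c(5, 3), 12),
             rand_array(c(4, 3), 13))
  g <- eegdg:::coral_align_grad(fs)
  for (k in 1:6) {
    i <- sample(3, 1)
    ii <- sample(length(fs[[i]]), 1); eps <- 1e-6
    fp <- fs; fp[[i]][[ii]] <- fp[[i]][[ii]] + eps
    fm <- fs; fm[[i]][[ii]] <- fm[[i]][[ii]] - eps
    fd <- (coral_align(fp) - coral_align(fm)) / (2 * eps)
    expect_equal(fd, g[[i]][[ii]], tolerance = 1e-5)
  }
})
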