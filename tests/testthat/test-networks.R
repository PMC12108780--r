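test_that("teacher and student layer shapes match the documented
           architecture for the reference configuration", {
  cfg <- network_config(C = 22, T = 1000, Nb = 4, n_classes = 4, fs = 250)
  expect_equal(cfg$C1, 63L)   # fs/4 rounded up to odd
  expect_shapes(audit_shapes(cfg, "teacher"))
  expect_shapes(audit_shapes(cfg, "student"))
  # pooled lengths follow floor division: 1000 -> 200 -> 40
  a <- audit_shapes(cfg, "teacher")
  expect_equal(a$unit2_out[1], 200)
  expect_equal(a$cls_in[1], 40)
})

test_that("layer shapes hold for random valid configurations", {
  set.seed(99)
  for (rep in 1:5) {
    cfg <- network_config(
      C = sample(3:16, 1), T = sample(c(75, 150, 250, 400), 1),
      Nb = sample(2:5, 1), n_classes = sample(2:5, 1),
      F1 = sample(2:6, 1), D = sample(1:2, 1), F2 = sample(2:5, 1),
      F3 = sample(2:6, 1), C1 = 2 * sample(3:12, 1) + 1,
      C2 = 2 * sample(2:7, 1) + 1, C3 = 2 * sample(2:7, 1) + 1,
      dropout_p = 0.3, fs = 100)
    expect_shapes(audit_shapes(cfg, "teacher"))
    expect_shapes(audit_shapes(cfg, "student"))
  }
})

test_that("dense units are densely connected with growth-rate input counts", {
  cfg <- tiny_net_config()
  net <- build_teacher(cfg)
  k0 <- cfg$F1 * cfg$D
  for (u in 1:2) {
    kin <- k0 + (u - 1) * 3 * cfg$F2
    for (l in 1:3) {
      W <- net$params[[sprintf("u%d_conv%d_W", u, l)]]
      # layer l consumes k0 + k (l - 1) channels, growth k = F2
      expect_equal(dim(W)[2], kin + (l - 1) * cfg$F2)
      expect_equal(dim(W)[3], cfg$F2)
    }
  }
})

test_that("student doubles the classifier width and splits z1/z2 evenly", {
  cfg <- tiny_net_config()
  tea <- build_teacher(cfg)
  stu <- build_student(cfg)
  expect_equal(dim(stu$params$cls_W)[3], 2L * cfg$F3)
  expect_equal(dim(tea$params$cls_W)[3], cfg$F3)
  expect_gt(n_parameters(stu), n_parameters(tea))
  X <- rand_array(c(3, cfg$C, cfg$T), 1)
  r <- forward_student(stu, X)
  T25 <- (cfg$T %/% 5) %/% 5
  expect_equal(dim(r$z1), c(3, cfg$F3 * T25))
  expect_equal(dim(r$z2), c(3, cfg$F3 * T25))
  expect_equal(rowSums(r$probs), rep(1, 3), tolerance = 1e-5)
  # probabilities strictly inside (0, 1)
  expect_true(all(r$probs > 0 & r$probs < 1))
})

test_that("evaluation-mode forward passes are deterministic", {
  cfg <- tiny_net_config()
  tea <- build_teacher(cfg)
  Xmb <- rand_array(c(2, cfg$Nb, cfg$C, cfg$T), 3)
  a <- forward_teacher(tea, Xmb)
  b <- forward_teacher(tea, Xmb)
  expect_identical(a, b)
  expect_equal(dim(a$feat), c(2, cfg$F3 * ((cfg$T %/% 5) %/% 5)))
  expect_equal(dim(a$probs), c(2, cfg$n_classes))
})

test_that("every trainable parameter receives gradient on a random batch", {
  cfg <- network_config(C = 4, T = 50, Nb = 2, n_classes = 3, F1 = 3, F2 = 2,
                        F3 = 3, C1 = 7, C2 = 5, C3 = 5, dropout_p = 0,
                        fs = 100)
  set.seed(4)
  for (kind in c("teacher", "student")) {
    net <- if (kind == "teacher") build_teacher(cfg) else build_student(cfg)
    Xin <- if (kind == "teacher") rand_array(c(50, 4, 2, 6), 5)
           else rand_array(c(50, 4, 6), 5)
    r <- eegdg:::net_forward(net, Xin, train = TRUE)
    g <- eegdg:::net_backward(net, r$cache, rep(0:2, 2))
    for (nm in names(net$params)) {
      expect_true(!is.null(g[[nm]]), info = paste(kind, nm))
      # biases feeding straight into batch-norm are degenerate directions
      if (!nm %in% c("temp_b", "fus_b"))
        expect_gt(max(abs(g[[nm]])), 0, label = paste(kind, nm))
    }
  }
})

test_that("network gradients agree with finite differences", {
  cfg <- network_config(C = 3, T = 50, Nb = 2, n_classes = 2, F1 = 2, F2 = 2,
                        F3 = 2, C1 = 7, C2 = 5, C3 = 5, dropout_p = 0,
                        fs = 100)
  set.seed(6)
  net <- build_teacher(cfg)
  Xin <- rand_array(c(50, 3, 2, 4), 7)
  y <- c(0L, 1L, 0L, 1L)
  r <- eegdg:::net_forward(net, Xin, train = TRUE)
  g <- eegdg:::net_backward(net, r$cache, y)
  loss_at <- function(nn)
    cross_entropy(t(eegdg:::net_forward(nn, Xin, train = TRUE)$probs), y)
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    ii <- sample(length(p), 1)
    eps <- 1e-5
    n2 <- net; n2$params[[nm]][[ii]] <- p[[ii]] + eps; Lp <- loss_at(n2)
    n2$params[[nm]][[ii]] <- p[[ii]] - eps; Lm <- loss_at(n2)
    expect_equal(g[[nm]][[ii]], (Lp - Lm) / (2 * eps), tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_net_config()
  set.seed(8)
  net <- build_student(cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  expect_identical(unclass(back$cfg), unclass(net$cfg))
  X <- rand_array(c(2, cfg$C, cfg$T), 9)
  expect_identical(forward_student(back, X), forward_student(net, X))
  unlink(path)
})

test_that("invalid network configurations are rejected", {
  expect_error(network_config(T = 20), "pool")
  expect_error(network_config(C1 = 10), "odd")
  expect_error(network_config(dropout_p = 1), "dropout_p")
  expect_error(network_config(n_classes = 1), "classes")
  expect_error(network_config(F1 = 0), "F1")
})
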