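# Layer-by-layer shape audit used by the network and acceptance tests.

# layer-by-layer shape audit via the forward cache
audit_shapes <- function(cfg, kind, n = 2) {
  set.seed(1)
  net <- if (kind == "teacher") build_teacher(cfg) else build_student(cfg)
  Xin <- if (kind == "teacher")
    rand_array(c(cfg$T, cfg$C, cfg$Nb, n), 1)
  else rand_array(c(cfg$T, cfg$C, n), 1)
  r <- eegdg:::net_forward(net, Xin, train = FALSE)
  T5 <- cfg$T %/% cfg$pool
  T25 <- T5 %/% cfg$pool
  k0 <- cfg$F1 * cfg$D
  F3e <- if (kind == "student") 2L * cfg$F3 else cfg$F3
  list(
    temporal_in = dim(r$cache$temp$X),        # (T, 1, C*n)
    depthwise_out = dim(r$cache$dw_elu),      # (T, F1*D, n)
    unit1_out = r$cache$pool1$d,              # (T, k0 + 3 F2, n)
    unit2_out = r$cache$pool2$d,              # (T//5, k0 + 6 F2, n)
    cls_in = dim(r$cache$cls$X),              # (T//25, k0 + 6 F2, n)
    feat = dim(r$feat),                       # (F3e * T25, n)
    probs = dim(r$probs),
    expected = list(
      temporal_in = c(cfg$T, 1L, cfg$C * n),
      depthwise_out = c(cfg$T, k0, n),
      unit1_out = c(cfg$T, k0 + 3L * cfg$F2, n),
      unit2_out = c(T5, k0 + 6L * cfg$F2, n),
      cls_in = c(T25, k0 + 6L * cfg$F2, n),
      feat = c(F3e * T25, n),
      probs = c(cfg$n_classes, n)))
}

expect_shapes <- function(a) {
  for (nm in names(a$expected)) expect_equal(a[[nm]], a$expected[[nm]])
}
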