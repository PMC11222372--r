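ns <- asNamespace("dsnet")

test_that("encoder channel schedule and spatial halving follow the contract", {
  cfg <- model_config()
  expect_identical(ns$stage_channels(cfg), c(16L, 32L, 64L, 128L, 256L))
  set.seed(10)
  cfg4 <- model_config(base_channels = 4L, token_dim = 32L, n_heads = 2L)
  m <- dsnet_model(cfg4, 32L)
  x <- array(rnorm(32^3 * 2), c(32, 32, 32, 2, 1))
  feats <- local({
    cur <- x
    out <- list()
    for (l in 1:5) {
      cur <- m$modules[[paste0("enc", l)]]$fwd(cur, FALSE)
      if (l %in% cfg4$transformer_stages)
        cur <- m$modules[[paste0("tf", l)]]$fwd(cur, FALSE)
      out[[l]] <- cur
      if (l < 5) cur <- m$modules[[paste0("pool", l)]]$fwd(cur, FALSE)
    }
    out
  })
  for (l in 1:5) {
    expect_equal(dim(feats[[l]])[4], ns$stage_channels(cfg4)[l])
    expect_equal(dim(feats[[l]])[1:3], rep(32 / 2^(l - 1), 3))
  }
})

test_that("conv blocks preserve shape, clamp at zero and are deterministic", {
  set.seed(11)
  cb <- ns$nn_conv_block(16L, 32L)
  x <- array(rnorm(8^3 * 16 * 1), c(8, 8, 8, 16, 1))
  y1 <- cb$fwd(x, training = FALSE)
  expect_identical(dim(y1), c(8L, 8L, 8L, 32L, 1L))
  expect_gte(min(y1), 0)
  y2 <- cb$fwd(x, training = FALSE)
  expect_identical(y1, y2)
  expect_error(ns$nn_conv3d(2, 0), "positive|invalid|dims")
})

test_that("tokenizer produces one token per spatial location", {
  set.seed(12)
  # 512 tokens at stage 5 for a 128^3 patch: (128/16)^3
  expect_equal(prod(rep(128 / 2^4, 3)), 512)
  f5 <- array(rnorm(2^3 * 4 * 2), c(2, 2, 2, 4, 2))
  proj <- diag(4)
  P <- matrix(0, 8, 4)
  tk <- tokenize(f5, proj, P)
  expect_identical(dim(tk), c(8L, 4L, 2L))
  # identity projection + zero P: tokens equal the flattened features
  expect_equal(tk[, , 1], matrix(f5[, , , , 1], 8))
  # round trip through detokenize with identity projections
  back <- detokenize(tk, diag(4), numeric(4), c(2, 2, 2))
  expect_equal(back, f5)
  expect_equal(detokenize(tk, matrix(0, 4, 4), numeric(4), c(2, 2, 2)),
               f5 * 0)
  expect_error(tokenize(f5, proj, matrix(0, 9, 4)), "tokens")
})

test_that("multi-head attention matches a literal evaluation of its equations", {
  set.seed(3)
  Tn <- 4L; Cp <- 6L; nh <- 2L
  X <- matrix(rnorm(Tn * Cp), Tn, Cp)
  p <- list(Wq = matrix(rnorm(Cp * Cp), Cp), Wk = matrix(rnorm(Cp * Cp), Cp),
            Wv = matrix(rnorm(Cp * Cp), Cp), Wo = matrix(rnorm(Cp * Cp), Cp),
            ln_gamma = runif(Cp, 0.5, 1.5), ln_beta = rnorm(Cp),
            n_heads = nh)
  got <- msa(X, p)

  # independent, literal evaluation
  lnref <- t(apply(X, 1, function(r)
    p$ln_gamma * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) +
      p$ln_beta))
  Q <- lnref %*% p$Wq; K <- lnref %*% p$Wk; V <- lnref %*% p$Wv
  dk <- Cp / nh
  heads <- lapply(seq_len(nh), function(i) {
    ix <- ((i - 1) * dk + 1):(i * dk)
    S <- Q[, ix] %*% t(K[, ix]) / sqrt(dk)
    A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
    expect_equal(rowSums(A), rep(1, Tn), tolerance = 1e-6)
    A %*% V[, ix]
  })
  want <- do.call(cbind, heads) %*% p$Wo
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("attention softmax degenerates correctly", {
  # one token, one head, identity projections: softmax over one key is 1,
  # so the output is LN of the input token
  X <- matrix(c(1, 2, -1, 0.5), 1, 4)
  p <- list(Wq = diag(4), Wk = diag(4), Wv = diag(4), Wo = diag(4),
            ln_gamma = rep(1, 4), ln_beta = rep(0, 4), n_heads = 1L)
  r <- as.vector(X)
  lnr <- (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
  expect_equal(as.vector(msa(X, p)), lnr, tolerance = 1e-9)

  # two identical tokens produce identical outputs
  X2 <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  out <- msa(X2, p)
  expect_equal(out[1, ], out[2, ])
})

test_that("transformer block has exact pre-norm residual structure", {
  set.seed(13)
  Cp <- 8L
  p <- ns$init_tf_block(Cp)
  p$n_heads <- 2L
  X <- matrix(rnorm(5 * Cp), 5, Cp)
  # zeroed sublayers: pure residual path, output equals input
  p0 <- p
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) p0[[nm]][] <- 0
  for (nm in c("b1", "b2")) p0[[nm]][] <- 0
  expect_equal(transformer_block(X, p0), X)
  # composition: two applications equal a 2-block stack
  y1 <- transformer_block(transformer_block(X, p), p)
  y2 <- transformer_block(transformer_block(X, p), p)
  expect_identical(y1, y2)
  # shape preserved
  expect_identical(dim(transformer_block(X, p)), dim(X))
})

test_that("channel attention matches the gating formula", {
  set.seed(5)
  x <- array(rnorm(4 * 4 * 4 * 8 * 1), c(4, 4, 4, 8, 1))
  hid <- 4L
  mlp <- list(W1 = matrix(rnorm(8 * hid), 8, hid), b1 = rnorm(hid),
              W2 = matrix(rnorm(hid * 8), hid, 8), b2 = rnorm(8))
  got <- channel_attention(x, mlp)
  # literal evaluation: shared MLP on global max/avg pooling, summed, sigmoid
  mp <- apply(x[, , , , 1], 4, max)
  ap <- apply(x[, , , , 1], 4, mean)
  mlp_f <- function(v) {
    h <- pmax(v %*% mlp$W1 + matrix(mlp$b1, 1), 0)
    as.vector(h %*% mlp$W2 + matrix(mlp$b2, 1))
  }
  s <- mlp_f(matrix(mp, 1)) + mlp_f(matrix(ap, 1))
  gate <- 1 / (1 + exp(-s))
  want <- x
  for (ci in 1:8) want[, , , ci, 1] <- x[, , , ci, 1] * gate[ci]
  expect_equal(got, want, tolerance = 1e-6)
  expect_true(all(gate > 0 & gate < 1))

  # zeroed MLP gives sigma(0) = 0.5 gates
  mlp0 <- lapply(mlp, function(w) w * 0)
  expect_equal(channel_attention(x, mlp0), 0.5 * x)

  # constant-per-channel input: both pooling pathways agree
  xc <- x
  for (ci in 1:8) xc[, , , ci, 1] <- ci
  expect_equal(apply(xc[, , , , 1], 4, max), apply(xc[, , , , 1], 4, mean))
})

test_that("spatial attention matches the gating formula", {
  set.seed(6)
  x <- array(rnorm(5 * 4 * 6 * 3 * 1), c(5, 4, 6, 3, 1))
  k <- 3L
  conv <- list(W = matrix(rnorm(2 * k^3), 2 * k^3, 1), b = rnorm(1), k = k)
  got <- spatial_attention(x, conv)
  # literal evaluation via the package's plain conv on the 2-channel map
  mx <- apply(x[, , , , 1], 1:3, max)
  av <- apply(x[, , , , 1], 1:3, mean)
  cat2 <- array(c(mx, av), c(5, 4, 6, 2, 1))
  s <- ns$cpp_conv3d_fw(cat2, dim(cat2), conv$W, conv$b, k, k %/% 2L)
  gate <- 1 / (1 + exp(-s[, , , 1, 1]))
  want <- x
  for (ci in 1:3) want[, , , ci, 1] <- x[, , , ci, 1] * gate
  expect_equal(got, want, tolerance = 1e-6)
  expect_true(all(gate > 0 & gate < 1))

  # zero conv: 0.5 gate
  conv0 <- list(W = conv$W * 0, b = 0, k = k)
  expect_equal(spatial_attention(x, conv0), 0.5 * x)

  # single-channel input: max and mean pooling both reproduce the channel
  x1 <- x[, , , 1, , drop = FALSE]
  expect_equal(apply(x1[, , , , 1, drop = FALSE], 1:3, max),
               apply(x1[, , , , 1, drop = FALSE], 1:3, mean))
})

test_that("zero-weight CBAM scales by exactly 0.25 and gates shrink", {
  set.seed(7)
  x <- array(rnorm(4^3 * 4), c(4, 4, 4, 4, 1))
  w0 <- list(mlp = list(W1 = matrix(0, 4, 2), b1 = numeric(2),
                        W2 = matrix(0, 2, 4), b2 = numeric(4)),
             conv = list(W = matrix(0, 2 * 27, 1), b = 0, k = 3L))
  expect_equal(cbam(x, w0), 0.25 * x)
  # with random weights, |output| <= |input| elementwise (gates < 1)
  w <- list(mlp = list(W1 = matrix(rnorm(8), 4, 2), b1 = rnorm(2),
                       W2 = matrix(rnorm(8), 2, 4), b2 = rnorm(4)),
            conv = list(W = matrix(rnorm(54), 54, 1), b = rnorm(1), k = 3L))
  expect_true(all(abs(cbam(x, w)) <= abs(x)))
})

test_that("full forward pass honours the output contracts", {
  set.seed(14)
  rc <- resolve_preset("dsnet-tiny")
  m <- dsnet_model(rc$model, 32L)
  x <- array(rnorm(32^3 * 2), c(32, 32, 32, 2, 1))
  out <- dsnet_forward(m, x)
  expect_identical(dim(out$binary), c(32L, 32L, 32L, 2L, 1L))
  expect_identical(dim(out$subfield), c(32L, 32L, 32L, 4L, 1L))
  expect_error(dsnet_forward(m, array(0, c(24, 32, 32, 2, 1))),
               "divisible")
})

test_that("single-branch model drops the binary head and parameters", {
  set.seed(15)
  dual <- dsnet_model(micro_model_config(), 16L)
  set.seed(15)
  single <- dsnet_model(micro_model_config(dual_branch = FALSE), 16L)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 2, 1))
  out <- dsnet_forward(single, x)
  expect_null(out$binary)
  expect_identical(dim(out$subfield), c(16L, 16L, 16L, 4L, 1L))
  expect_lt(n_parameters(single), n_parameters(dual))
})

test_that("every preset builds and completes forward + backward", {
  presets <- c("dsnet", "dsnet-no-cbam", "dsnet-no-transformer",
               "dsnet-single-branch", "dsnet-t1w", "dsnet-t2w",
               "dsnet-tf-l4", "dsnet-tf-l4l5", "dsnet-tiny")
  for (ps in presets) {
    rc <- resolve_preset(ps)
    cfg <- rc$model
    # desk-scale override: small channel/token counts, 32-voxel patches
    cfg$base_channels <- 4L; cfg$token_dim <- 32L; cfg$n_heads <- 2L
    set.seed(16)
    m <- dsnet_model(cfg, 32L)
    x <- array(rnorm(32^3 * cfg$in_channels), c(32, 32, 32, cfg$in_channels, 1))
    y <- array(sample(0:3, 32^3, TRUE), c(32, 32, 32, 1))
    out <- dsnet_forward(m, x, training = TRUE)
    ls <- if (cfg$dual_branch) loss_spec() else loss_spec(lambda1 = 0)
    fw <- ns$total_loss_fw(out$binary, out$subfield, y, ls)
    expect_true(is.finite(fw$loss))
    gr <- ns$total_loss_bw(fw, ls)
    ns$model_zero_grads(m)
    dx <- ns$dsnet_backward(m, gr$d_subfield, gr$d_binary)
    expect_identical(dim(dx), dim(x))
    # gradient reaches every parameter group (no dead branch)
    for (lm in ns$model_leaves(m)) {
      gn <- sum(vapply(lm$grads, function(g) sum(abs(g)), 0))
      expect_gt(gn, 0)
    }
  }
  expect_error(resolve_preset("dsnet-huge"), "unknown preset")
})

test_that("transformer placement variants share one input contract", {
  for (st in list(4L, 5L, c(4L, 5L))) {
    set.seed(17)
    cfg <- model_config(base_channels = 4L, token_dim = 32L, n_heads = 2L,
                        transformer_stages = st)
    m <- dsnet_model(cfg, 32L)
    x <- array(rnorm(32^3 * 2), c(32, 32, 32, 2, 1))
    out <- dsnet_forward(m, x)
    expect_identical(dim(out$subfield), c(32L, 32L, 32L, 4L, 1L))
  }
})
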