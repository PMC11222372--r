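# Transformer bottleneck (tokenizer + multi-head self-attention + FFN with
# pre-norm residuals) and the convolutional block attention module (CBAM)
# used on the skip connections.

ln_eps <- 1e-5

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

layernorm_fw <- function(X, gamma, beta) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, gamma, `*`) + rep(beta, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bw <- function(dY, cache, gamma) {
  dxhat <- sweep(dY, 2, gamma, `*`)
  dX <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dgamma = colSums(dY * cache$xhat), dbeta = colSums(dY))
}

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Multi-head self-attention over a token sequence
#'
#' Applies layer normalization to the tokens, projects them into per-head
#' queries, keys and values, computes scaled dot-product attention
#' `softmax(Q K' / sqrt(d_k)) V` per head, concatenates the heads and applies
#' the output projection. Exposed as a plain function so its output can be
#' checked against a literal evaluation of the attention equations.
#'
#' @param tokens numeric matrix (n_tokens x token_dim), one sequence.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (token_dim x token_dim),
#'   `ln_gamma`, `ln_beta` (length token_dim) and `n_heads`.
#' @return matrix of the same shape as `tokens` (the MSA output, without the
#'   residual connection).
#' @export
msa <- function(tokens, params) {
  msa_fw(tokens, params)$out
}

msa_fw <- function(X, p) {
  Cp <- ncol(X); nh <- p$n_heads
  if (Cp %% nh != 0) stop("token_dim must be divisible by n_heads")
  dk <- Cp / nh
  ln <- layernorm_fw(X, p$ln_gamma, p$ln_beta)
  Z <- ln$y
  Q <- Z %*% p$Wq; K <- Z %*% p$Wk; V <- Z %*% p$Wv
  O <- matrix(0, nrow(X), Cp)
  A <- vector("list", nh)
  for (i in seq_len(nh)) {
    idx <- ((i - 1) * dk + 1):(i * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    A[[i]] <- row_softmax(S)
    O[, idx] <- A[[i]] %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$Wo
  list(out = out, cache = list(ln = ln, Z = Z, Q = Q, K = K, V = V,
                               A = A, O = O, dk = dk, nh = nh))
}

msa_bw <- function(dout, cache, p) {
  cc <- cache
  dO <- dout %*% t(p$Wo)
  g <- list(Wo = t(cc$O) %*% dout)
  dQ <- matrix(0, nrow(dout), ncol(dout))
  dK <- dQ; dV <- dQ
  for (i in seq_len(cc$nh)) {
    idx <- ((i - 1) * cc$dk + 1):(i * cc$dk)
    Ai <- cc$A[[i]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(cc$V[, idx, drop = FALSE])
    dV[, idx] <- t(Ai) %*% dOh
    dS <- Ai * (dA - rowSums(dA * Ai))
    dQ[, idx] <- dS %*% cc$K[, idx, drop = FALSE] / sqrt(cc$dk)
    dK[, idx] <- t(dS) %*% cc$Q[, idx, drop = FALSE] / sqrt(cc$dk)
  }
  dZ <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  g$Wq <- t(cc$Z) %*% dQ
  g$Wk <- t(cc$Z) %*% dK
  g$Wv <- t(cc$Z) %*% dV
  lb <- layernorm_bw(dZ, cc$ln, p$ln_gamma)
  g$ln_gamma <- lb$dgamma; g$ln_beta <- lb$dbeta
  list(dX = lb$dX, grads = g)
}

#' One pre-norm transformer block
#'
#' Computes `y = MSA(LN(x)) + x` followed by `out = FFN(LN(y)) + y`, where
#' the FFN is a two-layer position-wise perceptron with GELU activation.
#'
#' @param tokens numeric matrix (n_tokens x token_dim).
#' @param params list with the [msa()] parameters plus `ln2_gamma`,
#'   `ln2_beta`, `W1`, `b1`, `W2`, `b2` (FFN weights).
#' @return matrix of the same shape as `tokens`.
#' @export
transformer_block <- function(tokens, params) {
  tf_block_fw(tokens, params)$out
}

tf_block_fw <- function(X, p) {
  att <- msa_fw(X, p)
  y <- att$out + X
  ln2 <- layernorm_fw(y, p$ln2_gamma, p$ln2_beta)
  Hpre <- sweep(ln2$y %*% p$W1, 2, p$b1, `+`)
  G <- gelu(Hpre)
  f <- sweep(G %*% p$W2, 2, p$b2, `+`)
  list(out = f + y,
       cache = list(att = att$cache, y = y, ln2 = ln2, Hpre = Hpre, G = G))
}

tf_block_bw <- function(dout, cache, p) {
  cc <- cache
  dG <- dout %*% t(p$W2)
  g <- list(W2 = t(cc$G) %*% dout, b2 = colSums(dout))
  dH <- dG * gelu_grad(cc$Hpre)
  g$W1 <- t(cc$ln2$y) %*% dH
  g$b1 <- colSums(dH)
  dln2y <- dH %*% t(p$W1)
  lb <- layernorm_bw(dln2y, cc$ln2, p$ln2_gamma)
  g$ln2_gamma <- lb$dgamma; g$ln2_beta <- lb$dbeta
  dy <- dout + lb$dX
  mb <- msa_bw(dy, cc$att, p)
  g <- c(g, mb$grads)
  list(dX = dy + mb$dX, grads = g)
}

tf_block_param_names <- c("ln_gamma", "ln_beta", "Wq", "Wk", "Wv", "Wo",
                          "ln2_gamma", "ln2_beta", "W1", "b1", "W2", "b2")

init_tf_block <- function(Cp, hidden = 4L * Cp) {
  xav <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(1 / nin)),
                                    nin, nout)
  list(ln_gamma = rep(1, Cp), ln_beta = rep(0, Cp),
       Wq = xav(Cp, Cp), Wk = xav(Cp, Cp), Wv = xav(Cp, Cp),
       Wo = xav(Cp, Cp),
       ln2_gamma = rep(1, Cp), ln2_beta = rep(0, Cp),
       W1 = xav(Cp, hidden), b1 = numeric(hidden),
       W2 = xav(hidden, Cp), b2 = numeric(Cp))
}

#' Tokenize a bottleneck feature map
#'
#' Flattens the spatial grid of a (D, H, W, C, N) feature map into a token
#' sequence (one token per spatial location), applies a linear projection
#' into the token space and adds a learnable positional table:
#' `tokens = X W + P`.
#'
#' @param f feature array (D, H, W, C, N).
#' @param proj projection matrix (C x token_dim).
#' @param P positional embedding matrix (n_tokens x token_dim).
#' @return array (n_tokens, token_dim, N).
#' @export
tokenize <- function(f, proj, P) {
  d <- dim(f); Tn <- prod(d[1:3])
  if (nrow(P) != Tn) stop("positional table has ", nrow(P),
                          " rows but the map yields ", Tn, " tokens")
  out <- array(0, c(Tn, ncol(proj), d[5]))
  for (n in seq_len(d[5]))
    out[, , n] <- matrix(f[, , , , n], nrow = Tn) %*% proj + P
  out
}

#' @rdname tokenize
#' @param tokens array (n_tokens, token_dim, N).
#' @param proj_back matrix (token_dim x C).
#' @param bias length-C bias of the inverse projection.
#' @param spatial_dims integer triple (D, H, W) with `prod == n_tokens`.
#' @export
detokenize <- function(tokens, proj_back, bias, spatial_dims) {
  Tn <- dim(tokens)[1]
  if (prod(spatial_dims) != Tn)
    stop("spatial dims do not match the number of tokens")
  N <- dim(tokens)[3]
  C <- ncol(proj_back)
  out <- array(0, c(spatial_dims, C, N))
  for (n in seq_len(N))
    out[, , , , n] <- array(sweep(matrix(tokens[, , n], Tn) %*% proj_back,
                                  2, bias, `+`),
                            c(spatial_dims, C))
  out
}

# Transformer stage module: tokenize -> blocks -> detokenize, batched.
nn_transformer <- function(C, Cp, n_tokens, n_blocks, n_heads,
                           spatial_dims) {
  m <- new_module("transformer")
  m$n_heads <- n_heads; m$n_blocks <- n_blocks
  m$spatial <- spatial_dims
  m$params$Wtok <- matrix(rnorm(C * Cp, sd = sqrt(1 / C)), C, Cp)
  m$params$P <- matrix(rnorm(n_tokens * Cp, sd = 0.02), n_tokens, Cp)
  for (b in seq_len(n_blocks)) {
    blk <- init_tf_block(Cp)
    names(blk) <- paste0("blk", b, "_", tf_block_param_names)
    m$params <- c(m$params, blk)
  }
  m$params$Wdet <- matrix(rnorm(Cp * C, sd = sqrt(1 / Cp)), Cp, C)
  m$params$bdet <- numeric(C)
  zero_grads(m)
  blk_params <- function(b) {
    p <- m$params[paste0("blk", b, "_", tf_block_param_names)]
    names(p) <- tf_block_param_names
    p$n_heads <- m$n_heads
    p
  }
  m$fwd <- function(x, training = TRUE) {
    d <- dim(x); Tn <- prod(d[1:3]); N <- d[5]
    if (Tn != nrow(m$params$P))
      stop("transformer stage built for ", nrow(m$params$P),
           " tokens; got ", Tn)
    m$cache <- list(d = d, X0 = vector("list", N),
                    blocks = vector("list", N))
    y <- array(0, d)
    for (n in seq_len(N)) {
      X <- matrix(x[, , , , n], nrow = Tn)
      Tk <- X %*% m$params$Wtok + m$params$P
      m$cache$X0[[n]] <- X
      caches <- vector("list", m$n_blocks)
      for (b in seq_len(m$n_blocks)) {
        r <- tf_block_fw(Tk, blk_params(b))
        caches[[b]] <- r$cache
        Tk <- r$out
      }
      m$cache$blocks[[n]] <- caches
      m$cache$Tlast <- if (n == 1) list(Tk) else c(m$cache$Tlast, list(Tk))
      y[, , , , n] <- array(sweep(Tk %*% m$params$Wdet, 2, m$params$bdet,
                                  `+`), d[1:4])
    }
    y
  }
  m$bwd <- function(dy) {
    d <- m$cache$d; Tn <- prod(d[1:3]); N <- d[5]
    dx <- array(0, d)
    for (n in seq_len(N)) {
      dOut <- matrix(dy[, , , , n], nrow = Tn)
      Tk <- m$cache$Tlast[[n]]
      m$grads$Wdet <- m$grads$Wdet + t(Tk) %*% dOut
      m$grads$bdet <- m$grads$bdet + colSums(dOut)
      dT <- dOut %*% t(m$params$Wdet)
      for (b in rev(seq_len(m$n_blocks))) {
        r <- tf_block_bw(dT, m$cache$blocks[[n]][[b]], blk_params(b))
        dT <- r$dX
        for (nm in tf_block_param_names) {
          key <- paste0("blk", b, "_", nm)
          m$grads[[key]] <- m$grads[[key]] + r$grads[[nm]]
        }
      }
      m$grads$P <- m$grads$P + dT
      m$grads$Wtok <- m$grads$Wtok + t(m$cache$X0[[n]]) %*% dT
      dx[, , , , n] <- array(dT %*% t(m$params$Wtok), d[1:4])
    }
    dx
  }
  m
}

#' Channel and spatial attention gates (CBAM)
#'
#' `channel_attention()` gates each channel by
#' `sigmoid(MLP(maxpool(x)) + MLP(avgpool(x)))` where both global-pooling
#' pathways share one two-layer MLP; `spatial_attention()` gates each voxel by
#' `sigmoid(conv([maxpool_c(x), avgpool_c(x)]))` with a 7x7x7 convolution over
#' the 2-channel map of channelwise max and mean. `cbam()` composes the two
#' (channel first). All three preserve the input shape and their gates lie
#' strictly in (0, 1).
#'
#' @param x feature array (D, H, W, C, N).
#' @param mlp list with `W1` (C x hidden), `b1`, `W2` (hidden x C), `b2`.
#' @return gated array, same shape as `x`.
#' @export
channel_attention <- function(x, mlp) {
  ca_fw(x, mlp)$y
}

ca_fw <- function(x, p) {
  d <- dim(x); C <- d[4]; N <- d[5]; rows <- prod(d[1:3])
  X <- matrix(x, nrow = rows)
  cm <- cpp_colmax(X)
  mx <- cm$max
  amax <- cm$which
  av <- colMeans(X)
  Pm <- matrix(mx, nrow = N, ncol = C, byrow = TRUE)
  Pa <- matrix(av, nrow = N, ncol = C, byrow = TRUE)
  A1m <- pmax(sweep(Pm %*% p$W1, 2, p$b1, `+`), 0)
  A1a <- pmax(sweep(Pa %*% p$W1, 2, p$b1, `+`), 0)
  S <- sweep(A1m %*% p$W2, 2, p$b2, `+`) +
    sweep(A1a %*% p$W2, 2, p$b2, `+`)
  G <- sigmoid(S)  # N x C
  gcol <- as.vector(t(G))
  Y <- sweep(X, 2, gcol, `*`)
  list(y = array(Y, d),
       cache = list(X = X, d = d, amax = amax, Pm = Pm, Pa = Pa,
                    A1m = A1m, A1a = A1a, G = G, gcol = gcol))
}

ca_bw <- function(dy, cache, p) {
  cc <- cache; d <- cc$d; C <- d[4]; N <- d[5]; rows <- prod(d[1:3])
  dY <- matrix(dy, nrow = rows)
  dX <- sweep(dY, 2, cc$gcol, `*`)
  dg <- colSums(dY * cc$X)                      # per (c, n) column
  dG <- matrix(dg, nrow = N, byrow = TRUE) * cc$G * (1 - cc$G)
  g <- list(W2 = t(cc$A1m) %*% dG + t(cc$A1a) %*% dG,
            b2 = 2 * colSums(dG))
  dA1m <- (dG %*% t(p$W2)) * (cc$A1m > 0)
  dA1a <- (dG %*% t(p$W2)) * (cc$A1a > 0)
  g$W1 <- t(cc$Pm) %*% dA1m + t(cc$Pa) %*% dA1a
  g$b1 <- colSums(dA1m) + colSums(dA1a)
  dPm <- dA1m %*% t(p$W1)   # N x C
  dPa <- dA1a %*% t(p$W1)
  # route the pooling gradients back into X
  dPm_col <- as.vector(t(dPm))
  dPa_col <- as.vector(t(dPa))
  for (j in seq_len(C * N))
    dX[cc$amax[j], j] <- dX[cc$amax[j], j] + dPm_col[j]
  dX <- sweep(dX, 2, dPa_col / rows, `+`)
  list(dx = array(dX, d), grads = g)
}

#' @rdname channel_attention
#' @param conv list with `W` (the (2 * k^3) x 1 convolution weight matrix in
#'   the package's conv layout), `b` (length-1 bias) and `k` (kernel size).
#' @export
spatial_attention <- function(x, conv) {
  sa_fw(x, conv)$y
}

sa_fw <- function(x, p) {
  d <- dim(x); C <- d[4]; N <- d[5]
  sp <- d[1:3]
  cat2 <- array(0, c(sp, 2, N))
  amax <- array(0L, c(sp, N))
  for (n in seq_len(N)) {
    M <- matrix(x[, , , , n], ncol = C)
    am <- max.col(M, ties.method = "first")
    amax[, , , n] <- array(am, sp)
    cat2[, , , 1, n] <- array(M[cbind(seq_len(nrow(M)), am)], sp)
    cat2[, , , 2, n] <- array(rowMeans(M), sp)
  }
  S <- cpp_conv3d_fw(cat2, dim(cat2), p$W, p$b, p$k, p$k %/% 2L)
  G <- sigmoid(S)   # (D,H,W,1,N)
  y <- array(0, d)
  for (n in seq_len(N)) for (ci in seq_len(C))
    y[, , , ci, n] <- x[, , , ci, n] * G[, , , 1, n]
  list(y = y, cache = list(x = x, d = d, cat2 = cat2, amax = amax, G = G))
}

sa_bw <- function(dy, cache, p) {
  cc <- cache; d <- cc$d; C <- d[4]; N <- d[5]; sp <- d[1:3]
  dx <- array(0, d)
  dG <- array(0, c(sp, 1, N))
  for (n in seq_len(N)) {
    acc <- array(0, sp)
    for (ci in seq_len(C)) {
      dx[, , , ci, n] <- dy[, , , ci, n] * cc$G[, , , 1, n]
      acc <- acc + dy[, , , ci, n] * cc$x[, , , ci, n]
    }
    dG[, , , 1, n] <- acc
  }
  dS <- dG * cc$G * (1 - cc$G)
  r <- cpp_conv3d_bw(cc$cat2, dim(cc$cat2), p$W, dS, p$k, p$k %/% 2L)
  dcat <- r$dx
  for (n in seq_len(N)) {
    dmax <- as.vector(dcat[, , , 1, n])
    davg <- as.vector(dcat[, , , 2, n]) / C
    am <- as.vector(cc$amax[, , , n])
    Md <- matrix(dx[, , , , n], ncol = C)
    Md <- Md + davg
    Md[cbind(seq_along(am), am)] <- Md[cbind(seq_along(am), am)] + dmax
    dx[, , , , n] <- array(Md, d[1:4])
  }
  list(dx = dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

#' @rdname channel_attention
#' @param weights list with elements `mlp` and `conv` as above.
#' @export
cbam <- function(x, weights) {
  spatial_attention(channel_attention(x, weights$mlp), weights$conv)
}

# CBAM skip-connection module.
nn_cbam <- function(C, reduction = 16L, spatial_kernel = 7L) {
  m <- new_module("cbam")
  hid <- max(1L, C %/% reduction)
  m$k <- as.integer(spatial_kernel)
  m$params$W1 <- matrix(rnorm(C * hid, sd = sqrt(1 / C)), C, hid)
  m$params$b1 <- numeric(hid)
  m$params$W2 <- matrix(rnorm(hid * C, sd = sqrt(1 / hid)), hid, C)
  m$params$b2 <- numeric(C)
  m$params$Ws <- matrix(rnorm(2 * m$k^3, sd = he_sd(2 * m$k^3)),
                        2 * m$k^3, 1)
  m$params$bs <- numeric(1)
  zero_grads(m)
  m$fwd <- function(x, training = TRUE) {
    mlp <- list(W1 = m$params$W1, b1 = m$params$b1,
                W2 = m$params$W2, b2 = m$params$b2)
    rc <- ca_fw(x, mlp)
    rs <- sa_fw(rc$y, list(W = m$params$Ws, b = m$params$bs, k = m$k))
    m$cache <- list(ca = rc$cache, sa = rs$cache, mlp = mlp)
    rs$y
  }
  m$bwd <- function(dy) {
    rs <- sa_bw(dy, m$cache$sa, list(W = m$params$Ws, b = m$params$bs,
                                     k = m$k))
    m$grads$Ws <- m$grads$Ws + rs$grads$W
    m$grads$bs <- m$grads$bs + rs$grads$b
    rc <- ca_bw(rs$dx, m$cache$ca, m$cache$mlp)
    m$grads$W1 <- m$grads$W1 + rc$grads$W1
    m$grads$b1 <- m$grads$b1 + rc$grads$b1
    m$grads$W2 <- m$grads$W2 + rc$grads$W2
    m$grads$b2 <- m$grads$b2 + rc$grads$b2
    rc$dx
  }
  m
}
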