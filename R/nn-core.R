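# Minimal neural-network substrate: modules are environments holding
# parameters, gradients and forward/backward closures.  Feature tensors are
# arrays (D, H, W, C, N).  Each module instance is used exactly once per
# forward pass, so activations needed by the backward pass are cached in the
# module environment.

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e
}

zero_grads <- function(mod) {
  mod$grads <- lapply(mod$params, function(p) array(0, dim(p) %||% length(p)))
  invisible(mod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

he_sd <- function(fan_in) sqrt(2 / fan_in)

# 3D convolution, stride 1, "same" padding for odd kernels.
nn_conv3d <- function(cin, cout, k = 3L, pad = k %/% 2L, init_sd = NULL) {
  m <- new_module("conv3d")
  if (cout < 1) stop("out_channels must be positive")
  m$k <- as.integer(k); m$pad <- as.integer(pad)
  m$cin <- cin; m$cout <- cout
  sd0 <- init_sd %||% he_sd(k^3 * cin)
  m$params$W <- matrix(rnorm(k^3 * cin * cout, sd = sd0), k^3 * cin, cout)
  m$params$b <- numeric(cout)
  zero_grads(m)
  m$fwd <- function(x, training = TRUE) {
    m$cache <- list(x = x, dims = dim(x))
    cpp_conv3d_fw(x, dim(x), m$params$W, m$params$b, m$k, m$pad)
  }
  m$bwd <- function(dy) {
    r <- cpp_conv3d_bw(m$cache$x, m$cache$dims, m$params$W, dy, m$k, m$pad)
    m$grads$W <- m$grads$W + r$dW
    m$grads$b <- m$grads$b + as.numeric(r$db)
    r$dx
  }
  m
}

# Transposed convolution, kernel 2, stride 2 (doubles resolution).
nn_convt3d <- function(cin, cout) {
  m <- new_module("convt3d")
  m$cin <- cin; m$cout <- cout
  m$params$W <- matrix(rnorm(cin * 8 * cout, sd = he_sd(cin)), cin, 8 * cout)
  m$params$b <- numeric(cout)
  zero_grads(m)
  m$fwd <- function(x, training = TRUE) {
    m$cache <- list(x = x, dims = dim(x))
    cpp_convt3d_fw(x, dim(x), m$params$W, m$params$b)
  }
  m$bwd <- function(dy) {
    r <- cpp_convt3d_bw(m$cache$x, m$cache$dims, m$params$W, dy)
    m$grads$W <- m$grads$W + r$dW
    m$grads$b <- m$grads$b + as.numeric(r$db)
    r$dx
  }
  m
}

nn_maxpool <- function() {
  m <- new_module("maxpool")
  m$fwd <- function(x, training = TRUE) {
    r <- cpp_maxpool3d_fw(x, dim(x))
    m$cache <- list(idx = r$idx, xlen = length(x), xdim = dim(x))
    r$y
  }
  m$bwd <- function(dy) {
    dx <- cpp_maxpool3d_bw(dy, m$cache$idx, m$cache$xlen)
    dim(dx) <- m$cache$xdim
    dx
  }
  m
}

# Batch normalization over (D, H, W, N) per channel.
nn_bn3d <- function(c, eps = 1e-5, momentum = 0.1) {
  m <- new_module("bn3d")
  m$c <- c; m$eps <- eps; m$momentum <- momentum
  m$params$gamma <- rep(1, c)
  m$params$beta <- rep(0, c)
  m$buffers$running_mean <- rep(0, c)
  m$buffers$running_var <- rep(1, c)
  zero_grads(m)
  m$fwd <- function(x, training = TRUE) {
    d <- dim(x); C <- d[4]; N <- d[5]; rows <- prod(d[1:3])
    X <- matrix(x, nrow = rows)
    ch <- rep(seq_len(C), times = N)
    if (training) {
      cs <- colSums(X); cs2 <- colSums(X^2)
      tot <- rows * N
      mu <- rowSums(matrix(cs, nrow = C)) / tot
      var <- rowSums(matrix(cs2, nrow = C)) / tot - mu^2
      var <- pmax(var, 0)
      m$buffers$running_mean <- (1 - m$momentum) * m$buffers$running_mean +
        m$momentum * mu
      m$buffers$running_var <- (1 - m$momentum) * m$buffers$running_var +
        m$momentum * var * tot / max(1, tot - 1)
    } else {
      mu <- m$buffers$running_mean
      var <- m$buffers$running_var
    }
    inv <- 1 / sqrt(var + m$eps)
    xhat <- sweep(sweep(X, 2, mu[ch]), 2, inv[ch], `*`)
    Y <- sweep(sweep(xhat, 2, m$params$gamma[ch], `*`), 2,
               m$params$beta[ch], `+`)
    m$cache <- list(xhat = xhat, inv = inv, ch = ch, d = d,
                    training = training, tot = rows * N)
    array(Y, d)
  }
  m$bwd <- function(dy) {
    cc <- m$cache; d <- cc$d; ch <- cc$ch; C <- d[4]
    dY <- matrix(dy, nrow = prod(d[1:3]))
    m$grads$gamma <- m$grads$gamma +
      rowSums(matrix(colSums(dY * cc$xhat), nrow = C))
    m$grads$beta <- m$grads$beta + rowSums(matrix(colSums(dY), nrow = C))
    dxhat <- sweep(dY, 2, m$params$gamma[ch], `*`)
    if (cc$training) {
      s1 <- rowSums(matrix(colSums(dxhat), nrow = C)) / cc$tot
      s2 <- rowSums(matrix(colSums(dxhat * cc$xhat), nrow = C)) / cc$tot
      dX <- sweep(dxhat, 2, s1[ch]) - sweep(cc$xhat, 2, s2[ch], `*`)
      dX <- sweep(dX, 2, cc$inv[ch], `*`)
    } else {
      dX <- sweep(dxhat, 2, cc$inv[ch], `*`)
    }
    array(dX, d)
  }
  m
}

# ConvBlock: 3x3x3 convolution -> batch norm -> ReLU.
nn_conv_block <- function(cin, cout, k = 3L) {
  m <- new_module("conv_block")
  m$conv <- nn_conv3d(cin, cout, k = k)
  m$bn <- nn_bn3d(cout)
  m$children <- list(conv = m$conv, bn = m$bn)
  m$fwd <- function(x, training = TRUE) {
    y <- m$bn$fwd(m$conv$fwd(x, training), training)
    m$cache <- list(mask = y > 0)
    y * m$cache$mask
  }
  m$bwd <- function(dy) {
    m$conv$bwd(m$bn$bwd(dy * m$cache$mask))
  }
  m
}

# Walk a module tree collecting leaf modules that own parameters.
leaf_modules <- function(mod, prefix = "") {
  if (!is.null(mod$children)) {
    out <- list()
    for (nm in names(mod$children))
      out <- c(out, leaf_modules(mod$children[[nm]],
                                 paste0(prefix, nm, ".")))
    return(out)
  }
  if (length(mod$params)) setNames(list(mod), sub("\\.$", "", prefix))
  else list()
}
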