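# Shared fixture builders for the test suite.

# Phantom configuration that fits a 32^3 grid (used by training tests).
tiny_phantom_config <- function(...) {
  phantom_config(grid_shape = c(32L, 32L, 32L), organ_axes = c(8, 6, 6),
                 n_distractors = 0L, ...)
}

# A very small network configuration for fast forward/backward tests.
micro_model_config <- function(...) {
  defaults <- list(in_channels = 2L, base_channels = 2L, n_stages = 4L,
                   transformer_stages = 4L, token_dim = 8L, n_heads = 2L,
                   cbam_reduction = 2L, spatial_attn_kernel = 3L,
                   branch_split_after = 1L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Random binary mask with roughly `p` foreground fraction.
random_mask <- function(dims, p = 0.3) {
  array(runif(prod(dims)) < p, dims)
}

# Reference flood-fill component labelling (26-connectivity), written
# independently of the package's C++ implementation.
ref_cc_label <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    queue <- integer(sum(mask))
    queue[1] <- v
    qlen <- 1L; qpos <- 0L
    lab[v] <- cur
    while (qpos < qlen) {
      qpos <- qpos + 1L
      uc <- arrayInd(queue[qpos], d)
      for (r in seq_len(nrow(nbr))) {
        w <- uc + nbr[r, ]
        if (any(w < 1) || any(w > d)) next
        wi <- w[1] + d[1] * (w[2] - 1) + d[1] * d[2] * (w[3] - 1)
        if (mask[wi] && lab[wi] == 0L) {
          lab[wi] <- cur
          qlen <- qlen + 1L
          queue[qlen] <- wi
        }
      }
    }
  }
  lab
}

# Brute-force surface extraction + directed distances for HD95 oracles.
ref_surface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (v in which(mask)) {
    uc <- arrayInd(v, d)
    onb <- FALSE
    for (a in 1:3) for (s in c(-1, 1)) {
      w <- uc; w[a] <- w[a] + s
      if (any(w < 1) || any(w > d)) { onb <- TRUE; break }
      wi <- w[1] + d[1] * (w[2] - 1) + d[1] * d[2] * (w[3] - 1)
      if (!mask[wi]) { onb <- TRUE; break }
    }
    out[v] <- onb
  }
  out
}

ref_hd <- function(a, b, spacing, percentile = 0.95) {
  A <- which(ref_surface(a), arr.ind = TRUE)
  B <- which(ref_surface(b), arr.ind = TRUE)
  A <- sweep(A - 1, 2, spacing, `*`)
  B <- sweep(B - 1, 2, spacing, `*`)
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
                Vectorize(function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))))
  pooled <- sort(c(apply(dmat, 1, min), apply(dmat, 2, min)))
  pooled[max(1L, ceiling(percentile * length(pooled)))]
}
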