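#' Network architecture configuration
#'
#' Every architectural degree of freedom of the dual-branch segmentation
#' network. The encoder has `n_stages` stages whose channel counts follow the
#' schedule `base_channels * 2^(l-1)`; a pre-norm transformer can be placed at
#' any of the deeper stages; CBAM gates the skip connections; the decoder
#' splits into a whole-hippocampus branch and a subfield branch after
#' `branch_split_after` up-samplings, coupled by residual addition from the
#' hippocampus branch into the subfield branch.
#'
#' @param in_channels number of input modalities (2 = T1w + T2w).
#' @param base_channels encoder channels at stage 1.
#' @param n_stages number of encoder stages (resolution halves per stage).
#' @param n_classes_subfield classes of the subfield branch (background +
#'   CA1-3 + CA4/DG + SUB).
#' @param n_classes_binary classes of the whole-hippocampus branch.
#' @param cbam_enabled gate skip connections with CBAM; off means direct
#'   skip connections.
#' @param transformer_stages integer vector of encoder stages that receive a
#'   transformer (default bottleneck only); empty vector disables it.
#' @param transformer_blocks transformer blocks per stage.
#' @param n_heads attention heads.
#' @param token_dim token embedding width; must be divisible by `n_heads`.
#' @param dual_branch build both decoder branches; off builds the subfield
#'   branch only.
#' @param branch_split_after decoder up-samplings before the branch split.
#' @param spatial_attn_kernel kernel size of the CBAM spatial-attention
#'   convolution.
#' @param cbam_reduction channel-MLP reduction ratio inside CBAM.
#' @return a `dsnet_model_config` list.
#' @export
model_config <- function(in_channels = 2L, base_channels = 16L,
                         n_stages = 5L, n_classes_subfield = 4L,
                         n_classes_binary = 2L, cbam_enabled = TRUE,
                         transformer_stages = 5L, transformer_blocks = 1L,
                         n_heads = 8L, token_dim = 512L, dual_branch = TRUE,
                         branch_split_after = 2L, spatial_attn_kernel = 7L,
                         cbam_reduction = 16L) {
  cfg <- list(in_channels = as.integer(in_channels),
              base_channels = as.integer(base_channels),
              n_stages = as.integer(n_stages),
              n_classes_subfield = as.integer(n_classes_subfield),
              n_classes_binary = as.integer(n_classes_binary),
              cbam_enabled = isTRUE(cbam_enabled),
              transformer_stages = as.integer(transformer_stages),
              transformer_blocks = as.integer(transformer_blocks),
              n_heads = as.integer(n_heads),
              token_dim = as.integer(token_dim),
              dual_branch = isTRUE(dual_branch),
              branch_split_after = as.integer(branch_split_after),
              spatial_attn_kernel = as.integer(spatial_attn_kernel),
              cbam_reduction = as.integer(cbam_reduction))
  if (cfg$token_dim %% cfg$n_heads != 0)
    stop("token_dim must be divisible by n_heads")
  if (cfg$branch_split_after >= cfg$n_stages - 1)
    stop("branch_split_after must be < n_stages - 1")
  if (length(cfg$transformer_stages) &&
      any(cfg$transformer_stages < 2 | cfg$transformer_stages > cfg$n_stages))
    stop("transformer_stages must lie in 2..n_stages")
  class(cfg) <- "dsnet_model_config"
  cfg
}

stage_channels <- function(cfg)
  as.integer(cfg$base_channels * 2^(seq_len(cfg$n_stages) - 1L))

#' Build the dual-branch segmentation network
#'
#' Instantiates all network parameters for a fixed patch size (the positional
#' table of each transformer stage is tied to the token count of that stage).
#' Weight initialization draws from the current R random number generator:
#' call `set.seed()` first for reproducible builds.
#'
#' @param cfg a [model_config()].
#' @param patch_size integer length 1 or 3; input patch dimensions, divisible
#'   by `2^(n_stages - 1)`.
#' @return a `dsnet_model` object.
#' @export
dsnet_model <- function(cfg = model_config(), patch_size = 128L) {
  patch <- as.integer(if (length(patch_size) == 1) rep(patch_size, 3)
                      else patch_size)
  div <- 2L^(cfg$n_stages - 1L)
  bad <- which(patch %% div != 0)
  if (length(bad))
    stop("patch axis ", paste(c("D", "H", "W")[bad], collapse = ","),
         " not divisible by ", div)
  ch <- stage_channels(cfg)
  S <- cfg$n_stages
  mod <- list()
  ins <- c(cfg$in_channels, ch[-S])
  for (l in seq_len(S)) {
    mod[[paste0("enc", l)]] <- nn_conv_block(ins[l], ch[l])
    if (l < S) mod[[paste0("pool", l)]] <- nn_maxpool()
  }
  for (l in cfg$transformer_stages) {
    sp <- patch %/% 2L^(l - 1L)
    if (any(sp < 1)) stop("transformer requested at stage ", l,
                          " where the map has <1 voxel")
    mod[[paste0("tf", l)]] <- nn_transformer(ch[l], cfg$token_dim, prod(sp),
                                             cfg$transformer_blocks,
                                             cfg$n_heads, sp)
  }
  if (cfg$cbam_enabled)
    for (l in seq_len(S - 1))
      mod[[paste0("cbam", l)]] <- nn_cbam(ch[l], cfg$cbam_reduction,
                                          cfg$spatial_attn_kernel)
  n_pre <- cfg$branch_split_after
  pre_stages <- seq(S - 1, S - n_pre)            # decoder stages before split
  post_stages <- seq(S - n_pre - 1, 1)           # after split
  for (l in pre_stages) {
    mod[[paste0("up", l)]] <- nn_convt3d(ch[l + 1], ch[l])
    mod[[paste0("dec", l)]] <- nn_conv_block(2 * ch[l], ch[l])
  }
  branches <- if (cfg$dual_branch) c("sub", "hip") else "sub"
  for (b in branches) for (l in post_stages) {
    mod[[paste0("up_", b, l)]] <- nn_convt3d(ch[l + 1], ch[l])
    mod[[paste0("dec_", b, l)]] <- nn_conv_block(2 * ch[l], ch[l])
  }
  mod[["head_sub"]] <- nn_conv3d(ch[1], cfg$n_classes_subfield, k = 1L,
                                 pad = 0L)
  if (cfg$dual_branch)
    mod[["head_bin"]] <- nn_conv3d(ch[1], cfg$n_classes_binary, k = 1L,
                                   pad = 0L)
  structure(list(cfg = cfg, patch = patch, modules = mod,
                 pre_stages = pre_stages, post_stages = post_stages),
            class = "dsnet_model")
}

model_leaves <- function(model) {
  out <- list()
  for (nm in names(model$modules))
    out <- c(out, leaf_modules(model$modules[[nm]], paste0(nm, ".")))
  out
}

#' @export
print.dsnet_model <- function(x, ...) {
  cat(sprintf("<dsnet_model> %d stages, base %d, patch %s, %s parameters\n",
              x$cfg$n_stages, x$cfg$base_channels,
              paste(x$patch, collapse = "x"),
              format(n_parameters(x), big.mark = ",")))
  cat(sprintf("  transformer at {%s}, CBAM %s, %s\n",
              paste(x$cfg$transformer_stages, collapse = ","),
              if (x$cfg$cbam_enabled) "on" else "off",
              if (x$cfg$dual_branch) "dual branch" else "single branch"))
  invisible(x)
}

#' @rdname dsnet_model
#' @param model a `dsnet_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model_leaves(model),
             function(m) sum(vapply(m$params, length, 0L)), 0))
}

#' Forward pass of the network
#'
#' @param model a [dsnet_model()].
#' @param x input array (D, H, W, C, N) or (D, H, W, C); spatial dims must be
#'   divisible by `2^(n_stages - 1)`.
#' @param training use batch statistics in batch norm (TRUE) or running
#'   statistics (FALSE).
#' @return list with `subfield` logits (D, H, W, n_classes_subfield, N) and,
#'   for dual-branch models, `binary` logits (D, H, W, n_classes_binary, N).
#' @export
dsnet_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  cfg <- model$cfg; S <- cfg$n_stages; md <- model$modules
  div <- 2L^(S - 1L)
  bad <- which(dim(x)[1:3] %% div != 0)
  if (length(bad))
    stop("input axis ", paste(c("D", "H", "W")[bad], collapse = ","),
         " not divisible by ", div)
  feats <- vector("list", S)
  cur <- x
  for (l in seq_len(S)) {
    cur <- md[[paste0("enc", l)]]$fwd(cur, training)
    if (l %in% cfg$transformer_stages)
      cur <- md[[paste0("tf", l)]]$fwd(cur, training)
    feats[[l]] <- cur
    if (l < S) cur <- md[[paste0("pool", l)]]$fwd(cur, training)
  }
  skips <- vector("list", S - 1)
  for (l in seq_len(S - 1))
    skips[[l]] <- if (cfg$cbam_enabled)
      md[[paste0("cbam", l)]]$fwd(feats[[l]], training) else feats[[l]]
  cur <- feats[[S]]
  for (l in model$pre_stages) {
    up <- md[[paste0("up", l)]]$fwd(cur, training)
    cur <- md[[paste0("dec", l)]]$fwd(cat_channels(up, skips[[l]]), training)
  }
  sub_cur <- cur; hip_cur <- cur
  for (l in model$post_stages) {
    up_s <- md[[paste0("up_sub", l)]]$fwd(sub_cur, training)
    cat_s <- cat_channels(up_s, skips[[l]])
    if (cfg$dual_branch) {
      up_h <- md[[paste0("up_hip", l)]]$fwd(hip_cur, training)
      cat_h <- cat_channels(up_h, skips[[l]])
      sub_in <- cat_s + cat_h      # residual fusion, hippocampus -> subfield
      hip_cur <- md[[paste0("dec_hip", l)]]$fwd(cat_h, training)
    } else {
      sub_in <- cat_s
    }
    sub_cur <- md[[paste0("dec_sub", l)]]$fwd(sub_in, training)
  }
  out <- list(subfield = md[["head_sub"]]$fwd(sub_cur, training))
  if (cfg$dual_branch)
    out$binary <- md[["head_bin"]]$fwd(hip_cur, training)
  out
}

# Backward pass; accumulates parameter gradients and returns d(input).
dsnet_backward <- function(model, d_subfield, d_binary = NULL) {
  cfg <- model$cfg; S <- cfg$n_stages; md <- model$modules
  d_sub_cur <- md[["head_sub"]]$bwd(d_subfield)
  d_hip_cur <- if (cfg$dual_branch) md[["head_bin"]]$bwd(d_binary) else NULL
  d_skips <- vector("list", S - 1)
  for (l in rev(model$post_stages)) {    # ascending stage order
    d_sub_in <- md[[paste0("dec_sub", l)]]$bwd(d_sub_cur)
    d_cat_s <- d_sub_in
    if (cfg$dual_branch) {
      d_cat_h <- md[[paste0("dec_hip", l)]]$bwd(d_hip_cur) + d_sub_in
      ch_up <- dim(d_cat_h)[4] / 2
      d_skips[[l]] <- add_maybe(d_skips[[l]],
                                slice_channels(d_cat_h, ch_up + 1,
                                               2 * ch_up))
      d_hip_cur <- md[[paste0("up_hip", l)]]$bwd(
        slice_channels(d_cat_h, 1, ch_up))
    }
    ch_up <- dim(d_cat_s)[4] / 2
    d_skips[[l]] <- add_maybe(d_skips[[l]],
                              slice_channels(d_cat_s, ch_up + 1, 2 * ch_up))
    d_sub_cur <- md[[paste0("up_sub", l)]]$bwd(slice_channels(d_cat_s, 1,
                                                              ch_up))
  }
  d_cur <- if (cfg$dual_branch) d_sub_cur + d_hip_cur else d_sub_cur
  for (l in rev(model$pre_stages)) {
    d_cat <- md[[paste0("dec", l)]]$bwd(d_cur)
    ch_up <- dim(d_cat)[4] / 2
    d_skips[[l]] <- add_maybe(d_skips[[l]],
                              slice_channels(d_cat, ch_up + 1, 2 * ch_up))
    d_cur <- md[[paste0("up", l)]]$bwd(slice_channels(d_cat, 1, ch_up))
  }
  d_feats <- vector("list", S)
  d_feats[[S]] <- d_cur
  for (l in seq_len(S - 1))
    d_feats[[l]] <- if (cfg$cbam_enabled)
      md[[paste0("cbam", l)]]$bwd(d_skips[[l]]) else d_skips[[l]]
  for (l in rev(seq_len(S))) {
    d <- d_feats[[l]]
    if (l %in% cfg$transformer_stages)
      d <- md[[paste0("tf", l)]]$bwd(d)
    d_in <- md[[paste0("enc", l)]]$bwd(d)
    if (l > 1)
      d_feats[[l - 1]] <- d_feats[[l - 1]] +
        md[[paste0("pool", l - 1)]]$bwd(d_in)
    else return(d_in)
  }
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

slice_channels <- function(x, from, to) {
  x[, , , from:to, , drop = FALSE]
}

add_maybe <- function(a, b) if (is.null(a)) b else a + b

# --- parameter bookkeeping ------------------------------------------------

model_zero_grads <- function(model) {
  for (m in model_leaves(model)) zero_grads(m)
  invisible(model)
}

#' Snapshot or restore all model parameters
#'
#' `model_state()` returns a deep copy of every parameter and batch-norm
#' buffer; `load_model_state()` writes one back into a model of identical
#' architecture. Used for checkpointing and checkpoint averaging.
#'
#' @param model a `dsnet_model`.
#' @return named list of numeric arrays.
#' @export
model_state <- function(model) {
  lv <- model_leaves(model)
  st <- list()
  for (nm in names(lv)) {
    for (pn in names(lv[[nm]]$params))
      st[[paste0(nm, "::", pn)]] <- lv[[nm]]$params[[pn]]
    for (bn in names(lv[[nm]]$buffers))
      st[[paste0(nm, "::buf::", bn)]] <- lv[[nm]]$buffers[[bn]]
  }
  st
}

#' @rdname model_state
#' @param state a list produced by `model_state()`.
#' @export
load_model_state <- function(model, state) {
  lv <- model_leaves(model)
  for (key in names(state)) {
    parts <- strsplit(key, "::", fixed = TRUE)[[1]]
    if (length(parts) == 3) lv[[parts[1]]]$buffers[[parts[3]]] <- state[[key]]
    else lv[[parts[1]]]$params[[parts[2]]] <- state[[key]]
  }
  invisible(model)
}

# Adam with L2 weight decay folded into the gradient.
adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (m in model_leaves(model)) {
    if (is.null(m$adam_m)) {
      m$adam_m <- lapply(m$params, function(p) p * 0)
      m$adam_v <- lapply(m$params, function(p) p * 0)
      m$adam_t <- 0L
    }
    m$adam_t <- m$adam_t + 1L
    t <- m$adam_t
    for (pn in names(m$params)) {
      g <- m$grads[[pn]] + weight_decay * m$params[[pn]]
      m$adam_m[[pn]] <- beta1 * m$adam_m[[pn]] + (1 - beta1) * g
      m$adam_v[[pn]] <- beta2 * m$adam_v[[pn]] + (1 - beta2) * g^2
      mhat <- m$adam_m[[pn]] / (1 - beta1^t)
      vhat <- m$adam_v[[pn]] / (1 - beta2^t)
      m$params[[pn]] <- m$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(model)
}
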