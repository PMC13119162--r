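# Low-level layer operations for the multimodal regression network.
# Images follow the R array layout H x W x C x N; convolutions are "valid"
# 3x3 cross-correlations, pooling is 2x2/stride-2 with argmax routing.

conv_fwd <- function(x, w, b) .conv2d_forward_cpp(x, w, b)
conv_bwd <- function(x, w, dy) .conv2d_backward_cpp(x, w, dy)
pool_fwd <- function(x) .maxpool2_forward_cpp(x)
pool_bwd <- function(dy, idx, dim_in) {
  .maxpool2_backward_cpp(dy, idx, as.integer(dim_in))
}

relu <- function(x) pmax(x, 0)

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv <- function(k, c_in, f) {
  list(w = glorot_uniform(c(k, k, c_in, f), k * k * c_in, k * k * f),
       b = numeric(f))
}

init_dense <- function(d_in, d_out) {
  list(w = glorot_uniform(c(d_in, d_out), d_in, d_out), b = numeric(d_out))
}

# spatial side length after `depth` conv(3x3 valid) + pool(2x2) blocks
conv_out_size <- function(size, depth) {
  for (i in seq_len(depth)) size <- (size - 2) %/% 2
  size
}

init_image_branch <- function(filters, c_in = 3) {
  list(c1 = init_conv(3, c_in, filters[1]),
       c2 = init_conv(3, filters[1], filters[2]),
       c3 = init_conv(3, filters[2], filters[3]))
}

image_branch_forward <- function(x, p) {
  z1 <- conv_fwd(x, p$c1$w, p$c1$b); a1 <- relu(z1); pl1 <- pool_fwd(a1)
  z2 <- conv_fwd(pl1$out, p$c2$w, p$c2$b); a2 <- relu(z2); pl2 <- pool_fwd(a2)
  z3 <- conv_fwd(pl2$out, p$c3$w, p$c3$b); a3 <- relu(z3); pl3 <- pool_fwd(a3)
  n <- dim(x)[4]
  list(flat = t(matrix(pl3$out, ncol = n)),
       cache = list(x = x, z1 = z1, pl1 = pl1, z2 = z2, pl2 = pl2,
                    z3 = z3, a3 = a3, pl3 = pl3))
}

# Backward through one image branch. Returns parameter gradients and the
# gradient with respect to the final conv layer's post-ReLU activations
# (`dact3`), which is what Grad-CAM pools.
image_branch_backward <- function(dflat, p, cache, grads_only = TRUE) {
  dp3 <- array(t(dflat), dim(cache$pl3$out))
  dact3 <- pool_bwd(dp3, cache$pl3$idx, dim(cache$a3))
  dz3 <- dact3 * (cache$z3 > 0)
  g3 <- conv_bwd(cache$pl2$out, p$c3$w, dz3)
  dact2 <- pool_bwd(g3$dx, cache$pl2$idx, dim(cache$z2))
  dz2 <- dact2 * (cache$z2 > 0)
  g2 <- conv_bwd(cache$pl1$out, p$c2$w, dz2)
  dact1 <- pool_bwd(g2$dx, cache$pl1$idx, dim(cache$z1))
  dz1 <- dact1 * (cache$z1 > 0)
  g1 <- conv_bwd(cache$x, p$c1$w, dz1)
  list(grads = list(c1 = list(w = g1$dw, b = g1$db),
                    c2 = list(w = g2$dw, b = g2$db),
                    c3 = list(w = g3$dw, b = g3$db)),
       dact3 = dact3)
}

time_branch_forward <- function(x, p) {
  z <- conv_fwd(x, p$c$w, p$c$b); a <- relu(z); pl <- pool_fwd(a)
  n <- dim(x)[4]
  list(flat = t(matrix(pl$out, ncol = n)),
       cache = list(x = x, z = z, pl = pl))
}

time_branch_backward <- function(dflat, p, cache) {
  dp <- array(t(dflat), dim(cache$pl$out))
  da <- pool_bwd(dp, cache$pl$idx, dim(cache$z))
  dz <- da * (cache$z > 0)
  g <- conv_bwd(cache$x, p$c$w, dz)
  list(grads = list(c = list(w = g$dw, b = g$db)))
}

add_bias <- function(z, b) z + rep(b, each = nrow(z))

head_forward <- function(feats, p) {
  h1 <- relu(add_bias(feats %*% p$d1$w, p$d1$b))
  h2 <- relu(add_bias(h1 %*% p$d2$w, p$d2$b))
  y <- add_bias(h2 %*% p$d3$w, p$d3$b)
  list(y = drop(y), cache = list(feats = feats, h1 = h1, h2 = h2))
}

head_backward <- function(dy, p, cache) {
  dy <- matrix(dy, ncol = 1)
  g3 <- list(w = crossprod(cache$h2, dy), b = colSums(dy))
  dh2 <- (dy %*% t(p$d3$w)) * (cache$h2 > 0)
  g2 <- list(w = crossprod(cache$h1, dh2), b = colSums(dh2))
  dh1 <- (dh2 %*% t(p$d2$w)) * (cache$h1 > 0)
  g1 <- list(w = crossprod(cache$feats, dh1), b = colSums(dh1))
  dfeats <- dh1 %*% t(p$d1$w)
  list(grads = list(d1 = g1, d2 = g2, d3 = g3), dfeats = dfeats)
}

# ---- Adam over nested parameter trees --------------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else array(0, dim(p) %||% length(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_init <- function(params) list(m = zeros_like(params),
                                   v = zeros_like(params), t = 0)

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  state$t <- state$t + 1
  t <- state$t
  step <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]  # trees may differ in order
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      step(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
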