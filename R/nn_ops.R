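# Internal neural-net primitives shared by the reconstruction network and
# the U-Net: thin wrappers over the Rcpp im2col/GEMM kernels plus Adam.
# Activations are H x W x C arrays; weights are (K*K*Cin) x Cout matrices
# with column index q = ki + K*kj + K*K*c (0-based).

as_chw <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

conv_fwd <- function(x, w, b, K) {
  nt_conv2d_fwd(as_chw(x), w, b, K)
}

conv_bwd <- function(x, w, gy, K) {
  nt_conv2d_bwd(as_chw(x), w, as_chw(gy), K)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

zeros_like_hw <- function(H, W, C) array(0, dim = c(H, W, C))

# He-style initialization for a conv weight of given shape
init_conv_w <- function(K, cin, cout, scale = 1) {
  matrix(stats::rnorm(K * K * cin * cout, sd = scale * sqrt(2 / (K * K * cin))),
         K * K * cin, cout)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# complex matrix <-> two-channel real array
cplx_to_ch <- function(z) {
  a <- array(0, dim = c(dim(z), 2L))
  a[, , 1] <- Re(z)
  a[, , 2] <- Im(z)
  a
}

ch_to_cplx <- function(a) {
  matrix(complex(real = a[, , 1], imaginary = a[, , 2]),
         dim(a)[1], dim(a)[2])
}
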