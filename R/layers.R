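# Internal layer primitives shared by the network module.
# Tensor layout: [H, W, C, N] arrays, values double.

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(x, dy) {
  dy[x <= 0] <- 0
  dy
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# He-normal initialization for a convolution weight array; the last dim is
# the output-channel dim, fan-in is everything else.
init_conv <- function(dims) {
  fan_in <- prod(dims[-length(dims)])
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim_or_len(p))),
       v = lapply(params, function(p) array(0, dim = dim_or_len(p))))
}

dim_or_len <- function(p) if (is.null(dim(p))) length(p) else dim(p)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
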