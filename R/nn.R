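# Minimal neural-network primitives shared by the contact predictor and the
# graph encoder: parameter initialization, row-softmax with its backward
# pass, and an Adam optimizer over named parameter lists. All gradients in
# this package are analytic and are verified against numerical
# differentiation in the test suite.

rmat <- function(nr, nc, sd = 0.1) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

softmaxRows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Backward of row-wise softmax: alpha is the forward output.
softmaxRowsBackward <- function(alpha, dalpha) {
  alpha * (dalpha - rowSums(dalpha * alpha))
}

# Row-softmax over entries where mask is TRUE; masked entries get weight 0.
maskedSoftmaxRows <- function(x, mask) {
  x[!mask] <- -Inf
  a <- softmaxRows(x)
  a[!mask] <- 0
  a
}

relu <- function(x) pmax(x, 0)

leakyRelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

dLeakyRelu <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# Numerically stable log(1 + exp(x)).
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

zerosLike <- function(params) lapply(params, function(p) p * 0)

addGrads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scaleGrads <- function(g, s) lapply(g, function(p) p * s)

adamInit <- function(params) {
  list(m = zerosLike(params), v = zerosLike(params), t = 0L)
}

# One Adam update; parameters named in `frozen` are left untouched (their
# optimizer state is not advanced either, so freezing is exact).
adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, frozen = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# proximal operator of the L1 penalty (soft-thresholding)
softThreshold <- function(w, thr) sign(w) * pmax(abs(w) - thr, 0)

# Weighted binary cross-entropy with logits. Returns loss and d(loss)/d(logit).
# Positive examples carry weight posWeight; the loss is normalized by the
# total weight so setting posWeight = 1 recovers plain mean BCE.
bceWithLogits <- function(logits, y, posWeight = 1) {
  w <- ifelse(y == 1, posWeight, 1)
  per <- y * softplus(-logits) + (1 - y) * softplus(logits)
  sw <- sum(w)
  loss <- sum(w * per) / sw
  grad <- w * (logistic(logits) - y) / sw
  list(loss = loss, grad = grad)
}
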