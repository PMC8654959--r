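## Internal neural-network engine: 1-D valid convolutions via im2col + BLAS
## matrix products, ReLU, inverted dropout, softmax cross-entropy with an L2
## penalty, and Adam.  All randomness comes from R's RNG so seeded runs are
## bit-reproducible.

.REP_WIDTHS <- c(BPF = 20L, PHYSCHEM = 31L, BLO62 = 20L)

## [n, P, ch] array -> [n*Pout, kl*ch] patch matrix (row index i + (p-1)*n)
.im2col <- function(A, kl) {
  dm <- dim(A); n <- dm[1]; P <- dm[2]; ch <- dm[3]
  Pout <- P - kl + 1L
  M <- matrix(0, n * Pout, kl * ch)
  for (j in seq_len(kl))
    M[, ((j - 1L) * ch + 1L):(j * ch)] <-
      matrix(A[, j:(j + Pout - 1L), , drop = FALSE], n * Pout, ch)
  M
}

## adjoint of .im2col: scatter-add patch gradients back onto the input grid
.col2im <- function(dM, kl, n, P, ch) {
  Pout <- P - kl + 1L
  dA <- array(0, c(n, P, ch))
  for (j in seq_len(kl)) {
    block <- array(dM[, ((j - 1L) * ch + 1L):(j * ch), drop = FALSE],
                   c(n, Pout, ch))
    dA[, j:(j + Pout - 1L), ] <- dA[, j:(j + Pout - 1L), ] + block
  }
  dA
}

.glorot <- function(nin, nout, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

## per-branch output positions after the two valid stride-1 convolutions
.branchDims <- function(cfg) {
  lapply(setNames(cfg@combination, cfg@combination), function(r) {
    g <- cfg@groups[[r]]
    d <- .REP_WIDTHS[[r]]
    P1 <- cfg@k - g@conv1Kernel + 1L
    P2 <- P1 - g@conv2Kernel + 1L
    if (P2 < 1L)
      .configError(sprintf("%s branch: kernels exhaust the %d input rows", r,
                           cfg@k))
    list(d = d, P1 = P1, P2 = P2, flat = P2 * g@conv2Filters)
  })
}

.initParams <- function(cfg) {
  dims <- .branchDims(cfg)
  groups <- lapply(setNames(cfg@combination, cfg@combination), function(r) {
    g <- cfg@groups[[r]]
    d <- dims[[r]]$d
    list(conv1 = list(W = .glorot(g@conv1Kernel * d, g@conv1Filters,
                                  g@conv1Kernel * d,
                                  g@conv1Kernel * g@conv1Filters),
                      b = numeric(g@conv1Filters)),
         conv2 = list(W = .glorot(g@conv2Kernel * g@conv1Filters,
                                  g@conv2Filters,
                                  g@conv2Kernel * g@conv1Filters,
                                  g@conv2Kernel * g@conv2Filters),
                      b = numeric(g@conv2Filters)))
  })
  nin <- sum(vapply(dims, function(x) x$flat, 1L))
  dense <- list()
  for (j in seq_along(cfg@denseLayers)) {
    u <- cfg@denseLayers[[j]]$units
    dense[[j]] <- list(W = .glorot(nin, u, nin, u), b = numeric(u))
    nin <- u
  }
  out <- list(W = .glorot(nin, 2L, nin, 2L), b = numeric(2L))
  list(groups = groups, dense = dense, out = out)
}

.dropoutMask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

## forward pass; training = TRUE draws dropout masks (kept in the cache)
.forwardPass <- function(params, cfg, stacks, training = FALSE) {
  dims <- .branchDims(cfg)
  n <- dim(stacks[[cfg@combination[1]]])[1]
  flats <- list(); gcache <- list()
  for (r in cfg@combination) {
    g <- cfg@groups[[r]]; dd <- dims[[r]]
    pg <- params$groups[[r]]
    M1 <- .im2col(stacks[[r]], g@conv1Kernel)
    Z1 <- M1 %*% pg$conv1$W
    Z1 <- Z1 + rep(pg$conv1$b, each = nrow(Z1))
    A1 <- pmax(Z1, 0)
    mask1 <- if (training) .dropoutMask(nrow(A1), ncol(A1), g@conv1Dropout)
    if (!is.null(mask1)) A1 <- A1 * mask1
    M2 <- .im2col(array(A1, c(n, dd$P1, g@conv1Filters)), g@conv2Kernel)
    Z2 <- M2 %*% pg$conv2$W
    Z2 <- Z2 + rep(pg$conv2$b, each = nrow(Z2))
    A2 <- pmax(Z2, 0)
    mask2 <- if (training) .dropoutMask(nrow(A2), ncol(A2), g@conv2Dropout)
    if (!is.null(mask2)) A2 <- A2 * mask2
    flats[[r]] <- matrix(array(A2, c(n, dd$P2, g@conv2Filters)), n, dd$flat)
    gcache[[r]] <- list(M1 = M1, Z1 = Z1, mask1 = mask1,
                        M2 = M2, Z2 = Z2, mask2 = mask2)
  }
  H <- do.call(cbind, flats[cfg@combination])
  dcache <- list()
  for (j in seq_along(params$dense)) {
    Hin <- H
    Zd <- H %*% params$dense[[j]]$W
    Zd <- Zd + rep(params$dense[[j]]$b, each = nrow(Zd))
    A <- pmax(Zd, 0)
    maskd <- if (training)
      .dropoutMask(nrow(A), ncol(A), cfg@denseLayers[[j]]$dropout)
    if (!is.null(maskd)) A <- A * maskd
    dcache[[j]] <- list(Hin = Hin, Zd = Zd, maskd = maskd)
    H <- A
  }
  logits <- H %*% params$out$W
  logits <- logits + rep(params$out$b, each = nrow(logits))
  ex <- exp(logits - apply(logits, 1L, max))
  probs <- ex / rowSums(ex)
  list(probs = probs,
       cache = list(groups = gcache, dense = dcache, Hout = H, n = n))
}

.sumSquares <- function(params) {
  s <- 0
  for (r in names(params$groups))
    s <- s + sum(params$groups[[r]]$conv1$W^2) +
      sum(params$groups[[r]]$conv2$W^2)
  for (d in params$dense) s <- s + sum(d$W^2)
  s + sum(params$out$W^2)
}

.lossFromProbs <- function(probs, y, params, l2) {
  eps <- 1e-12
  ce <- -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], eps)))
  ce + l2 * .sumSquares(params)
}

.backwardPass <- function(params, cfg, fwd, y, l2) {
  n <- fwd$cache$n
  probs <- fwd$probs
  Y <- matrix(0, n, 2L)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  dlog <- (probs - Y) / n

  grads <- params  # same shape; values overwritten below
  grads$out$W <- crossprod(fwd$cache$Hout, dlog) + 2 * l2 * params$out$W
  grads$out$b <- colSums(dlog)
  dH <- tcrossprod(dlog, params$out$W)

  for (j in rev(seq_along(params$dense))) {
    dc <- fwd$cache$dense[[j]]
    dA <- if (!is.null(dc$maskd)) dH * dc$maskd else dH
    dZ <- dA * (dc$Zd > 0)
    grads$dense[[j]]$W <- crossprod(dc$Hin, dZ) + 2 * l2 * params$dense[[j]]$W
    grads$dense[[j]]$b <- colSums(dZ)
    dH <- tcrossprod(dZ, params$dense[[j]]$W)
  }

  dims <- .branchDims(cfg)
  offset <- 0L
  for (r in cfg@combination) {
    g <- cfg@groups[[r]]; dd <- dims[[r]]; gc <- fwd$cache$groups[[r]]
    dFlat <- dH[, (offset + 1L):(offset + dd$flat), drop = FALSE]
    offset <- offset + dd$flat
    dA2 <- matrix(array(dFlat, c(n, dd$P2, g@conv2Filters)),
                  n * dd$P2, g@conv2Filters)
    if (!is.null(gc$mask2)) dA2 <- dA2 * gc$mask2
    dZ2 <- dA2 * (gc$Z2 > 0)
    grads$groups[[r]]$conv2$W <- crossprod(gc$M2, dZ2) +
      2 * l2 * params$groups[[r]]$conv2$W
    grads$groups[[r]]$conv2$b <- colSums(dZ2)
    dM2 <- tcrossprod(dZ2, params$groups[[r]]$conv2$W)
    dArr1 <- .col2im(dM2, g@conv2Kernel, n, dd$P1, g@conv1Filters)
    dA1 <- matrix(dArr1, n * dd$P1, g@conv1Filters)
    if (!is.null(gc$mask1)) dA1 <- dA1 * gc$mask1
    dZ1 <- dA1 * (gc$Z1 > 0)
    grads$groups[[r]]$conv1$W <- crossprod(gc$M1, dZ1) +
      2 * l2 * params$groups[[r]]$conv1$W
    grads$groups[[r]]$conv1$b <- colSums(dZ1)
  }
  grads
}

## recursive Adam over the nested parameter list
.adamInit <- function(params) {
  walk <- function(x) if (is.list(x)) lapply(x, walk) else x * 0
  list(m = walk(params), v = walk(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (ii in seq_along(p)) {
        r <- upd(p[[ii]], g[[ii]], m[[ii]], v[[ii]])
        out$p[[ii]] <- r$p; out$m[[ii]] <- r$m; out$v[[ii]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
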