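## Internal neural-network primitives. Activations are 4D arrays
## [height, width, channel, batch]. Convolutions are evaluated as im2col +
## GEMM so the heavy lifting runs in BLAS; every layer has an explicit
## backward pass. No external deep-learning runtime is involved.

nnConvForward <- function(x, Wt, stride = 1L, pad = 1L) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(Wt)[1]; Cout <- dim(Wt)[4]
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  if (pad > 0L) {
    P <- array(0, c(Hp, Wp, C, N))
    P[pad + seq_len(H), pad + seq_len(Wd), , ] <- x
  } else P <- x
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oy <- (seq_len(Ho) - 1L) * stride
  ox <- (seq_len(Wo) - 1L) * stride
  oyg <- rep(oy, times = Wo); oxg <- rep(ox, each = Ho)
  idx <- matrix(0L, Ho * Wo, k * k)
  for (kx in seq_len(k)) for (ky in seq_len(k))
    idx[, ky + (kx - 1L) * k] <- (oxg + kx - 1L) * Hp + (oyg + ky)
  dim(P) <- c(Hp * Wp, C * N)
  cols <- P[as.vector(idx), , drop = FALSE]     # (pos*k2, C*N), pos fastest
  dim(cols) <- c(Ho * Wo, k * k, C, N)
  cols <- aperm(cols, c(1, 4, 2, 3))
  dim(cols) <- c(Ho * Wo * N, k * k * C)
  Wm <- Wt; dim(Wm) <- c(k * k * C, Cout)
  out <- cols %*% Wm
  dim(out) <- c(Ho * Wo, N, Cout)
  out <- aperm(out, c(1, 3, 2))
  dim(out) <- c(Ho, Wo, Cout, N)
  list(out = out,
       cache = list(cols = cols, idx = idx, Wt = Wt,
                    dims = c(H, Wd, C, N, Hp, Wp, Ho, Wo, k, stride, pad)))
}

nnConvBackward <- function(dout, cache) {
  dm <- cache$dims
  H <- dm[1]; Wd <- dm[2]; C <- dm[3]; N <- dm[4]; Hp <- dm[5]; Wp <- dm[6]
  Ho <- dm[7]; Wo <- dm[8]; k <- dm[9]; pad <- dm[11]
  Wt <- cache$Wt; Cout <- dim(Wt)[4]
  dim(dout) <- c(Ho * Wo, Cout, N)
  dout <- aperm(dout, c(1, 3, 2))
  dim(dout) <- c(Ho * Wo * N, Cout)
  dW <- crossprod(cache$cols, dout)
  dim(dW) <- dim(Wt)
  Wm <- Wt; dim(Wm) <- c(k * k * C, Cout)
  dcols <- tcrossprod(dout, Wm)                  # (pos*N, k2*C)
  dim(dcols) <- c(Ho * Wo, N, k * k, C)
  dcols <- aperm(dcols, c(1, 3, 4, 2))
  dim(dcols) <- c(Ho * Wo, k * k, C * N)
  dP <- matrix(0, Hp * Wp, C * N)
  idx <- cache$idx
  for (off in seq_len(k * k)) {   # offsets map injectively to padded pixels
    ii <- idx[, off]
    dP[ii, ] <- dP[ii, ] + dcols[, off, ]
  }
  dim(dP) <- c(Hp, Wp, C, N)
  dx <- if (pad > 0L)
    dP[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE] else dP
  dim(dx) <- c(H, Wd, C, N)
  list(dx = dx, dW = dW)
}

nnBNForward <- function(x, gamma, beta, run, momentum = 0.9, train = TRUE,
                        eps = 1e-5) {
  d <- dim(x); C <- d[3]; M <- d[1] * d[2] * d[4]
  xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(M, C)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = M)
    v <- colMeans(xc * xc)
    run$mu <- momentum * run$mu + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mu; v <- run$var
    xc <- xm - rep(mu, each = M)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = M)
  out <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(out) <- c(d[1], d[2], d[4], C)
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, run = run,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d))
}

nnBNBackward <- function(dout, cache) {
  d <- cache$d; C <- d[3]; M <- d[1] * d[2] * d[4]
  dm <- aperm(dout, c(1, 2, 4, 3)); dim(dm) <- c(M, C)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  g <- cache$gamma * cache$invstd
  dx <- (dm - rep(dbeta / M, each = M) - xhat * rep(dgamma / M, each = M)) *
    rep(g, each = M)
  dim(dx) <- c(d[1], d[2], d[4], C)
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nnReluForward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
nnReluBackward <- function(dout, mask) dout * mask

nnGapForward <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- colMeans(xm); dim(out) <- c(d[3], d[4])
  list(out = out, cache = d)
}
nnGapBackward <- function(dout, d) {
  dx <- rep(as.vector(dout) / (d[1] * d[2]), each = d[1] * d[2])
  dim(dx) <- d
  dx
}

nnDenseForward <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x, W = W))
}
nnDenseBackward <- function(dout, cache) {
  list(dx = crossprod(cache$W, dout),
       dW = tcrossprod(dout, cache$x),
       db = rowSums(dout))
}

softmaxProbs <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(logits))
}

## ---- residual blocks -------------------------------------------------------

blockParamNames <- function(prefix, type, proj) {
  nm <- c("bn1_gamma", "bn1_beta", "conv1", "bn2_gamma", "bn2_beta", "conv2")
  if (type == "bottleneck")
    nm <- c(nm, "bn3_gamma", "bn3_beta", "conv3")
  if (proj) nm <- c(nm, "proj")
  paste0(prefix, nm)
}

blockForward <- function(x, params, bnrun, prefix, stride, type, train,
                         momentum) {
  P <- function(nm) params[[paste0(prefix, nm)]]
  runs <- list()
  b1 <- nnBNForward(x, P("bn1_gamma"), P("bn1_beta"),
                    bnrun[[paste0(prefix, "bn1")]], momentum, train)
  runs[[paste0(prefix, "bn1")]] <- b1$run
  r1 <- nnReluForward(b1$out)
  proj <- !is.null(P("proj"))
  sc <- if (proj) nnConvForward(r1$out, P("proj"), stride = stride, pad = 0L)
  if (type == "basic") {
    c1 <- nnConvForward(r1$out, P("conv1"), stride = stride, pad = 1L)
    b2 <- nnBNForward(c1$out, P("bn2_gamma"), P("bn2_beta"),
                      bnrun[[paste0(prefix, "bn2")]], momentum, train)
    runs[[paste0(prefix, "bn2")]] <- b2$run
    r2 <- nnReluForward(b2$out)
    c2 <- nnConvForward(r2$out, P("conv2"), stride = 1L, pad = 1L)
    out <- c2$out + if (proj) sc$out else x
    cache <- list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache, b2 = b2$cache,
                  r2 = r2$cache, c2 = c2$cache,
                  sc = if (proj) sc$cache, proj = proj, type = type)
  } else {
    c1 <- nnConvForward(r1$out, P("conv1"), stride = 1L, pad = 0L)
    b2 <- nnBNForward(c1$out, P("bn2_gamma"), P("bn2_beta"),
                      bnrun[[paste0(prefix, "bn2")]], momentum, train)
    runs[[paste0(prefix, "bn2")]] <- b2$run
    r2 <- nnReluForward(b2$out)
    c2 <- nnConvForward(r2$out, P("conv2"), stride = stride, pad = 1L)
    b3 <- nnBNForward(c2$out, P("bn3_gamma"), P("bn3_beta"),
                      bnrun[[paste0(prefix, "bn3")]], momentum, train)
    runs[[paste0(prefix, "bn3")]] <- b3$run
    r3 <- nnReluForward(b3$out)
    c3 <- nnConvForward(r3$out, P("conv3"), stride = 1L, pad = 0L)
    out <- c3$out + if (proj) sc$out else x
    cache <- list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache, b2 = b2$cache,
                  r2 = r2$cache, c2 = c2$cache, b3 = b3$cache, r3 = r3$cache,
                  c3 = c3$cache, sc = if (proj) sc$cache, proj = proj,
                  type = type)
  }
  list(out = out, cache = cache, runs = runs)
}

blockBackward <- function(dout, cache, prefix) {
  g <- list()
  if (cache$type == "basic") {
    dc2 <- nnConvBackward(dout, cache$c2)
    g[[paste0(prefix, "conv2")]] <- dc2$dW
    dr2 <- nnReluBackward(dc2$dx, cache$r2)
    db2 <- nnBNBackward(dr2, cache$b2)
    g[[paste0(prefix, "bn2_gamma")]] <- db2$dgamma
    g[[paste0(prefix, "bn2_beta")]] <- db2$dbeta
    dc1 <- nnConvBackward(db2$dx, cache$c1)
    g[[paste0(prefix, "conv1")]] <- dc1$dW
    dpre <- dc1$dx
  } else {
    dc3 <- nnConvBackward(dout, cache$c3)
    g[[paste0(prefix, "conv3")]] <- dc3$dW
    dr3 <- nnReluBackward(dc3$dx, cache$r3)
    db3 <- nnBNBackward(dr3, cache$b3)
    g[[paste0(prefix, "bn3_gamma")]] <- db3$dgamma
    g[[paste0(prefix, "bn3_beta")]] <- db3$dbeta
    dc2 <- nnConvBackward(db3$dx, cache$c2)
    g[[paste0(prefix, "conv2")]] <- dc2$dW
    dr2 <- nnReluBackward(dc2$dx, cache$r2)
    db2 <- nnBNBackward(dr2, cache$b2)
    g[[paste0(prefix, "bn2_gamma")]] <- db2$dgamma
    g[[paste0(prefix, "bn2_beta")]] <- db2$dbeta
    dc1 <- nnConvBackward(db2$dx, cache$c1)
    g[[paste0(prefix, "conv1")]] <- dc1$dW
    dpre <- dc1$dx
  }
  if (cache$proj) {
    dsc <- nnConvBackward(dout, cache$sc)
    g[[paste0(prefix, "proj")]] <- dsc$dW
    dpre <- dpre + dsc$dx
  }
  dr1 <- nnReluBackward(dpre, cache$r1)
  db1 <- nnBNBackward(dr1, cache$b1)
  g[[paste0(prefix, "bn1_gamma")]] <- db1$dgamma
  g[[paste0(prefix, "bn1_beta")]] <- db1$dbeta
  dx <- db1$dx
  if (!cache$proj) dx <- dx + dout
  list(dx = dx, grads = g)
}

## ---- whole-network forward / backward -------------------------------------

cnnBlockPlan <- function(config) {
  widths <- config$stage_widths
  blocks <- rep(config$blocks_per_stage, length.out = length(widths))
  plan <- list()
  cin <- widths[1]
  for (s in seq_along(widths)) {
    for (b in seq_len(blocks[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      cout <- widths[s]
      plan[[length(plan) + 1L]] <-
        list(prefix = sprintf("s%db%d_", s, b), cin = cin, cout = cout,
             stride = stride, proj = (cin != cout || stride != 1L))
      cin <- cout
    }
  }
  plan
}

cnnForward <- function(params, config, bnrun, x, train = TRUE) {
  momentum <- config$bn_momentum
  pad <- (dim(params$stem)[1] - 1L) %/% 2L
  st <- nnConvForward(x, params$stem, stride = config$stem_stride, pad = pad)
  h <- st$out
  caches <- list(stem = st$cache, blocks = list())
  for (bl in cnnBlockPlan(config)) {
    res <- blockForward(h, params, bnrun, bl$prefix, bl$stride,
                        config$block_type, train, momentum)
    h <- res$out
    caches$blocks[[bl$prefix]] <- res$cache
    for (nm in names(res$runs)) bnrun[[nm]] <- res$runs[[nm]]
  }
  bf <- nnBNForward(h, params$head_bn_gamma, params$head_bn_beta,
                    bnrun$head_bn, momentum, train)
  bnrun$head_bn <- bf$run
  rf <- nnReluForward(bf$out)
  gp <- nnGapForward(rf$out)
  dn <- nnDenseForward(gp$out, params$dense_W, params$dense_b)
  caches$head <- list(bf = bf$cache, rf = rf$cache, gp = gp$cache,
                      dn = dn$cache)
  list(logits = dn$out, caches = caches, bnrun = bnrun)
}

cnnBackward <- function(dlogits, caches, config) {
  grads <- list()
  hd <- caches$head
  dd <- nnDenseBackward(dlogits, hd$dn)
  grads$dense_W <- dd$dW; grads$dense_b <- dd$db
  dh <- nnGapBackward(dd$dx, hd$gp)
  dh <- nnReluBackward(dh, hd$rf)
  db <- nnBNBackward(dh, hd$bf)
  grads$head_bn_gamma <- db$dgamma; grads$head_bn_beta <- db$dbeta
  dh <- db$dx
  plan <- cnnBlockPlan(config)
  for (bl in rev(plan)) {
    res <- blockBackward(dh, caches$blocks[[bl$prefix]], bl$prefix)
    dh <- res$dx
    grads[names(res$grads)] <- res$grads
  }
  ds <- nnConvBackward(dh, caches$stem)
  grads$stem <- ds$dW
  grads
}

rmspropStep <- function(params, grads, opt, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- opt[[nm]]
    if (is.null(v)) v <- g * 0
    v <- rho * v + (1 - rho) * g * g
    opt[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(v) + eps)
  }
  list(params = params, opt = opt)
}
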