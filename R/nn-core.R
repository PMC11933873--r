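# Internal CNN-LSTM engine: forward pass, backpropagation and Adam.
#
# Layout: spectra enter as 1 x B "2D data matrices" with one channel;
# each conv block applies a 1x2 kernel with stride 2 followed by 1x2
# max-pooling (stride 2), so a block divides the band axis by four.
# The conv output is consumed by the LSTM as a sequence over the reduced
# band axis with the filter dimension as features; the final hidden state
# feeds a ReLU dense layer and a single linear regression output.
#
# Activations are held as [batch, length, channels] arrays; convolutions
# are evaluated as two matrix products (even/odd band positions), which
# keeps the whole engine in BLAS calls.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# band-axis lengths surviving each conv+pool block; a block is applied
# only while at least 4 positions remain (conv -> >=2, pool -> >=1)
.planBlocks <- function(inputBands, filters) {
  lens <- list()
  L <- inputBands
  for (k in seq_along(filters)) {
    if (L < 4) break
    Lc <- (L - 2) %/% 2 + 1
    Lp <- Lc %/% 2
    lens[[k]] <- c(conv = Lc, pool = Lp)
    L <- Lp
  }
  lens
}

.initParams <- function(arch, seed) {
  set.seed(seed)
  p <- list()
  Cin <- 1L
  for (k in seq_len(arch$nBlocks)) {
    Cout <- arch$filters[k]
    sc <- sqrt(2 / (2 * Cin))  # He initialization for ReLU conv
    p[[paste0("conv", k, ".W1")]] <- matrix(stats::rnorm(Cin * Cout, 0, sc),
                                            Cin, Cout)
    p[[paste0("conv", k, ".W2")]] <- matrix(stats::rnorm(Cin * Cout, 0, sc),
                                            Cin, Cout)
    p[[paste0("conv", k, ".b")]] <- numeric(Cout)
    Cin <- Cout
  }
  Fdim <- if (arch$nBlocks) arch$filters[arch$nBlocks] else 1L
  H <- arch$lstmUnits
  scx <- sqrt(1 / Fdim); sch <- sqrt(1 / H)
  p$lstm.Wx <- matrix(stats::rnorm(Fdim * 4 * H, 0, scx), Fdim, 4 * H)
  p$lstm.Wh <- matrix(stats::rnorm(H * 4 * H, 0, sch), H, 4 * H)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
  p$lstm.b <- b
  D <- arch$denseUnits
  p$dense.W1 <- matrix(stats::rnorm(H * D, 0, sqrt(2 / H)), H, D)
  p$dense.b1 <- numeric(D)
  p$dense.W2 <- matrix(stats::rnorm(D, 0, sqrt(1 / D)), D, 1)
  p$dense.b2 <- 0
  p
}

# forward pass; returns scaled predictions and, if cache=TRUE, the
# intermediate states needed by .nnBackward
.nnForward <- function(params, arch, X, cache = FALSE) {
  m <- nrow(X)
  A <- array(X, dim = c(m, ncol(X), 1L))
  caches <- if (cache) vector("list", arch$nBlocks)
  for (k in seq_len(arch$nBlocks)) {
    Lin <- dim(A)[2]; Cin <- dim(A)[3]
    Lc <- arch$lens[[k]][["conv"]]; Lp <- arch$lens[[k]][["pool"]]
    idx1 <- seq(1L, by = 2L, length.out = Lc)
    idx2 <- idx1 + 1L
    M1 <- matrix(A[, idx1, , drop = FALSE], m * Lc, Cin)
    M2 <- matrix(A[, idx2, , drop = FALSE], m * Lc, Cin)
    Z <- M1 %*% params[[paste0("conv", k, ".W1")]] +
         M2 %*% params[[paste0("conv", k, ".W2")]]
    Z <- sweep(Z, 2, params[[paste0("conv", k, ".b")]], "+")
    Rl <- pmax(Z, 0)
    Cout <- ncol(Z)
    Ac <- array(Rl, dim = c(m, Lc, Cout))
    po <- seq(1L, by = 2L, length.out = Lp)
    a1 <- Ac[, po, , drop = FALSE]
    a2 <- Ac[, po + 1L, , drop = FALSE]
    P <- pmax(a1, a2)
    if (cache)
      caches[[k]] <- list(M1 = M1, M2 = M2, relu = Z > 0, mask = a1 >= a2,
                          Lin = Lin, Cin = Cin, Lc = Lc, Lp = Lp,
                          idx1 = idx1, idx2 = idx2, Cout = Cout)
    A <- P
  }
  Tlen <- dim(A)[2]; Fdim <- dim(A)[3]
  H <- arch$lstmUnits
  h <- matrix(0, m, H); cC <- matrix(0, m, H)
  lstmCache <- if (cache) vector("list", Tlen)
  for (t in seq_len(Tlen)) {
    Xt <- matrix(A[, t, , drop = FALSE], m, Fdim)
    G <- Xt %*% params$lstm.Wx + h %*% params$lstm.Wh
    G <- sweep(G, 2, params$lstm.b, "+")
    i <- .sigmoid(G[, 1:H, drop = FALSE])
    f <- .sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
    cNew <- f * cC + i * g
    tc <- tanh(cNew)
    hNew <- o * tc
    if (cache)
      lstmCache[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                             cPrev = cC, hPrev = h, tc = tc)
    h <- hNew; cC <- cNew
  }
  Z1 <- sweep(h %*% params$dense.W1, 2, params$dense.b1, "+")
  D1 <- pmax(Z1, 0)
  out <- sweep(D1 %*% params$dense.W2, 2, params$dense.b2, "+")
  if (!cache) return(drop(out))
  list(out = drop(out),
       cache = list(conv = caches, lstm = lstmCache, A = A,
                    h = h, Z1 = Z1, D1 = D1, m = m,
                    Tlen = Tlen, Fdim = Fdim))
}

# gradients of mean((out - y)^2) w.r.t. every parameter
.nnBackward <- function(params, arch, fw, y) {
  cc <- fw$cache
  m <- cc$m; H <- arch$lstmUnits
  g <- list()
  dOut <- matrix(2 * (fw$out - y) / m, m, 1)
  g$dense.W2 <- crossprod(cc$D1, dOut)
  g$dense.b2 <- sum(dOut)
  dD1 <- dOut %*% t(params$dense.W2)
  dZ1 <- dD1 * (cc$Z1 > 0)
  g$dense.W1 <- crossprod(cc$h, dZ1)
  g$dense.b1 <- colSums(dZ1)
  dh <- dZ1 %*% t(params$dense.W1)
  dc <- matrix(0, m, H)
  dWx <- matrix(0, cc$Fdim, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dA <- array(0, dim = c(m, cc$Tlen, cc$Fdim))
  for (t in rev(seq_len(cc$Tlen))) {
    lc <- cc$lstm[[t]]
    do <- dh * lc$tc
    dcT <- dc + dh * lc$o * (1 - lc$tc^2)
    di <- dcT * lc$g
    dg <- dcT * lc$i
    df <- dcT * lc$cPrev
    dcPrev <- dcT * lc$f
    dG <- cbind(di * lc$i * (1 - lc$i),
                df * lc$f * (1 - lc$f),
                dg * (1 - lc$g^2),
                do * lc$o * (1 - lc$o))
    dWx <- dWx + crossprod(lc$Xt, dG)
    dWh <- dWh + crossprod(lc$hPrev, dG)
    db <- db + colSums(dG)
    dA[, t, ] <- dG %*% t(params$lstm.Wx)
    dh <- dG %*% t(params$lstm.Wh)
    dc <- dcPrev
  }
  g$lstm.Wx <- dWx; g$lstm.Wh <- dWh; g$lstm.b <- db
  for (k in rev(seq_len(arch$nBlocks))) {
    ck <- cc$conv[[k]]
    dP <- dA  # [m, Lp, Cout]
    dConv <- array(0, dim = c(m, ck$Lc, ck$Cout))
    po <- seq(1L, by = 2L, length.out = ck$Lp)
    dConv[, po, ] <- dP * ck$mask
    dConv[, po + 1L, ] <- dP * !ck$mask
    Mz <- matrix(dConv, m * ck$Lc, ck$Cout) * ck$relu
    g[[paste0("conv", k, ".W1")]] <- crossprod(ck$M1, Mz)
    g[[paste0("conv", k, ".W2")]] <- crossprod(ck$M2, Mz)
    g[[paste0("conv", k, ".b")]] <- colSums(Mz)
    dM1 <- Mz %*% t(params[[paste0("conv", k, ".W1")]])
    dM2 <- Mz %*% t(params[[paste0("conv", k, ".W2")]])
    dAprev <- array(0, dim = c(m, ck$Lin, ck$Cin))
    dAprev[, ck$idx1, ] <- array(dM1, dim = c(m, ck$Lc, ck$Cin))
    dAprev[, ck$idx2, ] <- array(dM2, dim = c(m, ck$Lc, ck$Cin))
    dA <- dAprev
  }
  g
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

.adamStep <- function(params, grads, state, lr, frozen = character(),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    if (any(startsWith(nm, frozen))) next
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
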