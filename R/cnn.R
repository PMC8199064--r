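# Compact 3D convolutional network for patch-based spectral classification.
#
# Architecture (two feature-extraction blocks, then a fully connected
# classifier): 3D valid convolution -> batch normalization -> max pooling
# over the spectral dimension only -> ReLU, twice; flatten; two fully
# connected layers with dropout; softmax output. Trained with AdamW on
# fixed mini-batches. Implemented directly on BLAS matrix products via
# im2col, fast enough for desk-scale patch sets on one CPU.
#
# Activation layout: a batch is a matrix (features x B). The feature order
# is channel-fastest, then patch row, col, band. With this order the
# im2col gather is a single row-subset `X[g, ]`, a convolution's GEMM
# output is already in layout order, and batch-norm statistics are plain
# row-recycled arithmetic — no transposes anywhere in the hot path.
# Input patches (channel count 1) arrive in extract_patches()'s
# (row, col, band) flatten order, which is the same convention.

cnn_geometry <- function(patch_dim, spec) {
  kh <- spec$kernel[1]; kw <- spec$kernel[2]; kd <- spec$kernel[3]
  pool <- spec$pool_spectral
  out1 <- c(patch_dim[1] - kh + 1L, patch_dim[2] - kw + 1L,
            patch_dim[3] - kd + 1L)
  if (any(out1 < 1L)) stop("patch too small for the convolution kernel")
  pool1 <- c(out1[1], out1[2], out1[3] %/% pool)
  out2 <- c(pool1[1] - kh + 1L, pool1[2] - kw + 1L, pool1[3] - kd + 1L)
  if (any(out2 < 1L)) stop("feature map too small for the second convolution")
  pool2 <- c(out2[1], out2[2], out2[3] %/% pool)
  nflat <- prod(pool2) * spec$filters[2]
  list(kernel = c(kh, kw, kd), pool = pool,
       out1 = out1, pool1 = pool1, out2 = out2, pool2 = pool2,
       F1 = spec$filters[1], F2 = spec$filters[2], nflat = nflat,
       idx1 = im2col_index(patch_dim[1], patch_dim[2], patch_dim[3], 1L,
                           kh, kw, kd),
       idx2 = im2col_index(pool1[1], pool1[2], pool1[3], spec$filters[1],
                           kh, kw, kd))
}

# im2col index matrix for the channel-fastest layout: K rows ordered
# (channel, kernel row, kernel col, kernel band), P = oh*ow*od columns
# ordered (out row, out col, out band). idx[k, p] indexes the input
# feature vector.
im2col_index <- function(h, w, d, cin, kh, kw, kd) {
  oh <- h - kh + 1L; ow <- w - kw + 1L; od <- d - kd + 1L
  kr <- seq_len(kh) - 1L; kc <- seq_len(kw) - 1L; kb <- seq_len(kd) - 1L
  koff <- as.vector(outer(seq_len(cin),
                          cin * as.vector(outer(outer(kr, kc * h, "+"),
                                                kb * h * w, "+")), "+"))
  or <- seq_len(oh) - 1L; oc <- seq_len(ow) - 1L; ob <- seq_len(od) - 1L
  base <- cin * as.vector(outer(outer(or, oc * h, "+"), ob * h * w, "+"))
  idx <- outer(koff, base, "+")
  storage.mode(idx) <- "integer"
  idx
}

# samples per im2col chunk, bounding the gather buffer to ~3e7 doubles
conv_chunk_size <- function(idx) {
  max(1L, as.integer(3e7 %/% length(idx)))
}

conv_fwd <- function(X, idx, W, b) {
  B <- ncol(X); K <- nrow(idx); P <- ncol(idx); Fo <- nrow(W)
  g <- as.vector(idx)
  out <- matrix(0, Fo * P, B)
  step <- conv_chunk_size(idx)
  for (j0 in seq(1L, B, by = step)) {
    j <- j0:min(j0 + step - 1L, B)
    Cm <- X[g, j, drop = FALSE]                 # (K*P, Bc) gather
    dim(Cm) <- c(K, P * length(j))
    Y <- W %*% Cm + b                           # b recycled down rows
    dim(Y) <- c(Fo * P, length(j))              # already channel-fastest
    out[, j] <- Y
  }
  out
}

conv_bwd <- function(X, dOut, idx, W) {
  B <- ncol(X); K <- nrow(idx); P <- ncol(idx); Fo <- nrow(W)
  g <- as.vector(idx)
  dW <- matrix(0, Fo, K); db <- numeric(Fo)
  dX <- matrix(0, nrow(X), B)
  step <- conv_chunk_size(idx)
  for (j0 in seq(1L, B, by = step)) {
    j <- j0:min(j0 + step - 1L, B)
    Bc <- length(j)
    Cm <- X[g, j, drop = FALSE]
    dim(Cm) <- c(K, P * Bc)
    dY <- dOut[, j, drop = FALSE]
    dim(dY) <- c(Fo, P * Bc)
    dW <- dW + tcrossprod(dY, Cm)
    db <- db + rowSums(dY)
    M <- crossprod(W, dY)                       # (K, P*Bc)
    dim(M) <- c(K * P, Bc)
    sums <- rowsum(M, g, reorder = TRUE)        # scatter-add (col2im)
    tgt <- as.integer(rownames(sums))
    dX[tgt, j] <- dX[tgt, j] + sums
  }
  list(dX = dX, dW = dW, db = db)
}

# Batch norm over each channel's (positions x batch) slab. With the
# channel-fastest layout a per-channel vector recycles correctly down the
# rows of the (F*P x B) activation matrix once expanded to length F*P.
bn_expand <- function(v, P) rep.int(v, P)

bn_fwd_train <- function(Z, P, F, gamma, beta, eps = 1e-5) {
  M <- Z; dim(M) <- c(F, length(Z) / F)
  mu <- rowMeans(M)
  va <- rowMeans(M^2) - mu^2
  invstd <- 1 / sqrt(va + eps)
  xhat <- (Z - bn_expand(mu, P)) * bn_expand(invstd, P)
  out <- xhat * bn_expand(gamma, P) + bn_expand(beta, P)
  list(out = out, xhat = xhat, invstd = invstd, mu = mu, va = va)
}

bn_fwd_eval <- function(Z, P, F, gamma, beta, run_mu, run_va, eps = 1e-5) {
  sc <- gamma / sqrt(run_va + eps)
  (Z - bn_expand(run_mu, P)) * bn_expand(sc, P) + bn_expand(beta, P)
}

bn_bwd <- function(dOut, cache, P, F, gamma) {
  xhat <- cache$xhat
  n <- length(dOut) / F                          # positions x batch
  rsum <- function(A) {
    M <- A; dim(M) <- c(F, n); rowSums(M)
  }
  dgamma <- rsum(dOut * xhat)
  dbeta <- rsum(dOut)
  dxhat <- dOut * bn_expand(gamma, P)
  m1 <- rsum(dxhat) / n
  m2 <- rsum(dxhat * xhat) / n
  dX <- (dxhat - bn_expand(m1, P) - xhat * bn_expand(m2, P)) *
    bn_expand(cache$invstd, P)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(Z, dims, F) {
  B <- ncol(Z); od <- dims[3]; od2 <- od %/% 2L
  A <- array(Z, c(F * dims[1] * dims[2], od, B))
  i1 <- seq(1L, 2L * od2, by = 2L)
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  mask <- A1 >= A2                               # ties go to the first band
  out <- pmax(A1, A2)
  dim(out) <- c(F * dims[1] * dims[2] * od2, B)
  list(out = out, mask = mask, od2 = od2)
}

pool_bwd <- function(dOut, cache, dims, F) {
  B <- ncol(dOut); od <- dims[3]; od2 <- cache$od2
  s <- F * dims[1] * dims[2]
  dOa <- array(dOut, c(s, od2, B))
  dA <- array(0, c(s, od, B))
  i1 <- seq(1L, 2L * od2, by = 2L)
  dA[, i1, ] <- dOa * cache$mask
  dA[, i1 + 1L, ] <- dOa * !cache$mask
  dim(dA) <- c(s * od, B)
  dA
}

cnn_init_params <- function(geo, nc, fc) {
  K1 <- nrow(geo$idx1); K2 <- nrow(geo$idx2)
  H1 <- fc[1]; H2 <- fc[2]
  list(
    W1 = matrix(stats::rnorm(geo$F1 * K1, sd = sqrt(2 / K1)), geo$F1, K1),
    b1 = numeric(geo$F1), g1 = rep(1, geo$F1), be1 = numeric(geo$F1),
    W2 = matrix(stats::rnorm(geo$F2 * K2, sd = sqrt(2 / K2)), geo$F2, K2),
    b2 = numeric(geo$F2), g2 = rep(1, geo$F2), be2 = numeric(geo$F2),
    Wf1 = matrix(stats::rnorm(H1 * geo$nflat, sd = sqrt(2 / geo$nflat)),
                 H1, geo$nflat),
    bf1 = numeric(H1),
    Wf2 = matrix(stats::rnorm(H2 * H1, sd = sqrt(2 / H1)), H2, H1),
    bf2 = numeric(H2),
    # zero-initialised classifier head: the decision direction is then set
    # purely by the accumulated gradient, which argmax reads correctly even
    # while the step magnitude (lr * steps) is still tiny
    Wf3 = matrix(0, nc, H2), bf3 = numeric(nc)
  )
}

cnn_forward <- function(params, geo, X, spec, train, bn_run = NULL) {
  P1 <- prod(geo$out1); P2 <- prod(geo$out2)
  cache <- list()
  Z1 <- conv_fwd(X, geo$idx1, params$W1, params$b1)
  if (train) {
    bn1 <- bn_fwd_train(Z1, P1, geo$F1, params$g1, params$be1)
    cache$bn1 <- bn1
    A1 <- bn1$out
  } else {
    A1 <- bn_fwd_eval(Z1, P1, geo$F1, params$g1, params$be1,
                      bn_run$mu1, bn_run$va1)
  }
  pl1 <- pool_fwd(A1, geo$out1, geo$F1)
  R1 <- pmax(pl1$out, 0)
  Z2 <- conv_fwd(R1, geo$idx2, params$W2, params$b2)
  if (train) {
    bn2 <- bn_fwd_train(Z2, P2, geo$F2, params$g2, params$be2)
    cache$bn2 <- bn2
    A2 <- bn2$out
  } else {
    A2 <- bn_fwd_eval(Z2, P2, geo$F2, params$g2, params$be2,
                      bn_run$mu2, bn_run$va2)
  }
  pl2 <- pool_fwd(A2, geo$out2, geo$F2)
  R2 <- pmax(pl2$out, 0)
  H1 <- params$Wf1 %*% R2 + params$bf1
  RH1 <- pmax(H1, 0)
  if (train && spec$dropout[1] > 0) {
    m1 <- matrix(stats::runif(length(RH1)) >= spec$dropout[1],
                 nrow(RH1), ncol(RH1)) / (1 - spec$dropout[1])
    RH1 <- RH1 * m1
    cache$drop1 <- m1
  }
  H2 <- params$Wf2 %*% RH1 + params$bf2
  RH2 <- pmax(H2, 0)
  if (train && spec$dropout[2] > 0) {
    m2 <- matrix(stats::runif(length(RH2)) >= spec$dropout[2],
                 nrow(RH2), ncol(RH2)) / (1 - spec$dropout[2])
    RH2 <- RH2 * m2
    cache$drop2 <- m2
  }
  logits <- (params$Wf3 %*% RH2 + params$bf3) * spec$head_scale
  c(cache,
    list(X = X, Z1 = Z1, pl1 = pl1, R1 = R1, Z2 = Z2, pl2 = pl2, R2 = R2,
         H1 = H1, RH1 = RH1, H2 = H2, RH2 = RH2, logits = logits))
}


cnn_softmax <- function(logits) {
  E <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(E, 2, colSums(E), "/")
}

cnn_backward <- function(params, geo, spec, fw, y_idx) {
  B <- ncol(fw$logits)
  probs <- cnn_softmax(fw$logits)
  dL <- probs
  dL[cbind(y_idx, seq_len(B))] <- dL[cbind(y_idx, seq_len(B))] - 1
  dL <- dL * (spec$head_scale / B)     # logits carry the head multiplier
  g <- list()
  g$Wf3 <- tcrossprod(dL, fw$RH2); g$bf3 <- rowSums(dL)
  dRH2 <- crossprod(params$Wf3, dL)
  if (!is.null(fw$drop2)) dRH2 <- dRH2 * fw$drop2
  dH2 <- dRH2 * (fw$H2 > 0)
  g$Wf2 <- tcrossprod(dH2, fw$RH1); g$bf2 <- rowSums(dH2)
  dRH1 <- crossprod(params$Wf2, dH2)
  if (!is.null(fw$drop1)) dRH1 <- dRH1 * fw$drop1
  dH1 <- dRH1 * (fw$H1 > 0)
  g$Wf1 <- tcrossprod(dH1, fw$R2); g$bf1 <- rowSums(dH1)
  dR2 <- crossprod(params$Wf1, dH1)
  dP2 <- dR2 * (fw$pl2$out > 0)
  dA2 <- pool_bwd(dP2, fw$pl2, geo$out2, geo$F2)
  bb2 <- bn_bwd(dA2, fw$bn2, prod(geo$out2), geo$F2, params$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  cv2 <- conv_bwd(fw$R1, bb2$dX, geo$idx2, params$W2)
  g$W2 <- cv2$dW; g$b2 <- cv2$db
  dR1 <- cv2$dX
  dP1 <- dR1 * (fw$pl1$out > 0)
  dA1 <- pool_bwd(dP1, fw$pl1, geo$out1, geo$F1)
  bb1 <- bn_bwd(dA1, fw$bn1, prod(geo$out1), geo$F1, params$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  cv1 <- conv_bwd(fw$X, bb1$dX, geo$idx1, params$W1)
  g$W1 <- cv1$dW; g$b1 <- cv1$db
  loss <- -mean(log(pmax(probs[cbind(y_idx, seq_len(B))], 1e-12)))
  list(grads = g, loss = loss)
}

adamw_step <- function(params, grads, state, t, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  decay_set <- c("W1", "W2", "Wf1", "Wf2", "Wf3")
  for (n in names(grads)) {
    gmat <- grads[[n]]
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * gmat
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * gmat^2
    mh <- state$m[[n]] / (1 - beta1^t)
    vh <- state$v[[n]] / (1 - beta2^t)
    delta <- lr * mh / (sqrt(vh) + eps)
    if (n %in% decay_set) delta <- delta + lr * wd * params[[n]]
    params[[n]] <- params[[n]] - delta
  }
  list(params = params, state = state)
}

# Train on flattened patches x (N x nfeat) with labels y. Mini-batches are
# formed once from a seeded shuffle and the same batch sequence is passed
# over `passes` times, each batch giving one AdamW step.
cnn_train <- function(spec, x, y, patch_dim) {
  classes <- sort(unique(y))
  nc <- length(classes)
  # Fixed multiplier on the zero-initialised classifier head (maximal-update
  # style parametrization): AdamW moves each weight by about lr per step, so
  # without a multiplier the logits could never reach order one within the
  # two-pass budget; 4/(lr*H2) makes one step move the logits by order one.
  if (is.null(spec$head_scale)) {
    spec$head_scale <- 4 / (spec$lr * spec$fc[2])
  }
  geo <- cnn_geometry(patch_dim, spec)
  set.seed(spec$seed)
  params <- cnn_init_params(geo, nc, spec$fc)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  y_idx <- match(y, classes)
  N <- nrow(x)
  ord <- sample.int(N)
  bs <- min(spec$batch_size, N)
  batches <- split(ord, ceiling(seq_along(ord) / bs))
  run <- list(mu1 = 0, va1 = 1, mu2 = 0, va2 = 1)
  t <- 0L; tb <- 0L
  losses <- numeric(0)
  for (pass in seq_len(spec$passes)) {
    for (bidx in batches) {
      Xb <- t(x[bidx, , drop = FALSE])
      fw <- cnn_forward(params, geo, Xb, spec, train = TRUE)
      bk <- cnn_backward(params, geo, spec, fw, y_idx[bidx])
      t <- t + 1L
      upd <- adamw_step(params, bk$grads, state, t, spec$lr,
                        spec$weight_decay)
      params <- upd$params; state <- upd$state
      # cumulative average of batch statistics for inference
      tb <- tb + 1L
      run$mu1 <- run$mu1 + (fw$bn1$mu - run$mu1) / tb
      run$va1 <- run$va1 + (fw$bn1$va - run$va1) / tb
      run$mu2 <- run$mu2 + (fw$bn2$mu - run$mu2) / tb
      run$va2 <- run$va2 + (fw$bn2$va - run$va2) / tb
      losses <- c(losses, bk$loss)
    }
  }
  list(params = params, geo = geo, classes = classes, spec = spec,
       bn_run = run, losses = losses, n_steps = t)
}

cnn_predict <- function(model, x, type = c("class", "prob"), chunk = 512L) {
  type <- match.arg(type)
  N <- nrow(x)
  nc <- length(model$classes)
  probs <- matrix(0, N, nc)
  for (j0 in seq(1L, N, by = chunk)) {
    j <- j0:min(j0 + chunk - 1L, N)
    fw <- cnn_forward(model$params, model$geo, t(x[j, , drop = FALSE]),
                      model$spec, train = FALSE, bn_run = model$bn_run)
    probs[j, ] <- t(cnn_softmax(fw$logits))
  }
  colnames(probs) <- as.character(model$classes)
  if (type == "prob") probs else model$classes[max.col(probs, "first")]
}
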