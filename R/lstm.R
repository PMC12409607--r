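## Minimal batched LSTM with backpropagation through time and an Adam
## optimizer, written against base R matrix algebra.  Token sequences are
## handled as integer index matrices; inputs are one-hot encoded on the
## fly.  Gate layout in the fused weight matrices is [input, forget,
## candidate, output], each a block of `hidden` columns.

.sigmoid <- function(x) 1 / (1 + exp(-x))

## One-hot matrix (B x V) from a 1-based index vector; index 0 = all-zero
## row (used for positions past the end of a sequence).
.onehot <- function(idx, V) {
  M <- matrix(0, length(idx), V)
  nz <- which(idx > 0L)
  if (length(nz)) M[cbind(nz, idx[nz])] <- 1
  M
}

## Parameter initialization.  Uniform(-scale, scale) weights; forget-gate
## biases start at 1 so memory cells are initially open.
.initParams <- function(V, hidden, n_layers, scale = 0.08) {
  params <- list()
  for (l in seq_len(n_layers)) {
    D <- if (l == 1L) V else hidden
    W <- matrix(stats::runif((D + hidden) * 4L * hidden, -scale, scale),
                D + hidden, 4L * hidden)
    b <- rep(0, 4L * hidden)
    b[(hidden + 1L):(2L * hidden)] <- 1
    params[[paste0("W", l)]] <- W
    params[[paste0("b", l)]] <- b
  }
  params$Wy <- matrix(stats::runif(hidden * V, -scale, scale), hidden, V)
  params$by <- rep(0, V)
  params
}

.nLayers <- function(params) sum(grepl("^W[0-9]+$", names(params)))

## Single forward step through all layers.  `state` is a list of per-layer
## h and c matrices (B x H).  Returns list(logits, state).
.lstmStep <- function(params, x, state) {
  L <- .nLayers(params)
  H <- ncol(state$h[[1]])
  inp <- x
  for (l in seq_len(L)) {
    z <- cbind(inp, state$h[[l]]) %*% params[[paste0("W", l)]]
    z <- z + rep(params[[paste0("b", l)]], each = nrow(z))
    i <- .sigmoid(z[, 1:H, drop = FALSE])
    f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * state$c[[l]] + i * g
    hh <- o * tanh(cc)
    state$c[[l]] <- cc
    state$h[[l]] <- hh
    inp <- hh
  }
  logits <- inp %*% params$Wy
  logits <- logits + rep(params$by, each = nrow(logits))
  list(logits = logits, state = state)
}

.zeroState <- function(B, H, L) {
  list(h = replicate(L, matrix(0, B, H), simplify = FALSE),
       c = replicate(L, matrix(0, B, H), simplify = FALSE))
}

## Row-wise softmax with max-shift.
.softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Forward + masked cross-entropy (+ gradients unless loss_only).
## input_idx / target_idx: B x T 1-based index matrices (0 = past end);
## mask: B x T, 1 where the target position contributes to the loss.
.lstmLossGrad <- function(params, input_idx, target_idx, mask,
                          loss_only = FALSE) {
  B <- nrow(input_idx)
  T_ <- ncol(input_idx)
  L <- .nLayers(params)
  H <- nrow(params$Wy)
  V <- ncol(params$Wy)
  n_mask <- sum(mask)
  state <- .zeroState(B, H, L)
  cache <- if (!loss_only) vector("list", T_)
  loss <- 0
  dlogits_store <- if (!loss_only) vector("list", T_)
  for (t in seq_len(T_)) {
    x <- .onehot(input_idx[, t], V)
    step_cache <- if (!loss_only) vector("list", L)
    inp <- x
    for (l in seq_len(L)) {
      h_prev <- state$h[[l]]
      c_prev <- state$c[[l]]
      z <- cbind(inp, h_prev) %*% params[[paste0("W", l)]]
      z <- z + rep(params[[paste0("b", l)]], each = nrow(z))
      i <- .sigmoid(z[, 1:H, drop = FALSE])
      f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      hh <- o * tc
      if (!loss_only) {
        step_cache[[l]] <- list(inp = inp, h_prev = h_prev, c_prev = c_prev,
                                i = i, f = f, g = g, o = o, tc = tc)
      }
      state$c[[l]] <- cc
      state$h[[l]] <- hh
      inp <- hh
    }
    logits <- inp %*% params$Wy
    logits <- logits + rep(params$by, each = nrow(logits))
    probs <- .softmaxRows(logits)
    m <- mask[, t]
    rows <- which(m > 0)
    if (length(rows)) {
      p_t <- probs[cbind(rows, target_idx[rows, t])]
      loss <- loss + sum(-log(pmax(p_t, 1e-12)))
    }
    if (!loss_only) {
      dl <- probs
      tgt <- target_idx[, t]
      nz <- which(tgt > 0L)
      dl[cbind(nz, tgt[nz])] <- dl[cbind(nz, tgt[nz])] - 1
      dl <- dl * (m / max(n_mask, 1L))
      dlogits_store[[t]] <- dl
      cache[[t]] <- list(layers = step_cache, h_top = inp)
    }
  }
  loss <- loss / max(n_mask, 1L)
  if (loss_only) return(list(loss = loss))

  grads <- lapply(params, function(p) if (is.matrix(p))
    matrix(0, nrow(p), ncol(p)) else rep(0, length(p)))
  names(grads) <- names(params)
  dh_next <- replicate(L, matrix(0, B, H), simplify = FALSE)
  dc_next <- replicate(L, matrix(0, B, H), simplify = FALSE)
  for (t in rev(seq_len(T_))) {
    dl <- dlogits_store[[t]]
    grads$Wy <- grads$Wy + crossprod(cache[[t]]$h_top, dl)
    grads$by <- grads$by + colSums(dl)
    d_from_above <- dl %*% t(params$Wy)
    for (l in rev(seq_len(L))) {
      cc_cache <- cache[[t]]$layers[[l]]
      dh <- d_from_above + dh_next[[l]]
      i <- cc_cache$i; f <- cc_cache$f; g <- cc_cache$g; o <- cc_cache$o
      tc <- cc_cache$tc
      do <- dh * tc
      dc <- dh * o * (1 - tc^2) + dc_next[[l]]
      di <- dc * g
      df <- dc * cc_cache$c_prev
      dg <- dc * i
      dz <- cbind(di * i * (1 - i),
                  df * f * (1 - f),
                  dg * (1 - g^2),
                  do * o * (1 - o))
      xin <- cbind(cc_cache$inp, cc_cache$h_prev)
      Wl <- paste0("W", l)
      bl <- paste0("b", l)
      grads[[Wl]] <- grads[[Wl]] + crossprod(xin, dz)
      grads[[bl]] <- grads[[bl]] + colSums(dz)
      dxin <- dz %*% t(params[[Wl]])
      D <- ncol(cc_cache$inp)
      d_from_above <- dxin[, 1:D, drop = FALSE]
      dh_next[[l]] <- dxin[, (D + 1):(D + H), drop = FALSE]
      dc_next[[l]] <- dc * f
    }
  }
  list(loss = loss, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

## One Adam update with optional global-norm gradient clipping.
.adamStep <- function(params, grads, opt, lr, clip_norm = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (!is.null(clip_norm)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm > clip_norm) {
      grads <- lapply(grads, function(g) g * (clip_norm / gnorm))
    }
  }
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

## Pack a TrainingPairSet into index/mask matrices for the batched LSTM.
## Input token t predicts target token t+1; positions whose target is the
## pad region get mask 0 and contribute exactly nothing to the loss.
.packPairs <- function(pairs) {
  vocab <- pairs@vocab
  lens <- lengths(pairs@input)
  T_ <- max(lens) - 1L
  B <- length(pairs@input)
  input_idx <- matrix(0L, B, T_)
  target_idx <- matrix(0L, B, T_)
  mask <- matrix(0, B, T_)
  for (s in seq_len(B)) {
    Lq <- lens[s]
    ii <- .tokenPositions(pairs@input[[s]], vocab)
    tt <- .tokenPositions(pairs@target[[s]], vocab)
    input_idx[s, seq_len(Lq - 1L)] <- ii[-Lq]
    target_idx[s, seq_len(Lq - 1L)] <- tt[-1L]
    mask[s, seq_len(Lq - 1L)] <- 1
  }
  list(input = input_idx, target = target_idx, mask = mask,
       steps = lens - 1L)
}

## Length-bucketed batch index sets: sequences are shuffled, grouped by
## length so each batch can be truncated to its own maximum, and the batch
## order is shuffled again.
.lengthBuckets <- function(steps, batch_size) {
  ord <- sample.int(length(steps))
  ord <- ord[order(steps[ord])]
  starts <- seq(1L, length(ord), by = batch_size)
  batches <- lapply(starts, function(s)
    ord[s:min(s + batch_size - 1L, length(ord))])
  batches[sample.int(length(batches))]
}
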