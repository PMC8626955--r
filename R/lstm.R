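# A compact two-layer LSTM, written in base R matrix code.
#
# Parameter layout per layer: Wx (input_dim x 4H), Wh (H x 4H), b (4H), with
# gate blocks in column order [input | forget | candidate | output]; the
# read-out is Wy (H x V), by (V).  Layer 1 consumes one-hot token vectors, so
# its input product is a row-selection of Wx.  Forward/backward passes are
# batched over sequences (teacher forcing, padded with a mask); a separate
# single-step path serves incremental sampling during tree search.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically safe row-wise softmax
.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

lstm_init <- function(vocab_size, hidden_size, n_layers = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- hidden_size
  runif_mat <- function(nr, nc, r) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    din <- if (l == 1L) vocab_size else H
    r <- 1 / sqrt(H)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias at +1, the usual LSTM trick
    layers[[l]] <- list(Wx = runif_mat(din, 4 * H, r),
                        Wh = runif_mat(H, 4 * H, r),
                        b = b)
  }
  list(layers = layers,
       Wy = runif_mat(H, vocab_size, 1 / sqrt(H)),
       by = numeric(vocab_size),
       hidden_size = H, n_layers = n_layers, vocab_size = vocab_size)
}

# ---- batched teacher-forced pass -------------------------------------------

# inputs: B x T integer matrix of input token indices (NA where padded)
# returns cached activations for the backward pass plus logits per step
lstm_forward <- function(net, inputs) {
  B <- nrow(inputs); Tm <- ncol(inputs)
  H <- net$hidden_size; L <- net$n_layers
  hs <- cs <- gates <- vector("list", L)
  for (l in seq_len(L)) {
    hs[[l]] <- vector("list", Tm + 1L)
    cs[[l]] <- vector("list", Tm + 1L)
    gates[[l]] <- vector("list", Tm)
    hs[[l]][[1]] <- matrix(0, B, H)
    cs[[l]][[1]] <- matrix(0, B, H)
  }
  logits <- vector("list", Tm)
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  for (t in seq_len(Tm)) {
    xidx <- inputs[, t]
    xidx[is.na(xidx)] <- 1L  # padded rows are masked out of the loss anyway
    for (l in seq_len(L)) {
      p <- net$layers[[l]]
      a <- if (l == 1L) p$Wx[xidx, , drop = FALSE] else x_low %*% p$Wx
      a <- a + hs[[l]][[t]] %*% p$Wh
      a <- sweep(a, 2, p$b, "+")
      gi <- .sigmoid(a[, idx_i, drop = FALSE])
      gf <- .sigmoid(a[, idx_f, drop = FALSE])
      gg <- tanh(a[, idx_g, drop = FALSE])
      go <- .sigmoid(a[, idx_o, drop = FALSE])
      cc <- gf * cs[[l]][[t]] + gi * gg
      tc <- tanh(cc)
      hh <- go * tc
      gates[[l]][[t]] <- list(i = gi, f = gf, g = gg, o = go, tc = tc)
      cs[[l]][[t + 1L]] <- cc
      hs[[l]][[t + 1L]] <- hh
      x_low <- hh
    }
    logits[[t]] <- sweep(hs[[L]][[t + 1L]] %*% net$Wy, 2, net$by, "+")
  }
  list(hs = hs, cs = cs, gates = gates, logits = logits, inputs = inputs)
}

# cross-entropy loss and full BPTT gradients
# targets: B x T integer matrix (NA = masked / padded)
lstm_backward <- function(net, fwd, targets) {
  inputs <- fwd$inputs
  B <- nrow(inputs); Tm <- ncol(inputs)
  H <- net$hidden_size; L <- net$n_layers; V <- net$vocab_size
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)

  grads <- list(layers = lapply(net$layers, function(p)
    list(Wx = matrix(0, nrow(p$Wx), ncol(p$Wx)),
         Wh = matrix(0, H, 4 * H), b = numeric(4 * H))),
    Wy = matrix(0, H, V), by = numeric(V))

  n_tok <- sum(!is.na(targets))
  loss <- 0
  dh_next <- dc_next <- vector("list", L)
  for (l in seq_len(L)) {
    dh_next[[l]] <- matrix(0, B, H)
    dc_next[[l]] <- matrix(0, B, H)
  }
  for (t in rev(seq_len(Tm))) {
    tg <- targets[, t]
    live <- !is.na(tg)
    # d logits: softmax - onehot, zero on masked rows
    probs <- .softmax_rows(fwd$logits[[t]])
    dlog <- probs
    rows <- which(live)
    if (length(rows)) {
      loss <- loss - sum(log(pmax(probs[cbind(rows, tg[rows])], 1e-300)))
      dlog[cbind(rows, tg[rows])] <- dlog[cbind(rows, tg[rows])] - 1
    }
    dlog[!live, ] <- 0
    dlog <- dlog / n_tok
    h_top <- fwd$hs[[L]][[t + 1L]]
    grads$Wy <- grads$Wy + crossprod(h_top, dlog)
    grads$by <- grads$by + colSums(dlog)
    dx_above <- dlog %*% t(net$Wy)
    for (l in rev(seq_len(L))) {
      g <- fwd$gates[[l]][[t]]
      dh <- dh_next[[l]] + dx_above
      dc <- dc_next[[l]] + dh * g$o * (1 - g$tc^2)
      dao <- (dh * g$tc) * g$o * (1 - g$o)
      dai <- (dc * g$g) * g$i * (1 - g$i)
      dag <- (dc * g$i) * (1 - g$g^2)
      daf <- (dc * fwd$cs[[l]][[t]]) * g$f * (1 - g$f)
      da <- cbind(dai, daf, dag, dao)
      p <- net$layers[[l]]
      gl <- grads$layers[[l]]
      if (l == 1L) {
        xidx <- inputs[, t]
        ok <- which(!is.na(xidx))
        if (length(ok)) {
          # scatter-add rows of da into Wx at the one-hot input rows
          agg <- rowsum(da[ok, , drop = FALSE], group = xidx[ok])
          ridx <- as.integer(rownames(agg))
          gl$Wx[ridx, ] <- gl$Wx[ridx, , drop = FALSE] + agg
        }
      } else {
        x_low <- fwd$hs[[l - 1L]][[t + 1L]]
        gl$Wx <- gl$Wx + crossprod(x_low, da)
      }
      gl$Wh <- gl$Wh + crossprod(fwd$hs[[l]][[t]], da)
      gl$b <- gl$b + colSums(da)
      grads$layers[[l]] <- gl
      dh_next[[l]] <- da %*% t(p$Wh)
      dc_next[[l]] <- dc * g$f
      dx_above <- if (l > 1L) da %*% t(p$Wx) else NULL
    }
  }
  list(loss = loss / n_tok * 1, grads = grads, n_tok = n_tok,
       total_nll = loss)
}

# ---- single-step incremental path (sampling / tree search) -----------------

lstm_state0 <- function(net) {
  H <- net$hidden_size
  lapply(seq_len(net$n_layers), function(l)
    list(h = numeric(H), c = numeric(H)))
}

# advance one token (by vocabulary index); returns list(state, logits)
lstm_step <- function(net, state, token_index) {
  H <- net$hidden_size
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  x <- NULL
  for (l in seq_len(net$n_layers)) {
    p <- net$layers[[l]]
    a <- if (l == 1L) p$Wx[token_index, ] else as.numeric(x %*% p$Wx)
    a <- a + as.numeric(state[[l]]$h %*% p$Wh) + p$b
    gi <- .sigmoid(a[idx_i]); gf <- .sigmoid(a[idx_f])
    gg <- tanh(a[idx_g]); go <- .sigmoid(a[idx_o])
    cc <- gf * state[[l]]$c + gi * gg
    hh <- go * tanh(cc)
    state[[l]] <- list(h = hh, c = cc)
    x <- matrix(hh, 1L)
  }
  logits <- as.numeric(x %*% net$Wy) + net$by
  list(state = state, logits = logits)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  walk <- function(p) lapply(p, function(x) {
    if (is.list(x)) walk(x) else zero_like(x)
  })
  shapes <- list(layers = net$layers, Wy = net$Wy, by = net$by)
  list(m = walk(shapes), v = walk(shapes), t = 0L)
}

adam_update <- function(net, grads, opt, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(param, grad, m, v) {
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    param <- param - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(param = param, m = m, v = v)
  }
  for (l in seq_along(net$layers)) {
    for (nm in c("Wx", "Wh", "b")) {
      u <- upd(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               opt$m$layers[[l]][[nm]], opt$v$layers[[l]][[nm]])
      net$layers[[l]][[nm]] <- u$param
      opt$m$layers[[l]][[nm]] <- u$m
      opt$v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("Wy", "by")) {
    u <- upd(net[[nm]], grads[[nm]], opt$m[[nm]], opt$v[[nm]])
    net[[nm]] <- u$param
    opt$m[[nm]] <- u$m
    opt$v[[nm]] <- u$v
  }
  list(net = net, opt = opt)
}
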