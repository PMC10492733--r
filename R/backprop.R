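# Reverse-mode gradients for the transformer classifier, hand-derived to
# mirror .forward_window() exactly. Gradients are returned as a named list
# congruent with the parameter list, for one window at a time; the training
# loop averages them over a batch.

# Layer-norm backward for one sub-layer. x is the pre-norm input (m x e),
# dy the gradient at the output. Returns dx plus gain/offset gradients.
.layernorm_bwd <- function(x, g, eps, dy) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# Gradient of one attention head. cache holds Q, K, V, A; X is the head's
# input; dH the gradient at the head output. Returns parameter gradients and
# the gradient with respect to X.
.attention_head_bwd <- function(cache, p, X, dH) {
  iscale <- 1 / sqrt(ncol(cache$Q))
  A <- cache$A
  dA <- dH %*% t(cache$V)
  dV <- t(A) %*% dH
  dS <- A * (dA - rowSums(dA * A))
  dQ <- (dS %*% cache$K) * iscale
  dK <- (t(dS) %*% cache$Q) * iscale
  list(dWq = t(X) %*% dQ, dbq = colSums(dQ),
       dWk = t(X) %*% dK, dbk = colSums(dK),
       dWv = t(X) %*% dV, dbv = colSums(dV),
       dX = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv))
}

# Full backward pass for one window. cache is .forward_window(..., cache =
# TRUE)$cache; dlogits the loss gradient at the softmax logits.
.backward_window <- function(params, cfg, cache, dlogits) {
  grads <- list()
  eps <- cfg$ln_eps
  m <- nrow(cache$Xfinal)

  # classification head
  grads[["out.W"]] <- outer(cache$hdd, dlogits)
  grads[["out.b"]] <- dlogits
  dhdd <- drop(params$out.W %*% dlogits)
  dhd <- if (is.null(cache$md)) dhdd else dhdd * cache$md
  dpre_d <- dhd * (cache$pre_d > 0)
  grads[["dense.W"]] <- outer(cache$pooled, dpre_d)
  grads[["dense.b"]] <- dpre_d
  dpooled <- drop(params$dense.W %*% dpre_d)
  dX <- matrix(dpooled / m, m, length(dpooled), byrow = TRUE)

  for (b in rev(seq_len(cfg$num_blocks))) {
    bc <- cache$blocks[[b]]
    g1 <- params[[sprintf("b%d.ln1.g", b)]]
    g2 <- params[[sprintf("b%d.ln2.g", b)]]
    W1 <- params[[sprintf("b%d.W1", b)]]
    W2 <- params[[sprintf("b%d.W2", b)]]
    Wo <- params[[sprintf("b%d.Wo", b)]]
    hp <- .head_params(params, b, cfg$num_heads)
    dk <- cfg$head_size

    if (!cfg$pre_norm) {
      ln2 <- .layernorm_bwd(bc$R2, g2, eps, dX)
      grads[[sprintf("b%d.ln2.g", b)]] <- ln2$dg
      grads[[sprintf("b%d.ln2.b", b)]] <- ln2$db
      dR2 <- ln2$dx
      dN1 <- dR2                       # residual branch
      dF2 <- dR2
      grads[[sprintf("b%d.W2", b)]] <- t(bc$F1d) %*% dF2
      grads[[sprintf("b%d.b2", b)]] <- colSums(dF2)
      dF1d <- dF2 %*% t(W2)
      dF1 <- if (is.null(bc$m1)) dF1d else dF1d * bc$m1
      dpre1 <- dF1 * (bc$pre1 > 0)
      grads[[sprintf("b%d.W1", b)]] <- t(bc$ff_in) %*% dpre1
      grads[[sprintf("b%d.b1", b)]] <- colSums(dpre1)
      dN1 <- dN1 + dpre1 %*% t(W1)
      ln1 <- .layernorm_bwd(bc$R1, g1, eps, dN1)
      grads[[sprintf("b%d.ln1.g", b)]] <- ln1$dg
      grads[[sprintf("b%d.ln1.b", b)]] <- ln1$db
      dR1 <- ln1$dx
      dXin <- dR1                      # residual branch around attention
      dOd <- dR1
      dO <- if (is.null(bc$mo)) dOd else dOd * bc$mo
      grads[[sprintf("b%d.Wo", b)]] <- t(bc$Hcat) %*% dO
      grads[[sprintf("b%d.bo", b)]] <- colSums(dO)
      dHcat <- dO %*% t(Wo)
      for (i in seq_len(cfg$num_heads)) {
        dH <- dHcat[, ((i - 1L) * dk + 1L):(i * dk), drop = FALSE]
        hb <- .attention_head_bwd(bc$heads[[i]], hp[[i]], bc$ln_in, dH)
        grads[[sprintf("b%d.h%d.Wq", b, i)]] <- hb$dWq
        grads[[sprintf("b%d.h%d.bq", b, i)]] <- hb$dbq
        grads[[sprintf("b%d.h%d.Wk", b, i)]] <- hb$dWk
        grads[[sprintf("b%d.h%d.bk", b, i)]] <- hb$dbk
        grads[[sprintf("b%d.h%d.Wv", b, i)]] <- hb$dWv
        grads[[sprintf("b%d.h%d.bv", b, i)]] <- hb$dbv
        dXin <- dXin + hb$dX
      }
      dX <- dXin
    } else {
      # pre-norm order: Xout = R2 = N1 + FF(LN2(N1)); N1 = R1 = Xin + MHA(LN1(Xin))
      dR2 <- dX
      dN1 <- dR2
      dF2 <- dR2
      grads[[sprintf("b%d.W2", b)]] <- t(bc$F1d) %*% dF2
      grads[[sprintf("b%d.b2", b)]] <- colSums(dF2)
      dF1d <- dF2 %*% t(W2)
      dF1 <- if (is.null(bc$m1)) dF1d else dF1d * bc$m1
      dpre1 <- dF1 * (bc$pre1 > 0)
      grads[[sprintf("b%d.W1", b)]] <- t(bc$ff_in) %*% dpre1
      grads[[sprintf("b%d.b1", b)]] <- colSums(dpre1)
      dff_in <- dpre1 %*% t(W1)
      ln2 <- .layernorm_bwd(bc$N1, g2, eps, dff_in)
      grads[[sprintf("b%d.ln2.g", b)]] <- ln2$dg
      grads[[sprintf("b%d.ln2.b", b)]] <- ln2$db
      dN1 <- dN1 + ln2$dx
      dXin <- dN1
      dOd <- dN1
      dO <- if (is.null(bc$mo)) dOd else dOd * bc$mo
      grads[[sprintf("b%d.Wo", b)]] <- t(bc$Hcat) %*% dO
      grads[[sprintf("b%d.bo", b)]] <- colSums(dO)
      dHcat <- dO %*% t(Wo)
      d_ln_in <- matrix(0, nrow(bc$ln_in), ncol(bc$ln_in))
      for (i in seq_len(cfg$num_heads)) {
        dH <- dHcat[, ((i - 1L) * dk + 1L):(i * dk), drop = FALSE]
        hb <- .attention_head_bwd(bc$heads[[i]], hp[[i]], bc$ln_in, dH)
        grads[[sprintf("b%d.h%d.Wq", b, i)]] <- hb$dWq
        grads[[sprintf("b%d.h%d.bq", b, i)]] <- hb$dbq
        grads[[sprintf("b%d.h%d.Wk", b, i)]] <- hb$dWk
        grads[[sprintf("b%d.h%d.bk", b, i)]] <- hb$dbk
        grads[[sprintf("b%d.h%d.Wv", b, i)]] <- hb$dWv
        grads[[sprintf("b%d.h%d.bv", b, i)]] <- hb$dbv
        d_ln_in <- d_ln_in + hb$dX
      }
      ln1 <- .layernorm_bwd(bc$Xin, g1, eps, d_ln_in)
      grads[[sprintf("b%d.ln1.g", b)]] <- ln1$dg
      grads[[sprintf("b%d.ln1.b", b)]] <- ln1$db
      dX <- dXin + ln1$dx
    }
  }
  grads
}
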