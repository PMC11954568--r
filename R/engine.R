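# Training engine: forward pass with cached intermediates, hand-derived
# reverse-mode gradients for the fixed architecture, and Adam.  Everything
# is plain dense matrix algebra; the high-level graph is materialized
# densely (intended for M+N up to a few thousand nodes).

# --- state construction ------------------------------------------------

# Precompute everything the per-epoch passes reuse: per-entity feature
# matrices and normalized adjacencies (or, for the "-L" variant, padded
# integer code matrices), the normalized high-level adjacency, and the
# training mask.
build_engine_state <- function(hg, mask, labels, control,
                               variant = "full") {
  st <- list(M = hg$M, N = hg$N, variant = variant,
             slope = control$leaky_slope, beta = control$beta,
             eps = control$eps,
             mask = as.matrix(mask), y = as.numeric(labels))
  st$Ah_hat <- normalize_adjacency(hg$Ah)
  if (variant == "-L") {
    smiles <- vapply(hg$drugs, function(g) g$smiles %||% g$drug_id, "")
    seqs <- vapply(hg$proteins, function(g) g$sequence, "")
    st$Cd <- t(vapply(smiles, encode_smiles_labels, numeric(control$max_smiles_len),
                      max_len = control$max_smiles_len))
    st$Cp <- t(vapply(seqs, encode_sequence_labels, numeric(control$max_seq_len),
                      max_len = control$max_seq_len))
    dimnames(st$Cd) <- NULL; dimnames(st$Cp) <- NULL
  } else {
    ents <- c(hg$drugs, hg$proteins)
    st$entities <- lapply(ents, function(g) {
      list(X = g$X, Ahat = normalize_adjacency(g$A), m = nrow(g$X))
    })
    st$is_drug <- c(rep(TRUE, hg$M), rep(FALSE, hg$N))
  }
  # full (M+N)^2 gradient scatter template for the Gram backward
  st$n_nodes <- hg$M + hg$N
  st
}

# SMILES character label-encoding, padded/truncated to max_len, scaled to
# [0, 1] so the linear projection sees order-one inputs.
.smiles_vocab <- strsplit(paste0("#%()+-./0123456789=@[]\\",
                                 "ABCDEFGHIKLMNOPRSTVWXYZ",
                                 "abcdefghiklmnoprstuy"), "")[[1]]

encode_smiles_labels <- function(s, max_len = 100L) {
  ch <- strsplit(s, "")[[1]]
  code <- match(ch, .smiles_vocab)
  code[is.na(code)] <- length(.smiles_vocab) + 1L
  code <- code[seq_len(min(length(code), max_len))]
  out <- numeric(max_len)
  out[seq_along(code)] <- code / (length(.smiles_vocab) + 1L)
  out
}

.aa_vocab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

encode_sequence_labels <- function(s, max_len = 1000L) {
  ch <- strsplit(toupper(s), "")[[1]]
  code <- match(ch, .aa_vocab)
  code[is.na(code)] <- length(.aa_vocab) + 1L
  code <- code[seq_len(min(length(code), max_len))]
  out <- numeric(max_len)
  out[seq_along(code)] <- code / (length(.aa_vocab) + 1L)
  out
}

# --- forward -----------------------------------------------------------

# Full forward pass; returns loss, bipartite scores, and (when keep=TRUE)
# every intermediate needed by engine_backward.
engine_forward <- function(st, params, keep = TRUE) {
  K <- length(grep("^ld\\.W", names(params)))
  cache <- list()

  # low level: entity embeddings -> Xh
  if (st$variant == "-L") {
    Xh <- rbind(st$Cd %*% params[["seq.Wd"]],
                st$Cp %*% params[["seq.Wp"]])
  } else {
    ent_caches <- vector("list", length(st$entities))
    Xh <- matrix(0, st$n_nodes, ncol(params[["ld.W1"]]))
    for (e in seq_along(st$entities)) {
      ent <- st$entities[[e]]
      pre <- if (st$is_drug[e]) "ld.W" else "lp.W"
      H <- vector("list", K + 1L)
      U <- vector("list", K)
      H[[1L]] <- ent$X
      for (k in seq_len(K)) {
        U[[k]] <- ent$Ahat %*% H[[k]]
        H[[k + 1L]] <- pmax(U[[k]] %*% params[[paste0(pre, k)]], 0)
      }
      Xh[e, ] <- colMeans(H[[K + 1L]])
      if (keep) ent_caches[[e]] <- list(H = H, U = U)
    }
    cache$ent <- ent_caches
  }
  cache$Xh <- Xh

  Lge <- length(grep("^ge\\.W", names(params)))
  A <- st$Ah_hat

  # graph encoder
  G <- vector("list", Lge + 1L); Q <- vector("list", Lge)
  G[[1L]] <- Xh
  for (l in seq_len(Lge)) {
    Q[[l]] <- A %*% G[[l]]
    G[[l + 1L]] <- tanh(Q[[l]] %*% params[[paste0("ge.W", l)]])
  }
  ZGE <- G[[Lge + 1L]]
  cache$G <- G; cache$Q <- Q

  if (st$variant == "-F") {
    Zt <- ZGE
  } else {
    # feature encoder
    Fm <- vector("list", Lge + 1L); P <- vector("list", Lge)
    Fm[[1L]] <- Xh
    for (l in seq_len(Lge)) {
      Pl <- Fm[[l]] %*% params[[paste0("fe.W", l)]]
      Pl <- sweep(Pl, 2L, params[[paste0("fe.b", l)]], `+`)
      P[[l]] <- Pl
      Fm[[l + 1L]] <- ifelse(Pl >= 0, Pl, st$slope * Pl)
    }
    ZFE <- Fm[[Lge + 1L]]
    cache$Fm <- Fm; cache$P <- P

    alpha <- if (st$variant == "-W") 0.5 else params[["alpha"]]
    ZI <- alpha * ZFE + (1 - alpha) * ZGE
    ZL <- A %*% ZI
    S <- row_softmax(ZL %*% t(ZL))
    Zt <- st$beta * (S %*% ZL) + ZL
    cache$ZFE <- ZFE; cache$ZGE <- ZGE; cache$ZI <- ZI
    cache$ZL <- ZL; cache$S <- S; cache$alpha <- alpha
  }
  cache$Zt <- Zt

  # decoder
  Ldec <- length(grep("^dec\\.W", names(params)))
  Dm <- vector("list", Ldec + 1L); Tm <- vector("list", Ldec)
  Dm[[1L]] <- Zt
  for (h in seq_len(Ldec)) {
    Tm[[h]] <- A %*% Dm[[h]]
    Dm[[h + 1L]] <- tanh(Tm[[h]] %*% params[[paste0("dec.W", h)]])
  }
  Zd <- Dm[[Ldec + 1L]]
  cache$Dm <- Dm; cache$Tm <- Tm

  # reconstruction and loss over the masked bipartite entries
  idx <- cbind(st$mask[, 1L], st$M + st$mask[, 2L])
  s <- rowSums(Zd[idx[, 1L], , drop = FALSE] *
                 Zd[idx[, 2L], , drop = FALSE])
  p <- pmin(pmax(sigmoid(s), st$eps), 1 - st$eps)
  loss <- mean(-st$y * log(p) - (1 - st$y) * log(1 - p))
  cache$Zd <- Zd; cache$p <- p; cache$idx <- idx
  cache$loss <- loss
  if (!keep) cache <- cache[c("Xh", "Zt", "Zd", "p", "loss")]
  cache
}

# Bipartite score matrix from a forward pass (no gradient caches).
engine_scores <- function(st, params) {
  fw <- engine_forward(st, params, keep = FALSE)
  yhat <- sigmoid(fw$Zd %*% t(fw$Zd))
  list(ydp = yhat[seq_len(st$M), st$M + seq_len(st$N), drop = FALSE],
       Zd = fw$Zd, Xh = fw$Xh, loss = fw$loss)
}

# --- backward ----------------------------------------------------------

engine_backward <- function(st, params, cache) {
  grads <- lapply(params, function(x) if (is.matrix(x)) x * 0 else 0)
  A <- st$Ah_hat
  nmask <- nrow(st$mask)

  # d loss / d score, scattered into the full node-pair grid; the Gram
  # product makes dL/dZd = (Gs + t(Gs)) %*% Zd.
  g <- (cache$p - st$y) / nmask
  Gs <- matrix(0, st$n_nodes, st$n_nodes)
  if (anyDuplicated(cache$idx) == 0L) {
    Gs[cache$idx] <- g
  } else {
    for (r in seq_len(nmask)) {
      i <- cache$idx[r, 1L]; j <- cache$idx[r, 2L]
      Gs[i, j] <- Gs[i, j] + g[r]
    }
  }
  G_Zd <- (Gs + t(Gs)) %*% cache$Zd

  # decoder
  Ldec <- length(grep("^dec\\.W", names(params)))
  G <- G_Zd
  for (h in rev(seq_len(Ldec))) {
    Dh <- cache$Dm[[h + 1L]]
    GE_ <- G * (1 - Dh * Dh)
    grads[[paste0("dec.W", h)]] <- crossprod(cache$Tm[[h]], GE_)
    G <- A %*% (GE_ %*% t(params[[paste0("dec.W", h)]]))
  }
  G_Zt <- G

  Lge <- length(grep("^ge\\.W", names(params)))
  if (st$variant == "-F") {
    G_ZGE <- G_Zt
    G_Xh_fe <- 0
  } else {
    S <- cache$S; ZL <- cache$ZL
    G_S <- st$beta * (G_Zt %*% t(ZL))
    G_ZL <- st$beta * (t(S) %*% G_Zt) + G_Zt
    # softmax rows: dC = S * (dS - rowSums(dS * S))
    G_C <- S * (G_S - rowSums(G_S * S))
    G_ZL <- G_ZL + (G_C + t(G_C)) %*% ZL
    G_ZI <- A %*% G_ZL
    if (st$variant != "-W")
      grads[["alpha"]] <- sum(G_ZI * (cache$ZFE - cache$ZGE))
    G_ZFE <- cache$alpha * G_ZI
    G_ZGE <- (1 - cache$alpha) * G_ZI

    # feature encoder
    G <- G_ZFE
    for (l in rev(seq_len(Lge))) {
      GP <- G * ifelse(cache$P[[l]] >= 0, 1, st$slope)
      grads[[paste0("fe.W", l)]] <- crossprod(cache$Fm[[l]], GP)
      grads[[paste0("fe.b", l)]] <- colSums(GP)
      G <- GP %*% t(params[[paste0("fe.W", l)]])
    }
    G_Xh_fe <- G
  }

  # graph encoder
  G <- G_ZGE
  for (l in rev(seq_len(Lge))) {
    Gl <- cache$G[[l + 1L]]
    GR <- G * (1 - Gl * Gl)
    grads[[paste0("ge.W", l)]] <- crossprod(cache$Q[[l]], GR)
    G <- A %*% (GR %*% t(params[[paste0("ge.W", l)]]))
  }
  G_Xh <- G + G_Xh_fe

  # low level
  if (st$variant == "-L") {
    grads[["seq.Wd"]] <- crossprod(st$Cd,
                                   G_Xh[seq_len(st$M), , drop = FALSE])
    grads[["seq.Wp"]] <- crossprod(st$Cp,
                                   G_Xh[st$M + seq_len(st$N), , drop = FALSE])
  } else {
    K <- length(grep("^ld\\.W", names(params)))
    for (e in seq_along(st$entities)) {
      ent <- st$entities[[e]]
      ec <- cache$ent[[e]]
      pre <- if (st$is_drug[e]) "ld.W" else "lp.W"
      GH <- matrix(G_Xh[e, ] / ent$m, nrow = ent$m,
                   ncol = length(G_Xh[e, ]), byrow = TRUE)
      for (k in rev(seq_len(K))) {
        GV <- GH * (ec$H[[k + 1L]] > 0)
        nm <- paste0(pre, k)
        grads[[nm]] <- grads[[nm]] + crossprod(ec$U[[k]], GV)
        GH <- ent$Ahat %*% (GV %*% t(params[[nm]]))
      }
    }
  }
  grads
}

# --- optimizer ---------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(x) if (is.matrix(x)) x * 0 else 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, frozen = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen) next
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm * gnm
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- training loop -----------------------------------------------------

train_engine <- function(st, params, control) {
  state <- adam_init(params)
  frozen <- if (st$variant == "-W") "alpha" else character()
  history <- data.frame(epoch = seq_len(control$epochs), loss = NA_real_,
                        alpha = NA_real_)
  for (ep in seq_len(control$epochs)) {
    cache <- engine_forward(st, params, keep = TRUE)
    if (!is.finite(cache$loss))
      stop(sprintf("non-finite training loss at epoch %d", ep),
           call. = FALSE)
    grads <- engine_backward(st, params, cache)
    upd <- adam_step(params, grads, state, control$lr, frozen = frozen)
    params <- upd$params
    state <- upd$state
    history$loss[ep] <- cache$loss
    history$alpha[ep] <- if (st$variant == "-F") NA_real_ else {
      if (st$variant == "-W") 0.5 else params[["alpha"]]
    }
    if (control$verbose && (ep %% 10L == 0L || ep == 1L))
      message(sprintf("epoch %4d  loss %.5f  alpha %s", ep,
                      cache$loss,
                      ifelse(is.na(history$alpha[ep]), "-",
                             sprintf("%.4f", history$alpha[ep]))))
  }
  list(params = params, history = history)
}
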