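# Non-causal transformer encoder with rotary position encoding, muP
# parameterization (1/head_dim attention scaling, variance-scaled init,
# width-scaled learning rates) and full attention-map export. Forward and
# backward passes are written directly against BLAS matrix products; the
# backward pass is verified against finite differences in the test suite.
#
# Layer structure follows the pre-normalization gated-feed-forward recipe:
#   x <- x + Wo * Attn(RMSNorm(x))
#   x <- x + W2 * (silu(W1 * RMSNorm(x)) . (W3 * RMSNorm(x)))
# with a final RMSNorm before any head.

#' Encoder configuration
#'
#' @param width Model width d (must equal `n_heads * head_dim`).
#' @param n_layers Number of transformer layers. The published aspect ratio
#'   is width/depth = 128, but any positive shape is accepted.
#' @param n_heads Attention heads.
#' @param context_length Maximum token count (1024 for BPE vocabularies,
#'   2048 for single-character models in the published setup).
#' @param vocab_size Total id-space size (both modality ranges + specials).
#' @param rope_base Rotary position base (default 10000).
#' @param ffn_mult Feed-forward expansion (hidden = round(ffn_mult * width),
#'   default 8/3).
#' @return An `momlm_config` list; `attention_scale` is fixed at
#'   `1/head_dim` (the muP prescription, not `1/sqrt(head_dim)`).
#' @export
encoder_config <- function(width = 64L, n_layers = 2L, n_heads = 4L,
                           context_length = 1024L, vocab_size = 64L,
                           rope_base = 10000, ffn_mult = 8 / 3) {
  if (width %% n_heads != 0L) stop("width must be divisible by n_heads")
  head_dim <- width %/% n_heads
  if (head_dim %% 2L != 0L) stop("head_dim must be even for rotary encoding")
  structure(list(width = as.integer(width), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
                 context_length = as.integer(context_length),
                 vocab_size = as.integer(vocab_size), rope_base = rope_base,
                 ffn_hidden = as.integer(round(ffn_mult * width)),
                 attention_scale = 1 / head_dim),
            class = "momlm_config")
}

#' @export
print.momlm_config <- function(x, ...) {
  cat(sprintf("<momlm_config> d=%d layers=%d heads=%d (head_dim=%d) ctx=%d vocab=%d\n",
              x$width, x$n_layers, x$n_heads, x$head_dim, x$context_length,
              x$vocab_size))
  invisible(x)
}

#' Initialize encoder parameters (muP scheme)
#'
#' Embeddings are initialized at width-independent scale (O(1) coordinates);
#' hidden weight matrices at variance 1/fan_in, with residual-output
#' projections additionally shrunk by 1/(2 n_layers); the unembedding starts
#' at zero so initial MLM logits are exactly uniform.
#'
#' @param config An `momlm_config`.
#' @param seed Integer seed.
#' @return Named list of parameter matrices/vectors.
#' @export
init_encoder <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$width; h <- config$ffn_hidden; V <- config$vocab_size
  nl <- config$n_layers
  rnormm <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  params <- list(emb = rnormm(V, d, 1))
  for (l in seq_len(nl)) {
    pre <- sprintf("L%d.", l)
    params[[paste0(pre, "g1")]] <- rep(1, d)
    params[[paste0(pre, "wq")]] <- rnormm(d, d, sqrt(1 / d))
    params[[paste0(pre, "wk")]] <- rnormm(d, d, sqrt(1 / d))
    params[[paste0(pre, "wv")]] <- rnormm(d, d, sqrt(1 / d))
    params[[paste0(pre, "wo")]] <- rnormm(d, d, sqrt(1 / (d * 2 * nl)))
    params[[paste0(pre, "g2")]] <- rep(1, d)
    params[[paste0(pre, "w1")]] <- rnormm(d, h, sqrt(1 / d))
    params[[paste0(pre, "w3")]] <- rnormm(d, h, sqrt(1 / d))
    params[[paste0(pre, "w2")]] <- rnormm(h, d, sqrt(1 / (h * 2 * nl)))
  }
  params$gf <- rep(1, d)
  params$unemb <- matrix(0, d, V)
  params
}

.RMS_EPS <- 1e-8

.rmsnorm_fwd <- function(x, g) {
  r <- sqrt(rowMeans(x * x) + .RMS_EPS)
  list(y = x * (rep(g, each = nrow(x)) / r), r = r)
}

.rmsnorm_bwd <- function(dy, x, g, r) {
  dyg <- dy * rep(g, each = nrow(dy))
  dg <- colSums(dy * (x / r))
  dx <- dyg / r - x * (rowSums(dyg * x) / (ncol(x) * r^3))
  list(dx = dx, dg = dg)
}

# Rotary-encoding tables, pre-expanded to the full (B*L) x d layout of the
# flattened batch (rows ordered (b-1)*L + l; positions 0-based; pair
# frequencies repeat per head). The rotation is applied as
#   rot(m) = m * COS + swap(m) * SIN
# where swap exchanges each odd/even column pair and SIN carries -sin on odd
# columns and +sin on even ones, so one gather and three vector ops replace
# per-pair arithmetic.
.rope_tables <- function(L, config, B = 1L) {
  dh <- config$head_dim; d <- config$width
  theta <- config$rope_base^(-(2 * (seq_len(dh / 2) - 1)) / dh)
  freqs <- rep(theta, config$n_heads)          # length d/2, aligned to heads
  ang <- outer(0:(L - 1), freqs)
  idx <- rep(seq_len(L), times = B)
  odd <- seq(1L, d, by = 2L); even <- seq(2L, d, by = 2L)
  CO <- matrix(0, B * L, d); SI <- matrix(0, B * L, d)
  CO[, odd] <- cos(ang)[idx, , drop = FALSE]
  CO[, even] <- CO[, odd, drop = FALSE]
  SI[, odd] <- -sin(ang)[idx, , drop = FALSE]
  SI[, even] <- -SI[, odd, drop = FALSE]
  perm <- as.vector(rbind(even, odd))          # swaps each (odd, even) pair
  list(cos = CO, sin = SI, perm = perm)
}

# apply rotary rotation to a (B*L x d) matrix with pre-expanded tables
.rope_apply <- function(m, tabs, B, invert = FALSE) {
  SI <- if (invert) -tabs$sin else tabs$sin
  m * tabs$cos + m[, tabs$perm, drop = FALSE] * SI
}

.sigm <- function(u) 1 / (1 + exp(-u))
.silu <- function(u) u / (1 + exp(-u))
.dsilu <- function(u) {
  s <- 1 / (1 + exp(-u))
  s * (1 + u * (1 - s))
}

# Core batched forward. ids: B x L integer matrix of 0-based token ids;
# mask: B x L logical, TRUE for real (non-pad) tokens. Returns the final
# hidden states ((B*L) x d, post final norm), attention tensors, and (when
# want_cache) every intermediate needed by .encoder_backward().
.encoder_forward_r <- function(params, config, ids, mask = NULL,
                               want_cache = FALSE, want_attn = TRUE) {
  ids <- rbind(ids)  # tolerate a vector
  B <- nrow(ids); L <- ncol(ids); d <- config$width
  H <- config$n_heads; dh <- config$head_dim
  if (L > config$context_length) {
    stop(sprintf("input of %d tokens exceeds context_length %d; truncate upstream",
                 L, config$context_length))
  }
  if (is.null(mask)) mask <- matrix(TRUE, B, L)
  x <- params$emb[as.integer(t(ids)) + 1L, , drop = FALSE]  # (B*L) x d
  tabs <- .rope_tables(L, config, B)
  # additive key mask per sequence (row vector repeated over query rows)
  keymask <- ifelse(t(mask), 0, -1e30)  # L x B
  cache <- if (want_cache) list(ids = ids, mask = mask, tabs = tabs,
                                layers = vector("list", config$n_layers))
  attns <- if (want_attn) vector("list", config$n_layers)
  P_store <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("L%d.", l)
    x_in <- x
    nrm <- .rmsnorm_fwd(x, params[[paste0(pre, "g1")]])
    a <- nrm$y
    Q <- .rope_apply(a %*% params[[paste0(pre, "wq")]], tabs, B)
    K <- .rope_apply(a %*% params[[paste0(pre, "wk")]], tabs, B)
    Vv <- a %*% params[[paste0(pre, "wv")]]
    O <- matrix(0, B * L, d)
    P_l <- array(0, c(B, H, L, L))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      km <- keymask[, b]
      for (hh in seq_len(H)) {
        cols <- ((hh - 1L) * dh + 1L):(hh * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) * config$attention_scale
        S <- S + rep(km, each = L)
        S <- S - S[cbind(seq_len(L), max.col(S, ties.method = "first"))]
        E <- exp(S)
        P <- E / rowSums(E)
        P_l[b, hh, , ] <- P
        O[rows, cols] <- P %*% Vv[rows, cols, drop = FALSE]
      }
    }
    attn_out <- O %*% params[[paste0(pre, "wo")]]
    x <- x_in + attn_out
    x_mid <- x
    nrm2 <- .rmsnorm_fwd(x, params[[paste0(pre, "g2")]])
    b2 <- nrm2$y
    U <- b2 %*% params[[paste0(pre, "w1")]]
    G <- b2 %*% params[[paste0(pre, "w3")]]
    Ssw <- .silu(U) * G
    x <- x + Ssw %*% params[[paste0(pre, "w2")]]
    if (want_attn) attns[[l]] <- P_l
    P_store[[l]] <- P_l
    if (want_cache) {
      cache$layers[[l]] <- list(x_in = x_in, a = a, r1 = nrm$r, Q = Q, K = K,
                                V = Vv, P = P_l, O = O, x_mid = x_mid,
                                b2 = b2, r2 = nrm2$r, U = U, G = G, Ssw = Ssw)
    }
  }
  nrmf <- .rmsnorm_fwd(x, params$gf)
  if (want_cache) {
    cache$x_final <- x
    cache$rf <- nrmf$r
    cache$B <- B; cache$L <- L
  }
  structure(list(hidden = nrmf$y, attentions = attns, B = B, L = L,
                 mask = mask, cache = cache),
            class = "momlm_enc_out")
}

# Backward through the encoder given d(hidden) ((B*L) x d). Returns named
# gradient list matching params.
.encoder_backward_r <- function(dhidden, params, config, cache) {
  B <- cache$B; L <- cache$L; d <- config$width
  H <- config$n_heads; dh <- config$head_dim
  grads <- list()
  bw <- .rmsnorm_bwd(dhidden, cache$x_final, params$gf, cache$rf)
  grads$gf <- bw$dg
  dx <- bw$dx
  for (l in rev(seq_len(config$n_layers))) {
    pre <- sprintf("L%d.", l)
    cc <- cache$layers[[l]]
    # ffn block
    dSsw <- tcrossprod(dx, params[[paste0(pre, "w2")]])
    grads[[paste0(pre, "w2")]] <- crossprod(cc$Ssw, dx)
    dU <- dSsw * cc$G * .dsilu(cc$U)
    dG <- dSsw * .silu(cc$U)
    grads[[paste0(pre, "w1")]] <- crossprod(cc$b2, dU)
    grads[[paste0(pre, "w3")]] <- crossprod(cc$b2, dG)
    db2 <- tcrossprod(dU, params[[paste0(pre, "w1")]]) +
      tcrossprod(dG, params[[paste0(pre, "w3")]])
    bw2 <- .rmsnorm_bwd(db2, cc$x_mid, params[[paste0(pre, "g2")]], cc$r2)
    grads[[paste0(pre, "g2")]] <- bw2$dg
    dx <- dx + bw2$dx
    # attention block
    dO <- tcrossprod(dx, params[[paste0(pre, "wo")]])
    grads[[paste0(pre, "wo")]] <- crossprod(cc$O, dx)
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d)
    dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (hh in seq_len(H)) {
        cols <- ((hh - 1L) * dh + 1L):(hh * dh)
        P <- cache$layers[[l]]$P[b, hh, , ]
        if (L == 1L) P <- matrix(P, 1L, 1L)
        dP <- tcrossprod(dO[rows, cols, drop = FALSE],
                         cc$V[rows, cols, drop = FALSE])
        dV[rows, cols] <- crossprod(P, dO[rows, cols, drop = FALSE])
        dS <- P * (dP - rowSums(dP * P))
        dS <- dS * config$attention_scale
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE])
      }
    }
    dQ <- .rope_apply(dQ, cache$tabs, B, invert = TRUE)
    dK <- .rope_apply(dK, cache$tabs, B, invert = TRUE)
    grads[[paste0(pre, "wq")]] <- crossprod(cc$a, dQ)
    grads[[paste0(pre, "wk")]] <- crossprod(cc$a, dK)
    grads[[paste0(pre, "wv")]] <- crossprod(cc$a, dV)
    da <- tcrossprod(dQ, params[[paste0(pre, "wq")]]) +
      tcrossprod(dK, params[[paste0(pre, "wk")]]) +
      tcrossprod(dV, params[[paste0(pre, "wv")]])
    bw1 <- .rmsnorm_bwd(da, cc$x_in, params[[paste0(pre, "g1")]], cc$r1)
    grads[[paste0(pre, "g1")]] <- bw1$dg
    dx <- dx + bw1$dx
  }
  # embedding gradient (scatter-add by token id)
  demb <- matrix(0, config$vocab_size, d)
  idvec <- as.integer(t(cache$ids)) + 1L
  demb <- rowsum(dx, group = idvec, reorder = FALSE)
  out <- matrix(0, config$vocab_size, d)
  out[as.integer(rownames(demb)), ] <- demb
  grads$emb <- out
  grads
}

#' Run the encoder over one or more tokenized sequences
#'
#' @param tokens A `momlm_tokens` object, a plain 0-based id vector, or a
#'   list of either (all the same length, or pass `pad_id` to pad).
#' @param config `momlm_config`.
#' @param params Parameter list from [init_encoder()] (or trained).
#' @param pad_id Id used to right-pad ragged inputs (required for ragged
#'   lists).
#' @return A `momlm_enc_out`: `hidden` ((B*L) x d final hidden states),
#'   `attentions` (per layer, array B x heads x L x L with rows of every map
#'   summing to 1), `mask`, `B`, `L`.
#' @export
encoder_forward <- function(tokens, config, params, pad_id = NULL) {
  if (inherits(tokens, "momlm_tokens")) tokens <- list(tokens)
  if (is.numeric(tokens)) tokens <- list(as.integer(tokens))
  idlist <- lapply(tokens, function(t) {
    if (inherits(t, "momlm_tokens")) t$ids else as.integer(t)
  })
  lens <- lengths(idlist)
  if (any(lens == 0L)) stop("empty token sequence")
  Lmax <- max(lens)
  if (length(unique(lens)) > 1L && is.null(pad_id)) {
    stop("ragged inputs need pad_id")
  }
  ids <- matrix(if (is.null(pad_id)) 0L else as.integer(pad_id),
                length(idlist), Lmax)
  mask <- matrix(FALSE, length(idlist), Lmax)
  for (i in seq_along(idlist)) {
    ids[i, seq_len(lens[i])] <- idlist[[i]]
    mask[i, seq_len(lens[i])] <- TRUE
  }
  .encoder_forward(params, config, ids, mask)
}

#' Attention-map stack for a single sequence
#'
#' Flattens the per-layer attention arrays of a batch-of-one forward into
#' the (n_layers * n_heads) x L x L channel stack consumed by the
#' convolutional attention probe.
#'
#' @param enc_out `momlm_enc_out` with B = 1.
#' @return 3-d array: channels x L x L.
#' @export
attention_stack <- function(enc_out) {
  stopifnot(enc_out$B == 1L)
  L <- enc_out$L
  nl <- length(enc_out$attentions)
  H <- dim(enc_out$attentions[[1]])[2]
  out <- array(0, c(nl * H, L, L))
  ch <- 0L
  for (l in seq_len(nl)) {
    for (hh in seq_len(H)) {
      ch <- ch + 1L
      out[ch, , ] <- enc_out$attentions[[l]][1, hh, , ]
    }
  }
  out
}

#' First-token pooled embedding
#'
#' The d-vector of hidden state at position 0 of each sequence (the leading
#' classification token in this package's input layouts).
#'
#' @param enc_out `momlm_enc_out`.
#' @return B x d matrix (one row per sequence).
#' @export
pooled_embedding <- function(enc_out) {
  idx <- (seq_len(enc_out$B) - 1L) * enc_out$L + 1L
  enc_out$hidden[idx, , drop = FALSE]
}

#' Per-position MLM logits
#'
#' @param enc_out `momlm_enc_out`.
#' @param params Encoder parameters (uses the unembedding matrix).
#' @return (B*L) x vocab_size score matrix.
#' @export
mlm_logits <- function(enc_out, params) {
  enc_out$hidden %*% params$unemb
}

# Cross-entropy over selected positions. logits (N x V), targets 0-based
# ids (length N), sel logical (length N). Returns loss and dlogits
# (normalized by the number of selected positions).
.masked_ce <- function(logits, targets, sel) {
  n <- sum(sel)
  if (n == 0L) return(list(loss = 0, dlogits = logits * 0))
  lg <- logits[sel, , drop = FALSE]
  lg <- lg - apply(lg, 1L, max)
  E <- exp(lg)
  Pm <- E / rowSums(E)
  tgt <- cbind(seq_len(n), targets[sel] + 1L)
  loss <- -mean(log(pmax(Pm[tgt], 1e-300)))
  dlg <- Pm
  dlg[tgt] <- dlg[tgt] - 1
  dlogits <- logits * 0
  dlogits[sel, ] <- dlg / n
  list(loss = loss, dlogits = dlogits)
}

#' Root-mean-square of hidden activations at initialization
#'
#' The muP coordinate check: the RMS of the residual stream entering the
#' final normalization should be approximately width-independent for a fixed
#' token input across widths.
#'
#' @param config,params Encoder configuration and parameters.
#' @param ids 0-based id vector.
#' @return Scalar RMS of the pre-norm residual stream.
#' @export
hidden_rms <- function(config, params, ids) {
  out <- .encoder_forward(params, config, matrix(as.integer(ids), nrow = 1L),
                          want_cache = TRUE, want_attn = FALSE)
  sqrt(mean(out$cache$x_final^2))
}
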