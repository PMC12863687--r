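# Interpretability probes.
#
# 1. Contrastive modality-invariance probe: a low-rank linear map W (k x d,
#    k = 16, temperature tau = 0.07) trained with the symmetric contrastive
#    (CLIP) objective on frozen gene/protein embeddings, 5% train / 95%
#    held-out. A joint multi-omic backbone should yield a probe that
#    generalizes; two single-omic backbones (dual-W control) should not.
# 2. Frozen-attention convolutional probe: a 4-layer 3x3 conv net over the
#    (layers x heads) x L x L attention stack, row-averaged into L logits
#    predicting per-residue nucleotide contact.

# project + row-normalize; errors on zero rows
.proj_norm <- function(Z, W) {
  U <- Z %*% t(W)
  nrm <- sqrt(rowSums(U^2))
  if (any(nrm == 0)) stop("zero-norm projected embedding")
  list(A = U / nrm, U = U, nrm = nrm)
}

#' Symmetric contrastive (CLIP) loss of a linear probe
#'
#' Projects gene embeddings X and protein embeddings Y by W (or by Wy for Y
#' when given, the dual-probe control), normalizes rows to unit length,
#' forms the similarity matrix S_ij = <x_i, y_j> / tau, and averages the
#' row-wise and column-wise cross-entropies whose correct label for row or
#' column i is i.
#'
#' @param X,Y N x d embedding matrices (row i of X pairs with row i of Y).
#' @param W k x d projection.
#' @param tau Temperature (default 0.07).
#' @param Wy Optional separate projection for Y.
#' @param grads Also return gradients d loss / dW (and dWy).
#' @return Loss scalar, or list(loss, dW, dWy) when `grads`.
#' @export
clip_loss <- function(X, Y, W, tau = 0.07, Wy = NULL, grads = FALSE) {
  N <- nrow(X)
  stopifnot(N >= 1L, nrow(Y) == N)
  px <- .proj_norm(X, W)
  py <- .proj_norm(Y, if (is.null(Wy)) W else Wy)
  S <- tcrossprod(px$A, py$A) / tau
  # row-wise softmax CE
  Sr <- S - apply(S, 1L, max)
  Pr <- exp(Sr) / rowSums(exp(Sr))
  Sc <- sweep(S, 2L, apply(S, 2L, max))
  Pc <- sweep(exp(Sc), 2L, colSums(exp(Sc)), "/")
  loss <- -(mean(log(pmax(diag(Pr), 1e-300))) +
              mean(log(pmax(diag(Pc), 1e-300)))) / 2
  if (!grads) return(loss)
  Eye <- diag(N)
  dS <- ((Pr - Eye) + (Pc - Eye)) / (2 * N)
  dA <- (dS %*% py$A) / tau
  dB <- (crossprod(dS, px$A)) / tau
  unnorm_bwd <- function(dA, pn) {
    (dA - pn$A * rowSums(dA * pn$A)) / pn$nrm
  }
  dUx <- unnorm_bwd(dA, px)
  dUy <- unnorm_bwd(dB, py)
  if (is.null(Wy)) {
    list(loss = loss, dW = crossprod(dUx, X) + crossprod(dUy, Y), dWy = NULL)
  } else {
    list(loss = loss, dW = crossprod(dUx, X), dWy = crossprod(dUy, Y))
  }
}

#' Train the contrastive modality-invariance probe
#'
#' AdamW on the projection matrix only (the backbone embeddings stay
#' frozen), learning rate linearly decayed to zero. `joint_single_W` trains
#' one shared W for both modalities; `dual_W_control` trains separate
#' projections for X and Y with the same loss (the single-omic control,
#' which deliberately has twice the parameters).
#'
#' @param X,Y N x d frozen embedding matrices (paired by row).
#' @param mode `"joint_single_W"` or `"dual_W_control"`.
#' @param train_frac Fraction of pairs used for training (default 0.05).
#' @param steps,lr Optimization settings (defaults 10000, 0.01).
#' @param tau,k Temperature and rank (defaults 0.07, 16; k must satisfy
#'   k < d/4).
#' @param seed Integer seed (split + init).
#' @return List: probe (`W`, `Wy`), `auroc` (held-out matched-vs-mismatched
#'   cosine similarity), `train_auroc`, `matched`, `mismatched` (held-out
#'   similarity samples), `train_idx`.
#' @export
train_probe <- function(X, Y, mode = c("joint_single_W", "dual_W_control"),
                        train_frac = 0.05, steps = 10000L, lr = 0.01,
                        tau = 0.07, k = 16L, seed = 1L) {
  mode <- match.arg(mode)
  d <- ncol(X); N <- nrow(X)
  if (k >= d / 4) stop("probe rank k must satisfy k < d/4")
  set.seed(seed)
  n_train <- max(2L, round(train_frac * N))
  if (N < 3L || N - n_train < 1L) stop("need at least 2 training pairs and a held-out pair")
  train_idx <- sort(sample(N, n_train))
  test_idx <- setdiff(seq_len(N), train_idx)
  Xt <- X[train_idx, , drop = FALSE]; Yt <- Y[train_idx, , drop = FALSE]
  W <- matrix(stats::rnorm(k * d, 0, sqrt(1 / d)), k, d)
  Wy <- if (mode == "dual_W_control") matrix(stats::rnorm(k * d, 0, sqrt(1 / d)), k, d)
  probe <- list(W = W, Wy = Wy)
  flat <- .own_params(Filter(Negate(is.null), probe))
  state <- .adam_init(flat)
  for (s in seq_len(steps)) {
    g <- clip_loss(Xt, Yt, probe$W, tau, probe$Wy, grads = TRUE)
    grads <- list(W = g$dW)
    if (!is.null(probe$Wy)) grads$Wy <- g$dWy
    scale <- 1 - (s - 1) / steps            # linear decay to zero
    upd <- .adam_step(flat, grads, state,
                      stats::setNames(rep(lr, length(flat)), names(flat)),
                      scale, c(0.9, 0.95), 1e-8, 1e-2)
    flat <- upd$params; state <- upd$state
    probe$W <- flat$W
    if (!is.null(probe$Wy)) probe$Wy <- flat$Wy
  }
  sim_stats <- function(idx) {
    A <- .proj_norm(X[idx, , drop = FALSE], probe$W)$A
    B <- .proj_norm(Y[idx, , drop = FALSE],
                    if (is.null(probe$Wy)) probe$W else probe$Wy)$A
    S <- tcrossprod(A, B)
    matched <- diag(S)
    mism <- S[row(S) != col(S)]
    list(matched = matched, mismatched = mism,
         auroc = metrics(c(matched, mism),
                         c(rep(1, length(matched)), rep(0, length(mism))),
                         "auroc"))
  }
  held <- sim_stats(test_idx)
  trn <- sim_stats(train_idx)
  list(W = probe$W, Wy = probe$Wy, mode = mode, auroc = held$auroc,
       train_auroc = trn$auroc, matched = held$matched,
       mismatched = held$mismatched, train_idx = train_idx)
}

#' Initialize the 4-layer convolutional attention probe
#'
#' 3x3 convolutions: channels -> 64 -> 64 -> 64 -> 1, same-padding; the
#' final L x L map is averaged over its last dimension into L logits and
#' passed through a sigmoid.
#'
#' @param n_channels Input channels (layers x heads of the backbone).
#' @param hidden Conv width (default 64).
#' @param seed Integer seed.
#' @return Probe parameter list.
#' @export
conv_probe <- function(n_channels, hidden = 64L, seed = 1L) {
  set.seed(seed)
  list(c1 = .conv_init(n_channels, hidden), c2 = .conv_init(hidden, hidden),
       c3 = .conv_init(hidden, hidden), c4 = .conv_init(hidden, 1L),
       n_channels = as.integer(n_channels), hidden = as.integer(hidden))
}

#' Forward pass of the attention probe
#'
#' @param stack channels x L x L attention stack ([attention_stack()]).
#' @param probe Probe from [conv_probe()].
#' @param cache Keep intermediates for the backward pass.
#' @return List: `prob` (L probabilities), `logits`, and `cache` if requested.
#' @export
conv_probe_forward <- function(stack, probe, cache = FALSE) {
  L <- dim(stack)[2]
  f1 <- .conv3_fwd(stack, probe$c1$w, probe$c1$b); a1 <- pmax(f1$y, 0)
  f2 <- .conv3_fwd(a1, probe$c2$w, probe$c2$b);    a2 <- pmax(f2$y, 0)
  f3 <- .conv3_fwd(a2, probe$c3$w, probe$c3$b);    a3 <- pmax(f3$y, 0)
  f4 <- .conv3_fwd(a3, probe$c4$w, probe$c4$b)
  logits <- rowMeans(matrix(f4$y[1, , ], L, L))
  out <- list(prob = stats::plogis(logits), logits = logits)
  if (cache) {
    out$cache <- list(stack = stack, f1 = f1, a1 = a1, f2 = f2, a2 = a2,
                      f3 = f3, a3 = a3, f4 = f4, L = L)
  }
  out
}

# gradient of BCE(probe(stack), labels) wrt probe params, one sample
.conv_probe_bwd <- function(dlogits, probe, cc) {
  L <- cc$L
  dy4 <- array(0, c(1L, L, L))
  dy4[1, , ] <- matrix(dlogits / L, L, L)
  b4 <- .conv3_bwd(dy4, cc$f4$cols, probe$c4$w, probe$hidden)
  dy3 <- b4$dx * (cc$f3$y > 0)
  b3 <- .conv3_bwd(dy3, cc$f3$cols, probe$c3$w, probe$hidden)
  dy2 <- b3$dx * (cc$f2$y > 0)
  b2 <- .conv3_bwd(dy2, cc$f2$cols, probe$c2$w, probe$hidden)
  dy1 <- b2$dx * (cc$f1$y > 0)
  b1 <- .conv3_bwd(dy1, cc$f1$cols, probe$c1$w, probe$n_channels)
  list(c1.w = b1$dw, c1.b = b1$db, c2.w = b2$dw, c2.b = b2$db,
       c3.w = b3$dw, c3.b = b3$db, c4.w = b4$dw, c4.b = b4$db)
}

#' Train the frozen-attention convolutional probe
#'
#' AdamW (lr 1e-3, betas 0.9/0.999, weight decay 1e-2), learning rate
#' linearly decayed to zero over `steps` steps at batch `batch` (clipped to
#' the dataset size). Only positions listed in `position_idx` (e.g. the
#' protein rows of a multi-omic input) contribute to the binary
#' cross-entropy.
#'
#' @param stacks List of channels x L x L attention stacks (the backbone
#'   stays frozen; only the probe trains).
#' @param labels List of 0/1 label vectors, one per kept position.
#' @param position_idx List of kept position indices per stack (default all).
#' @param steps,batch,lr Training settings (defaults 1000, 256, 1e-3).
#' @param test_idx Held-out stack indices.
#' @param standardize Z-score each input channel with mean/sd computed over
#'   the training stacks (default TRUE). Attention values live on the
#'   O(1/L) probability scale; standardizing conditions the first
#'   convolution without touching the frozen backbone.
#' @param seed Integer seed.
#' @return List: `probe`, `f1` (held-out, threshold 0.5), `f1_best`
#'   (held-out max over thresholds), `train_f1`, `predictions`.
#' @export
train_conv_probe <- function(stacks, labels, position_idx = NULL,
                             steps = 1000L, batch = 256L, lr = 1e-3,
                             test_idx = integer(0), standardize = TRUE,
                             seed = 1L) {
  n <- length(stacks)
  if (standardize) {
    tr <- setdiff(seq_len(n), test_idx)
    C <- dim(stacks[[1]])[1]
    mu <- numeric(C); sdv <- numeric(C)
    for (ch in seq_len(C)) {
      vals <- unlist(lapply(stacks[tr], function(s) as.vector(s[ch, , ])))
      mu[ch] <- mean(vals)
      sdv[ch] <- max(stats::sd(vals), 1e-8)
    }
    stacks <- lapply(stacks, function(s) {
      for (ch in seq_len(C)) s[ch, , ] <- (s[ch, , ] - mu[ch]) / sdv[ch]
      s
    })
  }
  if (is.null(position_idx)) {
    position_idx <- lapply(stacks, function(s) seq_len(dim(s)[2]))
  }
  if (all(unlist(lapply(labels, function(l) all(l == 0))))) {
    warning("all-negative labels: F1 is undefined and will be reported as 0")
  }
  train_i <- setdiff(seq_len(n), test_idx)
  probe <- conv_probe(dim(stacks[[1]])[1], seed = seed)
  flat <- .own_params(list(c1.w = probe$c1$w, c1.b = probe$c1$b,
                           c2.w = probe$c2$w, c2.b = probe$c2$b,
                           c3.w = probe$c3$w, c3.b = probe$c3$b,
                           c4.w = probe$c4$w, c4.b = probe$c4$b))
  state <- .adam_init(flat)
  set.seed(seed)
  bsz <- min(batch, length(train_i))
  dims <- vapply(stacks, function(s) dim(s)[2], integer(1))
  same_L <- length(unique(dims)) == 1L
  arr <- NULL; labmat <- NULL
  if (same_L) {
    L <- dims[1]; C <- dim(stacks[[1]])[1]
    arr <- array(0, c(n, C, L, L))
    labmat <- matrix(NA_real_, n, L)
    for (i in seq_len(n)) {
      arr[i, , , ] <- stacks[[i]]
      labmat[i, position_idx[[i]]] <- labels[[i]]
    }
  }
  batch_grads <- function(idx) {
    if (same_L) {
      g <- cpp_conv_probe_step(arr[idx, , , , drop = FALSE], length(idx), C, L,
                               probe$c1$w, probe$c1$b, probe$c2$w, probe$c2$b,
                               probe$c3$w, probe$c3$b, probe$c4$w, probe$c4$b,
                               labmat[idx, , drop = FALSE])
      g[c("c1.w", "c1.b", "c2.w", "c2.b", "c3.w", "c3.b", "c4.w", "c4.b")]
    } else {
      grads <- NULL
      for (i in idx) {
        fw <- conv_probe_forward(stacks[[i]], probe, cache = TRUE)
        keep <- position_idx[[i]]
        dlogit <- rep(0, fw$cache$L)
        dlogit[keep] <- (fw$prob[keep] - labels[[i]]) / (length(keep) * length(idx))
        g <- .conv_probe_bwd(dlogit, probe, fw$cache)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads
    }
  }
  for (s in seq_len(steps)) {
    idx <- if (bsz == length(train_i)) train_i else sample(train_i, bsz)
    grads <- batch_grads(idx)
    scale <- 1 - (s - 1) / steps
    upd <- .adam_step(flat, grads, state,
                      stats::setNames(rep(lr, length(flat)), names(flat)),
                      scale, c(0.9, 0.999), 1e-8, 1e-2)
    flat <- upd$params; state <- upd$state
    probe$c1 <- list(w = flat$c1.w, b = flat$c1.b)
    probe$c2 <- list(w = flat$c2.w, b = flat$c2.b)
    probe$c3 <- list(w = flat$c3.w, b = flat$c3.b)
    probe$c4 <- list(w = flat$c4.w, b = flat$c4.b)
  }
  collect <- function(idx) {
    pr <- unlist(lapply(idx, function(i) {
      conv_probe_forward(stacks[[i]], probe)$prob[position_idx[[i]]]
    }))
    list(pred = pr, truth = unlist(labels[idx]))
  }
  f1_at <- function(pred, truth, thr) {
    tp <- sum(pred >= thr & truth == 1); fp <- sum(pred >= thr & truth == 0)
    fn <- sum(pred < thr & truth == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  held <- if (length(test_idx)) collect(test_idx) else NULL
  trn <- collect(train_i)
  list(probe = probe,
       f1 = if (is.null(held)) NA_real_
            else metrics(held$pred, held$truth, "f1"),
       f1_best = if (is.null(held)) NA_real_
                 else max(vapply(seq(0.02, 0.98, by = 0.02),
                                 function(th) f1_at(held$pred, held$truth, th),
                                 numeric(1))),
       train_f1 = metrics(trn$pred, trn$truth, "f1"),
       predictions = held)
}

#' Compare attention probes from two backbone variants
#'
#' Trains identical convolutional probes on attention stacks produced by two
#' model variants (e.g. a dG-fine-tuned model and its base model) over
#' k-fold splits and reports the per-fold F1 difference. A positive mean
#' difference means variant A's attention maps carry more contact
#' information.
#'
#' @param stacks_a,stacks_b Stack lists from the two backbones (same
#'   underlying records).
#' @param labels,position_idx As in [train_conv_probe()].
#' @param n_folds Cross-validation folds (default 5).
#' @param steps,batch,lr,seed Probe training settings.
#' @return Data frame: fold, f1_a, f1_b, delta.
#' @export
compare_attention_probes <- function(stacks_a, stacks_b, labels,
                                     position_idx = NULL, n_folds = 5L,
                                     steps = 1000L, batch = 256L, lr = 1e-3,
                                     seed = 1L) {
  n <- length(stacks_a)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(n_folds), length.out = n))
  rows <- lapply(seq_len(n_folds), function(f) {
    te <- which(fold_of == f)
    fa <- train_conv_probe(stacks_a, labels, position_idx, steps, batch, lr,
                           test_idx = te, seed = seed + f)
    fb <- train_conv_probe(stacks_b, labels, position_idx, steps, batch, lr,
                           test_idx = te, seed = seed + f)
    data.frame(fold = f, f1_a = fa$f1, f1_b = fb$f1, delta = fa$f1 - fb$f1)
  })
  do.call(rbind, rows)
}
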