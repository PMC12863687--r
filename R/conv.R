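# Minimal 3x3 same-padded 2-D convolution (forward + backward) on
# channels x L x L arrays, via im2col so the work lands in BLAS. Shared by
# the attention-map probe and the pairwise contact head.

# Batched im2col for a 3x3 kernel over x (B, C, L, L): returns
# (B*L*L) x (9*C). Rows are grouped by sample, column-major over the grid
# within each sample; column block k (offset order (di, dj) row-major
# -1..1) holds the shifted channel maps.
.im2col3b <- function(x) {
  cpp_im2col3b(x, dim(x)[1], dim(x)[2], dim(x)[3])
}

# inverse scatter for gradients: dcols (B*L*L) x (9*C) -> (B, C, L, L)
.col2im3b <- function(dcols, B, C, L) {
  cpp_col2im3b(dcols, B, C, L)
}

# forward: x (B, C_in, L, L), w ((9*C_in) x C_out), b (C_out)
.conv3_fwdb <- function(x, w, b) {
  B <- dim(x)[1]; L <- dim(x)[3]
  cols <- .im2col3b(x)
  y <- sweep(cols %*% w, 2L, b, "+")
  list(y = aperm(array(y, c(L, L, B, ncol(w))), c(3, 4, 1, 2)), cols = cols)
}

# backward: dy (B, C_out, L, L); returns dx, dw, db
.conv3_bwdb <- function(dy, cols, w, C_in) {
  B <- dim(dy)[1]; L <- dim(dy)[3]
  dY <- matrix(aperm(dy, c(3, 4, 1, 2)), B * L * L, dim(dy)[2])
  dw <- crossprod(cols, dY)
  db <- colSums(dY)
  dx <- .col2im3b(dY %*% t(w), B, C_in, L)
  list(dx = dx, dw = dw, db = db)
}

# single-sample wrappers (x: C x L x L)
.conv3_fwd <- function(x, w, b) {
  r <- .conv3_fwdb(array(x, c(1L, dim(x))), w, b)
  list(y = array(r$y[1, , , ], dim = c(ncol(w), dim(x)[2], dim(x)[3])),
       cols = r$cols)
}

.conv3_bwd <- function(dy, cols, w, C_in) {
  r <- .conv3_bwdb(array(dy, c(1L, dim(dy))), cols, w, C_in)
  list(dx = array(r$dx[1, , , ], dim = c(C_in, dim(dy)[2], dim(dy)[3])),
       dw = r$dw, db = r$db)
}

.conv_init <- function(C_in, C_out, seed_offset = 0) {
  sd <- sqrt(2 / (9 * C_in))
  list(w = matrix(stats::rnorm(9 * C_in * C_out, 0, sd), 9 * C_in, C_out),
       b = rep(0, C_out))
}

#' Initialize the pairwise-feature residual contact head
#'
#' The head projects each position's d-vector to `proj_dim` dimensions,
#' builds the 2*proj_dim x L x L pair tensor (feature i concatenated with
#' feature j), and maps it through an 8-conv-layer residual network
#' (input conv to `channels`, three 2-conv residual blocks, output conv to
#' one channel) whose sigmoid output is the L x L contact probability map.
#'
#' @param d Encoder width.
#' @param proj_dim Per-position projection size (default 128).
#' @param channels Residual trunk width (default 32).
#' @param seed Integer seed.
#' @return Parameter list.
#' @export
pairwise_contact_head <- function(d, proj_dim = 128L, channels = 32L, seed = 1L) {
  set.seed(seed)
  ch <- channels
  list(proj = matrix(stats::rnorm(d * proj_dim, 0, sqrt(1 / d)), d, proj_dim),
       conv_in = .conv_init(2L * proj_dim, ch),
       blocks = lapply(1:3, function(i) list(c1 = .conv_init(ch, ch),
                                             c2 = .conv_init(ch, ch))),
       conv_out = .conv_init(ch, 1L),
       proj_dim = as.integer(proj_dim), channels = as.integer(ch))
}

#' Pairwise contact-map prediction for one protein
#'
#' @param hidden L x d hidden states of the protein's tokens.
#' @param head Head from [pairwise_contact_head()].
#' @return L x L matrix of probabilities in (0, 1); no symmetry is imposed.
#' @export
predict_contact_map <- function(hidden, head) {
  L <- nrow(hidden)
  f <- hidden %*% head$proj                       # L x proj_dim
  pd <- head$proj_dim
  pair <- array(0, c(2L * pd, L, L))
  for (j in seq_len(L)) {
    pair[seq_len(pd), , j] <- t(f)                # feature of i
    pair[pd + seq_len(pd), , j] <- f[j, ]         # feature of j
  }
  a <- .conv3_fwd(pair, head$conv_in$w, head$conv_in$b)$y
  a <- pmax(a, 0)
  for (bl in head$blocks) {
    h1 <- pmax(.conv3_fwd(a, bl$c1$w, bl$c1$b)$y, 0)
    h2 <- .conv3_fwd(h1, bl$c2$w, bl$c2$b)$y
    a <- pmax(a + h2, 0)
  }
  out <- .conv3_fwd(a, head$conv_out$w, head$conv_out$b)$y
  stats::plogis(matrix(out[1, , ], L, L))
}

#' Masked binary cross-entropy for a pairwise contact map
#'
#' The loss is computed only on residue pairs separated by at least
#' `min_separation` residues; an input shorter than `min_separation + 1`
#' masks every pair and is an error.
#'
#' @param prob L x L predicted probabilities.
#' @param truth L x L 0/1 contact labels.
#' @param min_separation Minimum |i - j| (default 12).
#' @return List: `loss`, `mask` (logical L x L), `n_pairs`.
#' @export
contact_map_loss <- function(prob, truth, min_separation = 12L) {
  L <- nrow(prob)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  mask <- sep >= min_separation
  if (!any(mask)) {
    stop(sprintf("no residue pairs with separation >= %d for L = %d",
                 min_separation, L))
  }
  p <- prob[mask]; y <- truth[mask]
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, mask = mask, n_pairs = sum(mask))
}
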