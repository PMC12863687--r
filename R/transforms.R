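# Exact transforms between per-residue and per-token label/prediction space
# for subword (BPE) tokenizations. Spans are the 0-based half-open character
# intervals carried by momlm_tokens; they tile the sequence, so every residue
# belongs to exactly one token.

.check_spans <- function(spans, n_residues = NULL) {
  spans <- as.matrix(spans)
  stopifnot(ncol(spans) == 2L)
  if (nrow(spans) > 0L) {
    stopifnot(all(spans[, 2L] > spans[, 1L]))
    if (nrow(spans) > 1L) {
      stopifnot(all(spans[-1L, 1L] == spans[-nrow(spans), 2L]))
    }
    stopifnot(spans[1L, 1L] == 0L)
  }
  if (!is.null(n_residues)) {
    total <- if (nrow(spans) == 0L) 0L else spans[nrow(spans), 2L]
    if (total != n_residues) {
      stop(sprintf("spans cover %d residues but %d labels supplied",
                   total, n_residues))
    }
  }
  spans
}

# token index (1-based) containing each residue
.residue_to_token <- function(spans) {
  rep(seq_len(nrow(spans)), times = spans[, 2L] - spans[, 1L])
}

#' Aggregate per-residue labels to per-token labels
#'
#' Classification labels take the per-span mode (ties resolved to the lowest
#' class id); regression values take the per-span arithmetic mean. This is
#' the train-time direction: targets are coarsened to match the token grid.
#'
#' @param residue_labels Vector covering every residue of the sequence.
#' @param spans Token spans (n x 2, 0-based half-open).
#' @param task `"classification"` or `"regression"`.
#' @return One label per token.
#' @export
aggregate_to_tokens <- function(residue_labels, spans,
                                task = c("classification", "regression")) {
  task <- match.arg(task)
  spans <- .check_spans(spans, length(residue_labels))
  tok <- .residue_to_token(spans)
  if (task == "regression") {
    as.numeric(tapply(as.numeric(residue_labels), tok, mean))
  } else {
    as.vector(tapply(residue_labels, tok, function(v) {
      tt <- table(v)
      # ties: lowest class id wins (names sort numerically when numeric-like)
      keys <- names(tt)[tt == max(tt)]
      num <- suppressWarnings(as.numeric(keys))
      key <- if (!anyNA(num)) keys[which.min(num)] else sort(keys)[1L]
      if (is.numeric(residue_labels)) as.numeric(key) else key
    }))
  }
}

#' Broadcast per-token values back to residues
#'
#' The test-time direction: each token's value is duplicated over every
#' residue the token contains, producing a prediction of the same length as
#' the per-residue ground truth.
#'
#' @param token_values One value per token.
#' @param spans Token spans (n x 2, 0-based half-open).
#' @return One value per residue.
#' @export
broadcast_to_residues <- function(token_values, spans) {
  spans <- .check_spans(spans)
  if (length(token_values) != nrow(spans)) {
    stop(sprintf("%d token values for %d spans", length(token_values), nrow(spans)))
  }
  rep(token_values, times = spans[, 2L] - spans[, 1L])
}

#' Coarsen a residue-level contact map to token space
#'
#' Token pair (i, j) is a contact iff any residue in token i contacts any
#' residue in token j.
#'
#' @param residue_map Square logical (or 0/1) residue x residue matrix.
#' @param spans Token spans covering the map's residues.
#' @return Logical token x token matrix.
#' @export
contact_map_to_token_space <- function(residue_map, spans) {
  residue_map <- as.matrix(residue_map)
  if (nrow(residue_map) != ncol(residue_map)) stop("contact map must be square")
  spans <- .check_spans(spans, nrow(residue_map))
  tok <- .residue_to_token(spans)
  n_tok <- nrow(spans)
  out <- matrix(FALSE, n_tok, n_tok)
  storage.mode(residue_map) <- "logical"
  # group rows then columns by token via rowsum on the indicator matrix
  rows <- rowsum(residue_map + 0, tok)
  both <- t(rowsum(t(rows), tok))
  out[] <- both > 0
  out
}

#' Token-space mask for excluding short-range contact pairs
#'
#' Token pair (i, j) participates in the loss iff any residue of token i is
#' at least `min_separation` residues away from any residue of token j
#' (the max over residue pairs of |r - s| >= min_separation).
#'
#' @param spans Token spans.
#' @param min_separation Minimum residue separation (default 12).
#' @return Logical token x token matrix, TRUE where the pair is kept.
#' @export
contact_mask_to_token_space <- function(spans, min_separation = 12L) {
  spans <- .check_spans(spans)
  n_tok <- nrow(spans)
  if (n_tok == 0L) return(matrix(logical(0), 0L, 0L))
  lo <- unname(spans[, 1L])    # first residue index in token (0-based)
  hi <- unname(spans[, 2L]) - 1L  # last residue index
  # max |r - s| over r in token i, s in token j = max(hi_j - lo_i, hi_i - lo_j)
  m1 <- outer(hi, lo, function(a, b) a - b)   # hi_i - lo_j
  pmax(m1, t(m1)) >= min_separation
}

#' Expand a token-level contact map to residue space
#'
#' Residue pair (n, m) receives the value of the token pair (i, j) where
#' token i contains residue n and token j contains residue m (block-constant
#' expansion).
#'
#' @param token_map Token x token matrix of values.
#' @param spans Token spans.
#' @return Residue x residue matrix.
#' @export
contact_map_to_residue_space <- function(token_map, spans) {
  token_map <- as.matrix(token_map)
  spans <- .check_spans(spans)
  if (nrow(token_map) != nrow(spans) || ncol(token_map) != nrow(spans)) {
    stop("token map dimensions do not match span count")
  }
  tok <- .residue_to_token(spans)
  token_map[tok, tok, drop = FALSE]
}
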