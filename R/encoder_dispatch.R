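# Dispatch layer between the compiled encoder core (src/encoder_core.cpp)
# and the pure-R reference implementation. The compiled core is the
# production path; the R reference stays for equivalence testing (the two
# are asserted to agree to near machine precision in the test suite).

.encoder_forward <- function(params, config, ids, mask = NULL,
                             want_cache = FALSE, want_attn = TRUE) {
  ids <- rbind(ids)
  storage.mode(ids) <- "integer"
  if (ncol(ids) > config$context_length) {
    stop(sprintf("input of %d tokens exceeds context_length %d; truncate upstream",
                 ncol(ids), config$context_length))
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ids), ncol(ids))
  res <- cpp_encoder_forward(params, unclass(config), ids, mask,
                             want_cache, want_attn)
  cache <- NULL
  if (want_cache) {
    cache <- res$cache
    cache$ids <- ids
  }
  structure(list(hidden = res$hidden, attentions = res$attentions,
                 B = res$B, L = res$L, mask = mask, cache = cache),
            class = "momlm_enc_out")
}

.encoder_backward <- function(dhidden, params, config, cache) {
  grads <- cpp_encoder_backward(dhidden, params, unclass(config), cache,
                                cache$ids)
  # norm gains come back as 1 x d matrices; restore vector shape so the
  # optimizer's matrix-only weight decay rule sees them as vectors
  for (nm in names(grads)) {
    if (grepl("(^|\\.)g(f|1|2)$", nm)) grads[[nm]] <- as.numeric(grads[[nm]])
  }
  grads
}
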