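# Masked-language-model pretraining: AdamW with muP learning-rate groups,
# one-cycle schedule, modality-pure context packing and the 80/10/10
# corruption recipe.

#' Optimizer plan with muP learning-rate groups
#'
#' The embedding/unembedding group trains at the fixed rate 0.05; every
#' other parameter trains at `hidden_lr_base * 32 / width`.
#'
#' @param width Model width (for the 32/width scaling).
#' @param embedding_lr Fixed embedding/unembedding rate (default 0.05).
#' @param hidden_lr_base Base rate for the scaled group (default 0.05).
#' @param adam_betas,adam_eps,weight_decay AdamW settings (defaults 0.9/0.95,
#'   1e-8, 1e-2).
#' @param warmup_tokens One-cycle warmup length in tokens.
#' @param start_end_scale Schedule scale at step 0 and at the final step
#'   (default 1e-5).
#' @return An `momlm_plan` list.
#' @export
optimizer_plan <- function(width, embedding_lr = 0.05, hidden_lr_base = 0.05,
                           adam_betas = c(0.9, 0.95), adam_eps = 1e-8,
                           weight_decay = 1e-2, warmup_tokens = 1e4,
                           start_end_scale = 1e-5) {
  structure(list(embedding_lr = embedding_lr,
                 hidden_lr = hidden_lr_base * 32 / width,
                 adam_betas = adam_betas, adam_eps = adam_eps,
                 weight_decay = weight_decay, warmup_tokens = warmup_tokens,
                 start_end_scale = start_end_scale),
            class = "momlm_plan")
}

# learning rate for a named encoder parameter under a plan
.param_lr <- function(name, plan) {
  if (name %in% c("emb", "unemb")) plan$embedding_lr else plan$hidden_lr
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# Deep copy of a parameter list. The compiled AdamW update mutates the
# parameter and moment vectors in place for speed, so every training loop
# takes ownership of its parameters through this before the first step.
.own_params <- function(params) {
  lapply(params, function(p) p + 0)
}

# One AdamW step (fused, in-place, in the compiled core). lrs: named vector
# of per-parameter learning rates; scale: schedule multiplier. Weight decay
# applies to matrices only (norm gains are left undecayed). `params` and
# `state` MUST be owned by the caller (see .own_params); both are mutated.
.adam_step <- function(params, grads, state, lrs, scale, betas, eps, wd) {
  state$t <- state$t + 1L
  decay <- vapply(names(grads), function(nm) !is.null(dim(params[[nm]])),
                  logical(1))
  cpp_adam_step_inplace(params, grads, state$m, state$v, state$t,
                        lrs[names(grads)], scale, betas[1], betas[2], eps, wd,
                        decay)
  list(params = params, state = state)
}

#' One-cycle learning-rate scale
#'
#' Cosine ramp from `floor` to 1 over the warmup, cosine decay back to
#' `floor` at `total_steps`; so scale(0) = floor, scale(warmup) = 1,
#' scale(total) = floor, monotone up then down.
#'
#' @param step Current step (0-based; clamped into range with a warning).
#' @param total_steps,warmup_steps Schedule shape.
#' @param floor Start/end scale (default 1e-5).
#' @return Scalar multiplier in `[floor, 1]`.
#' @export
lr_schedule <- function(step, total_steps, warmup_steps, floor = 1e-5) {
  if (step < 0 || step > total_steps) {
    warning("step outside [0, total_steps]; clamping")
    step <- min(max(step, 0), total_steps)
  }
  if (step <= warmup_steps) {
    frac <- if (warmup_steps == 0) 1 else step / warmup_steps
    floor + (1 - floor) * (1 - cos(pi * frac)) / 2
  } else {
    frac <- (step - warmup_steps) / (total_steps - warmup_steps)
    floor + (1 - floor) * (1 + cos(pi * frac)) / 2
  }
}

#' Build a masked-language-modeling batch
#'
#' Packs same-modality sequences into context rows (a leading cls, sequences
#' separated by the modality's sep, overlong sequences truncated), then
#' corrupts non-special positions at rate `mask_rate`, split 80% mask-token /
#' 10% random in-modality piece / 10% unchanged. Rows never mix ids from the
#' two modality ranges.
#'
#' @param pool List of `momlm_tokens` (both modalities allowed).
#' @param vocabs Vocabulary pair from [train_vocab_pair()].
#' @param context_length Maximum row length.
#' @param batch_tokens Target token count (the pool is recycled with
#'   reshuffling if needed).
#' @param mask_rate Corruption rate m (default 0.15).
#' @param frac_mask,frac_random Corruption mix (defaults 0.8 / 0.1; the
#'   remainder is left unchanged).
#' @param seed Integer seed.
#' @return An `momlm_mlm_batch`: input_ids, target_ids (B x L matrices),
#'   loss_mask, attn_mask (B x L logical), modality (per row).
#' @export
make_mlm_batch <- function(pool, vocabs, context_length = 128L,
                           batch_tokens = 2048L, mask_rate = 0.15,
                           frac_mask = 0.8, frac_random = 0.1, seed = 1L) {
  if (length(pool) == 0L) stop("empty sequence pool")
  set.seed(seed)
  rows <- list(); row_mod <- character(0)
  open <- list(nucleic = NULL, protein = NULL)
  total <- 0L
  flush_row <- function(m) {
    if (!is.null(open[[m]]) && length(open[[m]]) > 1L) {
      rows[[length(rows) + 1L]] <<- open[[m]]
      row_mod[length(rows)] <<- m
      total <<- total + length(open[[m]])
    }
    open[[m]] <<- NULL
  }
  order_idx <- sample(length(pool))
  i <- 0L
  while (total < batch_tokens) {
    i <- i + 1L
    if (i > length(order_idx)) {  # recycle with a fresh shuffle
      order_idx <- sample(length(pool))
      i <- 1L
    }
    tk <- pool[[order_idx[i]]]
    m <- tk$modality
    v <- vocabs[[m]]
    ids <- tk$ids
    if (length(ids) > context_length - 2L) ids <- ids[seq_len(context_length - 2L)]
    if (is.null(open[[m]])) open[[m]] <- v$special_ids$cls
    if (length(open[[m]]) + length(ids) + 1L > context_length) {
      flush_row(m)
      open[[m]] <- v$special_ids$cls
    }
    open[[m]] <- c(open[[m]], ids, v$special_ids$sep)
  }
  flush_row("nucleic"); flush_row("protein")
  B <- length(rows); L <- max(lengths(rows))
  input <- matrix(0L, B, L); attn <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    v <- vocabs[[row_mod[b]]]
    input[b, ] <- v$special_ids$pad
    input[b, seq_along(rows[[b]])] <- rows[[b]]
    attn[b, seq_along(rows[[b]])] <- TRUE
  }
  target <- input
  loss_mask <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    v <- vocabs[[row_mod[b]]]
    lo <- v$id_offset; hi <- v$id_offset + length(v$pieces) - 1L
    eligible <- which(attn[b, ] & input[b, ] >= lo & input[b, ] <= hi)
    if (length(eligible) == 0L) next
    hit <- eligible[stats::runif(length(eligible)) < mask_rate]
    if (length(hit) == 0L) next
    u <- stats::runif(length(hit))
    to_mask <- hit[u < frac_mask]
    to_rand <- hit[u >= frac_mask & u < frac_mask + frac_random]
    input[b, to_mask] <- v$special_ids$mask
    if (length(to_rand) > 0L) {
      input[b, to_rand] <- sample(lo:hi, length(to_rand), replace = TRUE)
    }
    loss_mask[b, hit] <- TRUE
  }
  structure(list(input_ids = input, target_ids = target, loss_mask = loss_mask,
                 attn_mask = attn, modality = row_mod),
            class = "momlm_mlm_batch")
}

# MLM loss + full gradient for one batch.
.mlm_step_grads <- function(params, config, batch) {
  out <- .encoder_forward(params, config, batch$input_ids, batch$attn_mask,
                          want_cache = TRUE, want_attn = FALSE)
  logits <- out$hidden %*% params$unemb
  sel <- as.logical(t(batch$loss_mask))
  tgt <- as.integer(t(batch$target_ids))
  ce <- .masked_ce(logits, tgt, sel)
  dhidden <- tcrossprod(ce$dlogits, params$unemb)
  grads <- .encoder_backward(dhidden, params, config, out$cache)
  grads$unemb <- crossprod(out$hidden, ce$dlogits)
  list(loss = ce$loss, grads = grads)
}

#' MLM loss of a batch under given parameters (no gradient)
#' @param params,config Encoder parameters and config.
#' @param batch An `momlm_mlm_batch`.
#' @return Mean cross-entropy over the corrupted positions.
#' @export
mlm_loss <- function(params, config, batch) {
  out <- .encoder_forward(params, config, batch$input_ids, batch$attn_mask,
                          want_attn = FALSE)
  logits <- out$hidden %*% params$unemb
  .masked_ce(logits, as.integer(t(batch$target_ids)),
             as.logical(t(batch$loss_mask)))$loss
}

#' Pretrain an encoder with masked language modeling
#'
#' @param pool List of `momlm_tokens` (the tokenized corpus).
#' @param config `momlm_config`.
#' @param vocabs Vocabulary pair.
#' @param plan `momlm_plan` from [optimizer_plan()].
#' @param budget_tokens Total training tokens (steps =
#'   ceil(budget / batch_tokens); a budget below one step leaves the
#'   parameters untouched).
#' @param batch_tokens Tokens per optimizer step.
#' @param mask_rate MLM corruption rate.
#' @param seed Integer seed; runs are bitwise reproducible.
#' @param params Optional initial parameters (default [init_encoder()]).
#' @param context_length Packing length (default `config$context_length`).
#' @return List: `params` (trained), `trace` (data frame step/tokens/loss),
#'   `config`.
#' @export
pretrain <- function(pool, config, vocabs, plan, budget_tokens = 1e5,
                     batch_tokens = 2048L, mask_rate = 0.15, seed = 1L,
                     params = NULL, context_length = NULL) {
  if (length(pool) == 0L) stop("empty corpus")
  if (is.null(params)) params <- init_encoder(config, seed = seed)
  params <- .own_params(params)        # in-place optimizer: take ownership
  if (is.null(context_length)) context_length <- config$context_length
  steps <- floor(budget_tokens / batch_tokens)
  if (steps < 1L) {
    return(list(params = params,
                trace = data.frame(step = integer(0), tokens = numeric(0),
                                   loss = numeric(0)),
                config = config))
  }
  warmup_steps <- min(steps, max(1L, round(plan$warmup_tokens / batch_tokens)))
  state <- .adam_init(params)
  lrs <- vapply(names(params), .param_lr, numeric(1), plan = plan)
  set.seed(seed)
  step_seeds <- sample.int(.Machine$integer.max - 1L, steps)
  trace <- data.frame(step = seq_len(steps), tokens = NA_real_, loss = NA_real_)
  tokens_seen <- 0
  for (s in seq_len(steps)) {
    batch <- make_mlm_batch(pool, vocabs, context_length, batch_tokens,
                            mask_rate = mask_rate, seed = step_seeds[s])
    res <- .mlm_step_grads(params, config, batch)
    if (!is.finite(res$loss)) {
      stop(sprintf("divergence: non-finite MLM loss at step %d", s))
    }
    scale <- lr_schedule(s - 1L, steps, warmup_steps, plan$start_end_scale)
    upd <- .adam_step(params, res$grads, state, lrs, scale,
                      plan$adam_betas, plan$adam_eps, plan$weight_decay)
    params <- upd$params; state <- upd$state
    tokens_seen <- tokens_seen + sum(batch$attn_mask)
    trace$tokens[s] <- tokens_seen
    trace$loss[s] <- res$loss
  }
  list(params = params, trace = trace, config = config)
}

#' Write a pretraining loss trace as CSV
#' @param trace Trace data frame from [pretrain()].
#' @param path Output file.
#' @export
write_loss_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Save / load encoder checkpoints as text
#'
#' Flat named-parameter archive (one `## name dims` header per parameter,
#' values in scientific text) with a JSON config sidecar.
#'
#' @param params,config Model to save.
#' @param path Checkpoint file path (config goes to `<path>.json`).
#' @export
save_checkpoint <- function(params, config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params)) {
    p <- params[[nm]]
    dims <- if (is.null(dim(p))) c(length(p), 1L) else dim(p)
    writeLines(sprintf("## %s %d %d", nm, dims[1], dims[2]), con)
    writeLines(paste(format(as.numeric(p), digits = 17), collapse = " "), con)
  }
  jsonlite::write_json(unclass(config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: list with `params` and `config`.
#' @export
load_checkpoint <- function(path) {
  lines <- readLines(path)
  heads <- grep("^## ", lines)
  params <- list()
  for (k in seq_along(heads)) {
    hdr <- strsplit(lines[heads[k]], " ")[[1]]
    toks <- strsplit(trimws(lines[heads[k] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks)
    nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
    params[[hdr[2]]] <- if (nc == 1L && grepl("^g", basename(hdr[2]))) vals
                        else matrix(vals, nr, nc)
  }
  cfgl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- structure(cfgl, class = "momlm_config")
  # gains are stored as n x 1; restore vector shape where params expect it
  for (nm in names(params)) {
    if (grepl("(^|\\.)g[12f]?$", nm) && !is.null(dim(params[[nm]]))) {
      params[[nm]] <- as.numeric(params[[nm]])
    }
  }
  list(params = params, config = config)
}
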