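# Task heads and fine-tuning: binding free-energy regression from the
# first-token embedding, per-residue contact tagging, sequence
# classification, the pairwise-feature ResNet contact map, and the
# dual-encoder single-omic control for dG.

#' Tokenize one complex record into the multi-omic input layout
#'
#' `[cls] protein tokens [sep] nucleic tokens ([sep] second nucleic tokens)`.
#' Protein tokens come from the protein vocabulary, nucleic tokens from the
#' nucleic vocabulary; the leading cls is the pooled "first token". If the
#' layout exceeds `context_length` the nucleic tail is truncated (never the
#' protein) with a warning.
#'
#' @param record One-row data frame (or list) with `protein_seq`,
#'   `nucleic_seq_1`, optional `nucleic_seq_2`.
#' @param vocabs Vocabulary pair from [train_vocab_pair()].
#' @param context_length Maximum token count (default Inf).
#' @return A `momlm_tokens` with extra fields `segments` (one of cls,
#'   protein, sep, nucleic1, nucleic2 per token) and `protein_spans` (the
#'   protein tokens' character spans).
#' @export
build_multiomic_input <- function(record, vocabs, context_length = Inf) {
  pseq <- record$protein_seq; n1 <- record$nucleic_seq_1
  n2 <- record$nucleic_seq_2
  if (is.null(pseq) || is.na(pseq) || nchar(pseq) == 0L) stop("empty protein")
  if (is.null(n1) || is.na(n1) || nchar(n1) == 0L) stop("empty nucleic sequence")
  vp <- vocabs$protein; vn <- vocabs$nucleic
  tp <- encode(pseq, vp)
  t1 <- encode(n1, vn)
  ids <- c(vp$special_ids$cls, tp$ids, vp$special_ids$sep, t1$ids)
  segments <- c("cls", rep("protein", length(tp$ids)), "sep",
                rep("nucleic1", length(t1$ids)))
  if (!is.null(n2) && !is.na(n2) && nchar(n2) > 0L) {
    t2 <- encode(n2, vn)
    ids <- c(ids, vn$special_ids$sep, t2$ids)
    segments <- c(segments, "sep", rep("nucleic2", length(t2$ids)))
  }
  if (length(ids) > context_length) {
    n_prot_part <- 2L + length(tp$ids)
    if (n_prot_part >= context_length) {
      stop("protein alone exceeds the context length")
    }
    warning(sprintf("truncating nucleic tail: %d -> %d tokens",
                    length(ids), context_length))
    ids <- ids[seq_len(context_length)]
    segments <- segments[seq_len(context_length)]
  }
  structure(list(ids = ids, segments = segments, modality = "multi",
                 protein_spans = tp$spans,
                 spans = NULL),
            class = "momlm_tokens")
}

#' Initialize a linear regression head
#' @param d Input width.
#' @param bias Initial bias (set it to the train-label mean for fast
#'   convergence).
#' @return List with `w` (d-vector, zero) and `b`.
#' @export
regression_head <- function(d, bias = 0) {
  list(w = rep(0, d), b = bias)
}

#' Predict binding free energy for one record
#'
#' @param params,config Encoder.
#' @param head Regression head (`w`, `b`).
#' @param record Complex record (protein + 1-2 nucleic sequences).
#' @param vocabs Vocabulary pair.
#' @return Predicted dG, kcal/mol.
#' @export
predict_dG <- function(params, config, head, record, vocabs) {
  tk <- build_multiomic_input(record, vocabs, config$context_length)
  out <- .encoder_forward(params, config,
                          matrix(tk$ids, nrow = 1L), want_attn = FALSE)
  sum(pooled_embedding(out)[1, ] * head$w) + head$b
}

# forward a batch of ragged id vectors, returning enc_out (padded)
.forward_idlist <- function(params, config, idlist, pad_id, want_cache = FALSE) {
  lens <- lengths(idlist)
  L <- max(lens); B <- length(idlist)
  ids <- matrix(as.integer(pad_id), B, L)
  mask <- matrix(FALSE, B, L)
  for (i in seq_len(B)) {
    ids[i, seq_len(lens[i])] <- idlist[[i]]
    mask[i, seq_len(lens[i])] <- TRUE
  }
  .encoder_forward(params, config, ids, mask, want_cache = want_cache,
                   want_attn = FALSE)
}

# generic fine-tuning Adam loop over minibatches; step_fn(params, heads,
# batch_idx, do_grads) must return list(loss, grads, hgrads). `heads` is a
# named list of head parameter lists.
.finetune_loop <- function(params, heads, n_records, epochs, batch, lr_of,
                           lr_head, step_fn, seed, plan) {
  params <- .own_params(params)        # in-place optimizer: take ownership
  heads <- lapply(heads, .own_params)
  state <- .adam_init(params)
  hstate <- .adam_init(unlist(heads, recursive = FALSE))
  steps_per_epoch <- max(1L, ceiling(n_records / batch))
  total_steps <- epochs * steps_per_epoch
  warmup <- max(1L, round(0.3 * total_steps))
  set.seed(seed)
  step <- 0L
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(n_records)
    for (sb in seq_len(steps_per_epoch)) {
      idx <- ord[((sb - 1L) * batch + 1L):min(sb * batch, n_records)]
      res <- step_fn(params, heads, idx)
      scale <- lr_schedule(step, total_steps, warmup, 1e-5)
      step <- step + 1L
      upd <- .adam_step(params, res$grads, state, lr_of, scale,
                        plan$adam_betas, plan$adam_eps, plan$weight_decay)
      params <- upd$params; state <- upd$state
      hflat <- unlist(heads, recursive = FALSE)
      hlrs <- stats::setNames(rep(lr_head, length(hflat)), names(hflat))
      hupd <- .adam_step(hflat, res$hgrads, hstate, hlrs, scale,
                         plan$adam_betas, plan$adam_eps, plan$weight_decay)
      hstate <- hupd$state
      for (nm in names(hupd$params)) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
        heads[[parts[1]]][[parts[2]]] <- hupd$params[[nm]]
      }
      losses <- c(losses, res$loss)
    }
  }
  list(params = params, heads = heads, losses = losses)
}

# per-parameter fine-tuning lrs: embeddings 1e-3, body 1e-4 * 1024 / width
.ft_lrs <- function(params, width, lr_emb = 1e-3, lr_body_base = 1e-4) {
  vapply(names(params), function(nm) {
    if (nm %in% c("emb", "unemb")) lr_emb else lr_body_base * 1024 / width
  }, numeric(1))
}

.ft_plan <- function() {
  structure(list(adam_betas = c(0.9, 0.95), adam_eps = 1e-8,
                 weight_decay = 1e-2), class = "momlm_plan")
}

#' Fine-tune the joint encoder for binding free-energy regression
#'
#' Mean-squared-error training of the encoder plus a linear head on the
#' first-token embedding, with the three learning-rate groups (head 1e-2,
#' embeddings 1e-3, remaining parameters 1e-4 * 1024/width), all one-cycle
#' decayed. Evaluation is on the held-out complexes of each requested fold.
#'
#' @param params,config Pretrained encoder.
#' @param dataset `momlm_complexes` with a `dG` column.
#' @param folds `momlm_folds` from [build_folds()].
#' @param vocabs Vocabulary pair.
#' @param epochs,batch Training length (defaults 64 / 256).
#' @param lr_head,lr_emb,lr_body_base Learning-rate groups.
#' @param folds_to_run Integer vector of fold ids (default: all).
#' @param seed Integer seed.
#' @param train_idx Optional explicit train-record indices (overrides the
#'   fold complement; lets a unit test deliberately allow train/test
#'   leakage to check capacity).
#' @return List: `metrics` (data frame fold/pcc/mae), `model` (trained
#'   params + head of the last fold run), `predictions` (pooled out-of-fold
#'   predictions over all folds run).
#' @export
finetune_dG <- function(params, config, dataset, folds, vocabs, epochs = 64L,
                        batch = 256L, lr_head = 1e-2, lr_emb = 1e-3,
                        lr_body_base = 1e-4, folds_to_run = NULL, seed = 1L,
                        train_idx = NULL) {
  idlist <- lapply(seq_len(nrow(dataset)), function(i) {
    build_multiomic_input(dataset[i, ], vocabs, config$context_length)$ids
  })
  pad_id <- vocabs$nucleic$special_ids$pad
  y_all <- dataset$dG
  if (is.null(folds_to_run)) folds_to_run <- seq_len(folds$n_folds)
  lr_of <- .ft_lrs(params, config$width, lr_emb, lr_body_base)
  plan <- .ft_plan()
  res_rows <- list(); model <- NULL
  preds_out <- data.frame(fold = integer(0), record = integer(0),
                          pred = numeric(0), truth = numeric(0))
  for (f in folds_to_run) {
    test_i <- which(!is.na(folds$fold_of_record) & folds$fold_of_record == f)
    train_i <- if (is.null(train_idx)) setdiff(seq_len(nrow(dataset)), test_i)
               else train_idx
    if (length(test_i) == 0L) stop(sprintf("fold %d has no test records", f))
    p <- params
    heads <- list(reg = regression_head(config$width, bias = mean(y_all[train_i])))
    step_fn <- function(p_cur, h_cur, idx) {
      sub <- train_i[idx]
      out <- .forward_idlist(p_cur, config, idlist[sub], pad_id, want_cache = TRUE)
      pooled <- pooled_embedding(out)
      pred <- as.numeric(pooled %*% h_cur$reg$w) + h_cur$reg$b
      err <- pred - y_all[sub]
      loss <- mean(err^2)
      dpred <- 2 * err / length(err)
      dh <- out$hidden * 0
      cls_rows <- (seq_len(out$B) - 1L) * out$L + 1L
      dh[cls_rows, ] <- outer(dpred, h_cur$reg$w)
      grads <- .encoder_backward(dh, p_cur, config, out$cache)
      grads$unemb <- p_cur$unemb * 0
      hg <- list(reg.w = as.numeric(crossprod(pooled, dpred)),
                 reg.b = sum(dpred))
      list(loss = loss, grads = grads, hgrads = hg)
    }
    fit <- .finetune_loop(p, heads, length(train_i), epochs,
                          min(batch, length(train_i)), lr_of, lr_head,
                          step_fn, seed + f, plan)
    # held-out evaluation
    out <- .forward_idlist(fit$params, config, idlist[test_i], pad_id)
    preds <- as.numeric(pooled_embedding(out) %*% fit$heads$reg$w) +
      fit$heads$reg$b
    res_rows[[length(res_rows) + 1L]] <- data.frame(
      fold = f,
      pcc = metrics(preds, y_all[test_i], "pcc"),
      mae = metrics(preds, y_all[test_i], "mae"))
    model <- list(params = fit$params, head = fit$heads$reg, config = config,
                  losses = fit$losses)
    preds_out <- rbind(preds_out,
                       data.frame(fold = f, record = test_i, pred = preds,
                                  truth = y_all[test_i]))
  }
  list(metrics = do.call(rbind, res_rows), model = model,
       predictions = preds_out)
}

#' Dual-encoder single-omic control for dG regression
#'
#' Encodes the protein with a protein-only encoder and the nucleic sequences
#' with a nucleic-only encoder, concatenates the two first-token embeddings
#' and applies a linear head. Both encoders are fine-tuned end-to-end with
#' the same learning-rate groups as the joint model.
#'
#' @param prot_params,nuc_params Single-omic encoder parameters.
#' @param config Shared encoder configuration.
#' @param dataset,folds,vocabs,epochs,batch,lr_head,lr_emb,lr_body_base,seed
#'   As in [finetune_dG()].
#' @param folds_to_run Folds to train/evaluate.
#' @return Same shape as [finetune_dG()].
#' @export
finetune_dG_dual <- function(prot_params, nuc_params, config, dataset, folds,
                             vocabs, epochs = 64L, batch = 256L,
                             lr_head = 1e-2, lr_emb = 1e-3,
                             lr_body_base = 1e-4, folds_to_run = NULL,
                             seed = 1L) {
  vp <- vocabs$protein; vn <- vocabs$nucleic
  plist <- lapply(dataset$protein_seq, function(s) {
    c(vp$special_ids$cls, encode(s, vp)$ids)
  })
  nlist <- lapply(seq_len(nrow(dataset)), function(i) {
    ids <- c(vn$special_ids$cls, encode(dataset$nucleic_seq_1[i], vn)$ids)
    n2 <- dataset$nucleic_seq_2[i]
    if (!is.na(n2) && nchar(n2) > 0L) {
      ids <- c(ids, vn$special_ids$sep, encode(n2, vn)$ids)
    }
    ids
  })
  y_all <- dataset$dG
  if (is.null(folds_to_run)) folds_to_run <- seq_len(folds$n_folds)
  d <- config$width
  plan <- .ft_plan()
  # one flat parameter list with prefixes so a single Adam state serves both
  tag <- function(pp, pre) stats::setNames(pp, paste0(pre, names(pp)))
  res_rows <- list(); model <- NULL
  for (f in folds_to_run) {
    test_i <- which(!is.na(folds$fold_of_record) & folds$fold_of_record == f)
    train_i <- setdiff(seq_len(nrow(dataset)), test_i)
    both <- c(tag(prot_params, "P."), tag(nuc_params, "N."))
    lr_of <- c(stats::setNames(.ft_lrs(prot_params, d), paste0("P.", names(prot_params))),
               stats::setNames(.ft_lrs(nuc_params, d), paste0("N.", names(nuc_params))))
    heads <- list(reg = list(w = rep(0, 2 * d), b = mean(y_all[train_i])))
    split_params <- function(bp) {
      list(p = stats::setNames(bp[grep("^P\\.", names(bp))],
                               sub("^P\\.", "", names(bp)[grep("^P\\.", names(bp))])),
           n = stats::setNames(bp[grep("^N\\.", names(bp))],
                               sub("^N\\.", "", names(bp)[grep("^N\\.", names(bp))])))
    }
    step_fn <- function(bp, h_cur, idx) {
      sp <- split_params(bp)
      sub <- train_i[idx]
      outp <- .forward_idlist(sp$p, config, plist[sub], vp$special_ids$pad,
                              want_cache = TRUE)
      outn <- .forward_idlist(sp$n, config, nlist[sub], vn$special_ids$pad,
                              want_cache = TRUE)
      pooled <- cbind(pooled_embedding(outp), pooled_embedding(outn))
      pred <- as.numeric(pooled %*% h_cur$reg$w) + h_cur$reg$b
      err <- pred - y_all[sub]
      dpred <- 2 * err / length(err)
      dhp <- outp$hidden * 0
      dhn <- outn$hidden * 0
      dhp[(seq_len(outp$B) - 1L) * outp$L + 1L, ] <-
        outer(dpred, h_cur$reg$w[seq_len(d)])
      dhn[(seq_len(outn$B) - 1L) * outn$L + 1L, ] <-
        outer(dpred, h_cur$reg$w[d + seq_len(d)])
      gp <- .encoder_backward(dhp, sp$p, config, outp$cache)
      gn <- .encoder_backward(dhn, sp$n, config, outn$cache)
      gp$unemb <- sp$p$unemb * 0; gn$unemb <- sp$n$unemb * 0
      grads <- c(tag(gp, "P."), tag(gn, "N."))
      hg <- list(reg.w = as.numeric(crossprod(pooled, dpred)),
                 reg.b = sum(dpred))
      list(loss = mean(err^2), grads = grads, hgrads = hg)
    }
    fit <- .finetune_loop(both, heads, length(train_i), epochs,
                          min(batch, length(train_i)), lr_of, lr_head,
                          step_fn, seed + f, plan)
    sp <- split_params(fit$params)
    outp <- .forward_idlist(sp$p, config, plist[test_i], vp$special_ids$pad)
    outn <- .forward_idlist(sp$n, config, nlist[test_i], vn$special_ids$pad)
    pooled <- cbind(pooled_embedding(outp), pooled_embedding(outn))
    preds <- as.numeric(pooled %*% fit$heads$reg$w) + fit$heads$reg$b
    res_rows[[length(res_rows) + 1L]] <- data.frame(
      fold = f, pcc = metrics(preds, y_all[test_i], "pcc"),
      mae = metrics(preds, y_all[test_i], "mae"))
    model <- list(prot_params = sp$p, nuc_params = sp$n,
                  head = fit$heads$reg, config = config)
  }
  list(metrics = do.call(rbind, res_rows), model = model)
}

#' Per-residue contact probabilities for one record
#'
#' Applies the tagging head (linear projection to one scalar + sigmoid) to
#' the hidden states of the protein positions of the multi-omic input. With
#' a byte-pair vocabulary the per-token probabilities are broadcast back to
#' residues via the protein token spans.
#'
#' @param params,config Encoder.
#' @param head Tagging head (`w`, `b`).
#' @param record Complex record.
#' @param vocabs Vocabulary pair.
#' @return Numeric vector of per-residue contact probabilities (protein
#'   length).
#' @export
predict_contacts_per_residue <- function(params, config, head, record, vocabs) {
  tk <- build_multiomic_input(record, vocabs, config$context_length)
  out <- .encoder_forward(params, config, matrix(tk$ids, nrow = 1L),
                          want_attn = FALSE)
  rows <- which(tk$segments == "protein")
  probs_tok <- stats::plogis(as.numeric(out$hidden[rows, , drop = FALSE] %*% head$w) +
                               head$b)
  broadcast_to_residues(probs_tok, tk$protein_spans)
}

#' Fine-tune the encoder for per-residue contact tagging
#'
#' Binary cross-entropy over protein positions only (the nucleic tokens take
#' part in the forward pass but receive no predictions), 32 epochs at batch
#' 256 by default, with the dG learning-rate groups. Per-residue labels are
#' aggregated to token space (mode) when the vocabulary is subword.
#'
#' @param params,config Pretrained encoder.
#' @param dataset `momlm_complexes` with a `contact_labels` attribute.
#' @param vocabs Vocabulary pair.
#' @param epochs,batch,lr_head,lr_emb,lr_body_base,seed Training settings.
#' @param test_idx Records held out for evaluation (default none).
#' @return List: `model` (params + head), `f1` (held-out F1, NA if no test
#'   set), `train_f1`.
#' @export
finetune_contact <- function(params, config, dataset, vocabs, epochs = 32L,
                             batch = 256L, lr_head = 1e-2, lr_emb = 1e-3,
                             lr_body_base = 1e-4, seed = 1L, test_idx = integer(0)) {
  labels <- attr(dataset, "contact_labels")
  if (is.null(labels)) stop("dataset has no contact labels")
  n <- nrow(dataset)
  toks <- lapply(seq_len(n), function(i) {
    build_multiomic_input(dataset[i, ], vocabs, config$context_length)
  })
  tok_labels <- lapply(seq_len(n), function(i) {
    aggregate_to_tokens(as.integer(labels[[i]]), toks[[i]]$protein_spans,
                        "classification") >= 1
  })
  pad_id <- vocabs$nucleic$special_ids$pad
  train_i <- setdiff(seq_len(n), test_idx)
  lr_of <- .ft_lrs(params, config$width, lr_emb, lr_body_base)
  heads <- list(tag = regression_head(config$width))
  idlist <- lapply(toks, `[[`, "ids")
  step_fn <- function(p_cur, h_cur, idx) {
    sub <- train_i[idx]
    out <- .forward_idlist(p_cur, config, idlist[sub], pad_id, want_cache = TRUE)
    dh <- out$hidden * 0
    loss_total <- 0; n_pos <- 0L
    hw_acc <- rep(0, config$width); hb_acc <- 0
    for (bi in seq_along(sub)) {
      i <- sub[bi]
      rows <- (bi - 1L) * out$L + which(toks[[i]]$segments == "protein")
      z <- as.numeric(out$hidden[rows, , drop = FALSE] %*% h_cur$tag$w) + h_cur$tag$b
      pr <- stats::plogis(z)
      yy <- as.numeric(tok_labels[[i]])
      loss_total <- loss_total - sum(yy * log(pmax(pr, 1e-12)) +
                                       (1 - yy) * log(pmax(1 - pr, 1e-12)))
      dz <- (pr - yy)
      dh[rows, ] <- dh[rows, ] + outer(dz, h_cur$tag$w)
      n_pos <- n_pos + length(z)
      hw_acc <- hw_acc + as.numeric(crossprod(out$hidden[rows, , drop = FALSE], dz))
      hb_acc <- hb_acc + sum(dz)
    }
    dh <- dh / n_pos
    grads <- .encoder_backward(dh, p_cur, config, out$cache)
    grads$unemb <- p_cur$unemb * 0
    list(loss = loss_total / n_pos,
         grads = grads,
         hgrads = list(tag.w = hw_acc / n_pos, tag.b = hb_acc / n_pos))
  }
  fit <- .finetune_loop(params, heads, length(train_i), epochs,
                        min(batch, length(train_i)), lr_of, lr_head,
                        step_fn, seed, .ft_plan())
  eval_f1 <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    preds <- unlist(lapply(idx, function(i) {
      predict_contacts_per_residue(fit$params, config, fit$heads$tag,
                                   dataset[i, ], vocabs)
    }))
    truth <- unlist(labels[idx])
    metrics(preds, as.numeric(truth), "f1")
  }
  list(model = list(params = fit$params, head = fit$heads$tag, config = config),
       f1 = eval_f1(test_idx), train_f1 = eval_f1(train_i))
}

#' Fine-tune a sequence classification head
#'
#' Softmax classification from the first-token embedding (linear projection
#' to `n_classes`), cross-entropy loss, same learning-rate groups as the
#' regression task. A generic harness for label-per-sequence tasks.
#'
#' @param params,config Pretrained encoder.
#' @param tokens_list List of `momlm_tokens` (or id vectors), one per example.
#' @param y Integer class labels (1-based).
#' @param n_classes Number of classes.
#' @param pad_id Pad id for ragged batches.
#' @param epochs,batch,lr_head,lr_emb,lr_body_base,seed Training settings.
#' @param test_idx Held-out examples.
#' @return List: `model`, `accuracy` (held-out, NA if none), `train_accuracy`.
#' @export
finetune_classify <- function(params, config, tokens_list, y, n_classes,
                              pad_id, epochs = 8L, batch = 32L,
                              lr_head = 1e-2, lr_emb = 1e-3,
                              lr_body_base = 1e-4, seed = 1L,
                              test_idx = integer(0)) {
  idlist <- lapply(tokens_list, function(t) {
    if (inherits(t, "momlm_tokens")) t$ids else as.integer(t)
  })
  n <- length(idlist)
  train_i <- setdiff(seq_len(n), test_idx)
  d <- config$width
  heads <- list(cls = list(w = matrix(0, d, n_classes), b = rep(0, n_classes)))
  lr_of <- .ft_lrs(params, d, lr_emb, lr_body_base)
  step_fn <- function(p_cur, h_cur, idx) {
    sub <- train_i[idx]
    out <- .forward_idlist(p_cur, config, idlist[sub], pad_id, want_cache = TRUE)
    pooled <- pooled_embedding(out)
    logits <- sweep(pooled %*% h_cur$cls$w, 2L, h_cur$cls$b, "+")
    ce <- .masked_ce(logits, y[sub] - 1L, rep(TRUE, length(sub)))
    dh <- out$hidden * 0
    dh[(seq_len(out$B) - 1L) * out$L + 1L, ] <- ce$dlogits %*% t(h_cur$cls$w)
    grads <- .encoder_backward(dh, p_cur, config, out$cache)
    grads$unemb <- p_cur$unemb * 0
    list(loss = ce$loss, grads = grads,
         hgrads = list(cls.w = crossprod(pooled, ce$dlogits),
                       cls.b = colSums(ce$dlogits)))
  }
  fit <- .finetune_loop(params, heads, length(train_i), epochs,
                        min(batch, length(train_i)), lr_of, lr_head,
                        step_fn, seed, .ft_plan())
  predict_cls <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    out <- .forward_idlist(fit$params, config, idlist[idx], pad_id)
    logits <- sweep(pooled_embedding(out) %*% fit$heads$cls$w, 2L,
                    fit$heads$cls$b, "+")
    mean(max.col(logits) == y[idx])
  }
  list(model = list(params = fit$params, head = fit$heads$cls, config = config),
       accuracy = predict_cls(test_idx), train_accuracy = predict_cls(train_i))
}
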