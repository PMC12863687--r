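make_pool <- function(n_nuc = 15, n_prot = 15, vocabs) {
  c(lapply(seq_len(n_nuc), function(i) encode(rand_dna(30), vocabs$nucleic)),
    lapply(seq_len(n_prot), function(i) encode(rand_protein(20), vocabs$protein)))
}

test_that("the one-cycle schedule hits its printed anchors and is unimodal", {
  expect_equal(lr_schedule(0, 100, 20), 1e-5)
  expect_equal(lr_schedule(20, 100, 20), 1)
  expect_equal(lr_schedule(100, 100, 20), 1e-5)
  xs <- vapply(0:100, lr_schedule, numeric(1), total_steps = 100,
               warmup_steps = 20)
  expect_true(all(diff(xs[1:21]) > 0))   # monotone up
  expect_true(all(diff(xs[21:101]) < 0)) # monotone down
  expect_warning(s <- lr_schedule(150, 100, 20), "clamping")
  expect_equal(s, 1e-5)
})

test_that("muP learning-rate groups follow the 32/width rule", {
  plan <- optimizer_plan(width = 256L)
  expect_equal(plan$embedding_lr, 0.05)
  expect_equal(plan$hidden_lr, 0.05 * 32 / 256)
  expect_equal(plan$adam_betas, c(0.9, 0.95))
  expect_equal(plan$weight_decay, 1e-2)
  expect_equal(momlm:::.param_lr("emb", plan), 0.05)
  expect_equal(momlm:::.param_lr("unemb", plan), 0.05)
  expect_equal(momlm:::.param_lr("L1.wq", plan), plan$hidden_lr)
})

test_that("MLM corruption respects rate, mix, and masking bookkeeping", {
  set.seed(61)
  vocabs <- toy_setup()$vocabs
  pool <- make_pool(vocabs = vocabs)
  # m = 0: input equals target, empty loss mask
  b0 <- make_mlm_batch(pool, vocabs, 64L, 1024L, mask_rate = 0, seed = 3L)
  expect_identical(b0$input_ids, b0$target_ids)
  expect_false(any(b0$loss_mask))
  # m = 1 with 100% mask-token: every eligible position is a mask id
  b1 <- make_mlm_batch(pool, vocabs, 64L, 1024L, mask_rate = 1,
                       frac_mask = 1, frac_random = 0, seed = 3L)
  mask_ids <- c(vocabs$nucleic$special_ids$mask, vocabs$protein$special_ids$mask)
  eligible <- b1$loss_mask
  expect_true(all(b1$input_ids[eligible] %in% mask_ids))
  # at m = 1 every non-special position is corrupted
  piece_max <- vocabs$protein$id_offset + length(vocabs$protein$pieces) - 1L
  expect_identical(b1$loss_mask, b1$attn_mask & b1$target_ids <= piece_max)
  # empirical corruption rate at m = 0.15 over >= 1e4 eligible positions
  hits <- 0; elig <- 0
  for (s in 1:8) {
    b <- make_mlm_batch(pool, vocabs, 64L, 2048L, mask_rate = 0.15, seed = s)
    piece <- b$attn_mask & b$target_ids <= piece_max
    hits <- hits + sum(b$loss_mask)
    elig <- elig + sum(piece)
  }
  expect_gt(elig, 1e4)
  expect_equal(hits / elig, 0.15, tolerance = 0.02 / 0.15)
  expect_error(make_mlm_batch(list(), vocabs), "empty")
})

test_that("no batch row ever mixes the two modality id ranges", {
  vocabs <- toy_setup()$vocabs
  pool <- make_pool(vocabs = vocabs)
  nuc_rng <- vocabs$nucleic$id_offset + seq_along(vocabs$nucleic$pieces) - 1L
  nuc_rng <- c(nuc_rng, unlist(vocabs$nucleic$special_ids))
  prot_rng <- vocabs$protein$id_offset + seq_along(vocabs$protein$pieces) - 1L
  prot_rng <- c(prot_rng, unlist(vocabs$protein$special_ids))
  n_rows <- 0L; violations <- 0L; mislabeled <- 0L
  for (s in 1:100) {
    b <- make_mlm_batch(pool, vocabs, 48L, 512L, seed = s)
    for (r in seq_len(nrow(b$input_ids))) {
      ids <- b$input_ids[r, b$attn_mask[r, ]]
      in_nuc <- ids %in% nuc_rng
      n_rows <- n_rows + 1L
      if (!(all(in_nuc) || all(!in_nuc))) violations <- violations + 1L
      lab <- if (all(in_nuc)) "nucleic" else "protein"
      if (b$modality[r] != lab) mislabeled <- mislabeled + 1L
    }
  }
  expect_gt(n_rows, 500L)
  expect_equal(violations, 0L)
  expect_equal(mislabeled, 0L)
})

test_that("pretraining is budgeted, reproducible, and reduces the loss", {
  s <- toy_setup()
  pool <- local({ set.seed(62); make_pool(10, 10, s$vocabs) })
  plan <- optimizer_plan(s$config$width, warmup_tokens = 1024)
  # zero budget: parameters untouched
  r0 <- pretrain(pool, s$config, s$vocabs, plan, budget_tokens = 100,
                 batch_tokens = 512L, seed = 9L, params = s$params)
  expect_identical(r0$params, s$params)
  expect_equal(nrow(r0$trace), 0L)
  r1 <- pretrain(pool, s$config, s$vocabs, plan, budget_tokens = 4096,
                 batch_tokens = 512L, seed = 9L)
  r2 <- pretrain(pool, s$config, s$vocabs, plan, budget_tokens = 4096,
                 batch_tokens = 512L, seed = 9L)
  expect_identical(r1$trace$loss, r2$trace$loss)   # bitwise determinism
  expect_lt(utils::tail(r1$trace$loss, 1), r1$trace$loss[1])
  expect_equal(r1$trace$loss[1], log(s$config$vocab_size), tolerance = 1e-6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_loss_trace(r1$trace, path)
  expect_equal(utils::read.csv(path)$loss, r1$trace$loss)
})

test_that("a toy model overfits a memorizable corpus", {
  s <- toy_setup(width = 48L, n_heads = 2L, seed = 63L)
  set.seed(63)
  fixed <- replicate(10, rand_dna(24))
  pool <- lapply(fixed, encode, vocabulary = s$vocabs$nucleic)
  plan <- optimizer_plan(s$config$width, warmup_tokens = 2048)
  r <- pretrain(pool, s$config, s$vocabs, plan, budget_tokens = 1e5,
                batch_tokens = 512L, seed = 63L)
  expect_lt(utils::tail(r$trace$loss, 1), 0.5 * log(s$config$vocab_size))
})

test_that("the optimal base learning rate transfers across widths (muP)", {
  vocabs <- toy_setup()$vocabs
  set.seed(64)
  pool <- make_pool(8, 8, vocabs)
  grid <- c(0.0125, 0.05, 0.2)
  final_loss <- function(width, base_lr) {
    cfg <- encoder_config(width = width, n_layers = 2L,
                          n_heads = width %/% 32L, context_length = 48L,
                          vocab_size = vocab_space_size(vocabs))
    plan <- optimizer_plan(width, embedding_lr = base_lr,
                           hidden_lr_base = base_lr, warmup_tokens = 1024)
    r <- pretrain(pool, cfg, vocabs, plan, budget_tokens = 8e3,
                  batch_tokens = 512L, seed = 64L)
    mean(utils::tail(r$trace$loss, 5))
  }
  best64 <- which.min(vapply(grid, function(lr) final_loss(64L, lr), numeric(1)))
  best256 <- which.min(vapply(grid, function(lr) final_loss(256L, lr), numeric(1)))
  expect_lte(abs(best64 - best256), 1L)
})
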