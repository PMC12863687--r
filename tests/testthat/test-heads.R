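test_that("the multi-omic input layout is [cls] protein [sep] nucleic (x2)", {
  vocabs <- toy_setup()$vocabs
  rec <- list(protein_seq = "MKV", nucleic_seq_1 = "ACGT",
              nucleic_seq_2 = NA_character_)
  tk <- build_multiomic_input(rec, vocabs)
  expect_equal(length(tk$ids), 1L + 3L + 1L + 4L)
  expect_equal(sum(tk$segments == "sep"), 1L)   # one sep between modalities
  rec2 <- list(protein_seq = "MKV", nucleic_seq_1 = "ACGT",
               nucleic_seq_2 = "AC")
  tk2 <- build_multiomic_input(rec2, vocabs)
  expect_equal(length(tk2$ids), 1L + 3L + 1L + 4L + 1L + 2L)
  # modality id ranges partition exactly at the seps
  vp <- vocabs$protein; vn <- vocabs$nucleic
  prot_rng <- vp$id_offset + seq_along(vp$pieces) - 1L
  nuc_rng <- vn$id_offset + seq_along(vn$pieces) - 1L
  expect_true(all(tk2$ids[tk2$segments == "protein"] %in% prot_rng))
  expect_true(all(tk2$ids[tk2$segments %in% c("nucleic1", "nucleic2")] %in% nuc_rng))
  expect_false(any(tk2$ids[tk2$segments == "protein"] %in% nuc_rng))
  # truncation removes the nucleic tail, never the protein
  expect_warning(tk3 <- build_multiomic_input(rec2, vocabs, context_length = 8L),
                 "truncating")
  expect_equal(length(tk3$ids), 8L)
  expect_equal(sum(tk3$segments == "protein"), 3L)
  expect_error(build_multiomic_input(list(protein_seq = "", nucleic_seq_1 = "A"),
                                     vocabs), "empty protein")
  expect_error(build_multiomic_input(list(protein_seq = "MK",
                                          nucleic_seq_1 = ""), vocabs),
               "empty nucleic")
})

test_that("a zero-weight regression head predicts its bias everywhere", {
  s <- toy_setup()
  head <- regression_head(s$config$width, bias = -7.5)
  for (i in 1:3) {
    rec <- list(protein_seq = rand_protein(8), nucleic_seq_1 = rand_dna(6),
                nucleic_seq_2 = NA)
    expect_equal(predict_dG(s$params, s$config, head, rec, s$vocabs), -7.5)
  }
})

test_that("dG fine-tuning memorizes a leaked test set (capacity sanity)", {
  ds <- gen_binding_dataset(n_families = 3L, proteins_per_family = 2L,
                            seqs_per_protein = 4L, n_near_duplicates = 0L,
                            seed = 71L)[1:20, ]
  s <- toy_setup(width = 64L, n_heads = 2L, seed = 71L)
  fake <- structure(list(fold_of_record = rep(1L, 20), pinned = character(0),
                         n_folds = 1L, pin_threshold = 1.5),
                    class = "momlm_folds")
  fit <- finetune_dG(s$params, s$config, ds, fake, s$vocabs, epochs = 200L,
                     batch = 20L, folds_to_run = 1L, seed = 71L,
                     train_idx = 1:20)
  expect_lt(fit$metrics$mae[1], 0.1)
  expect_gt(fit$metrics$pcc[1], 0.99)
})

test_that("fold-restricted fine-tuning reports PCC/MAE and handles degenerates", {
  # metric identities on the evaluation path
  expect_equal(metrics(c(1, 2, 3) + 1, c(1, 2, 3), "mae"), 1)
  expect_warning(expect_equal(metrics(rep(2, 5), rnorm(5), "pcc"), 0),
                 "undefined")
  # a fold with no test records errors
  ds <- gen_binding_dataset(n_families = 3L, proteins_per_family = 2L,
                            seqs_per_protein = 2L, n_near_duplicates = 0L,
                            seed = 72L)
  s <- toy_setup(seed = 72L)
  fake <- structure(list(fold_of_record = rep(NA_integer_, nrow(ds)),
                         pinned = character(0), n_folds = 2L,
                         pin_threshold = 1.5), class = "momlm_folds")
  expect_error(finetune_dG(s$params, s$config, ds, fake, s$vocabs,
                           epochs = 1L, folds_to_run = 1L), "no test records")
})

test_that("contact tagging predicts per protein residue with sigmoid(0) = 0.5", {
  s <- toy_setup()
  head <- regression_head(s$config$width)   # zero weights
  rec <- list(protein_seq = rand_protein(12), nucleic_seq_1 = rand_dna(6),
              nucleic_seq_2 = NA)
  pr <- predict_contacts_per_residue(s$params, s$config, head, rec, s$vocabs)
  expect_length(pr, 12L)                    # single-char vocab: one per residue
  expect_equal(pr, rep(0.5, 12L))
})

test_that("contact fine-tuning beats the all-positive baseline on planted motifs", {
  ds <- gen_contact_dataset(30, seed = 73L)
  s <- toy_setup(width = 32L, n_heads = 2L, seed = 73L)
  test_idx <- 25:30
  fit <- finetune_contact(s$params, s$config, ds, s$vocabs, epochs = 24L,
                          batch = 8L, seed = 73L, test_idx = test_idx)
  labels <- attr(ds, "contact_labels")
  p <- mean(unlist(labels[test_idx]))
  baseline <- 2 * p / (1 + p)               # all-positive F1 ceiling
  expect_gt(fit$f1, baseline)
  expect_error(finetune_contact(s$params, s$config,
                                ds[, c("protein_seq", "nucleic_seq_1",
                                       "nucleic_seq_2")],
                                s$vocabs), "no contact labels")
})

test_that("the pairwise contact head outputs bounded maps with the 12-residue mask", {
  set.seed(74)
  d <- 16L
  head <- pairwise_contact_head(d, proj_dim = 8L, channels = 8L, seed = 74L)
  L <- 24L
  hidden <- matrix(rnorm(L * d), L, d)
  prob <- predict_contact_map(hidden, head)
  expect_equal(dim(prob), c(L, L))
  expect_true(all(prob > 0 & prob < 1))
  truth <- matrix(rbinom(L * L, 1, 0.2), L, L)
  res <- contact_map_loss(prob, truth, 12L)
  # masked-pair fraction for L = 24: 2 * (13 * 12 / 2) / 576
  expect_equal(res$n_pairs / L^2, 2 * (13 * 12 / 2) / 576)
  expect_true(is.finite(res$loss))
  expect_error(contact_map_loss(prob[1:10, 1:10], truth[1:10, 1:10], 12L),
               "separation")
  # P@L = 1 when true contacts are exactly the top-L predicted pairs
  sel <- res$mask
  pv <- prob[sel]
  tv <- as.numeric(rank(-pv) <= L)
  expect_equal(metrics(pv, tv, "p_at_L", L = L), 1)
})

test_that("classification fine-tuning separates two synthetic classes", {
  s <- toy_setup(width = 32L, n_heads = 2L, seed = 75L)
  v <- s$vocabs$protein
  set.seed(75)
  n <- 40L
  y <- rep(1:2, each = n / 2)
  toks <- lapply(y, function(cl) {
    base <- if (cl == 1) "MKVL" else "WYED"
    c(v$special_ids$cls, encode(paste0(base, rand_protein(6)), v)$ids)
  })
  test_idx <- c(17:20, 37:40)
  fit <- finetune_classify(s$params, s$config, toks, y, 2L,
                           v$special_ids$pad, epochs = 30L, batch = 8L,
                           seed = 75L, test_idx = test_idx)
  expect_gt(fit$accuracy, 0.7)
  expect_gt(fit$train_accuracy, 0.9)
})

test_that("held-out recovery improves as label noise falls", {
  # sigma 2.0 vs 0.5 on a small joint encoder; the cleaner labels must not
  # recover worse (within noise slack)
  pccs <- vapply(c(2.0, 0.5), function(sig) {
    ds <- gen_binding_dataset(n_families = 4L, proteins_per_family = 4L,
                              seqs_per_protein = 4L, noise_sigma = sig,
                              n_near_duplicates = 0L, seed = 76L)
    s <- toy_setup(width = 32L, n_heads = 2L, seed = 76L)
    folds <- build_folds(ds, n_folds = 4L, seed = 76L)
    fit <- finetune_dG(s$params, s$config, ds, folds, s$vocabs,
                       epochs = 24L, batch = 8L, folds_to_run = 1L,
                       seed = 76L)
    fit$metrics$pcc[1]
  }, numeric(1))
  expect_gt(pccs[2], pccs[1] - 0.1)
})
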