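test_that("self-alignment score equals the mean self-substitution score", {
  r <- normalized_alignment_score("LLLLLLLLLL", "LLLLLLLLLL")
  expect_equal(r$normalized, 4)          # BLOSUM62 L/L = 4, no gaps
  expect_equal(r$raw, 40)
  expect_error(normalized_alignment_score("", "ACD"), "empty")
  # random uniform-composition self scores stay within the BLOSUM62
  # self-substitution range [4, 11]
  set.seed(31)
  selfs <- replicate(20, {
    s <- rand_protein(30)
    normalized_alignment_score(s, s)$normalized
  })
  expect_true(all(selfs >= 4 & selfs <= 11))
})

test_that("alignment is symmetric and matches the affine-gap DP oracle", {
  set.seed(32)
  for (i in 1:30) {
    a <- rand_protein(sample(3:12, 1)); b <- rand_protein(sample(3:12, 1))
    ra <- normalized_alignment_score(a, b)
    rb <- normalized_alignment_score(b, a)
    expect_equal(ra$raw, rb$raw)
    expect_equal(ra$normalized, rb$normalized)
  }
  # all pairs from a sample of the exhaustive length<=6 space over {A,C,D,E}
  set.seed(33)
  seqs <- unique(replicate(18, paste(sample(c("A", "C", "D", "E"),
                                            sample(1:6, 1), replace = TRUE),
                                     collapse = "")))
  for (a in seqs) {
    for (b in seqs) {
      expect_equal(normalized_alignment_score(a, b)$raw,
                   oracle_global_score(a, b, blosum62),
                   info = paste(a, b))
    }
  }
})

test_that("fold construction is protein-disjoint, seeded, and pins near-duplicates", {
  set.seed(34)
  prot <- replicate(20, rand_protein(25))
  recs <- data.frame(protein_seq = rep(prot, each = 2),
                     nucleic_seq_1 = replicate(40, rand_dna(8)),
                     dG = rnorm(40))
  f <- build_folds(recs, n_folds = 10L, seed = 7L)
  expect_length(f$pinned, 0L)            # mutually dissimilar random proteins
  expect_setequal(stats::na.omit(unique(f$fold_of_group)), 1:10)
  expect_true(all(table(f$fold_of_group) >= 1))
  # identical protein sequences land in the same fold via grouping
  expect_equal(length(unique(f$fold_of_record[recs$protein_seq == prot[1]])), 1L)
  # seeded reproducibility
  f2 <- build_folds(recs, n_folds = 10L, seed = 7L)
  expect_identical(f$fold_of_group, f2$fold_of_group)
  # planted near-duplicate pair (one substitution, score far above 1.5)
  dup <- prot[1]
  substr(dup, 3, 3) <- "W"
  recs2 <- rbind(recs, data.frame(protein_seq = dup,
                                  nucleic_seq_1 = rand_dna(8), dG = 0))
  f3 <- build_folds(recs2, n_folds = 10L, seed = 7L)
  expect_true(all(c(prot[1], dup) %in% f3$pinned))
  aud <- audit_folds(recs2, f3)
  expect_equal(nrow(aud$leaky_pairs), 0L)
  expect_lte(aud$max_cross_score, 1.5)
  expect_error(build_folds(recs[1:6, ], n_folds = 10L), "unpinned")
})

test_that("external-overlap filtering matches pairwise brute force", {
  set.seed(35)
  refs <- replicate(5, rand_protein(20))
  expect_identical(filter_external_overlap(refs[1:2], character(0)), refs[1:2])
  # identical to a reference: removed
  ext <- c(refs[1], replicate(5, rand_protein(20)))
  kept <- filter_external_overlap(ext, refs)
  expect_false(refs[1] %in% kept)
  # decision agrees with direct pairwise scoring
  manual <- ext[vapply(ext, function(e) {
    all(vapply(refs, function(r) {
      normalized_alignment_score(e, r)$normalized <= 1.5
    }, logical(1)))
  }, logical(1))]
  expect_identical(kept, manual)
})

test_that("contact labeling thresholds min heavy-atom distances", {
  atoms <- data.frame(chain = c("A", "B"), chain_type = c("protein", "nucleic"),
                      resno = c(1L, 1L), elety = c("CA", "P"),
                      x = c(0, 7.9), y = 0, z = 0)
  expect_true(label_contacts(atoms, 8))
  expect_false(label_contacts(atoms, 6))
  expect_error(label_contacts(atoms[1, ], 8), "nucleic")
  # synthetic 30-residue complex vs the all-pairs oracle, nested thresholds
  ds <- gen_contact_dataset(3, protein_length = 30L, coordinates = TRUE,
                            seed = 36L)
  for (st in attr(ds, "structures")) {
    l4 <- label_contacts(st, 4); l6 <- label_contacts(st, 6)
    l8 <- label_contacts(st, 8)
    expect_true(all(l4 <= l6) && all(l6 <= l8))   # monotone in threshold
    for (th in c(4, 6, 8)) {
      expect_equal(unname(label_contacts(st, th)),
                   unname(oracle_contacts(st, th)))
    }
  }
})

test_that("synthetic PDB files round-trip through the structure reader", {
  ds <- gen_contact_dataset(1, coordinates = TRUE, seed = 37L)
  st <- attr(ds, "structures")[[1]]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(st, path)
  at <- read_structure_atoms(path)
  expect_equal(sort(unique(at$chain_type)), c("nucleic", "protein"))
  expect_equal(unname(label_contacts(at, 8)),
               unname(attr(ds, "contact_labels")[[1]]))
})

test_that("random-guessing F1 ceiling matches its closed form and grid search", {
  expect_equal(max_random_f1(0), 0)
  expect_equal(max_random_f1(1), 2 / 3, tolerance = 1e-12)
  expect_error(max_random_f1(-0.1), "non-negative")
  for (r in c(0.01, 0.09, 0.16, 0.29, 0.5, 1, 2, 10)) {
    expect_equal(max_random_f1(r), oracle_max_random_f1(r), tolerance = 1e-6)
  }
})

test_that("metrics agree with brute-force formulas and handle degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(metrics(x, x, "pcc"), 1)
  expect_equal(metrics(x, x, "mae"), 0)
  expect_equal(metrics(x, rev(x), "pcc"), -1)
  expect_equal(metrics(x + 1, x, "mae"), 1)
  expect_warning(expect_equal(metrics(rep(1, 4), x, "pcc"), 0), "undefined")
  # mcc on TP=2 FP=1 FN=1 TN=6 (hand arithmetic: (12-1)/sqrt(3*3*7*7) = 11/21)
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  tru <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(metrics(pred, tru, "mcc"), 11 / 21)
  expect_equal(metrics(pred, tru, "f1"), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(metrics(pred, tru, "accuracy"), 0.8)
  # 100 random vectors against direct formulas
  set.seed(38)
  for (i in 1:100) {
    p <- runif(20); t <- runif(20)
    expect_equal(metrics(p, t, "pcc"), cor(p, t))
    expect_equal(metrics(p, t, "mae"), mean(abs(p - t)))
    expect_equal(metrics(p, t, "spearman"), cor(p, t, method = "spearman"))
  }
  # P@L = 1 when the true contacts are exactly the top-L predictions
  p <- c(0.9, 0.8, 0.1, 0.2, 0.7)
  t <- c(1, 1, 0, 0, 1)
  expect_equal(metrics(p, t, "p_at_L", L = 3), 1)
  # auroc of perfectly separated scores
  expect_equal(metrics(c(0.9, 0.8, 0.1), c(1, 1, 0), "auroc"), 1)
})

test_that("classification metrics match brute-force formulas on random vectors", {
  set.seed(39)
  for (i in 1:100) {
    pred <- rbinom(30, 1, 0.4); tru <- rbinom(30, 1, 0.4)
    tp <- sum(pred & tru); fp <- sum(pred & !tru)
    fn <- sum(!pred & tru); tn <- sum(!pred & !tru)
    if (2 * tp + fp + fn > 0) {
      expect_equal(metrics(pred, tru, "f1"), 2 * tp / (2 * tp + fp + fn))
    }
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den > 0) {
      expect_equal(metrics(pred, tru, "mcc"), (tp * tn - fp * fn) / den)
    }
    expect_equal(metrics(pred, tru, "accuracy"), mean(pred == tru))
  }
})
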