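test_that("gene/protein pairs satisfy the translation invariant", {
  pairs <- gen_gene_protein_pairs(25, c(10L, 30L), intron_rate = 0.2, seed = 41L)
  exons <- attr(pairs, "exons")
  for (i in seq_len(nrow(pairs))) {
    ex <- exons[[i]]
    coding <- paste(vapply(seq_len(nrow(ex)), function(k) {
      substr(pairs$gene[i], ex[k, 1] + 1L, ex[k, 2])
    }, character(1)), collapse = "")
    # independent oracle: Biostrings codon-table translation (the leading
    # codon is an ordinary codon here, not an initiator)
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(coding),
                                         no.init.codon = TRUE)),
      pairs$protein[i])
  }
})

test_that("intron-free genes have codon-arithmetic length and seeds reproduce", {
  pairs <- gen_gene_protein_pairs(10, c(12L, 12L), intron_rate = 0, seed = 42L)
  expect_true(all(nchar(pairs$gene) == 3 * 12 + 3))   # codons + stop
  p2 <- gen_gene_protein_pairs(10, c(12L, 12L), intron_rate = 0, seed = 42L)
  expect_identical(pairs$gene, p2$gene)
  p3 <- gen_gene_protein_pairs(10, c(12L, 12L), intron_rate = 0, seed = 43L)
  expect_false(any(p3$gene %in% pairs$gene))
  expect_error(gen_gene_protein_pairs(0), "positive")
})

test_that("noiseless binding labels equal the closed-form energy", {
  ds <- gen_binding_dataset(n_families = 3L, proteins_per_family = 3L,
                            seqs_per_protein = 4L, noise_sigma = 0,
                            n_near_duplicates = 0L, seed = 43L)
  model <- attr(ds, "model")
  for (i in seq_len(nrow(ds))) {
    expect_equal(ds$dG[i],
                 binding_true_dG(model, ds$family[i], ds$nucleic_seq_1[i]),
                 tolerance = 1e-9)
  }
  expect_equal(ds$dG, ds$dG_true, tolerance = 1e-12)
})

test_that("the family consensus is the strongest binder (exhaustive at W=6)", {
  ds <- gen_binding_dataset(n_families = 2L, proteins_per_family = 2L,
                            seqs_per_protein = 2L, motif_width = 6L,
                            noise_sigma = 0, n_near_duplicates = 0L,
                            shared_consensus = FALSE, seed = 44L)
  model <- attr(ds, "model")
  bases <- c("A", "C", "G", "T")
  all_sites <- do.call(paste0, expand.grid(rep(list(bases), 6L)))
  for (f in 1:2) {
    e <- vapply(all_sites, function(s) binding_true_dG(model, f, s), numeric(1))
    expect_identical(unname(all_sites[which.min(e)]), model$consensus[f])
    # and consensus energy is the family baseline exactly
    expect_equal(unname(min(e)), model$baselines[f])
  }
})

test_that("label noise has the configured variance", {
  ds <- gen_binding_dataset(n_families = 5L, proteins_per_family = 8L,
                            seqs_per_protein = 25L, noise_sigma = 1,
                            n_near_duplicates = 0L, seed = 45L)
  expect_gt(nrow(ds), 900)
  expect_equal(stats::var(ds$dG - ds$dG_true), 1, tolerance = 0.1)
})

test_that("binding generator gives homology-splittable families and PFMs", {
  ds <- gen_binding_dataset(seed = 46L)
  model <- attr(ds, "model")
  # PFM consensus equals the energy-model consensus (strict column maxima)
  for (f in seq_along(model$pfms)) {
    expect_identical(consensus_from_pfm(model$pfms[[f]]), model$consensus[f])
  }
  # cross-family protein pairs are dissimilar on average
  tags <- substr(unique(ds$protein_seq), 1, 4)
  fam <- match(tags, model$tags)
  prot <- unique(ds$protein_seq)
  set.seed(1)
  cross <- replicate(30, {
    ij <- sample(length(prot), 2)
    if (fam[ij[1]] != fam[ij[2]]) {
      normalized_alignment_score(prot[ij[1]], prot[ij[2]])$normalized
    } else NA_real_
  })
  expect_lt(mean(cross, na.rm = TRUE), 0)
  # bitwise reproducibility
  expect_identical(ds$dG, gen_binding_dataset(seed = 46L)$dG)
})

test_that("contact generator plants exact-ratio labels and matching coordinates", {
  ds <- gen_contact_dataset(50, coordinates = TRUE, seed = 47L)
  labels <- attr(ds, "contact_labels")
  # defaults: motif RKR + jitter 1 in length 17 gives exactly 5/17 positives
  rates <- vapply(labels, mean, numeric(1))
  expect_true(all(abs(rates - 5 / 17) < 1e-12))
  expect_equal(mean(unlist(labels)), 0.294, tolerance = 0.03)
  # coordinate-mode round trip at 8 Angstrom reproduces the planted labels
  for (i in seq_len(50)) {
    expect_equal(unname(label_contacts(attr(ds, "structures")[[i]], 8)),
                 unname(labels[[i]]))
  }
  # labels exist only for protein positions
  expect_true(all(lengths(labels) == nchar(ds$protein_seq)))
})
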