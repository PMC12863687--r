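# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

rand_protein <- function(n, alphabet = momlm::modality_alphabet("protein")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random contiguous span tiling of n residues
rand_spans <- function(n) {
  cuts <- sort(unique(c(0L, n, sample(seq_len(n - 1L),
                                      sample(0:(n - 1L), 1L)))))
  cbind(start = cuts[-length(cuts)], end = cuts[-1L])
}

# --- Gotoh affine-gap global alignment (scores only) -------------------------
# gap of length k costs open + k * extend (first gap character pays both).
oracle_global_score <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (a residue vs gap)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend,
                      Iy[i - 1, j] - open - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend,
                      Ix[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# --- residue/token transform oracles ----------------------------------------
oracle_aggregate <- function(labels, spans, task) {
  sapply(seq_len(nrow(spans)), function(i) {
    v <- labels[(spans[i, 1] + 1):spans[i, 2]]
    if (task == "regression") mean(v)
    else {
      tab <- table(v)
      min(as.numeric(names(tab)[tab == max(tab)]))
    }
  })
}

oracle_token_contact_map <- function(rmap, spans) {
  nt <- nrow(spans)
  out <- matrix(FALSE, nt, nt)
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      for (r in (spans[i, 1] + 1):spans[i, 2]) {
        for (s in (spans[j, 1] + 1):spans[j, 2]) {
          if (rmap[r, s]) out[i, j] <- TRUE
        }
      }
    }
  }
  out
}

oracle_token_mask <- function(spans, min_sep) {
  nt <- nrow(spans)
  out <- matrix(FALSE, nt, nt)
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      for (r in (spans[i, 1] + 1):spans[i, 2]) {
        for (s in (spans[j, 1] + 1):spans[j, 2]) {
          if (abs(r - s) >= min_sep) out[i, j] <- TRUE
        }
      }
    }
  }
  out
}

oracle_residue_map <- function(tmap, spans) {
  n <- spans[nrow(spans), 2]
  tok_of <- integer(n)
  for (i in seq_len(nrow(spans))) tok_of[(spans[i, 1] + 1):spans[i, 2]] <- i
  out <- matrix(0, n, n)
  for (r in seq_len(n)) for (s in seq_len(n)) out[r, s] <- tmap[tok_of[r], tok_of[s]]
  out
}

# --- contact labeling oracle -------------------------------------------------
oracle_contacts <- function(atoms, threshold) {
  prot <- atoms[atoms$chain_type == "protein", ]
  nuc <- atoms[atoms$chain_type == "nucleic", ]
  resnos <- sort(unique(prot$resno))
  sapply(resnos, function(rn) {
    p <- prot[prot$resno == rn, ]
    best <- Inf
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(nrow(nuc))) {
        d <- sqrt((p$x[i] - nuc$x[j])^2 + (p$y[i] - nuc$y[j])^2 +
                    (p$z[i] - nuc$z[j])^2)
        best <- min(best, d)
      }
    }
    best <= threshold
  })
}

# expected-F1 grid search over guess rates for a positive:negative ratio r
oracle_max_random_f1 <- function(r, grid = seq(0.001, 1, by = 0.001)) {
  p <- r / (1 + r)
  # random guesser at rate q and prevalence p: precision = p, recall = q
  max(vapply(grid, function(q) 2 * p * q / (p + q), numeric(1)))
}

# small full toy encoder for reuse across tests
toy_setup <- function(width = 32L, n_heads = 2L, seed = 1L) {
  vocabs <- momlm::train_vocab_pair(paste(momlm::modality_alphabet("nucleic"), collapse = ""),
                                    paste(momlm::modality_alphabet("protein"), collapse = ""),
                                    algorithm = "single_char")
  config <- momlm::encoder_config(width = width, n_layers = 2L,
                                  n_heads = n_heads, context_length = 64L,
                                  vocab_size = momlm::vocab_space_size(vocabs))
  list(vocabs = vocabs, config = config,
       params = momlm::init_encoder(config, seed = seed))
}
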