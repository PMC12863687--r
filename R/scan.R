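# Binding-specificity scanning: consensus extraction from position-frequency
# matrices, stochastic 5% mutation of the consensus, and ddG aggregation
# against a fine-tuned dG predictor (or the synthetic energy-model oracle).

.PFM_BASES <- c("A", "C", "G", "T")

#' Consensus sequence of a position-frequency matrix
#'
#' The per-column argmax base; ties resolve to the alphabetically first base
#' (A < C < G < T).
#'
#' @param pfm A 4 x W count matrix with rows A, C, G, T (a `counts` element
#'   or a plain matrix).
#' @return Length-W consensus string.
#' @export
consensus_from_pfm <- function(pfm) {
  counts <- if (is.list(pfm)) pfm$counts else pfm
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L, all(counts >= 0))
  if (any(colSums(counts) == 0)) stop("all-zero PFM column")
  if (!is.null(rownames(counts))) counts <- counts[.PFM_BASES, , drop = FALSE]
  paste(.PFM_BASES[apply(counts, 2L, which.max)], collapse = "")
}

#' Stochastically mutate a consensus sequence
#'
#' Each position is substituted independently with probability `p` to a
#' uniformly chosen different base. Draws are rejected and resampled until
#' `n_mutants` sequences are obtained that are mutually unique and all differ
#' from the consensus in at least one position.
#'
#' @param consensus Consensus DNA string.
#' @param p Per-position substitution probability (default 0.05).
#' @param n_mutants Number of unique mutants (default 8).
#' @param seed Integer seed.
#' @param force_change Reject draws identical to the consensus (default TRUE;
#'   set FALSE to study the raw binomial substitution process).
#' @param unique_mutants Reject duplicate mutants (default TRUE).
#' @return Character vector of `n_mutants` mutated sequences.
#' @export
mutate_consensus <- function(consensus, p = 0.05, n_mutants = 8L, seed = 1L,
                             force_change = TRUE, unique_mutants = TRUE) {
  W <- nchar(consensus)
  if (W == 0L) stop("empty consensus")
  if (unique_mutants && 3^W < n_mutants) {
    stop(sprintf("cannot draw %d unique mutants of a width-%d consensus",
                 n_mutants, W))
  }
  set.seed(seed)
  cons <- strsplit(consensus, "")[[1]]
  out <- character(0)
  guard <- 0L
  while (length(out) < n_mutants) {
    guard <- guard + 1L
    if (guard > 100000L) stop("mutant sampling did not converge")
    hit <- stats::runif(W) < p
    if (force_change && !any(hit)) next  # must differ from the consensus
    mut <- cons
    for (w in which(hit)) mut[w] <- sample(setdiff(.PFM_BASES, cons[w]), 1L)
    s <- paste(mut, collapse = "")
    if (unique_mutants && (s %in% out || (force_change && identical(s, consensus)))) next
    out <- c(out, s)
  }
  out
}

#' Mutation scan of a DNA-binding protein against its PFM
#'
#' Predicts dG for the PFM consensus and for `n_mutants` stochastic mutants,
#' reporting per-mutant ddG = dG(mutant) - dG(consensus). With a correctly
#' learned specificity the mean ddG is positive (mutating the consensus
#' weakens binding). `predict_fn(protein_seq, nucleic_seq)` abstracts the
#' predictor: pass [predict_dG()] bound to a fine-tuned model, or the
#' synthetic-model oracle for ground-truth scans.
#'
#' @param predict_fn Function (protein, nucleic) -> dG in kcal/mol.
#' @param dbp_protein Protein sequence of the DNA-binding protein.
#' @param pfm PFM counts (4 x W).
#' @param p,n_mutants,seed Passed to [mutate_consensus()].
#' @return List with `consensus`, `mutants`, `dG_consensus`, `ddG` (length
#'   `n_mutants`) and `mean_ddG`.
#' @export
ddg_scan <- function(predict_fn, dbp_protein, pfm, p = 0.05, n_mutants = 8L,
                     seed = 1L) {
  consensus <- consensus_from_pfm(pfm)
  mutants <- mutate_consensus(consensus, p = p, n_mutants = n_mutants, seed = seed)
  dg_cons <- predict_fn(dbp_protein, consensus)
  dg_mut <- vapply(mutants, function(m) predict_fn(dbp_protein, m), numeric(1))
  ddg <- unname(dg_mut - dg_cons)
  list(consensus = consensus, mutants = mutants, dG_consensus = dg_cons,
       ddG = ddg, mean_ddG = mean(ddg))
}

#' Read PFMs in JASPAR text format
#'
#' Parses `>`-headed records with four labeled count rows, e.g.
#' `A [ 3 10 0 ]`.
#'
#' @param path File with one or more JASPAR-format PFM records.
#' @return List of PFMs: each a list with `identifier` and `counts`
#'   (4 x W matrix, rows A/C/G/T).
#' @export
read_pfm_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' record headers found")
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    rows <- lapply(.PFM_BASES, function(b) {
      ln <- grep(sprintf("^%s\\b", b), block, value = TRUE)
      if (length(ln) != 1L) stop(sprintf("missing or duplicated %s row in record %d", b, k))
      as.numeric(regmatches(ln, gregexpr("[0-9]+\\.?[0-9]*", ln))[[1]])
    })
    W <- unique(lengths(rows))
    if (length(W) != 1L) stop(sprintf("ragged PFM rows in record %d", k))
    counts <- do.call(rbind, rows)
    rownames(counts) <- .PFM_BASES
    out[[k]] <- list(identifier = sub("^>\\s*", "", lines[heads[k]]),
                     counts = counts)
  }
  out
}

#' Write PFMs in JASPAR text format
#' @param pfms List of PFMs as returned by [read_pfm_jaspar()], or a single
#'   named count matrix.
#' @param path Output file.
#' @export
write_pfm_jaspar <- function(pfms, path) {
  if (is.matrix(pfms)) pfms <- list(list(identifier = "PFM1", counts = pfms))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$identifier), con)
    for (b in .PFM_BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(p$counts[b, ], collapse = " ")), con)
    }
  }
  invisible(path)
}
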