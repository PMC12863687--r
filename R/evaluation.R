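# Homology-aware evaluation: BLOSUM62 global-alignment similarity scores,
# leakage-free 10-fold construction pinned at a similarity threshold,
# distance-based contact labeling from 3D coordinates, standard metrics, and
# the analytic random-guessing F1 ceiling.

#' Normalized BLOSUM62 global alignment score
#'
#' End-to-end (Needleman-Wunsch) alignment under BLOSUM62 with affine gap
#' costs (a gap of length k costs `gap_open + k * gap_extend`), normalized by
#' the alignment length so that the self-score of a sequence equals the mean
#' BLOSUM62 self-substitution score of its composition (identical sequences
#' score roughly 4-11 per aligned position depending on residue content).
#'
#' @param a,b Protein sequences (canonical residues only).
#' @param gap_open,gap_extend Affine gap costs (defaults 11 / 1).
#' @return List with `raw` (total score) and `normalized` (score per aligned
#'   position).
#' @export
normalized_alignment_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_open, gapExtension = gap_extend)
  raw <- Biostrings::score(aln)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(raw = raw, normalized = raw / len)
}

# All-vs-all normalized alignment scores for a set of protein sequences.
# Returns a symmetric matrix (diagonal = self scores).
.pairwise_norm_scores <- function(seqs, gap_open = 11, gap_extend = 1) {
  n <- length(seqs)
  out <- matrix(0, n, n)
  if (n == 0L) return(out)
  subject <- Biostrings::AAStringSet(seqs)
  for (i in seq_len(n)) {
    js <- i:n
    aln <- Biostrings::pairwiseAlignment(
      subject[js], Biostrings::AAString(seqs[i]),
      substitutionMatrix = "BLOSUM62", type = "global",
      gapOpening = gap_open, gapExtension = gap_extend)
    raw <- Biostrings::score(aln)
    lens <- nchar(as.character(Biostrings::alignedPattern(aln)))
    out[i, js] <- raw / lens
    out[js, i] <- out[i, js]
  }
  out
}

#' Homology-safe cross-validation folds
#'
#' Groups complex records by exact protein sequence, pins every protein that
#' has a normalized alignment score above `pin_threshold` with any *other*
#' protein in the dataset to the train set of all folds, and distributes the
#' remaining protein groups over `n_folds` folds (greedy assignment of
#' seeded-shuffled groups to the currently smallest fold by complex count),
#' so no protein sequence ever appears in two folds.
#'
#' @param records A `momlm_complexes` data frame (see [read_complex_table()])
#'   or any data frame with a `protein_seq` column.
#' @param n_folds Number of folds (default 10).
#' @param pin_threshold Normalized-score threshold above which proteins are
#'   pinned to train (default 1.5).
#' @param seed Integer seed for the shuffle.
#' @return A `momlm_folds` object: list with `fold_of_group` (named integer
#'   vector over distinct protein sequences; `NA` = pinned to train),
#'   `fold_of_record` (per record, `NA` = pinned), `pinned` (sequences), and
#'   `n_folds`.
#' @export
build_folds <- function(records, n_folds = 10L, pin_threshold = 1.5, seed = 1L) {
  proteins <- unique(records$protein_seq)
  scores <- .pairwise_norm_scores(proteins)
  diag(scores) <- -Inf
  pinned <- proteins[apply(scores > pin_threshold, 1L, any)]
  free <- setdiff(proteins, pinned)
  if (length(free) < n_folds) {
    stop(sprintf("only %d unpinned protein groups for %d folds",
                 length(free), n_folds))
  }
  counts <- table(records$protein_seq)[free]
  set.seed(seed)
  ord <- sample(length(free))
  fold_sizes <- integer(n_folds)
  fold_of <- stats::setNames(rep(NA_integer_, length(proteins)), proteins)
  for (g in free[ord]) {
    f <- which.min(fold_sizes)
    fold_of[g] <- f
    fold_sizes[f] <- fold_sizes[f] + counts[[g]]
  }
  structure(list(fold_of_group = fold_of,
                 fold_of_record = unname(fold_of[records$protein_seq]),
                 pinned = pinned, n_folds = as.integer(n_folds),
                 pin_threshold = pin_threshold),
            class = "momlm_folds")
}

#' @export
print.momlm_folds <- function(x, ...) {
  cat(sprintf("<momlm_folds> %d folds over %d protein groups (%d pinned to train)\n",
              x$n_folds, length(x$fold_of_group), length(x$pinned)))
  invisible(x)
}

#' Audit a fold assignment for homology leakage
#'
#' Scans every test/train protein pair of every fold; returns the maximum
#' cross normalized score observed (must be <= the pin threshold for a
#' leakage-free split).
#'
#' @param records The records used to build the folds.
#' @param folds A `momlm_folds` object.
#' @return List with `max_cross_score` and `leaky_pairs` (data frame).
#' @export
audit_folds <- function(records, folds) {
  proteins <- names(folds$fold_of_group)
  scores <- .pairwise_norm_scores(proteins)
  diag(scores) <- -Inf
  worst <- -Inf
  leaks <- list()
  for (f in seq_len(folds$n_folds)) {
    test_i <- which(folds$fold_of_group == f)
    train_i <- which(is.na(folds$fold_of_group) | folds$fold_of_group != f)
    if (length(test_i) == 0L) next
    sub <- scores[test_i, train_i, drop = FALSE]
    worst <- max(worst, max(sub))
    bad <- which(sub > folds$pin_threshold, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      leaks[[length(leaks) + 1L]] <- data.frame(
        fold = f, test = proteins[test_i[bad[, 1L]]],
        train = proteins[train_i[bad[, 2L]]])
    }
  }
  list(max_cross_score = worst,
       leaky_pairs = if (length(leaks)) do.call(rbind, leaks)
                     else data.frame(fold = integer(0), test = character(0),
                                     train = character(0)))
}

#' Filter external proteins overlapping a reference set
#'
#' Drops every external protein whose normalized alignment score with any
#' reference protein exceeds `threshold` (the overlap rejection used before
#' scanning an external motif database against a fine-tuned model).
#'
#' @param external_proteins,reference_proteins Character vectors.
#' @param threshold Normalized-score threshold (default 1.5).
#' @return The retained external proteins.
#' @export
filter_external_overlap <- function(external_proteins, reference_proteins,
                                    threshold = 1.5) {
  if (length(reference_proteins) == 0L) return(external_proteins)
  keep <- vapply(external_proteins, function(e) {
    for (r in reference_proteins) {
      if (normalized_alignment_score(e, r)$normalized > threshold) return(FALSE)
    }
    TRUE
  }, logical(1))
  external_proteins[keep]
}

#' Label protein residues contacting a nucleotide
#'
#' A residue is a contact iff the minimum Euclidean distance between any of
#' its heavy atoms and any heavy atom of any nucleotide is at most
#' `threshold_angstrom`. Input is either an atom table (data frame with
#' columns `chain_type` in {"protein","nucleic"}, `resno`, `x`, `y`, `z`) or
#' a path to a PDB file, which must contain strictly one protein chain and
#' one or two nucleic acid chains.
#'
#' @param structure Atom data frame or PDB file path.
#' @param threshold_angstrom Distance threshold in Angstrom (4, 6 or 8 in the
#'   published evaluation, but any positive value is accepted).
#' @return Named logical vector over protein residue numbers (in `resno`
#'   order).
#' @export
label_contacts <- function(structure, threshold_angstrom = 8) {
  atoms <- if (is.character(structure)) read_structure_atoms(structure)
           else structure
  stopifnot(all(c("chain_type", "resno", "x", "y", "z") %in% names(atoms)))
  prot <- atoms[atoms$chain_type == "protein", , drop = FALSE]
  nuc <- atoms[atoms$chain_type == "nucleic", , drop = FALSE]
  if (nrow(prot) == 0L || nrow(nuc) == 0L) {
    stop("structure must contain both a protein chain and a nucleic chain")
  }
  nuc_xyz <- as.matrix(nuc[, c("x", "y", "z")])
  resnos <- sort(unique(prot$resno))
  out <- stats::setNames(logical(length(resnos)), resnos)
  for (i in seq_along(resnos)) {
    p_xyz <- as.matrix(prot[prot$resno == resnos[i], c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(p_xyz^2), rowSums(nuc_xyz^2), "+") -
      2 * p_xyz %*% t(nuc_xyz)
    out[i] <- sqrt(max(0, min(d2))) <= threshold_angstrom
  }
  out
}

#' Read a protein-nucleic acid complex PDB file as an atom table
#'
#' Classifies chains by residue names (standard amino acids vs. standard
#' nucleotides) and rejects structures that do not have exactly one protein
#' chain and one or two nucleic chains.
#'
#' @param path PDB file path.
#' @return Data frame with `chain`, `chain_type`, `resno`, `elety`, `x`, `y`,
#'   `z` (hydrogens excluded).
#' @export
read_structure_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!grepl("^H", at$elety), , drop = FALSE]  # heavy atoms only
  aa3 <- bio3d::aa.table$aa3
  nuc_res <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")
  chain_kind <- vapply(split(at$resid, at$chain), function(res) {
    if (all(res %in% aa3)) "protein"
    else if (all(res %in% nuc_res)) "nucleic"
    else "other"
  }, character(1))
  n_prot <- sum(chain_kind == "protein")
  n_nuc <- sum(chain_kind == "nucleic")
  if (n_prot != 1L || !(n_nuc %in% c(1L, 2L))) {
    stop(sprintf("structure rejected: %d protein chain(s), %d nucleic chain(s)",
                 n_prot, n_nuc))
  }
  data.frame(chain = at$chain,
             chain_type = unname(chain_kind[at$chain]),
             resno = at$resno, elety = at$elety,
             x = at$x, y = at$y, z = at$z)
}

#' Maximum F1 achievable by random guessing
#'
#' For a dataset with positive-to-negative ratio r (prevalence
#' p = r / (1 + r)), the expected F1 of guessing positive with rate q is
#' maximized at q = 1, giving 2p / (1 + p). This is the analytic ceiling an
#' uninformative classifier can reach.
#'
#' @param pos_to_neg_ratio Non-negative ratio r.
#' @return The F1 ceiling.
#' @export
max_random_f1 <- function(pos_to_neg_ratio) {
  if (pos_to_neg_ratio < 0) stop("ratio must be non-negative")
  p <- pos_to_neg_ratio / (1 + pos_to_neg_ratio)
  2 * p / (1 + p)
}

#' Prediction metrics
#'
#' @param predictions,truths Equal-length vectors. Classification metrics
#'   (`f1`, `mcc`, `accuracy`) expect 0/1 (predictions may be probabilities,
#'   thresholded at 0.5); `p_at_L` expects probabilities and 0/1 truths.
#' @param kind One of `"pcc"`, `"mae"`, `"f1"`, `"mcc"`, `"accuracy"`,
#'   `"spearman"`, `"p_at_L"`, `"auroc"`.
#' @param L For `p_at_L`: the number of top predictions scored (defaults to
#'   the vector length's square root rounded, callers normally pass the
#'   protein length).
#' @return Scalar metric value. A constant prediction or truth vector makes
#'   `pcc`/`spearman` undefined; these return 0 with a warning. An
#'   all-negative truth makes `f1` undefined; it returns 0 with a warning.
#' @export
metrics <- function(predictions, truths,
                    kind = c("pcc", "mae", "f1", "mcc", "accuracy",
                             "spearman", "p_at_L", "auroc"),
                    L = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(predictions) == length(truths))
  p <- as.numeric(predictions); t <- as.numeric(truths)
  if (kind %in% c("pcc", "spearman")) {
    if (stats::sd(p) == 0 || stats::sd(t) == 0) {
      warning(sprintf("%s undefined for constant vector; reporting 0", kind))
      return(0)
    }
    return(stats::cor(p, t, method = if (kind == "pcc") "pearson" else "spearman"))
  }
  if (kind == "mae") return(mean(abs(p - t)))
  if (kind == "p_at_L") {
    if (is.null(L)) L <- round(sqrt(length(p)))
    top <- order(p, decreasing = TRUE)[seq_len(min(L, length(p)))]
    return(mean(t[top]))
  }
  if (kind == "auroc") {
    pos <- p[t == 1]; neg <- p[t == 0]
    if (length(pos) == 0L || length(neg) == 0L) {
      warning("auroc undefined without both classes; reporting 0.5")
      return(0.5)
    }
    r <- rank(c(pos, neg))
    return((sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
             (length(pos) * length(neg)))
  }
  yhat <- as.numeric(p >= 0.5); y <- as.numeric(t >= 0.5)
  tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1); tn <- sum(yhat == 0 & y == 0)
  if (kind == "accuracy") return((tp + tn) / length(y))
  if (kind == "f1") {
    if (2 * tp + fp + fn == 0) {
      warning("f1 undefined (no positives anywhere); reporting 0")
      return(0)
    }
    return(2 * tp / (2 * tp + fp + fn))
  }
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) {
    warning("mcc undefined; reporting 0")
    return(0)
  }
  (tp * tn - fp * fn) / denom
}
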