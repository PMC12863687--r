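# File formats and run configuration. Coordinates are 0-based half-open
# everywhere inside the package (1-based only at the PDB boundary); energies
# are kcal/mol throughout.

#' Read a FASTA file
#'
#' Lowercase sequence characters are upcased with a warning.
#'
#' @param path FASTA file.
#' @return Named character vector (names are the full header lines without
#'   `>`); empty files give an empty vector.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase characters in FASTA input; upcasing")
    seqs <- toupper(seqs)
  }
  stats::setNames(unname(seqs), names(set))
}

#' Write sequences as wrapped FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a tab-separated complex table
#'
#' Columns: `protein_seq`, `nucleic_seq_1`, optionally `nucleic_seq_2` and
#' `dG` (kcal/mol). Rows whose protein or nucleic sequences contain
#' non-canonical characters are dropped and counted in a warning, mirroring
#' the standard-residue filter applied to binding databases.
#'
#' @param path TSV file with a header row.
#' @return A `momlm_complexes` data frame; attribute `n_dropped` records the
#'   rejected row count.
#' @export
read_complex_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_seq", "nucleic_seq_1") %in% names(df)))
  if (!"nucleic_seq_2" %in% names(df)) df$nucleic_seq_2 <- NA_character_
  df$nucleic_seq_2[!is.na(df$nucleic_seq_2) & df$nucleic_seq_2 == ""] <- NA_character_
  if (!"dG" %in% names(df)) df$dG <- NA_real_
  ok_chars <- function(s, alpha) {
    vapply(strsplit(s, ""), function(ch) all(ch %in% alpha), logical(1))
  }
  ok <- ok_chars(df$protein_seq, PROTEIN_ALPHABET) &
    ok_chars(df$nucleic_seq_1, NUCLEIC_ALPHABET) &
    (is.na(df$nucleic_seq_2) | ok_chars(df$nucleic_seq_2, NUCLEIC_ALPHABET)) &
    nchar(df$protein_seq) > 0 & nchar(df$nucleic_seq_1) > 0
  if (any(!ok)) {
    warning(sprintf("dropped %d row(s) with non-canonical or empty sequences",
                    sum(!ok)))
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  class(out) <- c("momlm_complexes", "data.frame")
  out
}

#' Write a complex table as TSV
#' @param records A `momlm_complexes` data frame.
#' @param path Output file.
#' @export
write_complex_table <- function(records, path) {
  keep <- intersect(c("protein_seq", "nucleic_seq_1", "nucleic_seq_2", "dG"),
                    names(records))
  utils::write.table(as.data.frame(records)[, keep, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

.known_config_keys <- c(
  "seed", "modality", "algorithm", "vocab_size", "tokenizer_max_chars",
  "width", "n_layers", "n_heads", "context_length", "rope_base",
  "mask_rate", "mask_frac_mask", "mask_frac_random",
  "embedding_lr", "hidden_lr_base", "adam_beta1", "adam_beta2", "adam_eps",
  "weight_decay", "warmup_tokens", "start_end_scale", "batch_tokens",
  "budget_tokens",
  "ft_epochs", "ft_batch", "lr_head", "lr_emb", "lr_body_base",
  "n_folds", "pin_threshold", "contact_threshold", "min_separation",
  "clip_tau", "clip_rank", "clip_train_frac", "clip_steps", "clip_lr",
  "probe_steps", "probe_batch", "probe_lr",
  "scan_p", "scan_n_mutants",
  "paths_in", "paths_out")

#' Default run configuration
#'
#' Every printed hyperparameter of the training recipe as a named list:
#' MLM mask rate 0.15 with the 80/10/10 corruption mix, AdamW
#' (0.9, 0.95, 1e-8, weight decay 1e-2), embedding learning rate 0.05 with
#' 32/width scaling for the remaining parameters, one-cycle schedule between
#' scale 1e-5 and 1, fine-tuning rates 1e-2 (head) / 1e-3 (embeddings) /
#' 1e-4 * 1024/width (body), 10 folds pinned at normalized score 1.5,
#' contrastive probe tau 0.07 and rank 16 trained on a 5% split for 10000
#' steps at lr 0.01, attention probe 1000 steps at batch 256 and lr 1e-3,
#' and the 5% / 8-mutant scan settings.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(seed = 1L, modality = "nucleic", algorithm = "bpe", vocab_size = 2048L,
       tokenizer_max_chars = 1e5, width = 64L, n_layers = 2L, n_heads = 4L,
       context_length = 1024L, rope_base = 10000,
       mask_rate = 0.15, mask_frac_mask = 0.8, mask_frac_random = 0.1,
       embedding_lr = 0.05, hidden_lr_base = 0.05, adam_beta1 = 0.9,
       adam_beta2 = 0.95, adam_eps = 1e-8, weight_decay = 1e-2,
       warmup_tokens = 1e9, start_end_scale = 1e-5, batch_tokens = 16384L,
       budget_tokens = 1e5,
       ft_epochs = 64L, ft_batch = 256L, lr_head = 1e-2, lr_emb = 1e-3,
       lr_body_base = 1e-4, n_folds = 10L, pin_threshold = 1.5,
       contact_threshold = 8, min_separation = 12L,
       clip_tau = 0.07, clip_rank = 16L, clip_train_frac = 0.05,
       clip_steps = 10000L, clip_lr = 0.01,
       probe_steps = 1000L, probe_batch = 256L, probe_lr = 1e-3,
       scan_p = 0.05, scan_n_mutants = 8L,
       paths_in = "", paths_out = "")
}

#' Load a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path YAML file (or NULL for pure defaults).
#' @return Full configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), .known_config_keys)
    if (length(unknown) > 0L) {
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(user)] <- user
  }
  cfg
}

#' Snapshot a configuration into an output directory
#'
#' Every command writes the exact configuration it ran with, so any run is
#' reproducible from its output directory alone.
#'
#' @param config Configuration list.
#' @param out_dir Output directory (created if needed).
#' @return Path of the written snapshot.
#' @export
write_config_snapshot <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "config_snapshot.yaml")
  yaml::write_yaml(config, path)
  path
}
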