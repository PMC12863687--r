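# Modality-disjoint tokenizers (byte-pair and single-character) with exact
# per-token character spans. Ids are 0-based throughout the package; the two
# modality id ranges never overlap, so a string such as "ACGT" tokenizes to
# different ids depending on whether it is read as DNA or as peptide.

NUCLEIC_ALPHABET <- c("A", "C", "G", "T", "U")
PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
SPECIAL_NAMES <- c("mask", "pad", "cls", "sep")

#' Canonical alphabet for a modality
#'
#' @param modality `"nucleic"` or `"protein"`.
#' @return Character vector of canonical single-letter symbols.
#' @export
modality_alphabet <- function(modality) {
  modality <- match.arg(modality, c("nucleic", "protein"))
  if (modality == "nucleic") NUCLEIC_ALPHABET else PROTEIN_ALPHABET
}

#' Drop sequences containing non-canonical characters
#'
#' @param sequences Character vector.
#' @param modality `"nucleic"` or `"protein"`.
#' @param warn Emit a warning naming how many sequences were dropped.
#' @return The surviving sequences (attribute `n_dropped` records the count).
#' @export
filter_canonical <- function(sequences, modality, warn = TRUE) {
  alpha <- modality_alphabet(modality)
  ok <- vapply(strsplit(sequences, ""), function(ch) all(ch %in% alpha), logical(1))
  if (warn && any(!ok)) {
    warning(sprintf("dropped %d %s sequence(s) with non-canonical characters",
                    sum(!ok), modality))
  }
  out <- sequences[ok]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

new_vocabulary <- function(pieces, modality, algorithm, id_offset, special_ids) {
  structure(list(pieces = pieces, modality = modality, algorithm = algorithm,
                 id_offset = as.integer(id_offset),
                 special_ids = lapply(special_ids, as.integer)),
            class = "momlm_vocab")
}

#' @export
print.momlm_vocab <- function(x, ...) {
  cat(sprintf("<momlm_vocab> %s/%s: %d pieces, ids [%d, %d], specials %s\n",
              x$modality, x$algorithm, length(x$pieces), x$id_offset,
              x$id_offset + length(x$pieces) - 1L,
              paste(sprintf("%s=%d", names(x$special_ids),
                            unlist(x$special_ids)), collapse = " ")))
  invisible(x)
}

# Greedy left-to-right selection of non-overlapping occurrences among
# candidate positions (needed for runs such as "AAAA" when merging "A","A").
.select_nonoverlapping <- function(pos) {
  if (length(pos) <= 1L) return(pos)
  keep <- pos[1L]
  last <- pos[1L]
  for (p in pos[-1L]) {
    if (p > last + 1L) {
      keep <- c(keep, p)
      last <- p
    }
  }
  keep
}

# One BPE merge pass over a flat symbol vector (sequence boundaries are
# sentinel symbols that never participate in merges).
.apply_merge <- function(syms, a, b, piece) {
  n <- length(syms)
  pos <- which(syms[-n] == a & syms[-1L] == b)
  pos <- .select_nonoverlapping(pos)
  if (length(pos) == 0L) return(syms)
  syms[pos] <- piece
  syms[-(pos + 1L)]
}

#' Train a tokenizer vocabulary
#'
#' Trains either a byte-pair-encoding vocabulary (iteratively merging the most
#' frequent adjacent symbol pair, ties broken lexicographically for
#' determinism) or a single-character vocabulary (one piece per canonical
#' symbol) on a corpus of one modality.
#'
#' @param corpus Character vector of training sequences. Sequences containing
#'   characters outside the modality alphabet are rejected with a warning.
#' @param modality `"nucleic"` or `"protein"`.
#' @param vocab_size Target number of pieces (alphabet included). Ignored for
#'   `single_char`. Must be at least the alphabet size.
#' @param algorithm `"bpe"` or `"single_char"`.
#' @param id_offset First token id of this vocabulary's piece range.
#' @param special_base First id of this vocabulary's four special tokens
#'   (mask, pad, cls, sep). Defaults to `id_offset + vocab_size`, which is
#'   only safe for a lone vocabulary; [train_vocab_pair()] lays out disjoint
#'   ranges for the two-modality case.
#' @param max_chars Cap on the number of characters sampled from the corpus
#'   for BPE pair counting (the training budget; default 1e5).
#' @return A `momlm_vocab` object.
#' @export
train_tokenizer <- function(corpus, modality, vocab_size = 64L,
                            algorithm = c("bpe", "single_char"),
                            id_offset = 0L, special_base = NULL,
                            max_chars = 1e5) {
  algorithm <- match.arg(algorithm)
  modality <- match.arg(modality, c("nucleic", "protein"))
  alpha <- modality_alphabet(modality)
  corpus <- filter_canonical(as.character(corpus), modality)
  if (length(corpus) == 0L) stop("empty corpus after filtering")
  if (algorithm == "single_char") {
    pieces <- alpha
  } else {
    if (vocab_size < length(alpha)) {
      stop(sprintf("vocab_size %d below alphabet size %d", vocab_size, length(alpha)))
    }
    # respect the character budget, whole sequences at a time
    lens <- cumsum(nchar(corpus))
    n_take <- max(1L, sum(lens <= max_chars))
    corpus <- corpus[seq_len(min(n_take, length(corpus)))]
    sent <- "\x01"
    syms <- unlist(lapply(corpus, function(s) c(strsplit(s, "")[[1]], sent)))
    pieces <- alpha
    while (length(pieces) < vocab_size) {
      n <- length(syms)
      if (n < 2L) break
      left <- syms[-n]; right <- syms[-1L]
      valid <- left != sent & right != sent
      if (!any(valid)) break
      pair_keys <- paste0(left[valid], "\x02", right[valid])
      tab <- table(pair_keys)
      best_n <- max(tab)
      if (best_n < 2L) break
      cand <- sort(names(tab)[tab == best_n])[1L]  # deterministic tie-break
      ab <- strsplit(cand, "\x02", fixed = TRUE)[[1]]
      piece <- paste0(ab[1L], ab[2L])
      syms <- .apply_merge(syms, ab[1L], ab[2L], piece)
      # the concatenation can coincide with an existing piece when the same
      # string arises from two different splits; merge but do not duplicate
      if (!(piece %in% pieces)) pieces <- c(pieces, piece)
    }
    if (length(pieces) < vocab_size) {
      warning(sprintf("corpus exhausted at %d pieces (requested %d)",
                      length(pieces), vocab_size))
    }
  }
  if (is.null(special_base)) special_base <- id_offset + length(pieces)
  specials <- as.list(seq.int(special_base, length.out = 4L))
  names(specials) <- SPECIAL_NAMES
  new_vocabulary(pieces, modality, algorithm, id_offset, specials)
}

#' Train a disjoint nucleic/protein vocabulary pair
#'
#' Lays out the combined 0-based id space: nucleic pieces first, protein
#' pieces second, then the eight special ids (four per modality). The two
#' piece ranges are disjoint by construction.
#'
#' @param nucleic_corpus,protein_corpus Training sequences per modality.
#' @param vocab_size Pieces per modality for BPE (the published budget is
#'   2^11 per modality).
#' @param algorithm `"bpe"` or `"single_char"`.
#' @param max_chars Character budget per modality for BPE training.
#' @return List with elements `nucleic`, `protein` (both `momlm_vocab`) and
#'   `n_ids` (total id-space size for an encoder embedding table).
#' @export
train_vocab_pair <- function(nucleic_corpus, protein_corpus, vocab_size = 64L,
                             algorithm = c("bpe", "single_char"),
                             max_chars = 1e5) {
  algorithm <- match.arg(algorithm)
  nuc <- train_tokenizer(nucleic_corpus, "nucleic", vocab_size, algorithm,
                         id_offset = 0L, special_base = 0L,  # placeholder
                         max_chars = max_chars)
  prot <- train_tokenizer(protein_corpus, "protein", vocab_size, algorithm,
                          id_offset = length(nuc$pieces), special_base = 0L,
                          max_chars = max_chars)
  base <- length(nuc$pieces) + length(prot$pieces)
  nuc$special_ids <- stats::setNames(as.list(seq.int(base, length.out = 4L)),
                                     SPECIAL_NAMES)
  prot$special_ids <- stats::setNames(as.list(seq.int(base + 4L, length.out = 4L)),
                                      SPECIAL_NAMES)
  list(nucleic = nuc, protein = prot, n_ids = base + 8L)
}

#' Total id-space size implied by a vocabulary pair
#' @param vocabs List as returned by [train_vocab_pair()].
#' @return Integer count of distinct ids (pieces of both modalities + specials).
#' @export
vocab_space_size <- function(vocabs) {
  max(unlist(lapply(vocabs[c("nucleic", "protein")], function(v) {
    max(v$id_offset + length(v$pieces) - 1L, unlist(v$special_ids))
  }))) + 1L
}

#' Encode a sequence into tokens with character spans
#'
#' Greedy longest-match segmentation against the vocabulary pieces. Spans are
#' 0-based half-open character intervals that tile the input exactly, so
#' [decode()] is an exact inverse and per-residue labels can be moved between
#' residue and token space.
#'
#' @param sequence A single string over the modality alphabet.
#' @param vocabulary A `momlm_vocab`.
#' @return A `momlm_tokens` object: list(ids, spans, modality) where `spans`
#'   is an n x 2 matrix of (start, end).
#' @export
encode <- function(sequence, vocabulary) {
  stopifnot(inherits(vocabulary, "momlm_vocab"), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) {
    return(structure(list(ids = integer(0),
                          spans = matrix(integer(0), ncol = 2,
                                         dimnames = list(NULL, c("start", "end"))),
                          modality = vocabulary$modality),
                     class = "momlm_tokens"))
  }
  piece_env <- new.env(parent = emptyenv())
  for (j in seq_along(vocabulary$pieces)) {
    assign(vocabulary$pieces[j], j, envir = piece_env)
  }
  maxlen <- max(nchar(vocabulary$pieces))
  ids <- integer(0); starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
      cand <- substr(sequence, i, i + len - 1L)
      j <- piece_env[[cand]]
      if (!is.null(j)) { hit <- j; break }
    }
    if (hit == 0L) {
      stop(sprintf("invalid character '%s' for %s vocabulary at position %d",
                   substr(sequence, i, i), vocabulary$modality, i))
    }
    ids <- c(ids, vocabulary$id_offset + hit - 1L)
    starts <- c(starts, i - 1L)
    ends <- c(ends, i - 1L + nchar(vocabulary$pieces[hit]))
    i <- i + nchar(vocabulary$pieces[hit])
  }
  structure(list(ids = ids,
                 spans = cbind(start = starts, end = ends),
                 modality = vocabulary$modality),
            class = "momlm_tokens")
}

#' Decode token ids back to the original string
#'
#' @param tokens A `momlm_tokens` object or a plain integer id vector.
#' @param vocabulary The vocabulary the ids were produced with.
#' @return The decoded string; errors on any id outside the vocabulary's
#'   piece range (including ids from the other modality).
#' @export
decode <- function(tokens, vocabulary) {
  stopifnot(inherits(vocabulary, "momlm_vocab"))
  ids <- if (inherits(tokens, "momlm_tokens")) tokens$ids else as.integer(tokens)
  if (length(ids) == 0L) return("")
  idx <- ids - vocabulary$id_offset + 1L
  bad <- idx < 1L | idx > length(vocabulary$pieces)
  if (any(bad)) {
    stop(sprintf("id %d outside the %s piece range [%d, %d]",
                 ids[which(bad)[1]], vocabulary$modality, vocabulary$id_offset,
                 vocabulary$id_offset + length(vocabulary$pieces) - 1L))
  }
  paste(vocabulary$pieces[idx], collapse = "")
}

#' @export
print.momlm_tokens <- function(x, ...) {
  cat(sprintf("<momlm_tokens> %s, %d tokens\n", x$modality, length(x$ids)))
  invisible(x)
}

#' Write a vocabulary as plain text
#'
#' One piece per line after a `#`-prefixed metadata header.
#' @param vocabulary A `momlm_vocab`.
#' @param path Output file.
#' @export
write_vocabulary <- function(vocabulary, path) {
  hdr <- sprintf("# momlm_vocab modality=%s algorithm=%s id_offset=%d %s",
                 vocabulary$modality, vocabulary$algorithm, vocabulary$id_offset,
                 paste(sprintf("%s=%d", names(vocabulary$special_ids),
                               unlist(vocabulary$special_ids)), collapse = " "))
  writeLines(c(hdr, vocabulary$pieces), path)
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#' @param path Input file.
#' @return A `momlm_vocab`.
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[A-Za-z0-9_]+", hdr))[[1]]
  fields <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  specials <- stats::setNames(as.list(as.integer(fields[SPECIAL_NAMES])),
                              SPECIAL_NAMES)
  new_vocabulary(lines[-1L], fields[["modality"]], fields[["algorithm"]],
                 as.integer(fields[["id_offset"]]), specials)
}
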