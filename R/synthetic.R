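# Seeded synthetic-data generators. These define the study conditions for
# every training experiment in the package: gene/protein pairs related by the
# standard genetic code (with GT..AG introns), a binding dataset whose dG is
# produced by a known recoverable energy model, and toy contact structures
# whose distance-derived labels equal the planted labels by construction.

.sample_chars <- function(alphabet, n) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate gene-protein pairs under the standard genetic code
#'
#' Each protein is a uniform random amino-acid string; its gene is built by
#' sampling a synonymous codon per residue (NCBI translation table 1),
#' inserting GT..AG-bounded random introns between codons at rate
#' `intron_rate`, and appending a stop codon. Translating the concatenated
#' exons therefore reproduces the protein exactly.
#'
#' @param n Number of pairs.
#' @param protein_length_range Length range (inclusive) for the proteins.
#' @param intron_rate Probability of an intron after each codon.
#' @param seed Integer seed; generation is a pure function of it.
#' @return A `momlm_gene_pairs` object: data frame with columns `gene`,
#'   `protein`, and an `exons` attribute (list of 0-based half-open interval
#'   matrices covering the coding codons of each gene, stop codon excluded).
#' @export
gen_gene_protein_pairs <- function(n, protein_length_range = c(20L, 40L),
                                   intron_rate = 0.15, seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  if (min(protein_length_range) < 1L) stop("zero-length proteins not allowed")
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  codons_of <- split(names(code), code)
  stops <- codons_of[["*"]]
  genes <- character(n); prots <- character(n); exons <- vector("list", n)
  len_choices <- seq(protein_length_range[1], protein_length_range[2])
  for (i in seq_len(n)) {
    len <- len_choices[sample.int(length(len_choices), 1L)]
    aa <- sample(PROTEIN_ALPHABET, len, replace = TRUE)
    parts <- character(0)
    ex_start <- integer(0); ex_end <- integer(0)
    pos <- 0L
    open_exon <- NA_integer_
    for (j in seq_len(len)) {
      codon <- sample(codons_of[[aa[j]]], 1L)
      if (is.na(open_exon)) open_exon <- pos
      parts <- c(parts, codon)
      pos <- pos + 3L
      if (stats::runif(1) < intron_rate) {
        ex_start <- c(ex_start, open_exon); ex_end <- c(ex_end, pos)
        open_exon <- NA_integer_
        intron <- paste0("GT", .sample_chars(c("A", "C", "G", "T"),
                                             sample(4:12, 1L)), "AG")
        parts <- c(parts, intron)
        pos <- pos + nchar(intron)
      }
    }
    if (!is.na(open_exon)) {
      ex_start <- c(ex_start, open_exon); ex_end <- c(ex_end, pos)
    }
    parts <- c(parts, sample(stops, 1L))  # trailing stop, outside the exons
    genes[i] <- paste(parts, collapse = "")
    prots[i] <- paste(aa, collapse = "")
    exons[[i]] <- cbind(start = ex_start, end = ex_end)
  }
  out <- data.frame(gene = genes, protein = prots, stringsAsFactors = FALSE)
  attr(out, "exons") <- exons
  class(out) <- c("momlm_gene_pairs", "data.frame")
  out
}

#' Closed-form binding free energy of the synthetic energy model
#'
#' @param model The `model` attribute of a [gen_binding_dataset()] result.
#' @param family Family index.
#' @param nucleic_seq Binding-site sequence (length = motif width).
#' @return Noiseless dG in kcal/mol.
#' @export
binding_true_dG <- function(model, family, nucleic_seq) {
  bases <- strsplit(nucleic_seq, "")[[1]]
  stopifnot(length(bases) == ncol(model$energies[[family]]))
  model$baselines[family] +
    sum(model$energies[[family]][cbind(match(bases, c("A", "C", "G", "T")),
                                       seq_along(bases))])
}

#' Generate a protein-nucleic binding dataset with known energies
#'
#' Proteins are organized in families: each family carries a fixed
#' `tag_length`-residue identity tag at the start of the sequence (the
#' learnable family signal) followed by random residues, so within-family
#' pairwise identity stays low enough that homology-based pinning does not
#' remove whole families from the test folds. Each family f has a baseline
#' energy and a position-specific penalty matrix over its motif: the true
#' label is `dG = baseline_f + sum_w energy_f[base_w, w] + N(0, sigma)` with
#' `energy_f[consensus_w, w] = 0` and positive penalties elsewhere, so the
#' consensus site is the strongest (most negative) binder of every family.
#' Binding sites are sampled near the consensus (per-position retention
#' probability `site_fidelity`, else a uniform different base). Optionally a
#' few near-duplicate proteins (single point mutants, normalized alignment
#' score far above 1.5) are planted to exercise the homology pinning rule.
#'
#' @param n_families,proteins_per_family,seqs_per_protein Dataset shape.
#' @param motif_width Binding-site width W.
#' @param noise_sigma Gaussian label noise, kcal/mol.
#' @param protein_length,tag_length Protein geometry (tag at positions
#'   1..tag_length identifies the family).
#' @param baseline_mean,baseline_sd Family baseline energy distribution
#'   (kcal/mol); baselines are the evenly spaced quantiles of
#'   N(mean, sd^2), randomly assigned to families.
#' @param penalty_range Uniform range for non-consensus penalties (kcal/mol).
#' @param site_fidelity Per-position probability that a sampled site keeps
#'   the consensus base.
#' @param shared_consensus When TRUE (default) all families share one
#'   consensus site and differ only in their penalty matrices and baselines;
#'   the binding site alone then carries no family information, so the
#'   family-by-site interaction genuinely requires both modalities. When
#'   FALSE each family draws its own consensus.
#' @param frac_double Fraction of records carrying a second (reverse
#'   complement) nucleic strand.
#' @param n_near_duplicates Number of planted point-mutant near-duplicate
#'   proteins.
#' @param seed Integer seed.
#' @return A `momlm_complexes` data frame (protein_seq, nucleic_seq_1,
#'   nucleic_seq_2, dG, family, dG_true) with attribute `model` (tags,
#'   consensus strings, energy matrices, baselines, PFM count matrices).
#' @export
gen_binding_dataset <- function(n_families = 6L, proteins_per_family = 8L,
                                seqs_per_protein = 8L, motif_width = 8L,
                                noise_sigma = 0.5, protein_length = 20L,
                                tag_length = 4L, baseline_mean = -10,
                                baseline_sd = 2.0, penalty_range = c(0.25, 1.75),
                                site_fidelity = 0.7, shared_consensus = TRUE,
                                frac_double = 0, n_near_duplicates = 2L,
                                seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  # distinct family tags
  tags <- character(0)
  while (length(tags) < n_families) {
    tags <- unique(c(tags, .sample_chars(PROTEIN_ALPHABET, tag_length)))
  }
  consensus <- character(n_families)
  energies <- vector("list", n_families)
  pfms <- vector("list", n_families)
  # evenly spaced quantiles of the baseline distribution, randomly assigned
  # to families: the realized spread (and with it the difficulty of the
  # recovery task) is then stable across seeds, while individual values
  # still vary with the assignment
  baselines <- sample(stats::qnorm((seq_len(n_families) - 0.5) / n_families,
                                   baseline_mean, baseline_sd))
  cons_shared <- .sample_chars(bases, motif_width)
  for (f in seq_len(n_families)) {
    consensus[f] <- if (shared_consensus) cons_shared
                    else .sample_chars(bases, motif_width)
    e <- matrix(stats::runif(4 * motif_width, penalty_range[1], penalty_range[2]),
                4, motif_width, dimnames = list(bases, NULL))
    e[cbind(match(strsplit(consensus[f], "")[[1]], bases), seq_len(motif_width))] <- 0
    energies[[f]] <- e
    pfm <- round(12 * exp(-e))  # strict per-column maximum at the consensus
    rownames(pfm) <- bases
    pfms[[f]] <- pfm
  }
  proteins <- list(); fam_of <- integer(0)
  for (f in seq_len(n_families)) {
    for (k in seq_len(proteins_per_family)) {
      proteins[[length(proteins) + 1L]] <-
        paste0(tags[f], .sample_chars(PROTEIN_ALPHABET, protein_length - tag_length))
      fam_of <- c(fam_of, f)
    }
  }
  proteins <- unlist(proteins)
  if (n_near_duplicates > 0L) {
    for (i in seq_len(min(n_near_duplicates, length(proteins)))) {
      p <- strsplit(proteins[i], "")[[1]]
      j <- sample(seq_along(p), 1L)
      p[j] <- sample(setdiff(PROTEIN_ALPHABET, p[j]), 1L)
      proteins <- c(proteins, paste(p, collapse = ""))
      fam_of <- c(fam_of, fam_of[i])
    }
  }
  sample_site <- function(f) {
    cons <- strsplit(consensus[f], "")[[1]]
    keep <- stats::runif(motif_width) < site_fidelity
    site <- cons
    for (w in which(!keep)) site[w] <- sample(setdiff(bases, cons[w]), 1L)
    paste(site, collapse = "")
  }
  rows <- vector("list", length(proteins) * seqs_per_protein)
  idx <- 0L
  for (i in seq_along(proteins)) {
    for (s in seq_len(seqs_per_protein)) {
      idx <- idx + 1L
      f <- fam_of[i]
      site <- sample_site(f)
      dg_true <- binding_true_dG(list(energies = energies, baselines = baselines),
                                 f, site)
      second <- if (stats::runif(1) < frac_double) revcomp_dna(site) else NA_character_
      rows[[idx]] <- data.frame(protein_seq = proteins[i], nucleic_seq_1 = site,
                                nucleic_seq_2 = second,
                                dG = dg_true + stats::rnorm(1, 0, noise_sigma),
                                family = f, dG_true = dg_true,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- list(tags = tags, consensus = consensus,
                             energies = energies, baselines = baselines,
                             pfms = pfms)
  class(out) <- c("momlm_complexes", "data.frame")
  out
}

#' Reverse complement of a DNA string
#' @param s DNA sequence over ACGT.
#' @return The reverse complement.
#' @export
revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a toy contact dataset with planted motif-driven labels
#'
#' Plants one copy of `motif` per protein (away from the termini); the
#' contacting residues are the motif positions dilated by `jitter` on each
#' side, so with the defaults (motif "RKR", jitter 1, protein length 17) the
#' positive rate is exactly 5/17 = 0.294 per protein. In coordinate mode a
#' synthetic complex is emitted per record: protein CA atoms on a 12-Angstrom
#' grid and one nucleic P atom placed 3-7.5 Angstrom from each contacting
#' residue, so distance-thresholded labels at 8 Angstrom reproduce the
#' planted labels exactly.
#'
#' @param n Number of records.
#' @param protein_length Protein length (17 gives the 0.29 positive ratio).
#' @param motif Planted protein motif.
#' @param jitter Dilation (residues) of the contact region around the motif.
#' @param nucleic_length Length of the random DNA partner.
#' @param coordinates Also build synthetic atom tables.
#' @param seed Integer seed.
#' @return A `momlm_complexes` data frame (protein_seq, nucleic_seq_1) with
#'   attributes `contact_labels` (list of logical vectors) and, if requested,
#'   `structures` (list of atom data frames compatible with
#'   [label_contacts()]).
#' @export
gen_contact_dataset <- function(n, protein_length = 17L, motif = "RKR",
                                jitter = 1L, nucleic_length = 10L,
                                coordinates = FALSE, seed = 1L) {
  set.seed(seed)
  mlen <- nchar(motif)
  if (protein_length < mlen + 2L * jitter + 2L) stop("protein too short for motif")
  bases <- c("A", "C", "G", "T")
  prot <- character(n); nuc <- character(n)
  labels <- vector("list", n); structures <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sample(PROTEIN_ALPHABET, protein_length, replace = TRUE)
    starts <- seq(jitter + 1L, protein_length - mlen - jitter + 1L)
    start <- starts[sample.int(length(starts), 1L)]
    p[start:(start + mlen - 1L)] <- strsplit(motif, "")[[1]]
    lab <- rep(FALSE, protein_length)
    lab[(start - jitter):(start + mlen - 1L + jitter)] <- TRUE
    prot[i] <- paste(p, collapse = "")
    nuc[i] <- .sample_chars(bases, nucleic_length)
    labels[[i]] <- lab
    if (coordinates) {
      pa <- data.frame(chain = "A", chain_type = "protein",
                       resno = seq_len(protein_length), elety = "CA",
                       x = 12 * seq_len(protein_length), y = 0, z = 0,
                       stringsAsFactors = FALSE)
      pos <- which(lab)
      na <- data.frame(chain = "B", chain_type = "nucleic",
                       resno = seq_along(pos), elety = "P",
                       x = 12 * pos, y = stats::runif(length(pos), 3, 7.5), z = 0,
                       stringsAsFactors = FALSE)
      structures[[i]] <- rbind(pa, na)
    }
  }
  out <- data.frame(protein_seq = prot, nucleic_seq_1 = nuc,
                    nucleic_seq_2 = NA_character_, stringsAsFactors = FALSE)
  attr(out, "contact_labels") <- labels
  if (coordinates) attr(out, "structures") <- structures
  class(out) <- c("momlm_complexes", "data.frame")
  out
}

#' Write a synthetic atom table as a minimal PDB file
#'
#' Emits ATOM records for the toy complexes produced by
#' [gen_contact_dataset()]; readable by [read_structure_atoms()].
#'
#' @param atoms Atom data frame (chain, chain_type, resno, elety, x, y, z).
#' @param path Output file.
#' @export
write_synthetic_pdb <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(atoms))) {
    resid <- if (atoms$chain_type[i] == "protein") "ALA" else "DA"
    elem <- substr(atoms$elety[i], 1, 1)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      i, atoms$elety[i], resid, atoms$chain[i], atoms$resno[i],
      atoms$x[i], atoms$y[i], atoms$z[i], elem), con)
  }
  writeLines("END", con)
  invisible(path)
}
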