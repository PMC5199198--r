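#' Generate a random base proteome
#'
#' Sequences are i.i.d. uniform over the 20 standard amino acids;
#' deterministic for a given seed. Used as the ancestor of a synthetic
#' strain family.
#'
#' @param n_proteins Number of proteins (>= 1). Ignored when `lengths` is
#'   given.
#' @param length_range Two-element integer vector; protein lengths are drawn
#'   uniformly from this range (minimum 30 residues).
#' @param seed Integer seed.
#' @param proteome_id,species_group_id Identifiers for the generated
#'   proteome.
#' @param lengths Optional explicit vector of protein lengths, overriding
#'   `n_proteins`/`length_range`.
#' @param ... Metadata fields passed to [proteome()].
#' @return A [proteome].
#' @export
generate_base_proteome <- function(n_proteins, length_range = c(100L, 400L),
                                   seed = 0L, proteome_id = "base",
                                   species_group_id = "sp1", lengths = NULL,
                                   ...) {
  with_private_seed(seed, {
    if (is.null(lengths)) {
      stopifnot(n_proteins >= 1, length(length_range) == 2,
                length_range[1] >= 30)
      lengths <- sample(length_range[1]:length_range[2], n_proteins,
                        replace = TRUE)
    }
    seqs <- vapply(lengths, function(L) {
      paste(sample(aa_standard, L, replace = TRUE), collapse = "")
    }, character(1))
    proteome(
      proteome_id,
      tibble::tibble(
        protein_id = sprintf("%s_p%03d", proteome_id, seq_along(seqs)),
        sequence = seqs),
      species_group_id = species_group_id, ...)
  })
}

#' Derive a strain proteome from a base proteome
#'
#' Emulates a sequenced strain of the same species: point substitutions,
#' gene loss and gene gain. Substitutions follow an exact-count model —
#' each retained protein has exactly `round(substitution_rate * length)`
#' positions changed to a different residue — so the per-protein identity
#' to the base is `1 - round(rate * L) / L` by construction (up to the rare
#' realignment gain of interacting substitutions). `floor(gene_loss_fraction
#' * n)` proteins are dropped (chosen at random) and `gene_gain_count` novel
#' random proteins appended.
#'
#' @param base The ancestral [proteome].
#' @param substitution_rate Fraction of residues substituted per protein,
#'   in \[0, 1).
#' @param gene_loss_fraction Fraction of proteins deleted, in \[0, 1).
#' @param gene_gain_count Number of novel random proteins appended.
#' @param seed Integer seed.
#' @param proteome_id Identifier of the strain proteome.
#' @param ... Metadata fields passed to [proteome()].
#' @return A [proteome] in the same species group as `base`.
#' @export
mutate_strain <- function(base, substitution_rate = 0.01,
                          gene_loss_fraction = 0, gene_gain_count = 0L,
                          seed = 0L, proteome_id = paste0(base$proteome_id,
                                                          "_strain"),
                          ...) {
  stopifnot(inherits(base, "proteome"),
            substitution_rate >= 0, substitution_rate < 1,
            gene_loss_fraction >= 0, gene_loss_fraction < 1,
            gene_gain_count >= 0)
  with_private_seed(seed, {
    prot <- base$proteins
    n_loss <- floor(gene_loss_fraction * nrow(prot))
    if (n_loss > 0) {
      prot <- prot[-sample.int(nrow(prot), n_loss), ]
    }
    seqs <- vapply(prot$sequence, substitute_exact,
                   character(1), rate = substitution_rate,
                   USE.NAMES = FALSE)
    gained <- character(0)
    if (gene_gain_count > 0) {
      gained <- vapply(seq_len(gene_gain_count), function(i) {
        L <- sample(100:400, 1)
        paste(sample(aa_standard, L, replace = TRUE), collapse = "")
      }, character(1))
    }
    proteome(
      proteome_id,
      tibble::tibble(
        protein_id = c(sub(base$proteome_id, proteome_id, prot$protein_id,
                           fixed = TRUE),
                       if (gene_gain_count > 0) {
                         sprintf("%s_gain%02d", proteome_id,
                                 seq_len(gene_gain_count))
                       }),
        sequence = c(seqs, gained)),
      species_group_id = base$species_group_id, ...)
  })
}

# Substitute exactly round(rate * L) positions, chosen without replacement,
# each replaced by a residue drawn uniformly from the 19 alternatives.
substitute_exact <- function(seq, rate) {
  L <- nchar(seq)
  n_sub <- round(rate * L)
  if (n_sub == 0) return(seq)
  pos <- sample.int(L, n_sub)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(aa_standard, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Specify one synthetic proteome family
#'
#' @param n_proteins Proteins in the base proteome.
#' @param length_range Protein length range (residues).
#' @param n_strains Number of derived strain proteomes.
#' @param substitution_rate,gene_loss_fraction,gene_gain_count Divergence
#'   parameters passed to [mutate_strain()].
#' @param seed Integer seed for this family.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_proteins = 50L, length_range = c(100L, 400L),
                        n_strains = 9L, substitution_rate = 0.01,
                        gene_loss_fraction = 0, gene_gain_count = 0L,
                        seed = 0L) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            gene_loss_fraction >= 0, gene_loss_fraction < 1)
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_range = as.integer(length_range),
         n_strains = as.integer(n_strains),
         substitution_rate = substitution_rate,
         gene_loss_fraction = gene_loss_fraction,
         gene_gain_count = as.integer(gene_gain_count),
         seed = as.integer(seed)),
    class = "family_spec"
  )
}

#' Generate a collection of strain-proteome families with ground truth
#'
#' Each family is one species group: a base proteome plus `n_strains`
#' derived strains. The base proteome is given annotation level 1 (strains
#' 0), mirroring the originally deposited, better-annotated genome, which
#' makes the expected survivor of a redundant family well defined. The
#' expected status of each proteome is computed analytically from the
#' generator's own bookkeeping: a strain is expected redundant iff its
#' retained proteins all reach the identity threshold
#' (`1 - round(rate * L)/L >= identity_threshold`) and the length-weighted
#' similarity of the strain to its base — retained identity weight over
#' retained-plus-gained length — reaches the similarity threshold.
#'
#' @param specs A list of [family_spec()] objects (or a single one).
#' @param identity_threshold,similarity_threshold Thresholds the ground
#'   truth is computed against (defaults 0.9).
#' @return A list with `proteomes` (list of [proteome]s) and `truth`
#'   (tibble: `proteome_id`, `species_group_id`, `expected_status`).
#' @export
generate_family_collection <- function(specs, identity_threshold = 0.9,
                                       similarity_threshold = 0.9) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "family_spec")))
  proteomes <- list()
  truth <- list()
  for (fi in seq_along(specs)) {
    sp <- specs[[fi]]
    fam_id <- sprintf("fam%02d", fi)
    base <- generate_base_proteome(
      sp$n_proteins, sp$length_range, seed = sp$seed,
      proteome_id = paste0(fam_id, "_base"), species_group_id = fam_id,
      annotation_level = 1L)
    strains <- lapply(seq_len(sp$n_strains), function(si) {
      mutate_strain(base, sp$substitution_rate, sp$gene_loss_fraction,
                    sp$gene_gain_count,
                    seed = sp$seed + si,
                    proteome_id = sprintf("%s_strain%02d", fam_id, si))
    })
    redundant <- vapply(strains, function(s) {
      strain_expected_redundant(base, s, sp$substitution_rate,
                                identity_threshold, similarity_threshold)
    }, logical(1))
    proteomes <- c(proteomes, list(base), strains)
    truth[[fi]] <- tibble::tibble(
      proteome_id = c(base$proteome_id,
                      vapply(strains, function(s) s$proteome_id,
                             character(1))),
      species_group_id = fam_id,
      expected_status = c("non-redundant",
                          ifelse(redundant, "redundant", "non-redundant"))
    )
  }
  list(proteomes = proteomes, truth = dplyr::bind_rows(truth))
}

# Analytic expectation of S(base, strain) from the exact-count model.
strain_expected_redundant <- function(base, strain, rate,
                                      identity_threshold,
                                      similarity_threshold) {
  retained <- intersect(sub(strain$proteome_id, base$proteome_id,
                            strain$proteins$protein_id, fixed = TRUE),
                        base$proteins$protein_id)
  rl <- base$proteins$length[base$proteins$protein_id %in% retained]
  ident <- 1 - round(rate * rl) / rl
  if (any(ident < identity_threshold)) return(FALSE)
  total_len <- sum(strain$proteins$length)
  sum(rl * ident) / total_len >= similarity_threshold
}

#' Write a synthetic collection to disk for the CLI workflow
#'
#' Writes one FASTA file per proteome, the metadata TSV and a ground-truth
#' TSV (`proteome_id`, `expected_status`).
#'
#' @param collection The result of [generate_family_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in collection$proteomes) {
    write_proteome_fasta(p, file.path(dir, paste0(p$proteome_id, ".fasta")))
  }
  write_metadata_table(proteomes_metadata(collection$proteomes),
                       file.path(dir, "metadata.tsv"))
  readr::write_tsv(collection$truth[, c("proteome_id", "expected_status")],
                   file.path(dir, "truth.tsv"))
  invisible(dir)
}
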