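#' Pipeline configuration
#'
#' Bundles the tunable parameters of the redundancy-minimization pipeline.
#' The defaults are the production settings: per-protein identity cut-off
#' 0.9, proteome similarity (edge) threshold 0.9, size-heuristic factor
#' 0.9, word size 5.
#'
#' @param identity_threshold Per-protein identity cut-off in (0, 1].
#' @param similarity_threshold Minimum proteome similarity for a redundancy
#'   edge, in (0, 1].
#' @param size_factor Size-heuristic factor in (0, 1].
#' @param word_size Word-filter k-mer length (integer >= 2).
#' @param seed Integer seed for reduction tie-breaking.
#' @param workers Reserved for per-group parallelism; results are
#'   independent of its value (groups share no state).
#' @return A list of class `prm_config`.
#' @export
prm_config <- function(identity_threshold = 0.9, similarity_threshold = 0.9,
                       size_factor = 0.9, word_size = 5L, seed = 0L,
                       workers = 1L) {
  for (v in c(identity_threshold, similarity_threshold, size_factor)) {
    if (!(v > 0 && v <= 1)) abort("Thresholds must be in (0, 1].")
  }
  if (as.integer(word_size) < 2) abort("`word_size` must be >= 2.")
  if (as.integer(workers) < 1) abort("`workers` must be >= 1.")
  structure(
    list(identity_threshold = identity_threshold,
         similarity_threshold = similarity_threshold,
         size_factor = size_factor, word_size = as.integer(word_size),
         seed = as.integer(seed), workers = as.integer(workers)),
    class = "prm_config"
  )
}

#' Run the redundancy-minimization pipeline on a list of proteomes
#'
#' Proteomes are partitioned by species group (the taxonomy heuristic),
#' every ordered pair within a group is compared subject to the size
#' heuristic, above-threshold comparisons become edges of a directed
#' redundancy graph, and each group's graph is reduced to a dominating set
#' by weakest-node elimination. Reference proteomes (and any ids on the
#' immune list) are protected from removal. Groups are fully independent,
#' so the result equals the union of per-group runs.
#'
#' @param proteomes A list of [proteome] objects with distinct ids.
#' @param config A [prm_config].
#' @param immune Extra proteome ids protected from removal, in addition to
#'   reference proteomes.
#' @param verbose Log per-group progress to stderr.
#' @return An object of class `prm_result`: a list with `statuses` (tibble:
#'   `proteome_id`, `species_group_id`, `status`, `representatives`
#'   list-column), `comparisons` (tibble over all groups), `graphs` (named
#'   list of per-group `redundancy_graph`s), `reductions` (named list of
#'   per-group `prm_reduction`s), `proteomes` and `config`.
#' @export
run_prm <- function(proteomes, config = prm_config(), immune = character(0),
                    verbose = FALSE) {
  stopifnot(all(vapply(proteomes, inherits, logical(1), "proteome")))
  ids <- vapply(proteomes, function(p) p$proteome_id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate proteome id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(proteomes) <- ids
  bad <- setdiff(immune, ids)
  if (length(bad) > 0) {
    abort(sprintf("Immune list id(s) not found: %s",
                  paste(bad, collapse = ", ")))
  }
  metadata <- proteomes_metadata(proteomes)
  groups <- group_by_species(proteomes)
  comparisons <- list()
  graphs <- list()
  reductions <- list()
  statuses <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    group <- proteomes[members]
    cmp <- compare_group(group,
                         identity_threshold = config$identity_threshold,
                         size_factor = config$size_factor,
                         word_size = config$word_size)
    gmeta <- metadata[metadata$proteome_id %in% members, ]
    graph <- build_graph(cmp, gmeta, threshold = config$similarity_threshold)
    protected <- union(gmeta$proteome_id[gmeta$is_reference],
                       intersect(immune, members))
    red <- reduce_graph(graph, protected = protected, seed = config$seed)
    if (verbose) {
      message(sprintf(
        "group %s: %d proteomes, %d/%d comparisons performed, %d edges, %d removed",
        g, length(members), sum(cmp$performed), nrow(cmp),
        nrow(graph$edges), length(red$removed)))
    }
    comparisons[[g]] <- cmp
    graphs[[g]] <- graph
    reductions[[g]] <- red
    statuses[[g]] <- tibble::tibble(
      proteome_id = members,
      species_group_id = g,
      status = ifelse(members %in% red$surviving, "non-redundant",
                      "redundant"),
      representatives = lapply(members, function(id) {
        if (id %in% red$surviving) character(0)
        else red$surviving_neighbours[[id]]
      })
    )
  }
  statuses <- dplyr::bind_rows(statuses)
  statuses <- statuses[order(statuses$proteome_id), ]
  structure(
    list(statuses = statuses,
         comparisons = dplyr::bind_rows(comparisons),
         graphs = graphs, reductions = reductions,
         proteomes = proteomes, config = config),
    class = "prm_result"
  )
}

#' Run the pipeline from FASTA files and a metadata table
#'
#' Reads one protein FASTA file per proteome from `fasta_dir` (named
#' `<proteome_id>.fasta`, `.fa` or `.faa`), joins the metadata table, and
#' runs [run_prm()]. Metadata rows without a FASTA file, or FASTA files
#' without a metadata row, are an error.
#'
#' @param fasta_dir Directory of per-proteome FASTA files.
#' @param metadata_path Path to the metadata TSV (see
#'   [read_metadata_table()]).
#' @param config A [prm_config].
#' @param immune Extra protected proteome ids.
#' @param out_dir If non-`NULL`, the results table (`results.tsv`),
#'   comparison records (`comparisons.tsv`) and graph edge lists
#'   (`edges.tsv`) are written there.
#' @param verbose Log progress to stderr.
#' @return A `prm_result` (see [run_prm()]).
#' @export
run_pipeline <- function(fasta_dir, metadata_path, config = prm_config(),
                         immune = character(0), out_dir = NULL,
                         verbose = FALSE) {
  metadata <- read_metadata_table(metadata_path)
  proteomes <- load_proteome_dir(fasta_dir, metadata)
  res <- run_prm(proteomes, config = config, immune = immune,
                 verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(res$statuses, file.path(out_dir, "results.tsv"))
    readr::write_tsv(res$comparisons, file.path(out_dir, "comparisons.tsv"))
    export_graph(merge_graphs(res$graphs),
                 file.path(out_dir, "edges.tsv"))
  }
  res
}

load_proteome_dir <- function(fasta_dir, metadata) {
  files <- list.files(fasta_dir, pattern = "\\.(fasta|fa|faa)$",
                      full.names = TRUE)
  file_ids <- sub("\\.(fasta|fa|faa)$", "", basename(files))
  no_file <- setdiff(metadata$proteome_id, file_ids)
  no_meta <- setdiff(file_ids, metadata$proteome_id)
  if (length(no_file) > 0 || length(no_meta) > 0) {
    abort(paste0(
      "Metadata/FASTA mismatch.",
      if (length(no_file)) paste0(" Missing FASTA: ",
                                  paste(no_file, collapse = ", ")),
      if (length(no_meta)) paste0(" Missing metadata: ",
                                  paste(no_meta, collapse = ", "))))
  }
  purrr::map(seq_len(nrow(metadata)), function(i) {
    md <- metadata[i, ]
    read_proteome_fasta(
      files[match(md$proteome_id, file_ids)],
      proteome_id = md$proteome_id,
      species_group_id = md$species_group_id,
      is_reference = md$is_reference,
      annotation_level = md$annotation_level,
      previous_state = md$previous_state
    )
  })
}

merge_graphs <- function(graphs) {
  structure(
    list(nodes = dplyr::bind_rows(lapply(graphs, `[[`, "nodes")),
         edges = dplyr::bind_rows(lapply(graphs, `[[`, "edges")),
         threshold = if (length(graphs)) graphs[[1]]$threshold else 0.9),
    class = "redundancy_graph"
  )
}

#' Incrementally update a previous pipeline result with new proteomes
#'
#' New proteomes are compared in both directions (heuristics applied)
#' against *all* same-group proteomes — previously redundant ones included,
#' since those were retained precisely for later comparisons — and against
#' each other. The redundancy graph is rebuilt from the old and new
#' comparison records, each old proteome's `previous_state` is set from its
#' prior status (1 non-redundant, 0 redundant), and the reduction is re-run.
#' A previously redundant proteome can thereby be reinstated when new data
#' make it the better representative; with no new proteomes the
#' previous-state rank component keeps the solution where it was.
#'
#' @param previous A `prm_result` from [run_prm()] or [run_pipeline()].
#' @param new_proteomes A list of [proteome] objects with ids disjoint from
#'   the previous run's.
#' @param config A [prm_config]; defaults to the previous run's.
#' @param immune Extra protected proteome ids (old or new).
#' @param verbose Log progress to stderr.
#' @return A new `prm_result` covering old and new proteomes.
#' @export
incremental_update <- function(previous, new_proteomes,
                               config = previous$config,
                               immune = character(0), verbose = FALSE) {
  stopifnot(inherits(previous, "prm_result"))
  old <- previous$proteomes
  new_ids <- vapply(new_proteomes, function(p) p$proteome_id, character(1))
  clash <- intersect(new_ids, names(old))
  if (length(clash) > 0) {
    abort(sprintf("New proteome id(s) collide with existing: %s",
                  paste(clash, collapse = ", ")))
  }
  # carry prior status into previous_state
  old <- lapply(old, function(p) {
    st <- previous$statuses$status[previous$statuses$proteome_id ==
                                     p$proteome_id]
    p$metadata$previous_state <- if (identical(st, "redundant")) 0L else 1L
    p
  })
  all_proteomes <- c(old, stats::setNames(new_proteomes, new_ids))
  metadata <- proteomes_metadata(all_proteomes)
  groups <- group_by_species(all_proteomes)
  graphs <- list()
  reductions <- list()
  statuses <- list()
  comparisons <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    newcomers <- intersect(members, new_ids)
    old_cmp <- previous$comparisons[
      previous$comparisons$subject_id %in% members &
        previous$comparisons$query_id %in% members, ]
    if (length(newcomers) == 0) {
      cmp <- old_cmp
    } else {
      cmp <- dplyr::bind_rows(
        old_cmp,
        compare_new_pairs(all_proteomes[members], newcomers, config))
    }
    gmeta <- metadata[metadata$proteome_id %in% members, ]
    graph <- build_graph(cmp, gmeta, threshold = config$similarity_threshold)
    protected <- union(gmeta$proteome_id[gmeta$is_reference],
                       intersect(immune, members))
    red <- reduce_graph(graph, protected = protected, seed = config$seed)
    if (verbose) {
      message(sprintf("group %s: %d proteomes (%d new), %d edges, %d removed",
                      g, length(members), length(newcomers),
                      nrow(graph$edges), length(red$removed)))
    }
    comparisons[[g]] <- cmp
    graphs[[g]] <- graph
    reductions[[g]] <- red
    statuses[[g]] <- tibble::tibble(
      proteome_id = members,
      species_group_id = g,
      status = ifelse(members %in% red$surviving, "non-redundant",
                      "redundant"),
      representatives = lapply(members, function(id) {
        if (id %in% red$surviving) character(0)
        else red$surviving_neighbours[[id]]
      })
    )
  }
  statuses <- dplyr::bind_rows(statuses)
  statuses <- statuses[order(statuses$proteome_id), ]
  structure(
    list(statuses = statuses,
         comparisons = dplyr::bind_rows(comparisons),
         graphs = graphs, reductions = reductions,
         proteomes = all_proteomes, config = config),
    class = "prm_result"
  )
}

# All ordered pairs touching at least one newcomer, with heuristics.
compare_new_pairs <- function(group, newcomers, config) {
  ids <- names(group)
  counts <- vapply(group, function(p) nrow(p$proteins), integer(1))
  indexes <- list()
  out <- list()
  k <- 0
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      if (!(a %in% newcomers) && !(b %in% newcomers)) next
      k <- k + 1
      if (!size_heuristic(counts[[b]], counts[[a]], config$size_factor)) {
        out[[k]] <- tibble::tibble(subject_id = a, query_id = b,
                                   similarity = NA_real_, performed = FALSE)
        next
      }
      if (is.null(indexes[[a]])) {
        indexes[[a]] <- build_seed_index(group[[a]], config$word_size)
      }
      m <- match_sequences(group[[b]], indexes[[a]],
                           config$identity_threshold)
      out[[k]] <- tibble::tibble(subject_id = a, query_id = b,
                                 similarity = similarity_score(m),
                                 performed = TRUE)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.prm_result <- function(x, ...) {
  n_red <- sum(x$statuses$status == "redundant")
  cat(sprintf("<prm_result> %d proteomes in %d species group(s): %d non-redundant, %d redundant\n",
              nrow(x$statuses), length(x$graphs),
              nrow(x$statuses) - n_red, n_red))
  invisible(x)
}

#' Export a redundancy graph as a TSV edge list
#'
#' Columns `source_id` (the redundant proteome), `target_id` (the proteome
#' it is redundant to) and `similarity` (12 significant digits, so the
#' round trip through [import_graph()] is lossless at that precision).
#' Node metadata is written alongside as `<path>.nodes.tsv`.
#'
#' @param graph A `redundancy_graph`.
#' @param path Output TSV path for the edge list.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  stopifnot(inherits(graph, "redundancy_graph"))
  edges <- tibble::tibble(
    source_id = graph$edges$from,
    target_id = graph$edges$to,
    similarity = sprintf("%.12g", graph$edges$similarity)
  )
  readr::write_tsv(edges, path)
  write_metadata_table(graph$nodes, paste0(path, ".nodes.tsv"))
  invisible(path)
}

#' Import a redundancy graph from a TSV edge list
#'
#' Inverse of [export_graph()]. When no `<path>.nodes.tsv` metadata file is
#' present, nodes are inferred from the edge endpoints with default
#' metadata.
#'
#' @param path Path to the edge-list TSV.
#' @param threshold Edge threshold recorded on the imported graph.
#' @return A `redundancy_graph`.
#' @export
import_graph <- function(path, threshold = 0.9) {
  if (!file.exists(path)) abort(sprintf("Edge list not found: %s", path))
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  required <- c("source_id", "target_id", "similarity")
  if (!all(required %in% names(edges))) {
    abort("Edge list needs columns source_id, target_id, similarity.")
  }
  sim <- suppressWarnings(as.numeric(edges$similarity))
  bad <- which(is.na(sim) | sim < 0 | sim > 1)
  if (nrow(edges) > 0 && length(bad) > 0) {
    abort(sprintf("Invalid similarity '%s' on line %d.",
                  edges$similarity[bad[1]], bad[1] + 1L))
  }
  nodes_path <- paste0(path, ".nodes.tsv")
  nodes <- if (file.exists(nodes_path)) {
    read_metadata_table(nodes_path)
  } else {
    ids <- unique(c(edges$source_id, edges$target_id))
    tibble::tibble(proteome_id = ids, species_group_id = "default",
                   is_reference = FALSE, priority_score = 1L,
                   annotation_level = 0L, previous_state = 1L)
  }
  structure(
    list(nodes = nodes,
         edges = tibble::tibble(from = edges$source_id,
                                to = edges$target_id, similarity = sim),
         threshold = threshold),
    class = "redundancy_graph"
  )
}
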