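#' Infer B-cell clones within one participant
#'
#' Partitions a participant's rearrangements by V gene, J gene, and junction
#' length, then single-linkage clusters each partition under normalized
#' Hamming distance between junction nucleotide sequences: two sequences are
#' linked when their distance is at or below `distance_threshold`, and the
#' connected components of the link graph become clones. Gene-level (not
#' allele-level) V/J keys are used because allele miscalls within a clone are
#' common.
#'
#' Clone labels are deterministic and order-independent: each clone is named
#' after its lexicographically smallest member `sequence_id`.
#'
#' @param rearrangements Tibble of rearrangements for a single participant
#'   (see [read_rearrangements()]).
#' @param distance_threshold Maximum normalized Hamming distance (fraction of
#'   junction positions, in `[0, 1]`) for two same-partition sequences to be
#'   clonally linked. Default 0.15, a conventional heavy-chain threshold.
#' @return Tibble with columns `sequence_id`, `clone_id`; one row per input
#'   sequence, input order preserved.
#' @seealso [assign_clones()] for whole-cohort assignment,
#'   [collapse_clones()] for the clone-isotype collapse.
#' @export
group_clones <- function(rearrangements, distance_threshold = 0.15) {
  stopifnot(is.numeric(distance_threshold), length(distance_threshold) == 1L,
            distance_threshold >= 0, distance_threshold <= 1)
  n <- nrow(rearrangements)
  if (n == 0L) {
    return(tibble(sequence_id = character(), clone_id = character()))
  }
  if (length(unique(rearrangements$participant_id)) != 1L) {
    stop("group_clones: rearrangements span multiple participant_ids; ",
         "use assign_clones() for cohort input", call. = FALSE)
  }
  if (any(!nzchar(rearrangements$junction))) {
    stop("group_clones: empty junction sequence(s)", call. = FALSE)
  }
  key <- paste(call_gene(rearrangements$v_call),
               call_gene(rearrangements$j_call),
               rearrangements$junction_length, sep = "|")
  clone_of <- character(n)
  for (idx in split(seq_len(n), key)) {
    comp <- .link_components(rearrangements$junction[idx], distance_threshold)
    for (members in split(idx, comp)) {
      clone_of[members] <- min(rearrangements$sequence_id[members])
    }
  }
  tibble(sequence_id = rearrangements$sequence_id, clone_id = clone_of)
}

# connected components of the graph linking junctions with normalized
# Hamming distance <= threshold; junctions are all the same length here
.link_components <- function(junctions, threshold) {
  k <- length(junctions)
  if (k == 1L) return(1L)
  L <- nchar(junctions[1])
  mat <- matrix(unlist(strsplit(junctions, "", fixed = TRUE), use.names = FALSE),
                nrow = k, ncol = L, byrow = TRUE)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  max_mismatch <- threshold * L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      if (sum(mat[i, ] != mat[j, ]) <= max_mismatch) parent[ri] <- rj
    }
  }
  vapply(seq_len(k), find, integer(1))
}

#' Assign clones across a cohort
#'
#' Applies [group_clones()] independently within each participant and binds
#' the per-participant assignments.
#'
#' @inheritParams group_clones
#' @return Tibble with `sequence_id`, `clone_id`, `participant_id`.
#' @export
assign_clones <- function(rearrangements, distance_threshold = 0.15) {
  pieces <- lapply(
    split(rearrangements, rearrangements$participant_id),
    function(x) {
      out <- group_clones(x, distance_threshold)
      out$participant_id <- x$participant_id
      out
    }
  )
  out <- dplyr::bind_rows(pieces)
  out[match(rearrangements$sequence_id, out$sequence_id), , drop = FALSE]
}

#' Collapse rearrangements into clone-isotype units
#'
#' Collapses sequences sharing a clone into the "unique BCR sequence" units
#' that all repertoire measures count: one record per (participant, clone,
#' isotype subclass). A class-switched clone lineage observed in several
#' isotypes therefore contributes one countable unit to each isotype.
#'
#' Per unit: `mutated` is TRUE when any member sequence carries at least
#' `mutation_gate` germline mismatches; `abundance` sums member
#' `duplicate_count`s; `v_allele` is the majority member V allele (ties
#' broken lexicographically); `representative_junction` is the junction of
#' the highest-`duplicate_count` member (ties broken lexicographically).
#'
#' @param rearrangements Rearrangement tibble (any number of participants).
#' @param assignments Clone assignments covering every `sequence_id`
#'   (from [group_clones()] or [assign_clones()]).
#' @param mutation_gate Minimum germline-mismatch count for a sequence to
#'   count as somatically hypermutated (default 1, i.e. one or more bases
#'   differing from the IMGT reference).
#' @return Tibble of clone records: `participant_id`, `clone_id`, `isotype`,
#'   `class_switched`, `v_allele`, `j_gene`, `junction_length`,
#'   `representative_junction`, `mutated`, `n_members`, `abundance`.
#' @export
collapse_clones <- function(rearrangements, assignments, mutation_gate = 1L) {
  stopifnot(mutation_gate >= 1L)
  missing <- setdiff(assignments$sequence_id, rearrangements$sequence_id)
  if (length(missing) > 0L) {
    stop("collapse_clones: assignment sequence_id(s) absent from rearrangements: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(rearrangements$sequence_id, assignments$sequence_id)
  if (length(uncovered) > 0L) {
    stop("collapse_clones: rearrangement(s) without clone assignment: ",
         paste(utils::head(uncovered, 10), collapse = ", "), call. = FALSE)
  }
  dat <- rearrangements
  dat$clone_id <- assignments$clone_id[match(dat$sequence_id, assignments$sequence_id)]
  dat$isotype <- map_isotype(dat$c_call)
  dat$v_allele <- first_call(dat$v_call)
  dat$j_gene <- call_gene(dat$j_call)

  key <- paste(dat$participant_id, dat$clone_id, dat$isotype, sep = "\r")
  ukey <- unique(key)
  g <- match(key, ukey)
  first <- !duplicated(g)
  n_members <- tabulate(g, nbins = length(ukey))

  out <- tibble(
    participant_id = dat$participant_id[first][order(g[first])],
    clone_id = dat$clone_id[first][order(g[first])],
    isotype = dat$isotype[first][order(g[first])],
    j_gene = dat$j_gene[first][order(g[first])],
    junction_length = dat$junction_length[first][order(g[first])],
    v_allele = dat$v_allele[first][order(g[first])],
    representative_junction = dat$junction[first][order(g[first])],
    mutated = as.vector(rowsum(as.integer(dat$mutation_count >= mutation_gate), g)) > 0L,
    n_members = n_members,
    abundance = as.integer(rowsum(dat$duplicate_count, g))
  )
  out$class_switched <- is_class_switched(out$isotype)

  # majority V allele and top-abundance junction need per-unit work only
  # where a unit has several member sequences
  multi <- which(n_members > 1L)
  if (length(multi) > 0L) {
    rows_by_g <- split(seq_along(g), g)
    for (u in multi) {
      r <- rows_by_g[[as.character(u)]]
      out$v_allele[u] <- .majority(dat$v_allele[r])
      out$representative_junction[u] <-
        .representative(dat$junction[r], dat$duplicate_count[r])
    }
  }
  out <- out[, c("participant_id", "clone_id", "isotype", "class_switched",
                 "v_allele", "j_gene", "junction_length",
                 "representative_junction", "mutated", "n_members", "abundance")]
  out[order(out$participant_id, out$clone_id, out$isotype), , drop = FALSE]
}

# majority vote with lexicographic tie-break
.majority <- function(x) {
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  min(winners)
}

# junction of the highest-abundance member, lexicographic tie-break
.representative <- function(junction, duplicate_count) {
  top <- junction[duplicate_count == max(duplicate_count)]
  min(top)
}

#' Write a clone-record table
#'
#' @param clones Clone records from [collapse_clones()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  readr::write_tsv(clones, path, progress = FALSE)
  invisible(path)
}
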