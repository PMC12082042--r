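#' Isotype counts, usage, and expression for one participant
#'
#' From a participant's clone-isotype records, tallies the number of unique
#' clone-collapsed sequences per isotype subclass (`count`), the proportion
#' of the repertoire each subclass occupies (`usage = count / N`), and the
#' log2-scale expression measure `log2(count + pseudo_count)`. The
#' pseudo-count (default 1) keeps expression defined for subclasses with
#' zero clones.
#'
#' @param clones Clone records for one participant ([collapse_clones()]).
#' @param pseudo_count Added inside the log2 for the expression measure.
#' @return Tibble with one row per subclass in canonical order: `isotype`,
#'   `count`, `usage`, `expression`.
#' @export
isotype_measures <- function(clones, pseudo_count = 1) {
  N <- nrow(clones)
  if (N == 0L) stop("isotype_measures: empty repertoire", call. = FALSE)
  counts <- table(factor(clones$isotype, levels = ISOTYPE_LEVELS))
  tibble(
    isotype = ISOTYPE_LEVELS,
    count = as.integer(counts),
    usage = as.numeric(counts) / N,
    expression = log2(as.numeric(counts) + pseudo_count)
  )
}

#' Class-switching proportion
#'
#' The proportion of a participant's unique clone-collapsed sequences that
#' are both class-switched (IgA, IgG, or IgE) and somatically hypermutated.
#' The mutation requirement distinguishes antigen-driven switching from
#' germline-encoded IgA/IgG expression; the mutation gate itself is fixed at
#' collapse time (see [collapse_clones()]).
#'
#' @param clones Clone records for one participant.
#' @return Fraction in `[0, 1]`.
#' @export
class_switching_proportion <- function(clones) {
  N <- nrow(clones)
  if (N == 0L) stop("class_switching_proportion: empty repertoire", call. = FALSE)
  sum(clones$class_switched & clones$mutated) / N
}

#' Per-V-allele usage and class switching
#'
#' V-allele usage is the number of unique *and mutated* clone-collapsed
#' sequences carrying a given V allele divided by the total number of unique
#' sequences; unmutated sequences do not count toward any allele's
#' numerator, so usages need not sum to 1. Per-allele class switching
#' additionally requires a switched isotype.
#'
#' @param clones Clone records for one participant.
#' @param alleles Optional character vector fixing the rows (and their
#'   order) of the output; defaults to the alleles observed in `clones`.
#' @return Tibble: `v_allele`, `usage`, `class_switching`.
#' @export
v_allele_measures <- function(clones, alleles = NULL) {
  N <- nrow(clones)
  if (N == 0L) stop("v_allele_measures: empty repertoire", call. = FALSE)
  if (is.null(alleles)) alleles <- sort(unique(clones$v_allele))
  fac <- factor(clones$v_allele, levels = alleles)
  usage <- table(fac[clones$mutated])
  switching <- table(fac[clones$mutated & clones$class_switched])
  tibble(
    v_allele = alleles,
    usage = as.numeric(usage) / N,
    class_switching = as.numeric(switching) / N
  )
}

#' Mean CDR3 length per isotype
#'
#' Arithmetic mean (or median) of junction length in nucleotides over a
#' participant's clone records of each subclass. Subclasses with no clones
#' are `NA`, not zero.
#'
#' @param clones Clone records for one participant.
#' @param stat Per-participant aggregator, `"mean"` (default) or `"median"`.
#' @return Named numeric vector over [ISOTYPE_LEVELS].
#' @export
cdr3_length_by_isotype <- function(clones, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  out <- vapply(ISOTYPE_LEVELS, function(iso) {
    x <- clones$junction_length[clones$isotype == iso]
    if (length(x) == 0L) NA_real_ else f(as.numeric(x))
  }, numeric(1))
  out
}

#' Hill-number diversity profile
#'
#' Computes the Hill diversity of a clone-abundance vector over a grid of
#' diversity orders q. With relative abundances \eqn{p_i}, the Hill number
#' of order q is \deqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}} for \eqn{q \ne 1},
#' and its \eqn{q \to 1} limit \eqn{\exp(-\sum_i p_i \log p_i)} (the
#' exponential of Shannon entropy) at q = 1. q = 0 is clone richness and
#' q = 2 the inverse Simpson index; larger q weights expanded clones more
#' heavily, so clonal expansion depresses the profile at q > 0.
#'
#' @param abundances Positive integer vector of per-clone abundances
#'   (summed read support per clone, isotypes merged).
#' @param q_grid Non-negative diversity orders; default 0 to 4 by 0.1.
#' @return List of class `hill_profile`: `q_grid`, `values` (\eqn{{}^qD}),
#'   `log_values` (natural log).
#' @export
hill_profile <- function(abundances, q_grid = seq(0, 4, by = 0.1)) {
  if (length(abundances) == 0L) {
    stop("hill_profile: empty abundance vector", call. = FALSE)
  }
  if (any(abundances <= 0)) {
    stop("hill_profile: abundances must be positive", call. = FALSE)
  }
  if (any(q_grid < 0)) stop("hill_profile: q must be >= 0", call. = FALSE)
  p <- abundances / sum(abundances)
  shannon <- -sum(p * log(p))
  values <- vapply(q_grid, function(q) {
    if (abs(q - 1) < 1e-10) exp(shannon)
    else sum(p^q)^(1 / (1 - q))
  }, numeric(1))
  structure(list(q_grid = q_grid, values = values, log_values = log(values)),
            class = "hill_profile")
}

#' @export
print.hill_profile <- function(x, ...) {
  cat("Hill diversity profile over", length(x$q_grid), "orders q in [",
      min(x$q_grid), ",", max(x$q_grid), "]\n")
  show <- x$q_grid %in% c(0, 1, 2)
  cat(paste0("  D_", x$q_grid[show], " = ", signif(x$values[show], 5),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Cohort-level measure-prevalence filter
#'
#' A class (isotype subclass or V allele) is retained when strictly more
#' than `min_usage` of a participant's unique sequences belong to it in at
#' least `ceiling(min_participant_fraction * n_participants)` participants.
#' Classes named in `always_keep` are retained unconditionally (IgE, whose
#' usage sits below the threshold in typical blood repertoires, is kept in
#' the isotype family for its clinical importance). The filter is applied
#' separately to the isotype and the V-allele family.
#'
#' @param usage Numeric matrix or data frame, participants x classes, of
#'   usage fractions.
#' @param min_usage Usage a class must exceed (strictly) to count as present
#'   in a participant. Default 0.01.
#' @param min_participant_fraction Fraction of participants in which a class
#'   must be present. Default 0.25.
#' @param always_keep Classes exempt from the filter.
#' @return Character vector of retained class names, in input column order.
#' @export
prevalence_filter <- function(usage, min_usage = 0.01,
                              min_participant_fraction = 0.25,
                              always_keep = character()) {
  usage <- as.matrix(usage)
  if (nrow(usage) == 0L) {
    stop("prevalence_filter: empty cohort", call. = FALSE)
  }
  need <- ceiling(min_participant_fraction * nrow(usage))
  present <- colSums(usage > min_usage, na.rm = TRUE)
  keep <- present >= need | colnames(usage) %in% always_keep
  colnames(usage)[keep]
}

#' Summarize one participant's repertoire
#'
#' Bundles every per-participant measure — isotype counts/usage/expression,
#' class switching, per-allele usage and switching, per-isotype CDR3
#' length, and the Hill diversity profile — into one list. Hill abundances
#' merge a clone's isotype records (diversity concerns clonal expansion,
#' which is read from summed read support, and isotype splitting would
#' inflate richness).
#'
#' @param clones Clone records for one participant.
#' @param q_grid Diversity orders for the Hill profile.
#' @param pseudo_count Passed to [isotype_measures()].
#' @param cdr3_stat Passed to [cdr3_length_by_isotype()].
#' @return List of class `repertoire_summary`.
#' @export
summarize_repertoire <- function(clones, q_grid = seq(0, 4, by = 0.1),
                                 pseudo_count = 1,
                                 cdr3_stat = c("mean", "median")) {
  if (nrow(clones) == 0L) {
    stop("summarize_repertoire: empty repertoire", call. = FALSE)
  }
  if (length(unique(clones$participant_id)) != 1L) {
    stop("summarize_repertoire: clone records span multiple participants",
         call. = FALSE)
  }
  clone_abund <- tapply(clones$abundance, clones$clone_id, sum)
  structure(list(
    participant_id = clones$participant_id[1],
    total_unique = nrow(clones),
    isotypes = isotype_measures(clones, pseudo_count = pseudo_count),
    class_switching = class_switching_proportion(clones),
    v_alleles = v_allele_measures(clones),
    cdr3_length = cdr3_length_by_isotype(clones, stat = cdr3_stat),
    hill = hill_profile(as.numeric(clone_abund), q_grid = q_grid)
  ), class = "repertoire_summary")
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat("Repertoire summary for", x$participant_id, "\n")
  cat("  unique clone-isotype sequences:", x$total_unique, "\n")
  cat("  class switching:", signif(x$class_switching, 4), "\n")
  cat("  Hill D_1:", signif(x$hill$values[which.min(abs(x$hill$q_grid - 1))], 5), "\n")
  invisible(x)
}

#' Build the cohort measure matrix
#'
#' Computes every analyzable measure for every participant and returns a
#' participants-by-measures tibble plus a machine-readable manifest mapping
#' each column to its measure family and class/allele. Measure columns:
#' `<iso>_usage`, `<iso>_expression`, `<iso>_cdr3_length` for the eight
#' subclasses; `class_switching`; `<allele>_usage` and
#' `<allele>_class_switching` for each observed V allele; and log-scale
#' Hill diversities `hill_logD_q0`, `hill_logD_q1`, `hill_logD_q2`.
#' Participants with zero clone records are skipped with a message.
#'
#' @param clones Clone records for the whole cohort.
#' @inheritParams summarize_repertoire
#' @param quiet Suppress the skip message.
#' @return Tibble with attribute `manifest` (tibble: `measure`, `family`,
#'   `class`).
#' @export
measure_matrix <- function(clones, q_grid = seq(0, 4, by = 0.1),
                           pseudo_count = 1, cdr3_stat = c("mean", "median"),
                           quiet = FALSE) {
  cdr3_stat <- match.arg(cdr3_stat)
  by_part <- split(clones, clones$participant_id)
  empty <- names(by_part)[vapply(by_part, nrow, integer(1)) == 0L]
  if (length(empty) > 0L) {
    if (!quiet) message("measure_matrix: skipping empty participant(s): ",
                        paste(empty, collapse = ", "))
    by_part <- by_part[setdiff(names(by_part), empty)]
  }
  alleles <- sort(unique(clones$v_allele))
  rows <- lapply(by_part, function(cl) {
    iso <- isotype_measures(cl, pseudo_count = pseudo_count)
    va <- v_allele_measures(cl, alleles = alleles)
    cdr3 <- cdr3_length_by_isotype(cl, stat = cdr3_stat)
    hp <- hill_profile(as.numeric(tapply(cl$abundance, cl$clone_id, sum)),
                       q_grid = c(0, 1, 2))
    vals <- c(
      stats::setNames(iso$usage, paste0(iso$isotype, "_usage")),
      stats::setNames(iso$expression, paste0(iso$isotype, "_expression")),
      stats::setNames(cdr3, paste0(ISOTYPE_LEVELS, "_cdr3_length")),
      class_switching = class_switching_proportion(cl),
      stats::setNames(va$usage, paste0(va$v_allele, "_usage")),
      stats::setNames(va$class_switching, paste0(va$v_allele, "_class_switching")),
      hill_logD_q0 = hp$log_values[1],
      hill_logD_q1 = hp$log_values[2],
      hill_logD_q2 = hp$log_values[3]
    )
    tibble::as_tibble_row(c(list(participant_id = cl$participant_id[1]),
                            as.list(vals)))
  })
  mat <- dplyr::bind_rows(rows)
  manifest <- dplyr::bind_rows(
    tibble(measure = paste0(ISOTYPE_LEVELS, "_usage"), family = "isotype_usage",
           class = ISOTYPE_LEVELS),
    tibble(measure = paste0(ISOTYPE_LEVELS, "_expression"),
           family = "isotype_expression", class = ISOTYPE_LEVELS),
    tibble(measure = paste0(ISOTYPE_LEVELS, "_cdr3_length"),
           family = "cdr3_length", class = ISOTYPE_LEVELS),
    tibble(measure = "class_switching", family = "class_switching", class = NA_character_),
    tibble(measure = paste0(alleles, "_usage"), family = "v_allele_usage",
           class = alleles),
    tibble(measure = paste0(alleles, "_class_switching"),
           family = "v_allele_class_switching", class = alleles),
    tibble(measure = c("hill_logD_q0", "hill_logD_q1", "hill_logD_q2"),
           family = "diversity", class = NA_character_)
  )
  attr(mat, "manifest") <- manifest
  mat
}

#' Apply the prevalence filter to a measure matrix
#'
#' Uses each participant's isotype usages to decide which isotype-linked
#' measures (usage, expression, CDR3 length) are retained, and the V-allele
#' usages to decide which allele-linked measures (usage, per-allele class
#' switching) are retained. Class switching and the diversity measures are
#' always analyzable. IgE measures are kept by default regardless of
#' prevalence.
#'
#' @param mat Measure matrix from [measure_matrix()] (must carry its
#'   `manifest` attribute).
#' @inheritParams prevalence_filter
#' @param always_keep_isotypes Isotypes exempt from the filter.
#' @param quiet Suppress the filter-decision message.
#' @return The filtered matrix; attributes `manifest` (subset) and
#'   `filter_log` (tibble of per-class decisions).
#' @export
filter_measure_matrix <- function(mat, min_usage = 0.01,
                                  min_participant_fraction = 0.25,
                                  always_keep_isotypes = "IgE",
                                  quiet = FALSE) {
  manifest <- attr(mat, "manifest")
  if (is.null(manifest)) {
    stop("filter_measure_matrix: measure matrix lacks its manifest attribute",
         call. = FALSE)
  }
  iso_usage <- as.matrix(mat[, paste0(ISOTYPE_LEVELS, "_usage")])
  colnames(iso_usage) <- ISOTYPE_LEVELS
  iso_keep <- prevalence_filter(iso_usage, min_usage, min_participant_fraction,
                                always_keep = always_keep_isotypes)
  allele_cols <- manifest$measure[manifest$family == "v_allele_usage"]
  alleles <- manifest$class[manifest$family == "v_allele_usage"]
  va_usage <- as.matrix(mat[, allele_cols, drop = FALSE])
  colnames(va_usage) <- alleles
  va_keep <- prevalence_filter(va_usage, min_usage, min_participant_fraction)

  keep <- manifest$family %in% c("class_switching", "diversity") |
    (manifest$family %in% c("isotype_usage", "isotype_expression", "cdr3_length") &
       manifest$class %in% iso_keep) |
    (manifest$family %in% c("v_allele_usage", "v_allele_class_switching") &
       manifest$class %in% va_keep)
  kept_measures <- manifest$measure[keep]
  log <- tibble(
    class = c(ISOTYPE_LEVELS, alleles),
    family = c(rep("isotype", length(ISOTYPE_LEVELS)), rep("v_allele", length(alleles))),
    retained = c(ISOTYPE_LEVELS %in% iso_keep, alleles %in% va_keep),
    reason = dplyr::case_when(
      c(ISOTYPE_LEVELS %in% always_keep_isotypes, rep(FALSE, length(alleles))) ~ "always_keep",
      c(ISOTYPE_LEVELS %in% iso_keep, alleles %in% va_keep) ~ "prevalent",
      TRUE ~ "below_prevalence"
    )
  )
  if (!quiet) {
    message("prevalence filter: retained ", sum(log$retained), "/", nrow(log),
            " classes (", length(kept_measures), " measures)")
  }
  out <- mat[, c("participant_id", kept_measures)]
  attr(out, "manifest") <- manifest[keep, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}
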