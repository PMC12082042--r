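#' Default per-group repertoire effect configuration
#'
#' Group-level generative parameters for the synthetic cohort generator.
#' Each exposure group has: an isotype mixture over the eight subclasses;
#' mutation probabilities for switched and unswitched clones; a clone-size
#' skew parameter (larger values give heavier-tailed clone abundances,
#' i.e. more clonal expansion and lower Hill diversity); V-allele sampling
#' weights over a 12-allele panel; the expected number of unique clones per
#' participant; and per-subclass CDR3 length means/SDs (nucleotides, drawn
#' as multiples of 3 to respect reading frame).
#'
#' The default effect directions mirror the pattern reported for smoking
#' and vaping exposure in blood IGH repertoires: dual-users shift usage
#' toward IgA and IgG1/IgG2 and away from IgM, switch and mutate more, use
#' IGHV5-51*01 / IGHV1-18*01 / IGHV3-7*01 more, and show more clonal
#' expansion; single-product users sit between dual and former, and never
#' smokers resemble former smokers. Magnitudes are generator conventions,
#' not estimates.
#'
#' @return Named list (one element per exposure group) of effect lists.
#' @seealso [default_cohort_config()], [simulate_repertoire()]
#' @export
default_group_effects <- function() {
  panel <- c("IGHV3-23*01", "IGHV3-30*01", "IGHV4-34*01", "IGHV1-69*01",
             "IGHV4-59*01", "IGHV3-7*01", "IGHV1-18*01", "IGHV5-51*01",
             "IGHV3-48*01", "IGHV1-2*01", "IGHV3-15*01", "IGHV2-5*01")
  wt <- function(x) stats::setNames(x / sum(x), panel)
  mix <- function(x) stats::setNames(x / sum(x), ISOTYPE_LEVELS)
  cdr3_mean <- stats::setNames(c(54, 54, 51, 51, 51, 51, 54, 48), ISOTYPE_LEVELS)
  cdr3_sd <- stats::setNames(rep(9, 8), ISOTYPE_LEVELS)
  base <- function(isotype_mixture, switch_mutation_rate, clone_size_shape,
                   v_allele_weights) {
    list(
      isotype_mixture = isotype_mixture,
      switch_mutation_rate = switch_mutation_rate,
      baseline_mutation_rate = 0.25,
      clone_size_shape = clone_size_shape,
      v_allele_weights = v_allele_weights,
      n_clones_mean = 300,
      cdr3_length_mean = cdr3_mean,
      cdr3_length_sd = cdr3_sd
    )
  }
  flat_panel <- wt(c(14, 10, 9, 8, 8, 7, 7, 6, 7, 9, 8, 7))
  mid_panel  <- wt(c(13, 10, 9, 8, 8, 7.5, 7.5, 7.5, 7, 7.5, 8, 7))
  dual_panel <- wt(c(11, 8.5, 9, 8, 8, 8, 9, 10, 7, 7.5, 7, 7))
  list(
    former = base(mix(c(44, 8, 20, 7, 12, 6, 2.7, 0.3)), 0.72, 0.30, flat_panel),
    never = base(mix(c(45, 9, 19, 6.5, 11.5, 5.7, 3, 0.3)), 0.68, 0.28, flat_panel),
    cigarette = base(mix(c(40, 7.5, 22.5, 8.5, 13, 6.2, 2, 0.3)), 0.78, 0.40, mid_panel),
    vaping = base(mix(c(41, 7.5, 22, 8.2, 12.8, 6, 2.2, 0.3)), 0.76, 0.38, mid_panel),
    dual = base(mix(c(33, 7, 26, 10.5, 14.5, 6.8, 1.9, 0.3)), 0.84, 0.60, dual_panel)
  )
}

#' Null group-effect configuration
#'
#' Every exposure group receives the former-smoker parameters, so no
#' group-dependent repertoire differences exist; downstream association
#' analyses should exhibit only false-positive calls at the FDR rate.
#'
#' @return Named list of identical effect lists.
#' @export
null_group_effects <- function() {
  eff <- default_group_effects()
  ref <- eff$former
  lapply(eff, function(x) ref)
}

#' Default synthetic cohort configuration
#'
#' Group sizes, covariate distributions, and repertoire effects emulating a
#' smoking/vaping case-mix: 44 former smokers, 41 never smokers, 41 vapers,
#' 51 cigarette smokers, and 57 dual-users (234 participants). Covariate
#' means and proportions (age, sex, race, pack-years, GOLD distribution,
#' CT wall area) follow the characteristics table of such a cohort;
#' never-smoker pack-years are fixed at 0.
#'
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the config and seed.
#' @param n_per_group Named integer vector of participants per exposure
#'   group.
#' @param group_effects Per-group effect lists ([default_group_effects()]).
#' @return List of class `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1,
                                  n_per_group = c(former = 44, never = 41,
                                                  vaping = 41, cigarette = 51,
                                                  dual = 57),
                                  group_effects = default_group_effects()) {
  covariates <- list(
    #            former  never  vaping cigarette dual
    age_mean = c(former = 69.6, never = 65.3, vaping = 64.4,
                 cigarette = 62.0, dual = 61.3),
    age_sd = c(former = 7.42, never = 9.96, vaping = 6.56,
               cigarette = 7.21, dual = 6.47),
    male_prob = c(former = 0.477, never = 0.293, vaping = 0.366,
                  cigarette = 0.392, dual = 0.491),
    nhw_prob = c(former = 0.864, never = 0.951, vaping = 0.902,
                 cigarette = 0.451, dual = 0.737),
    pack_years_mean = c(former = 43.0, never = 0, vaping = 52.2,
                        cigarette = 48.5, dual = 52.9),
    pack_years_sd = c(former = 23.3, never = 0, vaping = 24.6,
                      cigarette = 27.8, dual = 25.3),
    gold_probs = rbind(
      former = c(normal = 0.341, gold1 = 0.136, gold2_4 = 0.477, prism = 0.045),
      never = c(normal = 0.951, gold1 = 0, gold2_4 = 0.024, prism = 0.024),
      vaping = c(normal = 0.463, gold1 = 0.122, gold2_4 = 0.317, prism = 0.098),
      cigarette = c(normal = 0.431, gold1 = 0.059, gold2_4 = 0.392, prism = 0.118),
      dual = c(normal = 0.333, gold1 = 0.105, gold2_4 = 0.509, prism = 0.053)
    ),
    ics_prob = 0.30,
    wall_area_mean = c(former = 51.1, never = 42.7, vaping = 48.4,
                       cigarette = 52.6, dual = 52.6),
    wall_area_sd = c(former = 6.34, never = 4.81, vaping = 8.79,
                     cigarette = 8.97, dual = 9.14),
    emphysema_mean = c(former = 6.30, never = 1.24, vaping = 3.43,
                       cigarette = 3.43, dual = 3.10),
    n_pcs = 5
  )
  config <- list(seed = as.integer(seed), n_per_group = n_per_group,
                 covariates = covariates, group_effects = group_effects)
  class(config) <- "cohort_config"
  validate_cohort_config(config)
  config
}

#' Validate a cohort configuration
#'
#' Checks group sizes, probability-vector normalization (to 1e-12),
#' rate ranges, and positivity of shape and clone-count parameters.
#'
#' @param config A `cohort_config` list.
#' @return `config`, invisibly, or an error.
#' @export
validate_cohort_config <- function(config) {
  if (is.null(config$seed)) stop("cohort config: seed required", call. = FALSE)
  if (any(config$n_per_group < 1)) {
    stop("cohort config: group sizes must be >= 1", call. = FALSE)
  }
  bad_group <- setdiff(names(config$n_per_group), exposure_levels())
  if (length(bad_group) > 0L) {
    stop("cohort config: unknown group(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  for (g in names(config$n_per_group)) {
    eff <- config$group_effects[[g]]
    if (is.null(eff)) stop("cohort config: no effects for group ", g, call. = FALSE)
    .validate_group_effects(eff, g)
  }
  invisible(config)
}

.validate_group_effects <- function(eff, group) {
  err <- function(...) stop("group effects [", group, "]: ", ..., call. = FALSE)
  if (abs(sum(eff$isotype_mixture) - 1) > 1e-12) err("isotype_mixture must sum to 1")
  if (!identical(names(eff$isotype_mixture), ISOTYPE_LEVELS)) {
    err("isotype_mixture must be named over the 8 subclasses")
  }
  if (abs(sum(eff$v_allele_weights) - 1) > 1e-12) err("v_allele_weights must sum to 1")
  need <- c("IGHV5-51*01", "IGHV1-18*01", "IGHV3-7*01")
  if (!all(need %in% names(eff$v_allele_weights))) {
    err("v_allele panel must include ", paste(need, collapse = ", "))
  }
  for (r in c("switch_mutation_rate", "baseline_mutation_rate")) {
    if (eff[[r]] < 0 || eff[[r]] > 1) err(r, " must lie in [0, 1]")
  }
  if (eff$clone_size_shape <= 0) err("clone_size_shape must be positive")
  if (eff$n_clones_mean <= 0) err("n_clones_mean must be positive")
  invisible(eff)
}

# reverse isotype -> constant-region gene map
.C_CALL_OF <- c(IgM = "IGHM", IgD = "IGHD", IgA1 = "IGHA1", IgA2 = "IGHA2",
                IgG1 = "IGHG1", IgG2 = "IGHG2", IgG3 = "IGHG3", IgE = "IGHE")

.J_GENES <- paste0("IGHJ", 1:6)
.J_WEIGHTS <- c(0.05, 0.05, 0.10, 0.45, 0.15, 0.20)

# heavy-tailed clone abundance: P(k) proportional to k^(-alpha) on 1..500,
# alpha = 1 + 1/shape so larger shape means a heavier tail
.sample_abundance <- function(n, shape, kmax = 500L) {
  alpha <- 1 + 1 / shape
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

.random_junction <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# one substitution at a random position (keeps within-clone junction
# distance below any sensible clustering threshold)
.mutate_junction <- function(junction) {
  pos <- sample(nchar(junction), 1)
  old <- substr(junction, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  paste0(substr(junction, 1, pos - 1), new,
         substr(junction, pos + 1, nchar(junction)))
}

#' Simulate one participant's repertoire
#'
#' Draws a Poisson number of clones; per clone samples an isotype from the
#' group mixture, a V allele from the panel weights, a J gene, a CDR3
#' length (normal, rounded to a multiple of 3, floored at 9 nt), a uniform
#' random junction, a mutation indicator (rate by switched status, realized
#' as `1 + Poisson(2)` germline mismatches), and a heavy-tailed clone
#' abundance. Expanded clones may be emitted as several member rows with
#' near-identical junctions whose `duplicate_count`s sum to the clone
#' abundance, exercising the clonal-grouping stage. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param participant_id Participant identifier for the emitted rows.
#' @param effects One group's effect list (see [default_group_effects()]).
#' @return Rearrangement tibble (same dialect as [read_rearrangements()]).
#' @export
simulate_repertoire <- function(participant_id, effects) {
  .validate_group_effects(effects, participant_id)
  n_clones <- max(1L, stats::rpois(1, effects$n_clones_mean))
  isotype <- sample(ISOTYPE_LEVELS, n_clones, replace = TRUE,
                    prob = effects$isotype_mixture)
  v_allele <- sample(names(effects$v_allele_weights), n_clones, replace = TRUE,
                     prob = effects$v_allele_weights)
  j_gene <- sample(.J_GENES, n_clones, replace = TRUE, prob = .J_WEIGHTS)
  len <- pmax(9L, 3L * round(stats::rnorm(
    n_clones, effects$cdr3_length_mean[isotype],
    effects$cdr3_length_sd[isotype]) / 3))
  switched <- is_class_switched(isotype)
  mut_rate <- ifelse(switched, effects$switch_mutation_rate,
                     effects$baseline_mutation_rate)
  mutated <- stats::runif(n_clones) < mut_rate
  abundance <- .sample_abundance(n_clones, effects$clone_size_shape)

  junc <- vapply(len, .random_junction, character(1))

  # expanded clones may surface as several near-identical member sequences
  n_members <- rep(1L, n_clones)
  big <- abundance >= 3L
  if (any(big)) n_members[big] <- 1L + stats::rbinom(sum(big), 2, 0.15)
  n_members <- pmin(n_members, abundance)

  idx <- rep(seq_len(n_clones), n_members)   # clone index per emitted row
  member_no <- sequence(n_members)
  junction <- junc[idx]
  extra <- member_no > 1L
  if (any(extra)) {
    junction[extra] <- vapply(junction[extra], .mutate_junction, character(1),
                              USE.NAMES = FALSE)
  }
  dup <- ifelse(extra, 1L, abundance[idx] - (n_members[idx] - 1L))
  mut <- integer(length(idx))
  mut_row <- mutated[idx]
  if (any(mut_row)) mut[mut_row] <- 1L + stats::rpois(sum(mut_row), 2)

  tibble(
    sequence_id = sprintf("%s_s%05d", participant_id, seq_along(idx)),
    participant_id = participant_id,
    v_call = v_allele[idx],
    j_call = paste0(j_gene[idx], "*01"),
    c_call = unname(.C_CALL_OF[isotype[idx]]),
    junction = junction,
    junction_length = len[idx],
    mutation_count = mut,
    duplicate_count = as.integer(dup)
  )
}

#' Simulate participant metadata for a cohort
#'
#' Draws per-group covariates (age, sex, race, pack-years, GOLD group,
#' inhaled-corticosteroid use, income level, deprivation index, CT
#' measures, scanner, genetic PCs) from the configured distributions.
#' Never-smoker pack-years are fixed at 0. Uses the current RNG state.
#'
#' @param config A `cohort_config`.
#' @return Validated metadata tibble.
#' @export
simulate_metadata <- function(config) {
  cv <- config$covariates
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  ids <- sprintf("P%03d", seq_len(n))
  age <- round(stats::rnorm(n, cv$age_mean[groups], cv$age_sd[groups]), 1)
  sex <- stats::rbinom(n, 1, cv$male_prob[groups])
  race <- stats::rbinom(n, 1, cv$nhw_prob[groups])
  pack_years <- pmax(0.5, round(stats::rnorm(n, cv$pack_years_mean[groups],
                                             cv$pack_years_sd[groups]), 1))
  pack_years[groups == "never"] <- 0
  gold <- vapply(groups, function(g) {
    sample(gold_levels(), 1, prob = cv$gold_probs[g, gold_levels()])
  }, character(1))
  meta <- tibble(
    participant_id = ids,
    exposure_group = groups,
    age = age,
    sex = sex,
    race = race,
    pack_years = pack_years,
    gold_group = gold,
    ics_use = stats::runif(n) < cv$ics_prob,
    oral_steroids = FALSE,
    income_level = sample(1:6, n, replace = TRUE),
    deprivation_index = pmin(100, pmax(1, round(stats::rnorm(n, 50, 20)))),
    ct_emphysema_pct = round(pmax(0, stats::rnorm(
      n, cv$emphysema_mean[groups], cv$emphysema_mean[groups])), 2),
    ct_wall_area_pct = round(stats::rnorm(n, cv$wall_area_mean[groups],
                                          cv$wall_area_sd[groups]), 1),
    ct_scanner = sample(c("modelA", "modelB", "modelC"), n, replace = TRUE)
  )
  for (k in seq_len(cv$n_pcs)) {
    meta[[paste0("pc", k)]] <- round(stats::rnorm(n), 4)
  }
  validate_metadata(meta)
}

#' Simulate a full synthetic cohort
#'
#' Deterministically (given `config$seed`) generates participant metadata
#' and one repertoire per participant, optionally writing both files in the
#' dialects [read_metadata()] and [read_rearrangements()] consume.
#'
#' @param config A `cohort_config` (see [default_cohort_config()]).
#' @param metadata_path,rearrangements_path Optional output paths.
#' @param quiet Suppress progress messages.
#' @return List: `metadata` tibble, `rearrangements` tibble.
#' @export
simulate_cohort <- function(config, metadata_path = NULL,
                            rearrangements_path = NULL, quiet = FALSE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  metadata <- simulate_metadata(config)
  reps <- lapply(seq_len(nrow(metadata)), function(i) {
    simulate_repertoire(metadata$participant_id[i],
                        config$group_effects[[metadata$exposure_group[i]]])
  })
  rearrangements <- dplyr::bind_rows(reps)
  if (!quiet) {
    message("simulate_cohort: ", nrow(metadata), " participants, ",
            nrow(rearrangements), " rearrangement rows")
  }
  if (!is.null(metadata_path)) write_metadata(metadata, metadata_path)
  if (!is.null(rearrangements_path)) {
    write_rearrangements(rearrangements, rearrangements_path)
  }
  list(metadata = metadata, rearrangements = rearrangements)
}

#' Read / write a cohort configuration as YAML
#'
#' Serializes the `cohort_config` structure (seed, group sizes, covariate
#' generators, group effects) so simulation runs are reproducible from a
#' text file. Round-trips unchanged up to numeric representation.
#'
#' @param path YAML file path.
#' @param config A `cohort_config`.
#' @return `read_cohort_config()`: a validated `cohort_config`;
#'   `write_cohort_config()`: `path`, invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- default_cohort_config(
    seed = raw$seed,
    n_per_group = unlist(raw$n_per_group)
  )
  if (!is.null(raw$group_effects)) {
    for (g in names(raw$group_effects)) {
      for (field in names(raw$group_effects[[g]])) {
        val <- raw$group_effects[[g]][[field]]
        if (field %in% c("isotype_mixture", "v_allele_weights",
                         "cdr3_length_mean", "cdr3_length_sd")) {
          val <- unlist(val)
        }
        config$group_effects[[g]][[field]] <- val
      }
    }
  }
  validate_cohort_config(config)
  config
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  out <- list(
    seed = config$seed,
    n_per_group = as.list(config$n_per_group),
    group_effects = lapply(config$group_effects, function(eff) {
      lapply(eff, function(x) if (!is.null(names(x))) as.list(x) else x)
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
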