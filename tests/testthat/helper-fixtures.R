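# Fixture builders. All fixtures are generated in code at test time.

make_rearr <- function(sequence_id, junction,
                       participant_id = "P1",
                       v_call = "IGHV5-51*01", j_call = "IGHJ4*01",
                       c_call = "IGHM", mutation_count = 0L,
                       duplicate_count = 1L) {
  tibble::tibble(
    sequence_id = sequence_id,
    participant_id = participant_id,
    v_call = v_call,
    j_call = j_call,
    c_call = c_call,
    junction = junction,
    junction_length = nchar(junction),
    mutation_count = as.integer(mutation_count),
    duplicate_count = as.integer(duplicate_count)
  )
}

rand_junction <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random single-participant rearrangement set with deliberately colliding
# V/J/length partitions so clusters of several sequences arise
rand_rearr_instance <- function(n) {
  v <- sample(c("IGHV1-2*01", "IGHV3-23*01"), n, replace = TRUE)
  j <- sample(c("IGHJ4*01", "IGHJ6*01"), n, replace = TRUE)
  len <- sample(c(12L, 15L), n, replace = TRUE)
  base <- c(rand_junction(12), rand_junction(12), rand_junction(15))
  junction <- vapply(seq_len(n), function(i) {
    if (runif(1) < 0.6) {
      b <- if (len[i] == 12L) sample(base[1:2], 1) else base[3]
      nmut <- sample(0:3, 1)
      v <- strsplit(b, "")[[1]]
      if (nmut > 0) {
        pos <- sample(length(v), nmut)
        v[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      paste(v, collapse = "")
    } else {
      rand_junction(len[i])
    }
  }, character(1))
  make_rearr(sprintf("s%03d", seq_len(n)), junction, v_call = v, j_call = j)
}

# random clone-record table for tally-oracle tests
rand_clones <- function(n, participant = "P1") {
  isotype <- sample(bcrtools::ISOTYPE_LEVELS, n, replace = TRUE,
                    prob = c(40, 8, 20, 8, 12, 6, 5, 1))
  alleles <- c("IGHV5-51*01", "IGHV1-18*01", "IGHV3-7*01", "IGHV3-23*01",
               "IGHV4-34*01")
  tibble::tibble(
    participant_id = participant,
    clone_id = sprintf("c%05d", seq_len(n)),
    isotype = isotype,
    class_switched = bcrtools::is_class_switched(isotype),
    v_allele = sample(alleles, n, replace = TRUE),
    j_gene = sample(paste0("IGHJ", 1:6), n, replace = TRUE),
    junction_length = 3L * sample(4:25, n, replace = TRUE),
    representative_junction = NA_character_,
    mutated = runif(n) < 0.6,
    n_members = 1L,
    abundance = 1L + rpois(n, 2)
  )
}

# small metadata tibble resembling the cohort's covariate structure
small_metadata <- function(n_per_group = 8, seed = 42) {
  set.seed(seed)
  cfg <- bcrtools::default_cohort_config(
    seed = seed,
    n_per_group = setNames(rep(n_per_group, 5),
                           c("former", "never", "vaping", "cigarette", "dual"))
  )
  bcrtools::simulate_metadata(cfg)
}
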