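#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

#' Immunoglobulin heavy-chain isotype subclasses
#'
#' The eight IGH constant-region subclasses recognized by the pipeline, in
#' canonical order, and the subset produced by class-switch recombination
#' (everything except IgM and IgD).
#'
#' @format Character vectors.
#' @export
ISOTYPE_LEVELS <- c("IgM", "IgD", "IgA1", "IgA2", "IgG1", "IgG2", "IgG3", "IgE")

#' @rdname ISOTYPE_LEVELS
#' @export
SWITCHED_ISOTYPES <- c("IgA1", "IgA2", "IgG1", "IgG2", "IgG3", "IgE")

# constant-region gene -> subclass lookup (uppercase keys)
.ISOTYPE_MAP <- c(
  IGHM = "IgM", IGHD = "IgD", IGHA1 = "IgA1", IGHA2 = "IgA2",
  IGHG1 = "IgG1", IGHG2 = "IgG2", IGHG3 = "IgG3", IGHE = "IgE"
)

#' Map a constant-region gene call to an isotype subclass
#'
#' Maps IGH constant-region gene names (`IGHM`, `IGHA2`, ...) to subclass
#' labels (`IgM`, `IgA2`, ...). Matching is case-insensitive and tolerant of
#' IMGT allele suffixes (`"IGHA2*01"` maps to `IgA2`) and comma-separated
#' multi-calls (the first call wins). Any constant region outside the eight
#' IGH subclasses (e.g. `IGHG4` pseudogene calls, light-chain or TR constant
#' genes) is an error.
#'
#' @param c_call Character vector of constant-region gene calls.
#' @return Character vector of subclass labels (one of [ISOTYPE_LEVELS]).
#' @examples
#' map_isotype(c("IGHA2", "ighm", "IGHG1*03"))
#' @export
map_isotype <- function(c_call) {
  if (length(c_call) == 0L) return(character(0))
  if (any(is.na(c_call) | !nzchar(c_call))) {
    stop("map_isotype: empty or missing c_call", call. = FALSE)
  }
  key <- toupper(sub("\\*.*$", "", first_call(c_call)))
  iso <- unname(.ISOTYPE_MAP[key])
  if (anyNA(iso)) {
    bad <- unique(c_call[is.na(iso)])
    stop("map_isotype: unknown isotype constant region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  iso
}

#' Is an isotype subclass class-switched?
#'
#' @param isotype Character vector of subclass labels.
#' @return Logical vector; `TRUE` for IgA/IgG/IgE subclasses, `FALSE` for
#'   IgM and IgD.
#' @export
is_class_switched <- function(isotype) {
  if (!all(isotype %in% ISOTYPE_LEVELS)) {
    stop("is_class_switched: unknown isotype label(s): ",
         paste(setdiff(unique(isotype), ISOTYPE_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  isotype %in% SWITCHED_ISOTYPES
}

#' Resolve a multi-allele call to its first listed allele
#'
#' IMGT-style callers may report ambiguous assignments as comma-separated
#' lists (`"IGHV5-51*01,IGHV5-51*02"`); the first listed allele is taken,
#' which is deterministic and the common convention.
#'
#' @param call Character vector of (possibly multi-) allele calls.
#' @return Character vector of single allele calls.
#' @export
first_call <- function(call) {
  sub(",.*$", "", trimws(call))
}

#' Extract the gene part of an IMGT allele name
#'
#' `"IGHV5-51*01"` yields `"IGHV5-51"`. Gene-level keys are used for clonal
#' partitioning because allele miscalls within a clone are common.
#'
#' @param call Character vector of allele calls.
#' @return Character vector of gene names.
#' @export
call_gene <- function(call) {
  sub("\\*.*$", "", first_call(call))
}

# AIRR dialect used throughout: standard Rearrangement columns plus
# participant_id and a precomputed germline-mismatch count.
.REARRANGEMENT_FIELDS <- c(
  "sequence_id", "participant_id", "v_call", "j_call", "c_call",
  "junction", "junction_length", "mutation_count"
)

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated AIRR Rearrangement file with one row per sequenced
#' IGH transcript. Beyond the AIRR-standard columns (`sequence_id`, `v_call`,
#' `j_call`, `c_call`, `junction`, `junction_length`, `duplicate_count`) two
#' columns are required: `participant_id` and `mutation_count`, the number of
#' bases by which the aligned sequence differs from the IMGT germline
#' reference (precomputed upstream by the aligner).
#'
#' Rows are validated: `junction_length` must equal `nchar(junction)`,
#' `mutation_count` must be a non-negative integer and `duplicate_count` (1
#' when absent) a positive integer. Validation failures are reported with
#' their row indices. An empty file (header only) returns an empty tibble.
#'
#' @param path Path to a TSV file with a header row.
#' @param required_fields Character vector of columns that must be present.
#' @param quiet Suppress the row-count message.
#' @return A tibble of validated rearrangements, input order preserved.
#' @seealso [write_rearrangements()], [read_metadata()]
#' @export
read_rearrangements <- function(path, required_fields = .REARRANGEMENT_FIELDS,
                                quiet = FALSE) {
  if (!file.exists(path)) {
    stop("read_rearrangements: file not found: ", path, call. = FALSE)
  }
  dat <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(required_fields, names(dat))
  if (length(missing) > 0L) {
    stop("read_rearrangements: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(dat) == 0L) {
    return(.empty_rearrangements())
  }
  if (!"duplicate_count" %in% names(dat)) dat$duplicate_count <- "1"
  dat$duplicate_count[is.na(dat$duplicate_count)] <- "1"

  mut <- suppressWarnings(as.integer(dat$mutation_count))
  dup <- suppressWarnings(as.integer(dat$duplicate_count))
  jl  <- suppressWarnings(as.integer(dat$junction_length))

  bad <- which(
    is.na(mut) | mut < 0L |
    is.na(dup) | dup < 1L |
    is.na(jl) | jl != nchar(dat$junction) |
    is.na(dat$junction) | !grepl("^[ACGTNacgtn]+$", dat$junction) |
    is.na(dat$sequence_id) | is.na(dat$participant_id) |
    !grepl("\\*", first_call(dat$v_call))
  )
  if (length(bad) > 0L) {
    stop("read_rearrangements: validation failed for row(s): ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) " ...", call. = FALSE)
  }
  out <- tibble(
    sequence_id = dat$sequence_id,
    participant_id = dat$participant_id,
    v_call = dat$v_call,
    j_call = dat$j_call,
    c_call = dat$c_call,
    junction = toupper(dat$junction),
    junction_length = jl,
    mutation_count = mut,
    duplicate_count = dup
  )
  if (!quiet) {
    message("read_rearrangements: ", nrow(out), " rows from ",
            length(unique(out$participant_id)), " participant(s)")
  }
  out
}

.empty_rearrangements <- function() {
  tibble(
    sequence_id = character(), participant_id = character(),
    v_call = character(), j_call = character(), c_call = character(),
    junction = character(), junction_length = integer(),
    mutation_count = integer(), duplicate_count = integer()
  )
}

#' Write an AIRR rearrangement table
#'
#' @param rearrangements Tibble as returned by [read_rearrangements()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(rearrangements, path) {
  readr::write_tsv(rearrangements, path, progress = FALSE)
  invisible(path)
}

.EXPOSURE_LEVELS <- c("never", "former", "cigarette", "vaping", "dual")
.GOLD_LEVELS <- c("normal", "gold1", "gold2_4", "prism")

#' Exposure-group and spirometry-group levels
#'
#' Admissible levels for the smoking/vaping exposure variable and the GOLD
#' spirometry grouping. `former` and `normal` are the modelling reference
#' levels.
#'
#' @return Character vector of levels.
#' @export
exposure_levels <- function() .EXPOSURE_LEVELS

#' @rdname exposure_levels
#' @export
gold_levels <- function() .GOLD_LEVELS

#' Read a participant metadata table
#'
#' Reads a CSV with one row per participant carrying the exposure group and
#' model covariates. Required columns: `participant_id`, `exposure_group`
#' (never/former/cigarette/vaping/dual), `age`, `sex` (female/male or 0/1),
#' `race` (AA/NHW or 0/1), `pack_years`, `gold_group`
#' (normal/gold1/gold2_4/prism), `ics_use` (logical). Optional columns:
#' `oral_steroids` (participants flagged TRUE are excluded before
#' modelling), `income_level`, `deprivation_index`, `ct_emphysema_pct`,
#' `ct_wall_area_pct`, `ct_scanner`, and genetic principal components
#' `pc1`, `pc2`, .... Optional fields left absent stay missing; nothing is
#' imputed.
#'
#' @param path CSV path.
#' @param quiet Suppress the row-count message.
#' @return Tibble of participant metadata with validated factor levels.
#' @export
read_metadata <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("read_metadata: file not found: ", path, call. = FALSE)
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("participant_id", "exposure_group", "age", "sex", "race",
           "pack_years", "gold_group", "ics_use")
  missing <- setdiff(req, names(dat))
  if (length(missing) > 0L) {
    stop("read_metadata: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(dat$participant_id[duplicated(dat$participant_id)])
  if (length(dup) > 0L) {
    stop("read_metadata: duplicate participant_id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  dat <- validate_metadata(as_tibble(dat))
  if (!quiet) message("read_metadata: ", nrow(dat), " participants")
  dat
}

#' Validate an in-memory metadata tibble
#'
#' Applies the same level and consistency checks as [read_metadata()]:
#' admissible exposure and GOLD levels, numeric sex/race coding (0=female,
#' 1=male; 0=AA, 2=NHW recoded to 1), non-negative pack-years, and zero
#' pack-years for never-smokers.
#'
#' @param metadata Tibble with the metadata columns.
#' @return The validated tibble with `sex` and `race` coded 0/1 and
#'   `exposure_group`/`gold_group` as factors with reference levels
#'   `former` and `normal`.
#' @export
validate_metadata <- function(metadata) {
  bad_exp <- setdiff(unique(as.character(metadata$exposure_group)), .EXPOSURE_LEVELS)
  if (length(bad_exp) > 0L) {
    stop("metadata: unknown exposure_group level(s): ",
         paste(bad_exp, collapse = ", "), call. = FALSE)
  }
  bad_gold <- setdiff(unique(as.character(metadata$gold_group)), .GOLD_LEVELS)
  if (length(bad_gold) > 0L) {
    stop("metadata: unknown gold_group level(s): ",
         paste(bad_gold, collapse = ", "), call. = FALSE)
  }
  metadata$exposure_group <- factor(metadata$exposure_group,
                                    levels = c("former", setdiff(.EXPOSURE_LEVELS, "former")))
  metadata$gold_group <- factor(metadata$gold_group,
                                levels = c("normal", setdiff(.GOLD_LEVELS, "normal")))
  metadata$sex <- .code_binary(metadata$sex, zero = "female", one = "male", what = "sex")
  metadata$race <- .code_binary(metadata$race, zero = "AA", one = "NHW", what = "race")
  if (any(is.na(metadata$pack_years) | metadata$pack_years < 0)) {
    stop("metadata: pack_years must be non-negative and non-missing", call. = FALSE)
  }
  never_bad <- metadata$exposure_group == "never" & metadata$pack_years != 0
  if (any(never_bad)) {
    stop("metadata: never-smokers must have pack_years == 0; offending participant(s): ",
         paste(metadata$participant_id[never_bad], collapse = ", "), call. = FALSE)
  }
  metadata$ics_use <- as.logical(metadata$ics_use)
  if (anyNA(metadata$ics_use)) {
    stop("metadata: ics_use must be logical (TRUE/FALSE)", call. = FALSE)
  }
  metadata
}

# accept string labels or 0/1 numeric coding for binary covariates
.code_binary <- function(x, zero, one, what) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("metadata: ", what, " must be coded 0/1 or ", zero, "/", one,
           call. = FALSE)
    }
    return(as.numeric(x))
  }
  x <- as.character(x)
  if (!all(x %in% c(zero, one))) {
    stop("metadata: ", what, " must be coded 0/1 or ", zero, "/", one,
         "; saw: ", paste(setdiff(unique(x), c(zero, one)), collapse = ", "),
         call. = FALSE)
  }
  as.numeric(x == one)
}

#' Write a participant metadata table
#'
#' @param metadata Metadata tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  out$exposure_group <- as.character(out$exposure_group)
  out$gold_group <- as.character(out$gold_group)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
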