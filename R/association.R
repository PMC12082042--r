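#' Model specification for an analysis family
#'
#' Returns the covariate set and terms-of-interest for one of the named
#' analysis families. All families model a repertoire measure as the
#' response of an ordinary least-squares regression; they differ in the
#' adjustment set:
#'
#' * `primary` — age, sex, race, exposure group, GOLD spirometry group,
#'   pack-years, inhaled-corticosteroid use. Terms of interest are the
#'   exposure contrasts (vs former smokers), the demographics, and the GOLD
#'   contrasts (vs normal spirometry).
#' * `sensitivity_ses` — primary plus self-reported income level and the
#'   area-deprivation index; terms of interest are exposure and race.
#' * `sensitivity_pcs` — primary plus genetic principal components
#'   (`pc1`, `pc2`, ...); terms of interest are exposure and race.
#' * `interaction` — primary plus race-by-exposure cross-product terms;
#'   the cross-products are the terms of interest.
#' * `univariable_copd` — GOLD group and inhaled-corticosteroid use only;
#'   the GOLD contrasts are the terms of interest.
#' * `univariable_ct` — CT airway wall-area percent, CT scanner model, and
#'   inhaled-corticosteroid use; wall area is the term of interest.
#'
#' Reference levels are `former` (exposure) and `normal` (GOLD); sex is
#' coded 0 = female, 1 = male and race 0 = AA, 1 = NHW.
#'
#' @param family Analysis family name.
#' @param n_pcs Number of genetic principal components for
#'   `sensitivity_pcs`.
#' @return List of class `model_spec`: `family`, `covariates`,
#'   `interactions`, `terms_of_interest` (prefixes matched against design
#'   column names).
#' @export
model_spec <- function(family = c("primary", "sensitivity_ses", "sensitivity_pcs",
                                  "interaction", "univariable_copd",
                                  "univariable_ct"),
                       n_pcs = 5) {
  family <- match.arg(family)
  base_cov <- c("age", "sex", "race", "exposure_group", "gold_group",
                "pack_years", "ics_use")
  base_interest <- c("age", "sex", "race", "exposure_group:", "gold_group:")
  spec <- switch(family,
    primary = list(covariates = base_cov, interactions = NULL,
                   terms_of_interest = base_interest),
    sensitivity_ses = list(
      covariates = c(base_cov, "income_level", "deprivation_index"),
      interactions = NULL,
      terms_of_interest = c("race", "exposure_group:")),
    sensitivity_pcs = list(
      covariates = c(base_cov, paste0("pc", seq_len(n_pcs))),
      interactions = NULL,
      terms_of_interest = c("race", "exposure_group:")),
    interaction = list(
      covariates = base_cov,
      interactions = list(c("race", "exposure_group")),
      terms_of_interest = c("race:x:exposure_group:")),
    univariable_copd = list(
      covariates = c("gold_group", "ics_use"), interactions = NULL,
      terms_of_interest = c("gold_group:")),
    univariable_ct = list(
      covariates = c("ct_wall_area_pct", "ct_scanner", "ics_use"),
      interactions = NULL,
      terms_of_interest = c("ct_wall_area_pct"))
  )
  structure(c(list(family = family), spec), class = "model_spec")
}

#' Build a design matrix from participant metadata
#'
#' Expands a [model_spec()] against the metadata into a full-rank design
#' matrix with an intercept. Categorical covariates become dummy columns
#' named `"<var>:<level>"` against their reference level; interaction
#' cross-products are named `"<var1>:x:<var2>:<level>"`. Rows with missing
#' values in any used covariate are dropped (complete-case analysis) and
#' reported.
#'
#' @param metadata Validated metadata tibble ([read_metadata()]).
#' @param spec A `model_spec`.
#' @param quiet Suppress the dropped-row message.
#' @return List: `X` (numeric matrix, first column `intercept`),
#'   `participants` (row-to-participant mapping), `n_dropped`.
#' @export
build_design <- function(metadata, spec, quiet = FALSE) {
  missing_cov <- setdiff(spec$covariates, names(metadata))
  if (length(missing_cov) > 0L) {
    stop("build_design: metadata lacks covariate(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  dat <- metadata[, c("participant_id", spec$covariates)]
  complete <- stats::complete.cases(dat)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L && !quiet) {
    message("build_design: dropped ", n_dropped,
            " participant(s) with missing covariates")
  }
  dat <- dat[complete, , drop = FALSE]
  if (nrow(dat) == 0L) stop("build_design: no complete cases", call. = FALSE)

  cols <- list(intercept = rep(1, nrow(dat)))
  for (v in spec$covariates) {
    cols <- c(cols, .expand_covariate(dat[[v]], v))
  }
  if (!is.null(spec$interactions)) {
    for (pair in spec$interactions) {
      a <- .expand_covariate(dat[[pair[1]]], pair[1])
      b <- .expand_covariate(dat[[pair[2]]], pair[2])
      for (an in names(a)) for (bn in names(b)) {
        # canonical interaction name keeps the first variable's bare name
        nm <- paste0(sub(":.*$", "", an), ":x:", bn)
        cols[[nm]] <- a[[an]] * b[[bn]]
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- apply(X[, -1, drop = FALSE], 2, function(z) stats::var(z) == 0)
  if (any(const)) {
    warning("build_design: constant column(s): ",
            paste(names(const)[const], collapse = ", "), call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("build_design: design matrix is rank-deficient", call. = FALSE)
  }
  list(X = X, participants = dat$participant_id, n_dropped = n_dropped)
}

# expand one covariate into named numeric column(s); factors are dummy-coded
# against their reference (first) level, with an error if the reference is
# absent from the data
.expand_covariate <- function(x, name) {
  if (is.factor(x)) {
    if (!levels(x)[1] %in% as.character(x)) {
      stop("build_design: reference level '", levels(x)[1],
           "' of ", name, " absent from data", call. = FALSE)
    }
    lev <- levels(x)[-1]
    lev <- lev[lev %in% as.character(x)]
    out <- lapply(lev, function(l) as.numeric(x == l))
    names(out) <- paste0(name, ":", lev)
    out
  } else if (is.character(x)) {
    .expand_covariate(factor(x), name)
  } else if (is.logical(x)) {
    stats::setNames(list(as.numeric(x)), name)
  } else {
    stats::setNames(list(as.numeric(x)), name)
  }
}

#' Ordinary least-squares fit with per-term inference
#'
#' Fits `y ~ X` by QR-based least squares and returns, per column of the
#' design, the coefficient, its standard error from the residual variance
#' on `n - k` degrees of freedom, and the two-sided t-test p-value.
#'
#' @param X Numeric design matrix including the intercept column.
#' @param y Numeric response.
#' @return Tibble: `term`, `beta`, `se`, `p`, plus attributes `df_residual`
#'   and `sigma`.
#' @export
fit_linear <- function(X, y) {
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); k <- ncol(X)
  if (n < k + 1L) {
    stop("fit_linear: need more rows than columns (n=", n, ", k=", k, ")",
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < k) stop("fit_linear: singular design matrix", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - k
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  out <- tibble(term = colnames(X), beta = unname(beta), se = unname(se),
                p = unname(p))
  attr(out, "df_residual") <- df
  attr(out, "sigma") <- sqrt(sigma2)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR-adjusted p-values (q-values):
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1 and mapped
#' back to the input order. Delegates to [stats::p.adjust()] after
#' validating the inputs.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Assign significance tiers from q-values
#'
#' `significant` for q < 0.05, `suggestive` for 0.05 <= q < 0.1, otherwise
#' `null`.
#'
#' @param q Numeric vector of q-values.
#' @return Character vector of tiers.
#' @export
fdr_tier <- function(q) {
  dplyr::case_when(q < 0.05 ~ "significant",
                   q < 0.1 ~ "suggestive",
                   TRUE ~ "null")
}

#' Run an association family over a measure matrix
#'
#' Fits one linear model per measure with the family's adjustment set,
#' collects the terms-of-interest coefficients from every model, applies
#' Benjamini-Hochberg FDR across the whole family's (measure x term) pairs,
#' and assigns significance tiers. Participants flagged `oral_steroids` in
#' the metadata are excluded before modelling; measures with missing values
#' (e.g. CDR3 length of an isotype absent from some repertoires) fall back
#' to complete-case rows for that measure.
#'
#' @param mat Measure matrix (participants x measures) with a
#'   `participant_id` column, e.g. from [filter_measure_matrix()].
#' @param metadata Validated metadata covering every matrix participant.
#' @param family Analysis family name (see [model_spec()]), or a
#'   `model_spec` object.
#' @param measures Optional character vector restricting the analyzed
#'   measures (default: every non-id column of `mat`).
#' @param quiet Suppress progress messages.
#' @return Tibble of class `association_results`, sorted by q: `measure`,
#'   `term`, `beta`, `se`, `p`, `q`, `tier`, `family`, `n_used`.
#' @export
run_analysis <- function(mat, metadata, family = "primary", measures = NULL,
                         quiet = FALSE) {
  spec <- if (inherits(family, "model_spec")) family else model_spec(family)
  if (is.null(measures)) measures <- setdiff(names(mat), "participant_id")
  unmatched <- setdiff(mat$participant_id, metadata$participant_id)
  if (length(unmatched) > 0L) {
    stop("run_analysis: ", length(unmatched),
         " matrix participant(s) missing from metadata: ",
         paste(utils::head(unmatched, 5), collapse = ", "), call. = FALSE)
  }
  meta <- metadata[match(mat$participant_id, metadata$participant_id), , drop = FALSE]
  if ("oral_steroids" %in% names(meta)) {
    keep <- !isTRUE_vec(meta$oral_steroids)
    n_excl <- sum(!keep)
    if (n_excl > 0L && !quiet) {
      message("run_analysis: excluded ", n_excl,
              " participant(s) on oral corticosteroids")
    }
    mat <- mat[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  design <- build_design(meta, spec, quiet = quiet)
  idx <- match(design$participants, mat$participant_id)

  rows <- purrr::map_dfr(measures, function(m) {
    y <- mat[[m]][idx]
    ok <- !is.na(y)
    if (sum(ok) < ncol(design$X) + 2L) return(NULL)
    fit <- fit_linear(design$X[ok, , drop = FALSE], y[ok])
    keep <- .is_term_of_interest(fit$term, spec$terms_of_interest)
    fit <- fit[keep, , drop = FALSE]
    fit$measure <- m
    fit$n_used <- sum(ok)
    fit
  })
  if (nrow(rows) == 0L) {
    stop("run_analysis: no measure could be fitted", call. = FALSE)
  }
  rows$q <- bh_adjust(rows$p)
  rows$tier <- fdr_tier(rows$q)
  rows$family <- spec$family
  out <- rows[order(rows$q, rows$p), c("measure", "term", "beta", "se", "p",
                                       "q", "tier", "family", "n_used")]
  class(out) <- c("association_results", class(out))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

# prefixes ending in ":" match dummy/interaction expansions; bare names
# match exactly
.is_term_of_interest <- function(terms, interest) {
  hit <- rep(FALSE, length(terms))
  for (pat in interest) {
    if (endsWith(pat, ":")) {
      hit <- hit | startsWith(terms, pat)
    } else {
      hit <- hit | terms == pat
    }
  }
  hit
}

#' Write association results
#'
#' @param results `association_results` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(as_tibble(results), path, progress = FALSE)
  invisible(path)
}
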