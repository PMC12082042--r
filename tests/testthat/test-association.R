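test_that("design matrix dummy-codes against the reference levels", {
  meta <- small_metadata(8)
  des <- build_design(meta, model_spec("primary"), quiet = TRUE)
  expect_setequal(colnames(des$X), c(
    "intercept", "age", "sex", "race",
    "exposure_group:never", "exposure_group:cigarette", "exposure_group:vaping",
    "exposure_group:dual",
    "gold_group:gold1", "gold_group:gold2_4", "gold_group:prism",
    "pack_years", "ics_use"
  ))
  expect_equal(sum(grepl("^exposure_group:", colnames(des$X))), 4L)
  # independent full-rank check
  expect_equal(qr(des$X)$rank, ncol(des$X))
  expect_equal(des$n_dropped, 0L)
  # former (reference) rows have all-zero exposure dummies
  ref_rows <- meta$exposure_group == "former"
  expect_true(all(des$X[ref_rows, grepl("^exposure_group:", colnames(des$X))] == 0))
})

test_that("design building fails informatively on missing inputs", {
  meta <- small_metadata(6)
  expect_error(build_design(meta[, setdiff(names(meta), "ics_use")],
                            model_spec("primary"), quiet = TRUE), "ics_use")
  no_ref <- meta[meta$exposure_group != "former", ]
  expect_error(build_design(no_ref, model_spec("primary"), quiet = TRUE),
               "former")
})

test_that("rows with missing covariates are dropped, not imputed", {
  meta <- small_metadata(6)
  meta$age[c(2, 5)] <- NA
  des <- build_design(meta, model_spec("primary"), quiet = TRUE)
  expect_equal(des$n_dropped, 2L)
  expect_equal(length(des$participants), nrow(meta) - 2L)
})

test_that("interaction design contains race-by-exposure cross products", {
  meta <- small_metadata(8)
  # ensure both races appear within every exposure group so the
  # cross-products are estimable
  meta$race <- rep_len(c(0, 1), nrow(meta))
  des <- build_design(meta, model_spec("interaction"), quiet = TRUE)
  int_cols <- grep(":x:", colnames(des$X), value = TRUE)
  expect_setequal(int_cols, paste0("race:x:exposure_group:",
                                   c("never", "cigarette", "vaping", "dual")))
  i <- int_cols[1]
  lev <- sub("race:x:exposure_group:", "", i)
  expect_equal(des$X[, i],
               des$X[, "race"] * (meta$exposure_group == lev))
})

test_that("OLS recovers exact coefficients on noiseless data", {
  x <- 1:20
  X <- cbind(intercept = 1, x = x)
  fit <- fit_linear(X, 2 * x + 1)
  expect_equal(fit$beta[fit$term == "x"], 2, tolerance = 1e-12)
  expect_equal(fit$beta[fit$term == "intercept"], 1, tolerance = 1e-12)

  # response orthogonal to a centered covariate has a zero coefficient
  z <- scale(rnorm(20), scale = FALSE)[, 1]
  y <- rep(3, 20)
  fit2 <- fit_linear(cbind(intercept = 1, z = z), y)
  expect_equal(fit2$beta[fit2$term == "z"], 0, tolerance = 1e-10)
})

test_that("OLS beta/se/p match the normal-equations oracle and lm", {
  set.seed(91)
  for (rep in 1:10) {
    n <- 50
    X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.4))
    y <- 0.5 + 0.3 * X[, "a"] - 0.2 * X[, "c"] + rnorm(n)
    fit <- fit_linear(X, y)
    o <- oracle_ols(X, y)
    expect_equal(fit$beta, unname(o$beta), tolerance = 1e-8)
    expect_equal(fit$se, unname(o$se), tolerance = 1e-8)
    expect_equal(fit$p, unname(o$p), tolerance = 1e-8)
    lmfit <- summary(lm(y ~ X[, -1]))$coefficients
    expect_equal(fit$beta, unname(lmfit[, 1]), tolerance = 1e-10)
    expect_equal(fit$se, unname(lmfit[, 2]), tolerance = 1e-10)
  }
  expect_error(fit_linear(cbind(1, c(1, 2), c(2, 4))[, c(1, 2, 3)], c(1, 2)),
               "rows")
  Xs <- cbind(intercept = 1, a = 1:10, b = 2 * (1:10))
  expect_error(fit_linear(Xs, rnorm(10)), "singular")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  set.seed(101)
  for (rep in 1:50) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # order preservation
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FDR tiers are determined solely by q", {
  expect_equal(fdr_tier(c(0.01, 0.05, 0.07, 0.1, 0.5)),
               c("significant", "suggestive", "suggestive", "null", "null"))
})

test_that("run_analysis applies family-wide BH and reports aligned terms", {
  set.seed(111)
  meta <- small_metadata(10)
  n <- nrow(meta)
  mat <- tibble::tibble(
    participant_id = meta$participant_id,
    m1 = rnorm(n), m2 = rnorm(n)
  )
  res <- run_analysis(mat, meta, family = "primary", quiet = TRUE)
  expect_s3_class(res, "association_results")
  expect_setequal(unique(res$measure), c("m1", "m2"))
  expect_false(any(res$term %in% c("pack_years", "ics_use", "intercept")))
  expect_equal(res$q, bh_adjust(res$p), tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(!is.unsorted(res$q))

  expect_error(run_analysis(mat, meta[-1, ], quiet = TRUE), "missing from metadata")
})

test_that("a single measure-term family has q equal to p", {
  set.seed(112)
  meta <- small_metadata(10)
  mat <- tibble::tibble(participant_id = meta$participant_id,
                        m1 = rnorm(nrow(meta)))
  res <- run_analysis(mat, meta, family = "univariable_ct", quiet = TRUE)
  expect_equal(nrow(res), 1L)
  expect_equal(res$term, "ct_wall_area_pct")
  expect_equal(res$q, res$p)
})

test_that("participants on oral corticosteroids are excluded from models", {
  set.seed(113)
  meta <- small_metadata(10)
  meta$oral_steroids[1:5] <- TRUE
  mat <- tibble::tibble(participant_id = meta$participant_id,
                        m1 = rnorm(nrow(meta)))
  res <- run_analysis(mat, meta, family = "primary", quiet = TRUE)
  expect_equal(unique(res$n_used), nrow(meta) - 5L)
})

test_that("adjusting for a group-linked confounder shrinks exposure effects", {
  set.seed(114)
  meta <- small_metadata(30)
  # pack-years drives the measure and differs by group by construction
  y <- 0.01 * meta$pack_years + rnorm(nrow(meta), sd = 0.1)
  mat <- tibble::tibble(participant_id = meta$participant_id, m = y)
  adj <- run_analysis(mat, meta, family = "primary", quiet = TRUE)
  spec_no_py <- model_spec("primary")
  spec_no_py$covariates <- setdiff(spec_no_py$covariates, "pack_years")
  unadj <- run_analysis(mat, meta, family = spec_no_py, quiet = TRUE)
  never_adj <- abs(adj$beta[adj$term == "exposure_group:never"])
  never_unadj <- abs(unadj$beta[unadj$term == "exposure_group:never"])
  expect_lt(never_adj, never_unadj)
})

test_that("univariable COPD family uses the reduced covariate set", {
  set.seed(115)
  meta <- small_metadata(10)
  mat <- tibble::tibble(participant_id = meta$participant_id,
                        m1 = rnorm(nrow(meta)))
  res <- run_analysis(mat, meta, family = "univariable_copd", quiet = TRUE)
  expect_true(all(grepl("^gold_group:", res$term)))
  des <- build_design(meta, model_spec("univariable_copd"), quiet = TRUE)
  expect_setequal(colnames(des$X),
                  c("intercept", "gold_group:gold1", "gold_group:gold2_4",
                    "gold_group:prism", "ics_use"))
})
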