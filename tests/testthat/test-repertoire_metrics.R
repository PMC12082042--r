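test_that("isotype counts, usage, and expression follow their definitions", {
  cl <- rand_clones(10)
  cl$isotype <- "IgM"
  cl$class_switched <- FALSE
  m <- isotype_measures(cl)
  expect_equal(m$usage[m$isotype == "IgM"], 1.0)
  expect_equal(m$usage[m$isotype == "IgA2"], 0.0)
  expect_equal(m$expression[m$isotype == "IgM"], log2(11))
  expect_equal(m$expression[m$isotype == "IgE"], 0)  # log2(0 + 1)

  cl4 <- rand_clones(4)
  cl4$isotype <- c("IgM", "IgM", "IgM", "IgA1")
  m4 <- isotype_measures(cl4)
  expect_equal(m4$usage[m4$isotype == "IgM"], 0.75)
  expect_equal(m4$usage[m4$isotype == "IgA1"], 0.25)

  expect_error(isotype_measures(cl[0, ]), "empty")
})

test_that("all tally measures equal an independent brute-force recount", {
  set.seed(61)
  for (rep in 1:20) {
    cl <- rand_clones(sample(50:500, 1))
    m <- isotype_measures(cl)
    o <- oracle_isotype_tally(cl)
    expect_equal(m$count, unname(o$count))
    expect_equal(m$usage, unname(o$usage))
    expect_equal(m$expression, unname(o$expression))
    expect_equal(sum(m$usage), 1, tolerance = 1e-12)
    expect_equal(sum(m$count), nrow(cl))

    expect_equal(class_switching_proportion(cl), oracle_switching(cl))

    va <- v_allele_measures(cl)
    for (a in va$v_allele) {
      ov <- oracle_v_allele(cl, a)
      expect_equal(va$usage[va$v_allele == a], unname(ov["usage"]))
      expect_equal(va$class_switching[va$v_allele == a], unname(ov["switching"]))
    }
    cdr3 <- cdr3_length_by_isotype(cl)
    for (iso in ISOTYPE_LEVELS) {
      expect_equal(cdr3[[iso]], oracle_cdr3(cl, iso))
    }
  }
})

test_that("class switching requires both a switched isotype and mutation", {
  cl <- rand_clones(4)
  cl$isotype <- c("IgA2", "IgA2", "IgM", "IgG1")
  cl$class_switched <- is_class_switched(cl$isotype)
  cl$mutated <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(class_switching_proportion(cl), 2 / 4)

  cl$isotype <- "IgM"; cl$class_switched <- FALSE
  expect_equal(class_switching_proportion(cl), 0)

  # switching can never exceed the summed usage of switched classes
  set.seed(62)
  for (rep in 1:20) {
    cl <- rand_clones(sample(20:200, 1))
    m <- isotype_measures(cl)
    expect_lte(class_switching_proportion(cl),
               sum(m$usage[m$isotype %in% SWITCHED_ISOTYPES]) + 1e-12)
  }
})

test_that("V-allele usage counts only mutated clones", {
  cl <- rand_clones(3)
  cl$v_allele <- c("IGHV5-51*01", "IGHV5-51*01", "IGHV1-18*01")
  cl$isotype <- c("IgA1", "IgM", "IgM")
  cl$class_switched <- is_class_switched(cl$isotype)
  cl$mutated <- c(TRUE, TRUE, FALSE)
  va <- v_allele_measures(cl)
  expect_equal(va$usage[va$v_allele == "IGHV5-51*01"], 2 / 3)
  expect_equal(va$class_switching[va$v_allele == "IGHV5-51*01"], 1 / 3)
  expect_equal(va$usage[va$v_allele == "IGHV1-18*01"], 0)

  cl$mutated <- FALSE
  expect_true(all(v_allele_measures(cl)$usage == 0))
})

test_that("CDR3 length aggregates per isotype and marks absent classes missing", {
  cl <- rand_clones(2)
  cl$isotype <- "IgM"
  cl$junction_length <- c(45L, 51L)
  lens <- cdr3_length_by_isotype(cl)
  expect_equal(lens[["IgM"]], 48.0)
  expect_true(is.na(lens[["IgE"]]))
  med <- cdr3_length_by_isotype(cl, stat = "median")
  expect_equal(med[["IgM"]], 48)
})

test_that("Hill numbers match closed forms and the continuous q=1 limit", {
  # uniform abundances: D_q = S for every q
  hp <- hill_profile(rep(3, 7))
  expect_equal(hp$values, rep(7, length(hp$q_grid)), tolerance = 1e-10)
  expect_equal(hill_profile(c(1, 1, 1, 1), q_grid = 0)$values, 4)

  # frozen values for (4,2,1,1): p = (1/2, 1/4, 1/8, 1/8)
  hp2 <- hill_profile(c(4, 2, 1, 1), q_grid = c(0, 0.5, 1, 2))
  expect_equal(hp2$values[1], 4, tolerance = 1e-9)
  expect_equal(hp2$values[2], 3.66421356237309, tolerance = 1e-9)
  expect_equal(hp2$values[3], 3.36358566101486, tolerance = 1e-9)
  expect_equal(hp2$values[4], 2.90909090909091, tolerance = 1e-9)
  # the q=1 closed form agrees with the q -> 1 limit to 6 decimals
  lim <- hill_profile(c(4, 2, 1, 1), q_grid = c(1 - 1e-6, 1 + 1e-6))$values
  expect_equal(lim[1], hp2$values[3], tolerance = 1e-6)
  expect_equal(lim[2], hp2$values[3], tolerance = 1e-6)

  expect_equal(hp2$log_values, log(hp2$values))
  expect_error(hill_profile(c(1, 0, 2)), "positive")
  expect_error(hill_profile(numeric(0)), "empty")
})

test_that("Hill profiles agree with an independent diversity implementation", {
  set.seed(71)
  for (rep in 1:10) {
    x <- sample(1:40, sample(5:60, 1), replace = TRUE)
    hp <- hill_profile(x, q_grid = c(1, 2))
    expect_equal(hp$values[1], exp(vegan::diversity(x, "shannon")),
                 tolerance = 1e-10)
    expect_equal(hp$values[2], vegan::diversity(x, "invsimpson"),
                 tolerance = 1e-10)
  }
})

test_that("Hill profile is non-increasing in q and richness-anchored", {
  set.seed(72)
  for (rep in 1:50) {
    x <- sample(1:50, sample(3:80, 1), replace = TRUE)
    hp <- hill_profile(x)
    expect_equal(hp$values[1], length(x))
    expect_true(all(diff(hp$values) <= 1e-10))
  }
})

test_that("clonal expansion strictly lowers diversity at q > 0", {
  set.seed(73)
  for (k in c(3, 10, 25)) {
    S <- 40
    flat <- rep(1, S)
    expanded <- c(rep(1, S - k), k)  # same total reads, one expanded clone
    q <- c(0.5, 1, 2, 4)
    d_flat <- hill_profile(flat, q)$values
    d_exp <- hill_profile(expanded, q)$values
    expect_true(all(d_exp < d_flat))
  }
})

test_that("prevalence filter applies the strict >1% in >=25% rule with IgE kept", {
  usage <- matrix(0.02, nrow = 8, ncol = 1, dimnames = list(NULL, "IGHV5-51*01"))
  expect_equal(prevalence_filter(usage), "IGHV5-51*01")

  usage[] <- 0.005
  expect_equal(prevalence_filter(usage), character(0))

  # exactly at the 1% boundary: strictly-greater rule drops it
  usage[] <- 0.01
  expect_equal(prevalence_filter(usage), character(0))

  ige <- matrix(1e-4, nrow = 8, ncol = 1, dimnames = list(NULL, "IgE"))
  expect_equal(prevalence_filter(ige, always_keep = "IgE"), "IgE")

  expect_error(prevalence_filter(usage[0, , drop = FALSE]), "empty")
})

test_that("summarize_repertoire bundles consistent per-participant measures", {
  set.seed(81)
  cl <- rand_clones(200)
  s <- summarize_repertoire(cl)
  expect_equal(s$total_unique, 200)
  expect_equal(sum(s$isotypes$count), 200)
  expect_equal(sum(s$isotypes$usage), 1, tolerance = 1e-12)
  expect_equal(s$hill$values[1], length(unique(cl$clone_id)))
  expect_output(print(s), "Repertoire summary")
})

test_that("measure matrix columns reconcile with per-participant summaries", {
  set.seed(82)
  cl <- dplyr::bind_rows(rand_clones(150, "P1"), rand_clones(120, "P2"))
  mat <- measure_matrix(cl, quiet = TRUE)
  expect_equal(nrow(mat), 2L)
  p1 <- cl[cl$participant_id == "P1", ]
  m1 <- isotype_measures(p1)
  expect_equal(mat$IgM_usage[mat$participant_id == "P1"],
               m1$usage[m1$isotype == "IgM"])
  expect_equal(mat$class_switching[mat$participant_id == "P1"],
               class_switching_proportion(p1))
  expect_equal(mat$hill_logD_q0[mat$participant_id == "P1"],
               log(length(unique(p1$clone_id))))
  manifest <- attr(mat, "manifest")
  expect_true(all(setdiff(names(mat), "participant_id") %in% manifest$measure))
})

test_that("measure-matrix prevalence filtering keeps IgE and drops rare alleles", {
  set.seed(83)
  cl <- dplyr::bind_rows(lapply(sprintf("P%02d", 1:8), function(p) {
    x <- rand_clones(200, p)
    x$v_allele[1] <- "IGHV9-99*01"  # 1 mutated clone at most: usage <= 0.005
    x
  }))
  mat <- measure_matrix(cl, quiet = TRUE)
  filt <- filter_measure_matrix(mat, quiet = TRUE)
  kept <- attr(filt, "manifest")$measure
  expect_true("IgE_usage" %in% kept)
  expect_false("IGHV9-99*01_usage" %in% kept)
  expect_false("IGHV9-99*01_class_switching" %in% kept)
  expect_true("class_switching" %in% kept)
  log <- attr(filt, "filter_log")
  expect_equal(log$reason[log$class == "IgE"], "always_keep")
})
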