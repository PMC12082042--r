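# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (apart from trivial string helpers) so the tests compare
# two independent routes to the same quantity.

hamming_frac <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb) / length(va)
}

# clone partition by transitive closure over the all-pairs adjacency matrix
oracle_clone_partition <- function(rearr, threshold) {
  n <- nrow(rearr)
  gene <- function(x) sub("\\*.*$", "", sub(",.*$", "", x))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- i == j || (
        gene(rearr$v_call[i]) == gene(rearr$v_call[j]) &&
        gene(rearr$j_call[i]) == gene(rearr$j_call[j]) &&
        nchar(rearr$junction[i]) == nchar(rearr$junction[j]) &&
        hamming_frac(rearr$junction[i], rearr$junction[j]) <= threshold)
    }
  }
  repeat {
    nxt <- adj | ((adj %*% adj) > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      label <- label + 1L
      comp[adj[i, ]] <- label
    }
  }
  comp
}

# canonical form of a partition: sorted list of sorted member id sets
partition_sets <- function(ids, labels) {
  sets <- lapply(split(ids, labels), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

# step-up Benjamini-Hochberg evaluated directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# textbook OLS via explicit normal equations
oracle_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  p <- 2 * pt(-abs(beta / se), df = df)
  list(beta = beta, se = se, p = p)
}

# direct tallies over clone records, written against the measure definitions
oracle_isotype_tally <- function(clones) {
  N <- nrow(clones)
  isos <- c("IgM", "IgD", "IgA1", "IgA2", "IgG1", "IgG2", "IgG3", "IgE")
  counts <- vapply(isos, function(i) sum(clones$isotype == i), numeric(1))
  list(count = counts, usage = counts / N, expression = log2(counts + 1))
}

oracle_switching <- function(clones) {
  switched <- clones$isotype %in% c("IgA1", "IgA2", "IgG1", "IgG2", "IgG3", "IgE")
  sum(switched & clones$mutated) / nrow(clones)
}

oracle_v_allele <- function(clones, allele) {
  switched <- clones$isotype %in% c("IgA1", "IgA2", "IgG1", "IgG2", "IgG3", "IgE")
  c(usage = sum(clones$v_allele == allele & clones$mutated) / nrow(clones),
    switching = sum(clones$v_allele == allele & clones$mutated & switched) /
      nrow(clones))
}

oracle_cdr3 <- function(clones, iso) {
  x <- clones$junction_length[clones$isotype == iso]
  if (length(x) == 0) NA_real_ else sum(x) / length(x)
}

# direct Hill evaluation (independent arithmetic path: explicit power sums)
oracle_hill <- function(abund, q) {
  p <- abund / sum(abund)
  if (q == 1) return(prod(p^(-p)))
  sum(p^q)^(1 / (1 - q))
}
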