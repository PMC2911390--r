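# Independent brute-force oracles used to pin expected values.
# These deliberately avoid the code paths (and where possible the base
# functions) used by the implementation.

# random expression matrix on the log10_ratio scale (row-centered)
random_ratio_matrix <- function(n_genes, n_samples, gene_names = NULL,
                                centered = TRUE) {
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  if (centered) v <- v - rowMeans(v)
  rownames(v) <- if (is.null(gene_names))
    sprintf("G%04d", seq_len(n_genes)) else gene_names
  colnames(v) <- sprintf("S%03d", seq_len(n_samples))
  expr_matrix(v, scale = "log10_ratio")
}

# two-loop mean-difference score oracle: plain sums, one sample at a time
oracle_score <- function(values, up, down) {
  out <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) {
    s_up <- 0; n_up <- 0
    for (g in up) {
      x <- values[g, j]
      if (!is.na(x)) { s_up <- s_up + x; n_up <- n_up + 1 }
    }
    s_dn <- 0; n_dn <- 0
    for (g in down) {
      x <- values[g, j]
      if (!is.na(x)) { s_dn <- s_dn + x; n_dn <- n_dn + 1 }
    }
    out[j] <- s_up / n_up - (if (length(down)) s_dn / n_dn else 0)
  }
  out
}

# textbook Pearson correlation formula
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# full fixed-margin enumeration of the 2x2 Fisher test via choose();
# independent of the dhyper-based implementation
oracle_fisher <- function(tab, sided = "greater") {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, support) * choose(n - c1, r1 - support) /
    choose(n, r1)
  if (sided == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
  }
}

# per-row centering by an explicit loop
oracle_center <- function(v) {
  out <- v
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    out[i, ] <- x - mean(x[!is.na(x)])
  }
  out
}
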