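#' Per-gene correlations with the signature arm averages
#'
#' For every signature gene present in the matrix, computes the Pearson
#' correlation of its expression profile with the average profile of the
#' up arm and with the average profile of the down arm. A gene is
#' excluded from its own arm's average (leave-one-out): including it
#' would guarantee a spuriously positive correlation for small arms.
#' In a coherent signature, up genes correlate positively with the up
#' average and negatively with the down average, and conversely for
#' down genes.
#'
#' @param m an [expr_matrix] with `scale = "log10_ratio"`.
#' @param signature a [two_arm_signature] with at least two genes per
#'   arm present in `m`.
#' @return A data frame of class `arm_correlations` with columns `gene`,
#'   `arm`, `r_vs_up_avg`, `r_vs_down_avg`, `testable`. Genes with a
#'   zero-variance profile are reported with `NA` correlations and
#'   `testable = FALSE`.
#' @export
arm_correlations <- function(m, signature) {
  stopifnot(inherits(m, "expr_matrix"),
            inherits(signature, "two_arm_signature"))
  if (ncol(m$values) < 3)
    stop("coherence analysis needs at least 3 samples", call. = FALSE)
  up <- intersect(signature$up_genes, gene_ids(m))
  down <- intersect(signature$down_genes, gene_ids(m))
  if (length(up) < 2 || length(down) < 2)
    stop("each arm needs at least 2 genes present in the matrix ",
         sprintf("(found %d up, %d down)", length(up), length(down)),
         call. = FALSE)
  v <- m$values
  arm_avg <- function(genes)
    colMeans(v[genes, , drop = FALSE], na.rm = TRUE)
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  one_gene <- function(g, arm) {
    prof <- v[g, ]
    up_ref <- if (arm == "up") arm_avg(setdiff(up, g)) else arm_avg(up)
    down_ref <- if (arm == "down") arm_avg(setdiff(down, g)) else arm_avg(down)
    c(safe_cor(prof, up_ref), safe_cor(prof, down_ref))
  }
  res <- rbind(
    t(vapply(up, one_gene, numeric(2L), arm = "up")),
    t(vapply(down, one_gene, numeric(2L), arm = "down")))
  out <- data.frame(
    gene = c(up, down),
    arm = c(rep("up", length(up)), rep("down", length(down))),
    r_vs_up_avg = res[, 1L],
    r_vs_down_avg = res[, 2L],
    stringsAsFactors = FALSE, row.names = NULL)
  out$testable <- !is.na(out$r_vs_up_avg)
  class(out) <- c("arm_correlations", "data.frame")
  out
}

#' Fisher exact test for a 2x2 contingency table
#'
#' Exact conditional test on the hypergeometric distribution of the
#' top-left cell given the table margins. This single implementation
#' backs both the signature coherence test and the clinical response
#' contingency test. With `sided = "greater"` the upper tail of the
#' top-left cell is summed (enrichment of the first column in the first
#' row); with `sided = "two"` all tables with point probability not
#' exceeding that of the observed table are summed, as in
#' [stats::fisher.test()].
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param sided `"greater"` or `"two"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, 2), sided = "greater")
#' @export
fisher_exact_2x2 <- function(table, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("`table` must be 2x2", call. = FALSE)
  if (any(is.na(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8))
    stop("`table` must contain nonnegative integers", call. = FALSE)
  table <- round(table)
  n <- sum(table)
  if (n == 0) {
    warning("all-zero contingency table; p = 1", call. = FALSE)
    return(1)
  }
  a <- table[1L, 1L]
  r1 <- sum(table[1L, ])            # drawn
  c1 <- sum(table[, 1L])            # "white" population
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  dens <- stats::dhyper(support, c1, n - c1, r1)
  if (sided == "greater") {
    sum(dens[support >= a])
  } else {
    # relative tolerance matches fisher.test's handling of fp ties
    sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  }
}

#' Signature coherence test
#'
#' Tests whether a two-arm signature retains its structure in a new
#' dataset: most up-arm genes should correlate positively with the
#' up-arm average, and most down-arm genes should anticorrelate with it.
#' Genes are cross-tabulated by arm membership (rows) against the sign
#' of their correlation with the up-arm average (columns: positive vs
#' nonpositive), and the table is tested with the shared Fisher exact
#' test. The default one-sided ("greater") test targets the directional
#' coherence hypothesis; a two-sided test is available.
#'
#' @inheritParams arm_correlations
#' @param sided `"greater"` (default) or `"two"`.
#' @return An object of class `coherence_result`: list with `table`
#'   (2x2 counts), `p_value`, `per_gene` (the [arm_correlations] frame),
#'   and `sided`.
#' @export
coherence_test <- function(m, signature, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  per_gene <- arm_correlations(m, signature)
  usable <- per_gene[per_gene$testable, ]
  pos <- usable$r_vs_up_avg > 0
  is_up <- usable$arm == "up"
  tab <- matrix(c(sum(is_up & pos), sum(!is_up & pos),
                  sum(is_up & !pos), sum(!is_up & !pos)),
                nrow = 2L,
                dimnames = list(arm = c("up", "down"),
                                r_vs_up_avg = c("positive", "nonpositive")))
  structure(list(table = tab,
                 p_value = fisher_exact_2x2(tab, sided = sided),
                 per_gene = per_gene,
                 sided = sided),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("Signature coherence test (Fisher exact,",
      if (x$sided == "greater") "one-sided)\n" else "two-sided)\n")
  print(x$table)
  cat(sprintf("p-value: %.3g\n", x$p_value))
  n_bad <- sum(!x$per_gene$testable)
  if (n_bad)
    cat(sprintf("%d zero-variance gene(s) excluded\n", n_bad))
  invisible(x)
}

#' @export
plot.coherence_result <- function(x, ...) {
  pg <- x$per_gene[x$per_gene$testable, ]
  cols <- ifelse(pg$arm == "up", "firebrick", "navy")
  graphics::plot(pg$r_vs_up_avg, pg$r_vs_down_avg, col = cols,
                 pch = 19, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "r vs up-arm average",
                 ylab = "r vs down-arm average", ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  graphics::legend("topright", legend = c("up arm", "down arm"),
                   col = c("firebrick", "navy"), pch = 19, bty = "n")
  invisible(x)
}
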