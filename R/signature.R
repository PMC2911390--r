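#' Two-arm gene signature
#'
#' A pathway-activation signature with an "up" arm (genes that rise as
#' signaling through the pathway increases) and a "down" arm (genes that
#' fall). The arms must be disjoint; the down arm may be empty, in which
#' case the composite score reduces to the up-arm mean.
#'
#' @param name signature name.
#' @param up_genes character vector of up-arm gene symbols (at least one).
#' @param down_genes character vector of down-arm gene symbols (may be
#'   empty).
#' @return An object of class `two_arm_signature`.
#' @export
two_arm_signature <- function(name, up_genes, down_genes = character()) {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(up_genes) < 1)
    stop("a signature needs at least one up-arm gene", call. = FALSE)
  both <- intersect(up_genes, down_genes)
  if (length(both))
    stop("genes in both arms: ", paste(both, collapse = ", "),
         call. = FALSE)
  structure(list(name = as.character(name)[1L],
                 up_genes = up_genes, down_genes = down_genes),
            class = "two_arm_signature")
}

#' @export
print.two_arm_signature <- function(x, ...) {
  cat(sprintf("two_arm_signature '%s': %d up genes, %d down genes\n",
              x$name, length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' Read / write a two-arm signature file
#'
#' Two-column TSV with header `gene_symbol`, `arm`; `arm` is `up` or
#' `down`.
#'
#' @param path path to the signature file.
#' @param name signature name; defaults to the file name.
#' @return [read_signature()] returns a [two_arm_signature];
#'   [write_signature()] returns `path` invisibly.
#' @export
read_signature <- function(path, name = NULL) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (!all(c("gene_symbol", "arm") %in% names(tab)))
    stop("signature file must have columns 'gene_symbol' and 'arm'",
         call. = FALSE)
  bad <- setdiff(unique(tab$arm), c("up", "down"))
  if (length(bad))
    stop("invalid arm label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  two_arm_signature(name,
                    up_genes = tab$gene_symbol[tab$arm == "up"],
                    down_genes = tab$gene_symbol[tab$arm == "down"])
}

#' @rdname read_signature
#' @param signature a [two_arm_signature] to write.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "two_arm_signature"))
  tab <- data.frame(
    gene_symbol = c(signature$up_genes, signature$down_genes),
    arm = c(rep("up", length(signature$up_genes)),
            rep("down", length(signature$down_genes))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged RAS pathway signature (synthetic reconstruction)
#'
#' A 147-gene two-arm RAS/MEK/ERK pathway signature with 105 up-arm and
#' 42 down-arm genes, shipped as
#' `inst/extdata/ras_signature_synthetic.tsv`. The arm sizes and the
#' pathway-component genes discussed in the source literature (FOS, IER3,
#' DUSP1, DUSP4, DUSP5, DUSP6, SPRY4, ...) are preserved; the remaining
#' membership is a synthetic reconstruction from canonical RAS-MEK-ERK
#' transcriptional targets, because the original supplementary gene table
#' is not redistributable here. Treat membership, not arm structure, as
#' approximate.
#'
#' @return A [two_arm_signature] with 105 up and 42 down genes.
#' @examples
#' sig <- ras_signature()
#' sig
#' @export
ras_signature <- function() {
  path <- system.file("extdata", "ras_signature_synthetic.tsv",
                      package = "rassig", mustWork = TRUE)
  read_signature(path, name = "RAS_pathway_147")
}

#' Composite signature score per sample
#'
#' For each sample, the score is the mean log10 ratio of the up-arm
#' genes minus the mean log10 ratio of the down-arm genes, each mean
#' taken over the signature genes present in the matrix and non-missing
#' in that sample. Because the input is row-centered (log10 ratio to the
#' gene mean), the score averages to zero across the samples of a
#' dataset, which is what licenses zero as the activation threshold.
#'
#' @param m an [expr_matrix] with `scale = "log10_ratio"` (use
#'   [mean_normalize()] first; the scale requirement is enforced so that
#'   normalization is always explicit).
#' @param signature a [two_arm_signature].
#' @return An object of class `signature_scores`: a data frame with
#'   columns `sample_id` and `score`, and attributes `n_up_used`,
#'   `n_down_used`, and `signature` (the signature name).
#' @export
score_samples <- function(m, signature) {
  stopifnot(inherits(m, "expr_matrix"),
            inherits(signature, "two_arm_signature"))
  if (m$scale != "log10_ratio")
    stop("score_samples requires scale 'log10_ratio'; ",
         "call mean_normalize() first", call. = FALSE)
  up <- intersect(signature$up_genes, gene_ids(m))
  down <- intersect(signature$down_genes, gene_ids(m))
  if (length(up) == 0)
    stop("no up-arm gene of '", signature$name,
         "' is present in the matrix", call. = FALSE)
  absent <- missing_signature_genes(m, signature)
  if (length(absent))
    warning(length(absent), " signature gene(s) absent from the matrix: ",
            paste(absent, collapse = ", "), call. = FALSE)
  up_mean <- colMeans(m$values[up, , drop = FALSE], na.rm = TRUE)
  score <- if (length(down)) {
    up_mean - colMeans(m$values[down, , drop = FALSE], na.rm = TRUE)
  } else up_mean
  score[is.nan(score)] <- NA_real_
  out <- data.frame(sample_id = sample_ids(m), score = unname(score),
                    stringsAsFactors = FALSE)
  structure(out, n_up_used = length(up), n_down_used = length(down),
            signature = signature$name,
            class = c("signature_scores", "data.frame"))
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("signature_scores ('%s'): %d samples, %d up / %d down genes used\n",
              attr(x, "signature"), nrow(x),
              attr(x, "n_up_used"), attr(x, "n_down_used")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Classify samples as pathway-active
#'
#' A sample is called active when its score strictly exceeds the
#' threshold; ties at the threshold are inactive. The default threshold
#' of zero is the population mean score on mean-normalized data.
#'
#' @param scores a `signature_scores` object or a numeric vector.
#' @param threshold activation threshold (default 0).
#' @return Logical vector, one call per sample (named when sample ids are
#'   available).
#' @export
classify_active <- function(scores, threshold = 0) {
  s <- if (inherits(scores, "signature_scores")) {
    stats::setNames(scores$score, scores$sample_id)
  } else as.numeric(scores)
  s > threshold
}

#' Score change of treated samples relative to matched controls
#'
#' Pairs treated and control samples by sample id, forms the per-gene
#' log10 ratio of treated to matched control (the difference of log10
#' values), and scores that differenced matrix. By linearity of the
#' score this equals the difference of the two scores on a shared gene
#' set, and is the natural statistic for post-dose versus vehicle
#' comparisons.
#'
#' @param treated,control [expr_matrix] objects on the same (log10)
#'   scale, sharing gene ids and paired sample ids.
#' @param signature a [two_arm_signature].
#' @return A `signature_scores` object of per-pair score deltas.
#' @export
paired_score_change <- function(treated, control, signature) {
  stopifnot(inherits(treated, "expr_matrix"),
            inherits(control, "expr_matrix"))
  if (treated$scale != control$scale)
    stop("treated and control matrices are on different scales",
         call. = FALSE)
  genes <- intersect(gene_ids(treated), gene_ids(control))
  if (length(genes) == 0)
    stop("treated and control matrices share no genes", call. = FALSE)
  unpaired <- c(setdiff(sample_ids(treated), sample_ids(control)),
                setdiff(sample_ids(control), sample_ids(treated)))
  if (length(unpaired))
    stop("unpaired sample(s): ", paste(unpaired, collapse = ", "),
         call. = FALSE)
  samples <- sample_ids(treated)
  delta <- treated$values[genes, samples, drop = FALSE] -
    control$values[genes, samples, drop = FALSE]
  score_samples(expr_matrix(delta, scale = "log10_ratio"), signature)
}

#' Summarize a signature in a two-condition contrast
#'
#' Given per-gene log10 fold changes of a condition against a reference,
#' summarizes the signature as a mean linear fold change,
#' `10^(mean(up-arm log10 folds) - mean(down-arm log10 folds))` (the
#' down-arm term is zero when no down gene is available), with a
#' two-sided one-sample t test of the up-arm log10 fold changes against
#' zero.
#'
#' @param fold_log10 named numeric vector of per-gene log10 fold changes.
#' @param signature a [two_arm_signature].
#' @return An object of class `contrast_summary`: list with
#'   `mean_fold_change`, `p_value`, `n_genes` (signature genes used).
#' @export
contrast_signature <- function(fold_log10, signature) {
  stopifnot(inherits(signature, "two_arm_signature"))
  if (is.null(names(fold_log10)))
    stop("`fold_log10` must be named by gene symbol", call. = FALSE)
  fold_log10 <- fold_log10[!is.na(fold_log10)]
  up <- fold_log10[intersect(signature$up_genes, names(fold_log10))]
  down <- fold_log10[intersect(signature$down_genes, names(fold_log10))]
  if (length(up) < 2)
    stop("fewer than 2 up-arm genes with fold changes; ",
         "the t test is undefined", call. = FALSE)
  down_term <- if (length(down)) mean(down) else 0
  # limit of the t test for zero-variance fold changes
  p <- if (stats::sd(up) == 0) {
    if (mean(up) == 0) 1 else 0
  } else {
    stats::t.test(up, mu = 0)$p.value
  }
  structure(list(
    mean_fold_change = 10^(mean(up) - down_term),
    p_value = p,
    n_genes = length(up) + length(down)),
    class = "contrast_summary")
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf(
    "contrast_summary: mean fold change %.3g, p = %.3g (%d genes)\n",
    x$mean_fold_change, x$p_value, x$n_genes))
  invisible(x)
}
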