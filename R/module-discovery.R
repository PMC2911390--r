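#' Configuration for coherent-module discovery
#'
#' Thresholds and clustering parameters of the signature derivation
#' procedure. Defaults follow the published derivation: complete-linkage
#' hierarchical clustering of the Pearson correlation matrix with
#' Euclidean distance, a minimum mean pairwise correlation of 0.40
#' within a module, and a down-arm anticorrelation cutoff of -0.4.
#'
#' @param min_mean_pairwise_r minimum mean (or median, see `criterion`)
#'   off-diagonal pairwise Pearson correlation a cluster must reach to
#'   qualify as a coherent module; in (0, 1).
#' @param down_arm_max_r inclusive upper bound on the correlation of a
#'   down-arm candidate with the up-arm average profile; in (-1, 0).
#' @param linkage hierarchical clustering linkage; only `"complete"`.
#' @param distance distance on correlation-matrix rows; only
#'   `"euclidean"`.
#' @param min_module_size smallest admissible module (>= 2).
#' @param cut_scan_steps number of evenly spaced dendrogram cut heights
#'   scanned for qualifying clusters.
#' @param criterion summarize within-module pairwise correlation by its
#'   `"mean"` (default) or `"median"`.
#' @return A list of class `module_discovery_config`.
#' @export
module_discovery_config <- function(min_mean_pairwise_r = 0.40,
                                    down_arm_max_r = -0.4,
                                    linkage = "complete",
                                    distance = "euclidean",
                                    min_module_size = 10L,
                                    cut_scan_steps = 100L,
                                    criterion = c("mean", "median")) {
  linkage <- match.arg(linkage, "complete")
  distance <- match.arg(distance, "euclidean")
  criterion <- match.arg(criterion)
  stopifnot(min_mean_pairwise_r > 0, min_mean_pairwise_r < 1,
            down_arm_max_r > -1, down_arm_max_r < 0,
            min_module_size >= 2, cut_scan_steps >= 1)
  structure(list(min_mean_pairwise_r = min_mean_pairwise_r,
                 down_arm_max_r = down_arm_max_r,
                 linkage = linkage, distance = distance,
                 min_module_size = as.integer(min_module_size),
                 cut_scan_steps = as.integer(cut_scan_steps),
                 criterion = criterion),
            class = "module_discovery_config")
}

#' Pearson correlation matrix of gene profiles
#'
#' @param m an [expr_matrix] with at least 3 samples.
#' @param genes gene symbols to correlate; genes absent from the matrix
#'   are ignored, zero-variance genes are excluded with a warning.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m, genes = gene_ids(m)) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3)
    stop("correlation analysis needs at least 3 samples", call. = FALSE)
  genes <- intersect(genes, gene_ids(m))
  if (length(genes) < 2)
    stop("fewer than 2 requested genes present in the matrix",
         call. = FALSE)
  v <- m$values[genes, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  flat <- is.na(sds) | sds == 0
  if (any(flat)) {
    warning("excluding zero-variance gene(s): ",
            paste(genes[flat], collapse = ", "), call. = FALSE)
    v <- v[!flat, , drop = FALSE]
  }
  if (nrow(v) < 2)
    stop("fewer than 2 usable genes after excluding zero-variance ",
         "profiles", call. = FALSE)
  cc <- stats::cor(t(v), use = "pairwise.complete.obs")
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

.mean_offdiag_r <- function(corr, members, criterion = "mean") {
  sub <- corr[members, members, drop = FALSE]
  offdiag <- sub[upper.tri(sub)]
  if (criterion == "median") stats::median(offdiag) else mean(offdiag)
}

#' Find the largest coherent module in a correlation matrix
#'
#' Rows of the correlation matrix are clustered as feature vectors
#' (Euclidean distance, complete linkage) -- the standard correlation
#' heatmap workflow; since the matrix is symmetric, row and column
#' clustering coincide. Cut heights are scanned over evenly spaced
#' levels of the dendrogram, and every cluster of at least
#' `min_module_size` genes whose mean off-diagonal pairwise correlation
#' reaches `min_mean_pairwise_r` is a candidate. The largest candidate
#' wins; ties prefer higher mean correlation, then the lexicographically
#' smallest member set.
#'
#' @param corr symmetric correlation matrix from [correlation_matrix()].
#' @param config a [module_discovery_config()].
#' @return Character vector of module gene symbols (sorted), empty when
#'   no cluster qualifies.
#' @export
find_coherent_module <- function(corr, config = module_discovery_config()) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            inherits(config, "module_discovery_config"))
  genes <- rownames(corr)
  if (is.null(genes)) stop("`corr` must have gene row names", call. = FALSE)
  if (nrow(corr) < config$min_module_size) return(character())
  hc <- stats::hclust(stats::dist(corr, method = config$distance),
                      method = config$linkage)
  heights <- seq(0, max(hc$height), length.out = config$cut_scan_steps)
  best <- NULL
  best_r <- -Inf
  seen <- character()
  for (h in heights) {
    cl <- stats::cutree(hc, h = h)
    for (k in unique(cl)) {
      members <- sort(genes[cl == k])
      if (length(members) < config$min_module_size) next
      key <- paste(members, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      r <- .mean_offdiag_r(corr, members, config$criterion)
      if (r < config$min_mean_pairwise_r) next
      better <-
        is.null(best) ||
        length(members) > length(best) ||
        (length(members) == length(best) &&
           (r > best_r ||
              (r == best_r &&
                 paste(members, collapse = "\r") <
                   paste(best, collapse = "\r"))))
      if (better) { best <- members; best_r <- r }
    }
  }
  if (is.null(best)) return(character())
  # the returned module must itself satisfy the coherence criterion
  stopifnot(.mean_offdiag_r(corr, best, config$criterion) >=
              config$min_mean_pairwise_r)
  best
}

#' Intersect per-dataset modules
#'
#' @param modules list of character vectors of gene symbols.
#' @return Genes present in every module; warns when empty.
#' @export
intersect_modules <- function(modules) {
  stopifnot(is.list(modules), length(modules) >= 1)
  out <- Reduce(intersect, modules)
  if (length(out) == 0)
    warning("module intersection is empty", call. = FALSE)
  sort(out)
}

#' Select the down arm by anticorrelation with the up-arm average
#'
#' Every gene of the reference matrix outside the up arm whose Pearson
#' correlation with the average up-arm profile is at most
#' `down_arm_max_r` (inclusive; default -0.4) is selected.
#'
#' @param reference an [expr_matrix] (typically a cell-line panel).
#' @param up_genes character vector of up-arm gene symbols.
#' @param config a [module_discovery_config()].
#' @return Character vector of down-arm gene symbols (sorted).
#' @export
select_down_arm <- function(reference, up_genes,
                            config = module_discovery_config()) {
  stopifnot(inherits(reference, "expr_matrix"))
  up <- intersect(up_genes, gene_ids(reference))
  if (length(up) == 0)
    stop("no up-arm gene is present in the reference matrix",
         call. = FALSE)
  up_avg <- colMeans(reference$values[up, , drop = FALSE], na.rm = TRUE)
  candidates <- setdiff(gene_ids(reference), up_genes)
  if (length(candidates) == 0) return(character())
  r <- apply(reference$values[candidates, , drop = FALSE], 1L,
             function(x) {
               ok <- !is.na(x) & !is.na(up_avg)
               if (sum(ok) < 3 || stats::sd(x[ok]) == 0 ||
                   stats::sd(up_avg[ok]) == 0) return(NA_real_)
               stats::cor(x[ok], up_avg[ok])
             })
  sort(candidates[!is.na(r) & r <= config$down_arm_max_r])
}

#' Derive a two-arm signature from a gene superset across datasets
#'
#' Runs the full derivation: per dataset, the superset genes present in
#' the matrix are correlated and the largest coherent module is
#' extracted ([find_coherent_module()]); the up arm is the intersection
#' of the per-dataset modules; the down arm is selected on a reference
#' panel by anticorrelation with the up-arm average
#' ([select_down_arm()]).
#'
#' @param superset character vector of candidate gene symbols.
#' @param datasets named list of [expr_matrix] objects.
#' @param reference an [expr_matrix] used for down-arm selection.
#' @param config a [module_discovery_config()].
#' @param name name of the derived signature.
#' @return An object of class `discovery_report`: list with
#'   `per_dataset_modules`, `per_dataset_mean_r`, `up_arm`, `down_arm`,
#'   `signature` (a [two_arm_signature]), and `config`.
#' @export
build_signature <- function(superset, datasets, reference,
                            config = module_discovery_config(),
                            name = "discovered") {
  stopifnot(length(superset) >= 1, is.list(datasets),
            length(datasets) >= 1)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  modules <- list()
  mean_r <- numeric()
  for (nm in names(datasets)) {
    corr <- correlation_matrix(datasets[[nm]], genes = superset)
    mod <- find_coherent_module(corr, config)
    modules[[nm]] <- mod
    mean_r[[nm]] <- if (length(mod) >= 2)
      .mean_offdiag_r(corr, mod, config$criterion) else NA_real_
  }
  up <- suppressWarnings(intersect_modules(modules))
  if (length(up) == 0)
    stop("no gene survives the cross-dataset intersection; ",
         "consider relaxing min_mean_pairwise_r or min_module_size",
         call. = FALSE)
  down <- select_down_arm(reference, up, config)
  structure(list(per_dataset_modules = modules,
                 per_dataset_mean_r = mean_r,
                 up_arm = up, down_arm = down,
                 signature = two_arm_signature(name, up, down),
                 config = config),
            class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("discovery_report\n")
  for (nm in names(x$per_dataset_modules))
    cat(sprintf("  %s: module of %d genes (mean pairwise r %.3f)\n",
                nm, length(x$per_dataset_modules[[nm]]),
                x$per_dataset_mean_r[[nm]]))
  cat(sprintf("  up arm: %d genes; down arm: %d genes\n",
              length(x$up_arm), length(x$down_arm)))
  invisible(x)
}
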