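#' Expression matrix container
#'
#' A lightweight genes x samples container carrying its value scale.
#' Values are stored as a numeric matrix with gene symbols as row names and
#' sample identifiers as column names; missing measurements are `NA`.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must be named and names must be unique.
#' @param scale value scale of the matrix: `"raw_intensity"` (linear,
#'   strictly positive), `"log10_intensity"`, or `"log10_ratio"`
#'   (log10 ratio to the per-gene mean, i.e. row-centered log10 values).
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `scale`.
#' @examples
#' v <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("DUSP6", "SPRY4", "FOS"), c("s1", "s2")))
#' m <- expr_matrix(v, scale = "log10_intensity")
#' dim(m)
#' @export
expr_matrix <- function(values,
                        scale = c("log10_intensity", "raw_intensity",
                                  "log10_ratio")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  finite_ok <- is.na(values) | is.finite(values)
  if (!all(finite_ok))
    stop("non-finite values present (Inf); only NA marks missing data",
         call. = FALSE)
  if (scale == "raw_intensity" && any(values <= 0, na.rm = TRUE))
    stop("raw_intensity values must be strictly positive; ",
         "zero or negative intensities indicate corrupted input",
         call. = FALSE)
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param m an [expr_matrix].
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  n_na <- sum(is.na(x$values))
  if (n_na > 0)
    cat(sprintf("  %d missing values (%.1f%%)\n",
                n_na, 100 * n_na / length(x$values)))
  invisible(x)
}

# tokens treated as missing when parsing matrices (case-insensitive)
.na_tokens <- c("", "na", "nan", "null")

.parse_numeric_cells <- function(chr, path) {
  chr_trim <- trimws(chr)
  is_na <- tolower(chr_trim) %in% .na_tokens | is.na(chr_trim)
  out <- rep(NA_real_, length(chr))
  if (any(!is_na)) {
    parsed <- suppressWarnings(as.numeric(chr_trim[!is_na]))
    if (anyNA(parsed)) {
      bad <- chr_trim[!is_na][is.na(parsed)][1L]
      stop(sprintf("non-numeric cell '%s' in %s is not a recognized NA token",
                   bad, path), call. = FALSE)
    }
    out[!is_na] <- parsed
  }
  out
}

#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect has a header row of sample names, a first column of
#' gene (or probe) identifiers, and tab-separated numeric cells; empty
#' cells and the tokens `NA`, `NaN`, `null` (case-insensitive) are treated
#' as missing. The GCT dialect carries the standard two-line preamble
#' (`#1.2`, then `n_genes<TAB>n_samples`) followed by `Name` and
#' `Description` columns.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"gct"`.
#' @param scale declared value scale of the file (see [expr_matrix]);
#'   defaults to `"log10_intensity"`.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, format = c("tsv", "gct"),
                            scale = "log10_intensity") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3 || !startsWith(trimws(lines[1L]), "#1.2"))
      stop("malformed GCT preamble in ", path,
           ": expected version line '#1.2'", call. = FALSE)
    dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
    dims <- suppressWarnings(as.integer(dims[nzchar(dims)]))
    if (length(dims) < 2 || anyNA(dims))
      stop("malformed GCT dimensions line in ", path, call. = FALSE)
    body <- lines[-(1:2)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    header <- fields[[1L]]
    if (length(header) < 3 || header[1L] != "Name")
      stop("malformed GCT header in ", path,
           ": expected 'Name' and 'Description' columns", call. = FALSE)
    samples <- header[-(1:2)]
    rows <- fields[-1L]
    if (length(rows) != dims[1L] || length(samples) != dims[2L])
      stop(sprintf(
        "GCT dimension mismatch in %s: preamble declares %d x %d, body has %d x %d",
        path, dims[1L], dims[2L], length(rows), length(samples)),
        call. = FALSE)
    ids <- vapply(rows, `[`, character(1L), 1L)
    cells <- lapply(rows, function(f) {
      if (length(f) != length(header))
        stop("ragged GCT row in ", path, call. = FALSE)
      f[-(1:2)]
    })
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    if (length(header) < 2)
      stop("malformed header in ", path,
           ": expected gene id column plus at least one sample", call. = FALSE)
    samples <- header[-1L]
    rows <- fields[-1L]
    ids <- vapply(rows, `[`, character(1L), 1L)
    cells <- lapply(rows, function(f) {
      if (length(f) != length(header))
        stop("ragged row in ", path, call. = FALSE)
      f[-1L]
    })
  }
  if (anyDuplicated(samples))
    stop("duplicate sample names in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  vals <- matrix(.parse_numeric_cells(unlist(cells), path),
                 nrow = length(ids), byrow = TRUE,
                 dimnames = list(ids, samples))
  expr_matrix(vals, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Values are written at full double precision so that
#' [read_expression()] round-trips them exactly.
#'
#' @param m an [expr_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV with header `probe_id`, `gene_symbol`; many probes may
#' map to one gene, but each probe must map to exactly one gene.
#'
#' @param path path to the mapping file.
#' @return A data frame with columns `probe_id` and `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(pm)))
    stop("probe map must have columns 'probe_id' and 'gene_symbol'",
         call. = FALSE)
  pm <- pm[, c("probe_id", "gene_symbol")]
  dup <- unique(pm$probe_id[duplicated(pm$probe_id)])
  if (length(dup))
    stop("probes mapped to more than one gene: ",
         paste(dup, collapse = ", "), call. = FALSE)
  pm
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes mapping to the same gene symbol are averaged (unweighted
#' arithmetic mean on the matrix's current scale) over their non-missing
#' values; a gene cell is missing only when every contributing probe is
#' missing. Probes absent from the map are dropped.
#'
#' @param m an [expr_matrix] whose rows are probe identifiers.
#' @param probe_map data frame as returned by [read_probe_map()].
#' @return An [expr_matrix] with one row per gene symbol.
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(inherits(m, "expr_matrix"))
  idx <- match(rownames(m$values), probe_map$probe_id)
  keep <- !is.na(idx)
  if (!any(keep))
    stop("no probe of the matrix is present in the probe map", call. = FALSE)
  v <- m$values[keep, , drop = FALSE]
  gene <- probe_map$gene_symbol[idx[keep]]
  present <- !is.na(v)
  sums <- rowsum(ifelse(present, v, 0), gene)
  counts <- rowsum(present + 0, gene)
  out <- sums / counts          # 0/0 -> NaN where all probes missing
  out[counts == 0] <- NA_real_
  expr_matrix(out, scale = m$scale)
}

#' Center each gene to its mean: log10 ratio representation
#'
#' Converts a matrix of log10 intensities into log10 ratios to the
#' per-gene mean by subtracting each gene's arithmetic mean over its
#' non-missing samples. Raw intensities are log10-transformed first.
#' This is the representation the composite signature score is defined
#' on, and it is what makes a score of zero the population mean.
#'
#' @param m an [expr_matrix]. `raw_intensity` input is log10-transformed;
#'   `log10_ratio` input is re-centered (a numerical no-op).
#' @return An [expr_matrix] with `scale = "log10_ratio"` and row means
#'   zero to numerical tolerance.
#' @export
mean_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (ncol(v) < 2)
    stop("mean normalization needs at least 2 samples; ",
         "the ratio to the mean is degenerate for a single sample",
         call. = FALSE)
  if (m$scale == "raw_intensity") v <- log10(v)
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing))
    stop("gene(s) with no non-missing values: ",
         paste(rownames(v)[all_missing], collapse = ", "), call. = FALSE)
  centered <- v - rowMeans(v, na.rm = TRUE)
  expr_matrix(centered, scale = "log10_ratio")
}

#' Report signature genes absent from a matrix
#'
#' Gene matching throughout the package is case-sensitive exact string
#' matching; this helper lists the signature genes a platform lacks.
#'
#' @param m an [expr_matrix].
#' @param signature a [two_arm_signature].
#' @return Character vector of absent gene symbols (possibly empty).
#' @export
missing_signature_genes <- function(m, signature) {
  stopifnot(inherits(signature, "two_arm_signature"))
  setdiff(c(signature$up_genes, signature$down_genes), gene_ids(m))
}

#' Read gene sets from a GMT file
#'
#' @param path path to a GMT file (one set per line: name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
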