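#' Dose-response viability panel
#'
#' Cell lines by concentrations matrix of viability fractions relative
#' to vehicle control. The read-out concentration used as the
#' sensitivity metric is selected with [max_variance_concentration()].
#'
#' @param viability numeric matrix, one row per cell line (row names are
#'   line ids), one column per concentration; values are nonnegative
#'   viability fractions.
#' @param concentrations strictly increasing positive concentrations
#'   (molar), one per column.
#' @return An object of class `dose_response_panel`: list with
#'   `viability`, `concentrations`, `selected_index` (`NA` until a
#'   read-out dose is selected).
#' @export
dose_response_panel <- function(viability, concentrations) {
  if (!is.matrix(viability) || !is.numeric(viability))
    stop("`viability` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(viability)))
    rownames(viability) <- paste0("line", seq_len(nrow(viability)))
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != ncol(viability))
    stop("one concentration per viability column is required",
         call. = FALSE)
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0))
    stop("concentrations must be positive and strictly increasing",
         call. = FALSE)
  if (any(viability < 0, na.rm = TRUE))
    stop("viability fractions must be nonnegative", call. = FALSE)
  structure(list(viability = viability,
                 concentrations = concentrations,
                 selected_index = NA_integer_),
            class = "dose_response_panel")
}

#' @export
print.dose_response_panel <- function(x, ...) {
  cat(sprintf("dose_response_panel: %d lines x %d concentrations\n",
              nrow(x$viability), length(x$concentrations)))
  if (!is.na(x$selected_index))
    cat(sprintf("  read-out dose: %.3g M (column %d)\n",
                x$concentrations[x$selected_index], x$selected_index))
  invisible(x)
}

#' Select the read-out concentration by maximal across-line variance
#'
#' The read-out dose is the tested concentration at which the cell
#' lines' viabilities vary most (sample variance, n-1 denominator):
#' the dose with maximal power to discriminate between the lines'
#' responses. Ties resolve to the lowest concentration. Columns with
#' any missing viability are excluded from the argmax with a warning.
#'
#' @param panel a [dose_response_panel].
#' @return The panel with `selected_index` set; the chosen column index
#'   is `panel$selected_index`.
#' @export
max_variance_concentration <- function(panel) {
  stopifnot(inherits(panel, "dose_response_panel"))
  if (nrow(panel$viability) < 2)
    stop("variance across lines needs at least 2 lines", call. = FALSE)
  v <- apply(panel$viability, 2L, stats::var)
  has_na <- colSums(is.na(panel$viability)) > 0
  if (any(has_na)) {
    warning("excluding concentration column(s) with missing viability: ",
            paste(which(has_na), collapse = ", "), call. = FALSE)
    v[has_na] <- NA_real_
  }
  if (all(is.na(v)))
    stop("every concentration column has missing viability",
         call. = FALSE)
  panel$selected_index <- unname(which.max(v))  # first max = lowest dose
  panel
}

#' Per-line sensitivity at the selected read-out dose
#'
#' @param panel a [dose_response_panel] whose `selected_index` has been
#'   set by [max_variance_concentration()].
#' @return Named numeric vector of viabilities at the read-out dose;
#'   lower values mean greater sensitivity.
#' @export
sensitivity_vector <- function(panel) {
  stopifnot(inherits(panel, "dose_response_panel"))
  if (is.na(panel$selected_index))
    stop("no read-out concentration selected; ",
         "run max_variance_concentration() first", call. = FALSE)
  panel$viability[, panel$selected_index]
}

#' Correlation of signature score with drug sensitivity
#'
#' Pearson correlation between per-line signature scores and the
#' sensitivity read-out, with the usual two-sided p-value from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))`. Lines are matched by
#' name; unnamed inputs are matched by position.
#'
#' @param scores a `signature_scores` object or named numeric vector.
#' @param sensitivity named numeric vector from [sensitivity_vector()].
#' @return An object of class `association_result`: list with
#'   `pearson_r`, `p_value`, `n`.
#' @export
score_sensitivity_association <- function(scores, sensitivity) {
  s <- if (inherits(scores, "signature_scores")) {
    stats::setNames(scores$score, scores$sample_id)
  } else scores
  if (!is.null(names(s)) && !is.null(names(sensitivity))) {
    shared <- intersect(names(s), names(sensitivity))
    s <- s[shared]; sensitivity <- sensitivity[shared]
  }
  ok <- !is.na(s) & !is.na(sensitivity)
  s <- s[ok]; sensitivity <- sensitivity[ok]
  if (length(s) < 3)
    stop("at least 3 lines with both score and sensitivity are needed",
         call. = FALSE)
  if (stats::sd(s) == 0 || stats::sd(sensitivity) == 0)
    stop("zero variance in scores or sensitivities; ",
         "correlation is undefined", call. = FALSE)
  ct <- stats::cor.test(s, sensitivity, method = "pearson")
  structure(list(pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(s)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: R = %.3f, p = %.3g (n = %d)\n",
              x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Clinical response versus signature-score sign
#'
#' Cross-tabulates response labels (disease control versus progressive
#' disease) against whether the signature score falls below the
#' activation threshold, and tests the table with the shared Fisher
#' exact test (two-sided by default).
#'
#' @param scores a `signature_scores` object or named numeric vector.
#' @param labels character/factor per sample with values
#'   `"disease_control"` or `"progressive_disease"`; both must occur.
#' @param threshold score threshold (default 0).
#' @param sided `"two"` (default) or `"greater"`.
#' @return An object of class `response_table`: list with `table`
#'   (2x2 counts) and `p_value`.
#' @export
disease_control_association <- function(scores, labels, threshold = 0,
                                        sided = c("two", "greater")) {
  sided <- match.arg(sided)
  s <- if (inherits(scores, "signature_scores")) {
    stats::setNames(scores$score, scores$sample_id)
  } else scores
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("disease_control",
                                   "progressive_disease"))
  if (length(bad))
    stop("invalid response label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(names(s)) && !is.null(names(labels)))
    labels <- labels[names(s)]
  if (length(labels) != length(s))
    stop("one label per scored sample is required", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both response groups must be represented", call. = FALSE)
  below <- s < threshold
  tab <- matrix(c(sum(labels == "disease_control" & below),
                  sum(labels == "progressive_disease" & below),
                  sum(labels == "disease_control" & !below),
                  sum(labels == "progressive_disease" & !below)),
                nrow = 2L,
                dimnames = list(
                  response = c("disease_control", "progressive_disease"),
                  score = c("below_threshold", "at_or_above")))
  structure(list(table = tab,
                 p_value = fisher_exact_2x2(tab, sided = sided)),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat("response_table (Fisher exact)\n")
  print(x$table)
  cat(sprintf("p-value: %.3g\n", x$p_value))
  invisible(x)
}

#' Read / write a dose-response panel TSV
#'
#' First column `line_id`, one column per concentration with the molar
#' value as header.
#'
#' @param path path to the panel file.
#' @return A [dose_response_panel].
#' @export
read_panel <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1L] != "line_id")
    stop("panel file must start with a 'line_id' column", call. = FALSE)
  conc <- suppressWarnings(as.numeric(names(tab)[-1L]))
  if (anyNA(conc))
    stop("panel column headers after 'line_id' must be molar ",
         "concentrations", call. = FALSE)
  vals <- matrix(.parse_numeric_cells(unlist(tab[-1L]), path),
                 nrow = nrow(tab),
                 dimnames = list(tab$line_id, names(tab)[-1L]))
  dose_response_panel(vals, conc)
}
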