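#' Configuration of the planted-signature data generator
#'
#' The generator emulates the data-generating structure the signature
#' methodology assumes: a latent per-sample pathway-activation factor
#' drives an up-arm gene block positively and a down-arm block
#' negatively, embedded in a larger uncorrelated background "superset",
#' independently in each of several datasets. Under this factor model
#' the within-arm pairwise Pearson correlation converges to
#' `b^2 / (b^2 + noise_sd^2)` and the up-versus-down correlation to its
#' negative.
#'
#' Defaults mirror the published signature's geometry: 105 up and 42
#' down planted genes, 300 background genes, 50 samples per dataset
#' (typical cohort size in this setting), 4 datasets, loading `b = 1`
#' and noise standard deviation 0.5 (planted pairwise correlation 0.8).
#'
#' @param n_samples samples per dataset.
#' @param n_background_genes uncorrelated background genes.
#' @param up_module_size,down_module_size planted arm sizes.
#' @param module_strength loading `b >= 0` of the latent factor.
#' @param noise_sd standard deviation of the Gaussian noise on the
#'   log10 scale (> 0).
#' @param n_datasets number of independently generated datasets.
#' @param seed master seed; all randomness is derived from it through
#'   named substreams, so enlarging one gene block never perturbs the
#'   draws of another.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 50L,
                             n_background_genes = 300L,
                             up_module_size = 105L,
                             down_module_size = 42L,
                             module_strength = 1,
                             noise_sd = 0.5,
                             n_datasets = 4L,
                             seed = 1L) {
  stopifnot(n_samples >= 2, n_background_genes >= 0,
            up_module_size >= 0, down_module_size >= 0,
            module_strength >= 0, noise_sd > 0, n_datasets >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_background_genes = as.integer(n_background_genes),
                 up_module_size = as.integer(up_module_size),
                 down_module_size = as.integer(down_module_size),
                 module_strength = module_strength,
                 noise_sd = noise_sd,
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic substream seed: hash of the master seed and a key path,
# kept within the 32-bit signed range R's set.seed accepts
.substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

.substream_rnorm <- function(n, seed, ...) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.substream_seed(seed, ...))
  stats::rnorm(n)
}

.substream_runif <- function(n, seed, ...) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.substream_seed(seed, ...))
  stats::runif(n)
}

#' Generate datasets with a planted two-arm signature
#'
#' For each dataset, every sample draws a latent activation
#' `a ~ N(0, 1)`; an up-arm gene takes value `b * a + e`, a down-arm
#' gene `-b * a + e`, and a background gene `e`, with
#' `e ~ N(0, noise_sd)` independent per gene and sample, all on the
#' log10 scale. Rows are then centered exactly, so the matrices carry
#' `scale = "log10_ratio"`. Gene labels are shared across datasets;
#' each dataset has its own latent factor, mirroring cohorts that are
#' normalized internally.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_truth`: list with `signature`
#'   (the planted [two_arm_signature]), `activation` (list of per-sample
#'   latent values, one vector per dataset), and `matrices` (named list
#'   of [expr_matrix] objects).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  up <- if (config$up_module_size > 0)
    sprintf("UPG%03d", seq_len(config$up_module_size)) else character()
  down <- if (config$down_module_size > 0)
    sprintf("DNG%03d", seq_len(config$down_module_size)) else character()
  bg <- if (config$n_background_genes > 0)
    sprintf("BGG%03d", seq_len(config$n_background_genes)) else character()
  genes <- c(up, down, bg)
  loading <- c(rep(config$module_strength, length(up)),
               rep(-config$module_strength, length(down)),
               rep(0, length(bg)))
  matrices <- list()
  activation <- list()
  for (d in seq_len(config$n_datasets)) {
    dname <- paste0("dataset", d)
    samples <- sprintf("d%d_s%03d", d, seq_len(config$n_samples))
    a <- .substream_rnorm(config$n_samples, config$seed,
                          "activation", dname)
    v <- matrix(NA_real_, length(genes), config$n_samples,
                dimnames = list(genes, samples))
    for (g in seq_along(genes)) {
      eps <- config$noise_sd *
        .substream_rnorm(config$n_samples, config$seed,
                         "noise", dname, genes[g])
      v[g, ] <- loading[g] * a + eps
    }
    v <- v - rowMeans(v)
    matrices[[dname]] <- expr_matrix(v, scale = "log10_ratio")
    activation[[dname]] <- stats::setNames(a, samples)
  }
  signature <- if (length(up))
    two_arm_signature("planted", up, down) else NULL
  structure(list(signature = signature, activation = activation,
                 matrices = matrices, config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "synthetic_truth: %d dataset(s), %d samples each, %d genes (%d up / %d down planted)\n",
    cfg$n_datasets, cfg$n_samples,
    cfg$up_module_size + cfg$down_module_size + cfg$n_background_genes,
    cfg$up_module_size, cfg$down_module_size))
  invisible(x)
}

#' Generate a scored cohort with response labels
#'
#' Generates a single dataset and draws a binary clinical response per
#' sample with log-odds of progressive disease equal to
#' `effect * activation`: at `effect = 0` labels are independent of the
#' pathway (null calibration); large `effect` separates the groups by
#' score sign.
#'
#' @param config a [synthetic_config()] (its `n_datasets` is forced
#'   to 1).
#' @param effect nonnegative label-association strength.
#' @return List with `matrix` (an [expr_matrix]), `labels` (named
#'   character, `"disease_control"` / `"progressive_disease"`),
#'   `activation`, and `signature`.
#' @export
generate_scored_cohort <- function(config = synthetic_config(),
                                   effect = 0) {
  stopifnot(effect >= 0)
  config$n_datasets <- 1L
  truth <- generate_dataset(config)
  a <- truth$activation[[1L]]
  p_prog <- stats::plogis(effect * a)
  u <- .substream_runif(length(a), config$seed, "labels")
  labels <- ifelse(u < p_prog, "progressive_disease", "disease_control")
  list(matrix = truth$matrices[[1L]],
       labels = stats::setNames(labels, names(a)),
       activation = a,
       signature = truth$signature)
}

#' Generate a synthetic dose-response panel
#'
#' Per-line viabilities follow a four-parameter logistic curve in
#' concentration whose log10 EC50 is
#' `center - score_link * activation + noise`: higher pathway activation
#' means a lower EC50, i.e. greater sensitivity. With heterogeneous
#' EC50s the across-line viability variance peaks at mid-range doses.
#'
#' @param n_lines number of cell lines (>= 2).
#' @param concentrations strictly increasing positive molar doses
#'   (default: 8 half-log steps from 3e-9 to 1e-5, a typical screening
#'   range).
#' @param score_link strength of the activation-to-logEC50 link.
#' @param ec50_noise_sd standard deviation of the residual log10-EC50
#'   spread.
#' @param seed master seed.
#' @param activation optional per-line latent activation; drawn
#'   `N(0, 1)` when `NULL`.
#' @return A [dose_response_panel] with the generating `activation` and
#'   log10 EC50s attached as attributes.
#' @export
generate_dose_response <- function(n_lines,
                                   concentrations = 10^seq(-8.5, -5,
                                                           length.out = 8),
                                   score_link = 1,
                                   ec50_noise_sd = 0.25,
                                   seed = 1L,
                                   activation = NULL) {
  stopifnot(n_lines >= 2)
  if (is.null(activation))
    activation <- .substream_rnorm(n_lines, seed, "panel_activation")
  center <- mean(log10(concentrations))
  log_ec50 <- center - score_link * activation +
    ec50_noise_sd * .substream_rnorm(n_lines, seed, "panel_ec50")
  hill <- 1.5; top <- 1; bottom <- 0.05
  viab <- t(vapply(log_ec50, function(le)
    bottom + (top - bottom) / (1 + (concentrations / 10^le)^hill),
    numeric(length(concentrations))))
  rownames(viab) <- sprintf("line%03d", seq_len(n_lines))
  colnames(viab) <- format(concentrations, digits = 3)
  panel <- dose_response_panel(viab, concentrations)
  attr(panel, "activation") <- stats::setNames(activation,
                                               rownames(viab))
  attr(panel, "log_ec50") <- stats::setNames(log_ec50, rownames(viab))
  panel
}
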