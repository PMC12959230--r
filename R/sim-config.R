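#' Configuration for the synthetic sepal study generator
#'
#' Bundles every tunable of the synthetic-data module with defaults matching
#' the study design the package emulates: 11 wild-type control batches,
#' 16 cell-wall knockout mutants with 39 to 90 sepals each, and a wild-type
#' expression matrix of 27 individual sepals.
#'
#' @param n_control_batches number of wild-type control batches.
#' @param n_mutants number of knockout mutant genotypes. With the default 16,
#'   genotypes carry the cell-wall mutant names (`bglu42`, `csi1`, ...,
#'   `pmr6`, ...) so that exclusion experiments read naturally; other counts
#'   use generic `mut01`, `mut02`, ... labels.
#' @param sepals_per_genotype_range inclusive integer range from which each
#'   genotype's sample size is drawn uniformly.
#' @param control_mean_area mean wild-type sepal area, mm^2.
#' @param control_cv2 baseline squared coefficient of variation of sepal area
#'   in wild type (dimensionless).
#' @param effect_scale standard deviation of the lognormal multiplicative
#'   shift applied to each mutant's mean length and width; 0 disables mean
#'   effects.
#' @param planted_slope slope of the planted linear relation between a
#'   mutant's true area CV2 and the log10 mean wild-type expression of its
#'   gene; 0 disables the relation.
#' @param noise_sd standard deviation (log scale) of genotype-level lognormal
#'   scatter around the planted CV2 relation; 0 makes the relation exact.
#' @param n_expr_sepals number of individual wild-type sepals in the
#'   expression matrix.
#' @param n_expr_genes total genes in the expression matrix (the first
#'   `n_mutants` are the mapped mutant genes; the rest form the background
#'   cloud).
#' @param seed integer seed; fully determines every generated object.
#' @return an object of class `"sim_config"` (a validated list).
#' @seealso [simulate_study()], [simulate_measurements()],
#'   [simulate_expression()]
#' @export
sim_config <- function(n_control_batches = 11L,
                       n_mutants = 16L,
                       sepals_per_genotype_range = c(39L, 90L),
                       control_mean_area = 2.3,
                       control_cv2 = 0.01,
                       effect_scale = 0.05,
                       planted_slope = 0.012,
                       noise_sd = 0.15,
                       n_expr_sepals = 27L,
                       n_expr_genes = 200L,
                       seed = 1L) {
  cfg <- list(
    n_control_batches = as.integer(n_control_batches),
    n_mutants = as.integer(n_mutants),
    sepals_per_genotype_range = as.integer(sepals_per_genotype_range),
    control_mean_area = control_mean_area,
    control_cv2 = control_cv2,
    effect_scale = effect_scale,
    planted_slope = planted_slope,
    noise_sd = noise_sd,
    n_expr_sepals = as.integer(n_expr_sepals),
    n_expr_genes = as.integer(n_expr_genes),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  r <- cfg$sepals_per_genotype_range
  if (length(r) != 2L || anyNA(r)) {
    stop_invalid("'sepals_per_genotype_range' must be two integers")
  }
  if (r[1] > r[2]) {
    stop_invalid("'sepals_per_genotype_range' lower bound exceeds upper bound")
  }
  if (r[1] < 2L) {
    stop_invalid("'sepals_per_genotype_range' lower bound must be >= 2")
  }
  if (cfg$n_control_batches < 1L) stop_invalid("'n_control_batches' must be >= 1")
  if (cfg$n_mutants < 1L) stop_invalid("'n_mutants' must be >= 1")
  if (cfg$n_expr_sepals < 2L) stop_invalid("'n_expr_sepals' must be >= 2")
  if (cfg$n_expr_genes < 1L) stop_invalid("'n_expr_genes' must be >= 1")
  if (cfg$n_expr_genes < cfg$n_mutants) {
    stop_invalid("'n_expr_genes' must be at least 'n_mutants' (mapped genes)")
  }
  if (cfg$control_mean_area <= 0) stop_invalid("'control_mean_area' must be positive")
  if (cfg$control_cv2 <= 0) stop_invalid("'control_cv2' must be positive")
  if (cfg$effect_scale < 0) stop_invalid("'effect_scale' must be non-negative")
  if (cfg$noise_sd < 0) stop_invalid("'noise_sd' must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic sepal study configuration\n")
  cat(sprintf("  control batches: %d   mutants: %d   sepals/genotype: %d-%d\n",
              x$n_control_batches, x$n_mutants,
              x$sepals_per_genotype_range[1], x$sepals_per_genotype_range[2]))
  cat(sprintf("  control area: %.3g mm^2 (CV2 %.3g)   effect scale: %.3g\n",
              x$control_mean_area, x$control_cv2, x$effect_scale))
  cat(sprintf("  planted CV2 slope: %.3g per decade   genotype noise sd: %.3g\n",
              x$planted_slope, x$noise_sd))
  cat(sprintf("  expression: %d genes x %d sepals   seed: %d\n",
              x$n_expr_genes, x$n_expr_sepals, x$seed))
  invisible(x)
}

## Cell-wall mutant genotypes and their gene identifiers; used verbatim when
## n_mutants == 16 so the pmr6-exclusion experiments read naturally.
CELL_WALL_GENOTYPES <- c(
  "bglu42", "csi1", "cc1", "cesa6", "csld5", "cslg3", "expa15", "pme32",
  "pmei3", "pmr6", "mur4", "cslc8", "xth15", "xth6", "xth9", "galt29a"
)
CELL_WALL_GENE_IDS <- c(
  "AT5G36890", "AT2G22125", "AT1G45688", "AT5G64740", "AT1G02730",
  "AT4G23990", "AT2G03090", "AT3G43270", "AT5G20740", "AT3G54920",
  "AT1G30620", "AT2G24630", "AT4G14130", "AT5G65730", "AT4G03210",
  "AT1G08280"
)

#' @noRd
mutant_labels <- function(n) {
  if (n == 16L) CELL_WALL_GENOTYPES else sprintf("mut%02d", seq_len(n))
}

#' @noRd
mutant_gene_ids <- function(n) {
  if (n == 16L) CELL_WALL_GENE_IDS else sprintf("gene%04d", seq_len(n))
}
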