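## Per-genotype and per-gene statistics and the correlation screens.

PARAMETERS <- c("area", "length", "width", "aspect_ratio")
CONTROL_GENOTYPE <- "col0"

#' Mean, standard deviation and squared coefficient of variation
#'
#' The dispersion statistic used throughout the package is
#' `CV2 = (sd/mean)^2` with the sample (n - 1) standard deviation. CV2 is
#' dimensionless and invariant under positive rescaling of the measurement
#' units.
#'
#' @param values numeric vector of at least 2 positive values.
#' @return list with `n`, `mean`, `sd`, `cv2`.
#' @examples
#' cv2_stats(c(1, 2, 3))  # cv2 = 0.25
#' @export
cv2_stats <- function(values) {
  if (length(values) < 2L) stop_invalid("need at least 2 values")
  if (anyNA(values) || !is.numeric(values)) {
    stop_invalid("'values' must be numeric without missing entries")
  }
  if (any(values <= 0)) stop_invalid("'values' must be strictly positive")
  m <- mean(values)
  s <- stats::sd(values)
  list(n = length(values), mean = m, sd = s, cv2 = (s / m)^2)
}

#' Batch-corrected relative effect of a mutant on a parameter mean
#'
#' `rel_effect = (mean_mutant - mean_control) / mean_control`, the mutant's
#' mean shift relative to its own control batch; `abs_rel_effect` is its
#' magnitude, the quantity used in the correlation screens.
#'
#' @param mutant_mean mutant parameter mean.
#' @param control_mean control-batch parameter mean (> 0).
#' @return list with `rel_effect` and `abs_rel_effect`.
#' @export
relative_effect <- function(mutant_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop_invalid("'control_mean' must be positive")
  }
  rel <- (mutant_mean - control_mean) / control_mean
  list(rel_effect = rel, abs_rel_effect = abs(rel))
}

#' Per-gene expression summary across individual sepals
#'
#' Computes mean, sample sd, CV2 and log10 mean expression for every gene of
#' an expression matrix. Genes with zero mean are flagged
#' (`zero_mean = TRUE`, `log10_mean_expr = NA`) so log-scale screens can
#' exclude them explicitly.
#'
#' @param expr genes x samples numeric matrix (rownames = gene ids), or a
#'   list carrying an `expr` element (e.g. [simulate_expression()] output).
#' @return data frame with one row per gene: `gene_id`, `n`, `mean_expr`,
#'   `sd_expr`, `cv2_expr`, `log10_mean_expr`, `zero_mean`.
#' @export
expression_summary <- function(expr) {
  if (is.list(expr) && !is.data.frame(expr) && !is.null(expr$expr)) {
    expr <- expr$expr
  }
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop_invalid("need at least 2 samples per gene")
  if (any(expr < 0)) stop_invalid("expression values must be non-negative")
  m <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  zero <- m <= 0
  data.frame(
    gene_id = if (is.null(rownames(expr))) sprintf("g%04d", seq_len(nrow(expr)))
              else rownames(expr),
    n = ncol(expr),
    mean_expr = m,
    sd_expr = s,
    cv2_expr = ifelse(zero, NA_real_, (s / m)^2),
    log10_mean_expr = ifelse(zero, NA_real_, log10(m)),
    zero_mean = zero,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Two-sided Pearson correlation test
#'
#' Sample Pearson coefficient with the two-sided p-value from the exact
#' t-transform `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @param response,covariate labels stored in the result row.
#' @param excluded character vector of excluded unit labels, recorded
#'   (comma-separated) in the result.
#' @return one-row data frame: `response`, `covariate`, `n`, `r`, `p`,
#'   `excluded`.
#' @export
pearson_test <- function(x, y, response = "y", covariate = "x",
                         excluded = character(0)) {
  if (length(x) != length(y)) stop_invalid("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop_invalid("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values in correlation input")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_invalid("undefined correlation: an input has zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(response = response, covariate = covariate,
             n = length(x), r = unname(ct$estimate), p = ct$p.value,
             excluded = paste(excluded, collapse = ","),
             stringsAsFactors = FALSE)
}

#' @noRd
validate_measurements <- function(measurements) {
  need <- c("genotype", "batch", "sepal_id", "length", "width", "area",
            "aspect_ratio")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop_invalid("measurement table lacks required column(s): ",
                 paste(miss, collapse = ", "))
  }
  invisible(measurements)
}

#' Build the per-mutant screen table
#'
#' Joins, for every mutant genotype and shape parameter, the phenotype
#' statistics (n, mean, CV2, batch-corrected relative effect) with the
#' wild-type expression statistics of the mapped gene (mean, CV2, log10
#' mean). Mutants without a mapped gene, with a gene absent from the matrix,
#' or with zero mean expression are excluded with a warning and listed in
#' the `"rejects"` attribute.
#'
#' @param measurements measurement table (see [simulate_measurements()] for
#'   the schema); control rows carry genotype `col0`.
#' @param expr expression matrix (genes x samples) or
#'   [simulate_expression()] / [simulate_study()] output.
#' @param gene_map data frame `gene_id`, `genotype` mapping genes to
#'   mutants; taken from `expr` if absent.
#' @return data frame, one row per mutant x parameter, with attribute
#'   `"rejects"`.
#' @export
build_screen_table <- function(measurements, expr, gene_map = NULL) {
  validate_measurements(measurements)
  if (is.list(expr) && !is.data.frame(expr) && !is.null(expr$gene_map) &&
      is.null(gene_map)) {
    gene_map <- expr$gene_map
  }
  if (is.null(gene_map)) stop_invalid("a gene map (gene_id, genotype) is required")
  es <- expression_summary(expr)
  measurements$genotype <- norm_label(measurements$genotype)
  measurements$batch <- norm_label(measurements$batch)
  gene_map$genotype <- norm_label(gene_map$genotype)

  mutants <- setdiff(unique(measurements$genotype), CONTROL_GENOTYPE)
  rejects <- data.frame(genotype = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (g in mutants) {
    sub <- measurements[measurements$genotype == g, ]
    batch <- unique(sub$batch)
    if (length(batch) != 1L) {
      stop_invalid("mutant '", g, "' maps to ", length(batch),
                   " control batches; expected exactly one")
    }
    gi <- gene_map$gene_id[match(g, gene_map$genotype)]
    if (is.na(gi)) {
      rejects <- rbind(rejects, data.frame(genotype = g,
                                           reason = "no mapped gene"))
      next
    }
    ei <- match(gi, es$gene_id)
    if (is.na(ei)) {
      rejects <- rbind(rejects, data.frame(genotype = g,
                                           reason = "gene absent from matrix"))
      next
    }
    if (es$zero_mean[ei]) {
      rejects <- rbind(rejects, data.frame(genotype = g,
                                           reason = "zero mean expression"))
      next
    }
    ctrl <- measurements[measurements$genotype == CONTROL_GENOTYPE &
                           measurements$batch == batch, ]
    if (nrow(ctrl) < 2L) {
      stop_invalid("batch '", batch, "' has no control (", CONTROL_GENOTYPE,
                   ") measurements")
    }
    for (p in PARAMETERS) {
      st <- cv2_stats(sub[[p]])
      eff <- relative_effect(st$mean, mean(ctrl[[p]]))
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, gene_id = gi, batch = batch, parameter = p,
        n = st$n, mean = st$mean, sd = st$sd, cv2 = st$cv2,
        control_mean = mean(ctrl[[p]]),
        rel_effect = eff$rel_effect, abs_rel_effect = eff$abs_rel_effect,
        mean_expr = es$mean_expr[ei], cv2_expr = es$cv2_expr[ei],
        log10_mean_expr = es$log10_mean_expr[ei],
        stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(rejects)) {
    warning("excluded mutant(s): ",
            paste(sprintf("%s (%s)", rejects$genotype, rejects$reason),
                  collapse = "; "), call. = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop_invalid("no mutants left after applying the gene map")
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Run the full grid of correlation screens
#'
#' For each response (`abs_rel_effect`, `cv2`) of each shape parameter
#' against each expression covariate (`cv2_expr`, `log10_mean_expr`): a
#' two-sided Pearson test across mutants. Raw p-values are reported; a
#' multiple-testing correction hook is available but off by default.
#'
#' @param screen_table output of [build_screen_table()].
#' @param alpha significance threshold recorded alongside the results.
#' @param p_adjust method passed to [stats::p.adjust()] (default `"none"`).
#' @return data frame of correlation results, one row per screen.
#' @export
run_screens <- function(screen_table, alpha = 0.05, p_adjust = "none") {
  out <- list()
  for (resp in c("abs_rel_effect", "cv2")) {
    for (p in PARAMETERS) {
      sub <- screen_table[screen_table$parameter == p, ]
      for (cov in c("cv2_expr", "log10_mean_expr")) {
        ok <- !is.na(sub[[cov]])
        res <- pearson_test(sub[[cov]][ok], sub[[resp]][ok],
                            response = resp, covariate = cov,
                            excluded = sub$genotype[!ok])
        res$parameter <- p
        out[[length(out) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, out)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p < alpha
  out[, c("response", "parameter", "covariate", "n", "r", "p", "p_adj",
          "significant", "excluded")]
}

#' Wild-type reference band of CV2 per parameter
#'
#' Mean and sample sd of the per-batch control CV2 values, the dashed
#' reference band drawn behind mutant CV2 values.
#'
#' @param measurements measurement table; only control (`col0`) rows are
#'   used. At least 2 control batches are required.
#' @return data frame: `parameter`, `n_batches`, `mean_cv2`, `sd_cv2`.
#' @export
reference_band <- function(measurements) {
  validate_measurements(measurements)
  ctrl <- measurements[norm_label(measurements$genotype) == CONTROL_GENOTYPE, ]
  batches <- unique(norm_label(ctrl$batch))
  if (length(batches) < 2L) {
    stop_invalid("need at least 2 control batches for a reference band")
  }
  do.call(rbind, lapply(PARAMETERS, function(p) {
    cv2s <- vapply(batches, function(b) {
      cv2_stats(ctrl[[p]][norm_label(ctrl$batch) == b])$cv2
    }, numeric(1))
    data.frame(parameter = p, n_batches = length(batches),
               mean_cv2 = mean(cv2s), sd_cv2 = stats::sd(cv2s),
               stringsAsFactors = FALSE)
  }))
}

#' Screen for a sample-size confound
#'
#' Pearson test of each parameter's mutant CV2 against the mutant sample
#' size; a significant correlation would mean unequal sample sizes, not
#' biology, could drive the main screens.
#'
#' @param screen_table output of [build_screen_table()].
#' @return data frame of per-parameter correlation results.
#' @export
sample_size_confound <- function(screen_table) {
  out <- lapply(PARAMETERS, function(p) {
    sub <- screen_table[screen_table$parameter == p, ]
    res <- pearson_test(sub$n, sub$cv2, response = "cv2", covariate = "n")
    res$parameter <- p
    res
  })
  out <- do.call(rbind, out)
  out[, c("parameter", "response", "covariate", "n", "r", "p")]
}
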