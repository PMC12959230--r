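## The fitted-screen object: one call joins measurements with expression
## statistics and runs every correlation screen.

#' Fit the sepal robustness screen
#'
#' The package's central analysis step. Per mutant genotype it computes, for
#' each of the four shape parameters, the sample CV2 and the batch-corrected
#' relative effect, joins the wild-type expression statistics of the mapped
#' gene, and runs the full grid of Pearson correlation screens plus the
#' wild-type reference band and the sample-size confound check.
#'
#' @param measurements per-sepal measurement table (genotype, batch,
#'   sepal_id, length, width, area, aspect_ratio); control rows carry
#'   genotype `col0`.
#' @param expr wild-type expression matrix (genes x sepals) or a
#'   [simulate_study()] object (in which case `measurements` and `gene_map`
#'   default from it).
#' @param gene_map data frame `gene_id`, `genotype`.
#' @param alpha significance threshold (default 0.05).
#' @return an object of class `"sepal_screen"` with components
#'   `screen_table`, `screens`, `band`, `confound`, `rejects`,
#'   `measurements`, `alpha`.
#' @examples
#' fit <- sepal_screen(simulate_study(sim_config(seed = 1)))
#' fit
#' @export
sepal_screen <- function(measurements, expr = NULL, gene_map = NULL,
                         alpha = 0.05) {
  if (inherits(measurements, "sepal_study")) {
    study <- measurements
    measurements <- study$measurements
    if (is.null(expr)) expr <- study$expr
    if (is.null(gene_map)) gene_map <- study$gene_map
  }
  validate_measurements(measurements)
  measurements$genotype <- norm_label(measurements$genotype)
  measurements$batch <- norm_label(measurements$batch)
  st <- build_screen_table(measurements, expr, gene_map)
  out <- list(
    screen_table = st,
    screens = run_screens(st, alpha = alpha),
    band = reference_band(measurements),
    ## undefined when every mutant has the same n; recorded as NULL then
    confound = tryCatch(sample_size_confound(st), error = function(e) NULL),
    rejects = attr(st, "rejects"),
    measurements = measurements,
    alpha = alpha,
    call = match.call()
  )
  class(out) <- "sepal_screen"
  out
}

#' @export
print.sepal_screen <- function(x, ...) {
  n_mut <- length(unique(x$screen_table$genotype))
  cat(sprintf("Sepal robustness screen: %d mutants, alpha = %g\n",
              n_mut, x$alpha))
  key <- x$screens[x$screens$response == "cv2" &
                     x$screens$covariate == "log10_mean_expr", ]
  cat("CV2 vs log10 mean wild-type expression:\n")
  for (i in seq_len(nrow(key))) {
    cat(sprintf("  %-12s R = %+.3f  p = %.4g%s\n", key$parameter[i],
                key$r[i], key$p[i], if (key$significant[i]) " *" else ""))
  }
  if (nrow(x$rejects)) {
    cat(sprintf("excluded mutants: %s\n",
                paste(x$rejects$genotype, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.sepal_screen <- function(object, ...) {
  structure(list(screens = object$screens, band = object$band,
                 confound = object$confound, alpha = object$alpha,
                 n_mutants = length(unique(object$screen_table$genotype))),
            class = "summary.sepal_screen")
}

#' @export
print.summary.sepal_screen <- function(x, ...) {
  cat(sprintf("Sepal robustness screen (%d mutants, alpha = %g)\n\n",
              x$n_mutants, x$alpha))
  cat("Correlation screens:\n")
  print(x$screens[, c("response", "parameter", "covariate", "n", "r", "p",
                      "significant")], row.names = FALSE, digits = 3)
  cat("\nWild-type reference band (CV2 across control batches):\n")
  print(x$band, row.names = FALSE, digits = 3)
  cat("\nSample-size confound (CV2 vs n):\n")
  if (is.null(x$confound)) {
    cat("  undefined (no variation in sample size)\n")
  } else {
    print(x$confound, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot the CV2-versus-expression screens
#'
#' One panel per shape parameter: mutant CV2 against the chosen expression
#' covariate, with the least-squares line and the wild-type reference band
#' (mean +/- 1 sd across control batches) as dashed/dotted horizontals.
#'
#' @param x a `"sepal_screen"`.
#' @param covariate `"log10_mean_expr"` (default) or `"cv2_expr"`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sepal_screen <- function(x, covariate = "log10_mean_expr", ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  xlab <- if (covariate == "log10_mean_expr") {
    "log10 mean WT expression"
  } else {
    "WT expression CV2"
  }
  for (p in PARAMETERS) {
    sub <- x$screen_table[x$screen_table$parameter == p, ]
    sc <- x$screens[x$screens$response == "cv2" &
                      x$screens$parameter == p &
                      x$screens$covariate == covariate, ]
    graphics::plot(sub[[covariate]], sub$cv2, pch = 19,
                   xlab = xlab, ylab = sprintf("%s CV2", p),
                   main = sprintf("%s: R = %.2f, p = %.3g", p, sc$r, sc$p),
                   ...)
    ok <- !is.na(sub[[covariate]])
    graphics::abline(stats::lm(sub$cv2[ok] ~ sub[[covariate]][ok]),
                     col = "grey40")
    b <- x$band[x$band$parameter == p, ]
    graphics::abline(h = b$mean_cv2, lty = 2, col = "grey60")
    graphics::abline(h = b$mean_cv2 + c(-1, 1) * b$sd_cv2, lty = 3,
                     col = "grey60")
  }
  invisible(x)
}
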