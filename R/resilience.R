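## Resilience experiments: subsampling replicates and exhaustive
## leave-x-out re-testing of a fitted screen.

#' @noRd
resilience_report <- function(kind, spec, results, alpha) {
  structure(list(kind = kind, spec = spec, results = results,
                 combination_count = nrow(results),
                 fraction_significant = mean(results$p < alpha),
                 alpha = alpha),
            class = "resilience_report")
}

#' @export
print.resilience_report <- function(x, ...) {
  cat(sprintf("Resilience report (%s): %d correlation tests\n", x$kind,
              x$combination_count))
  cat(sprintf("  response: %s CV2  ~  %s\n", x$spec$parameter,
              x$spec$covariate))
  cat(sprintf("  significant at alpha = %g: %.1f%%\n", x$alpha,
              100 * x$fraction_significant))
  cat(sprintf("  r range [%.3f, %.3f], median p = %.3g\n",
              min(x$results$r), max(x$results$r),
              stats::median(x$results$p)))
  invisible(x)
}

#' Subsampling replicates of a correlation screen
#'
#' Repeatedly draws a fixed-size random subsample of sepals (without
#' replacement) from every mutant, recomputes each mutant's CV2 for the
#' chosen parameter, and re-runs the Pearson test against the (fixed)
#' expression covariate. Reports every (r, p) pair and the fraction of
#' replicates significant at `alpha`.
#'
#' The RNG substream of each (mutant, replicate) pair is keyed by the
#' genotype label, so the report does not depend on the row order of the
#' measurement table.
#'
#' @param object a fitted [sepal_screen()].
#' @param parameter shape parameter whose CV2 is the response.
#' @param covariate expression covariate (`"log10_mean_expr"` default, or
#'   `"cv2_expr"`).
#' @param n_subsample sepals drawn per mutant per replicate (default 30).
#' @param n_replicates number of replicates (default 1000).
#' @param seed master seed.
#' @param alpha significance threshold.
#' @param undersized policy for mutants with fewer than `n_subsample`
#'   sepals: `"fail"` (default) or `"all"` (use every sepal, with warning).
#' @return a `"resilience_report"` whose `results` holds one row
#'   (replicate, r, p) per replicate.
#' @export
subsample_replicates <- function(object, parameter = "area",
                                 covariate = "log10_mean_expr",
                                 n_subsample = 30L, n_replicates = 1000L,
                                 seed = 1L, alpha = 0.05,
                                 undersized = c("fail", "all")) {
  stopifnot(inherits(object, "sepal_screen"))
  undersized <- match.arg(undersized)
  if (n_subsample < 3L) stop_invalid("'n_subsample' must be >= 3")
  if (n_replicates < 1L) stop_invalid("'n_replicates' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_invalid("'alpha' must be in (0, 1)")
  if (!parameter %in% PARAMETERS) {
    stop_invalid("unknown parameter '", parameter, "'")
  }

  st <- object$screen_table[object$screen_table$parameter == parameter, ]
  mutants <- st$genotype
  covv <- st[[covariate]]
  if (anyNA(covv)) {
    keep <- !is.na(covv)
    mutants <- mutants[keep]
    covv <- covv[keep]
  }
  ## sepals sorted by id so the draw is independent of table row order
  vals <- lapply(mutants, function(g) {
    sub <- object$measurements[object$measurements$genotype == g, ]
    sub[[parameter]][order(sub$sepal_id)]
  })
  names(vals) <- mutants
  short <- vapply(vals, length, integer(1)) < n_subsample
  if (any(short)) {
    if (undersized == "fail") {
      stop_invalid("mutant(s) with fewer than n_subsample sepals: ",
                   paste(mutants[short], collapse = ", "))
    }
    warning("using all sepals for undersized mutant(s): ",
            paste(mutants[short], collapse = ", "), call. = FALSE)
  }
  hashes <- vapply(mutants, label_hash, integer(1))

  res <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    cv2s <- vapply(seq_along(mutants), function(mi) {
      v <- vals[[mi]]
      k <- min(n_subsample, length(v))
      sub_seed <- ((hashes[mi] * 131071 + rep_i) %% 2147483647) * 1.0
      sub_seed <- (sub_seed * 69069 + seed) %% 2147483647
      idx <- with_seed(sub_seed, sample.int(length(v), k))
      cv2_stats(v[idx])$cv2
    }, numeric(1))
    ct <- pearson_test(covv, cv2s, response = parameter,
                       covariate = covariate)
    res[[rep_i]] <- data.frame(replicate = rep_i, n = ct$n, r = ct$r,
                               p = ct$p)
  }
  resilience_report(
    kind = "subsample",
    spec = list(parameter = parameter, covariate = covariate,
                n_subsample = n_subsample, n_replicates = n_replicates,
                seed = seed, undersized = undersized),
    results = do.call(rbind, res), alpha = alpha
  )
}

#' @noRd
ordered_tuples <- function(n, x) {
  if (x == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  grow <- function(prefix) {
    if (length(prefix) == x) return(list(prefix))
    rest <- setdiff(seq_len(n), prefix)
    do.call(c, lapply(rest, function(j) grow(c(prefix, j))))
  }
  do.call(rbind, grow(integer(0)))
}

#' Exhaustive leave-x-out re-testing of a screen
#'
#' Removes the fixed exclusions (e.g. `pmr6`), then enumerates every
#' selection of `x` distinct remaining mutants, drops each selection in
#' turn, and recomputes the Pearson test of the response against the
#' expression covariate on the mutants that remain.
#'
#' Two enumeration conventions are provided. The default, `ordered = TRUE`,
#' counts ordered selections without repetition — n!/(n-x)! tests, e.g.
#' 16, 240 and 3360 for x = 1, 2, 3 on 16 mutants (and 15, 210, 2730 after
#' removing one mutant first). `ordered = FALSE` counts unordered subsets,
#' choose(n, x) tests; the two conventions yield the same multiset of
#' (r, p) values up to x! repeats.
#'
#' @param object a fitted [sepal_screen()] or a screen table from
#'   [build_screen_table()].
#' @param x number of mutants left out per test.
#' @param exclude genotype labels removed from the data before enumeration.
#' @param parameter shape parameter whose statistics form the response.
#' @param response `"cv2"` (default) or `"abs_rel_effect"`.
#' @param covariate expression covariate.
#' @param ordered enumeration convention (see Details).
#' @param alpha significance threshold.
#' @return a `"resilience_report"` whose `results` holds one row
#'   (combination, n, r, p) per test.
#' @export
leave_x_out <- function(object, x, exclude = character(0),
                        parameter = "area", response = "cv2",
                        covariate = "log10_mean_expr", ordered = TRUE,
                        alpha = 0.05) {
  st <- if (inherits(object, "sepal_screen")) object$screen_table else object
  if (!is.data.frame(st)) stop_invalid("'object' must be a screen or screen table")
  x <- as.integer(x)
  if (x < 0L) stop_invalid("'x' must be >= 0")
  sub <- st[st$parameter == parameter, ]
  ok <- !is.na(sub[[covariate]])
  sub <- sub[ok, ]
  exclude <- norm_label(exclude)
  missing_ex <- setdiff(exclude, sub$genotype)
  if (length(missing_ex)) {
    warning("exclusion(s) not present: ", paste(missing_ex, collapse = ", "),
            call. = FALSE)
  }
  sub <- sub[!sub$genotype %in% exclude, ]
  n <- nrow(sub)
  if (n - x < 3L) {
    stop_invalid("infeasible: ", n, " mutants after exclusions leaves ",
                 n - x, " (< 3) per test with x = ", x)
  }
  sel <- if (ordered) ordered_tuples(n, x) else {
    if (x == 0L) matrix(integer(0), 1L, 0L) else t(utils::combn(n, x))
  }
  res <- lapply(seq_len(nrow(sel)), function(i) {
    drop <- sel[i, ]
    keep <- if (length(drop)) setdiff(seq_len(n), drop) else seq_len(n)
    ct <- pearson_test(sub[[covariate]][keep], sub[[response]][keep],
                       response = response, covariate = covariate)
    data.frame(
      combination = paste(sub$genotype[drop], collapse = "+"),
      n = ct$n, r = ct$r, p = ct$p, stringsAsFactors = FALSE
    )
  })
  resilience_report(
    kind = sprintf("leave-%d-out%s", x,
                   if (length(exclude)) paste0(" (excluding ",
                                               paste(exclude, collapse = ","),
                                               ")") else ""),
    spec = list(x = x, exclude = exclude, parameter = parameter,
                response = response, covariate = covariate,
                ordered = ordered),
    results = do.call(rbind, res), alpha = alpha
  )
}

#' Density summary of a resilience report's p-values
#'
#' Kernel density of log10(p) over all tests of a report, renormalized so
#' the area under the curve is exactly 1 (reports of different sizes can be
#' overlaid on equal footing). Degenerate reports in which every test gives
#' the same p-value are returned as a flagged point mass.
#'
#' @param report a `"resilience_report"`.
#' @param reference_p optional reference p-value (e.g. from the full-data
#'   screen) carried into the summary and the plot.
#' @param alpha significance threshold marker.
#' @return an object of class `"pvalue_density"`.
#' @export
pvalue_distribution <- function(report, reference_p = NULL, alpha = 0.05) {
  stopifnot(inherits(report, "resilience_report"))
  p <- report$results$p
  if (length(p) == 0) stop_invalid("empty resilience report")
  out <- list(kind = report$kind, n = length(p),
              fraction_below_alpha = mean(p < alpha),
              reference_p = reference_p, alpha = alpha)
  if (diff(range(p)) == 0) {
    out$point_mass <- TRUE
    out$location <- p[1]
  } else {
    d <- stats::density(log10(p))
    auc <- sum(diff(d$x) * (d$y[-1] + d$y[-length(d$y)]) / 2)
    out$point_mass <- FALSE
    out$x <- d$x
    out$y <- d$y / auc
  }
  class(out) <- "pvalue_density"
  out
}

#' @export
print.pvalue_density <- function(x, ...) {
  cat(sprintf("p-value distribution (%s): %d tests\n", x$kind, x$n))
  if (x$point_mass) {
    cat(sprintf("  point mass at p = %.4g (zero spread)\n", x$location))
  } else {
    cat(sprintf("  log10(p) support [%.2f, %.2f]\n", min(x$x), max(x$x)))
  }
  cat(sprintf("  fraction below alpha = %g: %.1f%%\n", x$alpha,
              100 * x$fraction_below_alpha))
  invisible(x)
}

#' @export
plot.pvalue_density <- function(x, ...) {
  if (x$point_mass) {
    graphics::plot(log10(x$location), 1, type = "h", xlab = "log10 p",
                   ylab = "density", main = x$kind, ...)
  } else {
    graphics::plot(x$x, x$y, type = "l", xlab = "log10 p", ylab = "density",
                   main = x$kind, ...)
  }
  graphics::abline(v = log10(x$alpha), lty = 3, col = "darkred")
  if (!is.null(x$reference_p)) {
    graphics::abline(v = log10(x$reference_p), lty = 3, col = "darkblue")
  }
  invisible(x)
}
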