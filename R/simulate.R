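## Synthetic study generator.
##
## All generated objects are driven by a single seed in the sim_config.
## Ground truth (per-gene expression moments, per-genotype measurement
## moments) is drawn in its own seed block so that the expression matrix and
## the measurement table can be generated independently yet consistently.

SHAPE_FACTOR <- 0.75  # area = SHAPE_FACTOR * length * width for an ovate blade

#' @noRd
study_truth <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    n_m <- cfg$n_mutants
    genos <- mutant_labels(n_m)
    gene_ids <- mutant_gene_ids(n_m)
    n_bg <- cfg$n_expr_genes - n_m

    ## --- gene truth ------------------------------------------------------
    ## Mapped mutant genes span three decades of mean expression; the
    ## background cloud spans four and carries a fraction of highly variable
    ## outliers, giving the classic decreasing mean-CV2 scatter.
    log10_mapped <- stats::runif(n_m, 1, 4)
    log10_bg <- if (n_bg > 0) stats::runif(n_bg, 0, 4) else numeric(0)
    log10_all <- c(log10_mapped, log10_bg)
    mean_expr <- 10^log10_all
    cv2_expr <- (0.02 + 3 / mean_expr) * exp(stats::rnorm(length(mean_expr), 0, 0.3))
    hv <- rep(FALSE, length(mean_expr))
    if (n_bg > 0) {
      hv_bg <- stats::runif(n_bg) < 0.05
      hv[n_m + which(hv_bg)] <- TRUE
      cv2_expr[hv] <- cv2_expr[hv] * 10
    }
    genes <- data.frame(
      gene_id = c(gene_ids, if (n_bg > 0) sprintf("bg%04d", seq_len(n_bg))),
      genotype = c(genos, rep(NA_character_, n_bg)),
      mean_expr = mean_expr,
      cv2_expr = cv2_expr,
      log10_mean_expr = log10_all,
      hv_outlier = hv,
      stringsAsFactors = FALSE
    )

    ## --- genotype truth --------------------------------------------------
    mW0 <- sqrt(cfg$control_mean_area / (2 * SHAPE_FACTOR))
    mL0 <- 2 * mW0
    split_cv2 <- function(c_area) sqrt(1 + c_area) - 1  # equal L/W split
    batch_sd <- 0.4 * cfg$effect_scale
    batches <- sprintf("batch%02d", seq_len(cfg$n_control_batches))
    bL <- mL0 * exp(stats::rnorm(cfg$n_control_batches, 0, batch_sd))
    bW <- mW0 * exp(stats::rnorm(cfg$n_control_batches, 0, batch_sd))

    ## planted relation: true area CV2 linear in log10 mean expression of the
    ## knocked-out gene, with genotype-level lognormal scatter
    c_area_mut <- cfg$control_cv2 + cfg$planted_slope * (log10_mapped - 1)
    c_area_mut <- pmax(c_area_mut, 1e-6) *
      exp(stats::rnorm(n_m, 0, cfg$noise_sd))
    mut_batch_idx <- ((seq_len(n_m) - 1L) %% cfg$n_control_batches) + 1L
    mutL <- bL[mut_batch_idx] * exp(stats::rnorm(n_m, 0, cfg$effect_scale))
    mutW <- bW[mut_batch_idx] * exp(stats::rnorm(n_m, 0, cfg$effect_scale))

    geno_row <- function(genotype, batch, mL, mW, c_area) {
      cLW <- split_cv2(c_area)
      a <- 1 / cLW  # gamma shape of the width law
      cv2_aspect <- if (a > 2) (1 + cLW) * (a - 1) / (a - 2) - 1 else NA_real_
      data.frame(
        genotype = genotype, batch = batch,
        mean_length = mL, mean_width = mW,
        mean_area = SHAPE_FACTOR * mL * mW,
        mean_aspect = (mL / mW) / (1 - cLW),
        cv2_length = cLW, cv2_width = cLW,
        cv2_area = (1 + cLW)^2 - 1,
        cv2_aspect = cv2_aspect,
        stringsAsFactors = FALSE
      )
    }

    geno <- do.call(rbind, c(
      lapply(seq_len(cfg$n_control_batches), function(b) {
        geno_row("col0", batches[b], bL[b], bW[b], cfg$control_cv2)
      }),
      lapply(seq_len(n_m), function(i) {
        geno_row(genos[i], batches[mut_batch_idx[i]], mutL[i], mutW[i],
                 c_area_mut[i])
      })
    ))
    rownames(geno) <- NULL

    realized_slope <- if (n_m >= 3 && stats::var(log10_mapped) > 0) {
      mut <- geno$genotype != "col0"
      unname(stats::coef(stats::lm(geno$cv2_area[mut] ~ log10_mapped))[2])
    } else {
      NA_real_
    }

    list(genes = genes, genotypes = geno, realized_slope = realized_slope)
  })
}

#' Simulate a wild-type expression matrix with known ground truth
#'
#' Per-gene means span several orders of magnitude and per-gene CV2 follows a
#' decreasing trend in the mean plus a fraction of highly variable outliers
#' among the unmapped background genes. Per-sepal values are gamma draws
#' matching each gene's true mean and CV2.
#'
#' @param cfg a [sim_config()].
#' @return a list with `expr` (genes x sepals numeric matrix), `gene_map`
#'   (data frame `gene_id`, `genotype` for the mapped mutant genes) and
#'   `truth` (per-gene true moments).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- study_truth(cfg)
  g <- truth$genes
  expr <- with_seed(cfg$seed + 202L, {
    t(vapply(seq_len(nrow(g)), function(i) {
      rgamma_meancv2(cfg$n_expr_sepals, g$mean_expr[i], g$cv2_expr[i])
    }, numeric(cfg$n_expr_sepals)))
  })
  rownames(expr) <- g$gene_id
  colnames(expr) <- sprintf("wt_s%02d", seq_len(cfg$n_expr_sepals))
  gene_map <- g[!is.na(g$genotype), c("gene_id", "genotype")]
  rownames(gene_map) <- NULL
  list(expr = expr, gene_map = gene_map, truth = g)
}

#' Simulate a per-sepal measurement table with known ground truth
#'
#' Emulates the layout of a batch-matched mutant screen: one wild-type
#' (`col0`) block per control batch and one block per mutant, each mutant
#' assigned round-robin to a control batch. Per-sepal length and width are
#' independent gamma draws at the genotype's true mean and CV2; area and
#' aspect ratio derive deterministically from the same length and width
#' (`area = 0.75 * length * width`, `aspect_ratio = length / width`).
#'
#' @param cfg a [sim_config()].
#' @return a list with `measurements` (data frame: genotype, batch, sepal_id,
#'   length, width, area, aspect_ratio) and `truth` (per-genotype true
#'   moments plus the realized planted slope).
#' @export
simulate_measurements <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- study_truth(cfg)
  geno <- truth$genotypes
  r <- cfg$sepals_per_genotype_range
  tab <- with_seed(cfg$seed + 303L, {
    sizes <- seq.int(r[1], r[2])
    ns <- sizes[sample.int(length(sizes), nrow(geno), replace = TRUE)]
    do.call(rbind, lapply(seq_len(nrow(geno)), function(i) {
      n <- ns[i]
      L <- rgamma_meancv2(n, geno$mean_length[i], geno$cv2_length[i])
      W <- rgamma_meancv2(n, geno$mean_width[i], geno$cv2_width[i])
      data.frame(
        genotype = geno$genotype[i],
        batch = geno$batch[i],
        sepal_id = sprintf("%s_%s_s%03d", geno$genotype[i], geno$batch[i],
                           seq_len(n)),
        length = L, width = W,
        area = SHAPE_FACTOR * L * W,
        aspect_ratio = L / W,
        stringsAsFactors = FALSE
      )
    }))
  })
  rownames(tab) <- NULL
  list(measurements = tab,
       truth = list(genotypes = geno, realized_slope = truth$realized_slope))
}

#' Simulate a complete synthetic sepal study
#'
#' Generates a consistent bundle: the measurement table, the wild-type
#' expression matrix, the gene-to-mutant map and the shared ground truth.
#' The planted relation (if any) links each mutant's true area CV2 to the
#' log10 mean wild-type expression of its gene.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `"sepal_study"`: a list with `measurements`,
#'   `expr`, `gene_map`, `truth` and `cfg`.
#' @examples
#' study <- simulate_study(sim_config(seed = 7))
#' head(study$measurements)
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  ex <- simulate_expression(cfg)
  ms <- simulate_measurements(cfg)
  out <- list(
    measurements = ms$measurements,
    expr = ex$expr,
    gene_map = ex$gene_map,
    truth = list(genes = ex$truth, genotypes = ms$truth$genotypes,
                 realized_slope = ms$truth$realized_slope),
    cfg = cfg
  )
  class(out) <- "sepal_study"
  out
}

#' @export
print.sepal_study <- function(x, ...) {
  cat("Synthetic sepal study\n")
  cat(sprintf("  measurements: %d sepals, %d genotypes (%d control batches)\n",
              nrow(x$measurements),
              length(unique(x$measurements$genotype)),
              length(unique(x$measurements$batch))))
  cat(sprintf("  expression: %d genes x %d sepals (%d mapped to mutants)\n",
              nrow(x$expr), ncol(x$expr), nrow(x$gene_map)))
  cat(sprintf("  planted area-CV2 slope: %.4g (realized %.4g)\n",
              x$cfg$planted_slope, x$truth$realized_slope))
  invisible(x)
}
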