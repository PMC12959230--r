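# Shared fixtures: small, fast synthetic configurations used across files.

# study at the default (full-design) conditions but with a slim gene cloud,
# which leaves every screen unchanged (only mapped genes enter the screens)
quick_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_expr_genes = 30L, ...)
}

quick_study <- function(seed = 1L, ...) {
  simulate_study(quick_cfg(seed = seed, ...))
}

# hand-built measurement table with equal per-mutant sample sizes, for the
# degenerate-subsample and custom-layout tests
flat_table <- function(n_mutants = 5L, n_per = 12L, n_batches = 2L,
                       seed = 42L) {
  set.seed(seed)
  genos <- sprintf("m%02d", seq_len(n_mutants))
  batches <- sprintf("b%02d", ((seq_len(n_mutants) - 1L) %% n_batches) + 1L)
  blocks <- lapply(seq_len(n_mutants), function(i) {
    L <- rgamma_meancv2(n_per, 2.5, 0.01 * i)
    W <- rgamma_meancv2(n_per, 1.2, 0.01 * i)
    data.frame(genotype = genos[i], batch = batches[i],
               sepal_id = sprintf("%s_%02d", genos[i], seq_len(n_per)),
               length = L, width = W, area = 0.75 * L * W,
               aspect_ratio = L / W, stringsAsFactors = FALSE)
  })
  ctrl <- lapply(unique(batches), function(b) {
    L <- rgamma_meancv2(n_per, 2.5, 0.01)
    W <- rgamma_meancv2(n_per, 1.2, 0.01)
    data.frame(genotype = "col0", batch = b,
               sepal_id = sprintf("col0_%s_%02d", b, seq_len(n_per)),
               length = L, width = W, area = 0.75 * L * W,
               aspect_ratio = L / W, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(ctrl, blocks))
}

# matching expression matrix + gene map for a flat_table
flat_expression <- function(n_mutants = 5L, n_samples = 10L, seed = 43L) {
  set.seed(seed)
  genos <- sprintf("m%02d", seq_len(n_mutants))
  means <- 10^seq(1, 3, length.out = n_mutants)
  expr <- t(vapply(means, function(m) rgamma_meancv2(n_samples, m, 0.1),
                   numeric(n_samples)))
  rownames(expr) <- sprintf("g%02d", seq_len(n_mutants))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  list(expr = expr,
       gene_map = data.frame(gene_id = rownames(expr), genotype = genos,
                             stringsAsFactors = FALSE))
}
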