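## Table readers/writers with explicit validation, the xlsx convenience
## reader, and the end-to-end pipeline runner.

MEASUREMENT_COLUMNS <- c("genotype", "batch", "sepal_id", "length", "width",
                         "area", "aspect_ratio")

#' @noRd
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))))
  names(counts)[which.max(counts)]
}

#' Read and validate a per-sepal measurement table
#'
#' Delimiter (comma, semicolon or tab) is auto-detected from the header.
#' Rows with missing, non-numeric or non-positive measurement values are
#' rejected — never silently coerced — and returned in the `"rejects"`
#' attribute (and optionally written to a rejects file) with a reason each.
#' Genotype and batch labels are normalized to lower case.
#'
#' @param path delimited text file with a mandatory header carrying the
#'   columns genotype, batch, sepal_id, length, width, area, aspect_ratio.
#' @param rejects_path optional path; when given, rejected rows are written
#'   there as CSV.
#' @return validated measurement data frame with attribute `"rejects"`.
#' @export
read_measurement_table <- function(path, rejects_path = NULL) {
  if (!file.exists(path)) stop_invalid("measurement file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  miss <- setdiff(MEASUREMENT_COLUMNS, names(tab))
  if (length(miss)) {
    stop_invalid("missing required column(s): ", paste(miss, collapse = ", "))
  }
  tab <- tab[, MEASUREMENT_COLUMNS]
  num_cols <- c("length", "width", "area", "aspect_ratio")
  reasons <- character(nrow(tab))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad_na <- is.na(tab[[col]]) | tab[[col]] == ""
    bad_num <- !bad_na & is.na(v)
    bad_pos <- !bad_na & !bad_num & v <= 0
    reasons[bad_na & reasons == ""] <- paste0("missing value (", col, ")")
    reasons[bad_num & reasons == ""] <- paste0("non-numeric value (", col, ")")
    reasons[bad_pos & reasons == ""] <- paste0("non-positive value (", col, ")")
    tab[[col]] <- v
  }
  rejects <- cbind(tab[reasons != "", , drop = FALSE],
                   reason = reasons[reasons != ""])
  tab <- tab[reasons == "", , drop = FALSE]
  tab$genotype <- norm_label(tab$genotype)
  tab$batch <- norm_label(tab$batch)
  rownames(tab) <- NULL
  if (!is.null(rejects_path) && nrow(rejects)) {
    utils::write.csv(rejects, rejects_path, row.names = FALSE)
  }
  if (nrow(rejects)) {
    warning(nrow(rejects), " row(s) rejected while reading ", path,
            call. = FALSE)
  }
  attr(tab, "rejects") <- rejects
  tab
}

#' Write a measurement table as CSV at full double precision
#'
#' @param measurements measurement data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(measurements, path) {
  validate_measurements(measurements)
  out <- measurements
  for (col in c("length", "width", "area", "aspect_ratio")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wild-type expression matrix and its gene-to-mutant map
#'
#' The expression CSV holds gene ids in the first column and one column per
#' sepal sample. Duplicate gene ids or negative cells are schema errors.
#' The optional gene-map CSV (`gene_id`, `genotype`) attaches mutant labels;
#' mapped genes absent from the matrix are rejected with a warning, while
#' unmapped genes are retained as the background cloud.
#'
#' @param path expression CSV.
#' @param gene_map_path optional gene-map CSV.
#' @return list with `expr` (numeric matrix), `gene_map` (data frame or
#'   `NULL`) and `rejects` (data frame of dropped map rows).
#' @export
read_expression_matrix <- function(path, gene_map_path = NULL) {
  if (!file.exists(path)) stop_invalid("expression file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3L) stop_invalid("expression matrix needs >= 2 sample columns")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop_invalid("duplicate gene id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  expr <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(expr) <- "double"
  if (anyNA(expr)) stop_invalid("expression matrix contains missing cells")
  if (any(expr < 0)) stop_invalid("expression values must be non-negative")
  rownames(expr) <- ids
  gene_map <- NULL
  rejects <- data.frame(gene_id = character(0), genotype = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (!is.null(gene_map_path)) {
    gene_map <- utils::read.csv(gene_map_path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "genotype") %in% names(gene_map))) {
      stop_invalid("gene map needs columns gene_id, genotype")
    }
    gene_map$genotype <- norm_label(gene_map$genotype)
    absent <- !gene_map$gene_id %in% ids
    if (any(absent)) {
      rejects <- data.frame(gene_id = gene_map$gene_id[absent],
                            genotype = gene_map$genotype[absent],
                            reason = "gene absent from matrix",
                            stringsAsFactors = FALSE)
      warning("gene map entries absent from the matrix: ",
              paste(gene_map$gene_id[absent], collapse = ", "),
              call. = FALSE)
      gene_map <- gene_map[!absent, , drop = FALSE]
    }
  }
  list(expr = expr, gene_map = gene_map, rejects = rejects)
}

#' Convert a supplementary-style xlsx sheet to a canonical data frame
#'
#' Convenience reader for spreadsheet inputs (requires the `readxl`
#' package). Column names are lower-cased and common aliases
#' (`aspectratio`, `mutant`, `id`) are mapped onto the canonical
#' measurement schema; unmatched columns are kept as-is.
#'
#' @param path xlsx file.
#' @param sheet sheet name or index (default 1).
#' @param csv_path optional path; when given, the canonical table is also
#'   written there as CSV.
#' @return data frame.
#' @export
read_supplementary_xlsx <- function(path, sheet = 1, csv_path = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop_invalid("xlsx input requires the 'readxl' package")
  }
  tab <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  nm <- tolower(gsub("[ ._-]", "", names(tab)))
  alias <- c(aspectratio = "aspect_ratio", mutant = "genotype",
             line = "genotype", id = "sepal_id", sepal = "sepal_id")
  nm <- ifelse(nm %in% names(alias), alias[nm], nm)
  names(tab) <- nm
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  tab
}

#' Run the full analysis pipeline from a config
#'
#' Orchestrates reading the inputs, fitting the screen, the resilience
#' experiments and the p-value summaries, writing every result table as CSV
#' plus JSON reports and a machine-readable manifest into `out_dir`.
#' Identical config and seed reproduce identical outputs.
#'
#' @param config a named list or the path of a YAML file with fields
#'   `measurements`, `expression`, `gene_map` (input paths), `out_dir`, and
#'   optionally `alpha`, `seed`, `subsample` (fields `parameters`,
#'   `n_subsample`, `n_replicates`) and `leave_x_out` (list of specs with
#'   fields `x`, and optionally `exclude`, `parameter`).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (f in c("measurements", "expression", "gene_map", "out_dir")) {
    if (is.null(config[[f]])) stop_invalid("config field missing: ", f)
  }
  for (f in c("measurements", "expression", "gene_map")) {
    if (!file.exists(config[[f]])) {
      stop_invalid("input file not found: ", config[[f]], " (config field '",
                   f, "')")
    }
  }
  alpha <- config$alpha %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  meas <- read_measurement_table(config$measurements,
                                 rejects_path = file.path(out_dir,
                                                          "rejects.csv"))
  ex <- read_expression_matrix(config$expression, config$gene_map)
  fit <- sepal_screen(meas, ex$expr, ex$gene_map, alpha = alpha)

  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(fit$screen_table, "screen_table.csv")
  wr(fit$screens, "screens.csv")
  wr(fit$band, "reference_band.csv")
  wr(fit$confound, "confound.csv")

  sub_cfg <- config$subsample %||% list()
  sub_params <- sub_cfg$parameters %||% c("area", "length", "width")
  reports <- list()
  for (p in sub_params) {
    rep <- subsample_replicates(
      fit, parameter = p,
      n_subsample = as.integer(sub_cfg$n_subsample %||% 30L),
      n_replicates = as.integer(sub_cfg$n_replicates %||% 1000L),
      seed = seed, alpha = alpha, undersized = sub_cfg$undersized %||% "fail"
    )
    wr(rep$results, sprintf("subsample_%s.csv", p))
    reports[[sprintf("subsample_%s", p)]] <-
      rep[c("kind", "spec", "combination_count", "fraction_significant")]
  }
  for (spec in config$leave_x_out %||% list()) {
    rep <- leave_x_out(fit, x = spec$x,
                       exclude = spec$exclude %||% character(0),
                       parameter = spec$parameter %||% "area",
                       alpha = alpha)
    tag <- sprintf("leave%d%s_%s", spec$x,
                   if (length(spec$exclude %||% character(0)))
                     paste0("_ex_", paste(spec$exclude, collapse = "-"))
                   else "",
                   spec$parameter %||% "area")
    wr(rep$results, sprintf("%s.csv", tag))
    reports[[tag]] <-
      rep[c("kind", "spec", "combination_count", "fraction_significant")]
  }
  manifest <- list(
    inputs = list(measurements = config$measurements,
                  expression = config$expression,
                  gene_map = config$gene_map,
                  md5 = as.list(tools::md5sum(c(config$measurements,
                                                config$expression,
                                                config$gene_map)))),
    alpha = alpha, seed = seed,
    package = "sepalcv",
    package_version = as.character(utils::packageVersion("sepalcv")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(c(list(manifest = manifest), list(reports = reports)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
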