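# On-disk artifacts: expression matrix TSV, sample sheet TSV, GMT gene sets,
# result tables, and the pipeline config (YAML/JSON).

CONDITION_LEVELS <- c("control", "low", "high")
SET_CATEGORIES <- c("injury_module", "pathway", "feature_set")

#' Construct and validate an expression study
#'
#' An `ExpressionStudy` bundles a genes x samples matrix of log2 expression
#' with per-sample annotations: the hepatocyte lot, the treatment condition
#' (`control`, `low`, or `high` dose), and the replicate number.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). Log2 scale.
#' @param annotations Data frame with columns `sample_id`, `lot`, `condition`,
#'   `replicate`; one row per sample of `values`.
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `genes`, `samples`, `values`, `annotations`.
#' @export
expression_study <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || anyNA(genes) || any(!nzchar(genes)))
    stop("all genes must have non-empty symbols (rownames)")
  if (anyDuplicated(genes))
    stop("duplicate gene symbol: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (is.null(samples) || anyDuplicated(samples))
    stop("sample ids (colnames) must be present and unique")
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")

  required <- c("sample_id", "lot", "condition", "replicate")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  annotations <- as.data.frame(annotations)[, required]
  annotations$sample_id <- as.character(annotations$sample_id)
  annotations$lot <- as.character(annotations$lot)
  annotations$condition <- as.character(annotations$condition)

  extra <- setdiff(samples, annotations$sample_id)
  if (length(extra))
    stop("sample(s) in matrix but not in sample sheet: ",
         paste(extra, collapse = ", "))
  orphan <- setdiff(annotations$sample_id, samples)
  if (length(orphan))
    stop("sample(s) in sample sheet but not in matrix: ",
         paste(orphan, collapse = ", "))
  bad <- setdiff(unique(annotations$condition), CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition token(s): ", paste(bad, collapse = ", "),
         " (expected control/low/high)")
  rep_num <- suppressWarnings(as.integer(annotations$replicate))
  if (anyNA(rep_num) || any(rep_num < 1))
    stop("`replicate` must be a positive integer for every sample")
  annotations$replicate <- rep_num

  # align sheet rows with matrix column order
  annotations <- annotations[match(samples, annotations$sample_id), ]
  rownames(annotations) <- NULL

  structure(
    list(genes = genes, samples = samples, values = values,
         annotations = annotations),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", length(x$genes), "genes x", length(x$samples),
      "samples\n")
  cat("  lots:", paste(sort(unique(x$annotations$lot)), collapse = ", "), "\n")
  cat("  conditions:",
      paste(intersect(CONDITION_LEVELS, unique(x$annotations$condition)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression study from a matrix TSV and a sample sheet TSV
#'
#' The matrix file is TSV with a first column `gene` holding gene symbols and
#' one column of log2 expression per sample. The sample sheet is TSV with
#' columns `sample_id`, `lot`, `condition`, `replicate`.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return A validated [expression_study()] object.
#' @export
read_expression_study <- function(matrix_path, sample_sheet_path) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              colClasses = "character")
  if (ncol(mat_df) < 2)
    stop("expression matrix needs a gene column plus at least one sample")
  genes <- mat_df[[1]]
  num <- suppressWarnings(
    vapply(mat_df[-1], as.numeric, numeric(nrow(mat_df)))
  )
  num <- matrix(num, nrow = nrow(mat_df),
                dimnames = list(genes, names(mat_df)[-1]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at gene '", genes[bad[1]],
         "', sample '", colnames(num)[bad[2]], "'")
  }
  sheet <- utils::read.delim(sample_sheet_path, check.names = FALSE,
                             colClasses = "character")
  expression_study(num, sheet)
}

#' Write an expression study to a matrix TSV and a sample sheet TSV
#'
#' @param study An `ExpressionStudy`.
#' @param matrix_path,sample_sheet_path Output paths.
#' @param digits Decimal places used to format expression values.
#' @return Invisibly, the study.
#' @export
write_expression_study <- function(study, matrix_path, sample_sheet_path,
                                   digits = 6) {
  stopifnot(inherits(study, "ExpressionStudy"))
  out <- data.frame(gene = study$genes,
                    formatC(study$values, digits = digits, format = "f"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$annotations, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(study)
}

#' Construct a gene-set collection
#'
#' @param sets Named list; each element a list with `description` (string) and
#'   `members` (character vector of gene symbols, case-sensitive).
#' @param category One of `"injury_module"`, `"pathway"`, `"feature_set"`,
#'   recycled across sets, or a vector with one category per set.
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, category) {
  if (anyDuplicated(names(sets)))
    stop("duplicate set_id: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every set needs a non-empty id")
  category <- match.arg(category, SET_CATEGORIES, several.ok = TRUE)
  category <- rep_len(category, length(sets))
  sets <- Map(function(s, cat) {
    if (!length(s$members)) stop("empty gene set not allowed")
    list(description = as.character(s$description %||% ""),
         members = as.character(s$members), category = cat)
  }, sets, category)
  structure(list(sets = sets), class = "GeneSetCollection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1))
  cat("GeneSetCollection:", length(x$sets), "sets,",
      "member counts", min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_id`, `description`, then member gene symbols. Duplicate members
#' within a line are removed with a warning; lines with fewer than three
#' fields or duplicate set ids are errors.
#'
#' @param gmt_path Path to the GMT file.
#' @param category Category applied to every set in the file; one of
#'   `"injury_module"`, `"pathway"`, `"feature_set"`.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(gmt_path, category) {
  category <- match.arg(category, SET_CATEGORIES)
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    id <- fields[1]
    if (id %in% names(sets))
      stop("duplicate set_id: ", id)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set '", id, "': duplicate member(s) ",
              paste(unique(members[duplicated(members)]), collapse = ", "),
              " removed")
      members <- unique(members)
    }
    sets[[id]] <- list(description = fields[2], members = members)
  }
  gene_set_collection(sets, category)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `GeneSetCollection`.
#' @param gmt_path Output path.
#' @return Invisibly, the collection.
#' @export
write_gene_sets <- function(collection, gmt_path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(collection)
}

#' Write a results table as TSV
#'
#' Writes records as a tab-separated table with a header row. Numeric
#' columns are formatted to a fixed number of decimals; row order is
#' preserved as supplied.
#'
#' @param rows A data frame, or a list of records (named lists sharing one
#'   schema).
#' @param path Output path.
#' @param digits Decimal places for numeric (double) columns.
#' @return Invisibly, the data frame written.
#' @export
write_table <- function(rows, path, digits = 4) {
  if (!is.data.frame(rows)) {
    if (!length(rows)) stop("cannot infer a schema from an empty record list; supply a data frame")
    schema <- names(rows[[1]])
    ok <- vapply(rows, function(r) identical(names(r), schema), logical(1))
    if (!all(ok))
      stop("records do not share a schema (first mismatch at record ",
           which(!ok)[1], ")")
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = digits, format = "f")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Read a pipeline/synthetic config from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of config values.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml, .yml or .json: ", path)
}

#' Write a config list to YAML
#' @param config Named list.
#' @param path Output path (`.yaml`).
#' @return Invisibly, the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}

# Subset helper used throughout: replicate columns of one lot x condition arm.
arm_samples <- function(study, lot, condition) {
  ann <- study$annotations
  ann$sample_id[ann$lot == lot & ann$condition == condition]
}
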