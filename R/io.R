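#' Read and write flow-cytometry event tables as CSV
#'
#' Plain CSV with one row per event and columns `FSC`, `SSC`, `GFP`, `RFP`
#' (additional columns such as `label` are preserved).
#'
#' @param path File path.
#' @return `read_events()` returns a tibble of events.
#' @export
read_events <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_events
#' @param events Event tibble.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write an expression study as TSV matrix plus metadata sidecar
#'
#' The matrix file has genes as rows (first column `gene`) and samples as
#' columns; the sidecar has columns `sample_id`, `strain`, `timepoint`,
#' `replicate`.
#'
#' @param matrix_path,meta_path Paths of the matrix TSV and sidecar TSV.
#' @return `read_expression_study()` returns an [expression_study()].
#' @export
read_expression_study <- function(matrix_path, meta_path) {
  raw <- read.delim(matrix_path, check.names = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- raw[[1]]
  meta <- as_tibble(read.delim(meta_path, check.names = FALSE))
  expression_study(mat, meta)
}

#' @rdname read_expression_study
#' @param study An [expression_study()].
#' @export
write_expression_study <- function(study, matrix_path, meta_path) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(study$samples, meta_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(matrix_path)
}

#' Read and write gene-set collections in GMT format
#'
#' One set per line: name, description (the kind is stored here), then the
#' member gene ids, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()` returns a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  kind <- vapply(parts, `[`, character(1), 2)
  kind[!kind %in% c("regulon", "category", "go")] <- "category"
  gene_set_collection(sets, kind)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$kind[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulator-target table and aggregate it into regulon gene sets
#'
#' Two-column TSV (`regulator`, `target`); each regulator's targets become
#' one regulon-kind gene set (apply [filter_sets()] afterwards for the
#' more-than-15-targets rule).
#'
#' @param path File path.
#' @return A [gene_set_collection()] of regulon-kind sets.
#' @export
read_regulon_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  sets <- split(as.character(tab[[2]]), as.character(tab[[1]]))
  sets <- lapply(sets, unique)
  gene_set_collection(sets, "regulon")
}
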