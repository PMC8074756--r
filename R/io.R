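#' Read a count matrix with its sample sheet
#'
#' Count matrices are TSV files with feature ids in the first column and
#' one column per sample; the sample sheet is a TSV with columns
#' `sample`, `group` and optionally `dose_gy` and `time`.
#'
#' @param counts_path Path to the count TSV.
#' @param samples_path Optional path to the sample sheet TSV.
#' @return List with `counts` (integer matrix) and `samples` (data frame
#'   or `NULL`).
#' @export
read_count_matrix <- function(counts_path, samples_path = NULL) {
  tab <- read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  storage.mode(counts) <- "integer"
  samples <- NULL
  if (!is.null(samples_path)) {
    samples <- read.delim(samples_path)
    missing <- setdiff(colnames(counts), samples$sample)
    if (length(missing)) {
      stop("samples without sheet entry: ", paste(missing, collapse = ", "))
    }
    samples <- samples[match(colnames(counts), samples$sample), ]
  }
  list(counts = counts, samples = samples)
}

#' Write a table as TSV
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param rownames_as Optional name under which to emit row names as the
#'   first column.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, rownames_as = NULL) {
  x <- as.data.frame(x)
  if (!is.null(rownames_as)) {
    x <- cbind(setNames(data.frame(rownames(x)), rownames_as), x)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
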