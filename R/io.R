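# Dataset file I/O. Data files are TSV (or CSV, by extension) with a header
# row of variable names and non-negative integer codes; the intervention
# mask is a same-shape 0/1 table.

.sepFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a discrete dataset from file
#'
#' @param path TSV/CSV with a header of variable names; all cells must be
#'   non-negative integers.
#' @param maskPath optional same-shape 0/1 table marking intervened cells.
#' @param arities optional per-variable category counts; inferred as
#'   max code + 1 (at least 2) when absent.
#' @return a [DiscreteDataset-class].
#' @export
readDiscreteDataset <- function(path, maskPath = NULL, arities = NULL) {
  tab <- read.table(path, sep = .sepFor(path), header = TRUE,
                    check.names = FALSE)
  v <- as.matrix(tab)
  if (!is.numeric(v) || any(is.na(v)))
    stop("dataset cells must all be integers")
  if (any(v != round(v)) || any(v < 0))
    stop("dataset cells must be non-negative integers")
  mask <- NULL
  if (!is.null(maskPath)) {
    mtab <- read.table(maskPath, sep = .sepFor(maskPath), header = TRUE,
                       check.names = FALSE)
    mask <- as.matrix(mtab)
    if (!identical(dim(mask), dim(v)))
      stop("intervention mask shape does not match the dataset")
    if (!all(mask %in% c(0, 1))) stop("mask cells must be 0/1")
  }
  discreteDataset(v, arities = arities, mask = mask)
}

#' Write a discrete dataset (and its mask) to file
#'
#' @param dataset a [DiscreteDataset-class].
#' @param path output TSV/CSV path.
#' @param maskPath optional path for the 0/1 intervention mask.
#' @export
writeDiscreteDataset <- function(dataset, path, maskPath = NULL) {
  v <- dataset@values
  if (is.null(colnames(v))) colnames(v) <- .defaultLabels(ncol(v))
  write.table(v, path, sep = .sepFor(path), quote = FALSE, row.names = FALSE)
  if (!is.null(maskPath)) {
    m <- interventionMask(dataset) * 1L
    colnames(m) <- colnames(v)
    write.table(m, maskPath, sep = .sepFor(maskPath), quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
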