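#' Read a named numeric matrix from TSV
#'
#' Tab-delimited UTF-8 with a header row of sample ids and row ids in the
#' first column; missing values are encoded \code{NA}. Duplicated row or
#' column ids are a parse error.
#'
#' @param path file path.
#' @param what label used in error messages ("expression", ...).
#' @return numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path, what = "matrix") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("parse error in ", what, " '", path, "': duplicated row id '",
         ids[duplicated(ids)][1], "'")
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn))
    stop("parse error in ", what, " '", path, "': duplicated sample id '",
         cn[duplicated(cn)][1], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("parse error in ", what, " '", path, "': non-numeric values")
  rownames(m) <- ids
  m
}

#' Write a named numeric matrix as TSV
#'
#' Full-precision (17 significant digits) so round trips preserve doubles;
#' missing values are written \code{NA}.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param idColumn name of the first (row id) column.
#' @return The path, invisibly.
#' @export
writeMatrixTSV <- function(m, path, idColumn = "id") {
  m <- asNamedMatrix(m)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(paste(c(idColumn, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write survival tables
#'
#' TSV with columns sample, time, event, group.
#'
#' @param path file path.
#' @return data.frame (reader); the path invisibly (writer).
#' @export
readSurvivalTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "time", "event", "group")
  if (!all(need %in% names(df)))
    stop("parse error: survival table needs columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("parse error: duplicated sample id '",
         df$sample[duplicated(df$sample)][1], "'")
  df
}

#' @rdname readSurvivalTable
#' @param table survival data.frame.
#' @export
writeSurvivalTable <- function(table, path) {
  out <- table
  out$time <- sprintf("%.17g", out$time)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' Columns source, target, weight (and type when present); loadable as a
#' standard weighted edge list.
#'
#' @param network a [BipartiteNetwork-class] or an edges data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  ed <- if (is(network, "BipartiteNetwork")) network@edges else network
  out <- ed
  out$weight <- sprintf("%.17g", out$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
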