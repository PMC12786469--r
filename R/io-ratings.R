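# Ratings tables: CSV with one row per subject (subject_id, truth, one
# column per evaluator; empty cell = missing).

#' Read a ratings CSV into a RatingMatrix
#'
#' Expected columns: \code{subject_id}, \code{truth}, then one column
#' per evaluator; empty cells are missing ratings.
#'
#' @param path CSV file path.
#' @return A \code{RatingMatrix}.
#' @export
readRatings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "truth")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("ratings file missing column(s): ", paste(missing, collapse = ", "))
  evalCols <- setdiff(names(df), need)
  if (!length(evalCols)) stop("ratings file has no evaluator columns")
  rt <- as.matrix(df[evalCols])
  rt[rt == ""] <- NA
  ratingMatrix(df$truth, rt, subjects = df$subject_id)
}

#' Write a RatingMatrix to CSV
#'
#' @param rm a \code{RatingMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRatings <- function(rm, path) {
  stopifnot(is(rm, "RatingMatrix"))
  df <- data.frame(subject_id = rm@subjects, truth = rm@truth,
                   rm@ratings, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
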