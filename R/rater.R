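# Observer (rater) score tables: images x raters Likert scores with
# per-rater weights. Scores live on a 1-5 ordinal scale; missing cells are
# allowed (Krippendorff's alpha handles missingness by design).

#' Create a rater table
#'
#' @param scores Numeric matrix (images x raters) of Likert scores in
#'   `{1,...,5}` or `NA`; rownames are image ids, colnames rater ids.
#' @param weights Positive per-rater weights, recycled to the number of
#'   raters; defaults to 1. Used by [fuse_scores()] (e.g. double weight on
#'   radiologists relative to radiographers).
#' @return An object of class `rater_table`.
#' @export
rater_table <- function(scores, weights = 1) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(rownames(scores))) rownames(scores) <- paste0("img-", seq_len(nrow(scores)))
  if (is.null(colnames(scores))) colnames(scores) <- paste0("rater-", seq_len(ncol(scores)))
  bad <- which(!is.na(scores) & (scores < 1 | scores > 5), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(bad, 1, function(ij) {
      sprintf("%s/%s=%g", rownames(scores)[ij[1]], colnames(scores)[ij[2]],
              scores[ij[1], ij[2]])
    })
    moqam_abort(paste0("scores outside the 1-5 Likert range: ",
                       paste(cells, collapse = ", ")),
                "moqam_input_error")
  }
  unrated <- rownames(scores)[rowSums(!is.na(scores)) == 0]
  if (length(unrated) > 0) {
    moqam_abort(paste0("images with no scores: ", paste(unrated, collapse = ", ")),
                "moqam_input_error")
  }
  weights <- rep_len(as.numeric(weights), ncol(scores))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    moqam_abort("rater weights must be positive", "moqam_input_error")
  }
  names(weights) <- colnames(scores)
  structure(list(scores = scores,
                 image_ids = rownames(scores),
                 rater_ids = colnames(scores),
                 weights = weights),
            class = "rater_table")
}

#' @export
print.rater_table <- function(x, ...) {
  cat(sprintf("<rater_table> %d images x %d raters (%d missing cells)\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  cat("weights:", paste(sprintf("%s=%g", names(x$weights), x$weights),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Read a rater-score table from CSV
#'
#' Expects a header row, an `image_id` column (first column if unnamed) and
#' one column per rater. Blank cells become missing values, never zeros. An
#' optional weight row whose image id is `#weight` carries per-rater
#' weights; otherwise weights come from the `weights` argument (default 1).
#'
#' @param path CSV path (UTF-8, header row).
#' @param weights Optional per-rater weights overriding any `#weight` row.
#' @return A [rater_table()].
#' @export
read_rater_table <- function(path, weights = NULL) {
  if (!file.exists(path)) {
    moqam_abort(sprintf("file not found: %s", path), "moqam_input_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  id_col <- if ("image_id" %in% names(df)) "image_id" else names(df)[1]
  rater_cols <- setdiff(names(df), id_col)
  if (length(rater_cols) == 0) {
    moqam_abort(sprintf("%s has no rater columns", path), "moqam_input_error")
  }
  wrow <- df[[id_col]] == "#weight"
  file_weights <- NULL
  if (any(wrow, na.rm = TRUE)) {
    file_weights <- as.numeric(df[which(wrow)[1], rater_cols])
    df <- df[!wrow %in% TRUE, ]
  }
  scores <- as.matrix(df[rater_cols])
  storage.mode(scores) <- "double"
  rownames(scores) <- as.character(df[[id_col]])
  colnames(scores) <- rater_cols
  w <- weights %||% file_weights %||% 1
  rater_table(scores, weights = w)
}

#' Write a rater table to CSV
#'
#' Weights are stored in a `#weight` row so the table round-trips through
#' [read_rater_table()].
#'
#' @param table A [rater_table()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_rater_table <- function(table, path) {
  stopifnot(inherits(table, "rater_table"))
  df <- tibble::as_tibble(table$scores)
  df <- dplyr::bind_rows(
    tibble::as_tibble_row(as.list(table$weights)),
    df)
  df <- dplyr::bind_cols(
    tibble::tibble(image_id = c("#weight", table$image_ids)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Convert a rater table to a long tibble
#'
#' @param x A [rater_table()].
#' @param ... Unused.
#' @return A tibble with columns `image_id`, `rater`, `weight`, `score`
#'   (missing scores dropped).
#' @method tidy rater_table
#' @export
tidy.rater_table <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "image_id") |>
    tidyr::pivot_longer(-"image_id", names_to = "rater", values_to = "score") |>
    dplyr::mutate(weight = unname(x$weights[.data$rater]), .before = "score") |>
    dplyr::filter(!is.na(.data$score))
}
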