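#' Read an interval matrix from CSV
#'
#' Two dialects are supported.  `"bracket"` stores each interval as a single
#' string cell `"[a,b]"`; `"paired"` stores two numeric columns per variable,
#' named `<var>.lo` and `<var>.hi`.  In both dialects the first column holds
#' the case label and must be named `case`.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect `"bracket"` or `"paired"`.
#' @return an [interval_matrix].
#' @seealso [write_interval_csv()]
#' @export
read_interval_csv <- function(path, dialect = c("bracket", "paired")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (ncol(df) < 2L) stop("interval CSV needs a case column plus data columns")
  if (tolower(names(df)[1L]) != "case")
    stop("first column must be named 'case'")
  labels <- df[[1L]]
  if (dialect == "bracket") {
    m <- ncol(df) - 1L
    var_names <- names(df)[-1L]
    lower <- upper <- matrix(NA_real_, nrow(df), m)
    for (j in seq_len(m)) {
      for (i in seq_len(nrow(df))) {
        cell <- df[[j + 1L]][i]
        mm <- regmatches(cell, regexec(
          "^\\s*\\[\\s*([-+0-9.eE]+)\\s*,\\s*([-+0-9.eE]+)\\s*\\]\\s*$", cell))[[1L]]
        if (length(mm) != 3L)
          stop(sprintf("malformed interval cell '%s' at row %d, column '%s'",
                       cell, i, var_names[j]))
        a <- as.numeric(mm[2L]); b <- as.numeric(mm[3L])
        if (is.na(a) || is.na(b))
          stop(sprintf("non-numeric bound in cell '%s' at row %d, column '%s'",
                       cell, i, var_names[j]))
        lower[i, j] <- a; upper[i, j] <- b
      }
    }
  } else {
    nm <- names(df)[-1L]
    lo_cols <- grep("\\.lo$", nm, value = TRUE)
    var_names <- sub("\\.lo$", "", lo_cols)
    if (length(var_names) == 0L ||
        !setequal(nm, c(paste0(var_names, ".lo"), paste0(var_names, ".hi"))))
      stop("paired dialect requires matching '<var>.lo' and '<var>.hi' columns")
    num <- function(col, what) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
      if (length(bad) > 0L)
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     df[[col]][bad[1L]], bad[1L], col))
      v
    }
    lower <- sapply(paste0(var_names, ".lo"), num)
    upper <- sapply(paste0(var_names, ".hi"), num)
    lower <- matrix(lower, nrow = nrow(df))
    upper <- matrix(upper, nrow = nrow(df))
  }
  bad <- which(lower > upper, arr.ind = TRUE)
  if (nrow(as.matrix(bad)) > 0L && length(bad) > 0L) {
    bad <- as.matrix(bad)
    stop(sprintf("lower bound exceeds upper bound at row %d, column '%s'",
                 bad[1L, 1L], var_names[bad[1L, 2L]]))
  }
  interval_matrix(lower, upper, case_labels = labels, var_names = var_names)
}

#' Write an interval matrix to CSV
#'
#' Inverse of [read_interval_csv()]; the round trip
#' `read_interval_csv(write_interval_csv(X, f, d), d)` reproduces `X` at full
#' double precision (bounds are printed with 17 significant digits).
#'
#' @param X an [interval_matrix].
#' @param path output file path.
#' @param dialect `"bracket"` or `"paired"`.
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(X, path, dialect = c("bracket", "paired")) {
  stopifnot(inherits(X, "interval_matrix"))
  dialect <- match.arg(dialect)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (dialect == "bracket") {
    df <- data.frame(case = X$case_labels, stringsAsFactors = FALSE)
    for (j in seq_along(X$var_names))
      df[[X$var_names[j]]] <- sprintf("[%s,%s]",
                                      fmt(X$lower[, j]), fmt(X$upper[, j]))
  } else {
    df <- data.frame(case = X$case_labels, stringsAsFactors = FALSE)
    for (j in seq_along(X$var_names)) {
      df[[paste0(X$var_names[j], ".lo")]] <- fmt(X$lower[, j])
      df[[paste0(X$var_names[j], ".hi")]] <- fmt(X$upper[, j])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The faces interval dataset
#'
#' Twenty-seven cases (nine subjects, three image sequences each) by six
#' interval-valued facial distances, measured in pixels across a sequence of
#' photographs of the same face: eye span (X1), distance between the eyes
#' (X2), outer right/left eye to a point between nose and mouth (X3, X4), and
#' that point to the right/left outside of the mouth (X5, X6).  The interval
#' of each cell spans the variation of the distance across the sequence.
#'
#' @return a 27 x 6 [interval_matrix] with case labels FRA1..ROM3.
#' @examples
#' faces <- faces_dataset()
#' dim(faces)
#' @export
faces_dataset <- function() {
  path <- system.file("extdata", "faces.csv", package = "intervalpca",
                      mustWork = TRUE)
  read_interval_csv(path, dialect = "bracket")
}
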