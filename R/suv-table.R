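#' Subject-by-region mean uptake tables
#'
#' An `suv_table` holds the mean standardized uptake value (SUV) of every
#' region of interest (ROI) for every subject of one diagnostic group: a
#' numeric `K x N` matrix (K subjects in rows, N ROIs in columns) plus a
#' group label.  It is the input to group-wise network construction.
#'
#' @param values numeric matrix, subjects in rows and ROIs in columns.
#' @param subject_ids character vector of K unique subject identifiers;
#'   defaults to the matrix row names or `"s1"`, `"s2"`, ...
#' @param roi_labels character vector of N unique ROI labels; defaults to
#'   the matrix column names or `"roi1"`, `"roi2"`, ...
#' @param group single group label (e.g. `"AD"`, `"MCI"`, `"NC"`).
#'
#' @return An object of class `suv_table`: a list with elements `values`
#'   (the labelled matrix), `subject_ids`, `roi_labels` and `group`.
#' @examples
#' x <- suv_table(matrix(rnorm(12, mean = 5), 4, 3), group = "NC")
#' x
#' @seealso [correlation_distance()], [read_suv_table()], [simulate_cohort()]
#' @export
suv_table <- function(values, subject_ids = NULL, roi_labels = NULL,
                      group = "ungrouped") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (subjects x ROIs)")
  K <- nrow(values); N <- ncol(values)
  if (K < 2L) stop("an suv_table needs at least 2 subjects (got ", K, ")")
  if (N < 3L) stop("an suv_table needs at least 3 ROIs (got ", N, ")")
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(K))
  if (is.null(roi_labels)) roi_labels <- colnames(values)
  if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(N))
  subject_ids <- as.character(subject_ids)
  roi_labels <- as.character(roi_labels)
  if (length(subject_ids) != K) stop("`subject_ids` must have length ", K)
  if (length(roi_labels) != N) stop("`roi_labels` must have length ", N)
  if (anyDuplicated(roi_labels))
    stop("duplicate ROI labels: ",
         paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("missing or non-finite SUV at subject '", subject_ids[bad[1L, 1L]],
         "', ROI '", roi_labels[bad[1L, 2L]], "'")
  dimnames(values) <- list(subject_ids, roi_labels)
  structure(list(values = values, subject_ids = subject_ids,
                 roi_labels = roi_labels, group = as.character(group)[1L]),
            class = "suv_table")
}

#' @export
print.suv_table <- function(x, ...) {
  cat(sprintf("suv_table: %d subjects x %d ROIs, group '%s'\n",
              nrow(x$values), ncol(x$values), x$group))
  cat(sprintf("  SUV range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
summary.suv_table <- function(object, ...) {
  print(object)
  cat("  per-ROI mean SUV:\n")
  print(summary(colMeans(object$values)))
  invisible(object)
}

# subset subjects, keeping all ROIs; used by resampling and permutation
suv_subset <- function(x, rows, group = x$group) {
  structure(list(values = x$values[rows, , drop = FALSE],
                 subject_ids = x$subject_ids[rows],
                 roi_labels = x$roi_labels, group = group),
            class = "suv_table")
}

#' Read and write SUV tables
#'
#' Delimited-text serialization of [suv_table] objects.  The first column
#' holds subject identifiers, an optional `group` column holds the group
#' label, and the remaining columns (one per ROI, named in the header) hold
#' mean SUVs.  Numbers are written with full `%.17g` precision so a
#' write/read cycle restores values bit-exactly.
#'
#' @param path file path.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @param group group label to use when the file has no `group` column.
#' @param x an [suv_table].
#' @return `read_suv_table()` returns an [suv_table];
#'   `write_suv_table()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_suv_table(suv_table(matrix(1:8 / 2, 2, 4), group = "NC"), f)
#' read_suv_table(f)
#' @export
read_suv_table <- function(path, sep = ",", group = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("SUV table needs a subject column plus ROI columns")
  cn <- names(df)[-1L]  # before subsetting: `[.data.frame` mangles duplicates
  subject_ids <- as.character(df[[1L]])
  df <- df[-1L]
  if ("group" %in% cn) {
    gi <- which(cn == "group")[1L]
    grp <- unique(as.character(df[[gi]]))
    if (length(grp) != 1L)
      stop("SUV table mixes group labels: ", paste(grp, collapse = ", "))
    if (is.null(group)) group <- grp
    df <- df[-gi]
    cn <- cn[-gi]
  } else if (is.null(group)) group <- "ungrouped"
  if (anyDuplicated(cn))
    stop("duplicate ROI labels in header: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  names(df) <- cn
  vals <- as.matrix(df)
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))) &
                   !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-numeric SUV at row ", bad[1L, 1L], " (subject '",
           subject_ids[bad[1L, 1L]], "'), column '", names(df)[bad[1L, 2L]], "'")
    storage.mode(vals) <- "double"
  }
  nas <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nas) > 0L)
    stop("missing SUV at row ", nas[1L, 1L], " (subject '",
         subject_ids[nas[1L, 1L]], "'), column '", names(df)[nas[1L, 2L]], "'")
  suv_table(vals, subject_ids = subject_ids, roi_labels = names(df),
            group = group)
}

#' @rdname read_suv_table
#' @export
write_suv_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "suv_table"))
  num <- matrix(sprintf("%.17g", x$values), nrow(x$values))
  out <- cbind(subject = x$subject_ids, group = x$group, num)
  colnames(out) <- c("subject", "group", x$roi_labels)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
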