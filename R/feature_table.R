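#' Feature tables
#'
#' A `feature_table` holds a features-by-samples matrix together with a
#' per-feature kind (`"continuous"` or `"categorical"`).  Categorical
#' features are stored as integer level codes; the original labels are kept
#' in `levels`.  Missing values are `NA`.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique rownames (feature IDs) and colnames (sample IDs).
#'   Categorical features are integer level codes.
#' @param kinds character vector, one of `"continuous"`/`"categorical"` per
#'   feature.  Defaults to all-continuous.
#' @param levels named list mapping categorical feature IDs to their label
#'   vectors (code `k` means `levels[[id]][k]`).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, kinds = NULL, levels = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate feature ID: '", dup, "'")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample ID: '", dup, "'")
  }
  if (is.null(kinds)) kinds <- rep("continuous", nrow(values))
  kinds <- rep_len(as.character(kinds), nrow(values))
  stopifnot(all(kinds %in% c("continuous", "categorical")))
  names(kinds) <- rownames(values)
  structure(list(values = values, kinds = kinds, levels = levels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$values), " features x ", ncol(x$values),
      " samples (", sum(x$kinds == "categorical"), " categorical)\n",
      sep = "")
  invisible(x)
}

#' @rdname feature_table
#' @param t a `feature_table`
#' @export
n_features <- function(t) nrow(t$values)

#' @rdname feature_table
#' @export
n_samples <- function(t) ncol(t$values)

#' @rdname feature_table
#' @export
feature_ids <- function(t) rownames(t$values)

#' @rdname feature_table
#' @export
sample_ids <- function(t) colnames(t$values)

#' Read a feature table from a tab-separated file
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' A row whose non-missing cells are all numeric is typed continuous;
#' any other row is typed categorical and its labels are coded as integer
#' levels.  `NA` or empty cells are missing.
#'
#' @param path path to a TSV file.
#' @param kinds optional character vector (recycled or named by feature ID)
#'   overriding the inferred per-feature kind.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, kinds = NULL) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in '", path, "' at line ", bad,
         " (", nf[bad], " fields, expected ", nf[1L], ")")
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("'", path, "' has no sample columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature ID: '", ids[duplicated(ids)][1L], "'")
  }
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID: '", samples[duplicated(samples)][1L], "'")
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(cells) <- ids

  is_num_row <- apply(cells, 1L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || !anyNA(suppressWarnings(as.numeric(v)))
  })
  inferred <- ifelse(is_num_row, "continuous", "categorical")
  if (!is.null(kinds)) {
    if (!is.null(names(kinds))) {
      inferred[match(names(kinds), ids)] <- kinds
    } else {
      inferred <- rep_len(kinds, length(ids))
    }
  }

  values <- matrix(NA_real_, nrow(cells), ncol(cells),
                   dimnames = dimnames(cells))
  levels <- list()
  for (i in seq_len(nrow(cells))) {
    if (inferred[i] == "continuous") {
      values[i, ] <- suppressWarnings(as.numeric(cells[i, ]))
    } else {
      f <- factor(cells[i, ])
      values[i, ] <- as.numeric(f)
      levels[[ids[i]]] <- base::levels(f)
    }
  }
  feature_table(values, kinds = inferred, levels = levels)
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]: categorical codes are written back as
#' their labels, missing values as `NA`.
#'
#' @param t a [feature_table]
#' @param path output path
#' @export
write_feature_table <- function(t, path) {
  out <- matrix("", n_features(t), n_samples(t))
  for (i in seq_len(n_features(t))) {
    v <- t$values[i, ]
    if (t$kinds[i] == "categorical") {
      lab <- t$levels[[feature_ids(t)[i]]][v]
      out[i, ] <- ifelse(is.na(v), NA, lab)
    } else {
      out[i, ] <- ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE))
    }
  }
  df <- data.frame(feature = feature_ids(t), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature", sample_ids(t))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Align two feature tables on their shared samples
#'
#' Restricts both tables to the intersection of their sample IDs, in the
#' order they appear in `x`.  Dropped samples are reported with a warning.
#'
#' @param x,y [feature_table] objects.
#' @return A list with elements `x` and `y`, aligned column-wise.
#' @export
align_tables <- function(x, y) {
  shared <- intersect(sample_ids(x), sample_ids(y))
  if (length(shared) == 0L) {
    stop("the two tables share no sample IDs")
  }
  dropped <- setdiff(union(sample_ids(x), sample_ids(y)), shared)
  if (length(dropped)) {
    warning("dropping samples absent from one table: ",
            paste(dropped, collapse = ", "))
  }
  sub <- function(t) {
    t$values <- t$values[, shared, drop = FALSE]
    t
  }
  list(x = sub(x), y = sub(y))
}
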