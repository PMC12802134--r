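#' Feature tables for paired microbiome-metabolome analysis
#'
#' A `feature_table` holds a subjects-by-features numeric matrix for one
#' modality (`"taxa"` or `"metabolite"`) together with its transform state:
#' `"raw"` (counts or raw levels), `"relative_abundance"` (taxa rows summing
#' to one), or `"log_standardized"` (metabolite columns with mean 0, sd 1).
#' Subject and feature identifiers live in the matrix dimnames.
#'
#' @param values numeric matrix, subjects in rows, features in columns; both
#'   dimensions must be named with unique identifiers.
#' @param modality `"taxa"` or `"metabolite"`.
#' @param transform_state one of `"raw"`, `"relative_abundance"`,
#'   `"log_standardized"`.
#' @param log_mean,log_sd per-feature mean and standard deviation of the log
#'   levels, recorded by [transform_metabolites()] so the transform can be
#'   inverted (used by the semi-synthetic generator).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, modality = c("taxa", "metabolite"),
                          transform_state = c("raw", "relative_abundance",
                                              "log_standardized"),
                          log_mean = NULL, log_sd = NULL) {
  modality <- match.arg(modality)
  transform_state <- match.arg(transform_state)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature table values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature table contains NA or non-finite values")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature table needs subject (row) and feature (column) names")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate feature_ids")
  if (anyDuplicated(rownames(values))) stop("duplicate subject_ids")
  if (modality == "taxa" && transform_state == "relative_abundance" &&
      any(rowSums(values) > 1 + 1e-9)) {
    stop("relative-abundance rows must sum to at most 1")
  }
  structure(
    list(values = values, modality = modality,
         transform_state = transform_state,
         log_mean = log_mean, log_sd = log_sd),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s [%s]: %d subjects x %d features\n",
              x$modality, x$transform_state, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @rdname feature_table
#' @param x a `feature_table`.
#' @param ... unused.
#' @return `as_tibble()` returns a tibble with a `subject_id` column followed
#'   by one column per feature.
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$values), rownames = NA) |>
    tibble::rownames_to_column("subject_id") |>
    tibble::as_tibble()
}

subject_ids <- function(ft) rownames(ft$values)
feature_ids <- function(ft) colnames(ft$values)

#' Read a subjects-by-features table from delimited text
#'
#' The delimiter is sniffed from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma) unless given. Orientation is auto-detected when label
#' subject identifiers are supplied: the axis whose names overlap the label
#' ids is taken as subjects, preferring rows on ties.
#'
#' @param path path to a CSV/TSV file with one id column/header.
#' @param modality `"taxa"` or `"metabolite"`.
#' @param label_ids optional character vector of subject ids (from the label
#'   file) used for orientation detection.
#' @param delim optional delimiter override.
#' @return a raw [feature_table()].
#' @export
read_feature_table <- function(path, modality, label_ids = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE,
                          name_repair = "minimal")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate ids in first column of ", path)
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate feature_ids in header of ", path)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in ", path)
  if (anyNA(mat)) stop("missing cells in ", path)
  rownames(mat) <- ids
  if (!is.null(label_ids)) {
    row_hits <- length(intersect(rownames(mat), label_ids))
    col_hits <- length(intersect(colnames(mat), label_ids))
    if (row_hits == 0 && col_hits == 0) {
      stop("no axis of ", path, " matches the label subject ids")
    }
    if (col_hits > row_hits) mat <- t(mat)
  }
  feature_table(mat, modality = modality, transform_state = "raw")
}

#' Read per-subject binary labels
#'
#' @param path two-column CSV/TSV (`subject_id`, `label`); labels are coerced
#'   to 0/1 (0 = control, 1 = case).
#' @param delim optional delimiter override.
#' @return tibble with columns `subject_id` (character) and `label` (integer).
#' @export
read_labels <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  out <- tibble::tibble(subject_id = as.character(df[[1]]),
                        label = as.integer(df[[2]]))
  validate_labels(out)
  out
}

validate_labels <- function(labels) {
  stopifnot(all(c("subject_id", "label") %in% names(labels)))
  if (anyDuplicated(labels$subject_id)) stop("duplicate subject_ids in labels")
  if (!all(labels$label %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels$label)) < 2) stop("both classes must be present")
  invisible(labels)
}

#' Filter taxa by a minimum-count prevalence rule
#'
#' Keeps taxon *i* iff the fraction of subjects in which its count is at
#' least `min_count` is at least `min_frac` (boundaries inclusive on the
#' keep side). Feature order is preserved.
#'
#' @param ft raw taxa [feature_table()] of counts.
#' @param min_count count considered "present" (default 10).
#' @param min_frac minimum fraction of subjects at or above `min_count`
#'   (default 0.10).
#' @return filtered `feature_table`.
#' @export
filter_taxa <- function(ft, min_count = 10, min_frac = 0.10) {
  stopifnot(inherits(ft, "feature_table"), ft$modality == "taxa")
  if (ft$transform_state != "raw") stop("filter_taxa expects raw counts")
  frac <- colMeans(ft$values >= min_count)
  keep <- frac >= min_frac
  if (!any(keep)) {
    stop(sprintf("all taxa removed (min_count=%g, min_frac=%g)",
                 min_count, min_frac))
  }
  feature_table(ft$values[, keep, drop = FALSE], ft$modality, "raw")
}

#' Filter metabolites by detection prevalence
#'
#' Keeps metabolite *i* iff the fraction of subjects with a level strictly
#' above zero is at least `min_presence_frac`.
#'
#' @param ft raw metabolite [feature_table()]; zeros mark non-detection.
#' @param min_presence_frac minimum detected fraction (default 0.15).
#' @return filtered `feature_table`.
#' @export
filter_metabolites <- function(ft, min_presence_frac = 0.15) {
  stopifnot(inherits(ft, "feature_table"), ft$modality == "metabolite")
  if (ft$transform_state != "raw") stop("filter_metabolites expects raw levels")
  keep <- colMeans(ft$values > 0) >= min_presence_frac
  if (!any(keep)) {
    stop(sprintf("all metabolites removed (min_presence_frac=%g)",
                 min_presence_frac))
  }
  feature_table(ft$values[, keep, drop = FALSE], ft$modality, "raw")
}

#' Log-transform and standardize metabolite levels
#'
#' Zeros are replaced per metabolite by half its minimum positive observed
#' level, levels are natural-log transformed, and each column is centred and
#' scaled to unit population (n-denominator) standard deviation. The
#' per-feature mean and sd of the log levels are stored so the transform can
#' be inverted with `exp(x * log_sd + log_mean)`.
#'
#' @param ft filtered raw metabolite [feature_table()].
#' @return a `log_standardized` `feature_table` carrying `log_mean`/`log_sd`.
#' @export
transform_metabolites <- function(ft) {
  stopifnot(inherits(ft, "feature_table"), ft$modality == "metabolite")
  if (ft$transform_state == "log_standardized") stop("already transformed")
  v <- ft$values
  if (nrow(v) < 2) stop("standardization needs at least 2 subjects")
  v <- apply(v, 2, function(col) {
    pos <- col[col > 0]
    if (length(pos) == 0) stop("metabolite with no positive level")
    col[col <= 0] <- min(pos) / 2
    col
  })
  lg <- log(v)
  mu <- colMeans(lg)
  sd_pop <- sqrt(colMeans(sweep(lg, 2, mu)^2))
  if (any(sd_pop < 1e-12)) {
    stop("constant metabolite(s): ",
         paste(colnames(ft$values)[sd_pop < 1e-12], collapse = ", "))
  }
  z <- sweep(sweep(lg, 2, mu), 2, sd_pop, "/")
  rownames(z) <- rownames(ft$values)
  feature_table(z, "metabolite", "log_standardized",
                log_mean = mu, log_sd = sd_pop)
}

#' Invert the metabolite log-standardization
#'
#' @param z matrix of standardized log values (columns matching `log_mean`).
#' @param log_mean,log_sd the statistics stored by [transform_metabolites()].
#' @return matrix of strictly positive raw-scale levels.
#' @export
untransform_metabolites <- function(z, log_mean, log_sd) {
  exp(sweep(sweep(z, 2, log_sd, "*"), 2, log_mean, "+"))
}

#' Convert taxa counts to relative abundances
#'
#' @param ft raw taxa [feature_table()] of non-negative counts.
#' @return `feature_table` in `relative_abundance` state; rows sum to one.
#' @export
to_relative_abundance <- function(ft) {
  stopifnot(inherits(ft, "feature_table"), ft$modality == "taxa")
  rs <- rowSums(ft$values)
  if (any(rs <= 0)) {
    stop("all-zero subject row(s): ",
         paste(rownames(ft$values)[rs <= 0], collapse = ", "))
  }
  feature_table(ft$values / rs, "taxa", "relative_abundance")
}

#' Align paired tables and labels on their common subjects
#'
#' Restricts the taxa table, metabolite table, and labels to the
#' intersection of subject ids, in the order of the taxa table's surviving
#' subjects. Dropped subjects are reported with a warning.
#'
#' @param taxa,metab [feature_table()] objects.
#' @param labels tibble with `subject_id`, `label`.
#' @return list with elements `taxa`, `metab`, `labels`.
#' @export
align_inputs <- function(taxa, metab, labels) {
  validate_labels(labels)
  common <- intersect(intersect(subject_ids(taxa), subject_ids(metab)),
                      labels$subject_id)
  if (length(common) == 0) stop("no subjects shared by all three inputs")
  common <- subject_ids(taxa)[subject_ids(taxa) %in% common]
  dropped <- setdiff(unique(c(subject_ids(taxa), subject_ids(metab),
                              labels$subject_id)), common)
  if (length(dropped) > 0) {
    warning("dropped subjects absent from some input: ",
            paste(dropped, collapse = ", "))
  }
  lab <- labels[match(common, labels$subject_id), ]
  if (length(unique(lab$label)) < 2) {
    stop("a class disappeared after subject intersection")
  }
  list(
    taxa = feature_table(taxa$values[common, , drop = FALSE], "taxa",
                         taxa$transform_state),
    metab = feature_table(metab$values[common, , drop = FALSE], "metabolite",
                          metab$transform_state,
                          log_mean = metab$log_mean, log_sd = metab$log_sd),
    labels = lab
  )
}

#' Write a feature table back to CSV for audit
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(ft, path) {
  readr::write_csv(as_tibble.feature_table(ft), path)
  invisible(path)
}
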