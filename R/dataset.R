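#' Tabular dataset bound to a variable schema
#'
#' An `ap_dataset` couples a value table (rows = instances, columns = schema
#' variables) with its schema, an explicit missingness mask, and - once
#' [standardize()] has been applied - the per-variable mean/sd record needed
#' to invert the transform. Missing values are always represented by the mask
#' (and `NA` in the table), never by sentinel numbers.
#'
#' @param df data frame whose columns match the schema names (any order).
#' @param schema an [variable_schema()] object.
#' @param ids optional instance identifiers (default row numbers).
#' @return An object of class `ap_dataset`.
#' @export
as_dataset <- function(df, schema, ids = NULL) {
  validate_schema(schema)
  missing_cols <- setdiff(schema$name, names(df))
  if (length(missing_cols))
    stop("data is missing schema column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[schema$name]
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    if (schema$kind[i] == "continuous") {
      if (!is.numeric(df[[v]])) {
        suppressWarnings(num <- as.numeric(df[[v]]))
        bad <- which(!is.na(df[[v]]) & df[[v]] != "" & df[[v]] != "NA" & is.na(num))
        if (length(bad))
          stop("unparseable value in continuous column '", v, "' at row ", bad[1],
               ": '", df[[v]][bad[1]], "'")
        df[[v]] <- num
      }
    } else {
      vals <- as.character(df[[v]])
      vals[vals %in% c("", "NA")] <- NA_character_
      cats <- var_categories(schema, v)
      bad <- which(!is.na(vals) & !(vals %in% cats))
      if (length(bad))
        stop("unknown category in discrete column '", v, "' at row ", bad[1],
             ": '", vals[bad[1]], "'")
      df[[v]] <- vals
    }
  }
  mask <- is.na(as.matrix(df))
  dimnames(mask) <- list(NULL, names(df))
  if (is.null(ids)) ids <- seq_len(nrow(df))
  structure(
    list(data = df, schema = schema, mask = mask, ids = ids,
         standardization = NULL),
    class = "ap_dataset"
  )
}

#' @export
print.ap_dataset <- function(x, ...) {
  cat("<ap_dataset> ", nrow(x$data), " instances x ", ncol(x$data),
      " variables (", sum(x$mask), " missing cells",
      if (!is.null(x$standardization)) ", standardized" else "", ")\n", sep = "")
  print(utils::head(x$data, 6))
  invisible(x)
}

#' @export
dim.ap_dataset <- function(x) dim(x$data)

#' @export
as.data.frame.ap_dataset <- function(x, ...) x$data

n_instances <- function(data) nrow(data$data)

subset_dataset <- function(data, idx) {
  out <- data
  out$data <- data$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$mask <- data$mask[idx, , drop = FALSE]
  out$ids <- data$ids[idx]
  out
}

#' Read / write a delimited-text dataset against a schema
#'
#' Reads a delimited file with a header row, parses every column according to
#' the schema (erroring with the offending row and column on unparseable
#' continuous cells or unknown categories), and maps empty-string and `NA`
#' tokens to missing.
#'
#' @param path file path.
#' @param schema an [variable_schema()] object.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `read_dataset()` returns an `ap_dataset`; `write_dataset()` returns
#'   `path` invisibly.
#' @export
read_dataset <- function(path, schema, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"", comment.char = "")
  as_dataset(df, schema)
}

#' @rdname read_dataset
#' @param data an `ap_dataset`.
#' @export
write_dataset <- function(data, path, delim = ",") {
  utils::write.table(data$data, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Split a dataset into training and test parts
#'
#' Training receives `floor(n * train_fraction)` rows (or groups when
#' `group_key` is given, in which case all rows of a group land on the same
#' side, as when repeated measurements of one participant must not straddle
#' the split). The partition is disjoint, exhaustive and reproducible under a
#' fixed seed.
#'
#' @param data an `ap_dataset`.
#' @param train_fraction proportion in (0, 1); default 0.8.
#' @param seed integer seed for the random assignment.
#' @param group_key optional column name whose values define groups.
#' @return list with elements `train` and `test`, both `ap_dataset`s.
#' @export
split_train_test <- function(data, train_fraction = 0.8, seed = 1L,
                             group_key = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- n_instances(data)
  if (is.null(group_key)) {
    idx_train <- local_seed(seed, sample.int(n, floor(n * train_fraction)))
  } else {
    if (!group_key %in% names(data$data))
      stop("group_key column '", group_key, "' not found")
    groups <- unique(data$data[[group_key]])
    g_train <- local_seed(seed,
      sample(groups, floor(length(groups) * train_fraction)))
    idx_train <- which(data$data[[group_key]] %in% g_train)
  }
  list(train = subset_dataset(data, sort(idx_train)),
       test = subset_dataset(data, setdiff(seq_len(n), idx_train)))
}

std_stats <- function(stats_from) {
  schema <- stats_from$schema
  vars <- continuous_vars(schema, role = "explanatory")
  means <- sds <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    x <- stats_from$data[[v]][!stats_from$mask[, v]]
    if (length(x) < 2L)
      stop("need >= 2 non-missing values to standardize column '", v, "'")
    means[v] <- mean(x)
    sds[v] <- stats::sd(x)
    if (sds[v] == 0)
      stop("zero standard deviation in column '", v, "'; cannot standardize")
  }
  list(mean = means, sd = sds)
}

#' Standardize continuous explanatory variables
#'
#' Transforms every continuous explanatory column to
#' `(value - mean) / sd` using statistics estimated on `stats_from` (the
#' training rows); the response and discrete columns are untouched. The
#' mean/sd record is stored on the result so [unstandardize()] can invert the
#' transform exactly.
#'
#' @param data dataset to transform.
#' @param stats_from dataset supplying the statistics (default `data` itself).
#' @return The transformed `ap_dataset`, carrying a `standardization` record.
#' @export
standardize <- function(data, stats_from = data) {
  st <- std_stats(stats_from)
  out <- data
  for (v in names(st$mean))
    out$data[[v]] <- (data$data[[v]] - st$mean[v]) / st$sd[v]
  out$standardization <- st
  out
}

#' @rdname standardize
#' @export
unstandardize <- function(data) {
  st <- data$standardization
  if (is.null(st)) stop("dataset carries no standardization record")
  out <- data
  for (v in names(st$mean))
    out$data[[v]] <- data$data[[v]] * st$sd[v] + st$mean[v]
  out$standardization <- NULL
  out
}

#' Impute missing cells with training medians / modes
#'
#' Continuous missing cells receive the median of the non-missing training
#' values; discrete missing cells receive the modal training category (ties
#' broken by schema category order). The missingness mask is cleared.
#'
#' @param data dataset to impute.
#' @param stats_from dataset supplying medians/modes (default `data`).
#' @return The imputed `ap_dataset` with an all-`FALSE` mask.
#' @export
impute_median <- function(data, stats_from = data) {
  schema <- data$schema
  out <- data
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    miss <- out$mask[, v]
    src <- stats_from$data[[v]][!stats_from$mask[, v]]
    if (length(src) == 0L)
      stop("column '", v, "' is fully missing in the statistics source")
    if (!any(miss)) next
    fill <- if (schema$kind[i] == "continuous") {
      stats::median(src)
    } else {
      cats <- var_categories(schema, v)
      counts <- table(factor(src, levels = cats))
      cats[which.max(counts)]
    }
    out$data[[v]][miss] <- fill
  }
  out$mask[] <- FALSE
  out
}

#' Drop rows with continuous explanatory values outside 3 standard deviations
#'
#' Rows where any continuous explanatory value lies more than three training
#' standard deviations from the training mean are removed before surrogate
#' fitting, for sampling stability. Response and discrete values never
#' trigger removal; missing cells never trigger removal.
#'
#' @param data dataset to filter.
#' @param stats_from dataset supplying mean/sd (default `data`). If `data` is
#'   already standardized, the stored record is reused when `stats_from` is
#'   omitted.
#' @return The surviving rows as an `ap_dataset`; the removed rows are
#'   reported in the `outlier_report` attribute (a data frame with instance
#'   id, variable and value).
#' @export
filter_outliers_3sigma <- function(data, stats_from = NULL) {
  schema <- data$schema
  vars <- continuous_vars(schema, role = "explanatory")
  if (is.null(stats_from) && !is.null(data$standardization)) {
    means <- stats::setNames(rep(0, length(vars)), vars)
    sds <- stats::setNames(rep(1, length(vars)), vars)
  } else {
    if (is.null(stats_from)) stats_from <- data
    st <- std_stats(stats_from)
    means <- st$mean
    sds <- st$sd
  }
  report <- list()
  drop <- rep(FALSE, n_instances(data))
  for (v in vars) {
    x <- data$data[[v]]
    out <- !data$mask[, v] & abs(x - means[v]) > 3 * sds[v]
    out[is.na(out)] <- FALSE
    if (any(out))
      report[[v]] <- data.frame(id = data$ids[out], variable = v,
                                value = x[out], stringsAsFactors = FALSE)
    drop <- drop | out
  }
  res <- subset_dataset(data, which(!drop))
  attr(res, "outlier_report") <-
    if (length(report)) do.call(rbind, unname(report))
    else data.frame(id = integer(), variable = character(), value = numeric())
  res
}

#' @rdname filter_outliers_3sigma
#' @param x a filtered dataset.
#' @export
outlier_report <- function(x) attr(x, "outlier_report")
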