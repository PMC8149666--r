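#' Declare the variable schema of a tabular dataset
#'
#' A schema records, for every column of a dataset, whether it is continuous
#' or discrete, whether it is an explanatory or the response variable, whether
#' it may be intervened on during path planning, and - for variables with a
#' guideline-recommended direction of change - whether interventions should
#' increase or decrease it. Discrete variables carry an ordered list of valid
#' category labels.
#'
#' Invariants enforced: names are unique, exactly one variable has the
#' response role, every intervenable variable is a continuous explanatory
#' variable, and every discrete variable lists at least two categories.
#'
#' @param name character vector of variable names.
#' @param kind "continuous" or "discrete", recycled to `length(name)`.
#' @param role "explanatory" or "response", recycled.
#' @param intervenable logical, recycled; may the planner change the variable?
#' @param direction "increase", "decrease" or "free", recycled. Used by
#'   guideline-direction comparator paths; ignored elsewhere.
#' @param categories named list mapping each discrete variable name to its
#'   ordered character vector of category labels.
#' @return An object of class `ap_schema`: a data frame with one row per
#'   variable and a `categories` attribute.
#' @examples
#' variable_schema(
#'   name = c("bmi", "glucose", "sex", "sbp"),
#'   kind = c("continuous", "continuous", "discrete", "continuous"),
#'   role = c("explanatory", "explanatory", "explanatory", "response"),
#'   intervenable = c(TRUE, TRUE, FALSE, FALSE),
#'   direction = c("decrease", "decrease", "free", "free"),
#'   categories = list(sex = c("F", "M"))
#' )
#' @export
variable_schema <- function(name, kind, role, intervenable = FALSE,
                            direction = "free", categories = list()) {
  n <- length(name)
  s <- data.frame(
    name = as.character(name),
    kind = rep_len(as.character(kind), n),
    role = rep_len(as.character(role), n),
    intervenable = rep_len(as.logical(intervenable), n),
    direction = rep_len(as.character(direction), n),
    stringsAsFactors = FALSE
  )
  attr(s, "categories") <- categories
  class(s) <- c("ap_schema", "data.frame")
  validate_schema(s)
  s
}

validate_schema <- function(s) {
  stopifnot(inherits(s, "ap_schema"))
  if (anyDuplicated(s$name))
    stop("schema variable names must be unique")
  if (!all(s$kind %in% c("continuous", "discrete")))
    stop("kind must be 'continuous' or 'discrete'")
  if (!all(s$role %in% c("explanatory", "response")))
    stop("role must be 'explanatory' or 'response'")
  if (sum(s$role == "response") != 1L)
    stop("schema must declare exactly one response variable")
  if (!all(s$direction %in% c("increase", "decrease", "free")))
    stop("direction must be 'increase', 'decrease' or 'free'")
  bad <- s$intervenable & (s$role != "explanatory" | s$kind != "continuous")
  if (any(bad))
    stop("intervenable variables must be continuous explanatory variables: ",
         paste(s$name[bad], collapse = ", "))
  cats <- attr(s, "categories")
  for (v in s$name[s$kind == "discrete"]) {
    cv <- cats[[v]]
    if (is.null(cv) || length(cv) < 2L)
      stop("discrete variable '", v, "' must list at least 2 categories")
    if (anyDuplicated(cv))
      stop("duplicate categories for discrete variable '", v, "'")
  }
  invisible(s)
}

#' @export
print.ap_schema <- function(x, ...) {
  cat("<variable schema> ", nrow(x), " variables\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

response_var <- function(schema) schema$name[schema$role == "response"]

explanatory_vars <- function(schema) schema$name[schema$role == "explanatory"]

continuous_vars <- function(schema, role = NULL) {
  keep <- schema$kind == "continuous"
  if (!is.null(role)) keep <- keep & schema$role == role
  schema$name[keep]
}

discrete_vars <- function(schema, role = NULL) {
  keep <- schema$kind == "discrete"
  if (!is.null(role)) keep <- keep & schema$role == role
  schema$name[keep]
}

intervention_vars <- function(schema) schema$name[schema$intervenable]

var_categories <- function(schema, name) attr(schema, "categories")[[name]]

#' Read or write a variable schema
#'
#' Schemas are serialized as YAML or JSON (chosen by file extension): a list
#' of records with fields `name`, `kind`, `role`, `intervenable`, `direction`
#' and, for discrete variables, `categories`.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_schema()` returns an `ap_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  cats <- list()
  get1 <- function(r, f, default) if (is.null(r[[f]])) default else r[[f]]
  for (r in recs) {
    if (identical(get1(r, "kind", ""), "discrete"))
      cats[[r$name]] <- unlist(r$categories)
  }
  variable_schema(
    name = vapply(recs, function(r) r$name, ""),
    kind = vapply(recs, function(r) r$kind, ""),
    role = vapply(recs, function(r) r$role, ""),
    intervenable = vapply(recs, function(r) isTRUE(get1(r, "intervenable", FALSE)), TRUE),
    direction = vapply(recs, function(r) get1(r, "direction", "free"), ""),
    categories = cats
  )
}

#' @rdname read_schema
#' @param schema an `ap_schema` object.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  recs <- lapply(seq_len(nrow(schema)), function(i) {
    r <- list(
      name = schema$name[i], kind = schema$kind[i], role = schema$role[i],
      intervenable = schema$intervenable[i], direction = schema$direction[i]
    )
    if (schema$kind[i] == "discrete")
      r$categories <- as.list(var_categories(schema, schema$name[i]))
    r
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
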