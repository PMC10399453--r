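#' @useDynLib magiclasso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor median predict quantile rnorm runif rbinom sd var coef
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

ROLES <- c("continuous", "categorical", "excluded")
EXCLUSION_REASONS <- c("unstructured", "date", "free_text", "array",
                       "icd_code", "none")

#' Construct a variable schema
#'
#' A schema declares, for every column of a phenotype table, whether it is a
#' continuous predictor, a categorical predictor with a fixed set of levels,
#' or excluded from modelling (free text, dates, array fields, ICD code
#' matrices and other unstructured content).
#'
#' @param name character vector of variable names.
#' @param role character vector, each one of `"continuous"`,
#'   `"categorical"`, `"excluded"`.
#' @param levels list of character vectors of declared category labels, one
#'   per variable (`NULL` entries for non-categorical variables).
#' @param exclusion_reason character vector; required non-`"none"` for
#'   excluded variables.
#' @return A data frame of class `"var_schema"` with columns `name`, `role`,
#'   `levels` (list column) and `exclusion_reason`.
#' @export
var_schema <- function(name, role, levels = NULL, exclusion_reason = NULL) {
  name <- as.character(name)
  p <- length(name)
  role <- rep_len(as.character(role), p)
  if (is.null(levels)) levels <- vector("list", p)
  if (!is.list(levels)) levels <- list(levels)
  levels <- rep_len(levels, p)
  if (is.null(exclusion_reason)) exclusion_reason <- "none"
  exclusion_reason <- rep_len(as.character(exclusion_reason), p)
  out <- data.frame(name = name, role = role,
                    exclusion_reason = exclusion_reason,
                    stringsAsFactors = FALSE)
  out$levels <- lapply(levels, function(l) if (is.null(l)) NULL else as.character(l))
  class(out) <- c("var_schema", "data.frame")
  validate_schema(out)
  out
}

validate_schema <- function(schema) {
  if (anyDuplicated(schema$name))
    stop("duplicate variable names in schema: ",
         paste(unique(schema$name[duplicated(schema$name)]), collapse = ", "))
  bad_role <- setdiff(schema$role, ROLES)
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  bad_reason <- setdiff(schema$exclusion_reason, EXCLUSION_REASONS)
  if (length(bad_reason))
    stop("unknown exclusion_reason(s): ", paste(bad_reason, collapse = ", "))
  for (i in seq_len(nrow(schema))) {
    lv <- schema$levels[[i]]
    if (schema$role[i] == "categorical") {
      if (length(lv) < 2L)
        stop("categorical variable '", schema$name[i],
             "' must declare at least 2 levels")
      if (anyDuplicated(lv))
        stop("duplicate levels for variable '", schema$name[i], "'")
    } else if (length(lv))
      stop("variable '", schema$name[i], "' has role '", schema$role[i],
           "' and must not declare levels")
    if (schema$role[i] == "excluded" && schema$exclusion_reason[i] == "none")
      stop("excluded variable '", schema$name[i],
           "' requires a non-'none' exclusion_reason")
    if (schema$role[i] != "excluded" && schema$exclusion_reason[i] != "none")
      stop("variable '", schema$name[i],
           "' is not excluded but carries an exclusion_reason")
  }
  invisible(schema)
}

#' Read a variable schema from YAML or JSON
#'
#' The file holds a `variables` list with per-variable `name`, `role`,
#' optional `levels` and `exclusion_reason`, plus an optional top-level
#' `outcome` naming the target variable.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A `"var_schema"` data frame; if the file names an outcome it is
#'   attached as attribute `"outcome"`.
#' @export
read_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
  vars <- raw$variables
  if (is.null(vars)) stop("schema file lacks a 'variables' entry: ", path)
  sch <- var_schema(
    name = vapply(vars, function(v) as.character(v$name), ""),
    role = vapply(vars, function(v) as.character(v$role), ""),
    levels = lapply(vars, function(v) if (is.null(v$levels)) NULL else unlist(v$levels)),
    exclusion_reason = vapply(vars, function(v)
      if (is.null(v$exclusion_reason)) "none" else as.character(v$exclusion_reason), ""))
  if (!is.null(raw$outcome)) attr(sch, "outcome") <- as.character(raw$outcome)
  sch
}

#' Write a variable schema to YAML or JSON
#'
#' @param schema a `"var_schema"` data frame.
#' @param path destination path; format chosen by extension.
#' @param outcome optional outcome variable name stored at top level.
#' @export
write_schema <- function(schema, path, outcome = NULL) {
  vars <- lapply(seq_len(nrow(schema)), function(i) {
    v <- list(name = schema$name[i], role = schema$role[i])
    if (length(schema$levels[[i]])) v$levels <- as.list(schema$levels[[i]])
    if (schema$exclusion_reason[i] != "none")
      v$exclusion_reason <- schema$exclusion_reason[i]
    v
  })
  obj <- list(variables = vars)
  if (!is.null(outcome)) obj <- c(list(outcome = outcome), obj)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  else
    yaml::write_yaml(obj, path)
  invisible(path)
}

#' Construct a phenotype table
#'
#' The central container: a subjects-by-variables grid of partially observed
#' values together with its variable schema and the designated outcome.
#' Continuous columns are numeric, categorical columns character;
#' missingness is `NA`.
#'
#' @param data data frame of values (one column per schema variable).
#' @param schema a `"var_schema"` data frame covering every column of `data`.
#' @param outcome name of the target variable (must be non-excluded).
#' @param subject_ids unique subject identifiers; defaults to row numbers.
#' @return An object of class `"pheno_table"`.
#' @export
pheno_table <- function(data, schema, outcome, subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(data)))
  subject_ids <- as.character(subject_ids)
  x <- structure(list(data = as.data.frame(data, stringsAsFactors = FALSE),
                      schema = schema, outcome = outcome,
                      subject_ids = subject_ids),
                 class = "pheno_table")
  validate_pheno_table(x)
  x
}

validate_pheno_table <- function(x) {
  validate_schema(x$schema)
  if (anyDuplicated(x$subject_ids)) stop("subject_ids are not unique")
  if (length(x$subject_ids) != nrow(x$data))
    stop("subject_ids length does not match row count")
  extra <- setdiff(names(x$data), x$schema$name)
  if (length(extra))
    stop("columns absent from schema: ", paste(extra, collapse = ", "))
  miss <- setdiff(x$schema$name, names(x$data))
  if (length(miss))
    stop("schema variables absent from data: ", paste(miss, collapse = ", "))
  oi <- match(x$outcome, x$schema$name)
  if (is.na(oi)) stop("outcome '", x$outcome, "' is not a schema variable")
  if (x$schema$role[oi] == "excluded")
    stop("outcome '", x$outcome, "' is schema-excluded")
  for (i in seq_len(nrow(x$schema))) {
    nm <- x$schema$name[i]
    col <- x$data[[nm]]
    if (x$schema$role[i] == "categorical") {
      obs <- col[!is.na(col)]
      bad <- setdiff(unique(obs), x$schema$levels[[i]])
      if (length(bad))
        stop("variable '", nm, "' contains undeclared level(s): ",
             paste(bad, collapse = ", "))
    } else if (x$schema$role[i] == "continuous" && !is.numeric(col)) {
      stop("continuous variable '", nm, "' is not numeric")
    }
  }
  invisible(x)
}

#' @export
dim.pheno_table <- function(x) c(length(x$subject_ids), nrow(x$schema))

#' @export
print.pheno_table <- function(x, ...) {
  n_miss <- sum(is.na(as.matrix(x$data)))
  cat("Phenotype table: ", nrow(x$data), " subjects x ", nrow(x$schema),
      " variables\n", sep = "")
  cat("  outcome: ", x$outcome, " (observed in ",
      sum(!is.na(x$data[[x$outcome]])), " subjects)\n", sep = "")
  cat("  roles: ", sum(x$schema$role == "continuous"), " continuous, ",
      sum(x$schema$role == "categorical"), " categorical, ",
      sum(x$schema$role == "excluded"), " excluded\n", sep = "")
  cat("  missing cells: ", n_miss, " (",
      round(100 * n_miss / prod(dim(x)), 1), "%)\n", sep = "")
  invisible(x)
}

#' Read a phenotype table from delimited text
#'
#' Cells equal to any missing marker become `NA`; categorical cells are
#' validated against the schema's declared levels.
#'
#' @param path path to a CSV (or TSV, by extension) file with a header row.
#' @param schema a `"var_schema"` or path to a schema file.
#' @param outcome outcome name; defaults to the schema file's `outcome`.
#' @param missing_markers strings treated as missing (default `""`, `"NA"`).
#' @param id_column optional name of a subject-identifier column (not a
#'   schema variable).
#' @return A `"pheno_table"`.
#' @export
read_pheno_table <- function(path, schema, outcome = NULL,
                             missing_markers = c("", "NA"),
                             id_column = NULL) {
  if (is.character(schema) && length(schema) == 1L) schema <- read_schema(schema)
  if (is.null(outcome)) outcome <- attr(schema, "outcome")
  if (is.null(outcome)) stop("no outcome given and none in the schema file")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, na.strings = NULL)
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(raw)) stop("id column '", id_column, "' not found")
    ids <- raw[[id_column]]
    raw[[id_column]] <- NULL
  }
  unknown <- setdiff(names(raw), schema$name)
  if (length(unknown))
    stop("column(s) not declared in schema: ", paste(unknown, collapse = ", "))
  for (nm in names(raw)) {
    col <- raw[[nm]]
    col[col %in% missing_markers] <- NA
    role <- schema$role[match(nm, schema$name)]
    if (role == "continuous") {
      num <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & is.na(num)
      if (any(bad))
        stop("continuous variable '", nm, "' has non-numeric value(s): ",
             paste(head(unique(col[bad]), 3), collapse = ", "))
      col <- num
    }
    raw[[nm]] <- col
  }
  raw <- raw[, schema$name, drop = FALSE]
  pheno_table(raw, schema, outcome, subject_ids = ids)
}

#' Write a phenotype table to delimited text
#'
#' Missing cells are serialized as the empty string, so a round trip through
#' [read_pheno_table()] reproduces values and missingness exactly.
#'
#' @param x a `"pheno_table"`.
#' @param path destination CSV/TSV path.
#' @param id_column name under which subject identifiers are written
#'   (`NULL` to omit).
#' @export
write_pheno_table <- function(x, path, id_column = "subject_id") {
  out <- x$data
  for (nm in names(out)) out[[nm]] <- as.character(out[[nm]])
  if (!is.null(id_column)) out <- cbind(stats::setNames(
    data.frame(x$subject_ids, stringsAsFactors = FALSE), id_column), out)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Split subjects by outcome availability
#'
#' Partitions subjects into the measured set (outcome observed; the training
#' set) and the unmeasured set (outcome missing; the prediction targets).
#'
#' @param table a `"pheno_table"`.
#' @return An object of class `"measured_split"`: a list with integer index
#'   vectors `measured_idx`, `unmeasured_idx` and counts `n_measured`,
#'   `n_unmeasured`, `n_total`.
#' @export
split_measured <- function(table) {
  obs <- !is.na(table$data[[table$outcome]])
  if (!any(obs)) stop("outcome '", table$outcome,
                      "' is never observed: nothing to train on")
  out <- structure(list(measured_idx = which(obs),
                        unmeasured_idx = which(!obs),
                        n_measured = sum(obs),
                        n_unmeasured = sum(!obs),
                        n_total = length(obs)),
                   class = "measured_split")
  out
}

#' @export
print.measured_split <- function(x, ...) {
  cat("Measured/unmeasured split: ", x$n_measured, " measured + ",
      x$n_unmeasured, " unmeasured = ", x$n_total, " subjects\n", sep = "")
  invisible(x)
}

predictor_names <- function(table) {
  setdiff(table$schema$name[table$schema$role != "excluded"], table$outcome)
}

# restrict a table to a variable subset (outcome always kept)
subset_variables <- function(table, variables) {
  keep <- union(variables, table$outcome)
  keep <- table$schema$name[table$schema$name %in% keep]  # schema order
  sch <- table$schema[match(keep, table$schema$name), , drop = FALSE]
  class(sch) <- c("var_schema", "data.frame")
  pheno_table(table$data[, keep, drop = FALSE], sch, table$outcome,
              table$subject_ids)
}

#' @importFrom utils write.table
NULL
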