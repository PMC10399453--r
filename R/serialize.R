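# Model and report serialization.  A saved model JSON is sufficient to
# re-predict without refitting.

#' Write a fitted model to JSON
#'
#' @param model a `"magic_model"`.
#' @param path destination `.json` path.
#' @export
write_magic_model <- function(model, path) {
  cfg <- model$config
  cfg$parsimony <- as.list(cfg$parsimony)
  obj <- list(format = "magiclasso-model", version = 1L,
              outcome = model$outcome,
              variables = as.list(model$variables),
              terms = model$terms,
              intercept = model$intercept,
              y_mean = model$y_mean,
              lambda_min = model$lambda_min,
              cv_error = model$cv_error,
              n_train = model$n_train,
              chosen_step = model$chosen_step,
              holdout_correlation = model$holdout_correlation,
              seed = model$seed,
              config = cfg)
  # 17 significant digits: lossless round trip for doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path path written by [write_magic_model()].
#' @return A `"magic_model"` usable with [predict.magic_model()].
#' @export
read_magic_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "magiclasso-model"))
    stop("not a magiclasso model file: ", path)
  terms <- as.data.frame(obj$terms, stringsAsFactors = FALSE)
  if (is.null(terms$level)) terms$level <- NA_character_
  terms$level <- as.character(terms$level)
  terms$level[terms$level %in% c("NA", "")] <- NA_character_
  structure(list(outcome = obj$outcome,
                 variables = unlist(obj$variables),
                 terms = terms,
                 intercept = obj$intercept,
                 y_mean = obj$y_mean,
                 lambda_min = obj$lambda_min,
                 cv_error = obj$cv_error,
                 n_train = obj$n_train,
                 chosen_step = obj$chosen_step,
                 holdout_correlation = obj$holdout_correlation,
                 seed = obj$seed,
                 config = obj$config),
            class = "magic_model")
}

#' Write per-subject predictions to CSV
#'
#' @param predictions data frame from [predict.magic_model()].
#' @param path destination `.csv` path.
#' @export
write_predictions <- function(predictions, path) {
  write.csv(predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
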