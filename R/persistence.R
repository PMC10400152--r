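# Model persistence: self-describing JSON with a schema version, holding
# hyperparameters, centering/standardization constants and weights at full
# double precision.

MODEL_SCHEMA_VERSION <- "1.0"

#' Write a fitted model to JSON
#'
#' Supports `plsr_model`, `mlp_model` and [calibrate()] bundles.
#'
#' @param model the fitted model object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1L]
  if (!kind %in% c("plsr_model", "mlp_model", "calibration_model")) {
    fail("write_model: cannot persist objects of class '%s'", kind)
  }
  payload <- list(schema = MODEL_SCHEMA_VERSION, kind = kind,
                  fields = unclass(model))
  if (kind == "calibration_model") {
    payload$fields$model <- list(kind = class(model$model)[1L],
                                 fields = unclass(model$model))
    cv <- unclass(model$cv)
    cv$folds <- unclass(cv$folds)
    payload$fields$cv <- cv
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

restore_model <- function(kind, fields) {
  f <- fields
  if (kind == "plsr_model") {
    for (m in c("R", "P", "B")) f[[m]] <- as.matrix(f[[m]])
    f$Q <- as.numeric(unlist(f$Q))
    f$x_mean <- as.numeric(unlist(f$x_mean))
  } else if (kind == "mlp_model") {
    f$W1 <- as.matrix(f$W1)
    for (v in c("b1", "w2", "x_mean", "x_sd")) f[[v]] <- as.numeric(unlist(f[[v]]))
  } else {
    fail("read_model: unknown model kind '%s'", kind)
  }
  structure(f, class = kind)
}

#' Read a fitted model from JSON
#'
#' @param path file written by [write_model()].
#' @return The restored model object; predictions match the original.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, MODEL_SCHEMA_VERSION)) {
    fail("read_model: unsupported schema '%s' (expected %s)",
         payload$schema, MODEL_SCHEMA_VERSION)
  }
  if (payload$kind == "calibration_model") {
    f <- payload$fields
    inner <- restore_model(f$model$kind, f$model$fields)
    f$model <- inner
    f$cv$grid <- as.data.frame(f$cv$grid)
    class(f$cv) <- "cv_result"
    return(structure(f, class = "calibration_model"))
  }
  restore_model(payload$kind, payload$fields)
}
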