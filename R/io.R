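# Formats: localization CSV (the pipeline's exchange format), JSON
# serialization of transforms, drift traces and ROIs.

LOC_COLUMNS <- c("frame", "x_nm", "y_nm", "intensity", "width_nm",
                 "asymmetry", "channel")

#' Write a localization table to CSV
#'
#' Canonical schema: `frame,x_nm,y_nm,intensity,width_nm,asymmetry,channel`;
#' any extra columns (e.g. `label_id`, `z_nm`) are written after the
#' mandatory ones and survive a round-trip.  Full double precision is
#' preserved (15 significant digits).
#'
#' @param table localization data.frame.
#' @param path output file.
#' @export
write_localizations <- function(table, path) {
  missing <- setdiff(LOC_COLUMNS, names(table))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(table), LOC_COLUMNS)
  data.table::fwrite(table[, c(LOC_COLUMNS, extra), drop = FALSE], path)
  invisible(path)
}

#' Read a localization table from CSV
#' @param path CSV file with the canonical schema (extra columns allowed).
#' @return localization data.frame.
#' @export
read_localizations <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  missing <- setdiff(LOC_COLUMNS, names(tab))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Serialize a transform, drift trace or estimator result to JSON
#' @param x a `transform_model`, `drift_trace` or `estimator_result`.
#' @param path output file.
#' @export
write_model_json <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  if (!is.null(obj$coef)) obj$coef <- as.vector(t(obj$coef))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a transform or drift trace written by [write_model_json()]
#' @param path JSON file.
#' @return the deserialized object with its class restored.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "transform_model")) {
    ncoef <- if (obj$kind == "affine") 3 else 6
    obj$coef <- matrix(unlist(obj$coef), nrow = 2, byrow = TRUE, ncol = ncoef)
  }
  structure(obj, class = cls)
}

#' Write line/rect ROIs to a JSON file
#' @param rois list of [line_roi()] / [rect_roi()] objects.
#' @param path output file.
#' @export
write_rois_json <- function(rois, path) {
  items <- lapply(rois, function(r) {
    o <- unclass(r); o$.class <- class(r)[1]; o
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROIs written by [write_rois_json()]
#' @param path JSON file.
#' @return list of ROI objects.
#' @export
read_rois_json <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  lapply(items, function(o) {
    cls <- o$.class; o$.class <- NULL
    o <- lapply(o, function(f) if (is.list(f)) unlist(f) else f)
    structure(o, class = cls)
  })
}
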