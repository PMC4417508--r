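# All user-tunable parameters of the pipeline, with the published defaults.

.param_defaults <- list(
  pixel_size              = 0.645,  # um per pixel
  outline_channel         = 1L,     # red
  nuclei_channel          = 3L,     # blue
  type_channel            = 2L,     # green
  object_channel          = 2L,     # green
  segmentation_smoothing  = 5,      # h-minima depth, 8-bit units
  nuclear_smoothing       = 5,
  object_smoothing        = 10,
  min_fiber_area          = 100,    # um^2
  max_fiber_area          = 5000,   # um^2
  max_eccentricity        = 0.95,
  min_convexity           = 0.8,
  nuclear_border_distance = 10,     # um
  min_nuclear_size        = 5,      # um^2
  output_folder           = "output"
)

#' Default analysis parameters
#'
#' Returns the built-in defaults for every user parameter of the pipeline:
#' pixel size 0.645 um/px; outline/nuclei/type/object channels 1/3/2/2;
#' segmentation, nuclear and object smoothing depths 5, 5, 10 (8-bit
#' intensity units); fiber area bounds 100-5000 um^2; maximum eccentricity
#' 0.95; minimum convexity 0.8; nuclear border distance 10 um; minimum
#' nuclear size 5 um^2.
#'
#' @return An object of class `analysis_params` (named list).
#' @export
default_params <- function() {
  structure(.param_defaults, class = "analysis_params")
}

validate_params <- function(p) {
  num <- function(field, lo = -Inf, hi = Inf) {
    v <- p[[field]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || is.na(v) ||
        v < lo || v > hi)
      stop("invalid parameter '", field, "': must be a number in [",
           lo, ", ", hi, "]", call. = FALSE)
  }
  num("pixel_size", lo = .Machine$double.eps)
  for (f in c("outline_channel", "nuclei_channel", "type_channel",
              "object_channel")) num(f, 1, 3)
  for (f in c("segmentation_smoothing", "nuclear_smoothing",
              "object_smoothing")) num(f, 0)
  num("min_fiber_area", 0); num("max_fiber_area", 0)
  num("max_eccentricity", 0, 1); num("min_convexity", 0, 1)
  num("nuclear_border_distance", 0); num("min_nuclear_size", 0)
  if (p$min_fiber_area >= p$max_fiber_area)
    stop("invalid parameter 'min_fiber_area': must be < max_fiber_area",
         call. = FALSE)
  if (!is.character(p$output_folder))
    stop("invalid parameter 'output_folder': must be a path", call. = FALSE)
  invisible(p)
}

#' Load analysis parameters from a key/value file
#'
#' The configuration format is a plain-text `key = value` file (one pair
#' per line, `#` comments allowed) holding any subset of the parameter
#' names in [default_params()]; unset keys take their defaults. With
#' `path = NULL` the built-in defaults are returned. Out-of-range values
#' raise a validation error naming the offending field.
#'
#' @param path path to a parameter file, or `NULL` for the defaults.
#' @return An `analysis_params` object.
#' @seealso [load_params_excel()] for spreadsheet parameter tables,
#'   [write_params()] to persist a configuration.
#' @export
load_params <- function(path = NULL) {
  p <- .param_defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("cannot read parameter file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed parameter line: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(p))
        stop("unknown parameter '", key, "'")
      p[[key]] <- if (key == "output_folder") val else {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v)) stop("invalid parameter '", key, "': not a number")
        v
      }
    }
  }
  for (f in grep("_channel$", names(p), value = TRUE))
    p[[f]] <- as.integer(p[[f]])
  p <- structure(p, class = "analysis_params")
  validate_params(p)
  p
}

#' @rdname load_params
#' @param params an `analysis_params` object to write.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "analysis_params"))
  lines <- vapply(names(.param_defaults), function(k)
    paste(k, "=", format(params[[k]], scientific = FALSE)), "")
  writeLines(lines, path)
  invisible(path)
}

# Table-1-shaped label -> field name, matched on the lowercased label
.param_label_patterns <- c(
  pixel_size              = "pixel size",
  outline_channel         = "outline channel",
  nuclei_channel          = "nuclei channel",
  type_channel            = "type channel",
  object_channel          = "object channel",
  segmentation_smoothing  = "segmentation smoothing",
  nuclear_smoothing       = "nuclear smoothing",
  object_smoothing        = "object smoothing",
  min_fiber_area          = "minimum fiber area",
  max_fiber_area          = "maximum fiber area",
  max_eccentricity        = "eccentricity",
  min_convexity           = "convexity",
  nuclear_border_distance = "distance from bo",
  min_nuclear_size        = "nuclear size"
)

#' Load parameters from a two-column spreadsheet
#'
#' Convenience reader for spreadsheets laid out like the published default
#' parameter table: one row per parameter, first column the label, second
#' the value. Labels are matched case-insensitively on their distinctive
#' phrase. Requires the `readxl` package.
#'
#' @param path path to an `.xls`/`.xlsx` file.
#' @return An `analysis_params` object.
#' @export
load_params_excel <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("load_params_excel() requires the 'readxl' package")
  if (!file.exists(path)) stop("cannot read parameter file: ", path)
  sheet <- readxl::read_excel(path, col_names = FALSE)
  if (ncol(sheet) < 2L) stop("parameter sheet must have two columns")
  labels <- tolower(as.character(sheet[[1]]))
  values <- sheet[[2]]
  p <- .param_defaults
  for (field in names(.param_label_patterns)) {
    hit <- grep(.param_label_patterns[[field]], labels, fixed = TRUE)
    if (length(hit)) {
      v <- suppressWarnings(as.numeric(values[[hit[1]]]))
      if (is.na(v)) stop("invalid parameter '", field, "': not a number")
      p[[field]] <- v
    }
  }
  out_hit <- grep("output folder", labels, fixed = TRUE)
  if (length(out_hit)) p$output_folder <- as.character(values[[out_hit[1]]])
  for (f in grep("_channel$", names(p), value = TRUE))
    p[[f]] <- as.integer(p[[f]])
  p <- structure(p, class = "analysis_params")
  validate_params(p)
  p
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("<analysis_params>\n")
  for (k in names(.param_defaults))
    cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

# channel_roles view of the parameter set
params_roles <- function(params) {
  channel_roles(outline = params$outline_channel,
                nuclei = params$nuclei_channel,
                type = params$type_channel,
                object = params$object_channel)
}
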