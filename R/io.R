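# CSV readers/writers and JSON run configuration.
#
# Series formats (UTF-8, '.' decimal, RFC-4180):
#   flow:      time_s,velocity_mps,t_air_K      (t_air_C accepted, converted)
#   voltage:   time_s,t_upper_K,dT_K,voltage_V
#   heartbeat: time_s,value

.schemaCols <- list(
  flow = c("time_s", "velocity_mps", "t_air_K"),
  voltage = c("time_s", "t_upper_K", "dT_K", "voltage_V"),
  heartbeat = c("time_s", "value"))

.parseError <- function(path, msg, row = NULL) {
  where <- if (is.null(row)) path else sprintf("%s (row %d)", path, row)
  stop(sprintf("parse error in %s: %s", where, msg), call. = FALSE)
}

#' Read a time-series CSV
#'
#' Reads and validates one of the package's series formats.  Celsius
#' temperature columns (`t_air_C`) are converted to kelvin on read.
#' Malformed input (missing columns, NA values, non-increasing timestamps,
#' empty file) raises a parse error naming the offending row.
#'
#' @param path CSV file path.
#' @param schema `"flow"`, `"voltage"` or `"heartbeat"`.
#' @return a [FlowSignal-class], [VoltageTrace-class] (voltage traces are
#'   returned as a data.frame since alpha/Tlower are not stored in the
#'   file) or heartbeat data.frame.  For `schema = "voltage"` a data.frame
#'   with the file's columns.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTimeseries(flowSignal(0:4 / 10, 1, 311.15), f)
#' readTimeseries(f, "flow")
#' @export
readTimeseries <- function(path, schema = c("flow", "voltage", "heartbeat")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) .parseError(path, "file not found")
  if (file.size(path) == 0) .parseError(path, "empty file")
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) .parseError(path, conditionMessage(e)))
  if (nrow(df) == 0L) .parseError(path, "no data rows")
  want <- .schemaCols[[schema]]
  if (schema == "flow" && "t_air_C" %in% names(df) &&
      !"t_air_K" %in% names(df)) {
    df$t_air_K <- celsiusToKelvin(df$t_air_C)
    df$t_air_C <- NULL
  }
  missing <- setdiff(want, names(df))
  if (length(missing))
    .parseError(path, paste("missing column(s):",
                            paste(missing, collapse = ", ")))
  for (cn in want) {
    if (is.logical(df[[cn]]) && all(is.na(df[[cn]])))
      df[[cn]] <- as.numeric(df[[cn]])  # all-NA column reads as logical
    if (!is.numeric(df[[cn]]))
      .parseError(path, sprintf("column '%s' is not numeric", cn))
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad))
      .parseError(path, sprintf("non-finite value in '%s'", cn), bad[1L])
  }
  tt <- df$time_s
  if (length(tt) > 1L) {
    bad <- which(diff(tt) <= 0)
    if (length(bad))
      .parseError(path, "timestamps must be strictly increasing",
                  bad[1L] + 1L)
  }
  switch(schema,
    flow = flowSignal(tt, df$velocity_mps, df$t_air_K),
    voltage = df[, want],
    heartbeat = df[, want])
}

#' Write a series object to CSV
#'
#' @param x a [FlowSignal-class], [VoltageTrace-class] or heartbeat
#'   data.frame (`time_s`, `value`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTimeseries <- function(x, path) {
  df <- if (is(x, "FlowSignal")) {
    data.frame(time_s = x@t, velocity_mps = x@v, t_air_K = x@Tair)
  } else if (is(x, "VoltageTrace")) {
    data.frame(time_s = x@t, t_upper_K = x@Tupper, dT_K = x@dT,
               voltage_V = x@V)
  } else if (is.data.frame(x) && all(c("time_s", "value") %in% names(x))) {
    x[, c("time_s", "value")]
  } else stop("unsupported object for writeTimeseries", call. = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.defaultConfig <- function() {
  list(
    fluid = list(kappa = 0.0257, rhoAir = 1.2, mu = 1.8e-5, Pr = 0.71),
    plate = list(L = 0.01, A = 1e-4, m = 1e-5, cp = 500,
                 alphaDevice = 0.04125, TlowerC = 32),
    leg = list(length = 2.5e-3, crossSection = 1.96e-6, nNodes = 101),
    synth = list(fs = 100, duration = 8, nPerCombo = 6),
    detect = list(detect = 0.10, moderate = 0.245, severe = 0.335,
                  minSpacing = 0.45, window = 5, minCount = 3),
    train = list(speechSeeds = 5, size = 32, nrounds = 400,
                 testFraction = 0.25),
    seed = 1,
    outputDir = "airtherm-run",
    logLevel = "INFO")
}

#' Read and validate a run configuration
#'
#' JSON with blocks `fluid`, `plate`, `leg`, `synth`, `detect`, `train` and
#' scalars `seed`, `outputDir`, `logLevel`.  Missing blocks take package
#' defaults; unknown keys (top level or within a block) are rejected, and
#' numeric fields are validated by constructing the corresponding objects,
#' so an invalid value fails at load, before any stage runs.  `TlowerC` in
#' the `plate` block is Celsius and converted on read.
#'
#' @param path JSON file path (`NULL` gives the default configuration).
#' @return validated configuration list, with constructed `fluid`, `plate`
#'   objects under `$objects`.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    extra <- setdiff(names(user), names(cfg))
    if (length(extra))
      stop("unknown config key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    for (blk in names(user)) {
      if (is.list(cfg[[blk]])) {
        bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
        if (length(bad))
          stop(sprintf("unknown key(s) in '%s': %s", blk,
                       paste(bad, collapse = ", ")), call. = FALSE)
        cfg[[blk]][names(user[[blk]])] <- user[[blk]]
      } else cfg[[blk]] <- user[[blk]]
    }
  }
  fluid <- do.call(fluidProperties, cfg$fluid)
  plate <- with(cfg$plate,
    devicePlate(L = L, A = A, m = m, cp = cp, alphaDevice = alphaDevice,
                Tlower = celsiusToKelvin(TlowerC)))
  if (cfg$synth$duration <= 0 || cfg$synth$fs < 20)
    stop("synth block: need duration > 0 and fs >= 20", call. = FALSE)
  cfg$seed <- .assertCount(cfg$seed, "seed")
  cfg$objects <- list(fluid = fluid, plate = plate)
  cfg
}
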