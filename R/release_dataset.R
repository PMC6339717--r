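#' Construct a dissolution profile
#'
#' A `release_dataset` holds one cumulative dissolution--time profile: ordered
#' time points, cumulative drug dissolution in percent, and a symmetric
#' per-point error bar in percent. The error bars are interpreted as one
#' standard deviation of independent Gaussian measurement noise; they supply
#' the weights of the chi-square objective used throughout the package
#' (see [chi2_stat()]).
#'
#' @param time Numeric vector of sampling times, strictly increasing, all
#'   `>= 0`, in units of `time_unit`.
#' @param dissolution Numeric vector of cumulative dissolution values (%).
#' @param error Numeric vector of symmetric error bars (%), all `> 0`.
#' @param time_unit Unit of `time`: `"hour"` or `"day"`.
#' @param label Short text label for reports.
#'
#' @return An object of class `release_dataset`: a data frame with columns
#'   `time`, `dissolution_percent`, `error` and attributes `time_unit` and
#'   `label`.
#'
#' @details At least two points are required. Dissolution values outside
#'   \[0, 100\] raise a warning, not an error, so that user data with assay
#'   overshoot can still be fitted.
#'
#' @examples
#' ds <- release_dataset(c(0.5, 1, 2), c(12, 25, 41), c(2, 2, 3))
#' ds
#' @seealso [load_fixture()], [read_profile()], [write_profile()]
#' @export
release_dataset <- function(time, dissolution, error,
                            time_unit = c("hour", "day"), label = "") {
  time_unit <- match.arg(time_unit)
  n <- length(time)
  if (length(dissolution) != n || length(error) != n) {
    stop("`time`, `dissolution` and `error` must have equal length", call. = FALSE)
  }
  if (n < 2L) stop("a release dataset needs at least 2 points", call. = FALSE)
  if (!all(is.finite(time)) || !all(is.finite(dissolution)) || !all(is.finite(error))) {
    stop("all values must be finite", call. = FALSE)
  }
  if (any(time < 0)) {
    stop("negative time at row ", which(time < 0)[1L], call. = FALSE)
  }
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop("times must be strictly increasing; violation at row ", bad[1L] + 1L,
         " (t = ", time[bad[1L] + 1L], ")", call. = FALSE)
  }
  bad <- which(error <= 0)
  if (length(bad)) {
    stop("error bars must be positive; row ", bad[1L], " has error = ",
         error[bad[1L]], call. = FALSE)
  }
  if (any(dissolution < 0 | dissolution > 100)) {
    warning("dissolution values outside [0, 100] %", call. = FALSE)
  }
  structure(
    data.frame(time = as.numeric(time),
               dissolution_percent = as.numeric(dissolution),
               error = as.numeric(error)),
    time_unit = time_unit, label = as.character(label)[1L],
    class = c("release_dataset", "data.frame")
  )
}

#' @export
print.release_dataset <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Release dataset", if (nzchar(lab)) paste0("'", lab, "'") else "",
      "- ", nrow(x), " points, time in ", attr(x, "time_unit"), "s\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Time unit of a dissolution profile
#' @param ds A [release_dataset()].
#' @return `"hour"` or `"day"`.
#' @export
time_unit <- function(ds) attr(ds, "time_unit")

.fixture_names <- c("dox", "mtx", "plga", "ca_plga", "pd_pcl_nc")

#' Load a packaged dissolution profile
#'
#' Five published profiles ship with the package: `dox` and `mtx`
#' (doxorubicin and mitoxantrone released from layer-by-layer-coated liposomal
#' nanoparticles; 10 points over 1--48 h), `plga` and `ca_plga` (simvastatin
#' from PLGA-based nanoparticles; 12 points over 1--30 d), and `pd_pcl_nc`
#' (poly(epsilon-caprolactone) nanocapsules; 8 points over 0--6 h).
#'
#' @param name One of `"dox"`, `"mtx"`, `"plga"`, `"ca_plga"`, `"pd_pcl_nc"`.
#' @return A [release_dataset()].
#' @examples
#' load_fixture("dox")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% .fixture_names) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(.fixture_names, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "relkin",
                      mustWork = TRUE)
  read_profile(path)
}

#' Read a dissolution profile from CSV
#'
#' The dialect is comma-separated with header
#' `time,dissolution_percent,error`. The time unit is carried out-of-band:
#' either as a metadata comment line `# time_unit=hour` (or `day`) before the
#' header, or via the `time_unit` argument, which takes precedence. An
#' optional `# label=...` line sets the dataset label.
#'
#' @param source Path to a CSV file, or a connection.
#' @param time_unit Optional override of the unit recorded in the file.
#'   Required if the file carries no `# time_unit=` line.
#' @return A [release_dataset()]; all dataset invariants are enforced, and a
#'   violation names the offending row.
#' @export
read_profile <- function(source, time_unit = NULL) {
  lines <- readLines(source)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1L]))
  }
  if (is.null(time_unit)) time_unit <- get_meta("time_unit")
  if (is.null(time_unit)) {
    stop("no time unit: the file has no '# time_unit=' line and none was given",
         call. = FALSE)
  }
  label <- get_meta("label")
  if (is.null(label)) label <- ""
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  need <- c("time", "dissolution_percent", "error")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  release_dataset(df$time, df$dissolution_percent, df$error,
                  time_unit = time_unit, label = label)
}

#' Write a dissolution profile to CSV
#'
#' Emits the dialect read by [read_profile()]: metadata lines
#' `# time_unit=...` and (if the label is non-empty) `# label=...`, the
#' header, then one row per point at full precision, so that
#' `read_profile(write_profile(ds))` reproduces `ds` exactly.
#'
#' @param ds A [release_dataset()].
#' @param sink Path or connection to write to.
#' @return `sink`, invisibly.
#' @export
write_profile <- function(ds, sink) {
  stopifnot(inherits(ds, "release_dataset"))
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste0("# time_unit=", attr(ds, "time_unit")),
    if (nzchar(attr(ds, "label"))) paste0("# label=", attr(ds, "label")),
    "time,dissolution_percent,error",
    paste(fmt(ds$time), fmt(ds$dissolution_percent), fmt(ds$error), sep = ",")
  )
  writeLines(lines, sink)
  invisible(sink)
}
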