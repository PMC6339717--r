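#' Fit and rank all six release models on one profile
#'
#' Fits every model in the registry to the dataset by weighted chi-square
#' minimization, normalizes each minimum by its degrees of freedom
#' \eqn{N - m} (so one- and two-parameter models are comparable), and ranks
#' ascending: the best model is the one with the lowest
#' \eqn{\chi^2_{min}/\mathrm{d.o.f.}} A model whose fit fails outright is
#' kept as a flagged row rather than aborting the report.
#'
#' Exact ties (never observed on the packaged profiles) are broken in favour
#' of fewer parameters, then lexicographic model id.
#'
#' @param ds A [release_dataset()] with at least 3 points (so every model
#'   keeps at least one degree of freedom).
#' @param config A [fit_config()] passed to the nonlinear fits.
#' @param models Model identifiers to include; defaults to all six.
#' @return A `model_comparison`: list with `label`, `dataset`, ranked list
#'   `fits`, a summary data frame `table`, and `best_model`.
#' @examples
#' cmp <- compare_models(load_fixture("dox"))
#' cmp$best_model
#' @export
compare_models <- function(ds, config = fit_config(), models = kinetic_models()) {
  stopifnot(inherits(ds, "release_dataset"))
  if (nrow(ds) < 3L) stop("need at least 3 points to rank all models", call. = FALSE)
  fits <- lapply(models, function(id) {
    tryCatch(fit_model(id, ds, config), error = function(e) {
      spec <- model_spec(id)
      structure(list(model_id = spec$model_id, label = spec$label, m = spec$m,
                     params = stats::setNames(rep(NA_real_, spec$m), spec$param_names),
                     chi2_min = NA_real_, dof = nrow(ds) - spec$m,
                     chi2_per_dof = NA_real_, r2 = NA_real_, r2_adjusted = NA_real_,
                     converged = FALSE, n_starts_used = 0L, N = nrow(ds),
                     error = conditionMessage(e)),
                class = "release_fit")
    })
  })
  key <- vapply(fits, function(f) f$chi2_per_dof, numeric(1))
  key[is.na(key)] <- Inf
  m_of <- vapply(fits, function(f) f$m, integer(1))
  ids <- vapply(fits, function(f) f$model_id, character(1))
  ord <- order(key, m_of, ids)
  fits <- fits[ord]
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model_id, label = f$label, m = f$m,
               param_1 = f$params[1],
               param_2 = if (f$m >= 2) f$params[2] else NA_real_,
               chi2_min = f$chi2_min, dof = f$dof,
               chi2_per_dof = f$chi2_per_dof,
               r2_adjusted = f$r2_adjusted,
               converged = f$converged,
               row.names = NULL)
  }))
  structure(list(label = attr(ds, "label"), dataset = ds, fits = fits,
                 table = tab, best_model = fits[[1L]]$model_id),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}

.unit_symbol <- c(hour = "h", day = "d")

.param_units <- function(model_id, u) {
  switch(model_id,
    zero_order = c("%", paste0("% ", u, "^-1")),
    first_order = c("%", paste0(u, "^-1")),
    higuchi = paste0("% ", u, "^-1/2"),
    hixson_crowell = c("%^(1/3)", paste0("%^(1/3) ", u, "^-1")),
    power_law = c(paste0("% ", u, "^-n"), ""),
    hopfenberg = paste0("% ", u, "^-1"))
}

#' Render a model-comparison report
#'
#' Lays out one row per model in ranked order: model name with its parameter
#' count, the fitted parameters with units derived from the dataset's time
#' unit, and chi-square per degree of freedom. `text` and `markdown` round
#' displayed values to 4 decimals; `csv` keeps full precision for
#' machine consumption. A non-converged row is rendered with a flag, never
#' dropped. Ranking always uses full precision.
#'
#' @param report A `model_comparison` from [compare_models()].
#' @param style `"text"`, `"csv"` or `"markdown"`.
#' @return A character vector of report lines.
#' @examples
#' cat(render_report(compare_models(load_fixture("dox")), "markdown"), sep = "\n")
#' @export
render_report <- function(report, style = c("text", "csv", "markdown")) {
  style <- match.arg(style)
  stopifnot(inherits(report, "model_comparison"))
  u <- .unit_symbol[[time_unit(report$dataset)]]
  if (style == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    tab <- report$table
    tab$param_1 <- signif(tab$param_1, 10)
    tab$param_2 <- signif(tab$param_2, 10)
    tab$chi2_min <- signif(tab$chi2_min, 10)
    tab$chi2_per_dof <- signif(tab$chi2_per_dof, 10)
    tab$r2_adjusted <- signif(tab$r2_adjusted, 10)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    return(out)
  }
  fmt4 <- function(x) ifelse(is.na(x), "-", formatC(x, format = "f", digits = 4))
  rows <- lapply(report$fits, function(f) {
    units <- .param_units(f$model_id, u)
    par_str <- paste(mapply(function(nm, v, un) {
      paste0(nm, " = ", fmt4(v), if (nzchar(un)) paste0(" [", un, "]"))
    }, names(f$params), f$params, units[seq_along(f$params)]), collapse = ", ")
    c(model = paste0(f$label, " (m = ", f$m, ")"),
      parameters = par_str,
      chi2_per_dof = fmt4(f$chi2_per_dof),
      flag = if (f$converged) "" else "NOT CONVERGED")
  })
  mat <- do.call(rbind, rows)
  header <- c("Model", "Parameters", "chi2_min/d.o.f.", "")
  if (style == "markdown") {
    body <- apply(rbind(header, c("---", "---", "---:", "---"), mat), 1,
                  function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    return(c(paste0("**", report$label, "** (N = ", nrow(report$dataset), ")"),
             "", body))
  }
  widths <- pmax(nchar(header), apply(nchar(mat), 2, max))
  pad <- function(r) paste(mapply(formatC, r, width = widths, flag = "-"),
                           collapse = "  ")
  c(paste0(report$label, " (N = ", nrow(report$dataset), "), time in ",
           time_unit(report$dataset), "s"),
    pad(header), apply(mat, 1, pad))
}
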