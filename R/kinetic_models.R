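#' The six empirical release models
#'
#' The package compares six classical parametric laws for cumulative
#' dissolution \eqn{Q(t)} (in percent):
#'
#' \describe{
#'   \item{`zero_order`}{\eqn{Q(t) = A + B t}, two parameters.}
#'   \item{`first_order`}{\eqn{Q(t) = Q_0 \exp(k t / 2.303)}, two parameters
#'     (exponential with the decadic-logarithm factor).}
#'   \item{`higuchi`}{\eqn{Q(t) = k \sqrt{t}}, one parameter; the classical
#'     diffusion-controlled release law.}
#'   \item{`hixson_crowell`}{\eqn{Q(t) = (A + B t)^3}, two parameters; the
#'     cube-root law, i.e. \eqn{Q^{1/3}} affine in \eqn{t}.}
#'   \item{`power_law`}{\eqn{Q(t) = A t^n}, two parameters; the
#'     Korsmeyer--Peppas model, whose exponent \eqn{n} diagnoses the transport
#'     mechanism (\eqn{n = 1/2} is Fickian slab diffusion).}
#'   \item{`hopfenberg`}{\eqn{Q(t) = k t}, one parameter; the flat-geometry
#'     (\eqn{n = 1}) special case of the Hopfenberg surface-erosion family.}
#' }
#'
#' Nesting: the power law contains Higuchi (\eqn{n = 1/2}, \eqn{A = k}) and
#' Hopfenberg (\eqn{n = 1}, \eqn{A = k}); zero order with \eqn{A = 0} is
#' Hopfenberg.
#'
#' @return `kinetic_models()` returns the six model identifiers.
#' @examples
#' kinetic_models()
#' model_spec("power_law")
#' @name kinetic_models
NULL

.registry <- list(
  zero_order = list(
    model_id = "zero_order", label = "Zero order", m = 2L,
    param_names = c("A", "B"), linear_in_params = TRUE,
    basis = function(t) cbind(A = rep(1, length(t)), B = t),
    fun = function(p, t) p[["A"]] + p[["B"]] * t
  ),
  first_order = list(
    model_id = "first_order", label = "First order", m = 2L,
    param_names = c("Q0", "k"), linear_in_params = FALSE,
    fun = function(p, t) p[["Q0"]] * exp(p[["k"]] * t / 2.303)
  ),
  higuchi = list(
    model_id = "higuchi", label = "Higuchi", m = 1L,
    param_names = "k", linear_in_params = TRUE,
    basis = function(t) cbind(k = sqrt(t)),
    fun = function(p, t) p[["k"]] * sqrt(t)
  ),
  hixson_crowell = list(
    model_id = "hixson_crowell", label = "Hixson-Crowell", m = 2L,
    param_names = c("A", "B"), linear_in_params = FALSE,
    fun = function(p, t) (p[["A"]] + p[["B"]] * t)^3
  ),
  power_law = list(
    model_id = "power_law", label = "Power-law", m = 2L,
    param_names = c("A", "n"), linear_in_params = FALSE,
    fun = function(p, t) p[["A"]] * t^p[["n"]]
  ),
  hopfenberg = list(
    model_id = "hopfenberg", label = "Hopfenberg", m = 1L,
    param_names = "k", linear_in_params = TRUE,
    basis = function(t) cbind(k = t),
    fun = function(p, t) p[["k"]] * t
  )
)

#' @rdname kinetic_models
#' @export
kinetic_models <- function() names(.registry)

#' @rdname kinetic_models
#' @param model_id One of the identifiers returned by `kinetic_models()`.
#' @return `model_spec()` returns the registry entry: `model_id`, display
#'   `label`, parameter count `m`, `param_names`, `linear_in_params`, and the
#'   evaluation rule.
#' @export
model_spec <- function(model_id) {
  if (inherits(model_id, "relkin_model")) return(model_id)
  spec <- .registry[[match.arg(model_id, names(.registry))]]
  class(spec) <- "relkin_model"
  spec
}

#' Evaluate a release model
#'
#' Computes the predicted cumulative dissolution \eqn{Q(t)} of one of the six
#' models at the given times. Vectorized over `t`, preserving order.
#' \eqn{0^n} is defined as 0 for \eqn{n > 0}, so the power law handles a
#' profile that starts at \eqn{t = 0}; `t = 0` with \eqn{n \le 0} is a domain
#' error.
#'
#' @param model_id Model identifier (see [kinetic_models()]) or a spec from
#'   [model_spec()].
#' @param params Named numeric vector with exactly the model's parameters
#'   (e.g. `c(A = 20, n = 0.3)` for `power_law`).
#' @param t Numeric vector of times, all `>= 0`.
#' @return Numeric vector of predicted dissolution values (%).
#' @examples
#' evaluate_model("power_law", c(A = 23.3605, n = 0.2856), c(1, 24, 48))
#' @export
evaluate_model <- function(model_id, params, t) {
  spec <- model_spec(model_id)
  if (any(t < 0)) stop("negative time in `t`", call. = FALSE)
  miss <- setdiff(spec$param_names, names(params))
  if (length(miss)) {
    stop("missing parameter(s) for ", spec$model_id, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- as.list(params[spec$param_names])
  if (spec$model_id == "power_law" && any(t == 0) && p$n <= 0) {
    stop("power_law is undefined at t = 0 for n <= 0", call. = FALSE)
  }
  spec$fun(p, t)
}
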