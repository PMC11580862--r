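# Macrostate representation: named summary vectors with per-component
# variable transforms, and the augmented state that appends individual-level
# model parameters to the observables.
#
# The filter operates entirely in transformed space. Count-like components
# stay real-valued through the filter; rounding to integers is deferred to
# the synthesis consumers (largest-remainder rounding there).

#' Component transforms
#'
#' Constructors for the per-component variable transforms applied before the
#' Kalman filter sees a macrostate. `transform_log_eps()` is the
#' extinction-safe log transform x' = log(eps + x) with inverse
#' x = max(0, exp(x') - eps), used for counts whose distribution concentrates
#' near zero (e.g. wolves close to extinction). `transform_scale()`
#' multiplies by a constant to bring components of very different magnitude
#' (sheep vs. grass-patch counts) onto a common range, since a least-squares
#' filter otherwise learns only the largest-magnitude component.
#'
#' @param c positive scale constant.
#' @param eps positive offset of the log transform (default 0.001).
#' @return an object of class `abmkf_transform`.
#' @export
transform_identity <- function() {
  structure(list(kind = "identity"), class = "abmkf_transform")
}

#' @rdname transform_identity
#' @export
transform_scale <- function(c) {
  stopifnot(is.numeric(c), length(c) == 1, c > 0)
  structure(list(kind = "scale", c = c), class = "abmkf_transform")
}

#' @rdname transform_identity
#' @export
transform_log_eps <- function(eps = 0.001) {
  stopifnot(is.numeric(eps), length(eps) == 1, eps > 0)
  structure(list(kind = "log_eps", eps = eps), class = "abmkf_transform")
}

apply_transform <- function(tr, x) {
  switch(tr$kind,
    identity = x,
    scale = tr$c * x,
    log_eps = {
      if (any(x < 0)) stop("log_eps transform requires x >= 0")
      log(tr$eps + x)
    },
    stop("unknown transform kind: ", tr$kind)
  )
}

invert_transform <- function(tr, x) {
  switch(tr$kind,
    identity = x,
    scale = x / tr$c,
    log_eps = pmax(0, exp(x) - tr$eps),
    stop("unknown transform kind: ", tr$kind)
  )
}

#' Macrostate schema
#'
#' Declares the ordered components of a macrostate: names, one transform per
#' component, and a flag marking which components are model parameters
#' (appended to the observables so that individual-level parameters are
#' filtered jointly with the state).
#'
#' @param names character vector of component names (unique).
#' @param transforms list of [transform_identity()]-style transforms, one per
#'   component.
#' @param is_parameter logical vector, `TRUE` for parameter components.
#' @return an object of class `abmkf_schema`.
#' @export
macro_schema <- function(names, transforms, is_parameter = rep(FALSE, length(names))) {
  stopifnot(length(names) == length(transforms),
            length(names) == length(is_parameter),
            !anyDuplicated(names))
  stopifnot(all(vapply(transforms, inherits, TRUE, "abmkf_transform")))
  structure(list(names = as.character(names), transforms = transforms,
                 is_parameter = as.logical(is_parameter)),
            class = "abmkf_schema")
}

#' Macrostate vector
#'
#' An ordered, named summary of a microstate in *raw* (untransformed) units,
#' carrying its schema. Use [to_transformed()] / [from_transformed()] to move
#' between raw and filter space.
#'
#' @param values numeric vector (raw units), length matching the schema.
#' @param schema an [macro_schema()] object.
#' @return an object of class `abmkf_macro`.
#' @export
macro_vector <- function(values, schema) {
  stopifnot(inherits(schema, "abmkf_schema"), length(values) == length(schema$names))
  values <- as.numeric(values)
  names(values) <- schema$names
  structure(list(values = values, schema = schema), class = "abmkf_macro")
}

#' @export
print.abmkf_macro <- function(x, ...) {
  cat("macrostate (", length(x$values), " components)\n", sep = "")
  print(x$values)
  invisible(x)
}

#' Transform a macrostate into filter space
#'
#' Applies each component's transform (identity, scaling, or eps-log) and
#' returns the named numeric vector the Kalman filter operates on.
#'
#' @param mv an [macro_vector()].
#' @return named numeric vector in transformed units.
#' @export
to_transformed <- function(mv) {
  stopifnot(inherits(mv, "abmkf_macro"))
  out <- mapply(function(tr, x) apply_transform(tr, x),
                mv$schema$transforms, mv$values)
  names(out) <- mv$schema$names
  out
}

#' Invert a transformed vector back to raw macrostate units
#'
#' The eps-log inverse clamps at zero, so slightly negative filtered values
#' map to an empty count rather than an invalid one. Values stay real;
#' integer rounding is left to consumers that need it (synthesis).
#'
#' @param v named or plain numeric vector in transformed units.
#' @param schema an [macro_schema()] matching `v` in length.
#' @return an [macro_vector()] in raw units.
#' @export
from_transformed <- function(v, schema) {
  stopifnot(inherits(schema, "abmkf_schema"), length(v) == length(schema$names))
  raw <- mapply(function(tr, x) invert_transform(tr, x), schema$transforms, as.numeric(v))
  macro_vector(raw, schema)
}

#' Default macrostate schema for the wolf-sheep-grass model
#'
#' Wolves get the eps-log transform (extinction concentrates their
#' distribution at zero), sheep are scaled by 0.1 and the grass-patch count
#' by 0.01, bringing all three to a common order of magnitude. Parameter
#' components (reproduction rates in percent) are appended untransformed,
#' as they already sit in the same range as the log-wolf counts.
#'
#' @param parameters character vector of parameter-component names to append.
#' @return an [macro_schema()].
#' @export
default_wsg_schema <- function(parameters = c("wolf_reproduce_pct", "sheep_reproduce_pct")) {
  n <- c("wolves", "sheep", "grass", parameters)
  tr <- c(list(transform_log_eps(0.001), transform_scale(0.1), transform_scale(0.01)),
          replicate(length(parameters), transform_identity(), simplify = FALSE))
  macro_schema(n, tr, c(FALSE, FALSE, FALSE, rep(TRUE, length(parameters))))
}

#' Default macrostate schema for the minimal viral model
#'
#' Molecular totals (virus and cytokines) take the eps-log transform since
#' they span several orders of magnitude during an infection; lattice
#' category counts are scaled by 0.01; the immune-agent count and the
#' virus-killed counter are left in natural units.
#'
#' @param parameters character vector of parameter-component names to append.
#' @return an [macro_schema()].
#' @export
default_viral_schema <- function(parameters = "infect_rate_pct") {
  state <- c("virus_total", "antiviral_total", "proinflam_total", "damps_total",
             "epi_healthy", "epi_infected", "epi_necrosed", "epi_apoptosed", "epi_empty",
             "endo_normal", "endo_activated", "endo_dead",
             "immune_count", "apoptosis_by_virus")
  tr <- c(replicate(4, transform_log_eps(0.001), simplify = FALSE),
          replicate(8, transform_scale(0.01), simplify = FALSE),
          list(transform_identity(), transform_scale(0.01)),
          replicate(length(parameters), transform_identity(), simplify = FALSE))
  macro_schema(c(state, parameters), tr,
               c(rep(FALSE, length(state)), rep(TRUE, length(parameters))))
}
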