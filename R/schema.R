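#' Variable schema
#'
#' Every state variable in a store carries a schema declaring its default
#' value, units, how process updates are applied (`updater`), how the value is
#' partitioned between daughter cells at division (`divider`), and whether it
#' is recorded by the emitter.
#'
#' @param default Default value used when a hierarchy is built and no initial
#'   state is supplied.
#' @param units Unit tag, one of `"fg"`, `"mM"`, `"mV"`, `"pN"`, `"pN.um"`,
#'   `"um"`, `"radians"`, `"s"`, `"counts"`, `"dimensionless"` (free-form tags
#'   are allowed; they are compared verbatim).
#' @param updater One of `"accumulate"` (value + delta), `"set"` (replace), or
#'   `"nonnegative_accumulate"` (value + delta, clamped at 0).
#' @param divider One of `"halve"`, `"binomial"`, `"copy"`, `"split_list"`.
#' @param emit Logical; record this variable in the emitted time series.
#' @param properties Optional named list of per-variable properties such as
#'   `molecular_weight` (fg per count).
#' @return An object of class `cs_schema`.
#' @export
var_schema <- function(default = 0,
                       units = "dimensionless",
                       updater = c("accumulate", "set", "nonnegative_accumulate"),
                       divider = c("halve", "binomial", "copy", "split_list"),
                       emit = FALSE,
                       properties = list()) {
  updater <- match.arg(updater)
  divider <- match.arg(divider)
  structure(
    list(default = default, units = units, updater = updater,
         divider = divider, emit = emit, properties = properties),
    class = "cs_schema")
}

#' Apply a single update entry to a variable
#'
#' @param value Current value of the variable.
#' @param delta Update entry: either a bare value, or a list with elements
#'   `value` and (optionally) `units`. If units are supplied they must match
#'   the schema's units.
#' @param schema The variable's [var_schema()].
#' @return The new value.
#' @export
apply_update <- function(value, delta, schema) {
  if (!inherits(schema, "cs_schema")) stop("schema must be a cs_schema")
  if (is.list(delta) && !is.null(delta$value)) {
    if (!is.null(delta$units) && !identical(delta$units, schema$units)) {
      stop(sprintf("unit mismatch: update in '%s' applied to variable in '%s'",
                   delta$units, schema$units))
    }
    delta <- delta$value
  }
  switch(schema$updater,
    accumulate = value + delta,
    set = delta,
    nonnegative_accumulate = pmax(0, value + delta))
}

# Partition one variable's value between two daughters according to its
# divider. Returns list(d1, d2).
divide_value <- function(value, schema, divider = NULL) {
  divider <- divider %||% schema$divider
  switch(divider,
    halve = list(value / 2, value / 2),
    binomial = {
      n <- round(value)
      n1 <- stats::rbinom(1L, n, 0.5)
      list(n1, n - n1)
    },
    copy = list(value, value),
    split_list = {
      idx <- seq_along(value)
      list(value[idx %% 2L == 1L], value[idx %% 2L == 0L])
    },
    stop(sprintf("divider '%s' undefined", divider)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# safe named access on atomic vectors or lists: default when absent
vget <- function(x, nm, default = 0) {
  i <- match(nm, names(x))
  if (is.na(i)) default else x[[i]]
}
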