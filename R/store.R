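# Hierarchical state containers ("store trees").
#
# A store tree is a nested named list. Leaves are `cs_var` objects holding a
# value plus its schema; interior nodes are plain named lists representing
# compartments/stores. An interior node may carry attribute "divider" =
# "split_list" to mark a store of sub-compartments (e.g. flagella) that are
# alternately assigned to daughters at division.

# safe nested access: returns NULL when any level is missing
path_get <- function(tree, path) {
  for (p in path) {
    if (is.null(tree)) return(NULL)
    tree <- tree[[p]]
  }
  tree
}

# nested assignment creating intermediate stores as needed; value NULL deletes
path_set <- function(tree, path, value) {
  if (length(path) == 0) return(value)
  if (length(path) == 1) {
    if (is.null(value)) tree[[path]] <- NULL else tree[[path]] <- value
    return(tree)
  }
  sub <- tree[[path[1]]]
  if (is.null(sub)) sub <- list()
  tree[[path[1]]] <- path_set(sub, path[-1], value)
  tree
}

#' Create a store leaf
#'
#' @param value Current value.
#' @param schema The variable's [var_schema()].
#' @return A `cs_var` leaf node.
#' @export
store_leaf <- function(value, schema) {
  structure(list(value = value, schema = schema), class = "cs_var")
}

is_leaf <- function(x) inherits(x, "cs_var")

#' Extract plain values from a store subtree
#'
#' Strips schemas, returning the nested list of raw values (or a single value
#' for a leaf).
#'
#' @param node A store tree node.
#' @return Nested list of values.
#' @export
store_values <- function(node) {
  if (is_leaf(node)) return(node$value)
  lapply(node, store_values)
}

#' Flatten a store tree to named values
#'
#' @param tree Store tree.
#' @param emit_only Only include variables whose schema has `emit = TRUE`.
#' @return Named list; names are `/`-separated paths.
#' @export
store_flatten <- function(tree, emit_only = FALSE) {
  out <- list()
  walk <- function(node, prefix) {
    if (is_leaf(node)) {
      if (!emit_only || isTRUE(node$schema$emit)) out[[prefix]] <<- node$value
      return(invisible())
    }
    for (nm in names(node)) {
      walk(node[[nm]], if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm)
    }
  }
  walk(tree, "")
  out
}

# Merge a nested list of raw initial values onto a store tree (values only;
# schemas are kept). Unknown paths create schema-less leaves with a default
# schema (accumulate/halve), which keeps small experiments terse.
overlay_values <- function(tree, values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    node <- tree[[nm]]
    if (is.list(v) && !is_leaf(node) && !is.null(node)) {
      tree[[nm]] <- overlay_values(node, v)
    } else if (is_leaf(node)) {
      node$value <- v
      tree[[nm]] <- node
    } else if (is.list(v) && is.null(node)) {
      tree[[nm]] <- overlay_values(list(), v)
    } else {
      tree[[nm]] <- store_leaf(v, var_schema(default = v))
    }
  }
  tree
}

#' Divide an agent compartment's state between two daughters
#'
#' Walks the agent subtree and applies each variable's divider: `halve`
#' (value/2 each), `binomial` (fair binomial partition of a count; daughters
#' sum exactly to the parent), `copy` (both daughters inherit the value), and
#' `split_list` for stores of sub-compartments, whose children are assigned
#' alternately (odd-indexed to the first daughter).
#'
#' Uses the current R random number generator for binomial draws.
#'
#' @param agent_state Store subtree of a complete agent compartment.
#' @return List of two daughter subtrees.
#' @export
divide_state <- function(agent_state) {
  if (is_leaf(agent_state)) {
    halves <- divide_value(agent_state$value, agent_state$schema)
    return(list(store_leaf(halves[[1]], agent_state$schema),
                store_leaf(halves[[2]], agent_state$schema)))
  }
  if (identical(attr(agent_state, "divider"), "split_list")) {
    idx <- seq_along(agent_state)
    d1 <- agent_state[idx %% 2L == 1L]
    d2 <- agent_state[idx %% 2L == 0L]
    attr(d1, "divider") <- "split_list"
    attr(d2, "divider") <- "split_list"
    return(list(d1, d2))
  }
  d1 <- list(); d2 <- list()
  for (nm in names(agent_state)) {
    halves <- divide_state(agent_state[[nm]])
    d1[[nm]] <- halves[[1]]
    d2[[nm]] <- halves[[2]]
  }
  for (a in names(attributes(agent_state))) {
    if (a != "names") {
      attr(d1, a) <- attr(agent_state, a)
      attr(d2, a) <- attr(agent_state, a)
    }
  }
  list(d1, d2)
}
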