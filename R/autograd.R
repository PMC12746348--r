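# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# Each value flowing through the network is wrapped in a node (an
# environment) holding the forward value `v`, an accumulated gradient `g`,
# and a backward closure `bw` that pushes the node's gradient onto its
# parents. Nodes created while a tape is active are recorded in creation
# order, so the reversed tape is already a valid topological order for the
# backward sweep -- there is no need for an explicit graph sort.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$recording <- FALSE

#' Wrap an array as an autodiff leaf node
#'
#' Leaf nodes are the entry points of the computation graph: network
#' parameters (with `requires_grad = TRUE`) and input batches.
#'
#' @param v Numeric array or matrix.
#' @param requires_grad Keep a gradient for this node after backward.
#' @return An `ag_node` environment with fields `v` (value) and `g`
#'   (gradient, `NULL` until backward).
#' @keywords internal
ag_leaf <- function(v, requires_grad = FALSE) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$parents <- list()
  n$bw <- NULL
  n$requires_grad <- requires_grad
  class(n) <- "ag_node"
  n
}

ag_is_node <- function(x) inherits(x, "ag_node")

# Create an interior node. `bw` receives the node's gradient and must call
# ag_accum() on each parent that needs one.
ag_node <- function(v, parents, bw) {
  n <- ag_leaf(v)
  if (isTRUE(.ag$recording)) {
    n$parents <- parents
    n$bw <- bw
    .ag$tape[[length(.ag$tape) + 1L]] <- n
  }
  n
}

ag_accum <- function(node, grad) {
  if (is.null(node$g)) node$g <- grad else node$g <- node$g + grad
  invisible(node)
}

#' Record a forward computation on a fresh tape
#'
#' @param expr Expression building the graph (returns the output node).
#' @return List with the expression `result` and the recorded `tape`.
#' @keywords internal
ag_record <- function(expr) {
  old_tape <- .ag$tape
  old_rec <- .ag$recording
  .ag$tape <- list()
  .ag$recording <- TRUE
  on.exit({
    .ag$tape <- old_tape
    .ag$recording <- old_rec
  })
  res <- force(expr)
  list(result = res, tape = .ag$tape)
}

#' Reverse sweep through a recorded tape
#'
#' Seeds `root$g` with `grad` and propagates gradients to every leaf
#' reachable from the tape. Interior gradients are dropped afterwards;
#' leaves keep theirs until `ag_zero_grad()`.
#'
#' @keywords internal
ag_backward <- function(root, grad, tape) {
  root$g <- grad
  for (i in rev(seq_along(tape))) {
    node <- tape[[i]]
    if (!is.null(node$g) && !is.null(node$bw)) node$bw(node$g)
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

ag_value <- function(x) if (ag_is_node(x)) x$v else x
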