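## Reverse-mode differentiation tape.
##
## Every differentiable quantity is a "node": an environment holding the
## value, an accumulated gradient, its parent nodes, and a backward
## closure mapping the node's gradient to its parents' gradients. When
## the tape is recording, operations append their node to it; calling
## ag_backward() replays the tape in reverse. With recording off the same
## operations run value-only, so inference costs no graph bookkeeping.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- list()
.ag$len <- 0L

#' Create a differentiable tensor node
#'
#' @param value numeric array (any shape).
#' @param requires_grad should gradients be accumulated into this node?
#'   Set for trainable parameters; leave `FALSE` for data and fixed
#'   weights (gradients still flow *through* such nodes when needed).
#' @return a tensor node (environment with class `"ag_node"`).
#' @keywords internal
ag_node <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$parents <- NULL
  e$backward <- NULL
  class(e) <- "ag_node"
  e
}

#' @keywords internal
is_ag_node <- function(x) inherits(x, "ag_node")

# Coerce arrays to nodes so ops can mix constants and nodes.
as_node <- function(x) if (is_ag_node(x)) x else ag_node(x)

ag_value <- function(x) if (is_ag_node(x)) x$value else x

# Does a gradient need to be computed for this node?
needs_grad <- function(x) {
  is_ag_node(x) && (x$requires_grad || !is.null(x$parents))
}

#' Record an operation on the tape
#'
#' @param value result array.
#' @param parents list of parent nodes (non-nodes are ignored).
#' @param backward `function(grad)` returning a list of gradients, one
#'   per parent (NULL allowed for parents that need none).
#' @keywords internal
ag_op <- function(value, parents, backward) {
  out <- ag_node(value)
  if (.ag$recording) {
    out$parents <- parents
    out$backward <- backward
    .ag$len <- .ag$len + 1L
    if (.ag$len > length(.ag$tape)) {
      length(.ag$tape) <- max(64L, 2L * length(.ag$tape))
    }
    .ag$tape[[.ag$len]] <- out
  }
  out
}

#' Evaluate an expression while recording the tape
#' @keywords internal
ag_record <- function(expr) {
  old_rec <- .ag$recording
  .ag$recording <- TRUE
  on.exit(.ag$recording <- old_rec)
  expr
}

#' Evaluate an expression with recording off
#' @keywords internal
ag_no_grad <- function(expr) {
  old_rec <- .ag$recording
  .ag$recording <- FALSE
  on.exit(.ag$recording <- old_rec)
  expr
}

#' Backpropagate from a scalar loss node through the recorded tape
#'
#' Accumulates gradients into every ancestor node that requires them,
#' then clears the tape.
#' @param loss a scalar node produced while recording.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_ag_node(loss))
  loss$grad <- 1
  if (.ag$len > 0L) {
    for (i in seq(.ag$len, 1L)) {
      node <- .ag$tape[[i]]
      if (is.null(node$grad) || is.null(node$backward)) next
      pg <- node$backward(node$grad)
      for (k in seq_along(node$parents)) {
        p <- node$parents[[k]]
        if (!is_ag_node(p) || is.null(pg[[k]])) next
        p$grad <- if (is.null(p$grad)) pg[[k]] else p$grad + pg[[k]]
      }
      # free intermediate state as we go
      if (!node$requires_grad) node$grad <- NULL
      node$backward <- NULL
      node$parents <- NULL
    }
  }
  ag_clear_tape()
  invisible(NULL)
}

#' @keywords internal
ag_clear_tape <- function() {
  .ag$tape <- list()
  .ag$len <- 0L
  invisible(NULL)
}

#' Zero the gradients of a list of parameter nodes
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
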