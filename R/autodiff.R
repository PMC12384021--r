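#' @useDynLib nucleifuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm dnorm rnorm runif rpois sd quantile
#' @importFrom grDevices convertColor
NULL

# Minimal reverse-mode tape. A node is a mutable environment holding a value
# (an R array), its accumulated gradient, parent nodes, and a backward
# closure mapping the node's output gradient to per-parent gradients.
# Only nodes reachable from a parameter (rg = TRUE) are traversed.

.ad <- new.env(parent = emptyenv())
.ad$epoch <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$rg <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$rg, logical(1)))
  class(e) <- "ad_node"
  e
}

ad_param <- function(value) {
  e <- ad_node(value)
  e$rg <- TRUE
  e
}

ad_const <- function(value) ad_node(value)

as_node <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

node_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# Reverse sweep from a scalar (or seeded) root. Gradients of every reachable
# rg node are (re)computed; previous grads inside the traversed set are
# discarded, so parameter grads reflect exactly this graph.
ad_backward <- function(root, seed = 1) {
  .ad$epoch <- .ad$epoch + 1L
  ep <- .ad$epoch
  order <- vector("list", 512L)
  k <- 0L
  visit <- function(n) {
    if (!n$rg || identical(n$.ep, ep)) return(invisible())
    n$.ep <- ep
    for (p in n$parents) visit(p)
    k <<- k + 1L
    if (k > length(order)) order[[2L * k]] <<- NULL
    order[[k]] <<- n
    invisible()
  }
  visit(root)
  if (k == 0L) return(invisible())
  order <- order[seq_len(k)]
  for (n in order) n$grad <- NULL
  root$grad <- if (length(root$value) == 1L) seed else array(seed, dim(root$value))
  for (n in rev(order)) {
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (t in seq_along(ps)) {
      p <- ps[[t]]
      g <- gs[[t]]
      if (!p$rg || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!is.null(n$backfn)) n$grad <- n$grad  # keep for inspection
  }
  invisible()
}
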