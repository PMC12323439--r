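# Reverse-mode automatic differentiation on a linear tape.
#
# Every operation appends a node holding its forward value and a vector-Jacobian
# product closure; because nodes are appended in execution order the tape is
# already topologically sorted and the backward pass is a single reverse sweep.
# Values are plain R arrays; the convolution/pooling kernels live in src/.

tg_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tg_push <- function(tp, value, parents = integer(), vjp = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(value = value, parents = parents, vjp = vjp)
  tp$n <- n
  n
}

tg_leaf <- function(tp, value) tg_push(tp, value)

# `id` must be forced before tp$nodes is read: a nested op call passed as a
# lazy argument appends to the tape while being forced, and `[[` would
# otherwise fetch the node list from before that append.
tg_value <- function(tp, id) {
  force(id)
  tp$nodes[[id]]$value
}

# Backward sweep from a scalar loss node. Returns a list of gradients indexed
# by node id (NULL where no gradient flowed).
tg_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (i in seq(loss_id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tp$nodes[[i]]
    if (is.null(node$vjp)) next
    pg <- node$vjp(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}
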