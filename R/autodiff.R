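#' Reverse-mode automatic differentiation on arrays
#'
#' A compact tape for the volumetric model: nodes hold numeric arrays;
#' every operation records its parents and a backward closure; gradients
#' are accumulated by a reverse topological sweep. Only the operations the
#' model needs are provided (matrix product, elementwise arithmetic, row
#' softmax / layer norm, GELU, gather/scatter indexing, reductions).
#' Gather doubles as reshape, permutation, padding, cropping and im2col,
#' which keeps the op set small.
#'
#' @name autodiff
NULL

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L
.ad$last <- NULL
.ad$recording <- FALSE

# Nodes are environments (reference semantics: nesting the graph in plain
# lists would make any duplication copy the whole DAG as a tree). While
# the tape is recording, interior nodes are also appended to a global
# tape list; environments are never deep-copied, so the append is cheap.
ad_node <- function(val, parents = list(), backward = NULL) {
  # force arguments before taking a tape position: nested op calls in
  # `val`/`parents` must record their own nodes first (lazy evaluation)
  force(val); force(parents); force(backward)
  e <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  e$id <- .ad$counter
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  class(e) <- "ad_node"
  if (.ad$recording && !is.null(backward)) {
    # intrusive linked tape: O(1) append with no list copying
    e$prev <- .ad$last
    .ad$last <- e
  }
  e
}

# start recording interior nodes for a tape-replay backward sweep; the
# tape is a linked chain of nodes through their `prev` fields
ad_tape_start <- function() {
  .ad$last <- NULL
  .ad$recording <- TRUE
  invisible(NULL)
}

ad_tape_stop <- function() {
  .ad$recording <- FALSE
  .ad$last <- NULL
  invisible(NULL)
}

#' Wrap a value as a leaf node
#' @param val numeric array, matrix or scalar.
#' @keywords internal
ad_leaf <- function(val) ad_node(val)

as_ad <- function(x) if (inherits(x, "ad_node")) x else ad_leaf(x)

#' Run the backward sweep from a scalar loss node
#'
#' Accumulates `$grad` on every node reachable from `root`. Node ids are
#' assigned in creation order, so parents always precede children and
#' descending id order is a valid reverse topological order.
#' @param root scalar `ad_node`.
#' @keywords internal
ad_backward <- function(root) {
  stopifnot(length(root$val) == 1)
  root$grad <- array(1, dim = dim(root$val) %||% 1)
  if (.ad$recording) {
    # walk the linked tape backwards: creation order is topological order
    node <- .ad$last
    while (!is.null(node)) {
      if (!is.null(node$grad)) {
        gs <- node$backward(node$grad)
        parents <- node$parents
        for (j in seq_along(parents)) {
          gj <- gs[[j]]
          if (!is.null(gj)) {
            p <- parents[[j]]
            p$grad <- if (is.null(p$grad)) gj else p$grad + gj
          }
        }
        node$grad <- NULL   # free interior gradients as we go
      }
      node <- node$prev
    }
    return(invisible(root))
  }
  # fallback: DFS reachability, then descending id order
  visited <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L); nn <- 0L
  stack <- vector("list", 256L); ns <- 1L
  stack[[1]] <- root
  while (ns > 0L) {
    node <- stack[[ns]]; ns <- ns - 1L
    key <- as.character(node$id)
    if (!is.null(visited[[key]])) next
    visited[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", nn))
    nodes[[nn]] <- node
    for (p in node$parents) {
      ns <- ns + 1L
      if (ns > length(stack)) stack <- c(stack, vector("list", ns))
      stack[[ns]] <- p
    }
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(n) n$id, integer(1))
  for (i in order(ids, decreasing = TRUE)) {
    node <- nodes[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(root)
}

# ---- arithmetic ------------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av * bv, list(a, b),
          function(g) list(sum_to_shape(g * bv, av),
                           sum_to_shape(g * av, bv)))
}

# supports scalar-vs-array elementwise combinations
sum_to_shape <- function(g, template) {
  if (length(template) == 1) return(sum(g))
  g
}

ad_div <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av / bv, list(a, b),
          function(g) list(sum_to_shape(g / bv, av),
                           sum_to_shape(-g * av / bv^2, bv)))
}

# multiply by a plain numeric constant (no gradient for the constant)
ad_scale <- function(a, s) {
  ad_node(a$val * s, list(a), function(g) list(g * s))
}

ad_sqrt <- function(a) {
  v <- sqrt(a$val)
  ad_node(v, list(a), function(g) list(g * 0.5 / v))
}

ad_neg <- function(a) ad_scale(a, -1)

ad_pmax <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  take_a <- a$val >= b$val
  ad_node(pmax(a$val, b$val), list(a, b),
          function(g) list(g * take_a, g * !take_a))
}

# ---- linear algebra --------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

ad_transpose <- function(a) {
  ad_node(t(a$val), list(a), function(g) list(t(g)))
}

# add a length-d bias to every row of an n x d matrix
ad_add_bias <- function(a, bias) {
  bias <- as_ad(bias)
  ad_node(sweep(a$val, 2, as.vector(bias$val), "+"), list(a, bias),
          function(g) list(g, colSums(g)))
}

#' Precompute the scatter plan for a gather index
#'
#' Sort-based segment sums make the backward pass of [ad_gather()] fully
#' vectorised; plans are cached by the model code because the same index
#' matrices are reused every forward pass.
#' @keywords internal
gather_plan <- function(idx) {
  iv <- as.vector(idx)
  if (anyDuplicated(iv) == 0L) {
    return(list(iv = iv, dup = FALSE))
  }
  ord <- order(iv, method = "radix")
  sorted <- iv[ord]
  ends <- which(c(sorted[-1] != sorted[-length(sorted)], TRUE))
  list(iv = iv, dup = TRUE, ord = ord, ends = ends, targets = sorted[ends])
}

#' Gather: index into the flattened value, yielding a new shape
#'
#' `idx` is an integer vector/matrix of positions into `as.vector(x$val)`;
#' the output has `dim = out_dim` (or the dim of `idx`). Duplicated indices
#' accumulate their gradients, so the same op serves as im2col, reshape,
#' axis permutation, circular padding and cropping.
#' @keywords internal
ad_gather <- function(x, idx, out_dim = NULL, plan = NULL) {
  xv <- x$val
  if (is.null(plan)) plan <- gather_plan(idx)
  out <- as.vector(xv)[plan$iv]
  od <- out_dim %||% dim(idx)
  if (!is.null(od)) dim(out) <- od
  nx <- length(xv)
  dx <- dim(xv)
  ad_node(out, list(x), function(g) {
    gx <- numeric(nx)
    if (plan$dup) {
      cs <- cumsum(as.vector(g)[plan$ord])[plan$ends]
      gx[plan$targets] <- cs - c(0, cs[-length(cs)])
    } else {
      gx[plan$iv] <- g
    }
    if (!is.null(dx)) dim(gx) <- dx
    list(gx)
  })
}

# concatenate matrices column-wise
ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ad_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# ---- nonlinearities --------------------------------------------------------

ad_softmax_rows <- function(x) {
  v <- x$val
  v <- v - apply(v, 1, max)
  ev <- exp(v)
  y <- ev / rowSums(ev)
  ad_node(y, list(x), function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

ad_gelu <- function(x) {
  v <- x$val
  k <- sqrt(2 / pi)
  inner <- k * (v + 0.044715 * v^3)
  th <- tanh(inner)
  y <- 0.5 * v * (1 + th)
  ad_node(y, list(x), function(g) {
    sech2 <- 1 - th^2
    dinner <- k * (1 + 3 * 0.044715 * v^2)
    list(g * (0.5 * (1 + th) + 0.5 * v * sech2 * dinner))
  })
}

# row-wise layer normalisation with learned gain/bias (length-d vectors)
ad_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  gamma <- as_ad(gamma); beta <- as_ad(beta)
  v <- x$val
  mu <- rowMeans(v)
  xc <- v - mu
  var <- rowMeans(xc^2)
  inv <- 1 / sqrt(var + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$val)
  out <- sweep(xhat * gv[col(xhat)], 2, as.vector(beta$val), "+")
  # note: xhat * gv[col(xhat)] == sweep(xhat, 2, gv, "*")
  ad_node(out, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2, gv, "*")
    d <- ncol(v)
    gx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(gx, colSums(g * xhat), colSums(g))
  })
}

# ---- reductions ------------------------------------------------------------

ad_mean <- function(x) {
  n <- length(x$val)
  ad_node(mean(x$val), list(x), function(g) {
    gx <- array(as.numeric(g) / n, dim = dim(x$val) %||% n)
    list(gx)
  })
}

ad_sum <- function(x) {
  ad_node(sum(x$val), list(x), function(g) {
    gx <- array(as.numeric(g), dim = dim(x$val) %||% length(x$val))
    list(gx)
  })
}

# subtract a scalar node from every element
ad_sub_scalar <- function(a, s) {
  s <- as_ad(s)
  ad_node(a$val - as.numeric(s$val), list(a, s),
          function(g) list(g, -sum(g)))
}

#' Value of a node
#' @param x an `ad_node`.
#' @keywords internal
ad_value <- function(x) x$val
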