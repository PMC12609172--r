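# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order, which is a valid topological order
# for the backward sweep. Node values are plain base-R matrices; every op
# defines its vector-Jacobian product in a closure. This is all the machinery
# the network needs: the architectures here are straight-line compositions of
# dense layers, gather/scatter embedding lookups, pairwise softmax gates and
# batch normalization, so a full graph framework would be overkill.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# constants and leaves share the node structure; leaves just get read out
ad_const <- function(tape, value) ad_node(tape, value)
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accumulate <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Backward sweep from a scalar root (1x1 value).
ad_backward <- function(tape, root) {
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    g <- nd$grad
    ad_accumulate(nd$parents[[1L]], g %*% t(nd$parents[[2L]]$value))
    ad_accumulate(nd$parents[[2L]], crossprod(nd$parents[[1L]]$value, g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) {
    ad_accumulate(nd$parents[[1L]], nd$grad)
    ad_accumulate(nd$parents[[2L]], nd$grad)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(nd) {
    ad_accumulate(nd$parents[[1L]], nd$grad)
    ad_accumulate(nd$parents[[2L]], -nd$grad)
  })
}

# bias b is a 1 x d matrix broadcast over the rows of a
ad_add_bias <- function(tape, a, b) {
  ad_node(tape, sweep(a$value, 2L, as.vector(b$value), "+"), list(a, b),
    function(nd) {
      ad_accumulate(nd$parents[[1L]], nd$grad)
      ad_accumulate(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
    })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(nd) {
    ad_accumulate(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$value)
    ad_accumulate(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$value)
  })
}

# multiply each row of x (B x d) by the matching entry of column s (B x 1)
ad_mul_col <- function(tape, x, s) {
  sv <- as.vector(s$value)
  ad_node(tape, x$value * sv, list(x, s), function(nd) {
    g <- nd$grad
    ad_accumulate(nd$parents[[1L]], g * as.vector(nd$parents[[2L]]$value))
    ad_accumulate(nd$parents[[2L]],
                  matrix(rowSums(g * nd$parents[[1L]]$value), ncol = 1L))
  })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(nd) {
    ad_accumulate(nd$parents[[1L]], nd$grad * k)
  })
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tape, v, list(a), function(nd) {
    ad_accumulate(nd$parents[[1L]], nd$grad * nd$value * (1 - nd$value))
  })
}

ad_relu <- function(tape, a) {
  ad_node(tape, pmax(a$value, 0), list(a), function(nd) {
    ad_accumulate(nd$parents[[1L]], nd$grad * (nd$parents[[1L]]$value > 0))
  })
}

ad_square <- function(tape, a) {
  ad_node(tape, a$value^2, list(a), function(nd) {
    ad_accumulate(nd$parents[[1L]], 2 * nd$grad * nd$parents[[1L]]$value)
  })
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$value), list(a), function(nd) {
    ad_accumulate(nd$parents[[1L]], nd$grad / nd$parents[[1L]]$value)
  })
}

# clamp with straight-through gradient inside the open interval
ad_clamp <- function(tape, a, lo, hi) {
  ad_node(tape, pmin(pmax(a$value, lo), hi), list(a), function(nd) {
    inside <- nd$parents[[1L]]$value > lo & nd$parents[[1L]]$value < hi
    ad_accumulate(nd$parents[[1L]], nd$grad * inside)
  })
}

ad_one_minus <- function(tape, a) {
  ad_node(tape, 1 - a$value, list(a), function(nd) {
    ad_accumulate(nd$parents[[1L]], -nd$grad)
  })
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(nd) {
    p <- nd$parents[[1L]]
    ad_accumulate(p, matrix(as.vector(nd$grad), nrow(p$value), ncol(p$value)))
  })
}

ad_concat_cols <- function(tape, parts) {
  widths <- vapply(parts, function(p) ncol(p$value), integer(1L))
  ad_node(tape, do.call(cbind, lapply(parts, `[[`, "value")), parts,
    function(nd) {
      at <- 0L
      for (i in seq_along(nd$parents)) {
        idx <- seq.int(at + 1L, at + widths[i])
        ad_accumulate(nd$parents[[i]], nd$grad[, idx, drop = FALSE])
        at <- at + widths[i]
      }
    })
}

ad_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(nd) {
    p <- nd$parents[[1L]]
    g <- matrix(0, nrow(p$value), ncol(p$value))
    g[, idx] <- nd$grad
    ad_accumulate(p, g)
  })
}

# gather rows of an embedding table; backward scatter-adds into the table
ad_gather <- function(tape, table, idx) {
  ad_node(tape, table$value[idx, , drop = FALSE], list(table), function(nd) {
    p <- nd$parents[[1L]]
    g <- matrix(0, nrow(p$value), ncol(p$value))
    agg <- rowsum(nd$grad, group = idx)
    g[as.integer(rownames(agg)), ] <- agg
    ad_accumulate(p, g)
  })
}

# stack F field matrices (each B x E) into a (B*E) x F matrix, column-major
# within each field, so row r corresponds to sample (r-1) %% B + 1 and
# embedding dimension (r-1) %/% B + 1
ad_stack_fields <- function(tape, fields) {
  b <- nrow(fields[[1L]]$value)
  e <- ncol(fields[[1L]]$value)
  val <- vapply(fields, function(f) as.vector(f$value), numeric(b * e))
  ad_node(tape, val, fields, function(nd) {
    for (f in seq_along(nd$parents)) {
      ad_accumulate(nd$parents[[f]], matrix(nd$grad[, f], b, e))
    }
  })
}

# inverse reshape of one stacked column ((B*E) x 1) back to B x E
ad_unstack_col <- function(tape, s, b, e) {
  ad_node(tape, matrix(as.vector(s$value), b, e), list(s), function(nd) {
    ad_accumulate(nd$parents[[1L]], matrix(as.vector(nd$grad), ncol = 1L))
  })
}

# Batch normalization over columns. `state` is an environment carrying
# running_mean / running_var (updated in training mode only); eval mode uses
# the running statistics, train mode the per-batch population statistics.
ad_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.9, eps = 1e-5) {
  gv <- as.vector(gamma$value)
  bv <- as.vector(beta$value)
  if (training) {
    mu <- colMeans(x$value)
    va <- colMeans(x$value^2) - mu^2
    state$running_mean <- momentum * state$running_mean + (1 - momentum) * mu
    state$running_var <- momentum * state$running_var + (1 - momentum) * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(x$value, 2L, mu, "-") * rep(inv_sd, each = nrow(x$value))
  out <- sweep(xhat * rep(gv, each = nrow(xhat)), 2L, bv, "+")
  ad_node(tape, out, list(x, gamma, beta), function(nd) {
    g <- nd$grad
    ad_accumulate(nd$parents[[2L]], matrix(colSums(g * xhat), 1L))
    ad_accumulate(nd$parents[[3L]], matrix(colSums(g), 1L))
    dxhat <- g * rep(gv, each = nrow(g))
    if (training) {
      mh <- colMeans(dxhat)
      mxh <- colMeans(dxhat * xhat)
      dx <- (dxhat - rep(mh, each = nrow(g)) -
               xhat * rep(mxh, each = nrow(g))) * rep(inv_sd, each = nrow(g))
    } else {
      dx <- dxhat * rep(inv_sd, each = nrow(g))
    }
    ad_accumulate(nd$parents[[1L]], dx)
  })
}

# pairwise softmax over two score columns: returns P(first) = sigmoid(s1 - s2)
ad_pair_softmax <- function(tape, scores) {
  s1 <- ad_cols(tape, scores, 1L)
  s2 <- ad_cols(tape, scores, 2L)
  ad_sigmoid(tape, ad_sub(tape, s1, s2))
}

# inverted dropout with a fixed Bernoulli mask (training mode only)
ad_dropout <- function(tape, a, rate) {
  if (rate <= 0) return(a)
  mask <- matrix(
    stats::rbinom(length(a$value), 1L, 1 - rate) / (1 - rate),
    nrow(a$value), ncol(a$value))
  ad_mul(tape, a, ad_const(tape, mask))
}
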