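# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes in creation order; ad_backward() walks it in reverse,
# calling each node's vector-Jacobian product. Operands may be ad nodes or
# plain matrices (treated as constants); only node operands receive
# gradients. The op set is exactly what the encoders, fusion blocks and KAN
# head need -- this is not a general-purpose framework.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  t
}

is_ad <- function(x) is.environment(x) && !is.null(x$is_ad_node)

ad_val <- function(x) if (is_ad(x)) x$value else x

ad_node <- function(tape, value, parents = NULL, vjp = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$is_ad_node <- TRUE
  nd$value <- value
  nd$parents <- parents
  nd$vjp <- vjp
  nd$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# Leaf node for a trainable parameter matrix.
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from `root` (typically a 1x1 loss). After the call every
# leaf reachable from root carries its gradient in $grad.
ad_backward <- function(tape, root, seed = NULL) {
  if (is.null(seed)) seed <- array(1, dim = dim(root$value))
  root$grad <- seed
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      if (!is.null(gs[[k]])) ad_accum(ps[[k]], gs[[k]])
    }
    nd$grad <- NULL  # free intermediate gradients as we go
  }
  invisible(NULL)
}

node_parents <- function(...) {
  args <- list(...)
  args[vapply(args, is_ad, logical(1))]
}

# --- arithmetic -------------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- av %*% bv
  an <- is_ad(a); bn <- is_ad(b)
  ad_node(tape, out, parents = node_parents(a, b), vjp = function(g) {
    gs <- list()
    if (an) gs <- c(gs, list(tcrossprod(g, bv)))
    if (bn) gs <- c(gs, list(crossprod(av, g)))
    gs
  })
}

# Sparse constant matrix (Matrix::dgCMatrix) times dense node.
ad_spmm <- function(tape, S, x) {
  xv <- ad_val(x)
  out <- as.matrix(S %*% xv)
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(as.matrix(Matrix::crossprod(S, g)))
  })
}

ad_add <- function(tape, a, b) {
  out <- ad_val(a) + ad_val(b)
  an <- is_ad(a); bn <- is_ad(b)
  ad_node(tape, out, parents = node_parents(a, b), vjp = function(g) {
    gs <- list()
    if (an) gs <- c(gs, list(g))
    if (bn) gs <- c(gs, list(g))
    gs
  })
}

ad_sub <- function(tape, a, b) {
  out <- ad_val(a) - ad_val(b)
  an <- is_ad(a); bn <- is_ad(b)
  ad_node(tape, out, parents = node_parents(a, b), vjp = function(g) {
    gs <- list()
    if (an) gs <- c(gs, list(g))
    if (bn) gs <- c(gs, list(-g))
    gs
  })
}

ad_mul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- av * bv
  an <- is_ad(a); bn <- is_ad(b)
  ad_node(tape, out, parents = node_parents(a, b), vjp = function(g) {
    gs <- list()
    if (an) gs <- c(gs, list(g * bv))
    if (bn) gs <- c(gs, list(g * av))
    gs
  })
}

ad_scale <- function(tape, x, s) {
  out <- ad_val(x) * s
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) list(g * s))
}

# x + bias, bias broadcast across rows (bias is a 1 x k parameter).
ad_add_bias <- function(tape, x, b) {
  xv <- ad_val(x); bv <- ad_val(b)
  out <- sweep(xv, 2L, as.vector(bv), "+")
  xn <- is_ad(x); bnn <- is_ad(b)
  ad_node(tape, out, parents = node_parents(x, b), vjp = function(g) {
    gs <- list()
    if (xn) gs <- c(gs, list(g))
    if (bnn) gs <- c(gs, list(matrix(colSums(g), 1L)))
    gs
  })
}

# Per-column constant affine map: out[, j] = x[, j] * scale[j] + shift[j].
ad_affine_cols <- function(tape, x, scale, shift) {
  xv <- ad_val(x)
  out <- sweep(sweep(xv, 2L, scale, "*"), 2L, shift, "+")
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(sweep(g, 2L, scale, "*"))
  })
}

# --- activations ------------------------------------------------------------

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-ad_val(x)))
  ad_node(tape, s, parents = node_parents(x), vjp = function(g) {
    list(g * s * (1 - s))
  })
}

ad_tanh <- function(tape, x) {
  th <- tanh(ad_val(x))
  ad_node(tape, th, parents = node_parents(x), vjp = function(g) {
    list(g * (1 - th * th))
  })
}

ad_relu <- function(tape, x) {
  xv <- ad_val(x)
  out <- pmax(xv, 0)
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(g * (xv > 0))
  })
}

ad_leakyrelu <- function(tape, x, slope = 0.2) {
  xv <- ad_val(x)
  pos <- xv > 0
  out <- ifelse(pos, xv, slope * xv)
  dim(out) <- dim(xv)
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(g * ifelse(pos, 1, slope))
  })
}

ad_silu <- function(tape, x) {
  xv <- ad_val(x)
  s <- 1 / (1 + exp(-xv))
  out <- xv * s
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(g * (s + xv * s * (1 - s)))
  })
}

ad_clamp <- function(tape, x, lo, hi) {
  xv <- ad_val(x)
  inside <- xv >= lo & xv <= hi
  out <- pmin(pmax(xv, lo), hi)
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(g * inside)
  })
}

# --- reductions and reshaping ----------------------------------------------

ad_sum <- function(tape, x) {
  xv <- ad_val(x)
  ad_node(tape, matrix(sum(xv), 1L, 1L), parents = node_parents(x),
          vjp = function(g) list(array(g[1L], dim = dim(xv))))
}

ad_mean <- function(tape, x) {
  xv <- ad_val(x)
  n <- length(xv)
  ad_node(tape, matrix(mean(xv), 1L, 1L), parents = node_parents(x),
          vjp = function(g) list(array(g[1L] / n, dim = dim(xv))))
}

# Gather rows: out = x[idx, ]. Duplicated indices accumulate on backward.
ad_rows <- function(tape, x, idx) {
  xv <- ad_val(x)
  idx <- as.integer(idx)
  out <- cpp_gather_rows(xv, idx)
  nr <- nrow(xv)
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(cpp_scatter_rows(g, idx, nr))
  })
}

# Scatter-add rows of x into `ngroups` buckets keyed by `group`.
ad_scatter_rows <- function(tape, x, group, ngroups) {
  xv <- ad_val(x)
  out <- scatter_sum(xv, group, ngroups)
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(g[group, , drop = FALSE])
  })
}

# Gather columns: out = x[, idx]; used to expand per-head weights to
# per-feature width. Backward sums duplicates.
ad_cols <- function(tape, x, idx) {
  xv <- ad_val(x)
  idx <- as.integer(idx)
  out <- cpp_gather_cols(xv, idx)
  nc <- ncol(xv)
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(cpp_scatter_cols(g, idx, nc))
  })
}

ad_cbind_list <- function(tape, xs) {
  vals <- lapply(xs, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  out <- do.call(cbind, vals)
  isn <- vapply(xs, is_ad, logical(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, out, parents = xs[isn], vjp = function(g) {
    gs <- vector("list", sum(isn))
    j <- 0L
    for (k in seq_along(xs)) {
      if (isn[k]) {
        j <- j + 1L
        gs[[j]] <- g[, starts[k]:ends[k], drop = FALSE]
      }
    }
    gs
  })
}

ad_rbind_list <- function(tape, xs) {
  vals <- lapply(xs, ad_val)
  hts <- vapply(vals, nrow, integer(1))
  out <- do.call(rbind, vals)
  isn <- vapply(xs, is_ad, logical(1))
  ends <- cumsum(hts)
  starts <- ends - hts + 1L
  ad_node(tape, out, parents = xs[isn], vjp = function(g) {
    gs <- vector("list", sum(isn))
    j <- 0L
    for (k in seq_along(xs)) {
      if (isn[k]) {
        j <- j + 1L
        gs[[j]] <- g[starts[k]:ends[k], , drop = FALSE]
      }
    }
    gs
  })
}

# --- softmax over groups ----------------------------------------------------

# Column-wise softmax within row groups: rows sharing group[i] form one
# softmax support per column, stabilized by the per-group maximum. Used
# for GAT neighbourhoods, transformer attention rows and attention
# pooling.
ad_group_softmax <- function(tape, s, group, ngroups) {
  sv <- ad_val(s)
  group <- as.integer(group)
  a <- cpp_group_softmax(sv, group, as.integer(ngroups))
  ad_node(tape, a, parents = node_parents(s), vjp = function(g) {
    list(cpp_group_softmax_bwd(a, g, group, as.integer(ngroups)))
  })
}

# Fused attention scores over an edge list: per head h,
# scores[k, h] = scale * <Q[qidx[k]], K[kidx[k]]>_head-h-block.
ad_edge_scores <- function(tape, Q, K, qidx, kidx, nheads, scale) {
  Qv <- ad_val(Q); Kv <- ad_val(K)
  qidx <- as.integer(qidx); kidx <- as.integer(kidx)
  out <- cpp_edge_scores(Qv, Kv, qidx, kidx, as.integer(nheads), scale)
  qn <- is_ad(Q); kn <- is_ad(K)
  ad_node(tape, out, parents = node_parents(Q, K), vjp = function(g) {
    d <- cpp_edge_scores_bwd(g, Qv, Kv, qidx, kidx, scale)
    gs <- list()
    if (qn) gs <- c(gs, list(d$dQ))
    if (kn) gs <- c(gs, list(d$dK))
    gs
  })
}

# Fused attention aggregation: out[src[k], c] += alpha[k, head(c)] *
# V[dst[k], c]; replaces the gather/expand/multiply/scatter chain.
ad_attn_out <- function(tape, alpha, V, dst, src, ntok) {
  av <- ad_val(alpha); Vv <- ad_val(V)
  dst <- as.integer(dst); src <- as.integer(src)
  out <- cpp_attn_out(av, Vv, dst, src, as.integer(ntok))
  an <- is_ad(alpha); vn <- is_ad(V)
  ad_node(tape, out, parents = node_parents(alpha, V), vjp = function(g) {
    d <- cpp_attn_out_bwd(g, av, Vv, dst, src, nrow(Vv))
    gs <- list()
    if (an) gs <- c(gs, list(d$dA))
    if (vn) gs <- c(gs, list(d$dV))
    gs
  })
}

# --- normalization layers ---------------------------------------------------

# Row-wise layer normalization with learnable gain/shift.
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x)
  gv <- as.vector(ad_val(gamma)); bv <- as.vector(ad_val(beta))
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  vr <- rowMeans(xc * xc)
  inv <- 1 / sqrt(vr + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  xn <- is_ad(x); gn <- is_ad(gamma); bn <- is_ad(beta)
  ad_node(tape, out, parents = node_parents(x, gamma, beta), vjp = function(g) {
    gs <- list()
    if (xn) {
      gy <- sweep(g, 2L, gv, "*")
      t1 <- rowSums(gy)
      t2 <- rowSums(gy * xhat)
      gs <- c(gs, list((inv / d) * (d * gy - t1 - xhat * t2)))
    }
    if (gn) gs <- c(gs, list(matrix(colSums(g * xhat), 1L)))
    if (bn) gs <- c(gs, list(matrix(colSums(g), 1L)))
    gs
  })
}

# Per-feature batch normalization over the row (sample/node) dimension.
# `state` is an environment with $mean, $var updated in place while
# training; evaluation uses the running statistics.
ad_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ad_val(x)
  gv <- as.vector(ad_val(gamma)); bv <- as.vector(ad_val(beta))
  n <- nrow(xv)
  xn <- is_ad(x); gn <- is_ad(gamma); bn <- is_ad(beta)
  if (training) {
    mu <- colMeans(xv)
    xc <- sweep(xv, 2L, mu, "-")
    vr <- colMeans(xc * xc)
    unb <- if (n > 1L) vr * n / (n - 1L) else vr
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * unb
    inv <- 1 / sqrt(vr + eps)
    xhat <- sweep(xc, 2L, inv, "*")
    out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
    ad_node(tape, out, parents = node_parents(x, gamma, beta),
            vjp = function(g) {
      gs <- list()
      if (xn) {
        gy <- sweep(g, 2L, gv, "*")
        t1 <- colSums(gy)
        t2 <- colSums(gy * xhat)
        dx <- sweep(n * gy, 2L, t1, "-") - sweep(xhat, 2L, t2, "*")
        gs <- c(gs, list(sweep(dx, 2L, inv / n, "*")))
      }
      if (gn) gs <- c(gs, list(matrix(colSums(g * xhat), 1L)))
      if (bn) gs <- c(gs, list(matrix(colSums(g), 1L)))
      gs
    })
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- sweep(sweep(xv, 2L, state$mean, "-"), 2L, inv, "*")
    out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
    ad_node(tape, out, parents = node_parents(x, gamma, beta),
            vjp = function(g) {
      gs <- list()
      if (xn) gs <- c(gs, list(sweep(g, 2L, gv * inv, "*")))
      if (gn) gs <- c(gs, list(matrix(colSums(g * xhat), 1L)))
      if (bn) gs <- c(gs, list(matrix(colSums(g), 1L)))
      gs
    })
  }
}

# Inverted dropout; identity when not training.
ad_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(if (is_ad(x)) x else ad_node(tape, x))
  xv <- ad_val(x)
  keep <- matrix(stats::runif(length(xv)) >= p, nrow(xv), ncol(xv))
  sc <- 1 / (1 - p)
  out <- xv * keep * sc
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    list(g * keep * sc)
  })
}

# --- B-spline design matrix -------------------------------------------------

# Design matrix of B-spline basis functions evaluated at every entry of the
# column-stacked input (N x P -> N x (P * nb), feature-major blocks). The
# vector-Jacobian product uses the analytic derivative basis, so spline
# inputs that are themselves network activations receive gradients.
ad_bspline_design <- function(tape, x, grid, order) {
  xv <- ad_val(x)
  n <- nrow(xv); p <- ncol(xv)
  B <- bspline_basis(as.vector(xv), grid, order)
  nb <- ncol(B)
  out <- matrix(0, n, p * nb)
  for (j in seq_len(p)) {
    out[, ((j - 1L) * nb + 1L):(j * nb)] <- B[((j - 1L) * n + 1L):(j * n), ]
  }
  ad_node(tape, out, parents = node_parents(x), vjp = function(g) {
    Bd <- bspline_basis(as.vector(xv), grid, order, derivative = TRUE)
    dx <- matrix(0, n, p)
    for (j in seq_len(p)) {
      gb <- g[, ((j - 1L) * nb + 1L):(j * nb), drop = FALSE]
      dx[, j] <- rowSums(gb * Bd[((j - 1L) * n + 1L):(j * n), , drop = FALSE])
    }
    list(dx)
  })
}

# --- helpers ----------------------------------------------------------------

# Row scatter-add into a fixed number of buckets; absent buckets stay
# zero.
scatter_sum <- function(x, group, ngroups) {
  cpp_scatter_rows(x, as.integer(group), as.integer(ngroups))
}
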