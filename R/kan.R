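# Kolmogorov-Arnold network (KAN) regression head.
#
# Each KAN layer carries, per input-output edge, a learnable univariate
# function expressed in a B-spline basis over a fixed grid on [-1, 1], plus
# a residual "base" path through a SiLU activation. Layer inputs are
# rescaled to the grid domain with running min-max statistics (frozen at
# evaluation) and clamped, because B-splines vanish outside their support.

#' B-spline basis functions on a fixed grid
#'
#' Evaluates the `grid_size + order` B-spline basis functions (Cox-de Boor
#' recursion) at each point of `x`. The knot vector `grid` spans the domain
#' and is extended by `order` uniformly spaced knots on each side, so the
#' basis forms a partition of unity on the whole domain. Values of `x`
#' outside the domain are clamped to it.
#'
#' @param x Numeric vector of evaluation points.
#' @param grid Strictly increasing knot vector (default 5 intervals on
#'   \[-1, 1\]).
#' @param order Spline degree (default 3, cubic).
#' @param derivative If `TRUE`, return the first-derivative basis instead.
#' @return A `length(x)` by `length(grid) - 1 + order` matrix.
#' @examples
#' B <- bspline_basis(seq(-1, 1, 0.1))
#' stopifnot(all(abs(rowSums(B) - 1) < 1e-10))
#' @export
bspline_basis <- function(x, grid = seq(-1, 1, length.out = 6L), order = 3L,
                          derivative = FALSE) {
  if (!is.numeric(grid) || length(grid) < 2L || any(diff(grid) <= 0)) {
    abort("`grid` must be a strictly increasing knot vector of length >= 2.")
  }
  if (!is_count(order)) abort("`order` must be a positive integer.")
  order <- as.integer(order)
  lo <- grid[1L]; hi <- grid[length(grid)]
  x <- pmin(pmax(as.numeric(x), lo), hi)
  h_lo <- grid[2L] - grid[1L]
  h_hi <- hi - grid[length(grid) - 1L]
  ext <- c(lo - rev(seq_len(order)) * h_lo, grid,
           hi + seq_len(order) * h_hi)
  cpp_bspline_basis(x, ext, order, length(grid), isTRUE(derivative))
}

#' Parameters for one KAN layer
#'
#' @param in_dim,out_dim Layer widths.
#' @param grid_size Number of spline intervals on \[-1, 1\] (default 5).
#' @param order Spline degree (default 3).
#' @param seed Integer seed for initialization.
#' @return A list with the base weight matrix, spline coefficient matrix
#'   (flattened to `(in_dim * n_basis) x out_dim`), the knot grid and the
#'   running input-range state.
#' @export
kan_layer_params <- function(in_dim, out_dim, grid_size = 5L, order = 3L,
                             seed = 1L) {
  stopifnot(is_count(in_dim), is_count(out_dim), is_count(grid_size))
  nb <- grid_size + order
  with_seed(seed, {
    list(
      base = glorot(in_dim, out_dim),
      coef = matrix(rnorm(in_dim * nb * out_dim, sd = 0.1 / sqrt(nb)),
                    in_dim * nb, out_dim),
      grid = seq(-1, 1, length.out = grid_size + 1L),
      order = as.integer(order),
      in_dim = as.integer(in_dim),
      out_dim = as.integer(out_dim)
    )
  })
}

kan_layer_state <- function(in_dim) {
  st <- new.env(parent = emptyenv())
  st$mn <- rep(-1, in_dim)
  st$mx <- rep(1, in_dim)
  st$seen <- FALSE
  st
}

# Affine rescale of each input feature to the spline domain [-1, 1] using
# the running min-max range (monotone-expanding during training, frozen at
# evaluation), then clamp: B-splines vanish outside their support, so
# out-of-range values must not fall off the grid. The range only ever
# widens, keeping the normalization stable under the optimizer.
kan_normalize <- function(tape, x, st, training) {
  xv <- ad_val(x)
  if (training) {
    bmn <- apply(xv, 2L, min)
    bmx <- apply(xv, 2L, max)
    if (!st$seen) {
      st$mn <- bmn; st$mx <- bmx; st$seen <- TRUE
    } else {
      st$mn <- pmin(st$mn, bmn)
      st$mx <- pmax(st$mx, bmx)
    }
  }
  rng <- pmax(st$mx - st$mn, 1e-8)
  scale <- 2 / rng
  shift <- -(st$mx + st$mn) / rng
  ad_clamp(tape, ad_affine_cols(tape, x, scale, shift), -1, 1)
}

ad_kan_layer <- function(tape, x, p, st, training) {
  xn <- kan_normalize(tape, x, st, training)
  base <- ad_matmul(tape, ad_silu(tape, xn), p$base)
  design <- ad_bspline_design(tape, xn, p$grid, p$order)
  ad_add(tape, base, ad_matmul(tape, design, p$coef))
}

#' Forward pass of a single KAN layer
#'
#' Computes `out_q = sum_p [ base_pq * SiLU(x_p) + sum_k c_pqk B_k(x_p) ]`
#' for a single input vector or a matrix of row vectors. Inputs are mapped
#' to the spline domain with the layer's stored input range.
#'
#' @param x Numeric vector of length `in_dim`, or a matrix with `in_dim`
#'   columns.
#' @param params A [kan_layer_params()] list.
#' @param state Optional running-range state (defaults to the identity
#'   range \[-1, 1\]).
#' @return A vector of length `out_dim` (or a matrix of row outputs).
#' @export
kan_layer_forward <- function(x, params, state = NULL) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, 1L)
  if (ncol(x) != params$in_dim) {
    abort(sprintf("input width %d does not match layer in_dim %d.",
                  ncol(x), params$in_dim))
  }
  if (!all(is.finite(x))) abort("KAN layer input must be finite.")
  st <- state %||% kan_layer_state(params$in_dim)
  tape <- ad_tape()
  out <- ad_val(ad_kan_layer(tape, x, params, st, training = FALSE))
  if (vec_in) as.vector(out) else out
}

#' Parameters for a stacked KAN block
#'
#' @param widths Integer vector of layer widths, input first and 1 last
#'   (default `c(512, 256, 64, 1)`, matching a 512-wide fused input).
#' @param grid_size,order Spline grid settings shared by all layers.
#' @param seed Integer seed.
#' @param mlp If `TRUE`, build a width-matched linear+ReLU multilayer
#'   perceptron instead (the W/O-KAN ablation head).
#' @return A `kan_block_params` list with per-layer parameters and states.
#' @export
kan_block_params <- function(widths = c(512L, 256L, 64L, 1L), grid_size = 5L,
                             order = 3L, seed = 1L, mlp = FALSE) {
  stopifnot(length(widths) >= 2L, all(widths >= 1L))
  widths <- as.integer(widths)
  layers <- vector("list", length(widths) - 1L)
  states <- vector("list", length(widths) - 1L)
  for (i in seq_along(layers)) {
    if (mlp) {
      layers[[i]] <- with_seed(hash_seed("mlp", seed, i),
                               init_linear(widths[i], widths[i + 1L]))
    } else {
      layers[[i]] <- kan_layer_params(widths[i], widths[i + 1L], grid_size,
                                      order, seed = hash_seed("kan", seed, i))
    }
    states[[i]] <- kan_layer_state(widths[i])
  }
  structure(list(widths = widths, layers = layers, states = states,
                 mlp = mlp), class = "kan_block_params")
}

ad_kan_block <- function(tape, z, p, training) {
  h <- z
  nl <- length(p$layers)
  for (i in seq_len(nl)) {
    if (p$mlp) {
      h <- ad_linear(tape, h, p$layers[[i]])
      if (i < nl) h <- ad_relu(tape, h)
    } else {
      h <- ad_kan_layer(tape, h, p$layers[[i]], p$states[[i]], training)
    }
  }
  h
}

#' Map a fused representation to a predicted affinity
#'
#' Runs the stacked KAN block (or its MLP ablation twin) in evaluation
#' mode: running input ranges are frozen and no dropout is active.
#'
#' @param z Numeric vector whose length equals the block's input width, or
#'   a matrix of row vectors.
#' @param params A [kan_block_params()] object.
#' @return A single predicted value per input row.
#' @export
kan_block <- function(z, params) {
  vec_in <- is.null(dim(z))
  if (vec_in) z <- matrix(z, 1L)
  if (ncol(z) != params$widths[1L]) {
    abort(sprintf("input width %d does not match block width %d.",
                  ncol(z), params$widths[1L]))
  }
  tape <- ad_tape()
  out <- ad_val(ad_kan_block(tape, z, params, training = FALSE))
  if (vec_in && nrow(out) == 1L) as.vector(out) else out
}

#' Export the learned univariate spline curves of a KAN layer
#'
#' Evaluates every input-output edge function (spline part plus SiLU base
#' path) of one layer on a grid over the spline domain, for inspection or
#' plotting of what each edge has learned.
#'
#' @param params A [kan_layer_params()] list (or one layer of a
#'   [kan_block_params()] object).
#' @param n_points Number of evaluation points on \[-1, 1\].
#' @return A tibble with `input`, `output`, `x` and the edge function
#'   value `f`.
#' @export
kan_spline_table <- function(params, n_points = 101L) {
  if (!is.null(params$mlp) && params$mlp) {
    abort("an MLP head has no spline curves to export.")
  }
  x <- seq(-1, 1, length.out = n_points)
  B <- bspline_basis(x, params$grid, params$order)
  nb <- ncol(B)
  silu <- x / (1 + exp(-x))
  out <- vector("list", params$in_dim * params$out_dim)
  k <- 0L
  for (p in seq_len(params$in_dim)) {
    rows <- ((p - 1L) * nb + 1L):(p * nb)
    for (q in seq_len(params$out_dim)) {
      k <- k + 1L
      f <- as.vector(B %*% params$coef[rows, q]) +
        params$base[p, q] * silu
      out[[k]] <- tibble::tibble(input = p, output = q, x = x, f = f)
    }
  }
  dplyr::bind_rows(out)
}

#' Fit a univariate curve with a KAN block
#'
#' Small self-contained trainer used to demonstrate (and test) the
#' approximation capacity of the spline head: minimizes mean squared error
#' with Adam on all spline coefficients and base weights.
#'
#' @param x,y Numeric vectors of equal length (scalar regression pairs).
#' @param widths Layer widths; first entry must be 1.
#' @param steps Number of full-batch gradient steps.
#' @param lr Adam learning rate.
#' @param seed Integer seed for initialization.
#' @return A list with the trained `params`, a `predict(newx)` closure and
#'   the final training `mse`.
#' @export
kan_fit_curve <- function(x, y, widths = c(1L, 8L, 1L), steps = 500L,
                          lr = 0.01, seed = 1L) {
  stopifnot(length(x) == length(y), widths[1L] == 1L,
            widths[length(widths)] == 1L)
  p <- kan_block_params(widths, seed = seed)
  X <- matrix(x, ncol = 1L)
  Y <- matrix(y, ncol = 1L)
  flat <- flatten_params(p$layers)
  opt <- adam_state(flat)
  final_mse <- NA_real_
  for (s in seq_len(steps)) {
    tape <- ad_tape()
    wp <- wrap_params(tape, p$layers)
    pp <- p
    pp$layers <- wp
    pred <- ad_kan_block(tape, X, pp, training = TRUE)
    diff <- ad_sub(tape, pred, Y)
    loss <- ad_mean(tape, ad_mul(tape, diff, diff))
    final_mse <- ad_val(loss)[1L]
    ad_backward(tape, loss)
    grads <- collect_grads(wp)
    flat <- adam_step(flat, flatten_params(grads), opt, lr = lr)
    p$layers <- unflatten_params(flat, p$layers)
  }
  params <- p
  list(
    params = params,
    predict = function(newx) as.vector(kan_block(matrix(newx, ncol = 1L),
                                                 params)),
    mse = final_mse
  )
}
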