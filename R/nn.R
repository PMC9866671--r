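# Minimal computation-graph engine behind the segmentation models.
#
# A network is a DAG of nodes (input / conv / relu / pool / up / concat).
# Feature maps are H x W x C arrays in R's column-major layout; convolutions
# run through C++ im2col kernels. The backward pass walks the graph in
# reverse, accumulating gradients for the named parameter sets, which is all
# the freezing/fine-tuning machinery needs: an optimiser update is simply
# restricted to a set of parameter names.

nn_graph_new <- function() {
  list(nodes = list(), params = list(), shapes = list())
}

nn_add <- function(g, op, inputs = integer(), param = NULL, ...) {
  g$nodes[[length(g$nodes) + 1L]] <-
    c(list(op = op, inputs = inputs, param = param), list(...))
  g$id <- length(g$nodes)
  g
}

# He-normal initialisation for one conv parameter set.
nn_init_conv <- function(kh, kw, cin, cout) {
  w <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin * cout))
  list(W = w, b = numeric(cout), cin = cin, cout = cout,
       kh = kh, kw = kw)
}

nn_param_count <- function(p) length(p$W) + length(p$b)

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

downsum2 <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

# Forward pass. x: H x W x Cin array. Returns per-node outputs and caches.
nn_forward <- function(net, x) {
  outs <- vector("list", length(net$nodes))
  for (k in seq_along(net$nodes)) {
    nd <- net$nodes[[k]]
    outs[[k]] <- switch(nd$op,
      input = list(y = x),
      conv = {
        p <- net$params[[nd$param]]
        xin <- outs[[nd$inputs]]$y
        list(y = .conv2d_fwd(xin, p$W, p$b, p$cout, nd$pad, nd$dil))
      },
      relu = {
        y <- outs[[nd$inputs]]$y
        y[y < 0] <- 0
        list(y = y)
      },
      pool = {
        r <- .maxpool2_fwd(outs[[nd$inputs]]$y)
        list(y = r$y, idx = r$idx, insize = dim(outs[[nd$inputs]]$y))
      },
      up = list(y = upsample2(outs[[nd$inputs]]$y)),
      concat = {
        xs <- lapply(nd$inputs, function(i) outs[[i]]$y)
        d <- dim(xs[[1]])
        nc <- vapply(xs, function(a) dim(a)[3], numeric(1))
        list(y = array(unlist(xs, use.names = FALSE),
                       dim = c(d[1], d[2], sum(nc))), nc = nc)
      },
      abort(paste0("unknown op: ", nd$op))
    )
  }
  outs
}

# Backward pass from a gradient on the final node's output.
# Returns list(params = named grads, dinput = gradient at the input node).
nn_backward <- function(net, outs, dfinal) {
  n <- length(net$nodes)
  douts <- vector("list", n)
  douts[[n]] <- dfinal
  grads <- list()
  add_grad <- function(cur, extra) if (is.null(cur)) extra else cur + extra
  for (k in rev(seq_len(n))) {
    dy <- douts[[k]]
    if (is.null(dy)) next
    nd <- net$nodes[[k]]
    switch(nd$op,
      input = NULL,
      conv = {
        p <- net$params[[nd$param]]
        xin <- outs[[nd$inputs]]$y
        g <- .conv2d_bwd(xin, p$W, dy, nd$pad, nd$dil)
        if (is.null(grads[[nd$param]])) {
          grads[[nd$param]] <- list(W = g$dw, b = as.numeric(g$db))
        } else {
          grads[[nd$param]]$W <- grads[[nd$param]]$W + g$dw
          grads[[nd$param]]$b <- grads[[nd$param]]$b + as.numeric(g$db)
        }
        douts[[nd$inputs]] <- add_grad(douts[[nd$inputs]], g$dx)
      },
      relu = {
        m <- outs[[k]]$y > 0
        douts[[nd$inputs]] <- add_grad(douts[[nd$inputs]], dy * m)
      },
      pool = {
        dsz <- outs[[k]]$insize
        dx <- .maxpool2_bwd(dy, outs[[k]]$idx, dsz[1], dsz[2])
        douts[[nd$inputs]] <- add_grad(douts[[nd$inputs]], dx)
      },
      up = {
        douts[[nd$inputs]] <- add_grad(douts[[nd$inputs]], downsum2(dy))
      },
      concat = {
        nc <- outs[[k]]$nc
        off <- 0L
        for (m in seq_along(nd$inputs)) {
          sl <- dy[, , (off + 1L):(off + nc[m]), drop = FALSE]
          douts[[nd$inputs[m]]] <- add_grad(douts[[nd$inputs[m]]], sl)
          off <- off + nc[m]
        }
      }
    )
    if (nd$op != "input") douts[[k]] <- NULL # free memory early
  }
  list(params = grads, dinput = douts[[1L]])
}

# Pixelwise softmax over the channel axis of an H x W x K logit array.
softmax_channels <- function(z) {
  mx <- pmax(z[, , 1], z[, , 2], z[, , 3])
  e <- exp(z - as.vector(mx))
  s <- e[, , 1] + e[, , 2] + e[, , 3]
  e / as.vector(s)
}

# Gradient of a loss wrt logits given dL/dp and p (softmax Jacobian).
softmax_backward <- function(p, dp) {
  inner <- p[, , 1] * dp[, , 1] + p[, , 2] * dp[, , 2] + p[, , 3] * dp[, , 3]
  p * (dp - as.vector(inner))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       t = 0L)
}

# One Adam step restricted to `trainable` parameter names.
adam_step <- function(params, grads, state, trainable,
                      lr = 3e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in intersect(trainable, names(grads))) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      state$m[[nm]][[part]] <- beta1 * state$m[[nm]][[part]] + (1 - beta1) * g
      state$v[[nm]][[part]] <- beta2 * state$v[[nm]][[part]] +
        (1 - beta2) * g * g
      mhat <- state$m[[nm]][[part]] / bc1
      vhat <- state$v[[nm]][[part]] / bc2
      params[[nm]][[part]] <- params[[nm]][[part]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
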