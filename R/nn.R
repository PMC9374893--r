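# Minimal conv-net engine: a network is a linear "tape" of ops
# (conv3/conv1/inorm/relu/pool/unpool/save/add/sigmoid/softmax) executed on
# tensors stored as R arrays of dim (C, X, Y, Z). Pooling records argmax
# indices; unpooling restores values at exactly those positions (LIFO pairing
# with the pools). Backward walks the tape in reverse. No external framework
# is involved; the 3D convolutions run through im2col + BLAS in C++.

new_param_conv <- function(cin, cout, k) {
  fan_in <- cin * k^3
  w <- matrix(stats::rnorm(cout * cin * k^3, sd = sqrt(2 / fan_in)),
              nrow = cout)
  list(w = w, b = numeric(cout))
}

# ---- forward ops -----------------------------------------------------------

nn_forward <- function(model, x, train = FALSE) {
  # x: 3D array (X,Y,Z) or (C,X,Y,Z)
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  orig_sp <- dim(x)[2:4]
  if (!is.null(model$min_input) && any(orig_sp < model$min_input))
    stop("input ", paste(orig_sp, collapse = "x"),
         " is below this net's receptive-field minimum ",
         paste(model$min_input, collapse = "x"))
  dv <- model$divisor
  pad <- (dv - orig_sp %% dv) %% dv
  lo <- pad %/% 2L
  if (any(pad > 0L)) {
    sp <- orig_sp + pad
    xp <- array(0, c(dim(x)[1], sp))
    xp[, lo[1] + seq_len(orig_sp[1]), lo[2] + seq_len(orig_sp[2]),
       lo[3] + seq_len(orig_sp[3])] <- x
    x <- xp
  }
  caches <- if (train) vector("list", length(model$tape)) else NULL
  saved <- list()
  pool_stack <- list()
  P <- model$params
  for (i in seq_along(model$tape)) {
    op <- model$tape[[i]]
    switch(op$op,
      conv3 = {
        sp <- dim(x)[2:4]
        if (train) caches[[i]] <- list(x = x, shape = sp)
        x <- conv3_fw(x, sp, P[[op$par]]$w, P[[op$par]]$b)
      },
      conv1 = {
        d <- dim(x)
        xm <- matrix(x, d[1])
        if (train) caches[[i]] <- list(x = xm, d = d)
        x <- P[[op$par]]$w %*% xm + P[[op$par]]$b
        x <- array(x, c(nrow(P[[op$par]]$w), d[2:4]))
      },
      inorm = {
        d <- dim(x)
        xm <- matrix(x, d[1])
        mu <- rowMeans(xm)
        xc <- xm - mu
        invstd <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
        xhat <- xc * invstd
        g <- P[[op$par]]$g
        x <- array(xhat * g + P[[op$par]]$b, d)
        if (train) caches[[i]] <- list(xhat = xhat, invstd = invstd, d = d)
      },
      relu = {
        m <- x > 0
        x <- x * m
        if (train) caches[[i]] <- m
      },
      pool = {
        sp <- dim(x)[2:4]
        r <- maxpool_fw(x, sp, op$factor)
        pool_stack[[length(pool_stack) + 1L]] <- list(idx = r$idx, dim = dim(x))
        if (train) caches[[i]] <- list(idx = r$idx, in_dim = dim(x))
        x <- r$y
      },
      unpool = {
        top <- pool_stack[[length(pool_stack)]]
        pool_stack[[length(pool_stack)]] <- NULL
        if (train) caches[[i]] <- list(idx = top$idx, out_dim = dim(x))
        x <- unpool_fw(x, top$idx, top$dim)
      },
      save = {
        saved[[op$name]] <- x
      },
      add = {
        x <- x + saved[[op$name]]
      },
      sigmoid = {
        x <- 1 / (1 + exp(-x))
        if (train) caches[[i]] <- x
      },
      softmax = {
        d <- dim(x)
        xm <- matrix(x, d[1])
        xm <- exp(sweep(xm, 2, apply(xm, 2, max)))
        xm <- sweep(xm, 2, colSums(xm), "/")
        x <- array(xm, d)
        if (train) caches[[i]] <- x
      },
      stop("unknown op: ", op$op)
    )
  }
  sp <- dim(x)[2:4]
  y <- x[, lo[1] + seq_len(orig_sp[1]), lo[2] + seq_len(orig_sp[2]),
         lo[3] + seq_len(orig_sp[3]), drop = FALSE]
  dim(y) <- c(dim(x)[1], orig_sp)
  if (train) list(y = y, caches = caches, pad_lo = lo, padded_sp = sp) else y
}

# dy: gradient w.r.t. the (cropped) output. Returns list of parameter grads
# (same structure as model$params).
nn_backward <- function(model, fwd, dy) {
  lo <- fwd$pad_lo
  sp <- fwd$padded_sp
  d <- dim(dy)
  g <- array(0, c(d[1], sp))
  g[, lo[1] + seq_len(d[2]), lo[2] + seq_len(d[3]), lo[3] + seq_len(d[4])] <- dy
  grads <- rapply(model$params, function(p) p * 0, how = "replace")
  saved_grad <- list()
  caches <- fwd$caches
  P <- model$params
  for (i in rev(seq_along(model$tape))) {
    op <- model$tape[[i]]
    cc <- caches[[i]]
    switch(op$op,
      conv3 = {
        r <- conv3_bw(cc$x, cc$shape, P[[op$par]]$w, g)
        grads[[op$par]]$w <- grads[[op$par]]$w + r$dw
        grads[[op$par]]$b <- grads[[op$par]]$b + r$db
        g <- r$dx
      },
      conv1 = {
        gm <- matrix(g, dim(g)[1])
        grads[[op$par]]$w <- grads[[op$par]]$w + tcrossprod(gm, cc$x)
        grads[[op$par]]$b <- grads[[op$par]]$b + rowSums(gm)
        g <- array(crossprod(P[[op$par]]$w, gm), cc$d)
      },
      inorm = {
        gm <- matrix(g, dim(g)[1])
        gpar <- P[[op$par]]$g
        grads[[op$par]]$g <- grads[[op$par]]$g + rowSums(gm * cc$xhat)
        grads[[op$par]]$b <- grads[[op$par]]$b + rowSums(gm)
        dxhat <- gm * gpar
        n <- ncol(gm)
        g <- array(cc$invstd / n *
                     (n * dxhat - rowSums(dxhat) -
                        cc$xhat * rowSums(dxhat * cc$xhat)), cc$d)
      },
      relu = {
        g <- g * cc
      },
      pool = {
        g <- unpool_fw(g, cc$idx, cc$in_dim)
      },
      unpool = {
        g <- gather_idx(g, cc$idx, cc$out_dim)
      },
      save = {
        if (!is.null(saved_grad[[op$name]]))
          g <- g + saved_grad[[op$name]]
      },
      add = {
        saved_grad[[op$name]] <-
          if (is.null(saved_grad[[op$name]])) g else saved_grad[[op$name]] + g
      },
      sigmoid = {
        g <- g * cc * (1 - cc)
      },
      softmax = {
        ym <- matrix(cc, dim(cc)[1])
        gm <- matrix(g, dim(g)[1])
        g <- array(ym * sweep(gm, 2, colSums(gm * ym)), dim(cc))
      }
    )
  }
  grads
}

# ---- parameters as flat lists, ADAM ---------------------------------------

nn_param_count <- function(model) {
  sum(vapply(model$params, function(p) sum(lengths(lapply(p, as.numeric))),
             numeric(1)))
}

adam_init <- function(model) {
  zeros <- rapply(model$params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (i in seq_along(model$params)) {
    for (f in names(model$params[[i]])) {
      gr <- grads[[i]][[f]]
      state$m[[i]][[f]] <- beta1 * state$m[[i]][[f]] + (1 - beta1) * gr
      state$v[[i]][[f]] <- beta2 * state$v[[i]][[f]] + (1 - beta2) * gr^2
      mhat <- state$m[[i]][[f]] / b1t
      vhat <- state$v[[i]][[f]] / b2t
      model$params[[i]][[f]] <- model$params[[i]][[f]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(model = model, state = state)
}
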