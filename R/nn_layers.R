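# Internal layer engine. A network is a plain list of layer descriptors;
# forward passes return caches that the matching backward pass consumes, and
# parameter gradients come back in a tree parallel to layers_get_params().
# Weight init is Glorot-uniform drawn from the caller's RNG stream, so model
# construction is reproducible under set.seed().

act_apply <- function(y, act) {
  switch(act, tanh = tanh(y), relu = pmax(y, 0), linear = y,
         stop("unknown activation: ", act))
}

# derivative expressed through the activation output
act_grad_from_y <- function(y, act) {
  switch(act, tanh = 1 - y^2, relu = (y > 0) * 1, linear = array(1, dim(y)),
         stop("unknown activation: ", act))
}

glorot_mat <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

layer_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L, act = "tanh") {
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
       act = act,
       W = glorot_mat(cout, cin * k * k, cin * k * k, cout * k * k),
       b = numeric(cout))
}

layer_convT <- function(cin, cout, k, stride, pad, act = "linear") {
  list(type = "convT", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
       act = act,
       W = glorot_mat(cin, cout * k * k, cin * k * k, cout * k * k),
       b = numeric(cout))
}

layer_ps <- function(r) list(type = "ps", r = r)

layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)

# Pre-activation-free residual block: relu(body(x) + proj(x)); proj NULL means
# identity shortcut.
layer_residual <- function(body, proj = NULL)
  list(type = "residual", body = body, proj = proj)

as_cube <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- nn_conv_fwd(as_cube(x), layer$W, layer$b, layer$cin, layer$k,
                       layer$stride, layer$pad)
      y <- act_apply(y, layer$act)
      list(y = y, cache = list(x = x, y = y))
    },
    convT = {
      y <- nn_convT_fwd(as_cube(x), layer$W, layer$b, layer$cin, layer$k,
                        layer$stride, layer$pad)
      y <- act_apply(y, layer$act)
      list(y = y, cache = list(x = x, y = y))
    },
    ps = {
      cin <- dim(as_cube(x))[3L]
      list(y = nn_pixel_shuffle(as_cube(x), layer$r, cin),
           cache = list(cin = cin))
    },
    maxpool = {
      r <- nn_maxpool_fwd(as_cube(x), layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = list(idx = r$idx, H = dim(as_cube(x))[1L],
                                 W = dim(as_cube(x))[2L]))
    },
    residual = {
      fb <- net_forward(layer$body, x)
      sc <- if (is.null(layer$proj)) list(y = as_cube(x), caches = NULL)
            else net_forward(layer$proj, x)
      y <- act_apply(fb$y + sc$y, "relu")
      list(y = y, cache = list(body = fb$caches, proj = sc$caches, y = y, x = x))
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    conv = {
      g <- gy * act_grad_from_y(cache$y, layer$act)
      r <- nn_conv_bwd(as_cube(cache$x), layer$W, g, layer$cin, layer$k,
                       layer$stride, layer$pad)
      list(gx = r$gx, grads = list(W = r$gW, b = as.numeric(r$gb)))
    },
    convT = {
      g <- gy * act_grad_from_y(cache$y, layer$act)
      r <- nn_convT_bwd(as_cube(cache$x), layer$W, g, layer$cin, layer$k,
                        layer$stride, layer$pad)
      list(gx = r$gx, grads = list(W = r$gW, b = as.numeric(r$gb)))
    },
    ps = list(gx = nn_pixel_unshuffle(as_cube(gy), layer$r,
                                      cache$cin %/% (layer$r^2)),
              grads = NULL),
    maxpool = list(gx = nn_maxpool_bwd(as_cube(gy), cache$idx, cache$H, cache$W),
                   grads = NULL),
    residual = {
      g <- gy * act_grad_from_y(cache$y, "relu")
      rb <- net_backward(layer$body, cache$body, g)
      if (is.null(layer$proj)) {
        gx <- rb$gx + g
        gp <- NULL
      } else {
        rp <- net_backward(layer$proj, cache$proj, g)
        gx <- rb$gx + rp$gx
        gp <- rp$grads
      }
      list(gx = gx, grads = list(body = rb$grads, proj = gp))
    },
    stop("unknown layer type"))
}

net_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

net_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], gy)
    gy <- r$gx
    grads[[i]] <- r$grads
  }
  list(gx = gy, grads = grads)
}

layers_get_params <- function(layers) {
  lapply(layers, function(l) switch(l$type,
    conv = , convT = list(W = l$W, b = l$b),
    residual = list(body = layers_get_params(l$body),
                    proj = if (is.null(l$proj)) NULL else layers_get_params(l$proj)),
    NULL))
}

layers_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "convT")) {
      layers[[i]]$W <- params[[i]]$W
      layers[[i]]$b <- params[[i]]$b
    } else if (l$type == "residual") {
      layers[[i]]$body <- layers_set_params(l$body, params[[i]]$body)
      if (!is.null(l$proj))
        layers[[i]]$proj <- layers_set_params(l$proj, params[[i]]$proj)
    }
  }
  layers
}

# ---- tree utilities over nested lists of numeric leaves -------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x))
  else if (is.null(a)) NULL
  else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) tree_map2(f, x, y), a, b)
  else if (is.null(a)) NULL
  else f(a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_sq_norm <- function(a) {
  s <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else if (!is.null(x)) s <<- s + sum(x^2)
    invisible(NULL)
  }
  walk(a)
  s
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
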