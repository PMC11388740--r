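# The training core is hand-written, so its backward passes are validated
# against central finite differences on every layer type, including the
# container combinators.

grad_check_spec <- function(spec, xdim, seed, eps = 1e-5) {
  set.seed(seed)
  params <- irbedpose:::nn_init(spec)
  state <- irbedpose:::nn_state_init(spec)
  x <- array(rnorm(prod(xdim)), dim = xdim)
  fw <- irbedpose:::nn_forward(spec, params, state, x, training = TRUE)
  tgt <- fw$y * 0 + rnorm(length(fw$y))
  loss_of <- function(p, xx)
    sum((irbedpose:::nn_forward(spec, p, state, xx, training = TRUE)$y - tgt)^2)
  bk <- irbedpose:::nn_backward(spec, params, fw$cache, 2 * (fw$y - tgt))

  flat <- function(p, path = "") {
    if (is.numeric(p)) return(setNames(list(p), path))
    out <- list()
    for (i in seq_along(p))
      out <- c(out, flat(p[[i]], paste0(path, "/", i)))
    out
  }
  setleaf <- function(p, idx, v) {
    if (length(idx) == 0) return(v)
    p[[idx[1]]] <- setleaf(p[[idx[1]]], idx[-1], v)
    p
  }
  fp <- flat(params)
  fg <- flat(bk$grads)
  maxerr <- 0
  for (k in sample(seq_along(fp), min(5, length(fp)))) {
    idx <- as.integer(strsplit(names(fp)[k], "/")[[1]][-1])
    leaf <- fp[[k]]
    for (j in sample(length(leaf), min(3, length(leaf)))) {
      l1 <- leaf; l1[j] <- l1[j] + eps
      l2 <- leaf; l2[j] <- l2[j] - eps
      num <- (loss_of(setleaf(params, idx, l1), x) -
              loss_of(setleaf(params, idx, l2), x)) / (2 * eps)
      ana <- fg[[k]][j]
      maxerr <- max(maxerr, abs(num - ana) / max(1, abs(num), abs(ana)))
    }
  }
  for (j in sample(length(x), 4)) {
    x1 <- x; x1[j] <- x1[j] + eps
    x2 <- x; x2[j] <- x2[j] - eps
    num <- (loss_of(params, x1) - loss_of(params, x2)) / (2 * eps)
    maxerr <- max(maxerr, abs(num - bk$gx[j]) / max(1, abs(num), abs(bk$gx[j])))
  }
  maxerr
}

test_that("analytic gradients match finite differences for every layer type", {
  nn <- asNamespace("irbedpose")
  specs <- list(
    strided_conv = nn$nn_seq(nn$nn_conv(3, 3, 2, 3, stride = 2)),
    conv_bn_relu = nn$nn_seq(nn$nn_conv(3, 3, 2, 4), nn$nn_bn(4),
                             nn$nn_act("relu")),
    selu_avgpool = nn$nn_seq(nn$nn_conv(3, 3, 2, 3), nn$nn_act("selu"),
                             nn$nn_pool("avg", 5)),
    maxpool = nn$nn_seq(nn$nn_pool("max", 3), nn$nn_conv(1, 1, 2, 2, pad = 0)),
    upsample = nn$nn_seq(nn$nn_resize(factor = 2), nn$nn_conv(3, 3, 2, 2)),
    resize_to = nn$nn_seq(nn$nn_conv(3, 3, 2, 2), nn$nn_resize(h = 5, w = 7)),
    softmax2d = nn$nn_seq(nn$nn_conv(1, 1, 2, 3, pad = 0), nn$nn_softmax2d()),
    head = nn$nn_seq(nn$nn_conv(3, 3, 2, 4, stride = 2), nn$nn_gap(),
                     nn$nn_linear(4, 1), nn$nn_act("sigmoid")),
    residual_parcat = nn$nn_seq(
      nn$nn_parcat(nn$nn_seq(nn$nn_conv(1, 1, 2, 3, pad = 0),
                             nn$nn_act("selu")),
                   nn$nn_seq(nn$nn_conv(3, 3, 2, 3), nn$nn_bn(3))),
      nn$nn_res(nn$nn_seq(nn$nn_conv(3, 3, 6, 6), nn$nn_act("relu")))))
  for (nm in names(specs)) {
    err <- grad_check_spec(specs[[nm]], c(8, 10, 2, 3), seed = 42)
    expect_lt(err, 1e-5, label = paste0(nm, " gradient error"))
  }
})

test_that("AdamW steps reduce a simple regression loss", {
  nn <- asNamespace("irbedpose")
  spec <- nn$nn_seq(nn$nn_linear(3, 2))
  set.seed(1)
  params <- nn$nn_init(spec)
  state <- nn$nn_state_init(spec)
  x <- matrix(rnorm(3 * 16), 3, 16)
  w_true <- matrix(c(1, -2, 0.5, 0, 1, -1), 2, 3)
  y_true <- w_true %*% x
  opt <- nn$adamw_init(params)
  losses <- numeric(0)
  for (t in 1:200) {
    fw <- nn$nn_forward(spec, params, state, x)
    losses <- c(losses, mean((fw$y - y_true)^2))
    bk <- nn$nn_backward(spec, params, fw$cache,
                         2 * (fw$y - y_true) / length(y_true))
    r <- nn$adamw_step(params, bk$grads, opt, lr = 0.05, t = t)
    params <- r$params
    opt <- r$opt
  }
  expect_lt(tail(losses, 1), 0.01 * losses[1])
})

test_that("spatial softmax normalises each channel and one-cycle lr peaks at max", {
  nn <- asNamespace("irbedpose")
  x <- array(rnorm(6 * 5 * 3 * 2), dim = c(6, 5, 3, 2))
  y <- nn$spatial_softmax(x)
  sums <- apply(y, c(3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  lrs <- vapply(1:100, function(s) nn$one_cycle_lr(s, 100, 9e-4), numeric(1))
  expect_equal(max(lrs), 9e-4, tolerance = 1e-12)
  expect_lt(lrs[100], 9e-4 / 10)
})

test_that("with_seed is reproducible and leaves global RNG state intact", {
  nn <- asNamespace("irbedpose")
  set.seed(99)
  before <- .Random.seed
  a <- nn$with_seed(7, runif(5))
  expect_identical(.Random.seed, before)
  b <- nn$with_seed(7, runif(5))
  expect_identical(a, b)
  expect_true(derive_seed(1, "augment") != derive_seed(1, "fixtures"))
  expect_true(derive_seed(1, "augment") < 2^31)
})
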