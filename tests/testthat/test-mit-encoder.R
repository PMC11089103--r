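# Encoder geometry, SRA attention against a brute-force oracle, Mix-FFN
# contracts and pyramid shapes.

test_that("overlapped patch merging follows conv output geometry", {
  x <- random_image(64, 64)
  out <- overlapped_patch_merge(x, K = 7, S = 4, P = 3, c_out = 8)
  expect_identical(dim(out), c(16L, 16L, 8L))      # floor((64+6-7)/4)+1
  # K=1,S=1,P=0 keeps spatial dims
  out1 <- overlapped_patch_merge(x, K = 1, S = 1, P = 0, c_out = 4)
  expect_identical(dim(out1)[1:2], c(64L, 64L))
  expect_error(
    overlapped_patch_merge(random_image(6, 6), K = 7, S = 4, P = 0, c_out = 4),
    "too small")
  expect_error(overlapped_patch_merge(x, K = 2, S = 4, P = 0, c_out = 4),
               "overlap")
  # the 512-pixel arithmetic that yields the 1/4-resolution stage-1 grid
  expect_equal(floor((512 + 2 * 3 - 7) / 4) + 1, 128)
})

# direct per-row evaluation of softmax(Q K^T / sqrt(d)) V, loops only
brute_force_attention <- function(x, p, heads) {
  C <- ncol(x); d <- C / heads
  Q <- x %*% p$Wq + matrix(p$bq, nrow(x), C, byrow = TRUE)
  K <- x %*% p$Wk + matrix(p$bk, nrow(x), C, byrow = TRUE)
  V <- x %*% p$Wv + matrix(p$bv, nrow(x), C, byrow = TRUE)
  O <- matrix(0, nrow(x), C)
  for (j in seq_len(heads)) {
    ix <- ((j - 1) * d + 1):(j * d)
    for (n in seq_len(nrow(x))) {
      s <- as.numeric(K[, ix, drop = FALSE] %*% Q[n, ix]) / sqrt(d)
      a <- exp(s - max(s)); a <- a / sum(a)
      O[n, ix] <- colSums(a * V[, ix, drop = FALSE])
    }
  }
  O %*% p$Wo + matrix(p$bo, nrow(x), C, byrow = TRUE)
}

make_attn_params <- function(C, R = 1, seed = 5) {
  set.seed(seed)
  mk <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.3), nr, nc)
  p <- list(Wq = mk(C, C), bq = rnorm(C), Wk = mk(C, C), bk = rnorm(C),
            Wv = mk(C, C), bv = rnorm(C), Wo = mk(C, C), bo = rnorm(C))
  if (R > 1) {
    p$Wsr <- mk(R * R * C, C); p$bsr <- rnorm(C)
    p$srnorm.g <- runif(C, 0.5, 1.5); p$srnorm.b <- rnorm(C)
  }
  p
}

test_that("SRA with R = 1 reproduces brute-force full attention", {
  for (hw in list(c(4L, 4L), c(8L, 8L), c(16L, 16L))) {
    H <- hw[1]; W <- hw[2]; C <- 16L
    set.seed(H)
    x <- matrix(rnorm(H * W * C), H * W, C)
    p <- make_attn_params(C, seed = H)
    for (heads in c(1L, 4L)) {
      got <- efficient_self_attention(x, H, W, heads, R = 1L, params = p)
      want <- brute_force_attention(x, p, heads)
      expect_lt(max(abs(got - want)), 1e-5)
    }
  }
})

test_that("attention probability rows sum to one and K/V length is N / R^2", {
  H <- W <- 8L; C <- 8L
  x <- matrix(rnorm(H * W * C), H * W, C)
  p <- make_attn_params(C, R = 2)
  res <- mitseg:::attn_fwd(x, H, W, p, heads = 2L, R = 2L, eps = 1e-6)
  for (A in res$cache$A) {
    expect_equal(rowSums(A), rep(1, H * W), tolerance = 1e-6)
    expect_identical(ncol(A), H * W %/% 4L)   # sequence shortened by R^2
  }
  expect_error(
    efficient_self_attention(x, H, W, heads = 2L, R = 3L,
                             params = make_attn_params(C, R = 3)),
    "tile")
})

test_that("a single token attends only to itself", {
  C <- 6L
  x <- matrix(rnorm(C), 1L, C)
  p <- make_attn_params(C)
  p$bo <- rep(0, C)
  got <- efficient_self_attention(x, 1L, 1L, heads = 1L, R = 1L, params = p)
  v <- x %*% p$Wv + matrix(p$bv, 1L, C)
  expect_equal(got, v %*% p$Wo, tolerance = 1e-10)
})

test_that("Mix-FFN is a residual-ready map with the pinned hidden width", {
  H <- W <- 16L; C <- 32L
  x <- matrix(rnorm(H * W * C), H * W, C)
  zero <- list(W1 = matrix(0, C, 4 * C), b1 = rep(0, 4 * C),
               Wdw = array(0, c(3, 3, 4 * C)), bdw = rep(0, 4 * C),
               W2 = matrix(0, 4 * C, C), b2 = rep(0, C))
  # zeroed weights: the block contributes nothing, residual returns input
  expect_equal(x + mix_ffn(x, H, W, params = zero), x)
  out <- mix_ffn(x, H, W, mlp_ratio = 4L, seed = 2)
  expect_identical(dim(out), dim(x))
  ffn <- mitseg:::ffn_fwd(x, H, W, list(
    W1 = matrix(rnorm(C * 128), C), b1 = rep(0, 128),
    Wdw = array(0, c(3, 3, 128)), bdw = rep(0, 128),
    W2 = matrix(0, 128, C), b2 = rep(0, C)))
  expect_identical(ncol(ffn$cache$f1$out), 128L)   # mlp_ratio * C = 128
  expect_error(mix_ffn(x, 15L, W), "reshapeable")
})

test_that("encode yields the 1/4..1/32 pyramid with spec channel widths", {
  sp <- tiny_spec()
  pyr <- encode(random_image(64, 64), sp, seed = 3)
  dims <- sapply(pyr$levels, dim)
  expect_equal(dims[1, ], c(16, 8, 4, 2))
  expect_equal(dims[2, ], c(16, 8, 4, 2))
  expect_equal(dims[3, ], sp$hidden_dims)
  # strictly decreasing space, strictly increasing channels
  expect_true(all(diff(dims[1, ]) < 0) && all(diff(dims[3, ]) > 0))
  expect_error(encode(random_image(16, 16), sp), "minimum")
})

test_that("encoding is deterministic for fixed weights and input", {
  sp <- tiny_spec()
  img <- random_image(64, 96, seed = 9)
  params <- init_params(sp, "encoder", seed = 4)
  p1 <- encode(img, sp, params)
  p2 <- encode(img, sp, params)
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip the flat parameter container", {
  params <- init_params(tiny_spec(), "encoder", seed = 6)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(params, path)
  expect_identical(load_checkpoint(path), params)
})
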