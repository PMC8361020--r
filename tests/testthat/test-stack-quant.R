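test_that("median denoising matches a brute-force neighborhood median", {
  const <- array(5, c(4L, 4L, 4L))
  expect_equal(median_denoise(const), const)

  spike <- array(0, c(5L, 5L, 5L))
  spike[3L, 3L, 3L] <- 100
  expect_equal(median_denoise(spike), array(0, c(5L, 5L, 5L)))

  set.seed(1)
  a <- array(stats::runif(125L), c(5L, 5L, 5L))
  out <- median_denoise(a)
  refl <- function(i, n) hskit:::reflect_index(i, n)
  brute <- array(0, dim(a))
  for (z in 1:5) for (y in 1:5) for (x in 1:5) {
    vals <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      vals <- c(vals, a[refl(z + dz, 5L), refl(y + dy, 5L), refl(x + dx, 5L)])
    }
    brute[z, y, x] <- stats::median(vals)
  }
  expect_equal(out, brute)
})

test_that("unsharp masking is the identity on flat input and sharpens steps", {
  const <- array(3, c(4L, 6L, 6L))
  expect_equal(unsharp_enhance(const), const)

  set.seed(2)
  a <- array(stats::runif(144L, 1, 2), c(4L, 6L, 6L))
  expect_equal(unsharp_enhance(a, amount = 0), a)

  # a step along X gains contrast across the step
  step <- array(10, c(5L, 7L, 10L))
  step[, , 6:10] <- 50
  out <- unsharp_enhance(step)
  before <- mean(step[, , 6L]) - mean(step[, , 5L])
  after <- mean(out[, , 6L]) - mean(out[, , 5L])
  expect_gt(after, before)
  expect_true(all(out >= 0))
})

test_that("Richardson-Lucy fixes constants, stays non-negative, and matches a
           hand-computed one-step update", {
  const <- array(7, c(4L, 6L, 6L))
  expect_equal(rl_restore(const), const)

  set.seed(3)
  a <- array(stats::runif(240L, 0, 10), c(4L, 6L, 10L))
  expect_true(all(rl_restore(a) >= 0))

  # one iteration on a 1 x 1 x 5 stack with a (1,1,3) averaging PSF:
  # u1 = d * boxmean(d / boxmean(d)), reflected boundaries
  d <- array(c(1, 2, 5, 2, 1), c(1L, 1L, 5L))
  box <- function(v) {
    n <- length(v)
    idx <- function(i) hskit:::reflect_index(i, n)
    vapply(seq_len(n), function(i) mean(v[c(idx(i - 1L), i, idx(i + 1L))]), 0)
  }
  manual <- as.vector(d) * box(as.vector(d) / box(as.vector(d)))
  out <- rl_restore(d, psf_window = c(1L, 1L, 3L), iterations = 1L)
  expect_equal(as.vector(out), manual)
})

test_that("local equalization is neutral without skew signal and bounded", {
  # every box identical (and symmetric) -> identity
  pat <- array(rep(c(1, 2, 3, 4, 5, 6, 7), length.out = 7L * 14L * 14L),
               c(7L, 14L, 14L))
  expect_equal(equalize_local(pat), pat)

  set.seed(4)
  a <- array(stats::rexp(14L * 14L * 14L, 1 / 10), c(14L, 14L, 14L))
  out <- equalize_local(a, weight_bounds = c(0.5, 2))
  ratio <- out / pmax(a, .Machine$double.eps)
  expect_true(all(ratio <= 2 + 1e-8))
  expect_true(all(ratio >= 0.5 - 1e-8))

  # a multiplicative gradient over identical positively skewed texture is
  # flattened: the between-box variance of box means strictly decreases
  set.seed(5)
  tex <- array(stats::rexp(14L * 28L * 28L, 1 / 10), c(14L, 28L, 28L))
  xw <- seq(0.6, 1.8, length.out = 28L)
  grad <- sweep(tex, 3L, xw, `*`)
  eq <- equalize_local(grad)
  bm <- function(m) as.vector(hskit:::tile_apply(m, c(7L, 7L, 7L), mean)$values)
  expect_lt(stats::var(bm(eq)), stats::var(bm(grad)))
})

test_that("adaptive Otsu masks separate two classes and respect the floor", {
  fx <- make_synthetic_stack(shape = c(12L, 36L, 36L), pattern = "cube",
                             fg_mean = 100, noise_sd = 2, fg_noise_sd = 5,
                             bg_mean = 10, seed = 1L)
  a <- fx$stack$values
  mask <- adaptive_otsu_mask(a)
  expect_gt(dice_coef(mask, fx$truth$mask), 0.9)
  # no foreground voxel at or below the global floor, checked exhaustively
  floor <- 0.66 * hskit:::otsu_threshold(as.vector(a))
  expect_true(all(a[mask] > floor))

  expect_warning(empty <- adaptive_otsu_mask(array(1, c(4L, 4L, 4L))),
                 regexp = "distinct")
  expect_false(any(empty))
})

test_that("the Otsu routine agrees with the EBImage reference", {
  # both thresholds fall in the empty inter-mode valley where the Otsu
  # objective is flat, so compare the binarizations they induce rather
  # than the raw threshold values
  set.seed(6)
  x <- c(stats::rnorm(3000, 0.2, 0.05), stats::rnorm(1000, 0.7, 0.05))
  x <- pmin(pmax(x, 0), 1)
  img <- matrix(x, 80L)
  t_mine <- hskit:::otsu_threshold(as.vector(img))
  t_ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  expect_gt(mean((x > t_mine) == (x > t_ref)), 0.999)
  # and against a direct maximization of the between-class variance
  cand <- sort(unique(round(x, 3L)))
  bc <- vapply(cand, function(t) {
    w0 <- mean(x <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-1)
    w0 * w1 * (mean(x[x <= t]) - mean(x[x > t]))^2
  }, 0)
  t_brute <- cand[which.max(bc)]
  expect_gt(mean((x > t_mine) == (x > t_brute)), 0.999)
})

test_that("quantification recovers planted intensities and is deterministic", {
  fx <- make_synthetic_stack(shape = c(12L, 36L, 36L), pattern = "cube",
                             fg_mean = 100, noise_sd = 0, bg_mean = 0,
                             seed = 1L)
  q <- quantify_stack(fx$stack)
  expect_equal(q$mean_foreground_intensity, fx$truth$fg_mean,
               tolerance = 0.01)
  expect_identical(q$n_foreground, sum(q$mask))

  expect_warning(
    expect_warning(zero <- quantify_stack(array(0, c(8L, 10L, 10L))),
                   regexp = "distinct"),
    regexp = "empty")
  expect_identical(zero$mean_foreground_intensity, 0)
  expect_identical(zero$n_foreground, 0L)

  q2 <- quantify_stack(fx$stack)
  expect_identical(q$mean_foreground_intensity, q2$mean_foreground_intensity)
  expect_identical(q$mask, q2$mask)
})

test_that("segmentation quality holds across seeds (Dice > 0.9)", {
  for (seed in 1:10) {
    fx <- make_synthetic_stack(shape = c(12L, 36L, 36L), pattern = "cube",
                               fg_mean = 100, noise_sd = 2, fg_noise_sd = 5,
                               bg_mean = 10, seed = seed)
    q <- quantify_stack(fx$stack)
    expect_gt(dice_coef(q$mask, fx$truth$mask), 0.9)
  }
})

test_that("raising foreground intensity never lowers the recovered mean", {
  means <- vapply(c(20, 50, 100, 200), function(fg) {
    fx <- make_synthetic_stack(shape = c(12L, 36L, 36L), pattern = "diffuse",
                               fg_mean = fg, noise_sd = 2, bg_mean = 10,
                               seed = 5L)
    quantify_stack(fx$stack)$mean_foreground_intensity
  }, 0)
  expect_false(is.unsorted(means))
})

test_that("a planted ~12-fold intensity difference is recovered within [8, 12]", {
  lo <- make_synthetic_stack(shape = c(12L, 36L, 36L), pattern = "diffuse",
                             fg_mean = 5, noise_sd = 0.5, seed = 3L)
  hi <- make_synthetic_stack(shape = c(12L, 36L, 36L), pattern = "diffuse",
                             fg_mean = 58, noise_sd = 0.5, seed = 3L)
  m_lo <- quantify_stack(lo$stack)$mean_foreground_intensity
  m_hi <- quantify_stack(hi$stack)$mean_foreground_intensity
  ratio <- m_hi / m_lo
  expect_gte(ratio, 8)
  expect_lte(ratio, 12)
})

test_that("two-group ANOVA matches closed forms and the pooled t-test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  res <- compare_groups(c(1, 2, 3), c(7, 8, 9))
  expect_equal(res$f_statistic, 54)
  expect_equal(res$p_value, 0.0018, tolerance = 0.02)
  expect_identical(res$df, c(1, 4))

  set.seed(8)
  a <- stats::rnorm(6); b <- stats::rnorm(5, 1)
  res2 <- compare_groups(a, b)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res2$f_statistic, unname(tt$statistic)^2)
  expect_equal(res2$p_value, tt$p.value)

  expect_error(compare_groups(1, c(2, 3)), regexp = "n >= 2")
})

test_that("stacks survive a TIFF round trip", {
  fx <- make_synthetic_stack(shape = c(6L, 12L, 12L), pattern = "cube",
                             fg_mean = 100, noise_sd = 1, seed = 2L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(fx$stack, path)
  back <- read_stack_tiff(path)
  expect_identical(dim(back$values), dim(fx$stack$values))
  # writing rescales to [0,1]; shape and relative structure persist
  expect_gt(stats::cor(as.vector(back$values), as.vector(fx$stack$values)),
            0.99)
})
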