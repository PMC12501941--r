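test_that("replace_zeros floors exactly the zero cells", {
  v <- matrix(c(0, 2, NA, 4, 0, 6), 2, 3)
  q <- toy_quant(v)
  out <- replace_zeros(q)
  expect_equal(sum(out$values == 0.1, na.rm = TRUE), 2)
  expect_true(is.na(out$values[1, 2]))
  expect_equal(out$values[!is.na(v) & v != 0], v[!is.na(v) & v != 0])
  expect_error(replace_zeros(q, floor = 0), "floor")

  # no zeros -> identity; counted change matches zero count
  set.seed(1)
  v2 <- matrix(stats::runif(100, 1, 10), 10, 10)
  idx <- sample(100, 5)
  v2[idx] <- 0
  out2 <- replace_zeros(toy_quant(v2))
  expect_equal(sum(out2$values != v2), 5)
})

test_that("median_normalize equalizes channel medians at the grand median", {
  v <- cbind(c(2, 4, 6), c(1, 2, 3))
  out <- median_normalize(toy_quant(v))
  expect_equal(unname(out$values), cbind(c(1.5, 3, 4.5), c(1.5, 3, 4.5)))
  # already-equal medians -> identity; single channel -> identity
  expect_equal(median_normalize(out)$values, out$values)
  one <- toy_quant(cbind(c(1, 5, 9)))
  expect_equal(median_normalize(one)$values, one$values)
  # post-condition on random data
  set.seed(2)
  r <- toy_quant(matrix(stats::rexp(200) + 0.1, 20, 10))
  meds <- apply(median_normalize(r)$values, 2, stats::median)
  expect_lt(diff(range(meds)), 1e-9)
})

test_that("log2_transform is elementwise with NA propagation and input guards", {
  q <- toy_quant(matrix(c(8, 0.1, 1, NA), 2, 2))
  out <- log2_transform(q)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], log2(0.1))
  expect_equal(out$values[1, 2], 0)
  expect_true(is.na(out$values[2, 2]))
  expect_equal(out$stage, "raw-log2")
  expect_error(log2_transform(toy_quant(matrix(c(1, 0), 1, 2))),
               "nonpositive")
})

test_that("reference_scale subtracts each batch's reference mean", {
  # batch: refs (6,6,6) and samples (5,7) -> samples (-1,+1), refs 0
  v <- matrix(c(6, 6, 6, 5, 7), 1, 5)
  q <- toy_quant(v, is_reference = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                 ref_set = c(1L, 2L, 3L, NA, NA), stage = "raw-log2")
  out <- reference_scale(q)
  expect_equal(unname(out$values), matrix(c(0, 0, 0, -1, 1), 1, 5))

  # a whole-batch additive offset (all channels incl. refs) cancels
  v2 <- matrix(stats::rnorm(20), 2, 10)
  mk <- function(vals) toy_quant(
    vals, batch = rep(1:2, each = 5),
    is_reference = rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 2),
    ref_set = rep(c(1L, NA, NA, NA, NA), 2), stage = "raw-log2")
  shifted <- v2
  shifted[, 1:5] <- shifted[, 1:5] + 1
  shifted[, 6:10] <- shifted[, 6:10] - 1
  expect_equal(reference_scale(mk(shifted))$values,
               reference_scale(mk(v2))$values)

  bad <- toy_quant(matrix(1, 1, 2), batch = c(1L, 2L), stage = "raw-log2")
  expect_error(reference_scale(bad), "batch 1")
})

test_that("center_rows zeroes the finite sample mean and preserves differences", {
  q <- toy_quant(matrix(c(1, 2, 3), 1, 3), stage = "raw-log2")
  out <- center_rows(q)
  expect_equal(unname(out$values), matrix(c(-1, 0, 1), 1, 3))
  expect_equal(center_rows(out)$values, out$values)
  # NA row: mean over finite entries, NA preserved
  q2 <- toy_quant(matrix(c(1, NA, 5), 1, 3), stage = "raw-log2")
  out2 <- center_rows(q2)
  expect_equal(unname(out2$values), matrix(c(-2, NA, 2), 1, 3))
  # pairwise differences within a protein unchanged
  set.seed(3)
  m <- toy_quant(matrix(stats::rnorm(40), 4, 10), stage = "raw-log2")
  cm <- center_rows(m)
  expect_equal(apply(cm$values, 1, diff), apply(m$values, 1, diff))
})

test_that("cascade is scale-equivariant under whole-batch rescaling", {
  # zero-free world: the absolute zero floor (0.1) is the one cascade
  # step that is deliberately not scale-equivariant
  ds <- simulate_dataset(small_params(zero_rate = 0, n_contaminants = 0))
  q <- ds$quant
  k <- 3.7
  q2 <- q
  cols <- which(q$design$batch == 2)
  q2$values[, cols] <- q2$values[, cols] * k
  expect_equal(normalize_quant(q2)$values, normalize_quant(q)$values,
               tolerance = 1e-9)
})

test_that("noise-free batch effects vanish exactly after reference scaling", {
  p <- synthetic_params(n_proteins = 500, noise_sd = 0,
                        batch_effect_sd = 0.5, zero_rate = 0,
                        n_contaminants = 0, frac_de = 0.1, seed = 17)
  ds <- simulate_dataset(p)
  rs <- reference_scale(log2_transform(replace_zeros(ds$quant)))
  d <- rs$design
  # cross-batch replicates of one reference pool have zero variance
  for (r in unique(d$ref_set[d$is_reference])) {
    cols <- which(d$is_reference & d$ref_set == r)
    expect_lt(max(apply(rs$values[, cols], 1, stats::var)), 1e-18)
  }
  # replicate channels of one condition agree across batches
  grp <- paste(d$cell_line, d$dimension)
  for (g in unique(grp[!d$is_reference])) {
    cols <- which(!d$is_reference & grp == g)
    expect_lt(max(apply(rs$values[, cols], 1,
                        function(x) diff(range(x)))), 1e-9)
  }
})

test_that("PCA separates conditions with a dominant effect and reports sane variance", {
  # rank-1 data: component 1 explains everything
  v <- outer(stats::rnorm(30), c(1, 2, 3, 4))
  p1 <- run_pca(toy_quant(v, stage = "centered"), k = 2)
  expect_equal(p1$var_frac[1], 1, tolerance = 1e-12)
  expect_true(all(diff(p1$var_frac) <= 1e-12))

  # strong dimension effect: some leading PC separates 2D from 3D
  p <- synthetic_params(n_proteins = 400, effect_log2 = 3, frac_de = 0.3,
                        frac_common = 1, noise_sd = 0.2,
                        n_contaminants = 0, seed = 6)
  ds <- simulate_dataset(p)
  norm <- normalize_quant(ds$quant)
  pc <- run_pca(norm, k = 3, channels = "samples")
  dims <- pc$design$dimension
  sep <- vapply(1:3, function(i) {
    a <- pc$scores[dims == "3D", i]; b <- pc$scores[dims == "2D", i]
    abs(mean(a) - mean(b)) / (stats::sd(c(a - mean(a), b - mean(b))) + 1e-12)
  }, numeric(1))
  expect_gt(max(sep), 2)

  # rotation invariance of variance fractions (orthogonal mixing of
  # the protein dimension commutes with the row centering)
  set.seed(4)
  m <- matrix(stats::rnorm(120), 20, 6)
  rot <- qr.Q(qr(matrix(stats::rnorm(400), 20, 20)))
  f1 <- run_pca(toy_quant(m, stage = "centered"), k = 4)$var_frac
  f2 <- run_pca(toy_quant(rot %*% m, stage = "centered"), k = 4)$var_frac
  expect_equal(f1, f2, tolerance = 1e-9)

  expect_error(run_pca(toy_quant(matrix(0, 5, 4), stage = "centered")),
               "degenerate|variance")
})

test_that("correlation matrices behave at both levels", {
  set.seed(5)
  x <- stats::rnorm(50)
  v <- cbind(a = x, b = -x, c = x + stats::rnorm(50, 0, 0.2))
  cc <- correlation_matrix(toy_quant(v, stage = "centered"))
  expect_equal(dim(cc), c(3, 3))
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc, t(cc))
  expect_equal(cc["1:1", "1:2"], -1)
  expect_true(all(abs(cc) <= 1 + 1e-12))
  expect_warning(
    correlation_matrix(toy_quant(cbind(x, rep(1, 50)),
                                 stage = "centered")),
    "constant")

  # per-line ratio correlations mirror shared-effect structure:
  # lines A,B share effects; C,D share different effects
  n <- 300
  shared1 <- stats::rnorm(n); shared2 <- stats::rnorm(n)
  ratios <- cbind(A = shared1 + stats::rnorm(n, 0, 0.4),
                  B = shared1 + stats::rnorm(n, 0, 0.4),
                  C = shared2 + stats::rnorm(n, 0, 0.4),
                  D = shared2 + stats::rnorm(n, 0, 0.4))
  rc <- correlation_matrix(ratios, level = "ratio")
  expect_gt(rc["A", "B"], rc["A", "C"])
  expect_gt(rc["C", "D"], rc["B", "C"])
})
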