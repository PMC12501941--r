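test_that("generate_design places every sample once with full reference sets", {
  d <- generate_design(seed = 11)
  bio <- d[!d$is_reference, ]
  # 4 lines x 2 dims x 3 reps = 24 samples, each in exactly one slot
  expect_equal(nrow(bio), 24)
  expect_equal(anyDuplicated(bio$sample_id), 0)
  expect_equal(anyDuplicated(d$channel_id), 0)
  # every batch: 3 refs + 6 samples (forced by 24/4)
  per_batch <- table(d$batch, d$is_reference)
  expect_true(all(per_batch[, "TRUE"] == 3))
  expect_true(all(per_batch[, "FALSE"] == 6))
  # reference pools partition the samples
  expect_setequal(unique(bio$ref_set), 1:3)

  # minimal design
  d1 <- generate_design(cell_lines = "A", replicates = 1, n_batches = 1,
                        references_per_batch = 1, seed = 1)
  expect_equal(sum(!d1$is_reference), 2)
  expect_equal(sum(d1$is_reference), 1)

  # determinism
  expect_identical(generate_design(seed = 5), generate_design(seed = 5))
  expect_false(identical(generate_design(seed = 5),
                         generate_design(seed = 6)))
})

test_that("generate_design errors on plex-capacity overflow", {
  expect_error(
    generate_design(cell_lines = LETTERS[1:10], replicates = 3,
                    n_batches = 2, references_per_batch = 3),
    "capacity")
})

test_that("generate_truth honours the DE and common-sign counts", {
  d <- generate_design(seed = 2)
  p <- synthetic_params(n_proteins = 1000, frac_de = 0.1,
                        frac_common = 0.9, n_contaminants = 5, seed = 9)
  tr <- generate_truth(p, d)
  hum <- tr$proteins[!tr$proteins$is_contaminant, ]
  expect_equal(sum(hum$is_de), 100)
  expect_equal(sum(hum$is_common), 90)
  sign_cols <- grep("^sign_", names(hum))
  signs <- as.matrix(hum[, sign_cols])
  # common DE proteins share one sign; non-DE proteins have sign 0
  common <- signs[hum$is_common, , drop = FALSE]
  expect_true(all(apply(common, 1, function(s)
    all(s == s[1]) && s[1] %in% c(-1, 1))))
  expect_true(all(signs[!hum$is_de, ] == 0))
  # contaminants disjoint from DE
  expect_false(any(tr$proteins$is_de & tr$proteins$is_contaminant))

  p0 <- synthetic_params(n_proteins = 200, frac_de = 0, seed = 1)
  tr0 <- generate_truth(p0, d)
  expect_equal(sum(tr0$proteins$is_de), 0)
  expect_equal(max(abs(tr0$mu[, , "3D"] - tr0$mu[, , "2D"])), 0)
})

test_that("generate_quant is deterministic and structurally sound", {
  p <- small_params()
  ds1 <- simulate_dataset(p)
  ds2 <- simulate_dataset(p)
  expect_identical(ds1$quant$values, ds2$quant$values)
  v <- ds1$quant$values
  expect_true(all(v[is.finite(v)] >= 0))
  # contaminant rows: nonzero only in 3D sample channels
  d <- ds1$design
  cont <- grep("^CONT_MOUSE_", rownames(v))
  expect_length(cont, p$n_contaminants)
  not3d <- is.na(d$dimension) | d$dimension != "3D"
  expect_true(all(v[cont, not3d] == 0))
  expect_true(all(v[cont, !not3d] > 0))
  # no injected zeros in reference channels (human rows)
  refs <- which(d$is_reference)
  expect_true(all(v[-cont, refs] > 0))
})

test_that("noise-free replicates are identical within condition and batch offsets are exact", {
  p <- synthetic_params(n_proteins = 50, noise_sd = 0,
                        batch_effect_sd = 0, zero_rate = 0,
                        n_contaminants = 0, seed = 3)
  ds <- simulate_dataset(p)
  d <- ds$design; v <- ds$quant$values
  grp <- paste(d$cell_line, d$dimension)
  for (g in unique(grp[!d$is_reference])) {
    cols <- which(!d$is_reference & grp == g)
    if (length(cols) > 1)
      expect_equal(max(apply(v[, cols], 1, function(x) diff(range(x)))), 0)
  }

  # with batch effects only, cross-batch replicates differ by exactly
  # the per-(protein,batch) offset: verified via the reference channels
  # of the same pool, which carry the same offsets
  p2 <- synthetic_params(n_proteins = 50, noise_sd = 0,
                         batch_effect_sd = 0.6, zero_rate = 0,
                         n_contaminants = 0, seed = 3)
  ds2 <- simulate_dataset(p2)
  d2 <- ds2$design; v2 <- log2(ds2$quant$values)
  cols <- which(!d2$is_reference & grp == unique(grp[!d2$is_reference])[1])
  b <- d2$batch[cols]
  if (length(unique(b)) > 1) {
    i <- cols[1]; j <- cols[b != b[1]][1]
    ref_i <- which(d2$is_reference & d2$ref_set == 1 & d2$batch == d2$batch[i])
    ref_j <- which(d2$is_reference & d2$ref_set == 1 & d2$batch == d2$batch[j])
    expect_equal(v2[, i] - v2[, j], v2[, ref_i] - v2[, ref_j],
                 tolerance = 1e-9)
  }
})

test_that("injected zero fraction matches the binomial expectation", {
  p <- synthetic_params(n_proteins = 6000, zero_rate = 0.004,
                        n_contaminants = 0, seed = 8)
  ds <- simulate_dataset(p)
  sc <- which(!ds$design$is_reference)
  n_cells <- length(sc) * nrow(ds$quant$values)
  frac <- mean(ds$quant$values[, sc] == 0)
  sd3 <- 3 * sqrt(0.004 * 0.996 / n_cells)
  expect_lt(abs(frac - 0.004), sd3)
})

test_that("reference channels equal the linear mean of their pool (no batch effect)", {
  p <- synthetic_params(n_proteins = 80, noise_sd = 0.3,
                        batch_effect_sd = 0, zero_rate = 0,
                        n_contaminants = 0, seed = 21)
  ds <- simulate_dataset(p)
  d <- ds$design; v <- ds$quant$values
  for (r in unique(d$ref_set[d$is_reference])) {
    refcols <- which(d$is_reference & d$ref_set == r)
    samcols <- which(!d$is_reference & d$ref_set == r)
    pool <- rowMeans(v[, samcols, drop = FALSE])
    for (rc in refcols) expect_equal(v[, rc], pool, tolerance = 1e-12)
  }
})

test_that("quant/design/truth TSVs round-trip including the NA/zero distinction", {
  p <- synthetic_params(n_proteins = 30, n_contaminants = 3,
                        zero_rate = 0.01, seed = 5)
  ds <- simulate_dataset(p)
  q <- ds$quant
  q$values[2, 3] <- NA    # inject a missing value
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "q.tsv")
  write_quant_tsv(q, f)
  q2 <- read_quant_tsv(f)
  expect_equal(q2$values, q$values)
  expect_identical(is.na(q2$values), is.na(q$values))
  expect_equal(q2$design$batch, q$design$batch)
  expect_equal(q2$design$is_reference, q$design$is_reference)
  expect_equal(q2$stage, q$stage)
})
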