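# Small fixture builders shared across test files.

# Build a quant_matrix from a bare matrix plus per-channel metadata
# vectors; sensible defaults give one batch of biological samples.
toy_quant <- function(values, batch = rep(1L, ncol(values)),
                      cell_line = rep("L1", ncol(values)),
                      dimension = rep("2D", ncol(values)),
                      replicate = seq_len(ncol(values)),
                      is_reference = rep(FALSE, ncol(values)),
                      ref_set = rep(NA_integer_, ncol(values)),
                      stage = "linear") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  n <- ncol(values)
  design <- data.frame(
    channel_id = sprintf("%d:%d", batch, stats::ave(batch, batch,
                                                    FUN = seq_along)),
    batch = batch, channel = stats::ave(batch, batch, FUN = seq_along),
    sample_id = ifelse(is_reference,
                       sprintf("ref%s_b%d", ref_set, batch),
                       sprintf("%s_%s_r%d", cell_line, dimension,
                               replicate)),
    cell_line = ifelse(is_reference, NA_character_, cell_line),
    dimension = ifelse(is_reference, NA_character_, dimension),
    replicate = ifelse(is_reference, NA_integer_, replicate),
    is_reference = is_reference, ref_set = ref_set,
    stringsAsFactors = FALSE)
  colnames(values) <- design$channel_id
  quant_matrix(values, design, stage = stage)
}

# A 2-cell-line, 2-batch design small enough for fast tests: each line
# has `reps` replicates per dimension, plus `refs` reference channels
# per batch.
small_params <- function(...) {
  args <- list(n_proteins = 400, n_contaminants = 8, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_params, args)
}

# Brute-force weighted running-sum oracle, independent of gsea_score:
# explicit loop over the ranked list.
gsea_oracle <- function(scores, set, exponent = 1) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  hit <- names(s) %in% set
  nr <- sum(abs(s[hit])^exponent)
  if (nr == 0) { w <- rep(1, sum(hit)); nr <- sum(hit) }
  run <- numeric(length(s)); cur <- 0
  for (i in seq_along(s)) {
    if (hit[i]) {
      inc <- if (sum(abs(s[hit])^exponent) == 0) 1 / sum(hit)
             else abs(s[i])^exponent / nr
      cur <- cur + inc
    } else cur <- cur - 1 / (length(s) - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Exhaustive hypergeometric oracle: enumerate all C(N, n) query draws
# and count those with overlap >= k.
ora_oracle <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% inset) >= k)
  mean(hits)
}
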