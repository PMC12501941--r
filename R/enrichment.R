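#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least `k`
#' members of a gene set in a query of size `n` drawn from a universe
#' of size `N` containing `K` set members, computed by exact summation
#' of the hypergeometric mass over `k..min(K, n)`.
#'
#' @param query character vector of query accessions (must lie in
#'   `universe`).
#' @param set character vector: the gene set.
#' @param universe character vector: the background.
#' @return one-row data.frame: `N`, `K`, `n`, `k`, `p`.
#' @export
ora_test <- function(query, set, universe) {
  if (!all(query %in% universe))
    stop("query contains accessions outside the universe")
  K <- length(intersect(set, universe))
  if (K == 0) {
    out <- data.frame(N = length(universe), K = 0L,
                      n = length(unique(query)), k = 0L, p = NA_real_)
    attr(out, "note") <- "set disjoint from universe; skipped"
    return(out)
  }
  N <- length(universe)
  n <- length(unique(query))
  k <- length(intersect(query, set))
  p <- sum(stats::dhyper(k:min(K, n), K, N - K, n))
  p <- min(p, 1)
  data.frame(N = N, K = K, n = n, k = k, p = p)
}

#' Over-representation analysis over a gene-set collection
#'
#' Runs [ora_test()] per set and applies Benjamini-Hochberg adjustment
#' across the tested sets.
#'
#' @param query character vector of query accessions.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background accessions.
#' @return data.frame, one row per set with finite overlap, sorted by
#'   `p`, with `p_adj`.
#' @export
ora_analysis <- function(query, collection, universe) {
  rows <- lapply(names(collection), function(nm) {
    r <- ora_test(query, collection[[nm]], universe)
    r$set <- nm
    r
  })
  out <- do.call(rbind, rows)
  out <- out[, c("set", "N", "K", "n", "k", "p")]
  out <- out[!is.na(out$p), , drop = FALSE]
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled step-up procedure: sort the m p-values increasingly,
#' multiply the i-th by m/i, enforce monotonicity from the largest
#' down (cumulative minimum), cap at 1, and return in the input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p > 0 & p <= 1)))
  m <- sum(!is.na(p))
  if (m == 0) return(p)
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  o <- order(p[idx])
  ranked <- p[idx][o] * m / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  ranked <- pmin(ranked, 1)
  out[idx[o]] <- ranked
  out
}

#' Weighted running-sum enrichment score
#'
#' The classical weighted Kolmogorov-Smirnov-like statistic on a ranked
#' list: walking down the ranking, a hit increments the running sum by
#' its |score|^exponent (normalized so hits sum to 1) and a miss
#' decrements it by 1/(number of misses). The enrichment score ES is
#' the signed maximum deviation of the running sum from zero. With
#' `exponent = 0` this reduces to the classical KS statistic on the
#' set's ranks.
#'
#' If every hit has weight zero (all hit scores are 0 at exponent > 0),
#' hit increments fall back to equal weights so the sum remains
#' defined.
#'
#' @param ranking named numeric vector (accession -> score, e.g. a
#'   log2 3D/2D ratio); sorted internally in decreasing score order.
#'   Ties keep the incoming order, making the statistic deterministic.
#' @param set character vector of accessions.
#' @param exponent weighting exponent (default 1).
#' @return list with `es`, `running` (the running sum), `order`
#'   (accessions in ranked order), `hits` (logical in ranked order),
#'   `leading_edge` (accessions up to and including the extremum, for
#'   positive ES; after it, for negative ES).
#' @export
gsea_score <- function(ranking, set, exponent = 1) {
  if (anyNA(ranking)) stop("ranking contains NA scores")
  n <- length(ranking)
  o <- order(ranking, decreasing = TRUE)
  scores <- ranking[o]
  accs <- names(scores)
  hits <- accs %in% set
  nh <- sum(hits)
  if (nh == 0) stop("set does not intersect the ranking")
  if (nh == n) stop("set covers the entire ranking")
  w <- abs(scores)^exponent
  w[!hits] <- 0
  if (sum(w) == 0) w[hits] <- 1      # zero-weight fallback
  step <- ifelse(hits, w / sum(w), -1 / (n - nh))
  running <- cumsum(step)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  le <- if (es >= 0) accs[seq_len(i_max)][hits[seq_len(i_max)]]
        else accs[i_max:n][hits[i_max:n]]
  list(es = es, running = running, order = accs, hits = hits,
       leading_edge = le)
}

#' Permutation p-value for a GSEA enrichment score
#'
#' Gene-label permutation null: `B` random sets of the same size are
#' drawn from the ranking and scored. Following the standard GSEA
#' convention, the p-value is computed against the null scores sharing
#' the observed sign: for a positive observed ES,
#' `p = (1 + #{null ES >= observed among null ES >= 0}) /
#' (1 + #{null ES >= 0})` (mirrored for negative). Sign stratification
#' is what makes the p-value uniform under a random-set null; an
#' unstratified `(1 + #{|tail|}) / (B + 1)` would be capped near the
#' sign probability (~0.5). The normalized ES divides by the mean
#' |null ES| among null scores of the observed sign.
#'
#' @param ranking named numeric vector (see [gsea_score()]).
#' @param set character vector of accessions.
#' @param B number of permutations (>= 100).
#' @param seed RNG seed.
#' @param exponent weighting exponent.
#' @return one-row data.frame: `es`, `nes`, `p`, `size`, plus the
#'   leading edge as attribute `leading_edge`.
#' @export
gsea_permutation_p <- function(ranking, set, B = 1000, seed = 1L,
                               exponent = 1) {
  stopifnot(B >= 100)
  obs <- gsea_score(ranking, set, exponent)
  size <- sum(names(ranking) %in% set)
  set.seed(seed)
  null_es <- vapply(seq_len(B), function(i) {
    rs <- sample(names(ranking), size)
    gsea_score(ranking, rs, exponent)$es
  }, numeric(1))
  if (obs$es >= 0) {
    same <- null_es[null_es >= 0]
    p <- (1 + sum(same >= obs$es)) / (1 + length(same))
    denom <- mean(same)
  } else {
    same <- null_es[null_es < 0]
    p <- (1 + sum(same <= obs$es)) / (1 + length(same))
    denom <- mean(abs(same))
  }
  nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
  out <- data.frame(es = obs$es, nes = nes, p = p, size = size)
  attr(out, "leading_edge") <- obs$leading_edge
  out
}

#' GSEA over a gene-set collection
#' @param ranking named numeric vector of scores.
#' @param collection named list of gene sets.
#' @param B permutations per set.
#' @param seed RNG seed (each set gets a derived seed).
#' @param exponent weighting exponent.
#' @param min_size skip sets with fewer ranked members than this.
#' @return data.frame, one row per tested set, with BH-adjusted p.
#' @export
gsea_analysis <- function(ranking, collection, B = 1000, seed = 1L,
                          exponent = 1, min_size = 3) {
  rows <- list()
  for (i in seq_along(collection)) {
    nm <- names(collection)[i]
    size <- sum(names(ranking) %in% collection[[nm]])
    if (size < min_size || size >= length(ranking)) next
    r <- gsea_permutation_p(ranking, collection[[nm]], B = B,
                            seed = seed + i, exponent = exponent)
    r$set <- nm
    rows[[nm]] <- r
  }
  if (length(rows) == 0)
    return(data.frame(set = character(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0),
                      size = integer(0), p_adj = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[, c("set", "es", "nes", "p", "size")]
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}
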