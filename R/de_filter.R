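# Transcriptomic refinement: per-gene two-group Student t-tests on a
# normalized expression matrix, a permutation-based global FDR estimate for
# the p < alpha gene set, and reduction of molecular-weight candidate pools
# to proteins whose mRNA responds in either injury model.

# Vectorised equal-variance two-sample t over matrix rows. Returns t, df, p.
# Zero pooled variance: equal means -> t = 0, p = 1; unequal means -> t is a
# +/- Inf sentinel with p = 0.
.row_t <- function(m, idx_x, idx_y) {
  nx <- length(idx_x); ny <- length(idx_y)
  mx <- rowMeans(m[, idx_x, drop = FALSE])
  my <- rowMeans(m[, idx_y, drop = FALSE])
  vx <- rowSums((m[, idx_x, drop = FALSE] - mx)^2) / (nx - 1)
  vy <- rowSums((m[, idx_y, drop = FALSE] - my)^2) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mx - my) / se
  df <- nx + ny - 2
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  zero_var <- se == 0
  if (any(zero_var)) {
    eq <- zero_var & (mx == my)
    t[eq] <- 0; p[eq] <- 1
    ne <- zero_var & (mx != my)
    t[ne] <- sign(mx[ne] - my[ne]) * Inf
    p[ne] <- 0
  }
  list(t = t, df = df, p = p)
}

#' Unpaired two-tailed Student t-test
#'
#' Pooled-variance (equal-variance) two-sample t with
#' `df = length(x) + length(y) - 2`, the classical microarray gene-level
#' test. Welch's unequal-variance form is available behind a flag. Degenerate
#' zero-variance input returns `t = 0, p = 1` when the means agree and a
#' signed infinite t with `p = 0` (with a warning) when they differ.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param welch Use Welch's t instead of the pooled form.
#' @return List with `t`, `df`, `p`.
#' @export
student_t_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  if (welch) {
    fit <- stats::t.test(x, y, var.equal = FALSE)
    return(list(t = unname(fit$statistic), df = unname(fit$parameter),
                p = fit$p.value))
  }
  res <- .row_t(matrix(c(x, y), nrow = 1), seq_along(x),
                length(x) + seq_along(y))
  if (is.infinite(res$t[1])) {
    warning("zero pooled variance with unequal means; t is an Inf sentinel")
  }
  list(t = res$t[1], df = res$df, p = res$p[1])
}

#' Per-gene differential-expression tests
#'
#' Applies [student_t_test()] to every row of a normalized expression matrix
#' (treatment vs control) and flags genes with two-tailed `p < alpha`.
#'
#' @param matrix_ Numeric matrix, genes x samples, with rownames.
#' @param labels Character vector per sample: "control" or "treatment".
#' @param alpha Significance gate on the raw p-value (default 0.05); no
#'   multiplicity correction is applied at this step, by design — the global
#'   error rate is summarised separately by [permutation_fdr()].
#' @param welch Use Welch's t.
#' @return A `DEResult` data frame: gene, t, p, significant.
#' @export
test_all_genes <- function(matrix_, labels, alpha = 0.05, welch = FALSE) {
  stopifnot(is.matrix(matrix_), length(labels) == ncol(matrix_))
  idx_t <- which(labels == "treatment")
  idx_c <- which(labels == "control")
  if (length(idx_t) < 2L || length(idx_c) < 2L) {
    stop("need >= 2 samples per group")
  }
  if (welch) {
    res <- t(apply(matrix_, 1, function(row) {
      fit <- student_t_test(row[idx_t], row[idx_c], welch = TRUE)
      c(fit$t, fit$p)
    }))
    out <- data.frame(gene = rownames(matrix_), t = res[, 1], p = res[, 2],
                      stringsAsFactors = FALSE)
  } else {
    res <- .row_t(matrix_, idx_t, idx_c)
    out <- data.frame(gene = rownames(matrix_), t = res$t, p = res$p,
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  class(out) <- c("DEResult", "data.frame")
  out
}

# All balanced reassignments of samples to a treatment group of size k,
# excluding the identity, as a list of index vectors.
.balanced_relabelings <- function(n, k, identity_idx) {
  combos <- utils::combn(n, k, simplify = FALSE)
  Filter(function(ix) !identical(sort(ix), sort(identity_idx)), combos)
}

#' Permutation-based false discovery rate for the significant gene set
#'
#' Estimates the FDR of the `p < alpha` gene list as the average, over group
#' relabelings that preserve the group sizes, of the number of genes called
#' significant under the permuted labels divided by the observed number,
#' capped at 1. When the space of distinct relabelings (excluding the
#' identity) is no larger than `n_perm` it is enumerated exhaustively (with
#' 3 vs 3 groups there are only 19); otherwise `n_perm` relabelings are
#' drawn uniformly, excluding the identity.
#'
#' @param matrix_ Genes x samples matrix.
#' @param labels "control"/"treatment" per sample.
#' @param alpha Significance gate.
#' @param n_perm Number of permutations (>= 10).
#' @param seed Integer seed for the sampled case.
#' @param aggregate "mean" (default) or "median" across permutations.
#' @return List: `fdr` (NA with `estimable = FALSE` when no gene is
#'   significant under the true labels), `n_significant`, `n_perm_used`,
#'   `estimable`.
#' @export
permutation_fdr <- function(matrix_, labels, alpha = 0.05, n_perm = 1000,
                            seed = 1, aggregate = c("mean", "median")) {
  stopifnot(n_perm >= 10L)
  aggregate <- match.arg(aggregate)
  idx_t <- which(labels == "treatment")
  obs <- sum(test_all_genes(matrix_, labels, alpha)$significant)
  if (obs == 0L) {
    return(list(fdr = NA_real_, n_significant = 0L, n_perm_used = 0L,
                estimable = FALSE))
  }
  n <- ncol(matrix_); k <- length(idx_t)
  space <- .balanced_relabelings(n, k, idx_t)
  perms <- if (length(space) <= n_perm) {
    space
  } else {
    with_seed(seed, sample(space, n_perm, replace = TRUE))
  }
  null_counts <- vapply(perms, function(ix) {
    lab <- rep("control", n); lab[ix] <- "treatment"
    sum(test_all_genes(matrix_, lab, alpha)$significant)
  }, numeric(1))
  agg <- if (aggregate == "mean") mean(null_counts) else
    stats::median(null_counts)
  list(fdr = min(1, agg / obs), n_significant = obs,
       n_perm_used = length(perms), estimable = TRUE)
}

#' Refine a candidate pool by differential mRNA expression
#'
#' A candidate protein is retained when at least one of its mapped probes is
#' significant (at the DE results' alpha) in the noise model OR the ouabain
#' model — the most inclusive reading of a many-to-many probe map.
#' Candidates with no mapping are excluded from the refined pool and listed
#' in the `unmapped` sidecar, never silently dropped.
#'
#' @param pool A `CandidatePool` from [query_candidates()].
#' @param de_noise,de_ouabain `DEResult` data frames for the two injury
#'   models.
#' @param probe_map Data frame with columns `probe_id`, `accession`.
#' @return List: `refined` (a `CandidatePool`), `summary` (a
#'   `RefinementSummary`, see [summarize_refinement()]), `unmapped`
#'   (accessions lacking any probe mapping).
#' @export
refine_candidates <- function(pool, de_noise, de_ouabain, probe_map) {
  stopifnot(inherits(pool, "CandidatePool"))
  accs <- unique(pool$candidates$accession)
  sig_noise <- de_noise$gene[de_noise$significant]
  sig_ouab <- de_ouabain$gene[de_ouabain$significant]
  probes_of <- split(probe_map$probe_id, probe_map$accession)
  hit <- function(acc, sig) {
    pr <- probes_of[[acc]]
    !is.null(pr) && any(pr %in% sig)
  }
  mapped <- accs[accs %in% names(probes_of)]
  unmapped <- setdiff(accs, mapped)
  in_noise <- vapply(accs, hit, logical(1), sig = sig_noise)
  in_ouab <- vapply(accs, hit, logical(1), sig = sig_ouab)
  keep_accs <- accs[in_noise | in_ouab]
  refined <- pool
  refined$candidates <-
    pool$candidates[pool$candidates$accession %in% keep_accs, , drop = FALSE]
  rownames(refined$candidates) <- NULL
  summ <- summarize_refinement(
    signal = pool$window$center, pool_size = length(accs),
    noise_count = sum(in_noise), ouabain_count = sum(in_ouab),
    either_count = length(keep_accs)
  )
  list(refined = refined, summary = summ, unmapped = unmapped)
}

#' Refinement summary arithmetic
#'
#' Integer percentages (half away from zero) of a candidate pool responsive
#' in the noise model, the ouabain model, and either, plus the list-reduction
#' percentage `round(100 * (n - either) / n)`.
#'
#' @param signal Signal m/z the pool belongs to.
#' @param pool_size Number of candidates n.
#' @param noise_count,ouabain_count,either_count Responsive candidate counts.
#' @return A `RefinementSummary` one-row data frame.
#' @export
summarize_refinement <- function(signal, pool_size, noise_count,
                                 ouabain_count, either_count) {
  stopifnot(either_count <= noise_count + ouabain_count,
            either_count >= max(noise_count, ouabain_count),
            either_count <= pool_size)
  pct <- function(k) {
    if (pool_size == 0) 0L else as.integer(round_half_away(100 * k / pool_size))
  }
  out <- data.frame(
    signal = signal, candidates = pool_size,
    noise_n = noise_count, noise_pct = pct(noise_count),
    ouabain_n = ouabain_count, ouabain_pct = pct(ouabain_count),
    either_n = either_count, either_pct = pct(either_count),
    reduction_pct = if (pool_size == 0) 0L else
      as.integer(round_half_away(100 * (pool_size - either_count) / pool_size))
  )
  class(out) <- c("RefinementSummary", "data.frame")
  out
}
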