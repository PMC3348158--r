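# Per-replicate sub-seeds are spawned from one master seed by a counter
# through a multiplicative-congruential mix, so each draw is reproducible
# independently of evaluation order.
.subseed <- function(master, i) {
  s <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(i) * 16807
  as.integer(s %% 2147483647) + 1L
}

#' Null distribution of median split ages under tip resampling
#'
#' Draws `reps` random tip sets of size `n_draw`, without replacement
#' within a draw and independently across draws, from the resampling pool
#' (all tips, or all non-outgroup tips), and returns for each draw the
#' weighted median of the split ages of the tree pruned to that draw --
#' the value `median_event_age(split_events(prune_to_taxa(x, draw), bound))`
#' computed by an equivalent O(edges) subset scan.
#'
#' @param x a `chronogram`.
#' @param taxa a `taxon_table` covering the tree's tips (used for the pool
#'   policy).
#' @param n_draw tips per draw (between 2 and the pool size).
#' @param reps number of draws (default 1000).
#' @param bound node-age bound to read (`"mean"`, `"lower"`, `"upper"`).
#' @param pool `"mediterranean_only"` (exclude outgroup tips; default) or
#'   `"all_tips"`.
#' @param seed master seed; replicate r uses the sub-seed spawned at
#'   counter r.
#' @return numeric vector of `reps` null medians (Myr).
#' @export
null_median_distribution <- function(x, taxa, n_draw, reps = 1000,
                                     bound = c("mean", "lower", "upper"),
                                     pool = c("mediterranean_only", "all_tips"),
                                     seed = 1) {
  stopifnot(inherits(x, "chronogram"), reps >= 1)
  bound <- match.arg(bound)
  pool_tips <- .pool_tips(x, taxa, pool)
  if (n_draw < 2 || n_draw > length(pool_tips))
    stop(sprintf("n_draw must be in [2, %d] (pool size)", length(pool_tips)))
  pre <- .subset_precompute(x, bound)
  pool_idx <- match(pool_tips, x$phy$tip.label)
  .null_medians(pre, pool_idx, n_draw, reps, seed)
}

# vectorized-across-replicates presence propagation
.null_medians <- function(pre, pool_idx, n_draw, reps, seed) {
  nn <- pre$nn
  P <- matrix(FALSE, nn, reps)
  np <- length(pool_idx)
  for (r in seq_len(reps)) {
    set.seed(.subseed(seed, r))
    P[pool_idx[sample.int(np, n_draw)], r] <- TRUE
  }
  CNT <- matrix(0L, nn, reps)
  for (i in seq_along(pre$parent)) {
    p <- pre$parent[i]
    pc <- P[pre$child[i], ]
    CNT[p, ] <- CNT[p, ] + pc
    P[p, ] <- P[p, ] | pc
  }
  internal <- seq.int(pre$n + 1L, nn)
  ages <- pre$ages[internal]
  o <- order(ages)
  ages_s <- ages[o]
  W <- pmax(CNT[internal, , drop = FALSE][o, , drop = FALSE] - 1L, 0L)
  vapply(seq_len(reps), function(r) .weighted_median(ages_s, W[, r]),
         numeric(1))
}

#' Two-tailed verdict against an empirical null distribution
#'
#' The observed median is significantly different from random when it falls
#' outside the central `1 - alpha` span of the null distribution: strictly
#' below the empirical `alpha/2` quantile (verdict `"significant_young"`)
#' or strictly above the `1 - alpha/2` quantile (`"significant_old"`).
#' Quantiles use the inclusive empirical-CDF definition (type 1), so ties
#' with the quantile value count as inside -- a conservative reading.
#'
#' @param observed observed median split age (Myr).
#' @param null numeric vector of null medians.
#' @param alpha two-tailed significance level (default 0.05).
#' @return a `rand_test_result`: list with `observed`, `null`, `quantile`
#'   (inclusive empirical CDF of the observed value), `verdict`, `alpha`,
#'   and the null bounds `q_low`/`q_high`.
#' @export
two_tailed_outcome <- function(observed, null, alpha = 0.05) {
  stopifnot(length(null) >= 1, alpha > 0, alpha < 1)
  q_low <- unname(quantile(null, alpha / 2, type = 1))
  q_high <- unname(quantile(null, 1 - alpha / 2, type = 1))
  verdict <- if (observed < q_low) "significant_young"
             else if (observed > q_high) "significant_old"
             else "not_significant"
  structure(list(observed = observed,
                 null = null,
                 quantile = mean(null <= observed),
                 q_low = q_low, q_high = q_high,
                 alpha = alpha,
                 verdict = verdict),
            class = "rand_test_result")
}

#' @export
print.rand_test_result <- function(x, ...) {
  cat(sprintf(
    "Randomization test: observed median %.3g Myr, null central %d%% = [%.3g, %.3g]\n  verdict: %s (empirical quantile %.3f, %d replicates)\n",
    x$observed, round(100 * (1 - x$alpha)), x$q_low, x$q_high,
    x$verdict, x$quantile, length(x$null)))
  invisible(x)
}

#' Median-age randomization test for one status class
#'
#' Tests whether the species of a status class diversified earlier or later
#' than expected by chance: their observed median split age is compared to
#' the null distribution of medians from equally sized random tip draws,
#' once for each requested node-age bound (the point estimate, and the
#' lower and upper credibility bounds as sensitivity reruns). The null for
#' each bound reads the same bound as its observed value.
#'
#' @param x a `chronogram`.
#' @param taxa a `taxon_table` covering the tree's tips.
#' @param status the status class to test (must label at least 2 tips).
#' @param reps null replicates per bound (default 1000).
#' @param alpha two-tailed level (default 0.05).
#' @param seed master seed; each bound spawns its own sub-seed.
#' @param pool resampling pool policy, see [null_median_distribution()].
#' @param bounds bounds to run; lower/upper runs are skipped with a message
#'   when the tree carries no age intervals.
#' @return a named list of `rand_test_result` (NULL for skipped bounds),
#'   class `group_timing_test`, with attributes `status` and `n_draw`.
#' @export
group_timing_test <- function(x, taxa, status, reps = 1000, alpha = 0.05,
                              seed = 1,
                              pool = c("mediterranean_only", "all_tips"),
                              bounds = c("mean", "lower", "upper")) {
  stopifnot(inherits(x, "chronogram"))
  pool <- match.arg(pool)
  if (!status %in% taxa$status)
    stop(sprintf("status \"%s\" absent from the taxon table", status))
  tips <- .status_tips(x, taxa, status)
  if (length(tips) < 2)
    stop(sprintf("fewer than 2 tips carry status \"%s\"", status))
  has_iv <- !anyNA(x$lower[.internal_nodes(x)])
  out <- setNames(vector("list", length(bounds)), bounds)
  for (b in seq_along(bounds)) {
    bound <- bounds[b]
    if (bound != "mean" && !has_iv) {
      message(sprintf("skipping bound \"%s\": no age intervals on the tree",
                      bound))
      next
    }
    obs <- median_event_age(subset_split_events(x, tips, bound))
    null <- null_median_distribution(x, taxa, n_draw = length(tips),
                                     reps = reps, bound = bound, pool = pool,
                                     seed = .subseed(seed, 7000000 + b))
    out[[bound]] <- two_tailed_outcome(obs, null, alpha)
  }
  structure(out, class = "group_timing_test",
            status = status, n_draw = length(tips))
}

#' @export
print.group_timing_test <- function(x, ...) {
  cat(sprintf("Median split-age test for status \"%s\" (n = %d)\n",
              attr(x, "status"), attr(x, "n_draw")))
  for (b in names(x)) {
    if (is.null(x[[b]])) { cat(sprintf("  %s: skipped\n", b)); next }
    cat(sprintf("  %-5s observed %7.3g Myr  null [%.3g, %.3g]  %s\n",
                b, x[[b]]$observed, x[[b]]$q_low, x[[b]]$q_high,
                x[[b]]$verdict))
  }
  invisible(x)
}
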