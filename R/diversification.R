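#' Prune a chronogram to a set of tips
#'
#' Drops all tips outside `keep` and suppresses the resulting degree-2
#' nodes. Every surviving internal node keeps its original age -- which
#' equals the age, in the input tree, of the MRCA of its retained
#' descendant tips -- and carries its age interval through unchanged.
#' Ages are copied from the input tree node-by-node (via an MRCA lookup),
#' not re-accumulated from branch lengths, so they are bitwise identical
#' to the originals.
#'
#' @param x a `chronogram`.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `chronogram`.
#' @export
prune_to_taxa <- function(x, keep) {
  stopifnot(inherits(x, "chronogram"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, x$phy$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label(s): ", paste(head(unknown, 5), collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  if (length(keep) == ape::Ntip(x$phy)) return(x)
  sub <- ape::keep.tip(x$phy, keep)
  n_new <- ape::Ntip(sub)
  nn_new <- n_new + sub$Nnode
  # map each new internal node to its original node through an MRCA lookup
  # on one descendant tip from each of two different children
  kids <- vector("list", nn_new)
  for (i in seq_len(nrow(sub$edge)))
    kids[[sub$edge[i, 1]]] <- c(kids[[sub$edge[i, 1]]], sub$edge[i, 2])
  first_tip <- integer(nn_new)
  po <- .postorder_nodes(sub)
  for (v in po)
    first_tip[v] <- if (v <= n_new) v else first_tip[kids[[v]][1]]
  age <- lower <- upper <- rep(NA_real_, nn_new)
  age[seq_len(n_new)] <- 0
  for (v in seq.int(n_new + 1L, nn_new)) {
    pair <- sub$tip.label[c(first_tip[kids[[v]][1]], first_tip[kids[[v]][2]])]
    ov <- ape::getMRCA(x$phy, pair)
    age[v] <- x$age[ov]
    lower[v] <- x$lower[ov]
    upper[v] <- x$upper[ov]
  }
  sub$edge.length <- age[sub$edge[, 1]] - age[sub$edge[, 2]]
  out <- structure(list(phy = sub, age = age, lower = lower, upper = upper),
                   class = "chronogram")
  out
}

# internal nodes & tips in postorder (children before parents)
.postorder_nodes <- function(phy) {
  e <- ape::reorder.phylo(phy, "postorder")$edge
  c(e[, 2][!duplicated(e[, 2])], e[nrow(e), 1])  # all children, then root
}

#' Extract the diversification events of a chronogram
#'
#' Records one event per internal node, dated by the node age under the
#' requested bound, with weight `child count - 1`: a polytomy of k children
#' stands for the k-1 bifurcations it collapses, so the total event weight
#' always equals `n_tips - 1`.
#'
#' @param x a `chronogram` with at least 2 tips.
#' @param bound which node age to read (`"mean"`, `"lower"`, `"upper"`);
#'   the lower/upper bounds require age intervals on every internal node.
#' @return an `event_set`: a data frame with columns `age` (Myr) and
#'   `weight` (positive integer), with attributes `bound` and `height`.
#' @export
split_events <- function(x, bound = c("mean", "lower", "upper")) {
  stopifnot(inherits(x, "chronogram"))
  bound <- match.arg(bound)
  if (ape::Ntip(x$phy) < 2) stop("need at least 2 tips")
  internal <- .internal_nodes(x)
  ages <- switch(bound, mean = x$age, lower = x$lower, upper = x$upper)
  if (bound != "mean" && anyNA(ages[internal]))
    stop(sprintf("bound \"%s\" requested but age intervals are missing", bound))
  w <- tabulate(x$phy$edge[, 1], nbins = max(internal))[internal] - 1L
  event_set(ages[internal], w, bound = bound, height = tree_height(x))
}

#' Construct an event set
#' @param age numeric vector of event ages (Myr).
#' @param weight positive integer weights (collapsed bifurcation counts).
#' @param bound,height provenance attributes.
#' @return a data frame of class `event_set`.
#' @export
event_set <- function(age, weight = rep(1L, length(age)), bound = "mean",
                      height = NA_real_) {
  stopifnot(length(age) == length(weight), all(weight >= 1))
  out <- data.frame(age = as.numeric(age), weight = as.integer(weight))
  attr(out, "bound") <- bound
  attr(out, "height") <- height
  class(out) <- c("event_set", "data.frame")
  out
}

#' Weighted median event age
#'
#' The median of the multiset obtained by repeating each event age by its
#' weight; with an even total weight the midpoint (mean of the two central
#' values) is returned, matching [stats::median()] on the expanded vector.
#'
#' @param events an `event_set`.
#' @return the median age in Myr.
#' @export
median_event_age <- function(events) {
  if (nrow(events) == 0) stop("empty event set")
  .weighted_median(events$age, events$weight)
}

.weighted_median <- function(a, w) {
  o <- order(a)
  a <- a[o]; cw <- cumsum(as.numeric(w[o]))
  W <- cw[length(cw)]
  if (W %% 2 == 1) {
    a[which.max(cw >= (W + 1) / 2)]
  } else {
    lo <- a[which.max(cw >= W / 2)]
    hi <- a[which.max(cw >= W / 2 + 1)]
    (lo + hi) / 2
  }
}

#' Histogram of event ages
#'
#' Bins event weights into half-open age bins `[k*w, (k+1)*w)` ascending
#' from 0; every bin covering `[0, t_max]` is reported, including empty
#' ones. An event falling exactly on `t_max` when `t_max` is a bin edge is
#' counted in the last bin so that no weight is lost.
#'
#' @param events an `event_set`.
#' @param bin_width bin width in Myr (default 20).
#' @param t_max upper end of the binned range; defaults to the event set's
#'   tree height (or the oldest event), rounded up to a whole bin.
#' @return a data frame with columns `lower`, `upper`, `count`.
#' @export
event_histogram <- function(events, bin_width = 20, t_max = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(t_max)) {
    t_max <- attr(events, "height")
    if (is.null(t_max) || is.na(t_max)) t_max <- max(events$age)
  }
  nb <- max(1L, as.integer(ceiling(t_max / bin_width - 1e-9)))
  idx <- pmin(floor(events$age / bin_width) + 1L, nb)
  count <- vapply(seq_len(nb), function(b) sum(events$weight[idx == b]), 0)
  data.frame(lower = (seq_len(nb) - 1) * bin_width,
             upper = seq_len(nb) * bin_width,
             count = count)
}

#' Lineage-through-time curve
#'
#' Number of ancestral lineages of the extant tips as a function of age.
#' Starting from the root (count = root child count) the count increases by
#' `child count - 1` at each internal node in order of decreasing age; a
#' terminal point at age 0 with the tip count is appended.
#'
#' @param x a `chronogram` with at least 2 tips.
#' @return a data frame with columns `age` (Myr, decreasing) and
#'   `lineages` (non-decreasing), class `ltt_curve`.
#' @export
ltt_curve <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  n <- ape::Ntip(x$phy)
  if (n < 2) stop("need at least 2 tips")
  internal <- .internal_nodes(x)
  deg <- tabulate(x$phy$edge[, 1], nbins = max(internal))[internal]
  o <- order(x$age[internal], decreasing = TRUE)
  ages <- x$age[internal][o]
  inc <- deg[o] - 1L
  counts <- cumsum(c(inc[1] + 1L, inc[-1]))
  out <- data.frame(age = c(ages, 0), lineages = c(counts, n))
  # collapse duplicate terminal row when an internal node sits at age ~0
  class(out) <- c("ltt_curve", "data.frame")
  out
}

#' Split events of a tip subset without building the pruned tree
#'
#' Computes, directly on the full tree, the event set that
#' `split_events(prune_to_taxa(x, keep), bound)` would return: an internal
#' node of the full tree survives pruning iff at least two of its child
#' subtrees contain kept tips, and its event weight is that child-subtree
#' count minus 1. This is the O(edges) inner loop of the randomization
#' test; its equivalence to the prune-then-extract route is property-tested.
#'
#' @param x a `chronogram`.
#' @param keep character vector of tip labels (at least 2).
#' @param bound age bound to read.
#' @return an `event_set`.
#' @export
subset_split_events <- function(x, keep, bound = c("mean", "lower", "upper")) {
  bound <- match.arg(bound)
  idx <- match(keep, x$phy$tip.label)
  if (anyNA(idx)) stop("unknown tip label(s)")
  if (length(idx) < 2) stop("need at least 2 tips")
  pre <- .subset_precompute(x, bound)
  .subset_events_fast(pre, idx)
}

# cache postorder edges and the age vector for repeated subset queries
.subset_precompute <- function(x, bound) {
  phy <- x$phy
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  e <- ape::reorder.phylo(phy, "postorder")$edge
  ages <- switch(bound, mean = x$age, lower = x$lower, upper = x$upper)
  if (bound != "mean" && anyNA(ages[seq.int(n + 1L, nn)]))
    stop(sprintf("bound \"%s\" requested but age intervals are missing", bound))
  list(n = n, nn = nn, parent = e[, 1], child = e[, 2],
       ages = ages, bound = bound, height = tree_height(x))
}

.subset_events_fast <- function(pre, tip_idx) {
  pres <- logical(pre$nn)
  cnt <- integer(pre$nn)
  pres[tip_idx] <- TRUE
  for (i in seq_along(pre$parent)) {
    p <- pre$parent[i]; cc <- pre$child[i]
    if (pres[cc]) {
      pres[p] <- TRUE
      cnt[p] <- cnt[p] + 1L
    }
  }
  keep <- which(cnt >= 2L)
  event_set(pre$ages[keep], cnt[keep] - 1L,
            bound = pre$bound, height = pre$height)
}
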