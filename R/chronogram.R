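#' @importFrom stats median quantile runif rgeom setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' Construct a chronogram from an ape "phylo" tree
#'
#' A chronogram is a rooted ultrametric tree whose branch lengths are in
#' absolute time (Myr here), so that every node has an age and all extant
#' tips sit at age 0. The object wraps an [ape::read.tree()] style `phylo`
#' tree together with a node-age vector and optional per-node age
#' credibility bounds, indexed in `phylo` node order (tips `1..n`, then
#' internal nodes `n+1..n+Nnode`).
#'
#' Node ages are derived from branch lengths as the maximum root-to-tip
#' path depth minus the node's own depth; tips are then pinned at age 0 and
#' edge lengths recomputed as `age[parent] - age[child]`, which removes any
#' sub-tolerance numerical spread among tip depths.
#'
#' @param phy an object of class `phylo` with branch lengths.
#' @param lower,upper optional numeric vectors of node-age bounds, either of
#'   length `Ntip + Nnode` (NA where absent) or of length `Nnode` (internal
#'   nodes only, in `phylo` internal-node order).
#' @param tolerance maximum allowed relative ultrametricity violation:
#'   (max tip depth - min tip depth) / tree height.
#' @param check if `FALSE`, skip invariant checks (used to build objects for
#'   [validate_chronogram()]).
#' @return an object of class `chronogram`: a list with elements `phy`
#'   (the `phylo` tree), `age`, `lower`, `upper` (numeric, node-indexed).
#' @seealso [parse_chronogram()], [write_chronogram()], [validate_chronogram()]
#' @export
chronogram <- function(phy, lower = NULL, upper = NULL, tolerance = 1e-6,
                       check = TRUE) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" tree")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length)))
    stop("missing branch length on at least one edge")
  n <- length(phy$tip.label)
  m <- phy$Nnode
  nn <- n + m
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(n)])
  if (check) {
    if (anyDuplicated(phy$tip.label))
      stop("duplicate tip labels: ",
           paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                 collapse = ", "))
    spread <- h - min(depth[seq_len(n)])
    if (h > 0 && spread / h > tolerance)
      stop(sprintf(
        "tree is not ultrametric: tip depth spread %.6g exceeds tolerance %g of height %.6g",
        spread, tolerance, h))
  }
  age <- h - depth
  age[seq_len(n)] <- 0
  phy$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  expand_bound <- function(b) {
    if (is.null(b)) return(rep(NA_real_, nn))
    if (length(b) == m) b <- c(rep(NA_real_, n), b)
    if (length(b) != nn) stop("age bound vector has wrong length")
    as.numeric(b)
  }
  x <- structure(list(phy = phy, age = age,
                      lower = expand_bound(lower),
                      upper = expand_bound(upper)),
                 class = "chronogram")
  if (check) {
    bad <- validate_chronogram(x)
    if (nrow(bad) > 0)
      stop("invalid chronogram: ", paste(bad$message, collapse = "; "))
  }
  x
}

#' @export
print.chronogram <- function(x, ...) {
  n <- ape::Ntip(x$phy)
  cat(sprintf("Chronogram: %d tips, %d internal nodes, height %.4g Myr\n",
              n, x$phy$Nnode, tree_height(x)))
  has_iv <- sum(!is.na(x$lower[-seq_len(n)]))
  cat(sprintf("Age intervals on %d/%d internal nodes\n", has_iv, x$phy$Nnode))
  invisible(x)
}

#' Tree height (root age) of a chronogram
#' @param x a `chronogram`.
#' @return numeric, root age in Myr.
#' @export
tree_height <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  max(x$age)
}

#' Node ages of a chronogram
#'
#' @param x a `chronogram`.
#' @param bound which age to read: the point estimate (`"mean"`) or the
#'   lower/upper bound of the node-age credibility interval.
#' @return numeric vector over all nodes in `phylo` node order; tips have
#'   age 0 for every bound.
#' @export
node_ages <- function(x, bound = c("mean", "lower", "upper")) {
  stopifnot(inherits(x, "chronogram"))
  bound <- match.arg(bound)
  a <- switch(bound, mean = x$age, lower = x$lower, upper = x$upper)
  if (bound != "mean") a[seq_len(ape::Ntip(x$phy))] <- 0
  a
}

# internal: indices of internal nodes
.internal_nodes <- function(x) {
  n <- ape::Ntip(x$phy)
  seq.int(n + 1L, n + x$phy$Nnode)
}

#' Validate a chronogram without raising
#'
#' Checks every structural invariant of the class and returns the full list
#' of violations rather than stopping at the first: tips not at age 0,
#' negative implied branch lengths (an internal node not strictly older than
#' each child), age intervals that do not bracket the point age, and
#' duplicated tip labels.
#'
#' @param x a `chronogram` (possibly built with `check = FALSE`).
#' @return a data frame with columns `node` (index or NA) and `message`;
#'   zero rows for a valid tree.
#' @export
validate_chronogram <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  phy <- x$phy
  n <- ape::Ntip(phy)
  node <- integer(0); msg <- character(0)
  add <- function(nd, m) {
    node <<- c(node, nd); msg <<- c(msg, m)
  }
  if (anyDuplicated(phy$tip.label))
    add(NA_integer_, "duplicate tip labels")
  bad_tip <- which(abs(x$age[seq_len(n)]) > 1e-9)
  for (i in bad_tip) add(i, sprintf("tip %s has nonzero age", phy$tip.label[i]))
  el <- x$age[phy$edge[, 1]] - x$age[phy$edge[, 2]]
  bad_e <- which(el <= 0)
  for (i in bad_e)
    add(phy$edge[i, 2],
        sprintf("node %d is not strictly younger than its parent", phy$edge[i, 2]))
  iv <- which(!is.na(x$lower) | !is.na(x$upper))
  for (i in iv) {
    lo <- x$lower[i]; hi <- x$upper[i]
    if (is.na(lo) || is.na(hi))
      add(i, sprintf("node %d has a one-sided age interval", i))
    else if (lo > x$age[i] || x$age[i] > hi)
      add(i, sprintf("node %d interval (%g, %g) does not bracket age %g",
                     i, lo, hi, x$age[i]))
  }
  data.frame(node = node, message = msg, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Newick I/O with age-interval annotations
#
# Intervals are serialized as bracket comments in the style of NEXUS
# metadata, placed after the node (and any label), before the branch length:
#   (A:10,B:10)[&age_interval={8.1,12.5}]:30
# Plain Newick without comments is accepted; any other bracket comment
# (e.g. figtree metadata) is dropped, and internal node labels such as
# bootstrap supports are parsed and discarded.
# ---------------------------------------------------------------------------

.iv_pattern <- "\\[&age_interval=\\{([0-9eE.+-]+),([0-9eE.+-]+)\\}\\]"

#' Parse a Newick string into a chronogram
#'
#' @param text a Newick string (single tree). Branch lengths are required on
#'   every non-root edge and are read as Myr. Node-age credibility intervals
#'   may be annotated as `[&age_interval={lower,upper}]` comments directly
#'   after a node; other bracket comments and internal-node support labels
#'   are ignored.
#' @param tolerance relative ultrametricity tolerance (tip depth spread over
#'   tree height); default `1e-6`.
#' @return a `chronogram`.
#' @examples
#' x <- parse_chronogram("((A:10,B:10):30,C:40);")
#' tree_height(x)  # 40
#' @export
parse_chronogram <- function(text, tolerance = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  ivs <- list()
  k <- 0L
  repeat {
    m <- regexpr(.iv_pattern, text, perl = TRUE)
    if (m[1] == -1L) break
    k <- k + 1L
    grp <- regmatches(text, regexec(.iv_pattern, text, perl = TRUE))[[1]]
    ivs[[k]] <- as.numeric(grp[2:3])
    regmatches(text, m) <- sprintf("__iv%d__", k)
  }
  # drop any remaining foreign comments
  text <- gsub("\\[[^]]*\\]", "", text)
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) stop("unparseable Newick: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("unparseable Newick text")
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  lower <- upper <- rep(NA_real_, nn)
  strip <- function(labels, idx_offset) {
    for (i in which(nzchar(labels) & grepl("__iv[0-9]+__", labels))) {
      k <- as.integer(sub(".*__iv([0-9]+)__.*", "\\1", labels[i]))
      lower[idx_offset + i] <<- ivs[[k]][1]
      upper[idx_offset + i] <<- ivs[[k]][2]
      labels[i] <- sub("__iv[0-9]+__", "", labels[i])
    }
    labels
  }
  phy$tip.label <- strip(phy$tip.label, 0L)
  if (!is.null(phy$node.label)) {
    invisible(strip(phy$node.label, n))
    phy$node.label <- NULL  # support values etc. are parsed and ignored
  }
  chronogram(phy, lower = lower, upper = upper, tolerance = tolerance)
}

#' Read a chronogram from a Newick file
#' @param path path to a Newick file (one tree).
#' @param tolerance see [parse_chronogram()].
#' @return a `chronogram`.
#' @examples
#' # a small synthetic example tree shipped with the package
#' x <- read_chronogram(system.file("extdata", "example_tree.nwk",
#'                                  package = "divtime"))
#' tree_height(x)
#' @export
read_chronogram <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  parse_chronogram(paste(readLines(path, warn = FALSE), collapse = ""),
                   tolerance = tolerance)
}

# shortest decimal string that round-trips a double
.fmt_num <- function(v) {
  out <- sprintf("%.15g", v)
  bad <- as.numeric(out) != v
  out[bad] <- sprintf("%.17g", v[bad])
  out
}

#' Serialize a chronogram to Newick
#'
#' Branch lengths are written as `age[parent] - age[child]`; age intervals
#' are emitted as `[&age_interval={lower,upper}]` comments. Children are
#' written in the stored edge order, so repeated calls are byte-identical
#' and `parse_chronogram(write_chronogram(x))` reproduces `x`.
#'
#' @param x a `chronogram`.
#' @return a single Newick string, terminated by `;`.
#' @export
write_chronogram <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  .chronogram_newick(x)
}

# internal writer; `extra` maps node index -> labels of tips to append as
# additional children with branch length equal to the node's age (grafting).
.chronogram_newick <- function(x, extra = NULL) {
  phy <- x$phy
  n <- ape::Ntip(phy)
  kids <- vector("list", n + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  iv <- function(v) {
    if (is.na(x$lower[v])) return("")
    sprintf("[&age_interval={%s,%s}]", .fmt_num(x$lower[v]), .fmt_num(x$upper[v]))
  }
  rec <- function(v, parent_age) {
    if (v <= n) {
      core <- paste0(phy$tip.label[v], iv(v))
    } else {
      parts <- vapply(kids[[v]], rec, "", parent_age = x$age[v])
      if (!is.null(extra) && !is.null(extra[[as.character(v)]]))
        parts <- c(parts, paste0(extra[[as.character(v)]], ":",
                                 .fmt_num(x$age[v])))
      core <- paste0("(", paste(parts, collapse = ","), ")", iv(v))
    }
    if (is.na(parent_age)) core
    else paste0(core, ":", .fmt_num(parent_age - x$age[v]))
  }
  root <- n + 1L
  paste0(rec(root, NA_real_), ";")
}

#' Rescale a chronogram to a target height
#'
#' Multiplies every node age (and interval bound) by
#' `height / tree_height(x)`. Used to bring simulated trees to the absolute
#' time scale of an empirical assemblage.
#'
#' @param x a `chronogram`.
#' @param height target root age in Myr (> 0).
#' @return a `chronogram` of the requested height.
#' @export
rescale_chronogram <- function(x, height) {
  stopifnot(inherits(x, "chronogram"), is.numeric(height), height > 0)
  f <- height / tree_height(x)
  x$age <- x$age * f
  x$lower <- x$lower * f
  x$upper <- x$upper * f
  x$phy$edge.length <- x$phy$edge.length * f
  x
}
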