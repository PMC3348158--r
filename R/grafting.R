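#' Escalation ladder for taxonomic grafting
#'
#' The four placement levels, in the order they are attempted: MRCA of two
#' or more congeners; parent of a single congener (the node linking the
#' congener with its closest relative); MRCA of the family's members; MRCA
#' of the order's members.
#' @export
GRAFT_LEVELS <- c("two_congeners", "one_congener", "family", "order")

# backbone tips sharing a rank value with the request, excluding itself
.rank_members <- function(x, taxa, request, rank) {
  val <- request[[rank]]
  if (is.null(val) || !nzchar(val)) return(character(0))
  members <- taxa$species[taxa[[rank]] == val & taxa$species != request$species]
  intersect(x$phy$tip.label, members)
}

#' Find the attachment node for one graft request at one level
#'
#' * `two_congeners`: at least two backbone congeners -> their MRCA.
#' * `one_congener`: exactly one backbone congener -> that tip's parent
#'   (the node linking the congener with its closest non-congener); with
#'   two or more congeners their MRCA is used.
#' * `family` / `order`: at least one backbone member of the rank -> the
#'   MRCA of all backbone members (a single member's MRCA being its parent
#'   node).
#'
#' @param x a `chronogram` (the backbone).
#' @param taxa a `taxon_table` covering the backbone tips.
#' @param request a list or one-row data frame with `species`, `genus`,
#'   `family`, `order`.
#' @param level one of [GRAFT_LEVELS].
#' @return the attachment node index, or `NA` when the level does not apply.
#' @export
find_attachment <- function(x, taxa, request, level) {
  stopifnot(inherits(x, "chronogram"))
  level <- match.arg(level, GRAFT_LEVELS)
  phy <- x$phy
  parent_of <- function(tip_label) {
    i <- match(tip_label, phy$tip.label)
    phy$edge[phy$edge[, 2] == i, 1]
  }
  members <- switch(level,
    two_congeners = ,
    one_congener = .rank_members(x, taxa, request, "genus"),
    family = .rank_members(x, taxa, request, "family"),
    order = .rank_members(x, taxa, request, "order"))
  k <- length(members)
  if (level == "two_congeners") {
    if (k < 2) return(NA_integer_)
    return(ape::getMRCA(phy, members))
  }
  if (k == 0) return(NA_integer_)
  if (k == 1) return(parent_of(members))
  ape::getMRCA(phy, members)
}

# attach `labels[i]` as a new child of node `nodes[i]` with branch length
# equal to the node's age; pure index surgery, no branch-length arithmetic
.add_tips <- function(x, nodes, labels) {
  if (length(nodes) == 0) return(x)
  phy <- x$phy
  n <- ape::Ntip(phy)
  k <- length(labels)
  remap <- function(v) ifelse(v <= n, v, v + k)
  new_edge <- rbind(cbind(remap(phy$edge[, 1]), remap(phy$edge[, 2])),
                    cbind(remap(nodes), n + seq_len(k)))
  age <- c(x$age[seq_len(n)], rep(0, k), x$age[-seq_len(n)])
  lower <- c(x$lower[seq_len(n)], rep(NA_real_, k), x$lower[-seq_len(n)])
  upper <- c(x$upper[seq_len(n)], rep(NA_real_, k), x$upper[-seq_len(n)])
  new_phy <- structure(list(edge = new_edge,
                            edge.length = age[new_edge[, 1]] - age[new_edge[, 2]],
                            tip.label = c(phy$tip.label, labels),
                            Nnode = phy$Nnode),
                       class = "phylo")
  new_phy <- ape::reorder.phylo(new_phy, "cladewise")
  structure(list(phy = new_phy, age = age, lower = lower, upper = upper),
            class = "chronogram")
}

#' Graft unsequenced species onto a backbone chronogram
#'
#' Attaches each requested species at the first level of the escalation
#' ladder that applies, as a new tip whose branch length equals the age of
#' the attachment node (so the tip sits at age 0 and the node becomes, or
#' grows, a polytomy). No existing node age or backbone topology is
#' altered, and the result remains ultrametric. Species no level can place
#' are reported as `"unplaced"`, not treated as an error.
#'
#' By default attachment nodes are computed on the original backbone only,
#' so placements are independent of request order. With
#' `sequential = TRUE`, each grafted species immediately joins the working
#' tree and taxon table and can serve as a congener / family / order member
#' for later requests, mimicking a stepwise manual procedure.
#'
#' @param x the backbone `chronogram`.
#' @param taxa a `taxon_table` covering the backbone tips.
#' @param requests a data frame with columns `species`, `genus`, `family`,
#'   `order` (and optionally `status`) for the species to add; labels must
#'   not already be tips.
#' @param levels the escalation ladder to apply, a prefix or subset of
#'   [GRAFT_LEVELS], in order.
#' @param sequential whether grafted tips join the attachment pool.
#' @return the enriched `chronogram`, with a `graft_report` attribute: a
#'   data frame with one row per request (`species`, `level`, `node_age`,
#'   `branch_length`).
#' @export
apply_grafts <- function(x, taxa, requests, levels = GRAFT_LEVELS,
                         sequential = FALSE) {
  stopifnot(inherits(x, "chronogram"))
  levels <- match.arg(levels, GRAFT_LEVELS, several.ok = TRUE)
  if (anyDuplicated(requests$species))
    stop("duplicate request labels: ",
         paste(unique(requests$species[duplicated(requests$species)]),
               collapse = ", "))
  clash <- intersect(requests$species, x$phy$tip.label)
  if (length(clash) > 0)
    stop("request label(s) already in the tree: ",
         paste(clash, collapse = ", "))
  nr <- nrow(requests)
  placed_level <- rep("unplaced", nr)
  node_age <- rep(NA_real_, nr)
  if (!sequential) {
    nodes <- rep(NA_integer_, nr)
    for (i in seq_len(nr)) {
      req <- as.list(requests[i, ])
      for (lv in levels) {
        v <- find_attachment(x, taxa, req, lv)
        if (!is.na(v)) {
          nodes[i] <- v; placed_level[i] <- lv
          node_age[i] <- x$age[v]
          break
        }
      }
    }
    ok <- !is.na(nodes)
    out <- .add_tips(x, nodes[ok], requests$species[ok])
  } else {
    out <- x
    cur_taxa <- taxa
    remaining <- seq_len(nr)
    for (lv in levels) {
      still <- integer(0)
      for (i in remaining) {
        req <- as.list(requests[i, ])
        v <- find_attachment(out, cur_taxa, req, lv)
        if (!is.na(v)) {
          placed_level[i] <- lv
          node_age[i] <- out$age[v]
          out <- .add_tips(out, v, req$species)
          add <- requests[i, intersect(names(requests),
                                       c("species", "genus", "family",
                                         "order", "status"))]
          if (is.null(add$status)) add$status <- "native"
          cur_taxa <- taxon_table(rbind(as.data.frame(cur_taxa), add))
        } else still <- c(still, i)
      }
      remaining <- still
    }
  }
  report <- data.frame(species = requests$species, level = placed_level,
                       node_age = node_age, branch_length = node_age,
                       stringsAsFactors = FALSE)
  attr(out, "graft_report") <- report
  out
}

#' Chronogram series of increasing taxonomic coverage
#'
#' Applies [apply_grafts()] with each cumulative prefix of the escalation
#' ladder, giving four trees: species placeable between two congeners only;
#' plus single-congener placements; plus family-level; plus order-level.
#'
#' @inheritParams apply_grafts
#' @return a named list of four `chronogram`s
#'   (`congeners2`, `congeners1`, `family`, `order`), each carrying its
#'   `graft_report` attribute.
#' @export
chronogram_series <- function(x, taxa, requests, sequential = FALSE) {
  prefixes <- lapply(seq_along(GRAFT_LEVELS), function(k) GRAFT_LEVELS[1:k])
  out <- lapply(prefixes, function(lv)
    apply_grafts(x, taxa, requests, levels = lv, sequential = sequential))
  names(out) <- c("congeners2", "congeners1", "family", "order")
  out
}
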