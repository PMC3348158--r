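#' Simulate a birth-death chronogram
#'
#' Forward-in-time birth-death simulation of a crown clade (two starting
#' lineages), with either a target number of extant tips or a fixed total
#' duration as the stopping rule. Extinct lineages are pruned from the
#' output, so the returned tree contains extant species only, as in an
#' empirical chronogram. Runs that go extinct before satisfying the
#' stopping rule are retried with fresh draws from the same random stream;
#' the whole simulation is reproducible from `seed`.
#'
#' Under tip-count stopping the present is set just before the first event
#' that would follow the moment the target count is reached, so terminal
#' branches have positive length. Under duration stopping, birth and death
#' rates may vary through time via `epochs`, a data frame with columns
#' `start_age`, `end_age` (Myr before present, `start_age > end_age`,
#' contiguous, jointly covering `[0, duration]`), `birth` and `death`
#' (per lineage per Myr). Epoch schedules are tied to absolute ages and are
#' therefore only available with a duration stopping rule.
#'
#' @param n_tips target number of extant tips (tip-count stopping), or NULL.
#' @param duration total simulation time in Myr (duration stopping), or NULL.
#'   Exactly one of `n_tips`/`duration` must be given.
#' @param birth,death constant speciation/extinction rates per lineage per
#'   Myr; ignored when `epochs` is supplied.
#' @param epochs optional piecewise rate schedule (see Details).
#' @param seed integer seed; all randomness flows from it.
#' @param retries how many fresh attempts to make when the clade dies out
#'   (or fewer than 2 lineages survive) before raising an error.
#' @return a `chronogram` (no age intervals).
#' @examples
#' x <- simulate_bd_chronogram(n_tips = 10, birth = 1, death = 0, seed = 1)
#' ape::Ntip(x$phy)  # 10
#' @export
simulate_bd_chronogram <- function(n_tips = NULL, duration = NULL,
                                   birth = 0.08, death = 0.03,
                                   epochs = NULL, seed = NULL,
                                   retries = 100) {
  if (is.null(n_tips) == is.null(duration))
    stop("exactly one of 'n_tips' or 'duration' must be given")
  if (!is.null(n_tips) && n_tips < 2) stop("'n_tips' must be at least 2")
  if (!is.null(epochs)) {
    if (is.null(duration))
      stop("epoch rate schedules require a duration stopping rule")
    req <- c("start_age", "end_age", "birth", "death")
    if (!all(req %in% names(epochs))) stop("epochs need columns ",
                                           paste(req, collapse = ", "))
    epochs <- epochs[order(-epochs$start_age), ]
    if (any(epochs$birth < 0) || any(epochs$death < 0))
      stop("rates must be non-negative")
    if (abs(epochs$start_age[1] - duration) > 1e-9 ||
        abs(epochs$end_age[nrow(epochs)]) > 1e-9 ||
        (nrow(epochs) > 1 &&
         any(abs(epochs$end_age[-nrow(epochs)] - epochs$start_age[-1]) > 1e-9)))
      stop("epochs must be contiguous and cover [0, duration]")
  } else {
    if (birth < 0 || death < 0) stop("rates must be non-negative")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (attempt in seq_len(retries)) {
    res <- .bd_forward_once(n_tips, duration, birth, death, epochs)
    if (!is.null(res)) return(res)
  }
  stop(sprintf("clade went extinct in all %d attempts; increase rates or retries",
               retries))
}

# one forward pass; NULL on failure (extinction / <2 survivors)
.bd_forward_once <- function(n_tips, duration, birth, death, epochs) {
  cap <- 16L
  parent <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  state <- integer(cap)  # 0 active, 1 split, 2 dead
  nlin <- 2L
  parent[1:2] <- 0L; t0[1:2] <- 0; state[1:2] <- 0L
  active <- c(1L, 2L)
  t <- 0
  if (is.null(epochs)) {
    eb <- birth; ed <- death
    boundary <- if (is.null(duration)) Inf else duration
    ep_i <- 0L
  } else {
    ep_i <- 1L
    eb <- epochs$birth[1]; ed <- epochs$death[1]
    boundary <- duration - epochs$end_age[1]
  }
  present <- NA_real_
  repeat {
    na <- length(active)
    tot <- na * (eb + ed)
    dt <- if (tot > 0) stats::rexp(1, tot) else Inf
    if (t + dt >= boundary) {
      # epoch boundary or end of simulated time
      if (!is.null(duration) && boundary >= duration - 1e-12) {
        t <- duration; present <- duration; break
      }
      t <- boundary
      ep_i <- ep_i + 1L
      eb <- epochs$birth[ep_i]; ed <- epochs$death[ep_i]
      boundary <- duration - epochs$end_age[ep_i]
      next
    }
    t <- t + dt
    pick <- active[sample.int(na, 1L)]
    if (stats::runif(1) < eb / (eb + ed)) {
      # speciation: lineage `pick` ends, two daughters start
      state[pick] <- 1L; t1[pick] <- t
      if (nlin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t0) <- cap
        length(t1) <- cap; length(state) <- cap
      }
      kid <- nlin + 1:2
      parent[kid] <- pick; t0[kid] <- t; state[kid] <- 0L
      nlin <- nlin + 2L
      active <- c(active[active != pick], kid)
      if (!is.null(n_tips) && length(active) == n_tips) {
        present <- t + stats::rexp(1, length(active) * (eb + ed))
        break
      }
    } else {
      state[pick] <- 2L; t1[pick] <- t
      active <- active[active != pick]
      if (length(active) == 0L) return(NULL)
    }
  }
  if (length(active) < 2L) return(NULL)
  t1[active] <- present
  nwk <- .lineages_newick(parent[1:nlin], t0[1:nlin], t1[1:nlin], state[1:nlin])
  phy <- ape::read.tree(text = nwk)
  extant <- sprintf("s%d", active)
  phy <- ape::keep.tip(phy, extant)
  # deterministic relabelling in cladewise tip order
  phy$tip.label <- sprintf("t%03d", seq_along(phy$tip.label))
  chronogram(phy, tolerance = 1e-8)
}

.lineages_newick <- function(parent, t0, t1, state) {
  kids <- split(seq_along(parent), parent)
  rec <- function(i) {
    bl <- .fmt_num(t1[i] - t0[i])
    if (state[i] == 1L) {
      k <- kids[[as.character(i)]]
      paste0("(", rec(k[1]), ",", rec(k[2]), "):", bl)
    } else {
      paste0("s", i, ":", bl)
    }
  }
  paste0("(", rec(1L), ",", rec(2L), ");")
}

# ---------------------------------------------------------------------------
# Category labelling and taxonomy synthesis
# ---------------------------------------------------------------------------

#' Assign status categories and a synthetic taxonomy to tree tips
#'
#' Labels every tip of a chronogram with a biogeographic status and a nested
#' genus/family/order taxonomy, producing the taxon table the
#' diversification analysis consumes. Two labelling modes:
#'
#' * `"proportions"`: statuses are drawn independently per tip from the
#'   given proportions (exchangeable labels, the null the randomization
#'   test is calibrated against). Alternatively `counts` fixes the exact
#'   per-status composition and assigns it by random permutation.
#' * `"clade_enriched"`: the target status is concentrated in clades
#'   originating inside an age window. Candidate clades are the maximal
#'   clades whose root age falls in `window` (their parent, if any, being
#'   older than the window); candidates are selected in random order until
#'   they jointly cover about `proportions[target]` of the tips (always at
#'   least one clade). Tips inside selected clades receive the target
#'   status with probability `strength`; every other tip draws its status
#'   from the remaining proportions, renormalized with the target's mass
#'   removed, so the target status marks the enriched clades only. This is
#'   the age-structured signal the median-age randomization test is meant
#'   to detect.
#'
#' The taxonomy is synthesized by nested clade cuts: orders are clades of
#' geometric mean size `genus_size * family_genera * order_families` tips,
#' families are clades nested within orders, and genera clades nested within
#' families with geometric mean size `genus_size` (so sister tips often
#' share a genus). Only the containment structure matters; it makes
#' MRCA-based grafting testable.
#'
#' @param x a `chronogram`.
#' @param mode `"proportions"` or `"clade_enriched"`.
#' @param proportions named numeric vector over (a subset of)
#'   `STATUS_LEVELS`, summing to 1.
#' @param counts optional named integer vector of exact per-status counts
#'   (must sum to the number of tips); overrides random proportions.
#' @param target,window,strength clade-enrichment parameters: target status,
#'   `c(age_low, age_high)` in Myr, and the within-clade assignment
#'   probability in `[0, 1]`.
#' @param genus_size,family_genera,order_families expected sizes of the
#'   synthesized taxonomy (tips per genus, genera per family, families per
#'   order).
#' @param seed integer seed.
#' @return a `taxon_table` covering every tip.
#' @export
assign_categories <- function(x, mode = c("proportions", "clade_enriched"),
                              proportions = c(endemic = 0.105, native = 0.729,
                                              exotic = 0.166),
                              counts = NULL,
                              target = "endemic", window = NULL, strength = 1,
                              genus_size = 2, family_genera = 5,
                              order_families = 5, seed = NULL) {
  stopifnot(inherits(x, "chronogram"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  phy <- x$phy
  n <- ape::Ntip(phy)
  tips <- phy$tip.label
  if (is.null(counts)) {
    if (!all(names(proportions) %in% STATUS_LEVELS))
      stop("unknown status in proportions")
    if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  }

  kids <- vector("list", n + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  tipset <- function(v) {
    if (v <= n) return(v)
    unlist(lapply(kids[[v]], tipset))
  }

  # --- status ---------------------------------------------------------------
  if (!is.null(counts)) {
    if (!all(names(counts) %in% STATUS_LEVELS)) stop("unknown status in counts")
    if (sum(counts) != n) stop("counts must sum to the number of tips")
    status <- sample(rep(names(counts), counts))
  } else if (mode == "proportions") {
    status <- sample(names(proportions), n, replace = TRUE, prob = proportions)
  } else {
    if (is.null(window) || length(window) != 2 || window[1] >= window[2])
      stop("clade_enriched mode needs window = c(age_low, age_high)")
    if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
    if (!target %in% STATUS_LEVELS) stop("unknown target status")
    root <- n + 1L
    pa <- rep(NA_integer_, n + phy$Nnode)
    pa[phy$edge[, 2]] <- phy$edge[, 1]
    internal <- seq.int(n + 1L, n + phy$Nnode)
    in_win <- x$age[internal] >= window[1] & x$age[internal] <= window[2]
    maximal <- internal == root | x$age[pa[internal]] > window[2]
    cand <- internal[in_win & maximal]
    if (length(cand) == 0)
      stop("enrichment window contains no clade origins")
    p_t <- if (target %in% names(proportions)) proportions[[target]] else 0
    want <- round(p_t * n)
    cand <- cand[sample.int(length(cand))]
    sel_tips <- integer(0)
    for (v in cand) {
      if (length(sel_tips) >= max(want, 1)) break
      sel_tips <- union(sel_tips, tipset(v))
    }
    other <- proportions[setdiff(names(proportions), target)]
    draw_other <- function(k) {
      if (k == 0) return(character(0))
      if (sum(other) <= 0) return(rep(target, k))
      sample(names(other), k, replace = TRUE, prob = other / sum(other))
    }
    status <- character(n)
    in_sel <- seq_len(n) %in% sel_tips
    hit <- in_sel & stats::runif(n) < strength
    status[hit] <- target
    status[!hit] <- draw_other(sum(!hit))
  }

  # --- nested taxonomy ------------------------------------------------------
  cut_clades <- function(roots, mean_size) {
    groups <- list()
    visit <- function(v) {
      ts <- tipset(v)
      lim <- 1 + stats::rgeom(1, 1 / mean_size)
      if (v <= n || length(ts) <= lim) {
        groups[[length(groups) + 1L]] <<- list(root = v, tips = ts)
      } else {
        for (k in kids[[v]]) visit(k)
      }
    }
    for (r in roots) visit(r)
    groups
  }
  root <- n + 1L
  orders <- cut_clades(root, genus_size * family_genera * order_families)
  genus <- family <- order <- character(n)
  gi <- fi <- 0L
  for (oi in seq_along(orders)) {
    o <- orders[[oi]]
    order[o$tips] <- sprintf("ord%02d", oi)
    fams <- cut_clades(o$root, genus_size * family_genera)
    for (f in fams) {
      fi <- fi + 1L
      family[f$tips] <- sprintf("fam%03d", fi)
      gens <- cut_clades(f$root, genus_size)
      for (g in gens) {
        gi <- gi + 1L
        genus[g$tips] <- sprintf("gen%04d", gi)
      }
    }
  }
  taxon_table(data.frame(species = tips, genus = genus, family = family,
                         order = order, status = status,
                         stringsAsFactors = FALSE))
}

#' Attach synthetic age credibility intervals to a chronogram
#'
#' Every internal node of age `a` receives bounds
#' `(a * (1 - u1), a * (1 + u2))` with `u1, u2` drawn independently and
#' uniformly from `(0, relative_halfwidth]`, so `lower < a < upper` always
#' holds. Intervals of parents and children may overlap, as in real
#' posterior age estimates; no ordering constraint across nodes is imposed.
#'
#' @param x a `chronogram` (intervals, if present, are overwritten).
#' @param relative_halfwidth maximum relative half-width, in `(0, 1)`;
#'   default 0.25, a typical relative width of dated-node credibility
#'   intervals.
#' @param seed integer seed.
#' @return the chronogram with `lower`/`upper` set on all internal nodes.
#' @export
synthesize_age_intervals <- function(x, relative_halfwidth = 0.25,
                                     seed = NULL) {
  stopifnot(inherits(x, "chronogram"))
  if (relative_halfwidth <= 0 || relative_halfwidth >= 1)
    stop("relative_halfwidth must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  internal <- .internal_nodes(x)
  u1 <- relative_halfwidth * (1 - stats::runif(length(internal)))
  u2 <- relative_halfwidth * (1 - stats::runif(length(internal)))
  x$lower[internal] <- x$age[internal] * (1 - u1)
  x$upper[internal] <- x$age[internal] * (1 + u2)
  x
}

#' Generate per-locus alignment fixtures
#'
#' Writes one aligned FASTA file per locus over a shared taxon set, with a
#' chosen fraction of taxon-by-locus blocks entirely filled with `?`
#' (a taxon not sequenced for that locus -- the dominant mode of missing
#' data in multi-locus supermatrices). Residues are uniform random
#' nucleotides; no substitution model is implied.
#'
#' @param lengths integer vector of per-locus site counts.
#' @param n_taxa number of taxa shared across loci.
#' @param missing_fraction probability that a taxon is unsequenced for a
#'   locus (its block becomes all `?`).
#' @param seed integer seed.
#' @param dir output directory (created if needed); when `NULL`, nothing is
#'   written and only in-memory alignments are returned.
#' @param locus_names names for the loci (default `locus1`, ...).
#' @return invisibly, a list with `alignments` (named list of character
#'   matrices), `paths` (written files or NULL), `taxa`, and
#'   `realized_missing` (the realized fraction of all-`?` blocks).
#' @export
make_alignment_fixture <- function(lengths, n_taxa, missing_fraction = 0,
                                   seed = NULL, dir = NULL,
                                   locus_names = NULL) {
  stopifnot(all(lengths >= 1), n_taxa >= 1,
            missing_fraction >= 0, missing_fraction < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(locus_names)) locus_names <- sprintf("locus%d", seq_along(lengths))
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  alns <- vector("list", length(lengths))
  names(alns) <- locus_names
  n_missing <- 0L
  for (j in seq_along(lengths)) {
    m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * lengths[j],
                       replace = TRUE),
                nrow = n_taxa, dimnames = list(taxa, NULL))
    gone <- stats::runif(n_taxa) < missing_fraction
    m[gone, ] <- "?"
    n_missing <- n_missing + sum(gone)
    alns[[j]] <- m
  }
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(locus_names, ".fasta"))
    for (j in seq_along(alns)) write_fasta_alignment(alns[[j]], paths[j])
  }
  invisible(list(alignments = alns, paths = paths, taxa = taxa,
                 realized_missing = n_missing / (n_taxa * length(lengths))))
}
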