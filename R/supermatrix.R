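#' Read an aligned FASTA file as a character matrix
#'
#' @param path path to an aligned FASTA file. Sequences must all have the
#'   same length; `-` marks gaps and `?` missing data.
#' @return a character matrix (taxa x sites, uppercase) with taxon
#'   rownames.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  len <- lengths(seqs)
  if (length(unique(len)) != 1)
    stop("ragged alignment in ", path, ": sequence lengths ",
         paste(unique(len), collapse = ", "))
  m <- do.call(rbind, seqs)
  rownames(m) <- names(seqs)
  toupper(m)
}

#' Write a character-matrix alignment to FASTA
#' @param aln a character matrix with taxon rownames.
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path, nbchar = 80)
}

#' Block-filter parameters
#'
#' Conservation-based alignment filtering in the style of Gblocks. The
#' stated run parameters are the minimum block length (10 sites), the
#' maximum run of contiguous non-conserved positions (5), and the maximum
#' per-column gap fraction (50%); the conservation thresholds default to
#' the canonical values (a column is conserved when more than half the
#' sequences share the modal residue, highly conserved above 85%). No
#' bit-identity with any particular Gblocks release is claimed; the filter
#' is defined by the rules in [filter_blocks()].
#'
#' @param min_block_length minimum retained block length in sites.
#' @param max_contiguous_nonconserved longest run of non-conserved columns
#'   allowed inside a block.
#' @param max_gap_fraction columns with a larger gap fraction are excluded
#'   outright (and treated as non-conserved).
#' @param conserved_threshold,highly_conserved_threshold modal-residue
#'   frequency (over all sequences) that must be strictly exceeded.
#' @return a list of class `block_filter_params`.
#' @export
block_filter_params <- function(min_block_length = 10,
                                max_contiguous_nonconserved = 5,
                                max_gap_fraction = 0.5,
                                conserved_threshold = 0.5,
                                highly_conserved_threshold = 0.85) {
  stopifnot(min_block_length >= 1,
            max_contiguous_nonconserved >= 0,
            max_gap_fraction > 0, max_gap_fraction <= 1,
            conserved_threshold > 0, conserved_threshold <= 1,
            highly_conserved_threshold >= conserved_threshold,
            highly_conserved_threshold <= 1)
  structure(list(min_block_length = min_block_length,
                 max_contiguous_nonconserved = max_contiguous_nonconserved,
                 max_gap_fraction = max_gap_fraction,
                 conserved_threshold = conserved_threshold,
                 highly_conserved_threshold = highly_conserved_threshold),
            class = "block_filter_params")
}

#' Classify alignment columns by conservation
#'
#' A column whose gap fraction (`-` or `?`, over all sequences) exceeds
#' `max_gap_fraction` is `gap_excluded` (treated as non-conserved by the
#' block filter). Otherwise the frequency of the modal non-gap residue,
#' relative to the total number of sequences, decides: strictly above
#' `highly_conserved_threshold` -> `highly_conserved`, strictly above
#' `conserved_threshold` -> `conserved`, else `nonconserved`.
#'
#' @param aln a character matrix (taxa x sites).
#' @param params a [block_filter_params()] list.
#' @return a character vector of per-column labels.
#' @export
classify_positions <- function(aln, params = block_filter_params()) {
  stopifnot(is.matrix(aln))
  nseq <- nrow(aln)
  vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    is_gap <- col %in% c("-", "?")
    if (sum(is_gap) / nseq > params$max_gap_fraction) return("gap_excluded")
    res <- col[!is_gap]
    if (length(res) == 0) return("gap_excluded")
    f <- max(table(res)) / nseq
    if (f > params$highly_conserved_threshold) "highly_conserved"
    else if (f > params$conserved_threshold) "conserved"
    else "nonconserved"
  }, character(1))
}

#' Filter ambiguously aligned blocks from an alignment
#'
#' Three rules, applied in order: (i) every maximal run of more than
#' `max_contiguous_nonconserved` non-conserved columns (including
#' gap-excluded ones) is dropped; (ii) each remaining segment is trimmed so
#' that it starts and ends on a highly conserved column; (iii) segments
#' shorter than `min_block_length` are dropped. Retained columns keep
#' their input order.
#'
#' @param aln a character matrix (taxa x sites).
#' @param params a [block_filter_params()] list.
#' @return a list with `alignment` (the kept columns), `retained_fraction`,
#'   and `blocks` (data frame of 0-based half-open `[start, end)` column
#'   intervals in input coordinates).
#' @export
filter_blocks <- function(aln, params = block_filter_params()) {
  lab <- classify_positions(aln, params)
  nc <- length(lab)
  noncons <- lab %in% c("nonconserved", "gap_excluded")
  keep <- !noncons
  # (i) drop long non-conserved runs only; short runs stay (for now)
  r <- rle(noncons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] <= params$max_contiguous_nonconserved)
      keep[starts[i]:ends[i]] <- TRUE
  # (ii)+(iii) per surviving segment: trim to highly conserved ends, then
  # enforce the minimum block length
  blocks <- list()
  kr <- rle(keep)
  kends <- cumsum(kr$lengths)
  kstarts <- kends - kr$lengths + 1
  for (i in seq_along(kr$lengths)) {
    if (!kr$values[i]) next
    seg <- kstarts[i]:kends[i]
    hc <- seg[lab[seg] == "highly_conserved"]
    if (length(hc) == 0) next
    seg <- min(hc):max(hc)
    if (length(seg) < params$min_block_length) next
    blocks[[length(blocks) + 1L]] <- c(seg[1] - 1L, seg[length(seg)])
  }
  cols <- unlist(lapply(blocks, function(b) (b[1] + 1L):b[2]))
  blocks_df <- if (length(blocks) > 0)
    data.frame(start = vapply(blocks, `[`, 0, 1),
               end = vapply(blocks, `[`, 0, 2))
  else data.frame(start = numeric(0), end = numeric(0))
  list(alignment = aln[, cols, drop = FALSE],
       retained_fraction = length(cols) / nc,
       blocks = blocks_df)
}

#' Concatenate per-locus alignments into a supermatrix
#'
#' Builds the union of taxa across loci (sorted for determinism), pads the
#' block of any taxon absent from a locus with `?`, and records the
#' partition map.
#'
#' @param alignments a named list of character matrices (taxa x sites);
#'   names become locus names in the partition map.
#' @return an object of class `supermatrix`: list with `matrix` (taxa x
#'   total sites) and `partitions` (data frame `locus`, `start`, `end`;
#'   0-based half-open column intervals tiling the matrix).
#' @export
concatenate_loci <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) > 0)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    names(alignments) <- sprintf("locus%d", seq_along(alignments))
  for (nm in names(alignments)) {
    a <- alignments[[nm]]
    if (!is.matrix(a) || is.null(rownames(a)))
      stop("alignment ", nm, " must be a matrix with taxon rownames")
    if (anyDuplicated(rownames(a)))
      stop("duplicate taxon within locus ", nm)
  }
  taxa <- sort(unique(unlist(lapply(alignments, rownames))))
  widths <- vapply(alignments, ncol, 0L)
  total <- sum(widths)
  m <- matrix("?", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  at <- 0L
  for (a in alignments) {
    if (ncol(a) > 0)
      m[rownames(a), at + seq_len(ncol(a))] <- a
    at <- at + ncol(a)
  }
  ends <- cumsum(widths)
  partitions <- data.frame(locus = names(alignments),
                           start = ends - widths, end = ends,
                           stringsAsFactors = FALSE)
  structure(list(matrix = m, partitions = partitions), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d sites, %d partitions, %.1f%% missing\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$partitions),
              100 * missing_stats(x)))
  invisible(x)
}

#' Fraction of missing cells in a supermatrix
#' @param x a `supermatrix` (or a character matrix).
#' @return the fraction of `?` cells.
#' @export
missing_stats <- function(x) {
  m <- if (inherits(x, "supermatrix")) x$matrix else x
  sum(m == "?") / length(m)
}

#' Extract one locus back out of a supermatrix
#' @param x a `supermatrix`.
#' @param locus locus name from the partition map.
#' @return the character matrix of that partition's columns (all taxa).
#' @export
supermatrix_slice <- function(x, locus) {
  stopifnot(inherits(x, "supermatrix"))
  p <- x$partitions[x$partitions$locus == locus, ]
  if (nrow(p) != 1) stop("unknown locus: ", locus)
  x$matrix[, (p$start + 1L):p$end, drop = FALSE]
}

#' Write a supermatrix to disk
#'
#' Writes the concatenated alignment as FASTA, the partition map as a
#' RAxML-style partition file (`locus = start-end`, 1-based inclusive for
#' interoperability), and summary statistics as JSON.
#'
#' @param x a `supermatrix`.
#' @param prefix output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.partitions` and `<prefix>.json`.
#' @return invisibly, the three paths.
#' @export
write_supermatrix <- function(x, prefix) {
  stopifnot(inherits(x, "supermatrix"))
  paths <- paste0(prefix, c(".fasta", ".partitions", ".json"))
  write_fasta_alignment(x$matrix, paths[1])
  writeLines(sprintf("%s = %d-%d", x$partitions$locus,
                     x$partitions$start + 1L, x$partitions$end),
             paths[2])
  stats <- list(n_taxa = nrow(x$matrix), n_sites = ncol(x$matrix),
                n_partitions = nrow(x$partitions),
                missing_fraction = missing_stats(x),
                partition_widths = setNames(
                  as.list(x$partitions$end - x$partitions$start),
                  x$partitions$locus))
  jsonlite::write_json(stats, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
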