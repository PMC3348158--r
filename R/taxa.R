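#' Biogeographic status classes
#'
#' The closed set of status labels used throughout: species endemic to the
#' region, non-endemic natives, exotics (introduced species), and
#' extra-regional outgroups used only to root and calibrate the tree.
#' @export
STATUS_LEVELS <- c("endemic", "native", "exotic", "outgroup")

#' Load and validate a species status table
#'
#' Reads a tab-separated table with columns `species`, `genus`, `family`,
#' `order`, `status` assigning each species to a taxonomic hierarchy and a
#' biogeographic status class.
#'
#' @param path path to a TSV file with a header row.
#' @return a data frame of class `taxon_table` with the five columns as
#'   character vectors; per-status counts are available via [taxon_counts()].
#' @examples
#' taxa <- load_taxon_table(system.file("extdata", "example_taxa.tsv",
#'                                      package = "divtime"))
#' taxon_counts(taxa)
#' @export
load_taxon_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", strip.white = TRUE)
  taxon_table(df)
}

#' Validate a data frame as a taxon table
#'
#' @param df a data frame with columns `species`, `genus`, `family`,
#'   `order`, `status`.
#' @return the validated data frame, classed `taxon_table`.
#' @export
taxon_table <- function(df) {
  req <- c("species", "genus", "family", "order", "status")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, req]
  for (j in req) df[[j]] <- as.character(df[[j]])
  dup <- df$species[duplicated(df$species)]
  if (length(dup) > 0)
    stop("duplicate species: ", paste(unique(dup), collapse = ", "))
  bad <- which(!(df$status %in% STATUS_LEVELS))
  if (length(bad) > 0)
    stop(sprintf("unknown status %s in row %d (species %s)",
                 dQuote(df$status[bad[1]]), bad[1], df$species[bad[1]]))
  med <- df$status != "outgroup"
  empty <- med & (!nzchar(df$genus) | !nzchar(df$family) | !nzchar(df$order))
  if (any(empty))
    stop("empty genus/family/order for non-outgroup species: ",
         paste(df$species[empty], collapse = ", "))
  class(df) <- c("taxon_table", "data.frame")
  df
}

#' Species counts per status class
#' @param taxa a `taxon_table`.
#' @return a named integer vector over `STATUS_LEVELS`.
#' @export
taxon_counts <- function(taxa) {
  stopifnot(inherits(taxa, "taxon_table"))
  tab <- table(factor(taxa$status, levels = STATUS_LEVELS))
  setNames(as.integer(tab), STATUS_LEVELS)
}

#' Write a taxon table to TSV
#' @param taxa a `taxon_table`.
#' @param path output path.
#' @export
write_taxon_table <- function(taxa, path) {
  stopifnot(inherits(taxa, "taxon_table"))
  write.table(taxa, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# internal: tip labels carrying a given status, checked against the tree
.status_tips <- function(x, taxa, status) {
  labs <- taxa$species[taxa$status == status]
  intersect(x$phy$tip.label, labs)
}

# internal: resampling pool under a pool policy
.pool_tips <- function(x, taxa, pool = c("mediterranean_only", "all_tips")) {
  pool <- match.arg(pool)
  if (pool == "all_tips") return(x$phy$tip.label)
  out <- taxa$species[taxa$status == "outgroup"]
  setdiff(x$phy$tip.label, out)
}
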