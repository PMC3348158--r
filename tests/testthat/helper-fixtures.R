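# Shared fixtures: a 3-tip worked tree, a polytomy variant, and small
# builders for random trees and taxon tables.

T1_NWK <- "((A:10,B:10):30,C:40);"
POLY_NWK <- "((A:10,B:10,X:10):30,C:40);"

t1_tree <- function() parse_chronogram(T1_NWK)
poly_tree <- function() parse_chronogram(POLY_NWK)

t1_taxa <- function(status = c("native", "native", "native")) {
  taxon_table(data.frame(
    species = c("A", "B", "C"),
    genus = c("g1", "g1", "g2"),
    family = c("f1", "f1", "f1"),
    order = c("o1", "o1", "o1"),
    status = status,
    stringsAsFactors = FALSE))
}

random_chronogram <- function(n, seed, birth = 0.08, death = 0.03) {
  simulate_bd_chronogram(n_tips = n, birth = birth, death = death, seed = seed)
}

# tip labels of a random subset of a chronogram
random_tipset <- function(x, k, seed) {
  set.seed(seed)
  sample(x$phy$tip.label, k)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
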