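# brute-force Dice oracle: set overlap, independent of similarity_index()
dice_oracle <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  200 * length(intersect(A, B)) / (length(A) + length(B))
}

# random binary profile with at least one band
random_profile <- function(n, p = 0.5) {
  repeat {
    x <- rbinom(n, 1, p)
    if (sum(x) > 0) return(x)
  }
}

# minimal Clustal-format writer (header, two blank lines, one block)
write_clustal <- function(rows, path) {
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               sprintf("%-12s%s", names(rows), unname(rows))), path)
}

# did SI+UPGMA recover the generating tree? unrooted RF = 0 plus the
# outgroup attaching last in the rooted tree
recovered_topology <- function(dend, truth, outgroup = "PC") {
  t <- as_phylo(dend)
  if (ape::dist.topo(ape::unroot(t), ape::unroot(truth)) != 0) return(FALSE)
  last <- dend$merge[nrow(dend$merge), ]
  any(last < 0 & dend$labels[-last[last < 0]] == outgroup)
}
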