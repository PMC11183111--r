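# Shared fixtures, all built in code.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Spread of tip depths; 0 (within tolerance) means ultrametric.
tip_age_spread <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d))
}

# Independent brute-force null moments: enumerate subsets with utils::combn
# and score them with picante, which shares no code with the package engines.
brute_null_moments <- function(tree, metric, k) {
  tips <- tree$tip.label
  combs <- utils::combn(tips, k, simplify = FALSE)
  D <- stats::cophenetic(tree)
  vals <- vapply(combs, function(cc) {
    m <- matrix(1, 1, length(cc), dimnames = list("s", cc))
    switch(metric,
      PD = {
        # root-unforced PD: total spanning length via picante pd minus the
        # path from the subtree root to the tree root
        pr <- ape::keep.tip(tree, cc)
        sum(pr$edge.length)
      },
      MPD = picante::mpd(m, D[cc, cc, drop = FALSE]),
      MNTD = picante::mntd(m, D[cc, cc, drop = FALSE]))
  }, numeric(1))
  list(mean = mean(vals), sd = sqrt(mean((vals - mean(vals))^2)))
}
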