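# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Node ages in Myr, assuming the deepest tip sits at age 0. Element i is the
# age of node/tip i in ape's numbering.
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

# Genus token of a binomial tip label ("Genus_species" convention).
tip_genus <- function(labels) sub("_.*$", "", labels)

is_ultrametric_tree <- function(tree, tol = 1e-6) {
  n <- ape::Ntip(tree)
  if (n <= 1L) return(TRUE)
  depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
  diff(range(depth)) <= tol
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

assert_seed <- function(seed) {
  assert_scalar_number(seed, "seed")
  invisible(as.integer(seed))
}

# Deterministic substream seed, kept inside 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# Per-tree structures reused by the metric engines: patristic distances,
# tip x edge incidence, and edge lengths.
tree_precompute <- function(tree) {
  n <- ape::Ntip(tree)
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label, drop = FALSE]
  E <- nrow(tree$edge)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (t in seq_len(n)) desc[[t]] <- t
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    desc[[p]] <- c(desc[[p]], desc[[po$edge[i, 2L]]])
  }
  M <- matrix(0, n, E)
  for (e in seq_len(E)) M[desc[[tree$edge[e, 2L]]], e] <- 1
  list(n = n, tips = tree$tip.label, D = D, M = M,
       len = tree$edge.length, total_len = sum(tree$edge.length))
}

# Metric values for a batch of communities given as a B x k matrix of tip
# indices. Vectorised so the Monte-Carlo and enumeration engines stay fast.
metric_batch <- function(pre, ID, metric, include_root = FALSE) {
  if (is.vector(ID)) ID <- matrix(ID, nrow = 1L)
  B <- nrow(ID)
  k <- ncol(ID)
  if (metric == "PD") {
    Z <- matrix(0, B, pre$n)
    Z[cbind(rep(seq_len(B), k), as.vector(ID))] <- 1
    cnt <- Z %*% pre$M
    inc <- if (include_root) cnt > 0 else (cnt > 0 & cnt < k)
    as.vector(inc %*% pre$len)
  } else if (metric == "MPD") {
    if (k < 2L) stop("MPD requires communities of at least 2 species", call. = FALSE)
    tot <- numeric(B)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        tot <- tot + pre$D[cbind(ID[, i], ID[, j])]
      }
    }
    tot / (k * (k - 1) / 2)
  } else if (metric == "MNTD") {
    if (k < 2L) stop("MNTD requires communities of at least 2 species", call. = FALSE)
    mn <- matrix(Inf, B, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j) mn[, i] <- pmin(mn[, i], pre$D[cbind(ID[, i], ID[, j])])
      }
    }
    rowMeans(mn)
  } else {
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  }
}
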