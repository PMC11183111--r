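# Building a dated species-level phylogeny from a backbone: sister-genus
# grafting, genus-midpoint species binding, even-spacing age interpolation
# for undated nodes, pruning, and species age extraction.

# Age of the attachment point for a genus clade: midpoint of its stem
# branch. Returns list(node, attach_age, crown_age, stem_age).
genus_attachment <- function(tree, genus) {
  tips <- tree$tip.label[tip_genus(tree$tip.label) == genus]
  if (length(tips) == 0L)
    stop(sprintf("genus '%s' not found in tree", genus), call. = FALSE)
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, tips)
    clade_tips <- ape::extract.clade(tree, node)$tip.label
    if (length(clade_tips) > length(tips))
      warning(sprintf("genus '%s' is not monophyletic; using the MRCA of its %d tips",
                      genus, length(tips)), call. = FALSE)
  }
  if (node == n + 1L)
    stop(sprintf("genus '%s' spans the root; no stem branch to attach to", genus),
         call. = FALSE)
  parent <- tree$edge[tree$edge[, 2L] == node, 1L]
  stem_age <- ages[parent]
  crown_age <- ages[node]
  list(node = node, attach_age = (stem_age + crown_age) / 2,
       crown_age = crown_age, stem_age = stem_age)
}

# Attach a new tip at absolute age `age` on the stem branch above `node`,
# preserving ultrametricity (the new terminal branch has length `age`).
attach_tip_at_age <- function(tree, node, age, label) {
  crown_age <- node_ages(tree)[node]
  phytools::bind.tip(tree, label, edge.length = age,
                     where = node, position = age - crown_age)
}

#' Graft a missing genus onto a backbone tree
#'
#' Attaches a representative tip of a genus absent from the backbone as
#' sister to a designated genus already present: a new node is created at
#' the midpoint of the sister clade's stem branch and the representative
#' tip attaches there, so the tree stays ultrametric. For a non-monophyletic
#' sister genus the MRCA of its tips is used, with a warning.
#'
#' @param tree Ultrametric `phylo` with `Genus_species` tip labels.
#' @param missing Name of the genus to add (must be absent).
#' @param sister Name of the sister genus (must be present).
#' @param representative_species Tip label for the new representative;
#'   defaults to `<missing>_sp`.
#' @return The augmented ultrametric `phylo`.
#' @export
graft_missing_genus <- function(tree, missing, sister,
                                representative_species = paste0(missing, "_sp")) {
  genera <- tip_genus(tree$tip.label)
  if (missing %in% genera)
    stop(sprintf("genus '%s' is already present in the tree", missing), call. = FALSE)
  if (representative_species %in% tree$tip.label)
    stop(sprintf("tip '%s' already present", representative_species), call. = FALSE)
  at <- genus_attachment(tree, sister)
  attach_tip_at_age(tree, at$node, at$attach_age, representative_species)
}

#' Bind species to their genera at the genus midpoint
#'
#' Adds each species in `records` to the tree at the phylogenetic midpoint
#' of its genus: for a genus with two or more tips the attachment age is
#' `(stem age + crown age) / 2` on the genus stem branch; for a monotypic
#' genus it is half the stem-to-tip branch. Several species bound to one
#' genus form a pectinate series at the same age, kept strictly ordered by
#' subtracting a small epsilon (1e-8 Myr) from successive attachment ages.
#' Species already in the tree are skipped with a warning.
#'
#' @param tree Ultrametric `phylo`.
#' @param records Data frame with columns `species`, `genus` (and
#'   optionally `family`).
#' @param epsilon Age offset separating simultaneous attachments (Myr).
#' @return The augmented ultrametric `phylo`.
#' @export
bind_species_midpoint <- function(tree, records, epsilon = 1e-8) {
  if (!all(c("species", "genus") %in% names(records)))
    stop("`records` needs columns `species` and `genus`", call. = FALSE)
  bad <- records$genus != tip_genus(records$species)
  if (any(bad))
    stop("species binomials must start with their genus token: ",
         paste(records$species[bad], collapse = ", "), call. = FALSE)
  present <- records$species %in% tree$tip.label
  if (any(present)) {
    warning("already in tree, skipped: ",
            paste(records$species[present], collapse = ", "), call. = FALSE)
    records <- records[!present, , drop = FALSE]
  }
  for (g in unique(records$genus)) {
    new_sp <- records$species[records$genus == g]
    at <- genus_attachment(tree, g)          # errors if genus absent
    anchor_tips <- tree$tip.label[tip_genus(tree$tip.label) == g]
    for (i in seq_along(new_sp)) {
      age_i <- at$attach_age - (i - 1) * epsilon
      node <- if (length(anchor_tips) == 1L) {
        match(anchor_tips, tree$tip.label)
      } else {
        ape::getMRCA(tree, anchor_tips)
      }
      tree <- attach_tip_at_age(tree, node, age_i, new_sp[i])
    }
  }
  tree
}

#' Interpolate ages of undated nodes by even spacing
#'
#' Given a topology in which a subset of internal nodes carry age
#' constraints (by node label; the root must be constrained, tips are fixed
#' at age 0), assigns every undated node an age by spacing it evenly along
#' the path between its nearest dated ancestor and nearest dated
#' descendant: a chain of m undated nodes between ages a (ancestor) and d
#' (descendant) receives ages `a - i (a - d) / (m + 1)`. Branch lengths are
#' recomputed from the resulting ages. This reproduces the classic
#' branch-length-adjustment smoothing used when only some nodes of a
#' supertree are dated.
#'
#' @param tree A `phylo`; existing branch lengths are ignored. Node labels
#'   identify constrained nodes.
#' @param constraints Named numeric vector of ages (Myr); names are node
#'   labels (or `"root"` for the root).
#' @return Dated ultrametric `phylo` with branch lengths from the
#'   interpolated ages; node ages are stored in attribute `"ages"`.
#' @export
bladj_smooth <- function(tree, constraints) {
  n <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- n + 1L
  ids <- rep(NA_integer_, length(constraints))
  labs <- names(constraints)
  if (is.null(labs)) stop("`constraints` must be a named vector", call. = FALSE)
  node_labels <- tree$node.label
  for (i in seq_along(constraints)) {
    if (labs[i] == "root" && !("root" %in% node_labels)) {
      ids[i] <- root
    } else if (!is.null(node_labels) && labs[i] %in% node_labels) {
      ids[i] <- n + match(labs[i], node_labels)
    } else if (labs[i] %in% tree$tip.label) {
      ids[i] <- match(labs[i], tree$tip.label)
    } else {
      stop(sprintf("constraint label '%s' matches no node", labs[i]), call. = FALSE)
    }
  }
  age <- rep(NA_real_, n + nnode)
  age[seq_len(n)] <- 0
  age[ids] <- constraints
  if (is.na(age[root]))
    stop("the root must be age-constrained", call. = FALSE)
  parent_of <- integer(n + nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  dated0 <- !is.na(age)
  # consistency: every dated node younger than its nearest dated ancestor
  for (v in which(dated0)) {
    if (v == root) next
    p <- parent_of[v]
    while (!dated0[p]) p <- parent_of[p]
    if (age[v] >= age[p])
      stop(sprintf("constraint conflict: node %d (age %.4g) not younger than its dated ancestor (age %.4g)",
                   v, age[v], age[p]), call. = FALSE)
  }
  # chains: from each dated non-root vertex, walk up through undated nodes
  # to the nearest dated ancestor
  chains <- list()
  for (v in which(dated0)) {
    if (v == root) next
    path <- integer(0)
    p <- parent_of[v]
    while (!dated0[p]) {
      path <- c(p, path)           # ordered ancestor -> descendant
      p <- parent_of[p]
    }
    if (length(path) > 0)
      chains[[length(chains) + 1L]] <- list(anc = p, desc = v, mid = path)
  }
  if (length(chains) > 0) {
    ord <- order(-vapply(chains, function(ch) age[ch$desc], numeric(1)),
                 vapply(chains, function(ch) ch$desc, integer(1)))
    for (ch in chains[ord]) {
      vals <- c(age[ch$anc], age[ch$mid], age[ch$desc])
      # fill NA runs by even spacing between the flanking known ages
      i <- 2L
      while (i <= length(vals) - 1L) {
        if (is.na(vals[i])) {
          j <- i
          while (is.na(vals[j + 1L])) j <- j + 1L
          m <- j - i + 1L
          a <- vals[i - 1L]; d <- vals[j + 1L]
          vals[i:j] <- a - seq_len(m) * (a - d) / (m + 1L)
          i <- j + 1L
        } else i <- i + 1L
      }
      age[ch$mid] <- ifelse(is.na(age[ch$mid]), vals[seq_along(ch$mid) + 1L],
                            age[ch$mid])
    }
  }
  if (anyNA(age))
    stop("some nodes are unreachable from any dated descendant", call. = FALSE)
  len <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  if (any(len < -1e-9))
    stop("constraint conflict: negative branch length produced", call. = FALSE)
  tree$edge.length <- pmax(len, 0)
  attr(tree, "ages") <- age
  tree
}

#' Prune a tree to a species pool
#'
#' Restricts the tree to the given pool: the minimal rooted tree on the
#' pool's tips, with unary nodes collapsed (branch lengths summed) so node
#' ages are preserved.
#'
#' @param tree A `phylo`.
#' @param pool Character vector of species to keep.
#' @param drop_unknown If `TRUE`, pool members absent from the tree are
#'   dropped with a warning instead of raising an error.
#' @return The pruned `phylo`.
#' @export
prune_to_pool <- function(tree, pool, drop_unknown = FALSE) {
  unknown <- setdiff(pool, tree$tip.label)
  if (length(unknown) > 0) {
    if (!drop_unknown)
      stop("species not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
    warning(sprintf("dropping %d pool species absent from the tree", length(unknown)),
            call. = FALSE)
  }
  keep <- intersect(pool, tree$tip.label)
  if (length(keep) == 0L)
    stop("pool shares no species with the tree", call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    depth <- ape::node.depth.edgelength(tree)[match(keep, tree$tip.label)]
    return(ape::read.tree(text = sprintf("(%s:%.12g);", keep, depth)))
  }
  ape::keep.tip(tree, keep)
}

#' Species ages from an ultrametric tree
#'
#' The age of a species is the age of its parent node — equivalently its
#' terminal branch length — i.e. the time since it diverged from its
#' closest relative present in the tree. Note these are ages relative to
#' the sampled tree, not absolute clade ages.
#'
#' @param tree Ultrametric `phylo`.
#' @param tol Ultrametricity tolerance (Myr).
#' @return Named numeric vector of ages (Myr), one per tip.
#' @export
species_ages <- function(tree, tol = 1e-6) {
  if (!is_ultrametric_tree(tree, tol))
    stop("`tree` must be ultrametric", call. = FALSE)
  n <- ape::Ntip(tree)
  ages <- numeric(n)
  tip_edges <- match(seq_len(n), tree$edge[, 2L])
  ages <- tree$edge.length[tip_edges]
  names(ages) <- tree$tip.label
  ages
}
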