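# Seeded generators for trees, traits, assemblages, covariates and
# spatially autocorrelated responses. These emulate the statistical
# structure of a multi-landform mountain-flora survey so that every
# downstream stage can be exercised without external data.

#' Simulate an ultrametric Yule tree
#'
#' Draws a pure-birth (Yule) tree conditioned on the number of extant tips.
#' The returned tree is rooted, binary and ultrametric, with tip labels
#' `t1 ... tn`, and stands in for a dated megaphylogeny in tests and
#' simulation studies.
#'
#' @param n_tips Number of extant tips (>= 1).
#' @param birth_rate Speciation rate (per lineage per Myr, > 0).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return An ultrametric `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  assert_scalar_number(n_tips, "n_tips")
  if (n_tips < 1) stop("`n_tips` must be >= 1", call. = FALSE)
  assert_scalar_number(birth_rate, "birth_rate")
  if (birth_rate <= 0) stop("`birth_rate` must be positive", call. = FALSE)
  assert_seed(seed)
  set.seed(seed)
  if (n_tips == 1) {
    return(ape::read.tree(text = "(t1:0);"))
  }
  ape::rphylo(n = n_tips, birth = birth_rate, death = 0)
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Evolves a continuous trait along the tree by independent Gaussian
#' increments with variance `sigma2` per unit branch length, giving the
#' phylogenetic signal that makes environmental filtering produce
#' phylogenetic clustering in simulated assemblages.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian rate (variance per Myr, >= 0).
#' @param root_state Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root_state = 0, seed = 1L) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  assert_scalar_number(sigma2, "sigma2")
  if (sigma2 < 0) stop("`sigma2` must be nonnegative", call. = FALSE)
  assert_seed(seed)
  set.seed(seed)
  if (ape::Ntip(tree) == 1L) {
    tr <- stats::rnorm(1, root_state, sqrt(sigma2 * sum(tree$edge.length)))
    names(tr) <- tree$tip.label
    return(tr)
  }
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                  root.value = root_state, ancestor = FALSE)
}

#' Configuration for assemblage simulation
#'
#' Bundles the design of a synthetic multi-landform survey: how many
#' species and sites, the assembly mode, the filter width, and the
#' per-site richness range. Defaults mirror a 140-site, five-landform
#' survey at a desk-scale species pool.
#'
#' @param n_species Size of the species pool (>= 2).
#' @param n_sites_per_landform Sites per landform category.
#' @param n_landforms Number of landform categories (default 5; labels
#'   karst, karst-granitic, granitic, Danxia, desert).
#' @param mode Assembly mode: `"neutral"`, `"clustered"` (environmental
#'   filtering on a trait) or `"overdispersed"` (greedy maximisation of
#'   pairwise distance).
#' @param filter_strength Inverse squared filter width tau (>= 0); larger
#'   means stronger filtering in clustered mode.
#' @param richness_range Length-2 integer vector; per-site richness is
#'   drawn uniformly from this range.
#' @param seed Integer seed.
#' @return An object of class `assembly_config`.
#' @export
assembly_config <- function(n_species = 200L,
                            n_sites_per_landform = 28L,
                            n_landforms = 5L,
                            mode = c("neutral", "clustered", "overdispersed"),
                            filter_strength = 10,
                            richness_range = c(10L, 50L),
                            seed = 1L) {
  mode <- match.arg(mode)
  assert_scalar_number(n_species, "n_species")
  if (n_species < 2) stop("`n_species` must be >= 2", call. = FALSE)
  assert_scalar_number(filter_strength, "filter_strength")
  if (filter_strength < 0) stop("`filter_strength` must be nonnegative", call. = FALSE)
  if (length(richness_range) != 2L || any(richness_range < 1) ||
      richness_range[1] > richness_range[2])
    stop("`richness_range` must be an increasing pair of positive counts", call. = FALSE)
  if (richness_range[2] > n_species)
    stop("`richness_range` cannot exceed `n_species`", call. = FALSE)
  labels <- c("karst", "karst-granitic", "granitic", "Danxia", "desert")
  if (n_landforms > length(labels))
    labels <- c(labels, paste0("landform", seq_len(n_landforms - length(labels))))
  structure(list(
    n_species = as.integer(n_species),
    n_sites_per_landform = as.integer(n_sites_per_landform),
    n_landforms = as.integer(n_landforms),
    landform_labels = labels[seq_len(n_landforms)],
    mode = mode,
    filter_strength = filter_strength,
    richness_range = as.integer(richness_range),
    seed = assert_seed(seed)
  ), class = "assembly_config")
}

# Deterministic greedy maximin ordering of the species pool: start from the
# most distant pair, then repeatedly add the species with the largest
# minimum distance to the chosen set. Ties break lexicographically.
greedy_maximin_order <- function(D) {
  labs <- rownames(D)
  n <- nrow(D)
  Dm <- D
  diag(Dm) <- -Inf
  best <- which(Dm == max(Dm), arr.ind = TRUE)
  pair_labels <- t(apply(best, 1L, function(ij) sort(labs[ij])))
  first <- order(pair_labels[, 1L], pair_labels[, 2L])[1L]
  chosen <- match(pair_labels[first, ], labs)
  remaining <- setdiff(seq_len(n), chosen)
  mindist <- pmin(D[, chosen[1L]], D[, chosen[2L]])
  while (length(remaining) > 0L) {
    cand <- remaining[mindist[remaining] == max(mindist[remaining])]
    nxt <- cand[order(labs[cand])][1L]
    chosen <- c(chosen, nxt)
    remaining <- setdiff(remaining, nxt)
    mindist <- pmin(mindist, D[, nxt])
  }
  labs[chosen]
}

#' Simulate landform-structured assemblages
#'
#' Builds a site-by-species presence/absence matrix under one of three
#' assembly modes. In `neutral` mode each site is a uniform draw from the
#' pool; in `clustered` mode each landform has an optimum trait value (an
#' equally spaced quantile of the trait distribution) and species are drawn
#' without replacement with weight proportional to
#' `exp(-filter_strength * (trait - optimum)^2)`; in `overdispersed` mode
#' sites take the first k species of a deterministic greedy maximin
#' ordering of the pool by patristic distance.
#'
#' @param tree Ultrametric `phylo` giving the species pool (its tips).
#' @param trait Named tip trait vector (required for clustered mode).
#' @param config An [assembly_config()] object.
#' @return List with `matrix` (sites x species, 0/1) and `predictors`
#'   (data frame of `site_id`, `landform`).
#' @export
simulate_assemblages <- function(tree, trait = NULL, config = assembly_config()) {
  if (!inherits(config, "assembly_config"))
    stop("`config` must be an assembly_config object", call. = FALSE)
  tips <- tree$tip.label
  n <- length(tips)
  if (config$richness_range[2] > n)
    stop("`richness_range` exceeds the number of tree tips", call. = FALSE)
  if (config$mode == "clustered") {
    if (is.null(trait) || !all(tips %in% names(trait)))
      stop("clustered mode needs a trait value for every tip", call. = FALSE)
    trait <- trait[tips]
  }
  set.seed(config$seed)
  n_sites <- config$n_landforms * config$n_sites_per_landform
  landform <- rep(config$landform_labels, each = config$n_sites_per_landform)
  richness <- sample(seq(config$richness_range[1], config$richness_range[2]),
                     n_sites, replace = TRUE)
  mat <- matrix(0L, n_sites, n, dimnames = list(paste0("site_", seq_len(n_sites)), tips))
  if (config$mode == "clustered") {
    probs <- (seq_len(config$n_landforms) - 0.5) / config$n_landforms
    optima <- stats::quantile(trait, probs = probs, names = FALSE)
    names(optima) <- config$landform_labels
  }
  if (config$mode == "overdispersed") {
    ord <- greedy_maximin_order(ape::cophenetic.phylo(tree)[tips, tips])
  }
  for (s in seq_len(n_sites)) {
    k <- richness[s]
    sel <- switch(config$mode,
      neutral = sample(tips, k),
      clustered = {
        w <- exp(-config$filter_strength * (trait - optima[[landform[s]]])^2)
        if (sum(w) <= 0) w <- rep(1, n)
        sample(tips, k, prob = w)
      },
      overdispersed = ord[seq_len(k)]
    )
    mat[s, sel] <- 1L
  }
  list(matrix = mat,
       predictors = data.frame(site_id = rownames(mat), landform = landform,
                               stringsAsFactors = FALSE))
}

#' Simulate spatially autocorrelated covariates
#'
#' Generates columns `x = (I - lambda_x W)^{-1} eps` with `eps` i.i.d.
#' standard normal, i.e. covariates with simultaneous-autoregressive
#' spatial structure over the supplied weights.
#'
#' @param weights A [knn_weights()] object (or a row-standardized weight
#'   matrix).
#' @param lambda_x Autoregressive parameter, |lambda_x| < 1.
#' @param n_vars Number of columns to generate.
#' @param seed Integer seed.
#' @return Matrix with `n_vars` columns (`x1`, `x2`, ...).
#' @export
simulate_predictors <- function(weights, lambda_x = 0, n_vars = 1L, seed = 1L) {
  W <- weights_matrix(weights)
  assert_scalar_number(lambda_x, "lambda_x")
  if (abs(lambda_x) >= 1) stop("|lambda_x| must be < 1", call. = FALSE)
  assert_seed(seed)
  set.seed(seed)
  n <- nrow(W)
  A <- diag(n) - lambda_x * W
  eps <- matrix(stats::rnorm(n * n_vars), n, n_vars)
  x <- tryCatch(solve(A, eps),
                error = function(e) stop("(I - lambda_x W) is singular: ",
                                         conditionMessage(e), call. = FALSE))
  colnames(x) <- paste0("x", seq_len(n_vars))
  x
}

#' Simulate a spatial-error-model response
#'
#' Draws `y = X beta + u` with `u = (I - lambda_err W)^{-1} eps`,
#' `eps ~ N(0, sigma^2 I)` — the generating process of the spatial error
#' model, used for parameter-recovery experiments.
#'
#' @param X Design matrix (n x p).
#' @param beta Coefficient vector (length p).
#' @param weights A [knn_weights()] object or weight matrix.
#' @param lambda_err Spatial error parameter, |lambda_err| < 1.
#' @param sigma Innovation standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric response vector of length n.
#' @export
simulate_sem_response <- function(X, beta, weights, lambda_err = 0,
                                  sigma = 1, seed = 1L) {
  X <- as.matrix(X)
  W <- weights_matrix(weights)
  if (nrow(X) != nrow(W))
    stop("`X` and `weights` have different numbers of sites", call. = FALSE)
  if (length(beta) != ncol(X))
    stop("`beta` length must match ncol(X)", call. = FALSE)
  assert_scalar_number(lambda_err, "lambda_err")
  if (abs(lambda_err) >= 1) stop("|lambda_err| must be < 1", call. = FALSE)
  assert_scalar_number(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  assert_seed(seed)
  set.seed(seed)
  n <- nrow(X)
  eps <- stats::rnorm(n, sd = sigma)
  u <- solve(diag(n) - lambda_err * W, eps)
  as.vector(X %*% beta + u)
}

#' Uniform site coordinates on a rectangle
#'
#' Convenience generator for site longitude/latitude used only to build
#' spatial weights in simulations.
#'
#' @param n Number of sites.
#' @param lon_range,lat_range Coordinate ranges in degrees.
#' @param seed Integer seed.
#' @return Data frame with `lon`, `lat`.
#' @export
simulate_coords <- function(n, lon_range = c(80, 120), lat_range = c(20, 45),
                            seed = 1L) {
  assert_seed(seed)
  set.seed(seed)
  data.frame(lon = stats::runif(n, lon_range[1], lon_range[2]),
             lat = stats::runif(n, lat_range[1], lat_range[2]))
}
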