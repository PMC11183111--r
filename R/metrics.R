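# Community phylogenetic metrics: species richness, Faith's PD, MPD, MNTD
# and their standardized effect sizes (PDI, NRI, NTI) under the uniform
# null model, in which every k-species subset of the tree's tips is
# equiprobable. Null moments come from exhaustive enumeration, seeded
# Monte-Carlo sampling, or (for the means of PD and MPD) closed forms.

resolve_community <- function(tree, community) {
  if (length(community) == 0L)
    stop("`community` must be nonempty", call. = FALSE)
  idx <- match(community, tree$tip.label)
  if (anyNA(idx))
    stop("species not in tree: ",
         paste(community[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the community's
#' tips. By default the subtree is not forced to include the root, so a
#' singleton community has PD 0; set `include_root = TRUE` to add the path
#' to the root.
#'
#' @param tree A `phylo` with branch lengths.
#' @param community Character vector of species (tip labels).
#' @param include_root Force the spanning subtree to include the root?
#' @return PD in branch-length units (Myr for a dated tree).
#' @export
faith_pd <- function(tree, community, include_root = FALSE) {
  idx <- resolve_community(tree, community)
  k <- length(idx)
  if (k == 1L && !include_root) return(0)
  cnt <- integer(ape::Ntip(tree) + tree$Nnode)
  cnt[idx] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge)))
    cnt[po$edge[i, 1L]] <- cnt[po$edge[i, 1L]] + cnt[po$edge[i, 2L]]
  child_cnt <- cnt[tree$edge[, 2L]]
  inc <- if (include_root) child_cnt > 0L else (child_cnt > 0L & child_cnt < k)
  sum(tree$edge.length[inc])
}

#' Mean pairwise phylogenetic distance
#'
#' Mean patristic distance over all unordered pairs of community members;
#' reflects tree-wide (deep-node) phylogenetic structure.
#'
#' @inheritParams faith_pd
#' @return MPD (Myr).
#' @export
mpd <- function(tree, community) {
  idx <- resolve_community(tree, community)
  if (length(idx) < 2L)
    stop("MPD needs at least 2 species", call. = FALSE)
  D <- ape::cophenetic.phylo(tree)[community, community]
  mean(D[lower.tri(D)])
}

#' Mean nearest taxon distance
#'
#' Mean, over community members, of the patristic distance to the nearest
#' other member; reflects structure near the tips.
#'
#' @inheritParams faith_pd
#' @return MNTD (Myr).
#' @export
mntd <- function(tree, community) {
  idx <- resolve_community(tree, community)
  if (length(idx) < 2L)
    stop("MNTD needs at least 2 species", call. = FALSE)
  D <- ape::cophenetic.phylo(tree)[community, community]
  diag(D) <- Inf
  mean(apply(D, 1L, min))
}

mc_draws <- function(n, k, n_rand) {
  t(vapply(seq_len(n_rand), function(i) sample.int(n, k), integer(k)))
}

#' Null moments of PD, MPD or MNTD under the uniform null
#'
#' Mean and standard deviation of a metric over random k-species subsets of
#' the tree's tips, all subsets equiprobable. Engines: `"enumerate"` walks
#' every subset (exact; population sd), `"montecarlo"` draws `n_rand`
#' seeded subsets (sample sd), `"analytic"` computes the exact mean in
#' closed form (PD via per-edge inclusion probabilities, MPD as the mean of
#' all pairwise distances, which is independent of k) and delegates the sd
#' to Monte Carlo. `"auto"` enumerates when `choose(n, k) <= cap` and
#' otherwise uses Monte Carlo.
#'
#' @param tree A `phylo` with branch lengths.
#' @param metric One of `"PD"`, `"MPD"`, `"MNTD"`.
#' @param k Community size (>= 2; >= 1 for PD).
#' @param engine `"auto"`, `"enumerate"`, `"montecarlo"` or `"analytic"`.
#' @param n_rand Monte-Carlo draws.
#' @param seed Integer seed for Monte Carlo.
#' @param cap Largest `choose(n, k)` the enumeration engine accepts.
#' @param include_root Passed to the PD computation.
#' @param pre Optional precomputed tree structures (internal reuse).
#' @return Object of class `null_moments`: list with `metric`, `k`,
#'   `mean`, `sd`, `engine`, `n_rand`, `seed`.
#' @export
null_moments <- function(tree, metric = c("PD", "MPD", "MNTD"), k,
                         engine = c("auto", "enumerate", "montecarlo", "analytic"),
                         n_rand = 999L, seed = 1L, cap = 1e5,
                         include_root = FALSE, pre = NULL) {
  metric <- match.arg(metric)
  engine <- match.arg(engine)
  if (is.null(pre)) pre <- tree_precompute(tree)
  n <- pre$n
  k <- as.integer(k)
  kmin <- if (metric == "PD") 1L else 2L
  if (k < kmin || k > n)
    stop(sprintf("k must be in [%d, %d] for %s", kmin, n, metric), call. = FALSE)
  out <- list(metric = metric, k = k, engine = engine,
              n_rand = NA_integer_, seed = NA_integer_)
  if (k == n) {
    ID <- matrix(seq_len(n), nrow = 1L)
    out$mean <- metric_batch(pre, ID, metric, include_root)
    out$sd <- 0
    return(structure(out, class = "null_moments"))
  }
  ncomb <- choose(n, k)
  if (engine == "auto")
    engine <- if (ncomb <= cap) "enumerate" else "montecarlo"
  out$engine <- engine
  if (engine == "enumerate") {
    if (ncomb > cap)
      stop(sprintf("choose(%d, %d) = %.3g exceeds the enumeration cap (%g)",
                   n, k, ncomb, cap), call. = FALSE)
    ID <- t(utils::combn(n, k))
    vals <- numeric(nrow(ID))
    chunk <- 5000L
    for (start in seq(1L, nrow(ID), by = chunk)) {
      rows <- start:min(start + chunk - 1L, nrow(ID))
      vals[rows] <- metric_batch(pre, ID[rows, , drop = FALSE], metric, include_root)
    }
    out$mean <- mean(vals)
    out$sd <- sqrt(mean((vals - out$mean)^2))   # population sd: full distribution
    return(structure(out, class = "null_moments"))
  }
  if (engine == "analytic") {
    if (metric == "MNTD")
      stop("no closed form for the MNTD null mean; use enumerate or montecarlo",
           call. = FALSE)
    mean_an <- if (metric == "PD") {
      m <- colSums(pre$M)
      p_absent <- exp(lchoose(n - m, k) - lchoose(n, k))
      p_inside <- if (include_root) 0 else exp(lchoose(m, k) - lchoose(n, k))
      sum(pre$len * (1 - p_absent - p_inside))
    } else {
      mean(pre$D[lower.tri(pre$D)])
    }
    mc <- null_moments(tree, metric, k, engine = "montecarlo", n_rand = n_rand,
                       seed = seed, include_root = include_root, pre = pre)
    out$mean <- mean_an
    out$sd <- mc$sd
    out$n_rand <- mc$n_rand
    out$seed <- mc$seed
    return(structure(out, class = "null_moments"))
  }
  # montecarlo
  assert_seed(seed)
  set.seed(seed)
  ID <- mc_draws(n, k, n_rand)
  vals <- metric_batch(pre, ID, metric, include_root)
  out$mean <- mean(vals)
  out$sd <- stats::sd(vals)                     # sample sd: estimated distribution
  out$n_rand <- as.integer(n_rand)
  out$seed <- as.integer(seed)
  structure(out, class = "null_moments")
}

#' @export
print.null_moments <- function(x, ...) {
  cat(sprintf("Uniform-null moments of %s at k = %d (%s engine)\n",
              x$metric, x$k, x$engine))
  cat(sprintf("  mean = %.6g, sd = %.6g\n", x$mean, x$sd))
  invisible(x)
}

#' Standardized effect sizes of PD, MPD and MNTD for a site matrix
#'
#' For every site computes SR, PD, MPD, MNTD and the standardized effect
#' sizes PDI = (PD - mean_null) / sd_null, NRI = -(MPD - mean_null) /
#' sd_null and NTI = -(MNTD - mean_null) / sd_null under the uniform null,
#' with null moments cached per distinct richness. Positive NRI/NTI means
#' phylogenetic clustering, negative means overdispersion. The species
#' pool is the set of the tree's tips, so prune the tree to the union of
#' matrix species first if that is the intended pool. SES values are `NA`
#' when the null sd is 0 (e.g. a site containing the whole pool) or when
#' SR < 2 (MPD/MNTD undefined).
#'
#' @param tree A `phylo`; its tips define the null-model pool.
#' @param comm Sites-by-species 0/1 matrix with dimnames.
#' @param engine,n_rand,seed,cap,include_root See [null_moments()]. Per-k
#'   Monte-Carlo seeds are derived deterministically from `seed`.
#' @return Data frame with one row per site: `site`, `SR`, `PD`, `MPD`,
#'   `MNTD`, `PDI`, `NRI`, `NTI`. Attribute `"engine_info"` records the
#'   engine, `n_rand` and seed used.
#' @export
ses_metrics <- function(tree, comm, engine = "auto", n_rand = 999L,
                        seed = 1L, cap = 1e5, include_root = FALSE) {
  comm <- as.matrix(comm)
  if (nrow(comm) == 0L || is.null(colnames(comm)))
    stop("`comm` must be a nonempty matrix with species column names", call. = FALSE)
  if (!all(comm %in% c(0, 1)))
    stop("`comm` entries must be 0/1", call. = FALSE)
  missing_sp <- setdiff(colnames(comm), tree$tip.label)
  if (length(missing_sp) > 0)
    stop("matrix species not in tree: ",
         paste(utils::head(missing_sp, 5), collapse = ", "), call. = FALSE)
  pre <- tree_precompute(tree)
  sr <- rowSums(comm)
  if (any(sr < 1)) stop("every site must contain at least one species", call. = FALSE)
  ks <- sort(unique(sr))
  moments <- list()
  for (k in ks) {
    for (met in c("PD", "MPD", "MNTD")) {
      if (met != "PD" && k < 2) next
      met_i <- match(met, c("PD", "MPD", "MNTD"))
      eng <- if (met == "MNTD" && engine == "analytic") "montecarlo" else engine
      moments[[paste(met, k)]] <- null_moments(
        tree, met, k, engine = eng, n_rand = n_rand,
        seed = substream_seed(seed, 1000003 * met_i + 131 * k),
        cap = cap, include_root = include_root, pre = pre)
    }
  }
  res <- data.frame(site = rownames(comm), SR = as.integer(sr),
                    PD = NA_real_, MPD = NA_real_, MNTD = NA_real_,
                    PDI = NA_real_, NRI = NA_real_, NTI = NA_real_,
                    stringsAsFactors = FALSE)
  ses <- function(obs, mom, flip) {
    if (is.null(mom) || !is.finite(mom$sd) || mom$sd <= 0) return(NA_real_)
    z <- (obs - mom$mean) / mom$sd
    if (flip) -z else z
  }
  for (s in seq_len(nrow(comm))) {
    idx <- which(comm[s, ] == 1)
    k <- length(idx)
    res$PD[s] <- metric_batch(pre, matrix(idx, 1L), "PD", include_root)
    res$PDI[s] <- ses(res$PD[s], moments[[paste("PD", k)]], flip = FALSE)
    if (k >= 2) {
      res$MPD[s] <- metric_batch(pre, matrix(idx, 1L), "MPD")
      res$MNTD[s] <- metric_batch(pre, matrix(idx, 1L), "MNTD")
      res$NRI[s] <- ses(res$MPD[s], moments[[paste("MPD", k)]], flip = TRUE)
      res$NTI[s] <- ses(res$MNTD[s], moments[[paste("MNTD", k)]], flip = TRUE)
    }
  }
  attr(res, "engine_info") <- list(engine = engine, n_rand = n_rand,
                                   seed = seed, cap = cap,
                                   include_root = include_root)
  res
}

#' Per-flora metrics table
#'
#' Convenience wrapper combining [ses_metrics()] with the species
#' age-structure statistics of [mdt_stats()]: one row per site with SR,
#' PD, PDI, NRI, NTI, MDT, MDT_oldest and MDT_youngest.
#'
#' @inheritParams ses_metrics
#' @param fraction Age-quartile fraction passed to [mdt_stats()].
#' @return Data frame, one row per site.
#' @export
flora_metrics <- function(tree, comm, engine = "auto", n_rand = 999L,
                          seed = 1L, cap = 1e5, include_root = FALSE,
                          fraction = 0.25) {
  res <- ses_metrics(tree, comm, engine = engine, n_rand = n_rand,
                     seed = seed, cap = cap, include_root = include_root)
  ages <- species_ages(tree)
  comm <- as.matrix(comm)
  mdt <- t(vapply(seq_len(nrow(comm)), function(s) {
    unlist(mdt_stats(ages[colnames(comm)[comm[s, ] == 1]], fraction = fraction))
  }, numeric(3)))
  res$MDT <- mdt[, "MDT"]
  res$MDT_oldest <- mdt[, "MDT_oldest"]
  res$MDT_youngest <- mdt[, "MDT_youngest"]
  res
}
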