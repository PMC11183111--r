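# Species age structure of a flora: mean divergence time over all species
# and over the oldest / youngest age quartiles, plus the pairwise
# between-landform comparisons.

#' Mean divergence time and age-quartile means
#'
#' `MDT` is the arithmetic mean of the species ages; `MDT_oldest` and
#' `MDT_youngest` are the means of the oldest and youngest
#' `ceiling(fraction * n)` ages (at least one species each), so for
#' `fraction = 0.25` they are the age-quartile means.
#'
#' @param ages Numeric vector of species ages (Myr, all >= 0).
#' @param fraction Quartile fraction in (0, 0.5].
#' @return List with `MDT`, `MDT_oldest`, `MDT_youngest` (Myr).
#' @export
mdt_stats <- function(ages, fraction = 0.25) {
  if (length(ages) == 0L) stop("`ages` must be nonempty", call. = FALSE)
  if (any(!is.finite(ages)) || any(ages < 0))
    stop("`ages` must be finite and nonnegative", call. = FALSE)
  if (fraction <= 0 || fraction > 0.5)
    stop("`fraction` must be in (0, 0.5]", call. = FALSE)
  n <- length(ages)
  q <- max(1L, ceiling(fraction * n))
  srt <- sort(ages)
  list(MDT = mean(ages),
       MDT_oldest = mean(srt[(n - q + 1L):n]),
       MDT_youngest = mean(srt[seq_len(q)]))
}

star_code <- function(p) {
  ifelse(p < 1e-5, "****",
  ifelse(p < 1e-4, "***",
  ifelse(p < 1e-3, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

#' Pairwise two-sample t tests between landform groups
#'
#' For every unordered pair of groups runs a two-sided, independent-samples
#' t test on the metric (pooled variance by default, Welch optionally) and
#' assigns significance stars: `****` p < 0.00001, `***` p < 0.0001,
#' `**` p < 0.001, `*` p < 0.05, `ns` otherwise. Groups with fewer than 2
#' members are skipped with a warning.
#'
#' @param values Numeric metric vector (one element per site).
#' @param groups Group labels (landforms), same length as `values`.
#' @param var_equal Pooled-variance t (default) or Welch if `FALSE`.
#' @return Data frame with columns `group1`, `group2`, `n1`, `n2`, `t`,
#'   `df`, `p`, `stars`.
#' @export
pairwise_group_tests <- function(values, groups, var_equal = TRUE) {
  if (length(values) != length(groups))
    stop("`values` and `groups` must have the same length", call. = FALSE)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small) > 0)
    warning("groups with < 2 sites skipped: ", paste(small, collapse = ", "),
            call. = FALSE)
  gl <- names(tab)[tab >= 2]
  if (length(gl) < 2)
    stop("need at least 2 groups with at least 2 sites each", call. = FALSE)
  pairs <- utils::combn(gl, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- values[groups == g1]; y <- values[groups == g2]
    tt <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stars = star_code(tt$p.value),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
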