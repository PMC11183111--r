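# Readers and writers for the pipeline's plain-text formats: Newick trees,
# site-by-species CSV matrices, checklists and predictor tables, plus
# metadata sidecars that make every output reproducible.

#' Read a Newick tree
#'
#' Parses a Newick file (or literal string) with branch lengths, with a
#' parenthesis-balance check that reports the character offset of the
#' first imbalance.
#'
#' @param path Path to a Newick file, or a Newick string containing `;`.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  text <- if (grepl(";", path, fixed = TRUE)) path
          else paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("Newick parse error: unmatched ')' at character %d", i),
           call. = FALSE)
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: no tree found", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("Newick tree has no branch lengths", call. = FALSE)
  tree
}

#' Write a Newick tree
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a site-by-species presence/absence matrix
#'
#' Reads a CSV with a header row and row names, validates that every cell
#' is 0 or 1 and that site and species names are unique, and normalises
#' the result to sites-in-rows.
#'
#' @param path CSV path.
#' @param sites_in_rows Orientation of the file: `TRUE` (default) if rows
#'   are sites, `FALSE` if rows are species.
#' @param tree Optional `phylo`; species names are validated against its
#'   tips.
#' @return Integer matrix, sites in rows.
#' @export
read_matrix <- function(path, sites_in_rows = TRUE, tree = NULL) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-binary cell at row '%s', column '%s': %s",
                 rownames(m)[rc[1]], colnames(m)[rc[2]], m[bad[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate site or species names in matrix", call. = FALSE)
  storage.mode(m) <- "integer"
  if (!sites_in_rows) m <- t(m)
  if (!is.null(tree)) {
    missing_sp <- setdiff(colnames(m), tree$tip.label)
    if (length(missing_sp) > 0)
      stop("matrix species not in tree: ",
           paste(utils::head(missing_sp, 5), collapse = ", "), call. = FALSE)
  }
  m
}

#' Write a site-by-species matrix
#'
#' @param m Sites-by-species matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path)
  invisible(path)
}

# Write a CSV plus a YAML sidecar recording how it was produced.
write_with_sidecar <- function(df, path, meta = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  meta$file <- basename(path)
  meta$md5 <- unname(tools::md5sum(path))
  meta$package_version <- as.character(utils::packageVersion("floralith"))
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}
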