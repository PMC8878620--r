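# Newick serialization. ape's write.tree substitutes dashes for label
# metacharacters instead of quoting, so labels are quoted here per the Newick
# convention (single quotes, internal quotes doubled) and unquoted on read.

needs_quote <- function(lab) grepl("[](),:;'[ \t]", lab)

newick_quote <- function(lab) {
  ifelse(needs_quote(lab),
         paste0("'", gsub("'", "''", lab, fixed = TRUE), "'"),
         lab)
}

newick_unquote <- function(lab) {
  q <- grepl("^'.*'$", lab)
  lab[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[q]), fixed = TRUE)
  lab
}

phylo_to_newick <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  has_len <- !is.null(tree$edge.length)
  render <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- newick_quote(tree$tip.label[node])
    } else {
      e <- kids[[as.character(node)]]
      s <- paste0("(",
                  paste(vapply(e, function(i) render(tree$edge[i, 2L], i), ""),
                        collapse = ","),
                  ")")
      if (!is.null(tree$node.label)) {
        nl <- tree$node.label[node - ntip]
        if (!is.na(nl) && nzchar(nl)) s <- paste0(s, newick_quote(nl))
      }
    }
    if (has_len && !is.na(edge_idx)) {
      s <- paste0(s, ":", format(tree$edge.length[edge_idx], digits = 12))
    }
    s
  }
  root <- ntip + 1L
  paste0(render(root, NA_integer_), ";")
}

#' Write a tree to a Newick file
#'
#' Serializes an [ape::phylo] tree (as produced by [neighbor_joining()] or
#' [upgma()]) with branch lengths. Leaf labels containing Newick
#' metacharacters (commas, parentheses, colons, spaces, ...) are single-quoted
#' per the Newick convention.
#'
#' @param tree A `phylo` object with unique, non-empty tip labels.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label)) {
    stop("every leaf must carry a label")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths; clamp before writing")
  }
  writeLines(phylo_to_newick(tree), path)
  invisible(path)
}

#' Read a Newick tree file
#'
#' Quoted labels are unquoted, inverting [write_newick()].
#'
#' @param path Newick file path.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr$tip.label <- newick_unquote(tr$tip.label)
  tr
}

# Parse an in-memory Newick string (used by the tree builders).
parse_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  tr$tip.label <- newick_unquote(tr$tip.label)
  tr
}
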