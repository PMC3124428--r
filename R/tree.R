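#' Read an ultrametric tree
#'
#' Reads a rooted tree from a Newick file or a NEXUS TREES block (translate
#' tables are resolved; if the file holds several trees the first is used with
#' a warning) and validates ultrametricity: every tip's root-to-tip path
#' length must match the tree depth within a relative tolerance. Chronograms
#' exported by rate-smoothing software carry rounding noise, hence the
#' tolerance is configurable. Unrooted trees with a basal trifurcation are
#' accepted and treated as rooted at that node.
#'
#' @param path path to a Newick or NEXUS tree file.
#' @param ultra_tol maximum allowed relative deviation of any tip depth from
#'   the tree depth (default `1e-4`).
#' @return an [ape::phylo] tree with a `depth` attribute (root-to-tip time).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,(C:1.5,D:1.5):0.5);", tf)
#' tr <- read_tree(tf)
#' attr(tr, "depth")
#' @export
read_tree <- function(path, ultra_tol = 1e-4) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 5, warn = FALSE)
  first <- first[nzchar(trimws(first))][1]
  is_nexus <- !is.na(first) && grepl("^#nexus", trimws(first), ignore.case = TRUE)
  tr <- tryCatch(
    if (is_nexus) ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop(sprintf("format error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) > 1)
      warning(sprintf("%s contains %d trees; using the first", path, length(tr)),
              call. = FALSE)
    tr <- tr[[1]]
  }
  validate_tree(tr, ultra_tol)
}

#' Validate a tree as an ultrametric chronogram
#'
#' @param tr an [ape::phylo] tree with branch lengths.
#' @param ultra_tol relative ultrametricity tolerance.
#' @return the tree with a `depth` attribute.
#' @export
validate_tree <- function(tr, ultra_tol = 1e-4) {
  stopifnot(inherits(tr, "phylo"))
  if (ape::Ntip(tr) < 2) stop("tree must have at least 2 tips", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; an ultrametric chronogram is required",
         call. = FALSE)
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree has missing or negative branch lengths", call. = FALSE)
  depths <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  depth <- max(depths)
  if (depth <= 0) stop("tree depth must be positive", call. = FALSE)
  dev <- max(abs(depths - depth)) / depth
  if (dev > ultra_tol)
    stop(sprintf("tree is not ultrametric: max tip-depth deviation %.3g of depth %.6g exceeds tolerance %g",
                 dev, depth, ultra_tol), call. = FALSE)
  attr(tr, "depth") <- depth
  tr
}

#' Tree depth (root-to-tip time)
#'
#' @param tr a validated tree (from [read_tree()] or [validate_tree()]); a
#'   plain `phylo` is accepted and its depth computed.
#' @return the root-to-tip distance.
#' @export
tree_depth <- function(tr) {
  d <- attr(tr, "depth")
  if (!is.null(d)) return(d)
  max(ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))])
}

#' Reconcile an alignment with a tree
#'
#' Taxa present in the tree but absent from the alignment are pruned from a
#' working copy of the tree (with a warning); alignment taxa absent from the
#' tree are a hard error naming them.
#'
#' @param alignment a `pi_alignment`.
#' @param tree a validated ultrametric tree.
#' @return `list(alignment, tree)` over the common taxon set.
#' @export
reconcile <- function(alignment, tree) {
  stopifnot(inherits(alignment, "pi_alignment"), inherits(tree, "phylo"))
  missing_from_tree <- setdiff(alignment$taxa, tree$tip.label)
  if (length(missing_from_tree))
    stop(sprintf("locus '%s': taxa absent from the tree: %s", alignment$locus,
                 paste(missing_from_tree, collapse = ", ")), call. = FALSE)
  extra <- setdiff(tree$tip.label, alignment$taxa)
  if (length(extra)) {
    warning(sprintf("pruning %d tree tip(s) absent from locus '%s': %s",
                    length(extra), alignment$locus,
                    paste(utils::head(extra, 5), collapse = ", ")), call. = FALSE)
    tree <- validate_tree(ape::drop.tip(tree, extra))
  }
  list(alignment = alignment, tree = tree)
}
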