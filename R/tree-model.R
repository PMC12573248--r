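#' Read and validate a dated ultrametric species tree
#'
#' Parses a rooted Newick tree whose branch lengths are in absolute time
#' units (e.g. Ga, 10^9 years before present) and annotates every node with
#' its age before present. Tip ages must all equal zero within a relative
#' tolerance of the root age (ultrametricity); after validation they are
#' snapped to exactly 0 so that downstream strict inequalities on ages are
#' well defined.
#'
#' Time is expressed throughout the package as age before present: larger
#' ages are older, and every branch occupies the interval
#' `[death_age, birth_age]`.
#'
#' @param newick Either a Newick string or the path of a file containing
#'   one. A string is recognised by the presence of a `(` character.
#' @param ultrametric_tol Maximum allowed tip-age deviation, relative to the
#'   root age. Default `1e-6`.
#' @return An object of class `dated_tree`: a list with elements `phy` (the
#'   underlying `ape::phylo` tree), `node_age` (numeric vector of ages
#'   indexed by ape node number, tips first), `root` (root node number) and
#'   `root_age`.
#' @examples
#' tr <- read_dated_tree("((A:1,B:1):2,(C:2.5,D:2.5):0.5);")
#' tr$root_age  # 3
#' @export
read_dated_tree <- function(newick, ultrametric_tol = 1e-6) {
  if (length(newick) != 1L || !is.character(newick))
    stop_input("`newick` must be a single string (text or file path)")
  if (grepl("(", newick, fixed = TRUE)) {
    phy <- tryCatch(ape::read.tree(text = newick),
                    error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (!file.exists(newick))
      stop_input(sprintf("tree file not found: %s", newick))
    phy <- tryCatch(ape::read.tree(file = newick),
                    error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop_input("could not parse Newick input")
  as_dated_tree(phy, ultrametric_tol = ultrametric_tol)
}

#' Convert an ape phylo object into a validated dated tree
#'
#' @param phy A rooted `ape::phylo` tree with branch lengths in time units.
#' @param ultrametric_tol Relative tip-age tolerance (see
#'   [read_dated_tree()]).
#' @return A `dated_tree` object.
#' @export
as_dated_tree <- function(phy, ultrametric_tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop_input("`phy` must be a phylo object")
  if (is.null(phy$edge.length))
    stop_input("tree has no branch lengths; a dated tree is required")
  if (anyNA(phy$edge.length))
    stop_input("tree has missing branch lengths")
  if (any(phy$edge.length < 0))
    stop_input("tree has negative branch lengths")
  if (!ape::is.rooted(phy)) stop_input("tree must be rooted")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop_input("tree must have at least 2 tips")
  if (anyDuplicated(phy$tip.label))
    stop_input(sprintf("duplicate tip names: %s",
                       paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                             collapse = ", ")))

  depth <- ape::node.depth.edgelength(phy)  # distance from root
  root_age <- max(depth[seq_len(ntip)])
  if (root_age <= 0) stop_input("tree has zero total depth")
  tip_dev <- root_age - depth[seq_len(ntip)]
  rel_dev <- abs(tip_dev) / root_age
  if (any(rel_dev > ultrametric_tol)) {
    worst <- which.max(rel_dev)
    stop_input(sprintf(
      "tree is not ultrametric: tip '%s' deviates by %.6g (relative %.3g > tol %.3g)",
      phy$tip.label[worst], tip_dev[worst], rel_dev[worst], ultrametric_tol))
  }
  node_age <- root_age - depth
  node_age[seq_len(ntip)] <- 0  # snap tips exactly to the present

  structure(list(phy = phy,
                 node_age = node_age,
                 root = ntip + 1L,
                 root_age = root_age),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated ultrametric tree: %d tips, %d internal nodes, root age %.4g\n",
              length(x$phy$tip.label), x$phy$Nnode, x$root_age))
  invisible(x)
}

#' Tip labels of a dated tree
#' @param x A `dated_tree`.
#' @return Character vector of tip names.
#' @export
tree_tips <- function(x) {
  stopifnot(inherits(x, "dated_tree"))
  x$phy$tip.label
}

#' Remove tips from a dated tree
#'
#' Drops the named tips (e.g. organellar sequences such as mitochondrial and
#' chloroplast clades, which would otherwise masquerade as bacterial donor
#' sisters) and suppresses the resulting unary nodes by summing edge
#' durations, so surviving node ages are unchanged.
#'
#' @param tree A `dated_tree`.
#' @param drop Character vector of tip names to remove (may be empty).
#' @return A `dated_tree` without the dropped tips.
#' @export
prune_tips <- function(tree, drop) {
  stopifnot(inherits(tree, "dated_tree"))
  drop <- as.character(drop)
  if (length(drop) == 0L) return(tree)
  missing <- setdiff(drop, tree_tips(tree))
  if (length(missing))
    stop_input(sprintf("cannot prune non-existent tip(s): %s",
                       paste(missing, collapse = ", ")))
  keep_n <- length(tree_tips(tree)) - length(unique(drop))
  if (keep_n < 2L)
    stop_input("pruning would leave fewer than 2 tips")
  phy <- ape::drop.tip(tree$phy, unique(drop), collapse.singles = TRUE)
  as_dated_tree(phy)
}

#' Build the table of branch records
#'
#' Every edge of the tree yields one record identified by its child node:
#' `birth_age` is the age of the parent node and `death_age` the age of the
#' child (0 for extant tips). Each branch is labelled with the clade label
#' shared by all its descendant tips; branches whose descendants span
#' several labels get the distinct labels sorted and joined with `"+"`
#' (a mechanical ancestor label). Unlabelled tips yield `"unassigned"`.
#' `in_domain` is TRUE iff all descendant tips belong to the donor-domain
#' tip set (typically Bacteria).
#'
#' @param tree A `dated_tree`.
#' @param clades Optional `clade_map` (see [clade_map()]); if `NULL`, all
#'   branches are labelled `"unassigned"` and `in_domain` is TRUE for every
#'   branch (no domain restriction).
#' @return A data.frame with columns `branch_id`, `birth_age`, `death_age`,
#'   `clade_label`, `in_domain`. Tips are identified by their name, internal
#'   branches by their node label if present, else `"n<number>"`.
#' @export
branch_records <- function(tree, clades = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ntot <- ntip + nnode

  labels <- rep("unassigned", ntip)
  names(labels) <- phy$tip.label
  domain <- NULL
  if (!is.null(clades)) {
    clades <- validate_clade_map(clades, tree)
    got <- intersect(names(clades$labels), phy$tip.label)
    labels[got] <- clades$labels[got]
    domain <- clades$domain
  }
  tip_in_domain <- if (is.null(domain)) rep(TRUE, ntip) else
    phy$tip.label %in% domain

  # accumulate descendant label sets bottom-up over the edge matrix
  desc_labels <- vector("list", ntot)
  desc_labels[seq_len(ntip)] <- as.list(unname(labels))
  in_dom <- logical(ntot)
  in_dom[seq_len(ntip)] <- tip_in_domain
  in_dom[(ntip + 1L):ntot] <- TRUE
  # postorder: children before parents
  ord <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    par <- ord[k, 1L]; chd <- ord[k, 2L]
    desc_labels[[par]] <- c(desc_labels[[par]], desc_labels[[chd]])
    in_dom[par] <- in_dom[par] && in_dom[chd]
  }
  lab_of <- vapply(desc_labels, function(l) {
    u <- sort(unique(l))
    paste(u, collapse = "+")
  }, character(1))

  child <- phy$edge[, 2L]
  parent <- phy$edge[, 1L]
  ids <- branch_ids(phy)[child]
  rec <- data.frame(
    branch_id = ids,
    birth_age = tree$node_age[parent],
    death_age = tree$node_age[child],
    clade_label = lab_of[child],
    in_domain = in_dom[child],
    stringsAsFactors = FALSE)
  rec <- rec[order(rec$branch_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# stable printable id per node: tip name, node label, or "n<number>"
branch_ids <- function(phy) {
  ntip <- length(phy$tip.label)
  ids <- character(ntip + phy$Nnode)
  ids[seq_len(ntip)] <- phy$tip.label
  inner <- paste0("n", (ntip + 1L):(ntip + phy$Nnode))
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    use <- !is.na(nl) & nzchar(nl)
    inner[use] <- nl[use]
  }
  ids[(ntip + 1L):(ntip + phy$Nnode)] <- inner
  ids
}

#' Construct a clade map
#'
#' Associates tips with clade labels (total or partial) and optionally
#' designates the donor-domain tip set (the tips among which ghost sisters
#' may be chosen, typically all bacterial tips).
#'
#' @param labels Named character vector: names are tip names, values clade
#'   labels. May be `NULL` or partial.
#' @param domain Optional character vector of tip names forming the eligible
#'   donor domain; `NULL` means no restriction.
#' @return An object of class `clade_map`.
#' @export
clade_map <- function(labels = NULL, domain = NULL) {
  if (!is.null(labels)) {
    labels <- unlist(labels)
    if (is.null(names(labels)) || any(!nzchar(names(labels))))
      stop_input("clade map labels must be a named vector (tip -> label)")
    labels <- vapply(labels, as.character, character(1))
    if (any(!nzchar(labels)))
      stop_input("clade labels must be non-empty strings")
  }
  structure(list(labels = labels,
                 domain = if (is.null(domain)) NULL else as.character(domain)),
            class = "clade_map")
}

validate_clade_map <- function(clades, tree) {
  if (!inherits(clades, "clade_map")) stop_input("expected a clade_map object")
  tips <- tree_tips(tree)
  if (!is.null(clades$labels)) {
    bad <- setdiff(names(clades$labels), tips)
    if (length(bad))
      stop_input(sprintf("clade map names tips absent from the tree: %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!is.null(clades$domain)) {
    bad <- setdiff(clades$domain, tips)
    if (length(bad))
      stop_input(sprintf("domain tip set names tips absent from the tree: %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  clades
}

#' Read a two-column tip-to-label TSV
#'
#' Lines are `tip<TAB>label`; `#` starts a comment, blank lines ignored.
#'
#' @param path File path.
#' @return Named character vector of labels, usable as the `labels` argument
#'   of [clade_map()].
#' @export
read_clade_map <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("clade map file not found: %s", path))
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln)) return(character(0))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop_input(sprintf("malformed clade map line in %s (need tip<TAB>label)", path))
  labs <- vapply(parts, function(p) trimws(p[2L]), character(1))
  names(labs) <- vapply(parts, function(p) trimws(p[1L]), character(1))
  labs
}

#' Read a tip-set file (one name per line, `#` comments allowed)
#'
#' @param path File path.
#' @return Character vector of tip names.
#' @export
read_tip_set <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("tip set file not found: %s", path))
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  trimws(ln[nzchar(trimws(ln))])
}

# classed error helpers shared across modules ------------------------------

stop_input <- function(msg) {
  stop(structure(class = c("ghostshift_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_empty_space <- function(msg) {
  stop(structure(class = c("ghostshift_empty_space", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
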