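#' Define the acceptor window
#'
#' The acceptor branch runs from FECA (divergence of eukaryotes from their
#' closest sampled archaeal relatives, the Asgard archaea) down to LECA (the
#' most recent common ancestor of extant eukaryotes). Both ages are in the
#' tree's time units, as age before present.
#'
#' @param feca_age Age of FECA (older bound).
#' @param leca_age Age of LECA (younger bound), `feca_age > leca_age >= 0`.
#' @return An object of class `acceptor_window`.
#' @export
acceptor_window <- function(feca_age, leca_age) {
  feca_age <- as.numeric(feca_age); leca_age <- as.numeric(leca_age)
  if (length(feca_age) != 1L || length(leca_age) != 1L ||
      !is.finite(feca_age) || !is.finite(leca_age))
    stop_input("window ages must be single finite numbers")
  if (leca_age < 0) stop_input("leca_age must be >= 0")
  if (feca_age <= leca_age)
    stop_input(sprintf("feca_age (%g) must be strictly older than leca_age (%g)",
                       feca_age, leca_age))
  structure(list(feca_age = feca_age, leca_age = leca_age),
            class = "acceptor_window")
}

#' @export
print.acceptor_window <- function(x, ...) {
  cat(sprintf("Acceptor window: FECA %.4g -> LECA %.4g (span %.4g time units)\n",
              x$feca_age, x$leca_age, x$feca_age - x$leca_age))
  invisible(x)
}

#' Locate the FECA-LECA window on a dated tree
#'
#' `leca_age` is the age of the MRCA of the eukaryote tips and `feca_age`
#' the age of the MRCA of the eukaryote tips together with their archaeal
#' sister tips.
#'
#' @param tree A `dated_tree`.
#' @param euk_tips Tips of the eukaryote clade (non-empty).
#' @param sister_tips Tips of the archaeal sister clade, disjoint from
#'   `euk_tips`.
#' @return An `acceptor_window`.
#' @export
locate_window <- function(tree, euk_tips, sister_tips) {
  stopifnot(inherits(tree, "dated_tree"))
  euk_tips <- as.character(euk_tips); sister_tips <- as.character(sister_tips)
  if (!length(euk_tips) || !length(sister_tips))
    stop_input("euk_tips and sister_tips must be non-empty")
  if (length(intersect(euk_tips, sister_tips)))
    stop_input("euk_tips and sister_tips must be disjoint")
  tips <- tree_tips(tree)
  bad <- setdiff(c(euk_tips, sister_tips), tips)
  if (length(bad))
    stop_input(sprintf("tip(s) not found in tree: %s",
                       paste(utils::head(bad, 5), collapse = ", ")))
  leca_node <- mrca_node(tree, euk_tips)
  feca_node <- mrca_node(tree, c(euk_tips, sister_tips))
  if (leca_node == feca_node)
    stop_input(paste("the sister set is nested inside the eukaryote clade:",
                     "MRCA(eukaryotes) = MRCA(eukaryotes + sister),",
                     "giving a zero-length acceptor branch"))
  acceptor_window(feca_age = tree$node_age[feca_node],
                  leca_age = tree$node_age[leca_node])
}

mrca_node <- function(tree, tips) {
  if (length(tips) == 1L)
    return(match(tips, tree$phy$tip.label))
  ape::getMRCA(tree$phy, tips)
}

#' Build the FECA-LECA branch space
#'
#' Filters branch records to the eligible ghost-sister branches: bacterial
#' (`in_domain`) branches that strictly coexisted with the open acceptor
#' window, i.e. `birth_age > leca_age` and `death_age < feca_age`. Branches
#' merely touching a window endpoint are excluded because their ghost-birth
#' or transfer sampling interval would be empty.
#'
#' @param records Branch-record data.frame from [branch_records()].
#' @param window An `acceptor_window`.
#' @return An object of class `branch_space`: list with `branches` (the
#'   filtered records, ordered by `branch_id`) and `window`.
#' @export
build_branch_space <- function(records, window) {
  stopifnot(inherits(window, "acceptor_window"))
  need <- c("branch_id", "birth_age", "death_age", "clade_label", "in_domain")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_input(sprintf("records must be a data.frame with columns %s",
                       paste(need, collapse = ", ")))
  keep <- records$in_domain &
    records$birth_age > window$leca_age &
    records$death_age < window$feca_age
  br <- records[keep, need, drop = FALSE]
  if (nrow(br) == 0L)
    stop_empty_space("no eligible donor branches coexist with the FECA-LECA window")
  br <- br[order(br$branch_id), , drop = FALSE]
  rownames(br) <- NULL
  structure(list(branches = br, window = window), class = "branch_space")
}

#' @export
print.branch_space <- function(x, ...) {
  cat(sprintf("FECA-LECA branch space: %d eligible donor branches\n",
              nrow(x$branches)))
  print(x$window)
  cl <- table(x$branches$clade_label)
  cat("Clades:", paste(sprintf("%s (%d)", names(cl), cl), collapse = ", "), "\n")
  invisible(x)
}

#' Export a branch space as TSV for audit
#'
#' Columns: `branch_id`, `birth_age`, `death_age`, `clade_label`.
#'
#' @param space A `branch_space`.
#' @param path Output file path.
#' @param header Optional comment lines (without `#`) prepended to the file.
#' @return Invisibly, `path`.
#' @export
write_branch_space <- function(space, path, header = character(0)) {
  stopifnot(inherits(space, "branch_space"))
  df <- space$branches[, c("branch_id", "birth_age", "death_age", "clade_label")]
  write_tsv_commented(df, path, header)
}

# shared TSV writer: '#' header lines then a tab-separated table
write_tsv_commented <- function(df, path, header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
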