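#' Simulate a dated birth-death fixture tree
#'
#' Generates an ultrametric tree of extant tips under a constant-rate
#' birth-death process, for use as a test or demonstration stand-in for an
#' empirical dated tree. Extinct lineages are pruned: the ghost model adds
#' unsampled lineages analytically, it does not represent them as tips.
#' Stops either at a fixed number of extant tips `n` (backward simulation)
#' or at a fixed crown time `t_max` (forward simulation from two crown
#' lineages, with extinct side branches dropped).
#'
#' @param lambda Speciation rate (events per time unit), > 0.
#' @param mu Extinction rate, >= 0.
#' @param n Number of extant tips (>= 2), or `NULL`.
#' @param t_max Crown age in time units, or `NULL`. Exactly one of `n` and
#'   `t_max` must be given.
#' @param seed Integer seed (mandatory; full-extinction retries use derived
#'   substreams).
#' @param tip_prefix Tips are renamed `<prefix>1..N`.
#' @param max_retries Retries allowed when the forward process goes fully
#'   extinct before `t_max`.
#' @return A `dated_tree`.
#' @export
simulate_bd_tree <- function(lambda, mu = 0, n = NULL, t_max = NULL, seed,
                             tip_prefix = "t", max_retries = 100L) {
  if (!is.numeric(lambda) || lambda <= 0) stop_input("lambda must be > 0")
  if (!is.numeric(mu) || mu < 0) stop_input("mu must be >= 0")
  if (is.null(n) == is.null(t_max))
    stop_input("give exactly one stop condition: n or t_max")
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")

  if (!is.null(n)) {
    n <- as.integer(n)
    if (is.na(n) || n < 2L) stop_input("n must be >= 2")
    set.seed(derive_seed(seed, 0L))
    phy <- ape::rphylo(n, birth = lambda, death = mu, fossils = FALSE)
  } else {
    if (!is.numeric(t_max) || t_max <= 0) stop_input("t_max must be > 0")
    phy <- NULL
    for (try in 0:max_retries) {
      set.seed(derive_seed(seed, try))
      full <- ape::rlineage(birth = lambda, death = mu, Tmax = t_max)
      cand <- tryCatch(ape::drop.fossil(full), error = function(e) NULL)
      if (!is.null(cand) && inherits(cand, "phylo") &&
          length(cand$tip.label) >= 2L) { phy <- cand; break }
    }
    if (is.null(phy))
      stop_input(sprintf(
        "birth-death process went extinct before t_max in all %d attempts",
        max_retries + 1L))
  }
  phy$tip.label <- paste0(tip_prefix, seq_along(phy$tip.label))
  phy$node.label <- NULL
  as_dated_tree(phy)
}

#' Specify a hand-built branch-space fixture
#'
#' A fixture pins down an acceptor window and an explicit list of donor
#' branches (birth age, death age, clade label), bypassing tree
#' construction. Every branch must pass the [build_branch_space()]
#' eligibility filters against the window.
#'
#' @param feca Window FECA age.
#' @param leca Window LECA age.
#' @param branches data.frame with columns `birth`, `death` and optionally
#'   `label` (default `"donor"`).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(feca, leca, branches) {
  if (!is.data.frame(branches) || !all(c("birth", "death") %in% names(branches)))
    stop_input("branches must be a data.frame with columns birth, death")
  if (is.null(branches$label)) branches$label <- "donor"
  structure(list(feca = as.numeric(feca), leca = as.numeric(leca),
                 branches = data.frame(birth = as.numeric(branches$birth),
                                       death = as.numeric(branches$death),
                                       label = as.character(branches$label),
                                       stringsAsFactors = FALSE)),
            class = "fixture_spec")
}

#' Read a fixture specification from YAML or JSON
#'
#' Format: `{window: {feca: ..., leca: ...}, branches: [{birth: ..., death:
#' ..., label: ...}, ...]}`. Files ending in `.json` are parsed as JSON,
#' anything else as YAML.
#'
#' @param path File path.
#' @return A `fixture_spec`.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("fixture file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop_input(sprintf("cannot parse fixture %s: %s",
                                                    path, conditionMessage(e))))
  if (is.null(raw$window$feca) || is.null(raw$window$leca) ||
      !length(raw$branches))
    stop_input("fixture must define window {feca, leca} and a branches list")
  br <- do.call(rbind, lapply(raw$branches, function(b) {
    if (is.null(b$birth) || is.null(b$death))
      stop_input("every fixture branch needs birth and death ages")
    data.frame(birth = as.numeric(b$birth), death = as.numeric(b$death),
               label = if (is.null(b$label)) "donor" else as.character(b$label),
               stringsAsFactors = FALSE)
  }))
  fixture_spec(raw$window$feca, raw$window$leca, br)
}

#' Materialise a fixture as a branch space
#'
#' @param spec A `fixture_spec`.
#' @return A `branch_space` validated by the standard eligibility filters;
#'   errors if any fixture branch fails them.
#' @export
make_fixture_space <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  w <- acceptor_window(spec$feca, spec$leca)
  br <- spec$branches
  records <- data.frame(
    branch_id = sprintf("b%03d", seq_len(nrow(br))),
    birth_age = br$birth, death_age = br$death,
    clade_label = br$label, in_domain = TRUE,
    stringsAsFactors = FALSE)
  bad <- !(records$birth_age > w$leca_age & records$death_age < w$feca_age &
             records$birth_age > records$death_age & records$death_age >= 0)
  if (any(bad))
    stop_input(sprintf(
      "fixture branch(es) fail the window-overlap filters: %s",
      paste(sprintf("(%g,%g)", br$birth[bad], br$death[bad]), collapse = " ")))
  build_branch_space(records, w)
}

#' Simulate a labelled study tree emulating the eukaryogenesis setup
#'
#' Builds a complete synthetic dated tree of life with the structure the
#' simulation framework expects: a large bacterial domain, an archaeal
#' (Asgard-like) sister clade, a eukaryote crown clade, and a small nested
#' organellar clade to exercise pruning. The eukaryote stem attaches at the
#' FECA age and the eukaryote crown at the LECA age; bacterial tips are
#' grouped into synthetic phyla by slicing the bacterial subtree at a fixed
#' age (every lineage crossing that age founds one phylum).
#'
#' Defaults mirror the empirical setting the framework was designed for:
#' FECA at 2.42 and LECA at 1.89 Ga, a root (LUCA-like) age of 3.8 Ga, and
#' diversified-sampling-like rates giving a bacteria-dominated tree.
#'
#' @param seed Integer seed (mandatory).
#' @param n_bacteria,n_archaea,n_eukaryotes Extant tip counts per domain.
#' @param root_age,feca_age,leca_age,asgard_crown_age,bacteria_crown_age
#'   Node ages in Ga before present.
#' @param phylum_slice_age Age at which bacterial phyla are delimited.
#' @param lambda,mu Birth-death rates used for the within-domain subtree
#'   shapes (subtrees are rescaled to their target crown ages).
#' @param n_organelle Number of organellar tips grafted inside Bacteria.
#' @return A list of class `study_fixture`: `tree` (a `dated_tree`, with
#'   the organellar tips still present), `euk_tips`, `sister_tips`,
#'   `domain_tips` (bacterial tips, excluding organellar ones),
#'   `prune` (organellar tips), and `clades` (a `clade_map` with
#'   per-phylum bacterial labels).
#' @export
simulate_study_tree <- function(seed,
                                n_bacteria = 100L, n_archaea = 12L,
                                n_eukaryotes = 20L,
                                root_age = 3.8, feca_age = 2.42,
                                leca_age = 1.89,
                                asgard_crown_age = 1.6,
                                bacteria_crown_age = 3.4,
                                phylum_slice_age = 2.8,
                                lambda = 1, mu = 0.5,
                                n_organelle = 2L) {
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  stopifnot(root_age > bacteria_crown_age, root_age > feca_age,
            feca_age > leca_age, feca_age > asgard_crown_age,
            bacteria_crown_age > phylum_slice_age)

  sub_newick <- function(n, crown, prefix, round) {
    tr <- simulate_bd_tree(lambda, mu, n = n, seed = derive_seed(seed, round),
                           tip_prefix = prefix)
    phy <- tr$phy
    phy$edge.length <- phy$edge.length * (crown / tr$root_age)
    sub(";$", "", ape::write.tree(phy))
  }
  bact <- sub_newick(n_bacteria, bacteria_crown_age, "B", 1L)
  arch <- sub_newick(n_archaea, asgard_crown_age, "S", 2L)
  euk <- sub_newick(n_eukaryotes, leca_age, "E", 3L)

  newick <- sprintf("(%s:%.10f,(%s:%.10f,%s:%.10f):%.10f);",
                    bact, root_age - bacteria_crown_age,
                    euk, feca_age - leca_age,
                    arch, feca_age - asgard_crown_age,
                    root_age - feca_age)
  tree <- read_dated_tree(newick)

  bact_tips <- grep("^B", tree_tips(tree), value = TRUE)
  # organelles: relabel one bacterial cherry so pruning has work to do
  prune <- character(0)
  if (n_organelle > 0L) {
    prune <- utils::tail(bact_tips, n_organelle)
    lab <- tree$phy$tip.label
    lab[match(prune, lab)] <- paste0("ORG", seq_len(n_organelle))
    tree$phy$tip.label <- lab
    prune <- paste0("ORG", seq_len(n_organelle))
    bact_tips <- setdiff(bact_tips, utils::tail(bact_tips, n_organelle))
  }

  clabels <- bacterial_phyla(tree, bact_tips, phylum_slice_age)
  structure(list(tree = tree,
                 euk_tips = grep("^E", tree_tips(tree), value = TRUE),
                 sister_tips = grep("^S", tree_tips(tree), value = TRUE),
                 domain_tips = bact_tips,
                 prune = prune,
                 clades = clade_map(labels = clabels, domain = bact_tips)),
            class = "study_fixture")
}

# group tips by the ancestral lineage crossing `slice_age`: each branch with
# birth_age >= slice_age > death_age founds one synthetic phylum
bacterial_phyla <- function(tree, tips, slice_age) {
  phy <- tree$phy
  age <- tree$node_age
  tip_idx <- match(tips, phy$tip.label)
  parent_of <- integer(length(phy$tip.label) + phy$Nnode)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  founder <- vapply(tip_idx, function(i) {
    node <- i
    while (parent_of[node] != 0L && age[parent_of[node]] < slice_age)
      node <- parent_of[node]
    node
  }, integer(1))
  groups <- match(founder, sort(unique(founder)))
  labs <- sprintf("Phylum%02d", groups)
  names(labs) <- tips
  labs
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study tree: %d bacterial, %d archaeal, ",
                     "%d eukaryotic tips (+%d organellar)\n"),
              length(x$domain_tips), length(x$sister_tips),
              length(x$euk_tips), length(x$prune)))
  print(x$tree)
  invisible(x)
}
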