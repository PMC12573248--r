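test_that("read_dated_tree computes node ages and validates ultrametricity", {
  tr <- read_dated_tree("(A:1,B:1);")
  expect_s3_class(tr, "dated_tree")
  expect_equal(tr$root_age, 1)
  expect_equal(unname(tr$node_age[1:2]), c(0, 0))

  # forced violation must name the worst-offending tip
  expect_error(read_dated_tree("(A:1,B:2);"),
               "not ultrametric.*'A'", class = "ghostshift_input_error")

  # node ages match an independent root-to-tip path-sum oracle
  nwk <- "((A:1,B:1):2,(C:2.5,D:2.5):0.5);"
  tr <- read_dated_tree(nwk)
  phy <- ape::read.tree(text = nwk)
  expect_equal(unname(tr$node_age), unname(oracle_node_ages(phy)))
  ages <- tr$node_age
  ab <- ape::getMRCA(tr$phy, c("A", "B"))
  cd <- ape::getMRCA(tr$phy, c("C", "D"))
  expect_equal(ages[ab], 1)
  expect_equal(ages[cd], 2.5)
  expect_equal(ages[tr$root], 3)
})

test_that("read_dated_tree rejects malformed input", {
  expect_error(read_dated_tree("(A,B);"), class = "ghostshift_input_error")
  expect_error(read_dated_tree("not a tree"), class = "ghostshift_input_error")
  expect_error(read_dated_tree("/no/such/file.nwk"),
               "not found", class = "ghostshift_input_error")
  expect_error(read_dated_tree("(A:1,A:1);"), "duplicate",
               class = "ghostshift_input_error")
})

test_that("prune_tips drops tips, suppresses unary nodes, keeps ages", {
  tr <- read_dated_tree("((A:1,B:1):2,C:3);")
  expect_identical(prune_tips(tr, character(0)), tr)

  pr <- prune_tips(tr, "B")
  expect_setequal(tree_tips(pr), c("A", "C"))
  expect_equal(pr$root_age, 3)

  expect_error(prune_tips(tr, "Z"), "non-existent",
               class = "ghostshift_input_error")
  expect_error(prune_tips(tr, c("A", "B")), "fewer than 2",
               class = "ghostshift_input_error")
})

test_that("pruning a random tree preserves surviving MRCA ages", {
  tr <- simulate_bd_tree(lambda = 1, mu = 0.3, n = 64, seed = 11)
  set.seed(21)
  drop <- sample(tree_tips(tr), 10)
  pr <- prune_tips(tr, drop)
  keep <- tree_tips(pr)
  set.seed(22)
  for (i in 1:25) {
    pair <- sample(keep, 2)
    expect_equal(oracle_mrca_age(pr, pair), oracle_mrca_age(tr, pair),
                 tolerance = 1e-9)
  }
})

test_that("branch_records labels branches by their descendant tips", {
  tr <- read_dated_tree("(A:1,B:1);")
  rec <- branch_records(tr, clade_map(labels = c(A = "X", B = "Y")))
  expect_equal(rec$clade_label[match(c("A", "B"), rec$branch_id)], c("X", "Y"))

  tr <- read_dated_tree("((A:1,B:1):1,C:2);")
  rec <- branch_records(tr, clade_map(labels = c(A = "X", B = "X", C = "Y")))
  expect_equal(nrow(rec), 4L)  # edges = nodes - 1
  stem <- rec[!rec$branch_id %in% c("A", "B", "C"), ]
  expect_equal(stem$clade_label, "X")

  # mixed-descendant branches get sorted "+"-joined labels; unlabelled tips
  # fall back to "unassigned"
  rec2 <- branch_records(tr, clade_map(labels = c(A = "X", C = "Y")))
  expect_equal(rec2$clade_label[rec2$branch_id == "B"], "unassigned")
  expect_equal(stem$clade_label, "X")
  rec3 <- branch_records(tr, clade_map(labels = c(A = "X", B = "Z", C = "Y")))
  stem3 <- rec3[!rec3$branch_id %in% c("A", "B", "C"), ]
  expect_equal(stem3$clade_label, "X+Z")
})

test_that("branch_records matches the descendant-set oracle on a caterpillar", {
  nwk <- "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5);"
  tr <- read_dated_tree(nwk)
  labs <- c(A = "p", B = "q", C = "p", D = "r", E = "q", F = "s")
  rec <- branch_records(tr, clade_map(labels = labs))
  desc <- oracle_descendant_tips(tr$phy)
  ids <- ghostshift:::branch_ids(tr$phy)
  for (k in seq_len(nrow(rec))) {
    node <- match(rec$branch_id[k], ids)
    expected <- paste(sort(unique(unname(labs[desc[[node]]]))), collapse = "+")
    expect_equal(rec$clade_label[k], expected)
  }
})

test_that("branch records satisfy the structural invariants", {
  tr <- simulate_bd_tree(lambda = 1, mu = 0.2, n = 40, seed = 5)
  rec <- branch_records(tr)
  phy <- tr$phy
  expect_equal(nrow(rec), nrow(phy$edge))
  expect_equal(nrow(rec), length(phy$tip.label) + phy$Nnode - 1L)
  expect_true(all(rec$birth_age > rec$death_age))
  expect_true(all(rec$death_age >= 0))
  # branch durations reproduce the Newick edge lengths
  ids <- ghostshift:::branch_ids(phy)
  dur <- rec$birth_age - rec$death_age
  elen <- phy$edge.length[match(match(rec$branch_id, ids), phy$edge[, 2])]
  expect_equal(dur, elen, tolerance = 1e-9)
  # in_domain marks exactly the branches whose tips all sit in the domain
  dom <- tree_tips(tr)[1:20]
  rec2 <- branch_records(tr, clade_map(domain = dom))
  desc <- oracle_descendant_tips(phy)
  for (k in seq_len(nrow(rec2))) {
    node <- match(rec2$branch_id[k], ids)
    expect_equal(rec2$in_domain[k], all(desc[[node]] %in% dom))
  }
})

test_that("tip-set and clade-map files round-trip with comments", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "A", "", "B # trailing"), tf)
  expect_equal(read_tip_set(tf), c("A", "B"))
  cf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# tip\tlabel", "A\tX", "B\tY"), cf)
  expect_equal(read_clade_map(cf), c(A = "X", B = "Y"))
  expect_error(read_clade_map(tf), "malformed",
               class = "ghostshift_input_error")
})
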