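# residue graphs: construction, contact detection, descriptors, counts

test_that("conv graph applies the inclusive 8 A cutoff to C-alpha pairs", {
  mk <- function(d3) make_structure(
    resno = c(1, 10), resid = "GLY", elety = "CA",
    xyz = rbind(c(0, 0, 0), c(d3, 0, 0)), elesy = "C")
  near <- build_conv_graph(mk(7.9))
  far <- build_conv_graph(mk(8.1))
  has_conv <- function(g) any(g$edges$kind == "conv")
  expect_true(has_conv(near))
  expect_false(has_conv(far))
  at_cut <- build_conv_graph(mk(8.0))
  expect_true(has_conv(at_cut))    # "at most" is inclusive
})

test_that("straight C-alpha trace at 3.8 A connects i+-1 and i+-2 only", {
  n <- 10
  s <- make_structure(resno = 1:n, resid = "GLY", elety = "CA",
                      xyz = cbind(3.8 * (0:(n - 1)), 0, 0), elesy = "C")
  g <- build_conv_graph(s)
  conv <- g$edges[g$edges$kind == "conv", ]
  seps <- sort(unique(abs(conv$b - conv$a)))
  expect_equal(seps, c(1, 2))   # 3.8 and 7.6 in range, 11.4 out
  # adjacency is stored canonically (a < b), hence symmetric by construction
  expect_true(all(conv$a < conv$b))
})

test_that("conv edge set grows monotonically with the cutoff", {
  set.seed(2)
  s <- make_structure(resno = 1:15, resid = "GLY", elety = "CA",
                      xyz = matrix(runif(45, 0, 15), ncol = 3), elesy = "C")
  sizes <- vapply(c(4, 6, 8, 10, 12),
                  function(co) nrow(build_conv_graph(s, co)$edges), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("contact ingestion filters by kind and collapses duplicates", {
  s <- make_structure(resno = 1:50, resid = "GLY", elety = "CA",
                      xyz = cbind(3.8 * (0:49), 0, 0), elesy = "C")
  # empty records: only the covalent backbone path
  empty <- data.frame(protein_id = character(0), chain_a = character(0),
                      res_a = integer(0), chain_b = character(0),
                      res_b = integer(0), kind = character(0),
                      backbone = logical(0))
  gs <- ingest_contacts(s, empty)
  expect_true(all(gs$Plip$edges$kind == "covalent"))
  expect_equal(nrow(gs$Plip$edges), 49)
  rec <- data.frame(protein_id = "P", chain_a = "A", res_a = c(5, 5),
                    chain_b = "A", res_b = c(40, 40), kind = "hbond",
                    backbone = FALSE)
  gs <- ingest_contacts(s, rec)
  in_graph <- function(g, kind) sum(g$edges$kind == kind)
  expect_equal(in_graph(gs$Plip, "hbond"), 1)      # duplicate collapsed
  expect_equal(in_graph(gs$PlipHb, "hbond"), 1)
  expect_equal(in_graph(gs$PlipHp, "hydrophobic"), 0)
  # unresolvable reference: skipped with warning
  bad <- rbind(rec, data.frame(protein_id = "P", chain_a = "B", res_a = 1,
                               chain_b = "A", res_b = 2, kind = "hbond",
                               backbone = FALSE))
  expect_warning(gs2 <- ingest_contacts(s, bad), "unknown residues")
  expect_equal(sum(gs2$Plip$edges$kind == "hbond"), 1)
})

test_that("geometric detector honours distance thresholds", {
  # two alanine side-chain carbons: hydrophobic at 3.9, none at 4.1
  mk <- function(d) make_structure(
    resno = c(1, 10), resid = "ALA", elety = c("CB", "CB"),
    xyz = rbind(c(0, 0, 0), c(d, 0, 0)), elesy = "C")
  hit <- detect_contacts_geometric(mk(3.9))
  expect_equal(nrow(hit), 1)
  expect_identical(hit$kind, "hydrophobic")
  expect_equal(nrow(detect_contacts_geometric(mk(4.1))), 0)
  # helix backbone hydrogen bonds carry the backbone flag
  helix <- toy_structure("helix", 12)
  rec <- detect_contacts_geometric(helix)
  hb <- rec[rec$kind == "hbond", ]
  expect_true(any(hb$res_b - hb$res_a == 4))    # i, i+4 pattern
  expect_true(all(hb$backbone[hb$res_b - hb$res_a == 4]))
  # far-apart residues produce nothing
  expect_equal(nrow(detect_contacts_geometric(mk(50))), 0)
})

test_that("path, star, triangle and complete-graph descriptors match closed forms", {
  path3 <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  d <- graph_descriptors(path3)
  expect_equal(d$BN, c(0, 1 / 3, 0))
  expect_equal(d$CL, c(2 / 3, 1, 2 / 3))
  triangle <- graph_from_adjacency(matrix(1, 3, 3) - diag(3))
  dt <- graph_descriptors(triangle)
  expect_equal(dt$BN, rep(0, 3))
  expect_equal(dt$CL, rep(1, 3))
  expect_equal(dt$CC, rep(1, 3))
  # star: center plus 4 leaves
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  ds <- graph_descriptors(graph_from_adjacency(star))
  expect_equal(ds$BN[1], 6 / 10)
  expect_equal(ds$CC[1], 0)
  k4 <- graph_from_adjacency(matrix(1, 4, 4) - diag(4))
  expect_equal(graph_descriptors(k4)$BN, rep(0, 4))
  # clustering: neighbors {a, b, c} with a single a-b edge
  adj <- matrix(0, 4, 4)
  adj[1, 2:4] <- adj[2:4, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  expect_equal(graph_descriptors(graph_from_adjacency(adj))$CC[1], 1 / 3)
})

test_that("descriptors equal exhaustive shortest-path enumeration on random graphs", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(3:7, 1)
    adj <- random_adjacency(n, p = runif(1, 0.25, 0.8))
    g <- graph_from_adjacency(adj)
    got <- graph_descriptors(g)
    want <- bf_descriptors(adj)
    expect_equal(got$BN, want$BN, tolerance = 1e-12)
    expect_equal(got$CL, want$CL, tolerance = 1e-12)
    expect_equal(got$CC, want$CC, tolerance = 1e-12)
    expect_true(all(got$BN >= 0 & got$BN <= 1))
    expect_true(all(got$CL >= 0 & got$CL <= 1))
    expect_true(all(got$CC >= 0 & got$CC <= 1))
  }
})

test_that("descriptors are invariant under node relabeling", {
  set.seed(5)
  adj <- random_adjacency(6, 0.5)
  perm <- sample(6)
  padj <- adj[perm, perm]
  d1 <- graph_descriptors(graph_from_adjacency(adj))
  d2 <- graph_descriptors(graph_from_adjacency(padj))
  expect_equal(d1$BN[perm], d2$BN, tolerance = 1e-12)
  expect_equal(d1$CL[perm], d2$CL, tolerance = 1e-12)
  expect_equal(d1$CC[perm], d2$CC, tolerance = 1e-12)
})

test_that("closeness handles disconnected graphs over reachable nodes only", {
  # two components: an edge pair and an isolated node
  adj <- matrix(0, 3, 3); adj[1, 2] <- adj[2, 1] <- 1
  d <- graph_descriptors(graph_from_adjacency(adj))
  expect_equal(d$CL, c(1, 1, 0))
})

test_that("neighborhood count merges sequence regions with gaps above 5", {
  s <- make_structure(resno = 1:60, resid = "GLY", elety = "CA",
                      xyz = cbind(3.8 * (0:59), 0, 0), elesy = "C")
  mk_rec <- function(partners) data.frame(
    protein_id = "P", chain_a = "A", res_a = 10, chain_b = "A",
    res_b = partners, kind = "hbond", backbone = FALSE)
  # no long-range partners
  g0 <- ingest_contacts(s, mk_rec(13))$Plip
  expect_equal(neighborhood_count(g0)[10], 0)
  g1 <- ingest_contacts(s, mk_rec(30))$Plip
  expect_equal(neighborhood_count(g1)[10], 1)
  # partners at 2, 3, 30, 50: regions {2,3}, {30}, {50}
  g3 <- ingest_contacts(s, mk_rec(c(2, 3, 30, 50)))$Plip
  expect_equal(neighborhood_count(g3)[10], 3)
})

test_that("contact counts bucket by kind, locality and backbone flag", {
  s <- make_structure(resno = 1:40, resid = "GLY", elety = "CA",
                      xyz = cbind(3.8 * (0:39), 0, 0), elesy = "C")
  rec <- data.frame(protein_id = "P", chain_a = "A", res_a = c(10, 10),
                    chain_b = "A", res_b = c(13, 30),
                    kind = c("hbond", "hydrophobic"),
                    backbone = c(TRUE, FALSE))
  cc <- count_contacts(ingest_contacts(s, rec)$Plip)
  expect_equal(cc$PlipLC[10], 1); expect_equal(cc$PlipHbLC[10], 1)
  expect_equal(cc$PlipBbLC[10], 1)
  expect_equal(cc$PlipLR[10], 1); expect_equal(cc$PlipHpLR[10], 1)
  expect_equal(cc$PlipHpLC[10], 0); expect_equal(cc$PlipHbLR[10], 0)
  expect_equal(cc$PlipBbLR[10], 0)
  # partner side is counted too
  expect_equal(cc$PlipHbLC[13], 1)
  # covalent-only nodes count nothing
  expect_true(all(cc$PlipLC[c(1, 40)] == 0))
  expect_true(all(cc$PlipLR[c(1, 40)] == 0))
})

test_that("total counts decompose into per-kind counts on random graphs", {
  set.seed(10)
  for (rep in 1:10) {
    n <- 30
    s <- make_structure(resno = 1:n, resid = "GLY", elety = "CA",
                        xyz = cbind(3.8 * (0:(n - 1)), 0, 0), elesy = "C")
    n_rec <- 25
    rec <- data.frame(
      protein_id = "P", chain_a = "A",
      res_a = sample(n, n_rec, TRUE), chain_b = "A",
      res_b = sample(n, n_rec, TRUE),
      kind = sample(c("hbond", "hydrophobic", "other"), n_rec, TRUE),
      backbone = sample(c(TRUE, FALSE), n_rec, TRUE))
    rec <- rec[rec$res_a != rec$res_b, ]
    cc <- suppressWarnings(count_contacts(ingest_contacts(s, rec)$Plip))
    other_lc <- cc$PlipLC - cc$PlipHbLC - cc$PlipHpLC
    other_lr <- cc$PlipLR - cc$PlipHbLR - cc$PlipHpLR
    expect_true(all(other_lc >= 0))
    expect_true(all(other_lr >= 0))
  }
})
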