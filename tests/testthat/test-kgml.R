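test_that("a single reversible reaction yields two nodes and one edge", {
  g <- parse_kgml(toy_kgml(paste(
    compound_entry(1, "C00031", "D-Glucose"),
    compound_entry(2, "C00668"),
    '<entry id="3" name="ko:K00844 ec:2.7.1.1" type="ortholog" reaction="rn:R01786"/>',
    '<reaction id="9" name="rn:R01786" type="reversible">',
    '<substrate id="1" name="cpd:C00031"/><product id="2" name="cpd:C00668"/>',
    "</reaction>", sep = "\n")))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::E(g)$reversible)
  expect_equal(igraph::E(g)$reactions, "R01786")
  expect_setequal(strsplit(igraph::E(g)$enzymes, ";")[[1]],
                  c("K00844", "2.7.1.1"))
  expect_setequal(igraph::V(g)$name, c("C00031", "C00668"))
  expect_true("D-Glucose" %in% igraph::V(g)$display)
})

test_that("multi-substrate/product reactions expand to all pairs", {
  g <- parse_kgml(toy_kgml(paste(
    compound_entry(1, "C1"), compound_entry(2, "C2"),
    compound_entry(3, "C3"), compound_entry(4, "C4"),
    '<reaction id="1" name="rn:R1" type="irreversible">',
    '<substrate id="1" name="cpd:C1"/><substrate id="2" name="cpd:C2"/>',
    '<product id="3" name="cpd:C3"/><product id="4" name="cpd:C4"/>',
    "</reaction>", sep = "\n")))
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)
  # independent hand-built adjacency: substrates x products
  got <- igraph::as_edgelist(g)
  want <- rbind(c("C1", "C3"), c("C1", "C4"), c("C2", "C3"), c("C2", "C4"))
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
})

test_that("compounds without reactions are dropped; empty pathway is empty", {
  g <- parse_kgml(toy_kgml(paste(compound_entry(1, "C1"),
                                 compound_entry(2, "C2"), sep = "\n")))
  expect_equal(igraph::vcount(g), 0)
  expect_equal(igraph::ecount(g), 0)
})

test_that("malformed XML raises a parse error", {
  expect_error(parse_kgml("<pathway><entry></pathway>"), "malformed")
  expect_error(parse_kgml("<notapathway/>"), "pathway")
})

test_that("merge_pathways unions nodes, edges and annotations", {
  g1 <- parse_kgml(toy_kgml(paste(
    compound_entry(1, "C00031"), compound_entry(2, "CX"),
    '<reaction id="1" name="rn:R1" type="reversible">',
    '<substrate id="1" name="cpd:C00031"/><product id="2" name="cpd:CX"/>',
    "</reaction>", sep = "\n"), name = "path:rn00010"))
  g2 <- parse_kgml(toy_kgml(paste(
    compound_entry(1, "C00031"), compound_entry(2, "CX"),
    '<reaction id="1" name="rn:R2" type="irreversible">',
    '<substrate id="1" name="cpd:C00031"/><product id="2" name="cpd:CX"/>',
    "</reaction>", sep = "\n"), name = "path:rn00020"))
  m <- merge_pathways(list(g1, g2))
  expect_equal(igraph::vcount(m), 2)  # shared node appears once
  expect_equal(igraph::ecount(m), 1)  # same ordered pair merged
  expect_setequal(strsplit(igraph::E(m)$reactions, ";")[[1]], c("R1", "R2"))
  expect_setequal(igraph::graph_attr(m, "provenance"),
                  c("rn00010", "rn00020"))

  # disjoint graphs: node counts additive
  g3 <- parse_kgml(toy_kgml(paste(
    compound_entry(1, "CA"), compound_entry(2, "CB"),
    '<reaction id="1" name="rn:R3" type="reversible">',
    '<substrate id="1" name="cpd:CA"/><product id="2" name="cpd:CB"/>',
    "</reaction>", sep = "\n"), name = "path:rn00030"))
  m2 <- merge_pathways(list(g1, g3))
  expect_equal(igraph::vcount(m2),
               igraph::vcount(g1) + igraph::vcount(g3))
})

test_that("to_undirected collapses antiparallel edges and merges reactions", {
  edf <- data.frame(from = c("A", "B", "A"), to = c("B", "A", "B"),
                    reactions = c("R1", "R2", "R1"),
                    enzymes = c("1.1.1.1", "", ""),
                    reversible = c(TRUE, FALSE, TRUE))
  g <- igraph::graph_from_data_frame(edf, directed = TRUE)
  net <- to_undirected(g)
  expect_false(igraph::is_directed(net))
  expect_equal(igraph::ecount(net), 1)
  expect_setequal(strsplit(igraph::E(net)$reactions, ";")[[1]], c("R1", "R2"))
  # single directed edge also becomes one undirected edge
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", reactions = "R9", enzymes = "",
               reversible = FALSE), directed = TRUE)
  expect_equal(igraph::ecount(to_undirected(g2)), 1)
  expect_equal(igraph::vcount(to_undirected(igraph::make_empty_graph())), 0)
})

test_that("anomer fusion re-attaches edges, merges duplicates, drops loops", {
  edf <- data.frame(from = c("C00267", "C00221", "C00267"),
                    to = c("X", "X", "C00221"),
                    reactions = c("R1", "R2", "R3"),
                    enzymes = "", reversible = TRUE)
  net <- to_undirected(igraph::graph_from_data_frame(edf, directed = TRUE))
  f <- fuse_anomers(net, data.frame(anomer = c("C00267", "C00221"),
                                    canonical = "C00031"))
  expect_setequal(igraph::V(f)$name, c("C00031", "X"))
  expect_equal(igraph::ecount(f), 1)  # the two X edges merged, loop dropped
  expect_setequal(strsplit(igraph::E(f)$reactions, ";")[[1]], c("R1", "R2"))
  expect_equal(sort(igraph::graph_attr(f, "fusion_log")$anomer),
               c("C00221", "C00267"))
  # empty fusion table leaves the network unchanged
  f0 <- fuse_anomers(net, data.frame(anomer = character(0),
                                     canonical = character(0)))
  expect_equal(igraph::vcount(f0), igraph::vcount(net))
  # fusing into a fusion source is a configuration error
  expect_error(fuse_anomers(net, data.frame(anomer = c("C00267", "C00221"),
                                            canonical = c("C00221", "C00031"))),
               "source")
})

test_that("pool removal deletes nodes with incident edges and is idempotent", {
  expect_length(default_pool_metabolites(), 13)
  leaves <- sprintf("L%d", 1:5)
  edf <- data.frame(from = "C00001", to = leaves, reactions = "R1",
                    enzymes = "", reversible = TRUE)
  net <- to_undirected(igraph::graph_from_data_frame(edf, directed = TRUE))
  out <- remove_pool_metabolites(net)
  expect_setequal(igraph::V(out)$name, leaves)
  expect_equal(igraph::ecount(out), 0)
  expect_false(any(default_pool_metabolites() %in% igraph::V(out)$name))
  again <- remove_pool_metabolites(out)
  expect_equal(igraph::vcount(again), igraph::vcount(out))
  # empty pool list leaves the network unchanged
  expect_equal(igraph::vcount(remove_pool_metabolites(net, character(0))),
               igraph::vcount(net))
})

test_that("build_reference_network equals the manually composed stages", {
  net <- simulate_network(10, seed = 11)
  xml1 <- write_kgml(igraph::induced_subgraph(net, 1:6), pathway_id = "p1")
  xml2 <- write_kgml(igraph::induced_subgraph(net, 4:10), pathway_id = "p2")
  ft <- data.frame(anomer = "C90002", canonical = "C90001")
  pool <- "C90005"
  built <- build_reference_network(c(xml1, xml2), fusion_table = ft,
                                   pool = pool)
  manual <- remove_pool_metabolites(
    fuse_anomers(to_undirected(merge_pathways(list(parse_kgml(xml1),
                                                   parse_kgml(xml2)))), ft),
    pool)
  expect_equal(igraph::vcount(built), igraph::vcount(manual))
  expect_equal(igraph::ecount(built), igraph::ecount(manual))
  expect_setequal(igraph::V(built)$name, igraph::V(manual)$name)
  # fusing before pool removal equals the reverse order when the fusion
  # target is not a pool member
  alt <- fuse_anomers(remove_pool_metabolites(
    to_undirected(merge_pathways(list(parse_kgml(xml1), parse_kgml(xml2)))),
    pool), ft)
  expect_setequal(igraph::V(built)$name, igraph::V(alt)$name)
  expect_equal(igraph::ecount(built), igraph::ecount(alt))
  # single pathway without options equals to_undirected(parse)
  plain <- build_reference_network(xml1, fusion_table = NULL,
                                   pool = character(0))
  ref <- to_undirected(parse_kgml(xml1))
  expect_equal(igraph::ecount(plain), igraph::ecount(ref))
})

test_that("network invariants hold across simulated pathway collections", {
  for (seed in 1:5) {
    net <- simulate_network(12, mean_degree = 3, seed = seed)
    xmls <- c(write_kgml(igraph::induced_subgraph(net, 1:7), pathway_id = "a"),
              write_kgml(igraph::induced_subgraph(net, 5:12), pathway_id = "b"))
    graphs <- lapply(xmls, parse_kgml)
    super <- merge_pathways(graphs)
    expect_lte(igraph::vcount(super),
               sum(vapply(graphs, igraph::vcount, numeric(1))))
    undirected <- to_undirected(super)
    expect_lte(igraph::ecount(undirected), igraph::ecount(super))
    # merge never loses a reaction ID
    all_rxn <- unique(unlist(lapply(graphs, function(g)
      unlist(strsplit(igraph::E(g)$reactions, ";")))))
    merged_rxn <- unique(unlist(strsplit(igraph::E(super)$reactions, ";")))
    expect_setequal(merged_rxn, all_rxn)
  }
})

test_that("GraphML and SIF exports round-trip", {
  net <- simulate_network(8, seed = 2)
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gp)
  back <- read_network_graphml(gp)
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  sp <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(net, sp)
  lines <- readLines(sp)
  expect_length(lines, igraph::ecount(net))
  expect_true(all(grepl("\trxn\t", lines)))
})

test_that("the shipped toy pathway builds into the expected chain", {
  f <- system.file("extdata", "toy_glycolysis.xml", package = "metamod")
  net <- build_reference_network(
    f,
    fusion_table = read_fusion_table(
      system.file("extdata", "anomer_fusion.tsv", package = "metamod")),
    pool = read_pool_list(
      system.file("extdata", "pool_metabolites.tsv", package = "metamod")))
  # anomers fuse into D-glucose; the ATP/ADP currency edges disappear
  expect_setequal(igraph::V(net)$name, c("C00031", "C00668", "C00085"))
  expect_equal(igraph::ecount(net), 2)
  expect_true(all(grepl("K00845|K01810", igraph::E(net)$enzymes)))
})
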