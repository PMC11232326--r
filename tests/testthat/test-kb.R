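test_that("read_kb parses receptor complexes and enforces the role vocabulary", {
  dir <- withr::local_tempdir()
  writeLines(c("metabolite_id\treceptor\tspecies\tsource",
               "M1\tHRH1\thuman\tcurated",
               "M2\tGABBR1;GABBR2\thuman\tcurated",
               "M3\tADORA1\thuman\tcurated"),
             file.path(dir, "interactions.tsv"))
  writeLines(c("metabolite_id\tgene\trole",
               "M1\tHDC\tproducer",
               "M1\tHNMT\tconsumer"),
             file.path(dir, "enzymes.tsv"))
  writeLines(c("metabolite_id\tgene", "M1\tSLC22A3"),
             file.path(dir, "transporters.tsv"))
  writeLines(c("metabolite_id\tname\thmdb_id\tpubchem_cid\tclass_label",
               "M1\thistamine\tHMDB0000870\t774\tOrganic nitrogen compounds",
               "M2\tGABA\tHMDB0000112\t119\tOrganic acids and derivatives",
               "M3\tadenosine\tHMDB0000050\t60961\tNucleosides, nucleotides, and analogues"),
             file.path(dir, "metabolites.tsv"))

  kb <- read_kb_dir(dir, "human")
  expect_s3_class(kb, "mlr_kb")
  expect_equal(nrow(kb$interactions), 3L)
  expect_identical(receptor_subunits(kb$interactions$receptor[1]), "HRH1")
  expect_identical(receptor_subunits(kb$interactions$receptor[2]),
                   c("GABBR1", "GABBR2"))
  expect_identical(kb$interactions$receptor_canonical[2], "GABBR1;GABBR2")

  # unknown role is a closed-vocabulary error
  writeLines(c("metabolite_id\tgene\trole", "M1\tHDC\tmaker"),
             file.path(dir, "enzymes.tsv"))
  expect_error(read_kb_dir(dir, "human"), "role")

  # missing required column names file and column
  writeLines(c("metabolite_id\tgene\trole", "M1\tHDC\tproducer"),
             file.path(dir, "enzymes.tsv"))
  writeLines(c("metabolite_id\tcomplex", "M1\tHRH1"),
             file.path(dir, "interactions.tsv"))
  expect_error(read_kb_dir(dir, "human"), "receptor")
})

test_that("complex identity is order-insensitive", {
  expect_identical(canonical_receptor(c("B;A", "A;B", "X")),
                   c("A;B", "A;B", "X"))
})

test_that("validate_kb reports instead of throwing", {
  expect_identical(nrow(validate_kb(tiny_kb())), 0L)

  # enzyme annotation pointing at a missing metabolite -> one error
  kb <- kb_create("human",
    metabolites = data.frame(metabolite_id = "M1", name = "x"),
    interactions = data.frame(metabolite_id = "M1", receptor = "R1"),
    enzymes = data.frame(metabolite_id = "GHOST", gene = "G1", role = "producer"),
    transporters = data.frame(metabolite_id = character(0), gene = character(0)),
    strict = FALSE)
  issues <- validate_kb(kb)
  expect_identical(issues$severity, "error")
  expect_match(issues$message, "GHOST")

  # same interaction twice (in either subunit order) -> one warning
  kb2 <- kb_create("human",
    metabolites = data.frame(metabolite_id = "M1", name = "x"),
    interactions = data.frame(metabolite_id = c("M1", "M1"),
                              receptor = c("A;B", "B;A")),
    enzymes = data.frame(metabolite_id = character(0), gene = character(0),
                         role = character(0)),
    transporters = data.frame(metabolite_id = character(0), gene = character(0)),
    strict = FALSE)
  issues2 <- validate_kb(kb2)
  expect_identical(issues2$severity, "warning")
  expect_match(issues2$message, "duplicated")

  # orphan transporter annotation -> warning, not error
  kb3 <- kb_create("human",
    metabolites = data.frame(metabolite_id = c("M1", "M2"), name = c("x", "y")),
    interactions = data.frame(metabolite_id = "M1", receptor = "R1"),
    enzymes = data.frame(metabolite_id = character(0), gene = character(0),
                         role = character(0)),
    transporters = data.frame(metabolite_id = "M2", gene = "T1"),
    strict = FALSE)
  issues3 <- validate_kb(kb3)
  expect_identical(issues3$severity, "warning")
  expect_match(issues3$message, "no interaction")
})

test_that("summarize_kb counts roles, receptors and classes", {
  kb <- make_toy_kb(8, complex_fraction = 0.5, seed = 42)
  s <- summarize_kb(kb)
  expect_identical(sum(s$role_counts), s$n_enzyme_entries)
  expect_lt(abs(sum(s$role_percentages) - 100), 0.2)
  expect_identical(s$n_interactions, 8L)
  expect_identical(s$n_receptors,
                   length(unique(kb$interactions$receptor_canonical)))
  expect_identical(sum(s$class_counts), 8L)

  # empty KB: all counts 0, percentages defined as 0
  empty <- kb_create("human",
    metabolites = data.frame(metabolite_id = character(0), name = character(0)),
    interactions = data.frame(metabolite_id = character(0), receptor = character(0)),
    enzymes = data.frame(metabolite_id = character(0), gene = character(0),
                         role = character(0)),
    transporters = data.frame(metabolite_id = character(0), gene = character(0)))
  se <- summarize_kb(empty)
  expect_identical(se$n_enzyme_entries, 0L)
  expect_identical(unname(se$role_percentages), c(0, 0, 0))
})

test_that("kb TSV round trip preserves the knowledgebase", {
  kb <- make_toy_kb(6, complex_fraction = 0.5, seed = 7)
  dir <- withr::local_tempdir()
  write_kb(kb, dir)
  kb2 <- read_kb_dir(dir, "human")
  expect_equal(kb2$interactions$receptor_canonical,
               kb$interactions$receptor_canonical)
  expect_equal(kb2$enzymes, kb$enzymes, ignore_attr = TRUE)
  expect_equal(kb2$transporters, kb$transporters, ignore_attr = TRUE)
  expect_equal(kb2$metabolites, kb$metabolites, ignore_attr = TRUE)
})

test_that("map_orthologs maps, drops all-or-nothing, and is identity-idempotent", {
  kb <- tiny_kb()
  full_map <- c(P1 = "p1", P2 = "p2", C1 = "c1", TX1 = "tx1",
                RA = "ra", RB = "rb")
  mapped <- map_orthologs(kb, full_map, "mouse")
  expect_identical(attr(mapped, "drop_report"),
                   c(interactions = 0L, enzymes = 0L, transporters = 0L))
  expect_identical(mapped$interactions$receptor, "ra;rb")
  expect_identical(mapped$species, "mouse")
  expect_identical(nrow(validate_kb(mapped)[
    validate_kb(mapped)$severity == "error", ]), 0L)

  # one unmapped subunit kills the whole complex; enzyme tables are independent
  partial <- full_map[names(full_map) != "RB"]
  expect_message(mapped2 <- map_orthologs(kb, partial, "mouse"), "dropped")
  expect_identical(nrow(mapped2$interactions), 0L)
  expect_identical(attr(mapped2, "drop_report")[["interactions"]], 1L)
  expect_identical(nrow(mapped2$enzymes), 3L)  # enzymes all still mapped

  # unmapped enzyme but mapped interaction: interaction kept, enzyme dropped
  no_c1 <- full_map[names(full_map) != "C1"]
  expect_message(mapped3 <- map_orthologs(kb, no_c1, "mouse"), "dropped")
  expect_identical(nrow(mapped3$interactions), 1L)
  expect_identical(nrow(mapped3$enzymes), 2L)

  # identity gene map: gene content unchanged
  idmap <- setNames(names(full_map), names(full_map))
  mapped4 <- map_orthologs(kb, idmap, "mouse")
  expect_identical(sort(kb_genes(mapped4)), sort(kb_genes(kb)))
  expect_equal(mapped4$enzymes, kb$enzymes, ignore_attr = TRUE)

  expect_error(map_orthologs(kb, character(0), "mouse"), "empty")
})
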