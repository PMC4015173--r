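# Canonical RInChI assembly, serialization and parsing.

test_that("serialized strings follow the 0.02 grammar", {
  rx <- fx_reactions()
  for (nm in names(rx)) {
    s <- rinchi_serialize(build_rinchi(rx[[nm]])$rinchi)
    expect_match(s, "^RInChI=0\\.02\\.1S/", label = nm)
    expect_match(s, "(/d[+=-])?$", label = nm)
    expect_false(grepl("////", s, fixed = TRUE), label = nm)
    expect_false(endsWith(s, "/"), label = nm)
  }
})

test_that("group assignment, direction and sorting follow the byte order", {
  b <- build_rinchi(stub_rec("B2H6/h1H2", c("CH4/h1H4", "AsH3/h1H3")))
  r <- b$rinchi
  # products sort before the reactant ('A' < 'B' < 'C'), so they are group1
  expect_identical(r$group1, c("AsH3/h1H3", "CH4/h1H4"))
  expect_identical(r$group2, "B2H6/h1H2")
  expect_identical(r$direction, "minus")

  # swapped roles: identical groups, flipped direction
  b2 <- build_rinchi(stub_rec(c("CH4/h1H4", "AsH3/h1H3"), "B2H6/h1H2"))
  expect_identical(b2$rinchi$group1, r$group1)
  expect_identical(b2$rinchi$group2, r$group2)
  expect_identical(b2$rinchi$direction, "plus")

  # equilibrium keeps canonical group order, direction layer carries it
  b3 <- build_rinchi(stub_rec("B2H6/h1H2", c("CH4/h1H4", "AsH3/h1H3"),
                              direction = "equilibrium"))
  expect_identical(b3$rinchi$group1, r$group1)
  expect_match(rinchi_serialize(b3$rinchi), "/d=$")

  # unknown direction: layer omitted, still a valid RInChI
  b4 <- build_rinchi(stub_rec("CH4/h1H4", "B2H6/h1H2",
                              direction = "unspecified"))
  expect_identical(b4$rinchi$direction, "omitted")
  expect_no_error(rinchi_parse(rinchi_serialize(b4$rinchi)))
})

test_that("molecule input order never changes the string", {
  rx <- fx_reactions()$esterification
  base <- rinchi_serialize(build_rinchi(rx)$rinchi)
  for (i in 1:4) {
    perm <- rx
    perm$reactants <- perm$reactants[sample(length(perm$reactants))]
    perm$products <- perm$products[sample(length(perm$products))]
    expect_identical(rinchi_serialize(build_rinchi(perm)$rinchi), base)
  }
})

test_that("reactant-only reactions show only the first group", {
  s <- rinchi_serialize(build_rinchi(stub_rec("C2H6O/c1-2-3/h3H,2H2,1H3",
                                              character()))$rinchi)
  expect_false(grepl("///", s, fixed = TRUE))
  expect_identical(rinchi_parse(s)$group1, "C2H6O/c1-2-3/h3H,2H2,1H3")
})

test_that("duplicates within a group are preserved, not collapsed", {
  r <- build_rinchi(stub_rec(c("AsH3/h1H3", "AsH3/h1H3"), "CH4/h1H4"))$rinchi
  expect_identical(r$group1, c("AsH3/h1H3", "AsH3/h1H3"))
  expect_match(rinchi_serialize(r), "AsH3/h1H3//AsH3/h1H3", fixed = TRUE)
})

test_that("identity reactions drop the direction layer", {
  r <- build_rinchi(stub_rec("CH4/h1H4", "CH4/h1H4"))$rinchi
  expect_identical(r$direction, "omitted")
})

test_that("agents form group3 and never perturb groups 1/2", {
  plain <- build_rinchi(fx_reactions()$diels_alder)$rinchi
  no_agents <- fx_reactions()$diels_alder
  no_agents$agents <- list()
  bare <- build_rinchi(no_agents)$rinchi
  expect_identical(plain$group1, bare$group1)
  expect_identical(plain$group2, bare$group2)
  expect_length(plain$group3, 1L)
  expect_length(bare$group3, 0L)
})

test_that("parse is the exact inverse of serialize", {
  pool <- fx_body_pool()
  set.seed(42)
  for (i in 1:200) {
    r <- build_rinchi(random_reaction(pool))$rinchi
    s <- rinchi_serialize(r)
    p <- rinchi_parse(s)
    expect_identical(rinchi_serialize(p), s)
    expect_identical(p$group1, r$group1)
    expect_identical(p$group2, r$group2)
    expect_identical(p$group3, r$group3)
    expect_identical(p$direction, r$direction)
  }
})

test_that("parsing validates header, order and direction tokens", {
  good <- "RInChI=0.02.1S/C2H6/c1-2/h1-2H3///CH4/h1H4/d+"
  expect_identical(rinchi_parse(good)$direction, "plus")
  # tolerated variants
  expect_no_error(rinchi_parse(sub("0.02.1S", "0.02.1.S", good, fixed = TRUE)))
  expect_no_error(rinchi_parse(paste0(good, "/")))

  expect_error(rinchi_parse("InChI=1S/CH4/h1H4"),
               class = "rinchi_validation_error")
  expect_error(rinchi_parse("RInChI=0.03.1S/CH4/h1H4"),
               class = "rinchi_validation_error")
  # groups out of canonical order
  expect_error(
    rinchi_parse("RInChI=0.02.1S/CH4/h1H4//AsH3/h1H3///B2H6/h1H2/d+"),
    class = "rinchi_validation_error")
  expect_error(
    rinchi_parse("RInChI=0.02.1S/CH4/h1H4///AsH3/h1H3/d+"),
    class = "rinchi_validation_error")
})

test_that("build -> reconstruct -> build is idempotent", {
  for (nm in c("ester_pyrolysis", "esterification", "diels_alder")) {
    b <- build_rinchi(fx_reactions()[[nm]])
    s <- rinchi_serialize(b$rinchi)
    rec <- rinchi_to_reaction(b$rinchi, b$rauxinfo)
    expect_identical(rinchi_serialize(build_rinchi(rec)$rinchi), s, label = nm)
  }
})

test_that("rauxinfo mirrors the rinchi group structure", {
  b <- build_rinchi(fx_reactions()$diels_alder)
  expect_length(b$rauxinfo$group1, length(b$rinchi$group1))
  expect_length(b$rauxinfo$group2, length(b$rinchi$group2))
  expect_length(b$rauxinfo$group3, length(b$rinchi$group3))
  s <- rauxinfo_serialize(b$rauxinfo)
  expect_match(s, "^RAuxInfo=0\\.02\\.1/")
  back <- rauxinfo_parse(s)
  expect_identical(back$group1, b$rauxinfo$group1)
  expect_identical(back$group3, b$rauxinfo$group3)
})

test_that("sort_group modes order bodies as documented", {
  expect_identical(sort_group(c("B", "A")), c("A", "B"))
  expect_identical(sort_group(c("A", "A")), c("A", "A"))
  # enantiomer bodies share the major key under both modes
  e1 <- "C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m0/s1"
  e2 <- "C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m1/s1"
  expect_identical(sort_group(c(e2, e1)), c(e1, e2))
  expect_identical(sort_group(c(e2, e1), mode = "major_then_minor"),
                   c(e1, e2))
})

test_that("equilibrium direction survives a decode/rebuild cycle", {
  b <- build_rinchi(fx_reactions()$esterification)
  rec <- rinchi_to_reaction(b$rinchi, molfiles = FALSE)
  expect_identical(rec$direction, "equilibrium")
  expect_identical(rinchi_serialize(build_rinchi(rec)$rinchi),
                   rinchi_serialize(b$rinchi))
})
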