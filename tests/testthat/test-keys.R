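# Hashed keys: the InChIKey implementation against the official engine,
# the hash_block primitive, and the four reaction key variants.

key_blocks <- function(key) strsplit(key, "-", fixed = TRUE)[[1]]

test_that("inchikey byte-matches the official engine on every fixture", {
  for (nm in names(fx_mols)) {
    rec <- fx_records()[[nm]]
    expect_identical(inchikey(rec$inchi), oracle_inchikey(fx_mols[[nm]]),
                     label = nm)
  }
})

test_that("inchikey handles charge, protonation and stereo layers", {
  # pinned against the official engine's published behaviour
  expect_identical(inchikey("InChI=1S/CH4/h1H4"),
                   "VNWKTOKETHGBQD-UHFFFAOYSA-N")
  expect_identical(inchikey("InChI=1S/C2H7N/c1-2-3/h2-3H2,1H3/p+1"),
                   "QUSNBJAOOMFDIB-UHFFFAOYSA-O")
  expect_identical(inchikey("InChI=1S/C2H3O2/c1-2(3)4/h1H3/q-1"),
                   "RNGFHGOYAUAFKR-UHFFFAOYSA-N")
  expect_identical(
    inchikey("InChI=1S/C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m0/s1"),
    "BTANRVKWQNVYAZ-BYPYZUCNSA-N")
  expect_identical(
    inchikey("InChI=1S/C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m1/s1"),
    "BTANRVKWQNVYAZ-SCSAIBSYSA-N")

  expect_identical(inchikey("InChI=1S/CH4/h1H4"), inchikey("InChI=1S/CH4/h1H4"))
  expect_error(inchikey("InChI=1/CH4/h1H4"), class = "rinchi_validation_error")
})

test_that("distinct InChIs give distinct keys across the fixtures", {
  keys <- vapply(fx_records(), function(r) inchikey(r$inchi), character(1))
  inchis <- vapply(fx_records(), `[[`, character(1), "inchi")
  expect_identical(anyDuplicated(keys[!duplicated(inchis)]), 0L)
})

test_that("hash_block is a deterministic prefix-stable letter hash", {
  expect_identical(hash_block("", 15L), "UHFFFADPSCTJKWU")  # pinned constant
  expect_identical(nchar(hash_block("", 15L)), 15L)
  for (s in c("", "a", "CH4/h1H4", "/d+", strrep("x", 300))) {
    for (n in c(1L, 4L, 14L)) {
      expect_identical(hash_block(s, n), substr(hash_block(s, n + 1L), 1, n))
    }
    expect_identical(hash_block(s, 10L), hash_block(s, 10L))
    expect_match(hash_block(s, 15L), "^[A-Z]{15}$")
  }
})

test_that("no 15-letter block collision across 10^4 distinct strings", {
  corpus <- sprintf("synthetic-body-%d/c1-2/h1H", 1:10000)
  blocks <- vapply(corpus, hash_block, character(1), length = 15L)
  expect_identical(anyDuplicated(blocks), 0L)
})

test_that("long keys mirror the RInChI group structure", {
  r <- build_rinchi(fx_reactions()$ester_pyrolysis)$rinchi  # 1 -> 2, no agents
  ka <- long_rinchikey(r, "A")
  kb <- long_rinchikey(r, "B")

  expect_identical(lengths(regmatches(ka, gregexpr("--", ka, fixed = TRUE))),
                   1L)                                   # one group boundary
  expect_match(ka, "^aSA-[A-Z]{5}-")
  expect_match(kb, "^bSA-[FBEU][A-Z]{4}-")

  # one 27-character InChIKey per molecule, in RInChI order
  for (grp in strsplit(sub("^aSA-[A-Z]{5}-", "", ka), "--", fixed = TRUE)[[1]])
    expect_match(grp, "^([A-Z]{14}-[A-Z]{10}-[A-Z])(-[A-Z]{14}-[A-Z]{10}-[A-Z])*$")
  keys_in_order <- regmatches(ka, gregexpr("[A-Z]{14}-[A-Z]{8}SA-[A-Z]", ka))[[1]]
  want <- vapply(c(r$group1, r$group2),
                 function(b) inchikey(paste0("InChI=1S/", b)), character(1))
  expect_identical(keys_in_order, unname(want))

  # versions A and B differ only in block 2
  expect_identical(sub("^aSA-[A-Z]{5}", "", ka), sub("^bSA-[A-Z]{5}", "", kb))
})

test_that("version-B block 2 spells the direction", {
  pool <- fx_body_pool()
  r <- build_rinchi(stub_rec("AsH3/h1H3", "CH4/h1H4"))$rinchi
  expect_identical(r$direction, "plus")
  expect_match(key_blocks(long_rinchikey(r, "B"))[2], "^F")
  expect_match(key_blocks(short_rinchikey(r, "B"))[2], "^F")

  rb <- build_rinchi(stub_rec("CH4/h1H4", "AsH3/h1H3"))$rinchi
  expect_identical(rb$direction, "minus")
  expect_match(key_blocks(long_rinchikey(rb, "B"))[2], "^B")

  # same groups, flipped direction: B keys differ only in block 2's letter
  ka <- key_blocks(short_rinchikey(r, "B"))
  kb <- key_blocks(short_rinchikey(rb, "B"))
  expect_identical(ka[-2], kb[-2])
  expect_identical(substr(ka[2], 2, 5), substr(kb[2], 2, 5))

  req <- build_rinchi(stub_rec("AsH3/h1H3", "CH4/h1H4",
                                    direction = "equilibrium"))$rinchi
  expect_match(key_blocks(short_rinchikey(req, "B"))[2], "^E")
  run <- build_rinchi(stub_rec("AsH3/h1H3", "CH4/h1H4",
                                    direction = "unspecified"))$rinchi
  expect_match(key_blocks(short_rinchikey(run, "B"))[2], "^U")
})

test_that("short keys have constant length regardless of molecule count", {
  small <- build_rinchi(stub_rec("CH4/h1H4", "C2H6/c1-2/h1-2H3"))$rinchi
  big_bodies <- sprintf("C%dH%d/c1-2/h1H", 11:60, 24:73)
  big <- build_rinchi(stub_rec(big_bodies[1:25], big_bodies[26:50]))$rinchi
  for (v in c("A", "B")) {
    expect_identical(nchar(short_rinchikey(small, v)),
                     nchar(short_rinchikey(big, v)))
  }
  expect_identical(length(key_blocks(short_rinchikey(big, "A"))), 5L)
  expect_identical(length(key_blocks(short_rinchikey(big, "B"))), 8L)
  blocks_a <- key_blocks(short_rinchikey(big, "A"))
  expect_identical(nchar(blocks_a), c(3L, 5L, 15L, 15L, 15L))
  blocks_b <- key_blocks(short_rinchikey(big, "B"))
  expect_identical(nchar(blocks_b), c(3L, 5L, 10L, 10L, 10L, 5L, 5L, 5L))
})

test_that("enantiomeric reactions differ exactly where the figures say", {
  ra <- build_rinchi(fx_reactions()$substitution_a)$rinchi
  rb <- build_rinchi(fx_reactions()$substitution_b)$rinchi

  # short B: only the minor blocks of the two reaction sides move
  ba <- key_blocks(short_rinchikey(ra, "B"))
  bb <- key_blocks(short_rinchikey(rb, "B"))
  differ <- which(ba != bb)
  expect_true(all(differ %in% 6:7))
  expect_identical(ba[8], bb[8])          # empty group3 minor block matches
  expect_identical(ba[3:5], bb[3:5])      # majors identical

  # short A: both populated group blocks differ, the empty one matches
  aa <- key_blocks(short_rinchikey(ra, "A"))
  ab <- key_blocks(short_rinchikey(rb, "A"))
  expect_identical(aa[1:2], ab[1:2])
  expect_false(aa[3] == ab[3])
  expect_false(aa[4] == ab[4])
  expect_identical(aa[5], ab[5])          # group3 empty for both
})

test_that("keys are pure functions of the identifier string", {
  for (nm in c("diels_alder", "esterification", "reduction_a")) {
    r <- build_rinchi(fx_reactions()[[nm]])$rinchi
    reparsed <- rinchi_parse(rinchi_serialize(r))
    expect_identical(rinchikey_bundle(r), rinchikey_bundle(reparsed),
                     label = nm)
    expect_identical(long_rinchikey(rinchi_serialize(r)),
                     long_rinchikey(r), label = nm)
  }
})

test_that("protonation letters count around N and clamp with a warning", {
  p1 <- build_rinchi(stub_rec("C2H7N/c1-2-3/h2-3H2,1H3/p+1",
                                   "CH4/h1H4"))$rinchi
  blocks <- key_blocks(short_rinchikey(p1, "B"))
  proton_flags <- substr(blocks[6:8], 1, 1)
  expect_true("O" %in% proton_flags)      # the +1 group
  expect_true("N" %in% proton_flags)      # the neutral group
  expect_warning(rinchi:::protonation_letter(40L), "clamp")
})
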