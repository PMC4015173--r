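# Corpus-level analyses on identifier strings.

mk_corpus <- function(recs) {
  rinchi_corpus(vapply(recs, function(r)
    rinchi_serialize(build_rinchi(r)$rinchi), character(1)))
}

flip_direction <- function(s) {
  if (endsWith(s, "/d+")) sub("/d\\+$", "/d-", s)
  else if (endsWith(s, "/d-")) sub("/d-$", "/d+", s)
  else s
}

test_that("find_duplicates groups byte-identical strings", {
  rxs <- fx_reactions()
  corpus <- mk_corpus(list(rxs$diels_alder, rxs$diels_alder,
                           rxs$diels_alder, rxs$ester_pyrolysis))
  dup <- find_duplicates(corpus)
  expect_identical(dup$n_unique, 2L)
  expect_identical(dup$n_duplicates, 2L)
  expect_identical(dup$groups, list(1:3))

  # one differing product stereocentre: not duplicates
  corpus2 <- mk_corpus(list(rxs$reduction_a, rxs$reduction_b))
  expect_identical(find_duplicates(corpus2)$n_duplicates, 0L)

  # order of the input file never changes the outcome
  corpus3 <- mk_corpus(list(rxs$ester_pyrolysis, rxs$diels_alder,
                            rxs$diels_alder, rxs$diels_alder))
  expect_identical(find_duplicates(corpus3)$n_unique, 2L)
  expect_identical(find_duplicates(corpus3)$n_duplicates, 2L)
})

test_that("core mode ignores agents and direction", {
  da <- fx_reactions()$diels_alder
  da_other_agent <- da
  da_other_agent$agents <- fx_records()["ammonia"]
  corpus <- mk_corpus(list(da, da_other_agent))
  expect_identical(find_duplicates(corpus)$n_duplicates, 0L)
  expect_identical(find_duplicates(corpus, mode = "core")$n_duplicates, 1L)
})

test_that("search_partner honours role and direction", {
  rxs <- fx_reactions()
  corpus <- mk_corpus(list(rxs$diels_alder,      # butadiene+ethene -> cyclohexene (water agent)
                           rxs$dehydrogenation,  # cyclohexene -> benzene + H2 (Pt agent)
                           rxs$esterification))  # equilibrium
  cyclohexene <- fx_records()$cyclohexene$inchi

  as_product <- search_partner(corpus, cyclohexene, role = "product")
  expect_identical(as_product$entry, 1L)
  as_reactant <- search_partner(corpus, cyclohexene, role = "reactant")
  expect_identical(as_reactant$entry, 2L)
  any_role <- search_partner(corpus, cyclohexene, role = "any")
  expect_setequal(any_role$entry, c(1L, 2L))

  # a pure product matches nothing as reactant
  benzene <- fx_records()$benzene$inchi
  expect_identical(nrow(search_partner(corpus, benzene, role = "reactant")), 0L)

  # agents match only the agent role
  water <- fx_records()$water$inchi
  expect_true(1L %in% search_partner(corpus, water, role = "agent")$entry)

  # equilibrium participants match both sides
  etoac <- fx_records()$ethyl_acetate$inchi
  expect_identical(search_partner(corpus, etoac, role = "reactant")$entry, 3L)
  expect_identical(search_partner(corpus, etoac, role = "product")$entry, 3L)

  expect_error(search_partner(corpus, "garbage"),
               class = "rinchi_validation_error")
})

test_that("search role 'any' is the union of the role-specific searches", {
  rxs <- fx_reactions()
  corpus <- mk_corpus(unname(rxs))
  for (q in c(fx_records()$water$inchi, fx_records()$cyclohexene$inchi,
              fx_records()$ethanol$inchi)) {
    got_any <- search_partner(corpus, q, role = "any")
    union_rows <- unique(do.call(rbind, lapply(
      c("reactant", "product", "agent"),
      function(ro) search_partner(corpus, q, role = ro))))
    expect_setequal(
      paste(got_any$entry, got_any$group),
      paste(union_rows$entry, union_rows$group))
  }
})

test_that("ring_change reports the connectivity-layer ring arithmetic", {
  da <- rinchi_serialize(build_rinchi(fx_reactions()$diels_alder)$rinchi)
  rep_da <- ring_change(da)
  expect_identical(rep_da$ring_count_delta, 1L)       # 0 rings -> 1 ring
  expect_false(rep_da$direction_unspecified)
  expect_identical(rep_da$rings_per_molecule_delta, 1 - 0)

  # identity entry: benzene -> benzene, no change (direction omitted)
  ident <- rinchi_serialize(build_rinchi(stub_rec(
    "C6H6/c1-2-4-6-5-3-1/h1-6H", "C6H6/c1-2-4-6-5-3-1/h1-6H"))$rinchi)
  expect_identical(ring_change(ident)$ring_count_delta, 0L)

  # ring opening: delta -1; acyclic side flags the empty denominator
  opening <- rinchi_serialize(build_rinchi(stub_rec(
    "C6H10/c1-2-4-6-5-3-1/h1-2H,3-6H2",
    "C6H12O/c1-2-3-4-5-6-7/h6H,2-5H2,1H3"))$rinchi)
  rep_open <- ring_change(opening)
  expect_identical(rep_open$ring_count_delta, -1L)
  expect_true(rep_open$empty_denominator)
  expect_identical(rep_open$rings_per_cyclic_molecule_delta, 0 - 1)
})

test_that("stereo_change counts layer designations per molecule", {
  red <- rinchi_serialize(build_rinchi(fx_reactions()$reduction_a)$rinchi)
  rep_red <- stereo_change(red)
  expect_identical(rep_red$stereocentre_count_delta, 1)  # achiral -> 1 centre
  expect_identical(rep_red$stereocentre_delta_per_molecule, 1)

  # enantiomeric entries report identical counts
  rep_a <- stereo_change(rinchi_serialize(
    build_rinchi(fx_reactions()$reduction_a)$rinchi))
  rep_b <- stereo_change(rinchi_serialize(
    build_rinchi(fx_reactions()$reduction_b)$rinchi))
  expect_identical(rep_a$stereocentre_count_delta,
                   rep_b$stereocentre_count_delta)

  # racemization written as an equilibrium: zero magnitude
  rac <- rinchi_serialize(build_rinchi(stub_rec(
    "C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m0/s1",
    "C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m1/s1",
    direction = "equilibrium"))$rinchi)
  rep_rac <- stereo_change(rac)
  expect_identical(rep_rac$stereocentre_delta_per_molecule, 0)
  expect_true(rep_rac$direction_unspecified)

  # double-bond designations count unless restricted to /t
  cis_trans <- rinchi_serialize(build_rinchi(stub_rec(
    "C4H8/c1-3-4-2/h3-4H,1-2H3",
    "C4H8/c1-3-4-2/h3-4H,1-2H3/b4-3+"))$rinchi)
  expect_identical(stereo_change(cis_trans)$stereocentre_count_delta, 1)
  expect_identical(
    stereo_change(cis_trans, stereo_mode = "t_only")$stereocentre_count_delta,
    0)
})

test_that("ring and stereo deltas negate under a direction flip", {
  for (nm in c("diels_alder", "reduction_a", "dehydrogenation")) {
    s <- rinchi_serialize(build_rinchi(fx_reactions()[[nm]])$rinchi)
    flipped <- flip_direction(s)
    expect_identical(ring_change(flipped)$ring_count_delta,
                     -ring_change(s)$ring_count_delta, label = nm)
    expect_identical(
      stereo_change(flipped)$stereocentre_delta_per_molecule,
      -stereo_change(s)$stereocentre_delta_per_molecule, label = nm)
  }
})

test_that("corpus_stats counts entries, molecules and compression", {
  rxs <- fx_reactions()
  recs <- c(rep(list(rxs$diels_alder), 3), list(rxs$ester_pyrolysis),
            list(rxs$reduction_a))
  corpus <- mk_corpus(recs)
  st <- corpus_stats(corpus)
  expect_identical(st$n_entries, 5L)
  expect_identical(st$n_unique_reactions, 3L)
  expect_identical(st$n_duplicates, 2L)
  # diels_alder x3: 4 molecules each; pyrolysis 3; reduction 2
  expect_identical(st$n_molecule_occurrences, 3L * 4L + 3L + 2L)
  expect_identical(st$n_unique_molecules,
                   length(unique(corpus$index$body)))
  st2 <- corpus_stats(corpus, source_text = strrep("x", 10000))
  expect_lt(st2$compression_ratio, 1)
})
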