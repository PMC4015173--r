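# Toy molecules, reactions and synthetic corpora.
#
# Everything a test or demo needs is generated here in code: small
# hand-specified V2000 connection tables with known ring and stereocentre
# counts, reaction templates built from them, and a seed-deterministic
# RDfile corpus with injected duplicates and agent variations whose ground
# truth (unique count, duplicate groups, per-entry ring/stereo deltas) is
# recorded in a manifest at generation time.  The corpus emulates the
# shape of vendor reaction databases -- many small reactions, some exact
# repeats distinguished only by free-text comments, per-reaction agent
# variations -- not their chemistry.

make_molfile <- function(symbols, coords, bonds, title = "") {
  atoms <- data.frame(
    x = coords[, 1L], y = coords[, 2L],
    z = if (ncol(coords) > 2L) coords[, 3L] else 0,
    symbol = symbols
  )
  b <- if (length(bonds) > 0L) {
    do.call(rbind, lapply(bonds, function(bb) {
      data.frame(from = bb[1L], to = bb[2L], order = bb[3L],
                 stereo = if (length(bb) > 3L) bb[4L] else 0L)
    }))
  } else {
    data.frame(from = integer(), to = integer(), order = integer(),
               stereo = integer())
  }
  write_ctab(structure(
    list(title = title, program = "  rinchi", comment = "",
         atoms = atoms, bonds = b, properties = character()),
    class = "ctab"))
}

# Zig-zag 2D coordinates for a chain of n atoms.
zigzag <- function(n) {
  cbind(x = 0.866 * (seq_len(n) - 1L), y = rep(c(0, 0.5), length.out = n))
}

#' Fixture molecules
#'
#' A named list of small V2000 molfiles with known structure: acyclic and
#' cyclic hydrocarbons, oxygen/nitrogen species, and a chiral alcohol in
#' both enantiomeric forms (wedge-bond 2D stereochemistry).
#'
#' @return Named list of molfile strings.
#' @export
fixture_molfiles <- function() {
  ring6 <- cbind(x = c(0, 0.866, 0.866, 0, -0.866, -0.866),
                 y = c(1, 0.5, -0.5, -1, -0.5, 0.5))
  chain <- function(n, orders) {
    lapply(seq_len(n - 1L), function(i) c(i, i + 1L, orders[i]))
  }
  chiral_c4 <- function(tip, wedge, title) {
    make_molfile(c("C", "C", "C", "C", tip),
                 rbind(c(0, 0), c(0.866, 0.5), c(1.732, 0),
                       c(2.598, 0.5), c(0.866, 1.5)),
                 list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(2, 5, 1, wedge)),
                 title = title)
  }
  butanol <- function(wedge) chiral_c4("O", wedge, "butan-2-ol")
  chlorobutane <- function(wedge) chiral_c4("Cl", wedge, "2-chlorobutane")
  list(
    methane = make_molfile("C", cbind(0, 0), list(), "methane"),
    water = make_molfile("O", cbind(0, 0), list(), "water"),
    ammonia = make_molfile("N", cbind(0, 0), list(), "ammonia"),
    hydrogen_chloride = make_molfile("Cl", cbind(0, 0), list(),
                                     "hydrogen chloride"),
    platinum = make_molfile("Pt", cbind(0, 0), list(), "platinum"),
    hydrogen = make_molfile(c("H", "H"), zigzag(2), list(c(1, 2, 1)),
                            "hydrogen"),
    ethanol = make_molfile(c("C", "C", "O"), zigzag(3),
                           chain(3, c(1, 1)), "ethanol"),
    ethene = make_molfile(c("C", "C"), zigzag(2), list(c(1, 2, 2)), "ethene"),
    butadiene = make_molfile(c("C", "C", "C", "C"), zigzag(4),
                             chain(4, c(2, 1, 2)), "1,3-butadiene"),
    benzene = make_molfile(rep("C", 6L), ring6,
                           list(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2),
                                c(4, 5, 1), c(5, 6, 2), c(6, 1, 1)),
                           "benzene"),
    cyclohexene = make_molfile(rep("C", 6L), ring6,
                               list(c(1, 2, 2), c(2, 3, 1), c(3, 4, 1),
                                    c(4, 5, 1), c(5, 6, 1), c(6, 1, 1)),
                               "cyclohexene"),
    acetic_acid = make_molfile(c("C", "C", "O", "O"),
                               rbind(c(0, 0), c(0.866, 0.5),
                                     c(0.866, 1.5), c(1.732, 0)),
                               list(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)),
                               "acetic acid"),
    ethyl_acetate = make_molfile(c("C", "C", "O", "O", "C", "C"),
                                 rbind(c(0, 0), c(0.866, 0.5),
                                       c(0.866, 1.5), c(1.732, 0),
                                       c(2.598, 0.5), c(3.464, 0)),
                                 list(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1),
                                      c(4, 5, 1), c(5, 6, 1)),
                                 "ethyl acetate"),
    butan2one = make_molfile(c("C", "C", "O", "C", "C"),
                             rbind(c(0, 0), c(0.866, 0.5), c(0.866, 1.5),
                                   c(1.732, 0), c(2.598, 0.5)),
                             list(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1),
                                  c(4, 5, 1)),
                             "butan-2-one"),
    butan2ol_a = butanol(1L),
    butan2ol_b = butanol(6L),
    butan2cl_a = chlorobutane(1L),
    butan2cl_b = chlorobutane(6L)
  )
}

#' Ground-truth annotations for the fixture molecules
#'
#' Ring and tetrahedral-stereocentre counts stated independently of any
#' identifier machinery, so tests can verify the connectivity-layer
#' arithmetic against them (and against a graph-cycle oracle).
#'
#' @return Data frame: `molecule`, `rings`, `stereocentres`.
#' @export
fixture_annotations <- function() {
  data.frame(
    molecule = c("methane", "water", "ammonia", "hydrogen_chloride",
                 "platinum", "hydrogen", "ethanol", "ethene", "butadiene",
                 "benzene", "cyclohexene", "acetic_acid", "ethyl_acetate",
                 "butan2one", "butan2ol_a", "butan2ol_b", "butan2cl_a",
                 "butan2cl_b"),
    rings = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L,
              0L, 0L, 0L),
    stereocentres = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                      0L, 1L, 1L, 1L, 1L)
  )
}

# One reaction template: molecule names resolved against fixture_molfiles().
fixture_reaction <- function(reactant_names, product_names,
                             agent_names = character(),
                             direction = "forward") {
  mf <- fixture_molfiles()
  grab <- function(nm) molfiles_to_inchi(mf[nm])
  reaction_record(
    reactants = grab(reactant_names),
    products = grab(product_names),
    agents = if (length(agent_names) > 0L) grab(agent_names) else list(),
    direction = direction
  )
}

#' Fixture reactions
#'
#' Reaction templates with known structural ground truth: a one-to-two
#' ester pyrolysis, an esterification equilibrium, a Diels-Alder ring
#' formation (ring change +1), an enantiomeric ketone-reduction pair
#' (stereocentre change +1, mirror forms), and a two-step chain
#' (diene + ethene -> cyclohexene -> benzene) for multistep combination.
#'
#' @return Named list of `reaction_record`s.
#' @export
fixture_reactions <- function() {
  list(
    ester_pyrolysis = fixture_reaction("ethyl_acetate",
                                       c("acetic_acid", "ethene")),
    esterification = fixture_reaction(c("acetic_acid", "ethanol"),
                                      c("ethyl_acetate", "water"),
                                      direction = "equilibrium"),
    diels_alder = fixture_reaction(c("butadiene", "ethene"), "cyclohexene",
                                   agent_names = "water"),
    reduction_a = fixture_reaction("butan2one", "butan2ol_a"),
    reduction_b = fixture_reaction("butan2one", "butan2ol_b"),
    # SN2-style substitution with inversion: chiral on both sides, so the
    # two mirror forms make an enantiomeric reaction pair
    substitution_a = fixture_reaction(c("butan2ol_a", "hydrogen_chloride"),
                                      c("butan2cl_b", "water")),
    substitution_b = fixture_reaction(c("butan2ol_b", "hydrogen_chloride"),
                                      c("butan2cl_a", "water")),
    dehydrogenation = fixture_reaction("cyclohexene",
                                       c("benzene", "hydrogen"),
                                       agent_names = "platinum")
  )
}

# ---- generated reaction families ------------------------------------------

# Linear 1-alkanol: C1-...-Cn-OH.
alkanol_molfile <- function(n) {
  make_molfile(c(rep("C", n), "O"), zigzag(n + 1L),
               lapply(seq_len(n), function(i) c(i, i + 1L, 1L)),
               title = sprintf("1-alkanol C%d", n))
}

# Linear 1-alkene: C1=C2-...-Cn.
alkene_molfile <- function(n) {
  stopifnot(n >= 2L)
  make_molfile(rep("C", n), zigzag(n),
               lapply(seq_len(n - 1L), function(i)
                 c(i, i + 1L, if (i == 1L) 2L else 1L)),
               title = sprintf("1-alkene C%d", n))
}

# ---- synthetic corpus ------------------------------------------------------

rd_record_text <- function(reactant_molfiles, product_molfiles, agents,
                           comment = NULL, rireg = NULL) {
  counts <- sprintf("%3d%3d", length(reactant_molfiles),
                    length(product_molfiles))
  out <- c(
    if (is.null(rireg)) "$RFMT" else sprintf("$RFMT $RIREG %s", rireg),
    "$RXN", "", "      rinchi", "", counts,
    unlist(lapply(c(reactant_molfiles, product_molfiles),
                  function(m) c("$MOL", m)))
  )
  for (a in agents) {
    out <- c(out,
             sprintf("$DTYPE RXN:VARIATION(%d):%s", a$variation, a$field),
             "$DATUM $MFMT",
             a$molfile)
  }
  if (!is.null(comment)) {
    out <- c(out, "$DTYPE COMMENT", paste("$DATUM", comment))
  }
  out
}

#' Generate a synthetic RDfile corpus with known ground truth
#'
#' Assembles `n_reactions` reaction entries from the fixture templates and
#' a generated homologous family (alcohol dehydrations of increasing chain
#' length), injects a fraction of exact duplicate records distinguished
#' only by a free-text comment field, and gives a fraction of the records
#' two catalyst variations (so one record expands to two identifier
#' entries).  Everything is deterministic for a fixed seed.
#'
#' The manifest records the ground truth the pipeline must reproduce:
#' per-entry template, expected duplicate-group structure, expected unique
#' and duplicate counts, expected molecule occurrence and unique-molecule
#' counts, and per-entry ring/stereocentre deltas.
#'
#' @param n_reactions Number of identifier entries the corpus expands to
#'   (variation expansion included).
#' @param dup_fraction Fraction of entries that are exact duplicates of
#'   another entry.
#' @param agent_fraction Fraction of base reactions given two agent
#'   variations instead of a single agent set.
#' @param seed Integer seed; the same seed reproduces the RDfile byte for
#'   byte.
#' @return A list with `rdfile` (text), and `manifest` (list: `entries`
#'   data frame with template/delta columns, `n_entries`, `n_unique`,
#'   `n_duplicates`, `n_molecule_occurrences`, `n_unique_molecules`).
#' @export
make_corpus <- function(n_reactions = 100L, dup_fraction = 0.1,
                        agent_fraction = 0.2, seed = 1L) {
  stopifnot(n_reactions >= 1L)
  with_seed(seed, {
    n_dup <- floor(n_reactions * dup_fraction)
    agent_pool <- list(
      list(name = "water", molfile = fixture_molfiles()$water),
      list(name = "ammonia", molfile = fixture_molfiles()$ammonia),
      list(name = "hydrogen_chloride",
           molfile = fixture_molfiles()$hydrogen_chloride),
      list(name = "platinum", molfiles = NULL,
           molfile = fixture_molfiles()$platinum)
    )

    # Base reactions (before duplication): dehydrations of chain length
    # 2, 3, 4, ... -- all pairwise distinct -- plus the named templates.
    # Records tagged for variation expand to two entries, so draw base
    # reactions until the expanded entry count reaches n_unique.
    n_unique <- n_reactions - n_dup
    base <- list()
    entries_left <- n_unique
    chain_len <- 2L
    while (entries_left > 0L) {
      two_variations <- entries_left >= 2L && stats::runif(1) < agent_fraction
      nv <- if (two_variations) 2L else 1L
      ag_idx <- sample.int(length(agent_pool), nv)
      base[[length(base) + 1L]] <- list(
        template = sprintf("dehydration_C%d", chain_len),
        reactants = list(alkanol_molfile(chain_len)),
        products = list(alkene_molfile(chain_len),
                        fixture_molfiles()$water),
        n_reactant = 1L, n_product = 2L,
        ring_delta = 0L, stereo_delta = 0L,
        agent_names = vapply(agent_pool[ag_idx], `[[`, character(1), "name"),
        agent_molfiles = lapply(agent_pool[ag_idx], `[[`, "molfile")
      )
      entries_left <- entries_left - nv
      chain_len <- chain_len + 1L
    }

    # Duplicate records: copies of randomly chosen base records, identical
    # but for a free-text comment, appended in random positions.  A copy
    # of a two-variation record contributes two duplicate entries, so
    # copies are drawn from single-variation records until the duplicate
    # budget is spent.
    singles <- which(vapply(base, function(b)
      length(b$agent_names) == 1L, logical(1)))
    dup_of <- if (n_dup > 0L)
      sample(singles, n_dup, replace = TRUE) else integer()

    records <- c(
      lapply(seq_along(base), function(i) c(base[[i]], list(copy_of = i))),
      lapply(dup_of, function(i)
        c(base[[i]], list(copy_of = i,
                          comment = sprintf("free-text note %d",
                                            stats::rpois(1, 10)))))
    )
    records <- records[sample.int(length(records))]

    rd_lines <- c("$RDFILE 1", "$DATM 2026-01-01")
    entry_rows <- list()
    for (k in seq_along(records)) {
      rec <- records[[k]]
      agents <- lapply(seq_along(rec$agent_names), function(v)
        list(variation = v, field = "CATALYST",
             molfile = rec$agent_molfiles[[v]]))
      rd_lines <- c(rd_lines,
                    rd_record_text(rec$reactants, rec$products, agents,
                                   comment = rec$comment, rireg = k))
      for (v in seq_along(rec$agent_names)) {
        entry_rows[[length(entry_rows) + 1L]] <- data.frame(
          record = k, variation = v, template = rec$template,
          agent = rec$agent_names[v],
          content_key = sprintf("%s|%s", rec$copy_of, rec$agent_names[v]),
          n_molecules = rec$n_reactant + rec$n_product + 1L,
          ring_delta = rec$ring_delta, stereo_delta = rec$stereo_delta
        )
      }
    }
    entries <- do.call(rbind, entry_rows)

    # Unique molecules across the corpus, by construction: one alkanol and
    # one alkene per chain length, water (product and sometimes agent),
    # and the non-water agents actually used.
    chain_lens <- as.integer(sub("dehydration_C", "",
                                 unique(entries$template)))
    mol_names <- c(sprintf("alkanol_C%d", chain_lens),
                   sprintf("alkene_C%d", chain_lens),
                   "water", setdiff(unique(entries$agent), "water"))

    list(
      rdfile = paste(rd_lines, collapse = "\n"),
      manifest = list(
        entries = entries,
        n_entries = nrow(entries),
        n_unique = length(unique(entries$content_key)),
        n_duplicates = nrow(entries) - length(unique(entries$content_key)),
        n_molecule_occurrences = sum(entries$n_molecules),
        n_unique_molecules = length(unique(mol_names))
      )
    )
  })
}
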