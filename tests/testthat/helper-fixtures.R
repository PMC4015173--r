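# Shared test fixtures.  Engine conversions are memoised inside the
# package, so calling these repeatedly across test files costs one obabel
# invocation per distinct molfile for the whole run.

fx_mols <- fixture_molfiles()
fx_ann <- fixture_annotations()

.fx_env <- new.env()
fx_reactions <- function() {
  if (is.null(.fx_env$rx)) .fx_env$rx <- fixture_reactions()
  .fx_env$rx
}

fx_records <- function() {
  if (is.null(.fx_env$recs)) .fx_env$recs <- molfiles_to_inchi(fx_mols)
  .fx_env$recs
}

# A pool of InChI bodies for grammar/property tests that do not need the
# engine: real bodies from the fixtures plus manufactured formula-only
# bodies (syntactically valid layer text is all the grammar cares about).
fx_body_pool <- function() {
  real <- vapply(fx_records(), function(m)
    sub("^InChI=1S/", "", m$inchi), character(1))
  fake <- sprintf("C%dH%d/c1-%d/h1H", 5:24, 12:31, 2:21)
  unique(c(unname(real), fake))
}

# Reaction built from bare InChI bodies (no engine involvement).
stub_rec <- function(reactants, products, agents = character(),
                     direction = "forward") {
  stub <- function(b) mol_record(NA_character_, paste0("InChI=1S/", b))
  reaction_record(lapply(reactants, stub), lapply(products, stub),
                  lapply(agents, stub), direction = direction)
}

# Random stub reaction built from the body pool (no engine involvement).
random_reaction <- function(pool,
                            direction = c("forward", "equilibrium",
                                          "unspecified")) {
  stub <- function(b) mol_record(NA_character_, paste0("InChI=1S/", b))
  nr <- sample(0:3, 1L)
  np <- sample(if (nr == 0L) 1:3 else 0:3, 1L)
  na <- sample(0:2, 1L)
  reaction_record(
    reactants = lapply(sample(pool, nr, replace = TRUE), stub),
    products = lapply(sample(pool, np, replace = TRUE), stub),
    agents = lapply(sample(pool, na, replace = TRUE), stub),
    direction = sample(direction, 1L)
  )
}

# Independent ring-count oracle: cycle rank of the heavy-atom graph of a
# molfile, via igraph, never via the InChI connectivity layer.
oracle_ring_count <- function(molfile) {
  ct <- rinchi:::read_ctab(molfile)
  heavy <- which(ct$atoms$symbol != "H")
  keep <- ct$bonds$from %in% heavy & ct$bonds$to %in% heavy
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = match(ct$bonds$from[keep], heavy),
                   to = match(ct$bonds$to[keep], heavy)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(heavy))
  )
  igraph::ecount(g) - igraph::vcount(g) + igraph::count_components(g)
}

# Official-engine InChIKey oracle (Open Babel embeds the official InChI
# library); used only to check the package's own implementation.
oracle_inchikey <- function(molfile) {
  f <- tempfile(fileext = ".mol")
  on.exit(unlink(f))
  writeLines(molfile, f)
  out <- suppressWarnings(
    system2("obabel", c(f, "-oinchikey"), stdout = TRUE, stderr = FALSE))
  out[nzchar(out)][1L]
}
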