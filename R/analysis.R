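# Database-scale operations on collections of RInChI strings.
#
# A corpus is a set of identifier strings plus an inverted index mapping
# every InChI body to the entries it occurs in and the role it plays
# there.  Everything below -- deduplication, partner search, ring and
# stereocentre change statistics, summaries -- works on the strings alone;
# no structure files are touched.

#' Build a RInChI corpus
#'
#' @param rinchis Character vector of RInChI strings, or a file path
#'   (one identifier per line, UTF-8) when `from_file = TRUE`.
#' @param source_ids Optional provenance tags, recycled to the entries.
#' @param from_file Read `rinchis` as a path.
#' @return An object of class `rinchi_corpus`: a list with `entries`
#'   (data frame: `rinchi`, `source_id`) and `index` (data frame: `body`,
#'   `entry`, `group`, `role`).  Roles follow the direction layer: for
#'   `/d-` group 1 holds the products; both sides of an equilibrium are
#'   `"equilibrium-participant"`; entries without a direction layer get
#'   `"unspecified-participant"`, matched by either side in searches.
#' @export
rinchi_corpus <- function(rinchis, source_ids = NULL, from_file = FALSE) {
  if (from_file) {
    source_ids <- source_ids %||% rinchis
    rinchis <- readLines(rinchis, warn = FALSE, encoding = "UTF-8")
    rinchis <- rinchis[nzchar(rinchis)]
  }
  source_ids <- rep_len(source_ids %||% "", length(rinchis))

  rows <- vector("list", length(rinchis))
  for (i in seq_along(rinchis)) {
    r <- as_rinchi(rinchis[i])
    roles12 <- switch(
      r$direction,
      plus = c("reactant", "product"),
      minus = c("product", "reactant"),
      equilibrium = c("equilibrium-participant", "equilibrium-participant"),
      omitted = c("unspecified-participant", "unspecified-participant"))
    grp <- list(r$group1, r$group2, r$group3)
    role <- c(roles12, "agent")
    bodies <- unlist(grp) %||% character()
    rows[[i]] <- if (length(bodies) == 0L) NULL else data.frame(
      body = bodies,
      entry = i,
      group = rep(1:3, times = lengths(grp)),
      role = rep(role, times = lengths(grp))
    )
  }

  structure(
    list(entries = data.frame(rinchi = as.character(rinchis),
                              source_id = source_ids),
         index = do.call(rbind, rows) %||%
           data.frame(body = character(), entry = integer(),
                      group = integer(), role = character())),
    class = "rinchi_corpus"
  )
}

#' @export
print.rinchi_corpus <- function(x, ...) {
  cat(sprintf("<rinchi_corpus> %d entries, %d molecule occurrences\n",
              nrow(x$entries), nrow(x$index)))
  invisible(x)
}

# Identifier string with the agent group and direction layer removed, for
# the opt-in "core" duplicate mode.
core_string <- function(rinchi_string) {
  r <- as_rinchi(rinchi_string)
  rinchi_serialize(new_rinchi(r$group1, r$group2, character(), "omitted"))
}

#' Find duplicate reactions
#'
#' Duplicate means byte-identical identifier string -- the sorted-list
#' semantics of deduplicating with a text sort.  Records that differ only
#' in free-text comments are duplicates by construction, because comments
#' never enter the identifier.  `mode = "core"` additionally ignores
#' agents and the direction layer.
#'
#' @param corpus A `rinchi_corpus`.
#' @param mode `"full"` (default) or `"core"`.
#' @return A list with `groups` (list of integer entry-index vectors, one
#'   per duplicated identifier), `n_unique` and `n_duplicates`
#'   (`entries - unique`).
#' @export
find_duplicates <- function(corpus, mode = c("full", "core")) {
  mode <- match.arg(mode)
  keys <- corpus$entries$rinchi
  if (mode == "core") keys <- vapply(keys, core_string, character(1))
  split_idx <- split(seq_along(keys), keys)
  groups <- unname(split_idx[lengths(split_idx) > 1L])
  groups <- groups[order(vapply(groups, min, integer(1)))]
  list(groups = groups,
       n_unique = length(split_idx),
       n_duplicates = length(keys) - length(split_idx))
}

#' Search a corpus for a reaction partner
#'
#' @param corpus A `rinchi_corpus`.
#' @param query An InChI string (`InChI=1S/...`).
#' @param role `"reactant"`, `"product"`, `"agent"` or `"any"`.  Entries
#'   whose direction layer is `/d=` (and entries with no direction layer)
#'   match both the reactant and the product role.
#' @return A data frame of matching index rows (`entry`, `group`, `role`)
#'   with the entries' identifier strings attached.
#' @export
search_partner <- function(corpus, query, role = c("any", "reactant",
                                                   "product", "agent")) {
  role <- match.arg(role)
  if (!is.character(query) || length(query) != 1L ||
      !startsWith(query, "InChI=1S/"))
    stop_validation("query must be a standard InChI ('InChI=1S/...')",
                    rule = "inchi_prefix")
  parse_inchi_layers(query)      # malformed queries error here, not silently miss
  body <- strip_inchi_prefix(query)

  idx <- corpus$index[corpus$index$body == body, , drop = FALSE]
  keep <- switch(
    role,
    any = rep(TRUE, nrow(idx)),
    agent = idx$role == "agent",
    reactant = idx$role %in% c("reactant", "equilibrium-participant",
                               "unspecified-participant"),
    product = idx$role %in% c("product", "equilibrium-participant",
                              "unspecified-participant"))
  out <- idx[keep, , drop = FALSE]
  out$rinchi <- corpus$entries$rinchi[out$entry]
  out$source_id <- corpus$entries$source_id[out$entry]
  rownames(out) <- NULL
  out
}

# ---- structural change reports --------------------------------------------

# Orient one entry's groups 1/2 by its direction layer.  For /d= and for
# entries with no direction layer there is no preferred side; deltas are
# then reported as magnitudes and flagged.
oriented_sides <- function(r) {
  switch(r$direction,
         plus = list(reactants = r$group1, products = r$group2, signed = TRUE),
         minus = list(reactants = r$group2, products = r$group1, signed = TRUE),
         list(reactants = r$group1, products = r$group2, signed = FALSE))
}

group_ring_stats <- function(bodies) {
  comps <- unlist(lapply(bodies, function(b) {
    p <- parse_inchi_layers(paste0("InChI=1S/", b))
    vapply(p$components, `[[`, integer(1), "rings")
  })) %||% integer()
  list(total = sum(comps), n_molecules = length(comps),
       n_cyclic = sum(comps >= 1L))
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Ring-change report for one reaction identifier
#'
#' Ring counts come straight from the connectivity layers: per molecule
#' (each component of a multi-component InChI counts as one molecule),
#' rings = edges - atoms + 1.  Deltas are product side minus reactant
#' side, oriented by the direction layer; entries with no usable
#' orientation (equilibrium, or no direction layer) report the magnitude
#' and set `direction_unspecified`.  Ratios with an empty denominator
#' (no molecules, or no cyclic molecules) are reported as 0 with
#' `empty_denominator` set, keeping corpus scans total.
#'
#' @param entry A RInChI string or `rinchi` object.
#' @return A list: `ring_count_delta`, `rings_per_molecule_delta`,
#'   `rings_per_cyclic_molecule_delta`, `direction_unspecified`,
#'   `empty_denominator`, and the per-side totals under `reactants` /
#'   `products`.
#' @export
ring_change <- function(entry) {
  r <- as_rinchi(entry)
  s <- oriented_sides(r)
  rs <- group_ring_stats(s$reactants)
  ps <- group_ring_stats(s$products)

  delta <- ps$total - rs$total
  per_mol <- safe_ratio(ps$total, ps$n_molecules) -
    safe_ratio(rs$total, rs$n_molecules)
  per_cyc <- safe_ratio(ps$total, ps$n_cyclic) -
    safe_ratio(rs$total, rs$n_cyclic)
  empty_den <- rs$n_molecules == 0 || ps$n_molecules == 0 ||
    rs$n_cyclic == 0 || ps$n_cyclic == 0
  if (!s$signed) {
    delta <- abs(delta); per_mol <- abs(per_mol); per_cyc <- abs(per_cyc)
  }
  list(ring_count_delta = delta,
       rings_per_molecule_delta = per_mol,
       rings_per_cyclic_molecule_delta = per_cyc,
       direction_unspecified = !s$signed,
       empty_denominator = empty_den,
       reactants = rs, products = ps)
}

group_stereo_counts <- function(bodies, stereo_mode) {
  unlist(lapply(bodies, function(b) {
    p <- parse_inchi_layers(paste0("InChI=1S/", b))
    vapply(p$components, function(comp) {
      length(comp$t) + if (stereo_mode == "t_and_b") length(comp$b) else 0L
    }, numeric(1))
  })) %||% numeric()
}

#' Stereocentre-change report for one reaction identifier
#'
#' Stereocentres are counted from the stereo layers of each molecule's
#' InChI: tetrahedral (`/t`) designations plus, by default, double-bond
#' (`/b`) designations.  The reported delta is the product-side mean per
#' molecule minus the reactant-side mean, oriented like [ring_change()].
#'
#' @param entry A RInChI string or `rinchi` object.
#' @param stereo_mode `"t_and_b"` (default) or `"t_only"`.
#' @return A list: `stereocentre_delta_per_molecule`,
#'   `stereocentre_count_delta`, `direction_unspecified`,
#'   `empty_denominator`, and per-side counts.
#' @export
stereo_change <- function(entry, stereo_mode = c("t_and_b", "t_only")) {
  stereo_mode <- match.arg(stereo_mode)
  r <- as_rinchi(entry)
  s <- oriented_sides(r)
  rc <- group_stereo_counts(s$reactants, stereo_mode)
  pc <- group_stereo_counts(s$products, stereo_mode)

  delta_mean <- safe_ratio(sum(pc), length(pc)) - safe_ratio(sum(rc), length(rc))
  delta_tot <- sum(pc) - sum(rc)
  if (!s$signed) { delta_mean <- abs(delta_mean); delta_tot <- abs(delta_tot) }
  list(stereocentre_delta_per_molecule = delta_mean,
       stereocentre_count_delta = delta_tot,
       direction_unspecified = !s$signed,
       empty_denominator = length(rc) == 0 || length(pc) == 0,
       reactants = list(total = sum(rc), n_molecules = length(rc)),
       products = list(total = sum(pc), n_molecules = length(pc)))
}

#' Ring/stereo change table for a whole corpus
#'
#' @param corpus A `rinchi_corpus`.
#' @param stereo_mode Passed to [stereo_change()].
#' @return A data frame with one row per entry and the delta columns of
#'   [ring_change()] and [stereo_change()].
#' @export
change_report <- function(corpus, stereo_mode = c("t_and_b", "t_only")) {
  stereo_mode <- match.arg(stereo_mode)
  rows <- lapply(seq_len(nrow(corpus$entries)), function(i) {
    rr <- ring_change(corpus$entries$rinchi[i])
    sc <- stereo_change(corpus$entries$rinchi[i], stereo_mode)
    data.frame(entry = i,
               ring_count_delta = rr$ring_count_delta,
               rings_per_molecule_delta = rr$rings_per_molecule_delta,
               rings_per_cyclic_molecule_delta = rr$rings_per_cyclic_molecule_delta,
               stereocentre_delta_per_molecule = sc$stereocentre_delta_per_molecule,
               direction_unspecified = rr$direction_unspecified,
               empty_denominator = rr$empty_denominator)
  })
  do.call(rbind, rows)
}

#' Corpus summary statistics
#'
#' Entry, unique-reaction and duplicate counts, molecule occurrence and
#' unique-molecule counts over all three groups, and -- when the source
#' reaction file text is supplied -- the size of the one-identifier-per-
#' line corpus relative to its source.
#'
#' @param corpus A `rinchi_corpus`.
#' @param source_text Optional source RD/RXN file text (or its byte size)
#'   for the compression ratio.
#' @return A list of counts; `compression_ratio` is RInChI bytes divided
#'   by source bytes (`NA` without a source).
#' @export
corpus_stats <- function(corpus, source_text = NULL) {
  dup <- find_duplicates(corpus)
  corpus_bytes <- sum(nchar(corpus$entries$rinchi, type = "bytes") + 1L)
  source_bytes <- if (is.null(source_text)) NA_real_
    else if (is.numeric(source_text)) source_text
    else sum(nchar(source_text, type = "bytes") + 1L)
  list(
    n_entries = nrow(corpus$entries),
    n_unique_reactions = dup$n_unique,
    n_duplicates = dup$n_duplicates,
    n_molecule_occurrences = nrow(corpus$index),
    n_unique_molecules = length(unique(corpus$index$body)),
    corpus_bytes = corpus_bytes,
    source_bytes = source_bytes,
    compression_ratio = if (is.na(source_bytes)) NA_real_
      else corpus_bytes / source_bytes
  )
}
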