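# Reading and writing MDL reaction files.
#
# RXNfiles hold one reaction: a header, a counts line, and the reactant
# and product molfiles each introduced by "$MOL".  RDfiles wrap many such
# reactions, each introduced by "$RFMT", and attach data fields ($DTYPE /
# $DATUM pairs) that may embed agent molfiles -- catalysts, solvents,
# reagents -- possibly tagged with a variation index.

#' Reaction record
#'
#' @param reactants,products,agents Lists of [mol_record()]s (may be
#'   empty; a reaction without a known product is valid).
#' @param direction One of `"forward"`, `"backward"`, `"equilibrium"`,
#'   `"unspecified"`.  RXN input is always `"forward"`: the arrow points
#'   left to right.
#' @param source_id Free-text provenance tag; never part of the identity.
#' @param data Named character vector of free-text data fields carried
#'   along from an RDfile record.
#' @return An object of class `reaction_record`.
#' @export
reaction_record <- function(reactants = list(), products = list(),
                            agents = list(),
                            direction = c("forward", "backward",
                                          "equilibrium", "unspecified"),
                            source_id = "", data = character()) {
  direction <- match.arg(direction)
  structure(
    list(reactants = reactants, products = products, agents = agents,
         direction = direction, source_id = source_id, data = data),
    class = "reaction_record"
  )
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record> %d reactant(s) -> %d product(s), %d agent(s), %s\n",
              length(x$reactants), length(x$products), length(x$agents),
              x$direction))
  invisible(x)
}

# Slice the lines of one molfile (everything up to and including M  END)
# starting at `from`; returns list(text, next_line).
take_molfile <- function(lines, from, index = NA_integer_) {
  ends <- which(trimws(lines) == "M  END")
  ends <- ends[ends >= from]
  if (length(ends) == 0L)
    stop_format(sprintf("molfile %s is truncated (no 'M  END')",
                        ifelse(is.na(index), "", index)), index = index)
  list(text = paste(lines[from:ends[1L]], collapse = "\n"),
       next_line = ends[1L] + 1L)
}

#' Read an RXNfile
#'
#' The declared reactant/product counts must match the embedded molfiles:
#' the first *N* molfiles are reactants, the next *M* products.  A third
#' count, the agent-bearing dialect some vendors write, is honoured when
#' present.  The arrow of an RXN is directional, so the record's direction
#' is `"forward"`.
#'
#' @param text RXNfile text (string or character vector of lines).
#' @param compute_inchi Derive InChIs for all molecules through the engine
#'   (default `TRUE`).
#' @return A `reaction_record`.
#' @export
read_rxn <- function(text, compute_inchi = TRUE) {
  lines <- split_lines(text)
  if (length(lines) < 5L || !startsWith(lines[1L], "$RXN"))
    stop_format("not an RXNfile: missing '$RXN' header", index = 1L)
  counts <- lines[5L]
  n_r <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_p <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  n_a <- suppressWarnings(as.integer(substr(counts, 7L, 9L)))
  if (is.na(n_r) || is.na(n_p))
    stop_format(sprintf("unreadable RXN counts line: %s", dQuote(counts)))
  if (is.na(n_a)) n_a <- 0L

  mol_starts <- which(trimws(lines) == "$MOL")
  n_total <- n_r + n_p + n_a
  if (length(mol_starts) != n_total)
    stop_format(sprintf(
      "RXN declares %d molecule(s) but embeds %d '$MOL' block(s)",
      n_total, length(mol_starts)), index = length(mol_starts) + 1L)

  molfiles <- vector("list", n_total)
  for (i in seq_len(n_total))
    molfiles[[i]] <- take_molfile(lines, mol_starts[i] + 1L, index = i)$text

  mols <- if (compute_inchi && n_total > 0L) {
    molfiles_to_inchi(molfiles)
  } else {
    lapply(molfiles, function(m)
      structure(list(molfile = m, inchi = NULL, auxinfo = NULL),
                class = "mol_record"))
  }

  reaction_record(
    reactants = mols[seq_len(n_r)],
    products = if (n_p > 0L) mols[n_r + seq_len(n_p)] else list(),
    agents = if (n_a > 0L) mols[n_r + n_p + seq_len(n_a)] else list(),
    direction = "forward",
    source_id = trimws(lines[2L])
  )
}

mol_text <- function(m) {
  if (is.character(m$molfile) && !is.na(m$molfile)) return(m$molfile)
  if (!is.null(m$inchi)) return(inchi_to_molfile(m$inchi, m$auxinfo))
  stop_format("molecule has neither a molfile nor an InChI")
}

#' Write an RXNfile
#'
#' Agents are emitted as trailing molfiles only in the (non-standard)
#' agent-count dialect selected by `include_agents = TRUE`; the default
#' strict dialect drops them with a warning, since a plain RXN has nowhere
#' to put them.
#'
#' @param rxn A `reaction_record`.
#' @param include_agents Emit agents using a third count field.
#' @return RXNfile text.
#' @export
write_rxn <- function(rxn, include_agents = FALSE) {
  stopifnot(inherits(rxn, "reaction_record"))
  agents <- rxn$agents
  if (length(agents) > 0L && !include_agents) {
    warning("RXN output has no agent slot; ", length(agents),
            " agent(s) dropped (use include_agents = TRUE to keep them)")
    agents <- list()
  }
  counts <- if (include_agents && length(agents) > 0L)
    sprintf("%3d%3d%3d", length(rxn$reactants), length(rxn$products),
            length(agents))
  else
    sprintf("%3d%3d", length(rxn$reactants), length(rxn$products))
  blocks <- unlist(lapply(c(rxn$reactants, rxn$products, agents),
                          function(m) c("$MOL", mol_text(m))))
  paste(c("$RXN", rxn$source_id, "      rinchi", "", counts, blocks),
        collapse = "\n")
}

# Move species appearing identically on both sides of the arrow into the
# agent group: group 3 is defined as the molecules present on both sides.
# One agent copy is created per matched reactant/product pair.
reclassify_agents <- function(rxn) {
  key <- function(m) m$inchi %||% m$molfile
  rk <- vapply(rxn$reactants, key, character(1))
  pk <- vapply(rxn$products, key, character(1))
  drop_r <- integer(); drop_p <- integer()
  for (i in seq_along(rk)) {
    j <- which(pk == rk[i] & !(seq_along(pk) %in% drop_p))
    if (length(j) > 0L) { drop_r <- c(drop_r, i); drop_p <- c(drop_p, j[1L]) }
  }
  if (length(drop_r) == 0L) return(rxn)
  rxn$agents <- c(rxn$agents, rxn$reactants[drop_r])
  rxn$reactants <- rxn$reactants[-drop_r]
  rxn$products <- rxn$products[-drop_p]
  rxn
}

#' Read an RDfile
#'
#' Splits the file into `$RFMT` records, reads each embedded RXN, and
#' routes `$DTYPE`/`$DATUM` molfile fields whose names match the
#' configured agent patterns into the record's agent list (keeping any
#' `VARIATION(k)` index for [expand_variations()]).  Free-text datums are
#' retained under `$data` but never affect identity.  A malformed record
#' produces a per-record error in the `errors` attribute; the remaining
#' records are still returned.
#'
#' @param text RDfile text.
#' @param config A [rinchi_config()]; `agent_field_patterns` decides which
#'   data fields hold agents.
#' @param compute_inchi Derive InChIs through the engine.
#' @return A list of `reaction_record`s; failed records are reported in
#'   `attr(, "errors")` (named by record index).
#' @export
read_rdfile <- function(text, config = rinchi_config(), compute_inchi = TRUE) {
  lines <- split_lines(text)
  if (length(lines) < 1L || !startsWith(lines[1L], "$RDFILE"))
    stop_format("not an RDfile: missing '$RDFILE' header", index = 1L)

  starts <- which(startsWith(lines, "$RFMT"))
  if (length(starts) == 0L) return(list())
  bounds <- c(starts, length(lines) + 1L)

  records <- list()
  errors <- character()
  for (k in seq_along(starts)) {
    chunk <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    rec <- tryCatch(
      read_rd_record(chunk, config, compute_inchi, k),
      rinchi_error = function(e) e
    )
    if (inherits(rec, "condition")) {
      errors[as.character(k)] <- conditionMessage(rec)
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  attr(records, "errors") <- errors
  records
}

read_rd_record <- function(chunk, config, compute_inchi, k) {
  rireg <- regmatches(chunk[1L], regexec("\\$RIREG\\s+(\\S+)", chunk[1L]))[[1L]]
  source_id <- if (length(rireg) == 2L) paste("RIREG", rireg[2L])
               else sprintf("record %d", k)

  rxn_at <- which(startsWith(chunk, "$RXN"))
  if (length(rxn_at) == 0L)
    stop_format(sprintf("record %d has no embedded $RXN", k), index = k)
  dtype_at <- which(startsWith(chunk, "$DTYPE"))
  rxn_end <- if (length(dtype_at) > 0L) dtype_at[1L] - 1L else length(chunk)
  rec <- read_rxn(chunk[rxn_at[1L]:rxn_end], compute_inchi = compute_inchi)
  rec$source_id <- source_id

  agent_molfiles <- list()
  agent_variation <- integer()
  data <- character()
  pat <- paste0("(", paste(config$agent_field_patterns, collapse = ")|("), ")")
  i <- 1L
  while (i <= length(chunk)) {
    if (startsWith(chunk[i], "$DTYPE")) {
      dname <- trimws(sub("^\\$DTYPE", "", chunk[i]))
      if (i + 1L > length(chunk) || !startsWith(chunk[i + 1L], "$DATUM"))
        stop_format(sprintf("record %d: $DTYPE %s has no $DATUM", k, dname),
                    index = k)
      dval <- trimws(sub("^\\$DATUM", "", chunk[i + 1L]))
      if (startsWith(dval, "$MFMT")) {
        mf <- take_molfile(chunk, i + 2L, index = k)
        if (grepl(pat, dname, ignore.case = TRUE)) {
          v <- regmatches(dname,
                          regexec("VARIATION\\((\\d+)\\)", dname,
                                  ignore.case = TRUE))[[1L]]
          agent_molfiles[[length(agent_molfiles) + 1L]] <- mf$text
          agent_variation <- c(agent_variation,
                               if (length(v) == 2L) as.integer(v[2L]) else NA_integer_)
        }
        i <- mf$next_line
      } else {
        data[dname] <- dval
        i <- i + 2L
      }
    } else {
      i <- i + 1L
    }
  }

  if (length(agent_molfiles) > 0L) {
    agents <- if (compute_inchi) molfiles_to_inchi(agent_molfiles)
              else lapply(agent_molfiles, function(m)
                structure(list(molfile = m, inchi = NULL, auxinfo = NULL),
                          class = "mol_record"))
    for (j in seq_along(agents)) attr(agents[[j]], "variation") <- agent_variation[j]
    rec$agents <- c(rec$agents, agents)
  }
  rec$data <- data
  reclassify_agents(rec)
}

#' Expand the agent variations of an RDfile record
#'
#' A record whose agent fields carry `VARIATION(k)` indices describes one
#' core reaction run under several agent sets.  This returns one
#' `reaction_record` per variation, each sharing the reactants and
#' products and holding that variation's agents (plus any agents with no
#' variation index, which belong to every variation).  A record without
#' variation tags expands to itself.
#'
#' @param rxn A `reaction_record` from [read_rdfile()].
#' @return A list of `reaction_record`s, one per variation.
#' @export
expand_variations <- function(rxn) {
  stopifnot(inherits(rxn, "reaction_record"))
  vars <- vapply(rxn$agents, function(a)
    attr(a, "variation") %||% NA_integer_, integer(1))
  idx <- sort(unique(vars[!is.na(vars)]))
  if (length(idx) == 0L) return(list(rxn))
  lapply(idx, function(v) {
    out <- rxn
    out$agents <- rxn$agents[is.na(vars) | vars == v]
    out$source_id <- sprintf("%s variation %d", rxn$source_id, v)
    out
  })
}
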