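# Combining an ordered sequence of single-step identifiers into one
# overall-reaction identifier.
#
# Working purely on sets of InChI bodies: species consumed before they are
# ever produced open the overall reaction, species produced after they are
# last consumed close it, and everything that lives only in the middle is
# an intermediate that cancels out.  All step agents merge into group 3 --
# once steps are combined the identifier can no longer distinguish
# reagents, solvents and catalysts of the intermediate steps.

orient_step <- function(r, k, override) {
  ov <- if (length(override) >= k) override[k] else NA_character_
  flip <- switch(
    r$direction,
    plus = FALSE,
    minus = TRUE,
    equilibrium = {
      if (is.na(ov))
        stop_validation(sprintf(
          "step %d is an equilibrium; supply orientation[%d] = 'forward' or 'backward'",
          k, k), rule = "orientation")
      identical(ov, "backward")
    },
    omitted = {
      if (is.na(ov)) FALSE else identical(ov, "backward")
    })
  if (flip) list(reactants = r$group2, products = r$group1, agents = r$group3)
  else list(reactants = r$group1, products = r$group2, agents = r$group3)
}

#' Combine a multistep sequence into an overall RInChI
#'
#' Takes the single-step RInChIs in their sequential order and produces
#' the identifier of the overall transformation: the initial starting
#' materials, the final products, and -- in group 3 -- every agent of
#' every step.  Intermediates (produced in one step, consumed in a later
#' one) vanish from groups 1/2.  A species that qualifies as both an
#' overall starting material and an overall product (for example a
#' catalyst consumed in the first step and regenerated in the last) is
#' reported as an agent, keeping each species in exactly one group.
#' Orientation is taken from each step's direction layer; equilibrium
#' steps are rejected unless an explicit orientation override says which
#' way they ran, and steps without a direction layer are read as written
#' unless overridden.
#'
#' @param steps A list of `rinchi` objects or RInChI strings, in order
#'   (length >= 1).
#' @param orientation Optional character vector (`"forward"`/
#'   `"backward"`, `NA` to not override) recycled over the steps.
#' @return A `rinchi` object for the overall reaction.
#' @export
combine_steps <- function(steps, orientation = NA_character_) {
  if (length(steps) < 1L)
    stop_validation("a step sequence needs at least one step", rule = "length")
  steps <- lapply(steps, as_rinchi)
  orientation <- rep_len(orientation, length(steps))
  oriented <- lapply(seq_along(steps), function(k)
    orient_step(steps[[k]], k, orientation))

  species <- unique(unlist(lapply(oriented, function(s)
    c(s$reactants, s$products))))
  n <- length(steps)
  first_consumed <- last_consumed <- first_produced <- last_produced <-
    stats::setNames(rep(NA_integer_, length(species)), species)
  for (k in seq_len(n)) {
    s <- oriented[[k]]
    for (b in unique(s$reactants)) {
      if (is.na(first_consumed[b])) first_consumed[b] <- k
      last_consumed[b] <- k
    }
    for (b in unique(s$products)) {
      if (is.na(first_produced[b])) first_produced[b] <- k
      last_produced[b] <- k
    }
  }

  is_reactant <- !is.na(first_consumed) &
    (is.na(first_produced) | first_consumed <= first_produced)
  is_product <- !is.na(last_produced) &
    (is.na(last_consumed) | last_produced >= last_consumed)

  both <- is_reactant & is_product         # unchanged end to end: agent
  reactants <- species[is_reactant & !both]
  products <- species[is_product & !both]
  agents <- unique(c(unlist(lapply(oriented, `[[`, "agents")), species[both]))

  stub <- function(b) mol_record(NA_character_, paste0("InChI=1S/", b))
  build_rinchi(reaction_record(
    reactants = lapply(reactants, stub),
    products = lapply(products, stub),
    agents = lapply(agents, stub),
    direction = "forward"
  ))$rinchi
}
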