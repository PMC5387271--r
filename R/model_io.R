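#' Read a model from its YAML description
#'
#' The model dialect is a small YAML document:
#'
#' \preformatted{
#' name: insulin_receptor
#' species:
#'   - {name: IR_beta, initial: 16}
#'   - {name: insulin, initial: 1, fixed: true}
#' reactions:
#'   - "IR_beta + insulin -> IR_beta_pY1164 : k1"
#'   - "IR_beta_pY1164 -> IR_beta_refrac : k2"
#'   - "IR_beta_refrac -> IR_beta : k3"
#' parameters: {k1: 0.5, k2: 1.0, k3: 0.1}
#' readouts: [IR_beta_pY1164]
#' }
#'
#' Reaction strings are `"reactants -> products : rate"` with `+`-separated
#' multisets; an empty side denotes a constant source or a sink. `readouts`
#' is optional and defaults to all non-fixed species.
#'
#' @param path Path to the YAML file.
#' @return A `"reaction_model"`.
#' @seealso [write_model_yaml()] for the inverse; the pair round-trips.
#' @export
read_model_yaml <- function(path) {
  kp_check(file.exists(path), sprintf("model file not found: %s", path))
  doc <- yaml::read_yaml(path)
  for (key in c("species", "reactions", "parameters")) {
    kp_check(!is.null(doc[[key]]), sprintf("model YAML lacks required key '%s'", key))
  }
  sp <- lapply(doc$species, function(s) {
    kp_check(!is.null(s$name) && !is.null(s$initial),
             "each species needs 'name' and 'initial'")
    species(s$name, s$initial, fixed = isTRUE(s$fixed))
  })
  rx <- lapply(doc$reactions, parse_reaction)
  pars <- unlist(doc$parameters)
  reaction_model(sp, rx, pars, readouts = doc$readouts)
}

# "A + B -> C : k" -> reaction(); either side may be empty.
parse_reaction <- function(s) {
  kp_check(is.character(s) && length(s) == 1L, "reaction entries must be strings")
  main <- strsplit(s, ":", fixed = TRUE)[[1]]
  kp_check(length(main) == 2L,
           sprintf("malformed reaction '%s': expected 'reactants -> products : rate'", s))
  rate <- trimws(main[2])
  sides <- strsplit(main[1], "->", fixed = TRUE)[[1]]
  kp_check(length(sides) == 2L || (length(sides) == 1L && grepl("->", main[1])),
           sprintf("malformed reaction '%s': missing '->'", s))
  side <- function(txt) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(character())
    trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  }
  lhs <- if (length(sides) >= 1L) side(sides[1]) else character()
  rhs <- if (length(sides) >= 2L) side(sides[2]) else character()
  reaction(lhs, rhs, rate = rate)
}

#' Write a model to the YAML dialect
#'
#' @param model A `"reaction_model"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  kp_check(inherits(model, "reaction_model"), "model must be a reaction_model")
  sp <- lapply(seq_len(nrow(model$species)), function(i) {
    s <- list(name = model$species$name[i], initial = model$species$initial[i])
    if (model$species$fixed[i]) s$fixed <- TRUE
    s
  })
  rx <- vapply(model$reactions, function(r) {
    sprintf("%s -> %s : %s",
            paste(r$reactants, collapse = " + "),
            paste(r$products, collapse = " + "),
            r$rate)
  }, character(1))
  doc <- list(species = sp,
              reactions = as.list(rx),
              parameters = as.list(model$parameters),
              readouts = model$readouts)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
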