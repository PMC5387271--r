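#' Define a chemical species
#'
#' A species has a name, a non-negative initial amount (molecule count or
#' concentration) and an optional `fixed` flag. Fixed species act as constant
#' inputs: reactions never change their amount, so they enter propensities as
#' constant factors. The canonical example is an extracellular ligand such as
#' insulin held at its stimulation level.
#'
#' @param name Species identifier (non-empty string).
#' @param initial_amount Non-negative initial amount.
#' @param fixed Logical; if `TRUE` the amount is held constant.
#' @return An object of class `"kp_species"`.
#' @export
#' @examples
#' species("insulin", 1, fixed = TRUE)
species <- function(name, initial_amount, fixed = FALSE) {
  kp_check(is.character(name) && length(name) == 1L && nzchar(name),
           "species name must be a non-empty string")
  kp_check(is.numeric(initial_amount) && length(initial_amount) == 1L &&
             is.finite(initial_amount) && initial_amount >= 0,
           sprintf("initial amount of '%s' must be a finite non-negative number", name))
  structure(list(name = name,
                 initial_amount = as.numeric(initial_amount),
                 fixed = isTRUE(fixed)),
            class = "kp_species")
}

#' Define a mass-action reaction
#'
#' Reactants and products are multisets of species names, given as character
#' vectors with repetition (e.g. `c("A", "A")` for `2A`). The kinetics are
#' mass action: the propensity is the rate parameter times the product of the
#' current reactant amounts (one factor per multiset entry).
#'
#' @param reactants Character vector of reactant species names (may be empty
#'   for a constant source).
#' @param products Character vector of product species names (may be empty
#'   for a sink).
#' @param rate Name of the kinetic rate parameter.
#' @return An object of class `"kp_reaction"`.
#' @export
#' @examples
#' reaction(c("IR_beta", "insulin"), "IR_beta_pY1164", rate = "k1")
reaction <- function(reactants, products, rate) {
  kp_check(is.character(rate) && length(rate) == 1L && nzchar(rate),
           "rate must name a single kinetic parameter")
  reactants <- as.character(reactants %||% character())
  products <- as.character(products %||% character())
  structure(list(reactants = reactants, products = products, rate = rate),
            class = "kp_reaction")
}

#' Assemble a mass-action reaction model
#'
#' Validates cross-references (every reaction rate exists in the parameter
#' table, every named species is declared), positivity of parameters and the
#' presence of at least one non-fixed species, and freezes the result into a
#' simulable `"reaction_model"`.
#'
#' @param species A list of [species()] objects.
#' @param reactions A list of [reaction()] objects.
#' @param parameters Named numeric vector of positive kinetic parameters.
#' @param readouts Character vector of species names to report in simulation
#'   output; defaults to all non-fixed species.
#' @return An object of class `"reaction_model"`.
#' @seealso [ir_receptor_model()] for the bundled insulin-receptor example.
#' @export
reaction_model <- function(species, reactions, parameters, readouts = NULL) {
  kp_check(is.list(species) && length(species) > 0L &&
             all(vapply(species, inherits, logical(1), "kp_species")),
           "species must be a non-empty list of species() objects")
  kp_check(is.list(reactions) &&
             all(vapply(reactions, inherits, logical(1), "kp_reaction")),
           "reactions must be a list of reaction() objects")
  nm <- vapply(species, `[[`, character(1), "name")
  kp_check(!anyDuplicated(nm), "species names must be unique")
  kp_check(is.numeric(parameters) && length(parameters) > 0L &&
             !is.null(names(parameters)) && all(nzchar(names(parameters))),
           "parameters must be a named numeric vector")
  kp_check(all(is.finite(parameters)) && all(parameters > 0),
           "all kinetic parameters must be positive")
  for (r in reactions) {
    kp_check(r$rate %in% names(parameters),
             sprintf("rate parameter '%s' is not in the parameter table", r$rate))
    unknown <- setdiff(c(r$reactants, r$products), nm)
    kp_check(length(unknown) == 0L,
             sprintf("reaction references undeclared species: %s",
                     paste(unknown, collapse = ", ")))
  }
  fixed <- vapply(species, `[[`, logical(1), "fixed")
  kp_check(any(!fixed), "model must contain at least one non-fixed species")
  readouts <- readouts %||% nm[!fixed]
  kp_check(all(readouts %in% nm), "readouts must name declared species")
  structure(list(
    species = data.frame(
      name = nm,
      initial = vapply(species, `[[`, numeric(1), "initial_amount"),
      fixed = fixed,
      stringsAsFactors = FALSE),
    reactions = lapply(reactions, unclass),
    parameters = parameters,
    readouts = as.character(readouts)
  ), class = "reaction_model")
}

#' @export
print.reaction_model <- function(x, ...) {
  cat(sprintf("Mass-action reaction model: %d species, %d reactions, %d parameters\n",
              nrow(x$species), length(x$reactions), length(x$parameters)))
  for (r in x$reactions) {
    cat(sprintf("  %s -> %s : %s = %g\n",
                if (length(r$reactants)) paste(r$reactants, collapse = " + ") else "0",
                if (length(r$products)) paste(r$products, collapse = " + ") else "0",
                r$rate, x$parameters[[r$rate]]))
  }
  fx <- x$species$name[x$species$fixed]
  if (length(fx)) cat("  fixed inputs:", paste(fx, collapse = ", "), "\n")
  cat("  readouts:", paste(x$readouts, collapse = ", "), "\n")
  invisible(x)
}

#' Minimal insulin-receptor activation model
#'
#' A three-state model of insulin receptor beta activation. In the presence of
#' insulin (a fixed input), the receptor is phosphorylated on tyrosine 1164;
#' the phosphorylated receptor is then dephosphorylated into a refractory
#' state that lumps internalisation, degradation and synthesis into a single
#' delay, from which the receptor becomes functional again:
#'
#' \preformatted{
#'   IR_beta + insulin -> IR_beta_pY1164   (k1)
#'   IR_beta_pY1164    -> IR_beta_refrac   (k2)
#'   IR_beta_refrac    -> IR_beta          (k3)
#' }
#'
#' The cyclic stoichiometry conserves the total receptor amount. Default rate
#' and initial values are package choices for a plausible minutes-scale
#' response (they are not literature-fitted estimates): with the defaults the
#' phosphorylation peak falls within the first five minutes of stimulation.
#'
#' @param k1 Phosphorylation rate (per minute per unit insulin), > 0.
#' @param k2 Dephosphorylation/inactivation rate (per minute), > 0.
#' @param k3 Recovery rate from the refractory state (per minute), > 0.
#' @param ir0 Initial amount of unphosphorylated receptor, > 0.
#' @param insulin0 Fixed insulin level.
#' @return A `"reaction_model"` with readout `IR_beta_pY1164`.
#' @export
#' @examples
#' m <- ir_receptor_model()
#' stoichiometry_matrix(m)
ir_receptor_model <- function(k1 = 0.5, k2 = 1.0, k3 = 0.1,
                              ir0 = 16, insulin0 = 1) {
  for (v in c(k1 = k1, k2 = k2, k3 = k3)) {
    kp_check(is.numeric(v) && is.finite(v) && v > 0,
             "all rate constants must be positive")
  }
  kp_check(is.numeric(ir0) && ir0 > 0, "ir0 must be positive")
  kp_check(is.numeric(insulin0) && insulin0 >= 0, "insulin0 must be non-negative")
  reaction_model(
    species = list(
      species("IR_beta", ir0),
      species("IR_beta_pY1164", 0),
      species("IR_beta_refrac", 0),
      species("insulin", insulin0, fixed = TRUE)),
    reactions = list(
      reaction(c("IR_beta", "insulin"), "IR_beta_pY1164", rate = "k1"),
      reaction("IR_beta_pY1164", "IR_beta_refrac", rate = "k2"),
      reaction("IR_beta_refrac", "IR_beta", rate = "k3")),
    parameters = c(k1 = k1, k2 = k2, k3 = k3),
    readouts = c("IR_beta", "IR_beta_pY1164", "IR_beta_refrac"))
}

#' Stoichiometry matrix of a model
#'
#' Column r gives the net change of each species when reaction r fires.
#' Rows of fixed species are identically zero (constant inputs).
#'
#' @param model A `"reaction_model"`.
#' @return Integer matrix, species x reactions, with dimnames.
#' @export
stoichiometry_matrix <- function(model) {
  kp_check(inherits(model, "reaction_model"), "model must be a reaction_model")
  nm <- model$species$name
  S <- matrix(0L, nrow = length(nm), ncol = length(model$reactions),
              dimnames = list(nm, vapply(model$reactions, `[[`, character(1), "rate")))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in r$reactants) S[s, j] <- S[s, j] - 1L
    for (s in r$products) S[s, j] <- S[s, j] + 1L
  }
  S[model$species$fixed, ] <- 0L
  S
}

# Effective linear/affine decomposition of the propensity vector: for each
# reaction, the product of fixed-reactant initial amounts folds into an
# effective rate; at most one non-fixed reactant (multiplicity 1) is allowed.
# Returns list(A, b) with d x/dt = A x + b over the free species, or signals
# an unsupported-model error for nonlinear kinetics.
linear_rate_system <- function(model) {
  S <- stoichiometry_matrix(model)
  free <- !model$species$fixed
  free_names <- model$species$name[free]
  init <- stats::setNames(model$species$initial, model$species$name)
  n <- length(free_names)
  A <- matrix(0, n, n, dimnames = list(free_names, free_names))
  b <- stats::setNames(numeric(n), free_names)
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    fr <- r$reactants[r$reactants %in% free_names]
    eff <- model$parameters[[r$rate]] *
      prod(init[r$reactants[!(r$reactants %in% free_names)]])
    if (length(fr) == 0L) {
      b <- b + S[free_names, j] * eff
    } else if (length(fr) == 1L) {
      A[, fr] <- A[, fr] + S[free_names, j] * eff
    } else {
      kp_stop(sprintf(
        "reaction %d has %d non-fixed reactants: propensity is nonlinear, analytic solution unsupported",
        j, length(fr)), "kinpipe_unsupported_model_error")
    }
  }
  list(A = A, b = b, free_names = free_names)
}

#' Analytic solution of a linear kinetic model
#'
#' Exact trajectory for models whose propensities are linear (at most affine)
#' in the non-fixed species — true of any mass-action network in which each
#' reaction consumes at most one non-fixed molecule, such as the
#' insulin-receptor model with insulin fixed. The solution is computed by
#' matrix exponential of the (augmented, if a constant source is present)
#' rate matrix at each requested time, and serves as an independent oracle
#' for the numerical simulators.
#'
#' @param model A `"reaction_model"` with linear kinetics.
#' @param times Increasing numeric vector of time points (first >= 0).
#' @return A [time_course()] over the model readouts.
#' @export
linear_solution <- function(model, times) {
  check_times(times)
  sys <- linear_rate_system(model)
  x0 <- model$species$initial[!model$species$fixed]
  n <- length(x0)
  # augmented generator handles the affine term via exp([[A,b],[0,0]] t)
  M <- rbind(cbind(sys$A, sys$b), 0)
  vals <- matrix(NA_real_, length(times), n, dimnames = list(NULL, sys$free_names))
  for (i in seq_along(times)) {
    e <- as.matrix(Matrix::expm(Matrix::Matrix(M * times[i])))
    vals[i, ] <- e[seq_len(n), , drop = FALSE] %*% c(x0, 1)
  }
  full <- readout_matrix(model, times, vals)
  time_course(times, full)
}

# Assemble the readout matrix from the free-species solution, padding fixed
# species with their constant amounts.
readout_matrix <- function(model, times, free_vals) {
  out <- matrix(NA_real_, length(times), length(model$readouts),
                dimnames = list(NULL, model$readouts))
  for (v in model$readouts) {
    i <- match(v, model$species$name)
    out[, v] <- if (model$species$fixed[i]) model$species$initial[i] else free_vals[, v]
  }
  out
}

check_times <- function(times) {
  kp_check(is.numeric(times) && length(times) >= 1L && all(is.finite(times)),
           "times must be a finite numeric vector")
  kp_check(times[1] >= 0 && all(diff(times) > 0),
           "times must be strictly increasing with times[1] >= 0")
  invisible(TRUE)
}

# Replace a kinetic parameter or a species initial amount by name; used by the
# scan module. Returns a modified copy (models are immutable values).
set_quantity <- function(model, name, value) {
  if (name %in% names(model$parameters)) {
    kp_check(is.finite(value) && value > 0,
             sprintf("scanned parameter '%s' must stay positive", name))
    model$parameters[[name]] <- value
  } else if (name %in% model$species$name) {
    kp_check(is.finite(value) && value >= 0,
             sprintf("initial amount of '%s' must stay non-negative", name))
    model$species$initial[model$species$name == name] <- value
  } else {
    kp_stop(sprintf("'%s' is neither a parameter nor a species of the model", name),
            "kinpipe_validation_error")
  }
  model
}

get_quantity <- function(model, name) {
  if (name %in% names(model$parameters)) return(model$parameters[[name]])
  if (name %in% model$species$name)
    return(model$species$initial[model$species$name == name])
  kp_stop(sprintf("'%s' is neither a parameter nor a species of the model", name),
          "kinpipe_validation_error")
}
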