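## Built-in reaction models. Lotka-Volterra is the demonstration system;
## immigration-death and pure-death have closed-form transient laws and serve
## as analytic oracles for the density estimators.

#' Stochastic Lotka-Volterra predator-prey model
#'
#' Three mass-action reactions: prey birth (`Preys += 1`, propensity
#' `k1 * Preys`), predation (`Preys -= 1`, `Predators += 1`, propensity
#' `k2 * Preys * Predators`) and predator death (`Predators -= 1`, propensity
#' `k3 * Predators`).
#'
#' The defaults place the coexistence equilibrium at
#' `(Preys, Predators) = (k3/k2, k1/k2) = (250, 250)` and start the system
#' there; the deterministic oscillation period around that point is
#' `2 * pi / sqrt(k1 * k3) ~ 6.3` time units, and at this population scale
#' both species persist beyond t = 100 in most stochastic runs. Oscillation
#' period and survival are parameter-dependent, not properties of the model
#' family.
#'
#' @param k1 prey birth rate constant (per prey per unit time).
#' @param k2 predation rate constant (per prey-predator pair per unit time).
#' @param k3 predator death rate constant (per predator per unit time).
#' @param prey0,pred0 initial copy numbers.
#' @return A [ReactionModel-class] with species `Preys`, `Predators`.
#' @export
lotkaVolterra <- function(k1 = 1, k2 = 0.004, k3 = 1, prey0 = 250L, pred0 = 250L) {
  if (any(c(k1, k2, k3) < 0)) stop("parameter error: rate constants must be >= 0")
  if (prey0 < 0 || pred0 < 0) stop("parameter error: initial counts must be >= 0")
  reactionModel(
    species = c("Preys", "Predators"),
    reactions = list(
      list(change = c(1L, 0L),  rate = k1, reactants = c(1L, 0L)),   # prey birth
      list(change = c(-1L, 1L), rate = k2, reactants = c(1L, 1L)),   # predation
      list(change = c(0L, -1L), rate = k3, reactants = c(0L, 1L))),  # predator death
    x0 = c(prey0, pred0), label = "lotka-volterra")
}

#' Immigration-death process
#'
#' Constant influx at rate `k` and per-capita death at rate `mu`. Starting
#' from `x0 = 0` the transient law is exactly
#' `X(t) ~ Poisson((k/mu) * (1 - exp(-mu * t)))`, with stationary mean
#' `k/mu` — an exact oracle for density estimation.
#'
#' @param k immigration rate (events per unit time).
#' @param mu per-capita death rate.
#' @param x0 initial copy number (default 0, for the Poisson law above).
#' @return A [ReactionModel-class] with species `X`.
#' @export
immigrationDeath <- function(k, mu, x0 = 0L) {
  if (k < 0 || mu < 0) stop("parameter error: rates must be >= 0")
  reactionModel(
    species = "X",
    reactions = list(
      list(change = 1L,  rate = k,  reactants = 0L),
      list(change = -1L, rate = mu, reactants = 1L)),
    x0 = x0, label = "immigration-death")
}

#' Pure-death process
#'
#' `n0` independent particles each dying at per-capita rate `mu`:
#' `X(t) ~ Binomial(n0, exp(-mu * t))` exactly — the transient oracle for the
#' master-equation estimator.
#'
#' @param mu per-capita death rate.
#' @param n0 initial copy number.
#' @return A [ReactionModel-class] with species `X`.
#' @export
pureDeath <- function(mu, n0) {
  if (mu < 0) stop("parameter error: mu must be >= 0")
  if (n0 < 0) stop("parameter error: n0 must be >= 0")
  reactionModel(
    species = "X",
    reactions = list(list(change = -1L, rate = mu, reactants = 1L)),
    x0 = n0, label = "pure-death")
}

#' Read a mass-action model from a declarative YAML file
#'
#' The config lists `species`, `x0`, an optional `label`, and `reactions`,
#' each with a `rate` constant and `reactants` / `products` maps from species
#' name to multiplicity (missing species default to 0); the state-change
#' vector is `products - reactants`.
#'
#' @param path YAML file path.
#' @return A [ReactionModel-class].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("species: [X]", "x0: [0]", "reactions:",
#'              "  - rate: 10", "    products: {X: 1}",
#'              "  - rate: 1", "    reactants: {X: 1}"), cfg)
#' readModelConfig(cfg)
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || is.null(cfg$x0) || is.null(cfg$reactions))
    stop(sprintf("model config %s must define species, x0 and reactions", path))
  species <- as.character(cfg$species)
  mult <- function(map) {
    out <- integer(length(species))
    if (!is.null(map)) {
      unknown <- setdiff(names(map), species)
      if (length(unknown))
        stop(sprintf("model config %s: unknown species %s", path,
                     paste(unknown, collapse = ", ")))
      out[match(names(map), species)] <- as.integer(unlist(map))
    }
    out
  }
  reactions <- lapply(cfg$reactions, function(rx) {
    if (is.null(rx$rate)) stop(sprintf("model config %s: reaction without rate", path))
    r <- mult(rx$reactants); p <- mult(rx$products)
    list(change = p - r, rate = as.numeric(rx$rate), reactants = r)
  })
  reactionModel(species, reactions, as.integer(cfg$x0),
                label = if (is.null(cfg$label)) basename(path) else cfg$label)
}
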