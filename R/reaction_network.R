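#' General elementary reaction networks
#'
#' Representation of a well-mixed system of `M` chemical species undergoing
#' `R` irreversible elementary reactions
#' \eqn{\sum_i \beta_{ij} X_i \to \sum_i \gamma_{ij} X_i}, with dual
#' semantics: deterministic mass-action rates (constants `k`, concentration
#' scale) and stochastic propensities (constants \eqn{\kappa}, copy-number
#' scale), linked through the system volume.
#'
#' @param species character vector of species labels (length `M`).
#' @param reactions list of reactions, each a list with elements `educts` and
#'   `products` (named integer vectors of stoichiometric coefficients, names
#'   from `species`; empty/NULL for zero-order sides) and `k`, the positive
#'   deterministic rate constant (units depend on the reaction order).
#' @param volume positive system volume.
#' @return A `reaction_network` with educt matrix `beta` (M x R), product
#'   matrix `gamma` (M x R), net stoichiometry `A = gamma - beta`, rate
#'   constants `k` and `volume`.
#' @examples
#' net <- reaction_network(
#'   species = "X",
#'   reactions = list(
#'     list(educts = NULL, products = c(X = 1), k = 10),
#'     list(educts = c(X = 1), products = NULL, k = 1)
#'   ))
#' mass_action_rhs(net, c(X = 10))
#' @export
reaction_network <- function(species, reactions, volume = 1) {
  stopifnot(is.character(species), length(species) >= 1, volume > 0,
            is.list(reactions), length(reactions) >= 1)
  M <- length(species); R <- length(reactions)
  beta <- gamma <- matrix(0L, M, R, dimnames = list(species, NULL))
  k <- numeric(R)
  fill <- function(mat, coefs, j) {
    if (is.null(coefs) || length(coefs) == 0) return(mat)
    if (is.null(names(coefs)) || !all(names(coefs) %in% species))
      stop("stoichiometric coefficients must be named after species")
    if (any(coefs < 0) || any(coefs != floor(coefs)))
      stop("stoichiometric coefficients must be nonnegative integers")
    mat[names(coefs), j] <- as.integer(coefs)
    mat
  }
  for (j in seq_len(R)) {
    rx <- reactions[[j]]
    beta <- fill(beta, rx$educts, j)
    gamma <- fill(gamma, rx$products, j)
    if (is.null(rx$k) || rx$k <= 0) stop("each reaction needs a positive rate constant k")
    k[j] <- rx$k
  }
  structure(list(species = species, beta = beta, gamma = gamma,
                 A = gamma - beta, k = k, volume = volume),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", length(x$species), "species,",
      ncol(x$beta), "reactions, V =", x$volume, "\n")
  for (j in seq_len(ncol(x$beta))) {
    lhs <- side_string(x$beta[, j], x$species)
    rhs <- side_string(x$gamma[, j], x$species)
    cat(sprintf("  %s -> %s   (k = %g)\n", lhs, rhs, x$k[j]))
  }
  invisible(x)
}

side_string <- function(coef, species) {
  nz <- which(coef > 0)
  if (!length(nz)) return("0")
  paste(ifelse(coef[nz] > 1, paste0(coef[nz], " "), ""), species[nz],
        sep = "", collapse = " + ")
}

#' Stochastic reaction constant
#'
#' Converts the deterministic rate constant of reaction `j` to its stochastic
#' counterpart: \eqn{\kappa_j = k_j V \prod_i \beta_{ij}! / V^{\beta_{ij}}}.
#' First-order reactions have \eqn{\kappa = k}; zero-order reactions scale
#' with the volume; higher-order reactions scale inversely with it.
#'
#' @param network a [reaction_network].
#' @param j reaction index (1-based).
#' @return The positive stochastic constant \eqn{\kappa_j}.
#' @export
stochastic_constant <- function(network, j) {
  stopifnot(inherits(network, "reaction_network"))
  if (j < 1 || j > ncol(network$beta)) stop("invalid reaction index")
  b <- network$beta[, j]
  V <- network$volume
  network$k[j] * V * prod(factorial(b) / V^b)
}

# All stochastic constants at once.
stochastic_constants <- function(network) {
  vapply(seq_len(ncol(network$beta)), function(j) stochastic_constant(network, j),
         numeric(1))
}

#' Reaction propensity
#'
#' Probability per unit time that reaction `j` fires in state `n`:
#' \eqn{w_j(n) = \kappa_j \prod_i {n_i \choose \beta_{ij}}}, counting the
#' distinct educt combinations. Zero whenever some `n_i < beta_ij`.
#' Binomial coefficients are evaluated in exact integer arithmetic for
#' `n < 1e6` and via log-gamma beyond.
#'
#' @param network a [reaction_network].
#' @param n named or positional vector of copy numbers (nonnegative integers).
#' @param j reaction index.
#' @return The nonnegative propensity.
#' @export
propensity <- function(network, n, j) {
  stopifnot(inherits(network, "reaction_network"))
  if (j < 1 || j > ncol(network$beta)) stop("invalid reaction index")
  if (any(n < 0)) stop("copy numbers must be nonnegative")
  b <- network$beta[, j]
  kap <- stochastic_constant(network, j)
  kap * prod(binom_exact(n, b))
}

# choose(n, b) elementwise: exact products at desk scale, log-gamma above.
binom_exact <- function(n, b) {
  out <- numeric(length(n))
  for (i in seq_along(n)) {
    if (b[i] == 0) { out[i] <- 1; next }
    if (n[i] < b[i]) { out[i] <- 0; next }
    out[i] <- if (n[i] < 1e6) {
      prod((n[i] - seq_len(b[i]) + 1) / seq_len(b[i]))
    } else {
      exp(lgamma(n[i] + 1) - lgamma(b[i] + 1) - lgamma(n[i] - b[i] + 1))
    }
  }
  out
}

#' Deterministic mass-action right-hand side
#'
#' Concentration rate of change under the law of mass action:
#' \eqn{\dot c_i = \sum_j a_{ij} k_j \prod_l c_l^{\beta_{lj}}}.
#'
#' @param network a [reaction_network].
#' @param conc concentration vector (nonnegative).
#' @return Named vector \eqn{\dot c}.
#' @export
mass_action_rhs <- function(network, conc) {
  stopifnot(inherits(network, "reaction_network"))
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  R <- ncol(network$beta)
  rates <- vapply(seq_len(R), function(j) {
    network$k[j] * prod(conc^network$beta[, j])
  }, numeric(1))
  drop(network$A %*% rates)
}

#' Exact stochastic simulation of a reaction network
#'
#' Direct-method Gillespie algorithm: exponential waiting time with the total
#' propensity, reaction chosen with probability proportional to its
#' propensity, state updated by the reaction's net stoichiometry. When all
#' propensities vanish the state is frozen until `t_end`.
#'
#' @param network a [reaction_network].
#' @param n0 initial copy numbers (nonnegative integers, length M).
#' @param t_end simulation horizon.
#' @param seed optional integer seed (applied locally).
#' @param t_record times at which to record the state (piecewise-constant
#'   interpolation); defaults to 201 equispaced times on `[0, t_end]`.
#' @return Data frame with column `t` and one column per species.
#' @export
simulate_ssa <- function(network, n0, t_end, seed = NULL, t_record = NULL) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0,
            length(n0) == length(network$species), all(n0 >= 0))
  if (is.null(t_record)) t_record <- seq(0, t_end, length.out = 201)
  stopifnot(all(t_record >= 0), all(t_record <= t_end), !is.unsorted(t_record))
  kap <- stochastic_constants(network)
  states <- with_seed(seed,
    ssa_network_cpp(kap, network$beta, network$A, as.integer(n0), t_record))
  out <- data.frame(t = t_record)
  for (i in seq_along(network$species)) out[[network$species[i]]] <- states[, i]
  out
}
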