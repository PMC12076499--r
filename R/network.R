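#' Declarative chemical reaction networks
#'
#' A `crn_network` couples a species table, a list of mass-action reactions and
#' a named vector of rate constants. The network is the single source of truth
#' from which ODE right-hand sides are generated (see [build_rhs()]); equations
#' are never hand-coded elsewhere in the package.
#'
#' @details Species are identified by 1-based contiguous indices. A species
#' flagged `constant` (for example a catalyst held at fixed concentration by
#' the experimental setup) is carried in the state vector so indices stay
#' aligned with the literature numbering, but its time derivative is pinned to
#' zero by every generated right-hand side. Constant species must have zero
#' net stoichiometry in all reactions; they may still appear in rate laws
#' through the rate-law exponents.
#'
#' @param species data.frame with columns `index` (1-based contiguous
#'   integers), `name` (unique strings) and `constant` (logical).
#' @param reactions list of [reaction()] objects.
#' @param kappa named numeric vector of positive rate constants; names must
#'   cover every rate-constant key used by `reactions`. `NA` entries are
#'   allowed as placeholders for externally supplied parameterizations but
#'   reject at [build_rhs()] time.
#' @param time_unit unit of time for the rate constants: `"s"`, `"h"` or `"d"`.
#' @return An object of class `crn_network`.
#' @seealso [reaction()], [build_rhs()], [ablate_reaction()],
#'   [conserved_moieties()], [fmoc_network()], [toy_oscillator()]
#' @export
crn_network <- function(species, reactions, kappa, time_unit = "h") {
  species <- as.data.frame(species)
  stopifnot(all(c("index", "name", "constant") %in% names(species)))
  species$index <- as.integer(species$index)
  species$name <- as.character(species$name)
  species$constant <- as.logical(species$constant)
  if (!identical(species$index, seq_len(nrow(species))))
    stop("species indices must be unique and contiguous from 1")
  if (anyDuplicated(species$name))
    stop("species names must be unique")
  if (!is.list(reactions) || !all(vapply(reactions, inherits, TRUE, "crn_reaction")))
    stop("`reactions` must be a list of reaction() objects")
  kappa <- validate_kappa(kappa)
  time_unit <- match.arg(time_unit, c("s", "h", "d"))

  labels <- vapply(reactions, function(r) r$label, "")
  if (anyDuplicated(labels)) stop("reaction labels must be unique")
  keys <- vapply(reactions, function(r) r$rate_constant, "")
  missing_keys <- setdiff(keys, names(kappa))
  if (length(missing_keys))
    stop("unknown rate-constant key(s): ", paste(missing_keys, collapse = ", "))

  net <- structure(
    list(species = species, reactions = reactions, kappa = kappa,
         time_unit = time_unit),
    class = "crn_network")
  net <- compile_network(net)
  validate_network(net)
  net
}

#' Define a single mass-action reaction
#'
#' @param reactants named numeric vector: species name -> stoichiometric
#'   coefficient consumed.
#' @param products named numeric vector: species name -> coefficient produced.
#' @param rate_constant key into the network's rate-constant vector.
#' @param exponents optional named numeric vector of rate-law exponents. By
#'   default the reactant stoichiometry; supplying exponents explicitly allows
#'   catalytic species that appear in the rate law with zero net
#'   stoichiometry.
#' @param label unique reaction identifier; defaults to the rate-constant key.
#' @param suppress integer vector of species indices whose state update must
#'   ignore this reaction (used by partial ablation, see
#'   [ablate_reaction()]). Normally empty.
#' @return An object of class `crn_reaction`.
#' @export
reaction <- function(reactants, products, rate_constant, exponents = NULL,
                     label = rate_constant, suppress = integer(0)) {
  chk_stoich <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
      stop(what, " must be a named vector (species names)")
    if (any(x < 0)) stop(what, " must be nonnegative")
    x
  }
  reactants <- chk_stoich(as.numeric_named(reactants), "reactants")
  products <- chk_stoich(as.numeric_named(products), "products")
  if (is.null(exponents)) exponents <- reactants
  exponents <- chk_stoich(as.numeric_named(exponents), "exponents")
  structure(
    list(reactants = reactants, products = products,
         rate_constant = as.character(rate_constant),
         exponents = exponents, label = as.character(label),
         suppress = as.integer(suppress)),
    class = "crn_reaction")
}

as.numeric_named <- function(x) {
  if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(x), names(x))
}

validate_kappa <- function(kappa) {
  if (is.null(names(kappa)) || any(!nzchar(names(kappa))))
    stop("rate constants must be a named numeric vector")
  kappa <- stats::setNames(as.numeric(kappa), names(kappa))
  bad <- !is.na(kappa) & kappa <= 0
  if (any(bad))
    stop("rate constants must be positive: ", paste(names(kappa)[bad], collapse = ", "))
  kappa
}

# Precompute the matrix form used by the RHS builder:
#   S_net   M x R  net stoichiometry (products - reactants)
#   S_eff   M x R  net stoichiometry with suppressed and constant entries zeroed
#   E       M x R  rate-law exponents
compile_network <- function(net) {
  M <- nrow(net$species)
  R <- length(net$reactions)
  S <- matrix(0, M, R)
  E <- matrix(0, M, R)
  for (j in seq_len(R)) {
    r <- net$reactions[[j]]
    idx <- match(names(r$reactants), net$species$name)
    if (anyNA(idx)) stop("unknown species in reactants of '", r$label, "'")
    S[idx, j] <- S[idx, j] - r$reactants
    idx <- match(names(r$products), net$species$name)
    if (anyNA(idx)) stop("unknown species in products of '", r$label, "'")
    S[idx, j] <- S[idx, j] + r$products
    idx <- match(names(r$exponents), net$species$name)
    if (anyNA(idx)) stop("unknown species in exponents of '", r$label, "'")
    E[idx, j] <- r$exponents
    if (length(r$suppress) && any(r$suppress < 1 | r$suppress > M))
      stop("suppressed species index out of range in '", r$label, "'")
  }
  S_eff <- S
  for (j in seq_len(R)) {
    sup <- net$reactions[[j]]$suppress
    if (length(sup)) S_eff[sup, j] <- 0
  }
  S_eff[net$species$constant, ] <- 0
  net$S_net <- S
  net$S_eff <- S_eff
  net$E <- E
  net$rate_keys <- vapply(net$reactions, function(r) r$rate_constant, "")
  net$labels <- vapply(net$reactions, function(r) r$label, "")
  net
}

validate_network <- function(net) {
  const <- net$species$constant
  if (any(const) && length(net$reactions)) {
    if (any(abs(net$S_net[const, , drop = FALSE]) > 0))
      stop("constant species must have zero net stoichiometry in every reaction")
  }
  invisible(net)
}

#' @export
print.crn_network <- function(x, ...) {
  cat("<crn_network> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, time unit '", x$time_unit, "'\n", sep = "")
  cat("species:", paste0(x$species$index, ":", x$species$name,
                         ifelse(x$species$constant, "*", "")), "\n")
  for (r in x$reactions) {
    lhs <- paste(ifelse(r$reactants > 1, paste0(r$reactants, " "), ""),
                 names(r$reactants), sep = "", collapse = " + ")
    rhs <- paste(ifelse(r$products > 1, paste0(r$products, " "), ""),
                 names(r$products), sep = "", collapse = " + ")
    sup <- if (length(r$suppress))
      paste0("  [suppressed for species ", paste(r$suppress, collapse = ","), "]") else ""
    cat(sprintf("  %-16s %s -> %s  (k = %s)%s\n", r$label, lhs, rhs,
                r$rate_constant, sup))
  }
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param network a [crn_network()].
#' @param effective if `TRUE` (default) return the matrix actually used in the
#'   state update, i.e. with rows of constant species and any
#'   ablation-suppressed entries zeroed; if `FALSE`, the raw net
#'   stoichiometry.
#' @return species x reactions numeric matrix with dimnames.
#' @export
stoichiometry_matrix <- function(network, effective = TRUE) {
  S <- if (effective) network$S_eff else network$S_net
  dimnames(S) <- list(network$species$name, network$labels)
  S
}

#' Flow (CSTR) conditions
#'
#' Describes an open, instantaneously well-mixed continuous stirred-tank
#' reactor: every non-constant species gains `D * (y_in - y)` from the
#' combined in/outflow at dilution rate `D` (units 1/time; the residence time
#' is `1/D`). `D = 0` reduces to a closed (batch) reactor.
#'
#' @param y_in inflow concentrations, one per species (M). Species not
#'   supplied in the feed get 0.
#' @param D dilution rate, >= 0, in 1/time_unit of the network.
#' @return An object of class `flow_conditions`.
#' @export
flow_conditions <- function(y_in, D) {
  y_in <- as.numeric(y_in)
  if (any(y_in < 0)) stop("inflow concentrations must be nonnegative")
  if (length(D) != 1 || is.na(D) || D < 0) stop("dilution rate D must be a single value >= 0")
  structure(list(y_in = y_in, D = as.numeric(D)), class = "flow_conditions")
}

#' Build the mass-action ODE right-hand side of a network
#'
#' Returns a pure function `(t, y) -> dy/dt` computing `S %*% v(y)` with rates
#' `v_j = k_j * prod_s y_s^exponent(s, j)`. Derivatives of constant species are
#' fixed at zero. The returned function also accepts a batch of states as a
#' `B x M` matrix and then returns a `B x M` matrix of derivatives, which the
#' training code relies on.
#'
#' @param network a [crn_network()].
#' @return function of `(t, y)`; attributes `n_species` and `constant` carry
#'   the species count and the constant-species mask for downstream plumbing.
#' @export
build_rhs <- function(network) {
  k <- network$kappa[network$rate_keys]
  if (anyNA(k))
    stop("rate constant(s) not set (NA): ",
         paste(unique(network$rate_keys[is.na(k)]), collapse = ", "))
  E <- network$E
  M <- nrow(E)
  R <- ncol(E)
  # per-reaction list of (species index, exponent) with nonzero exponent
  supp <- lapply(seq_len(R), function(j) {
    s <- which(E[, j] != 0)
    list(s = s, e = E[s, j])
  })
  S_eff <- network$S_eff
  f <- function(t, y) {
    if (is.matrix(y)) {
      cpp_ma_rhs(y, k, E, S_eff)
    } else {
      v <- k
      for (j in seq_len(R)) {
        sj <- supp[[j]]
        for (i in seq_along(sj$s)) {
          e <- sj$e[i]
          v[j] <- v[j] * (if (e == 1) y[sj$s[i]] else y[sj$s[i]]^e)
        }
      }
      drop(S_eff %*% v)
    }
  }
  structure(f, n_species = M, constant = network$species$constant,
            class = c("crn_rhs", "function"))
}

#' Reaction rates at a state
#'
#' Rates `v_j(y) = k_j * prod y^e` for every reaction; mostly a test and
#' diagnostics helper.
#' @param network a [crn_network()].
#' @param y state vector.
#' @return named numeric vector of rates.
#' @export
reaction_rates <- function(network, y) {
  k <- network$kappa[network$rate_keys]
  v <- numeric(length(k))
  for (j in seq_along(v)) {
    s <- which(network$E[, j] != 0)
    v[j] <- k[j] * prod(y[s]^network$E[s, j])
  }
  stats::setNames(v, network$labels)
}

#' Add flow (CSTR) terms to a right-hand side
#'
#' Wraps a batch RHS with the standard well-mixed CSTR balance:
#' `dy/dt = rhs(t, y) + D * (y_in - y)` applied to non-constant species only.
#'
#' @param rhs function from [build_rhs()] (or any function carrying the same
#'   `n_species`/`constant` attributes, e.g. [augmented_rhs()]).
#' @param flow a [flow_conditions()].
#' @return a new RHS function with the same batch semantics.
#' @export
apply_flow <- function(rhs, flow) {
  stopifnot(inherits(flow, "flow_conditions"))
  M <- attr(rhs, "n_species")
  if (is.null(M)) stop("rhs must carry an `n_species` attribute (use build_rhs())")
  if (length(flow$y_in) != M)
    stop("y_in has length ", length(flow$y_in), " but the network has ", M, " species")
  const <- attr(rhs, "constant")
  open_sp <- !const
  y_in <- flow$y_in
  D <- flow$D
  f <- function(t, y) {
    dy <- rhs(t, y)
    if (is.matrix(y)) {
      dy[, open_sp] <- dy[, open_sp] +
        D * (matrix(y_in[open_sp], nrow(y), sum(open_sp), byrow = TRUE) - y[, open_sp])
    } else {
      dy[open_sp] <- dy[open_sp] + D * (y_in[open_sp] - y[open_sp])
    }
    dy
  }
  structure(f, n_species = M, constant = const, class = c("crn_rhs", "function"))
}

#' Remove a reaction, fully or from selected species' equations
#'
#' Full ablation drops the reaction. Partial ablation (a non-`NULL` `species`
#' argument) keeps the reaction but removes its contribution from the state
#' update of the given species only, leaving the rest of the ODE system
#' unaltered — the construct used to emulate a hidden reaction pathway.
#'
#' @param network a [crn_network()].
#' @param label reaction label to ablate.
#' @param species optional integer indices (or species names) to restrict the
#'   ablation to; `NULL` removes the reaction entirely.
#' @return a modified copy of the network.
#' @export
ablate_reaction <- function(network, label, species = NULL) {
  j <- match(label, network$labels)
  if (is.na(j)) stop("unknown reaction label: ", label)
  if (is.null(species)) {
    network$reactions <- network$reactions[-j]
  } else {
    if (is.character(species)) {
      idx <- match(species, network$species$name)
      if (anyNA(idx)) stop("unknown species name(s): ",
                           paste(species[is.na(idx)], collapse = ", "))
      species <- idx
    }
    species <- as.integer(species)
    if (any(species < 1 | species > nrow(network$species)))
      stop("species index out of range")
    r <- network$reactions[[j]]
    r$suppress <- sort(unique(c(r$suppress, species)))
    network$reactions[[j]] <- r
  }
  compile_network(network)
}

#' Conserved moieties of a network
#'
#' Computes an orthonormal basis of the left null space of the effective
#' stoichiometric matrix restricted to non-constant species. Each basis vector
#' `w` satisfies `t(w) %*% S = 0`, so `sum(w * y(t))` is constant along any
#' batch trajectory (a conserved moiety such as a molecular backbone that is
#' only ever transferred between species).
#'
#' @param network a [crn_network()].
#' @param tol singular-value threshold relative to the largest singular value.
#' @return matrix with one column per conserved quantity, rows over all
#'   species (zero at constant species); 0 columns if there are none.
#' @export
conserved_moieties <- function(network, tol = 1e-10) {
  const <- network$species$constant
  S <- network$S_eff[!const, , drop = FALSE]
  M <- nrow(network$species)
  if (nrow(S) == 0) return(matrix(0, M, 0))
  sv <- svd(S, nu = nrow(S))
  rank <- sum(sv$d > tol * max(sv$d, 1e-300))
  null_dim <- nrow(S) - rank
  W <- matrix(0, M, null_dim)
  if (null_dim > 0) W[!const, ] <- sv$u[, (rank + 1):nrow(S), drop = FALSE]
  rownames(W) <- network$species$name
  W
}

#' Rescale the time unit of a network
#'
#' Changing the time unit by a factor `c` (e.g. seconds to hours, c = 3600)
#' multiplies every rate constant by `c`; concentration units are unchanged,
#' so first- and second-order constants rescale by the same factor. Solving in
#' either unit yields identical trajectories at corresponding times.
#'
#' @param network a [crn_network()].
#' @param to target unit: `"s"`, `"h"` or `"d"`.
#' @return the rescaled network.
#' @export
rescale_time_unit <- function(network, to) {
  to <- match.arg(to, c("s", "h", "d"))
  fac <- time_unit_seconds(to) / time_unit_seconds(network$time_unit)
  network$kappa <- network$kappa * fac
  network$time_unit <- to
  network
}

time_unit_seconds <- function(unit) {
  switch(unit, s = 1, h = 3600, d = 86400,
         stop("unknown time unit: ", unit))
}

# Analytic Jacobian d(rhs)/dy of the mass-action part, batched (compiled).
# Returns a function (t, Y) -> array B x M x M (or M x M for a vector state).
mass_action_jacobian <- function(network) {
  k <- network$kappa[network$rate_keys]
  if (anyNA(k))
    stop("rate constant(s) not set (NA): ",
         paste(unique(network$rate_keys[is.na(k)]), collapse = ", "))
  E <- network$E
  S <- network$S_eff
  M <- nrow(E)
  function(t, y) {
    vec <- !is.matrix(y)
    Y <- if (vec) matrix(y, 1) else y
    J <- cpp_ma_jac(Y, k, E, S)
    if (vec) matrix(J[1, , ], M, M) else J
  }
}
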