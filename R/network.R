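#' Mass-action rate law
#'
#' @param kappa nonnegative rate constant, or the name of a network parameter.
#' @return A rate-law object for use in [reaction()].
#' @export
mass_action <- function(kappa) {
  if (is.character(kappa)) {
    stopifnot(length(kappa) == 1L)
    return(structure(list(type = "mass_action", kappa = kappa), class = "scrn_rate"))
  }
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  if (kappa < 0) stop("mass-action rate constant must be nonnegative, got ", kappa)
  structure(list(type = "mass_action", kappa = kappa), class = "scrn_rate")
}

#' Restricted arithmetic rate law
#'
#' Propensities that are not mass-action (e.g. saturating or
#' occupancy-limited kinetics) are written as a restricted arithmetic
#' expression over state variables and named parameters. The grammar admits
#' `+`, `-`, `*`, `/`, integer powers, numeric literals, species names,
#' the aliases `x1..xd` (declared species order), parameter names, and the
#' bounded monotone function `hill(x, K, h) = x^h / (K^h + x^h)`.
#' No other function calls are evaluated.
#'
#' @param expr a string with the expression, e.g. `"(Dtot - (x1 + x2)) * (k1a + k1b * x2)"`.
#' @return A rate-law object for use in [reaction()].
#' @export
rate_expression <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  structure(list(type = "expression", expr = expr), class = "scrn_rate")
}

#' Define a reaction
#'
#' @param reactant,product named integer vectors (species name -> count);
#'   species omitted are zero. The reactant and product vectors must differ.
#' @param rate a rate law from [mass_action()] or [rate_expression()].
#' @export
reaction <- function(reactant, product, rate) {
  stopifnot(inherits(rate, "scrn_rate"))
  as_counts <- function(v, what) {
    if (length(v) == 0L) return(integer(0))
    if (is.null(names(v)) || any(names(v) == ""))
      stop("reaction ", what, " vector must be named by species")
    if (any(v < 0) || any(v != round(v)))
      stop("reaction ", what, " counts must be nonnegative integers")
    v <- v[v > 0]
    storage.mode(v) <- "integer"
    v
  }
  structure(list(reactant = as_counts(reactant, "reactant"),
                 product  = as_counts(product, "product"),
                 rate     = rate),
            class = "scrn_reaction")
}

# dense length-d stoichiometric vector from a sparse named count map
.dense_counts <- function(counts, species) {
  out <- integer(length(species))
  if (length(counts)) {
    idx <- match(names(counts), species)
    if (anyNA(idx)) stop("unknown species in reaction: ",
                         paste(names(counts)[is.na(idx)], collapse = ", "))
    out[idx] <- as.integer(counts)
  }
  out
}

.expr_whitelist <- c("+", "-", "*", "/", "^", "(", "hill")

.validate_expr <- function(e, allowed, label) {
  if (is.numeric(e)) return(invisible(TRUE))
  if (is.name(e)) {
    if (!(as.character(e) %in% allowed))
      stop("rate expression for ", label, " uses unknown symbol '",
           as.character(e), "'")
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!(fn %in% .expr_whitelist))
      stop("rate expression for ", label, " uses disallowed function '", fn, "'")
    if (fn == "^") {
      ex <- e[[3]]
      if (!(is.numeric(ex) && length(ex) == 1L && ex == round(ex)))
        stop("rate expression for ", label, " must use integer literal powers")
    }
    for (k in seq_along(e)[-1]) .validate_expr(e[[k]], allowed, label)
    return(invisible(TRUE))
  }
  stop("rate expression for ", label, " contains an unsupported construct")
}

#' Assemble a reaction network
#'
#' A stochastic chemical reaction network: an ordered species list, a
#' non-empty list of reactions (each with reactant and product stoichiometry
#' and a rate law) and named nonnegative parameters. States are vectors of
#' molecule counts in declared species order. Construction validates that no
#' reaction has identical reactant and product vectors, that every species
#' takes part in at least one reaction, that rate constants are nonnegative
#' and that expression rate laws only reference known symbols.
#'
#' @param species character vector of species names (length d >= 1).
#' @param reactions list of [reaction()] objects.
#' @param parameters named numeric vector of nonnegative parameter values.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, parameters = numeric()) {
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species), is.list(reactions), length(reactions) >= 1L)
  if (length(parameters)) {
    stopifnot(is.numeric(parameters), !is.null(names(parameters)))
    if (any(parameters < 0)) stop("parameters must be nonnegative")
  }
  d <- length(species)
  aliases <- paste0("x", seq_len(d))
  used <- logical(d)
  compiled <- vector("list", length(reactions))
  for (r in seq_along(reactions)) {
    rx <- reactions[[r]]
    if (!inherits(rx, "scrn_reaction")) stop("reactions must be built with reaction()")
    vm <- .dense_counts(rx$reactant, species)
    vp <- .dense_counts(rx$product, species)
    if (all(vm == vp))
      stop("reaction ", r, " has identical reactant and product vectors")
    used <- used | (vm > 0) | (vp > 0)
    rate <- rx$rate
    if (rate$type == "mass_action") {
      if (is.character(rate$kappa) && !(rate$kappa %in% names(parameters)))
        stop("reaction ", r, " references unknown parameter '", rate$kappa, "'")
      lang <- NULL
    } else {
      lang <- str2lang(rate$expr)
      .validate_expr(lang, c(species, aliases, names(parameters)),
                     paste0("reaction ", r))
    }
    compiled[[r]] <- list(vminus = vm, vplus = vp, vnet = vp - vm,
                          rate = rate, expr_lang = lang)
  }
  if (!all(used))
    stop("species appearing in no reaction: ",
         paste(species[!used], collapse = ", "))
  structure(list(species = species, reactions = compiled,
                 parameters = parameters, d = d),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction network:", x$d, "species (", paste(x$species, collapse = ", "),
      "),", length(x$reactions), "reactions\n")
  for (r in seq_along(x$reactions)) {
    rx <- x$reactions[[r]]
    side <- function(v) {
      nz <- which(v > 0)
      if (!length(nz)) return("0")
      paste(ifelse(v[nz] > 1, paste0(v[nz], " "), ""), x$species[nz],
            sep = "", collapse = " + ")
    }
    rl <- rx$rate
    lab <- if (rl$type == "mass_action") paste0("mass action, kappa = ", rl$kappa)
           else paste0("expr: ", rl$expr)
    cat(sprintf("  [%d] %s -> %s   (%s)\n", r, side(rx$vminus), side(rx$vplus), lab))
  }
  if (length(x$parameters))
    cat("parameters:", paste(names(x$parameters), x$parameters,
                             sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# exact falling factorial (m)_l, vectorised over m
.falling_factorial <- function(m, l) {
  out <- rep(1, length(m))
  if (l > 0) for (i in seq_len(l)) out <- out * (m - i + 1)
  out
}

.hill <- function(x, K, h) x^h / (K^h + x^h)

# evaluate all per-reaction propensities Lambda at a matrix of states
# (rows = states, columns = species); returns n_reactions x n_states
.propensity_matrix <- function(network, states, check = TRUE) {
  nr <- length(network$reactions)
  ns <- nrow(states)
  out <- matrix(0, nr, ns)
  env <- new.env(parent = baseenv())
  assign("hill", .hill, envir = env)
  for (p in names(network$parameters))
    assign(p, unname(network$parameters[[p]]), envir = env)
  for (i in seq_len(network$d)) {
    assign(network$species[i], states[, i], envir = env)
    assign(paste0("x", i), states[, i], envir = env)
  }
  for (r in seq_len(nr)) {
    rx <- network$reactions[[r]]
    if (rx$rate$type == "mass_action") {
      kap <- rx$rate$kappa
      if (is.character(kap)) kap <- unname(network$parameters[[kap]])
      lam <- rep(kap, ns)
      for (i in which(rx$vminus > 0))
        lam <- lam * .falling_factorial(states[, i], rx$vminus[i])
    } else {
      lam <- eval(rx$expr_lang, envir = env)
      if (length(lam) == 1L) lam <- rep(lam, ns)
    }
    if (check && (any(!is.finite(lam)) || any(lam < 0))) {
      bad <- which(!is.finite(lam) | lam < 0)[1]
      stop("propensity of reaction ", r, " is negative or non-finite at state (",
           paste(states[bad, ], collapse = ","), ")")
    }
    out[r, ] <- lam
  }
  out
}

#' Evaluate the propensity of a single reaction at a state
#'
#' Mass-action laws evaluate to
#' \eqn{\kappa \prod_i (x_i)_{(v^-)_i}} with \eqn{(m)_\ell} the falling
#' factorial; expression laws evaluate the stored arithmetic expression.
#'
#' @param network a [reaction_network()].
#' @param which index of the reaction.
#' @param x nonnegative integer state vector in declared species order.
#' @return The nonnegative rate. An expression evaluating to a negative or
#'   non-finite value is an error naming the reaction and state.
#' @export
evaluate_propensity <- function(network, which, x) {
  stopifnot(inherits(network, "reaction_network"),
            length(x) == network$d, all(x >= 0))
  .propensity_matrix(network, matrix(x, nrow = 1), check = TRUE)[which, 1]
}

## ---- JSON network dialect -------------------------------------------------

#' Read / write a network in the JSON dialect
#'
#' The on-disk form is
#' \preformatted{
#' {"species": [...], "parameters": {...},
#'  "reactions": [{"reactant": {"S": 1, ...}, "product": {...},
#'                 "rate": {"type": "mass_action", "kappa": <name-or-number>}
#'                       | {"type": "expression", "expr": "..."}}, ...],
#'  "state_space": {"origin": {...}, "bound": M | null}}
#' }
#' Round trips are lossless. The optional `state_space` block is returned in
#' the `state_space` attribute.
#'
#' @param path file path (or, for `write_network`, the destination).
#' @return `read_network`: a [reaction_network()] with a `state_space`
#'   attribute (list with `origin` and `bound`, possibly NULL).
#' @export
read_network <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  network_from_spec(spec)
}

#' @rdname read_network
#' @param spec a list with the parsed JSON structure (as from
#'   `jsonlite::read_json(..., simplifyVector = FALSE)`).
#' @export
network_from_spec <- function(spec) {
  species <- vapply(spec$species, as.character, character(1))
  params <- numeric(0)
  if (!is.null(spec$parameters) && length(spec$parameters))
    params <- vapply(spec$parameters, as.numeric, numeric(1))
  reactions <- lapply(spec$reactions, function(rx) {
    counts <- function(m) {
      if (is.null(m) || !length(m)) return(integer(0))
      vapply(m, as.integer, integer(1))
    }
    rate <- if (identical(rx$rate$type, "mass_action")) {
      k <- rx$rate$kappa
      mass_action(if (is.character(k)) k else as.numeric(k))
    } else if (identical(rx$rate$type, "expression")) {
      rate_expression(rx$rate$expr)
    } else stop("unknown rate law type: ", rx$rate$type)
    reaction(counts(rx$reactant), counts(rx$product), rate)
  })
  net <- reaction_network(species, reactions, params)
  ss <- NULL
  if (!is.null(spec$state_space)) {
    origin <- vapply(spec$state_space$origin, as.integer, integer(1))
    bound <- spec$state_space$bound
    ss <- list(origin = .dense_counts(origin, species),
               bound = if (is.null(bound)) NULL else as.integer(bound))
  }
  attr(net, "state_space") <- ss
  net
}

#' @rdname read_network
#' @param network a [reaction_network()].
#' @param origin,bound optional state-space block to embed (origin is a
#'   state vector in species order; bound a sup-norm truncation level).
#' @export
write_network <- function(network, path, origin = NULL, bound = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  sparse <- function(v) {
    nz <- which(v != 0)
    as.list(setNames(as.integer(v[nz]), network$species[nz]))
  }
  rxs <- lapply(network$reactions, function(rx) {
    rate <- if (rx$rate$type == "mass_action")
      list(type = "mass_action", kappa = rx$rate$kappa)
    else list(type = "expression", expr = rx$rate$expr)
    list(reactant = sparse(rx$vminus), product = sparse(rx$vplus), rate = rate)
  })
  spec <- list(species = as.list(network$species),
               parameters = as.list(network$parameters),
               reactions = rxs)
  ss <- attr(network, "state_space")
  if (!is.null(origin)) ss <- list(origin = origin, bound = bound)
  if (!is.null(ss)) {
    spec$state_space <- list(origin = sparse(ss$origin),
                             bound = if (is.null(ss$bound)) NULL else ss$bound)
  }
  jsonlite::write_json(spec, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a comparison matrix as JSON (`{"A": [[...], ...]}`)
#' @param path file path.
#' @return `read_comparison_matrix`: the m x d matrix.
#' @export
read_comparison_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- obj$A
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  comparison_matrix(A)
}

#' @rdname read_comparison_matrix
#' @param A the comparison matrix.
#' @export
write_comparison_matrix <- function(A, path) {
  jsonlite::write_json(list(A = unclass(A)), path, digits = NA, pretty = TRUE)
  invisible(path)
}
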