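# Markov-chain senescence engine. Each leaf occupies one of n discrete
# states (texture + deformation snapshot combinations); the probability of
# keeping the current state over a time span t is exp(-ln2 * t / tau_i(e)),
# where the half-life tau_i and the transition weights X_ij are bilinear
# functions of normalized temperature and humidness. Populations of leaves
# evolve stochastically under a seasonal environment schedule.

#' Environmental conditions
#'
#' Normalized temperature and humidness, both in `[0, 1]`
#' (0 = cold / dry, 1 = warm / wet). Physical units, if any, must be mapped
#' onto this square by the caller (e.g. linearly from a degrees-Celsius and
#' percent-relative-humidity range).
#'
#' @param temperature Normalized temperature in `[0, 1]`.
#' @param humidness Normalized humidness in `[0, 1]`.
#' @return An object of class `leaf_env`.
#' @export
leaf_env <- function(temperature, humidness) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature < 0 || temperature > 1 ||
      !is.numeric(humidness) || length(humidness) != 1 ||
      !is.finite(humidness) || humidness < 0 || humidness > 1) {
    stop("temperature and humidness must be scalars in [0, 1]", call. = FALSE)
  }
  structure(list(temperature = temperature, humidness = humidness),
            class = "leaf_env")
}

as_leaf_env <- function(e) {
  if (inherits(e, "leaf_env")) return(e)
  if (is.list(e) && !is.null(e$temperature) && !is.null(e$humidness)) {
    return(leaf_env(e$temperature, e$humidness))
  }
  if (is.numeric(e) && length(e) == 2) return(leaf_env(e[1], e[2]))
  stop("cannot interpret environment; use leaf_env()", call. = FALSE)
}

#' Bilinear interpolation over the four environmental extremes
#'
#' Interpolates four corner constants, ordered (dry-cold, dry-warm,
#' wet-cold, wet-warm), at the given environment:
#' `(1-h)(1-w) c_dc + (1-h) w c_dw + h (1-w) c_wc + h w c_ww`
#' with `w` the temperature and `h` the humidness. At each corner of the
#' unit square the corresponding constant is returned exactly.
#'
#' @param env A [leaf_env()] (or numeric `c(temperature, humidness)`).
#' @param corners Numeric vector of four corner constants in the order
#'   dry-cold, dry-warm, wet-cold, wet-warm.
#' @return Interpolated scalar.
#' @export
bilinear_interp <- function(env, corners) {
  env <- as_leaf_env(env)
  corners <- as.numeric(corners)
  if (length(corners) != 4 || any(!is.finite(corners))) {
    stop("corners must be four finite constants", call. = FALSE)
  }
  w <- env$temperature
  h <- env$humidness
  (1 - h) * (1 - w) * corners[1] + (1 - h) * w * corners[2] +
    h * (1 - w) * corners[3] + h * w * corners[4]
}

#' Senescence specification
#'
#' Defines the leaf state machine: state names with opaque texture labels
#' (and optional deformation-snapshot references), per-state half-life
#' corner constants, per-pair transition corner constants, and the set of
#' absorbing (terminal, e.g. fallen) states.
#'
#' @param states Character vector of state names, or a data frame / list
#'   with `name`, `texture_label` and optional `snapshot` per state.
#' @param tau_corners n x 4 matrix of positive half-life constants (time
#'   units) at the four environmental extremes, ordered dry-cold, dry-warm,
#'   wet-cold, wet-warm; one row per state.
#' @param X_corners n x n x 4 array of transition corner constants in
#'   `[0, 1]` (slice k holds the constants for extreme k, same corner
#'   order); the diagonal is ignored. For each environment the interpolated
#'   off-diagonal weights of a row are renormalized to sum to one before
#'   use.
#' @param absorbing Character vector (or integer indices) of absorbing
#'   states.
#' @return An object of class `senescence_spec`.
#' @export
senescence_spec <- function(states, tau_corners, X_corners,
                            absorbing = character(0)) {
  if (is.data.frame(states) || (is.list(states) && !is.null(states[[1]]$name))) {
    if (is.data.frame(states)) {
      names_ <- states$name
      textures <- if (!is.null(states$texture_label)) states$texture_label else names_
      snapshots <- if (!is.null(states$snapshot)) states$snapshot else rep(NA_character_, length(names_))
    } else {
      names_ <- vapply(states, function(s) s$name, character(1))
      textures <- vapply(states, function(s) {
        if (is.null(s$texture_label)) s$name else s$texture_label
      }, character(1))
      snapshots <- vapply(states, function(s) {
        if (is.null(s$snapshot)) NA_character_ else as.character(s$snapshot)
      }, character(1))
    }
  } else {
    names_ <- as.character(states)
    textures <- names_
    snapshots <- rep(NA_character_, length(names_))
  }
  n <- length(names_)
  if (n < 1 || anyDuplicated(names_)) {
    stop("states must be uniquely named", call. = FALSE)
  }
  tau_corners <- as.matrix(tau_corners)
  if (!all(dim(tau_corners) == c(n, 4)) || any(!is.finite(tau_corners)) ||
      any(tau_corners <= 0)) {
    stop("tau_corners must be an n x 4 matrix of positive half-lives",
         call. = FALSE)
  }
  X_corners <- as.array(X_corners)
  if (length(dim(X_corners)) != 3 || !all(dim(X_corners) == c(n, n, 4)) ||
      any(!is.finite(X_corners)) || any(X_corners < 0) || any(X_corners > 1)) {
    stop("X_corners must be an n x n x 4 array with values in [0, 1]",
         call. = FALSE)
  }
  for (k in 1:4) for (i in seq_len(n)) X_corners[i, i, k] <- 0
  if (is.numeric(absorbing)) absorbing <- names_[absorbing]
  if (!all(absorbing %in% names_)) {
    stop("absorbing states must be among the state names", call. = FALSE)
  }
  abs_flag <- names_ %in% absorbing
  for (i in seq_len(n)) {
    if (!abs_flag[i] && all(X_corners[i, , ] == 0)) {
      stop(sprintf(
        "state '%s' is not absorbing but has all-zero transition constants; a leaf must be able to leave it",
        names_[i]), call. = FALSE)
    }
  }
  structure(
    list(states = names_, texture_labels = textures, snapshots = snapshots,
         tau_corners = tau_corners, X_corners = X_corners,
         absorbing = abs_flag),
    class = "senescence_spec"
  )
}

#' Probability of keeping the current state
#'
#' The self-retention probability over an elapsed time `t` under environment
#' `e` is `exp(-lambda_i(e) * t)` with decay rate
#' `lambda_i(e) = ln(2) / tau_i(e)`, where the half-life `tau_i(e)` is the
#' bilinear interpolation of the state's four corner constants. At
#' `t = tau_i(e)` the probability is exactly one half.
#'
#' @param env A [leaf_env()].
#' @param t Elapsed time (>= 0), in the same units as the half-lives.
#' @param state_index State index (1-based).
#' @param spec A [senescence_spec()].
#' @return Probability in `(0, 1]`.
#' @export
p_stay <- function(env, t, state_index, spec) {
  stopifnot(inherits(spec, "senescence_spec"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("t must be a non-negative scalar", call. = FALSE)
  }
  tau <- bilinear_interp(env, spec$tau_corners[state_index, ])
  exp(-(log(2) / tau) * t)
}

#' Environment-conditioned transition matrix
#'
#' Row i has diagonal `P_ii = p_stay(env, t, i)` and off-diagonal entries
#' `(1 - P_ii) * X_ij(env)`, where the interpolated transition weights
#' `X_ij(env)` of the row are renormalized to sum to one over `j != i`.
#' Absorbing states get a diagonal of exactly 1. Every row sums to 1.
#'
#' @param env A [leaf_env()].
#' @param t Step duration (>= 0).
#' @param spec A [senescence_spec()].
#' @return n x n row-stochastic matrix with state names as dimnames.
#' @export
transition_matrix <- function(env, t, spec) {
  stopifnot(inherits(spec, "senescence_spec"))
  env <- as_leaf_env(env)
  n <- length(spec$states)
  P <- matrix(0, n, n, dimnames = list(spec$states, spec$states))
  for (i in seq_len(n)) {
    if (spec$absorbing[i]) {
      P[i, i] <- 1
      next
    }
    pii <- p_stay(env, t, i, spec)
    x <- vapply(seq_len(n), function(j) {
      if (j == i) 0 else bilinear_interp(env, spec$X_corners[i, j, ])
    }, numeric(1))
    s <- sum(x)
    if (s <= 0) {
      if (pii < 1) {
        stop(sprintf(
          "state '%s' has zero interpolated transition weight at this environment",
          spec$states[i]), call. = FALSE)
      }
      P[i, i] <- 1
      next
    }
    P[i, ] <- (1 - pii) * x / s
    P[i, i] <- pii
  }
  P
}

#' Leaf population
#'
#' @param size Number of leaves.
#' @param initial_state Initial state index (1-based) for every leaf, or a
#'   per-leaf integer vector.
#' @return An object of class `leaf_population` with `assignments` and an
#'   empty `history`.
#' @export
leaf_population <- function(size, initial_state = 1L) {
  if (!is.numeric(size) || size < 1) {
    stop("population size must be a positive integer", call. = FALSE)
  }
  size <- as.integer(size)
  assignments <- rep_len(as.integer(initial_state), size)
  structure(list(assignments = assignments, history = NULL),
            class = "leaf_population")
}

#' Evolve a leaf population through an environment schedule
#'
#' Per epoch, each leaf independently samples its next state from its row of
#' the epoch's transition matrix (built with the epoch duration as the time
#' argument). Draws come from a counter-based uniform stream keyed by
#' (seed, leaf id, epoch), so identical inputs yield identical histories and
#' results do not depend on evaluation order. Sampling uses only each leaf's
#' current state, never its history (the Markov property holds by
#' construction).
#'
#' @param pop A [leaf_population()].
#' @param schedule List of epochs, each a list with `env` (a [leaf_env()] or
#'   `c(temperature, humidness)`) and `duration` (> 0). Entries with
#'   `temperature`/`humidness`/`duration` fields are also accepted.
#' @param spec A [senescence_spec()].
#' @param seed Integer seed for the per-leaf random streams.
#' @return The population with updated `assignments` and `history`, a
#'   (number of epochs + 1) x n count matrix whose first row is the initial
#'   distribution.
#' @export
evolve_population <- function(pop, schedule, spec, seed = 1L) {
  stopifnot(inherits(pop, "leaf_population"),
            inherits(spec, "senescence_spec"))
  if (!length(schedule)) stop("schedule must have at least one epoch", call. = FALSE)
  n <- length(spec$states)
  if (any(pop$assignments < 1L) || any(pop$assignments > n)) {
    stop("population assignments must be valid state indices", call. = FALSE)
  }
  npop <- length(pop$assignments)
  cur <- pop$assignments
  history <- matrix(0L, length(schedule) + 1L, n,
                    dimnames = list(NULL, spec$states))
  history[1L, ] <- tabulate(cur, nbins = n)
  for (ep in seq_along(schedule)) {
    epoch <- schedule[[ep]]
    env <- if (!is.null(epoch$env)) as_leaf_env(epoch$env) else as_leaf_env(epoch)
    duration <- epoch$duration
    if (!is.numeric(duration) || duration <= 0) {
      stop("epoch durations must be positive", call. = FALSE)
    }
    P <- transition_matrix(env, duration, spec)
    cum <- t(apply(P, 1, cumsum))
    u <- hash_uniform(seed, seq_len(npop), ep)
    nxt <- integer(npop)
    for (s in unique(cur)) {
      idx <- which(cur == s)
      nxt[idx] <- pmin(findInterval(u[idx], cum[s, ]) + 1L, n)
    }
    cur <- nxt
    history[ep + 1L, ] <- tabulate(cur, nbins = n)
  }
  pop$assignments <- cur
  pop$history <- history
  pop
}

#' @export
print.senescence_spec <- function(x, ...) {
  cat(sprintf("<senescence_spec: %d states (%s)%s>\n",
              length(x$states), paste(x$states, collapse = ", "),
              if (any(x$absorbing)) {
                paste0("; absorbing: ",
                       paste(x$states[x$absorbing], collapse = ", "))
              } else ""))
  invisible(x)
}

#' @export
print.leaf_population <- function(x, ...) {
  cat(sprintf("<leaf_population: %d leaves%s>\n", length(x$assignments),
              if (is.null(x$history)) "" else {
                sprintf(", %d epochs of history", nrow(x$history) - 1L)
              }))
  invisible(x)
}
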