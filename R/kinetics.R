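#' Build a mass-action kinetic model
#'
#' Species are held as initial concentrations in micromolar; each reaction
#' carries reactant and product stoichiometry maps, a forward rate constant
#' and an optional reverse rate constant, all with mass-action rate laws
#' (rate = k times the product of reactant concentrations raised to their
#' stoichiometries). Time is in seconds.
#'
#' @param species named numeric vector of initial concentrations (uM),
#'   all >= 0.
#' @param reactions a list; each element a list with `reactants` and
#'   `products` (named integer stoichiometry vectors over species names),
#'   `rate` (forward rate constant >= 0), optional `reverse_rate` and `id`.
#' @return An object of class `kinetic_model`.
#' @examples
#' m <- kinetic_model(c(A = 1, B = 0),
#'                    list(list(reactants = c(A = 1), products = c(B = 1),
#'                              rate = 0.1)))
#' @export
kinetic_model <- function(species, reactions = list()) {
  stopifnot(is.numeric(species), !is.null(names(species)),
            all(nzchar(names(species))), all(species >= 0))
  species <- species[!duplicated(names(species))]
  reactions <- lapply(seq_along(reactions), function(i) {
    r <- reactions[[i]]
    stopifnot(is.list(r), !is.null(r$rate))
    r$reactants <- check_stoich(r$reactants, names(species), "reactant")
    r$products <- check_stoich(r$products, names(species), "product")
    if (r$rate < 0) stop("rate constants must be >= 0")
    if (!is.null(r$reverse_rate) && r$reverse_rate < 0) {
      stop("rate constants must be >= 0")
    }
    if (is.null(r$id)) r$id <- sprintf("r%d", i)
    r
  })
  structure(list(species = species, reactions = reactions),
            class = "kinetic_model")
}

check_stoich <- function(st, species_names, side) {
  if (is.null(st) || !length(st)) return(stats::setNames(integer(0), character(0)))
  stopifnot(is.numeric(st), !is.null(names(st)))
  if (any(st != round(st) | st < 1)) {
    stop(sprintf("%s stoichiometries must be positive integers", side))
  }
  unknown <- setdiff(names(st), species_names)
  if (length(unknown)) {
    stop(sprintf("unknown %s species: %s", side, paste(unknown, collapse = ", ")))
  }
  st <- tapply(as.integer(st), names(st), sum)
  stats::setNames(as.integer(st), names(st))
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic_model: %d species, %d reactions (%d reversible)\n",
              length(x$species), length(x$reactions),
              sum(vapply(x$reactions, function(r) !is.null(r$reverse_rate),
                         logical(1)))))
  invisible(x)
}

# split reversible reactions into elementary irreversible steps
elementary_reactions <- function(model) {
  out <- list()
  for (r in model$reactions) {
    out[[length(out) + 1]] <- list(reactants = r$reactants,
                                   products = r$products, rate = r$rate)
    if (!is.null(r$reverse_rate)) {
      out[[length(out) + 1]] <- list(reactants = r$products,
                                     products = r$reactants,
                                     rate = r$reverse_rate)
    }
  }
  out
}

#' Simulate a kinetic model
#'
#' Deterministic integration of the mass-action ODE system
#' `dc/dt = S v(c)` with a stiff-capable solver (`deSolve::lsoda`), reported
#' on a uniform time grid including 0 and `t_end`.
#'
#' @param model a [kinetic_model].
#' @param t_end end time in seconds (> 0).
#' @param n_points number of output points (default 1501).
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-10).
#' @return An object of class `kinetic_trajectory`: list with `time`
#'   (seconds), `conc` (matrix, one column per species, uM), `rtol`,
#'   `atol`.
#' @export
simulate_model <- function(model, t_end, n_points = 1501,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "kinetic_model"), t_end > 0, n_points >= 2)
  sp <- names(model$species)
  rx <- elementary_reactions(model)
  nr <- length(rx)
  ns <- length(sp)
  S <- matrix(0, ns, nr, dimnames = list(sp, NULL))
  react_idx <- vector("list", nr)
  react_pow <- vector("list", nr)
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- rx[[j]]
    k[j] <- r$rate
    if (length(r$reactants)) {
      S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    }
    if (length(r$products)) {
      S[names(r$products), j] <- S[names(r$products), j] + r$products
    }
    react_idx[[j]] <- match(names(r$reactants), sp)
    react_pow[[j]] <- as.numeric(r$reactants)
  }
  rhs <- function(t, y, p) {
    v <- k
    for (j in seq_len(nr)) {
      ix <- react_idx[[j]]
      if (length(ix)) v[j] <- v[j] * prod(y[ix]^react_pow[[j]])
    }
    list(as.numeric(S %*% v))
  }
  times <- seq(0, t_end, length.out = n_points)
  out <- if (nr == 0) {
    cbind(time = times,
          matrix(rep(model$species, each = n_points), ncol = ns,
                 dimnames = list(NULL, sp)))
  } else {
    res <- deSolve::lsoda(model$species, times, rhs, NULL,
                          rtol = rtol, atol = atol)
    if (attr(res, "istate")[1] < 0) {
      stop("ODE integration failed: ",
           paste(deSolve::diagnostics(res), collapse = " "))
    }
    res
  }
  structure(list(time = out[, "time"],
                 conc = out[, sp, drop = FALSE],
                 rtol = rtol, atol = atol),
            class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat(sprintf("kinetic_trajectory: %d species over [0, %g] s (%d points)\n",
              ncol(x$conc), max(x$time), length(x$time)))
  invisible(x)
}

#' @export
as.data.frame.kinetic_trajectory <- function(x, ...) {
  sp <- colnames(x$conc)
  data.frame(time = rep(x$time, times = length(sp)),
             species = rep(sp, each = length(x$time)),
             concentration = as.vector(x$conc))
}

#' Write a trajectory as tidy CSV
#'
#' Long format: `time,species,concentration`.
#'
#' @param traj a `kinetic_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify a competitive mass-action inhibitor
#'
#' @param name inhibitor species name (e.g. `"curcumin"`).
#' @param concentration initial free-inhibitor concentration in uM
#'   (default 20).
#' @param targets character vector of target species names (>= 1).
#' @param k_on association rate constant, 1/(uM s).
#' @param k_off dissociation rate constant, 1/s.
#' @return A list of class `inhibition_spec`.
#' @export
inhibition_spec <- function(name = "curcumin", concentration = 20, targets,
                            k_on, k_off) {
  stopifnot(concentration >= 0, length(targets) >= 1, k_on >= 0, k_off >= 0)
  structure(list(name = name, concentration = concentration,
                 targets = as.character(targets), k_on = k_on, k_off = k_off),
            class = "inhibition_spec")
}

#' Inject an inhibitor into a kinetic model
#'
#' Adds a free-inhibitor species and, per target, an inert target-inhibitor
#' complex with the reversible binding reaction
#' `target + inhibitor <-> complex` (mass action, `k_on`/`k_off`). All
#' original reactions are untouched; sequestered target is simply removed
#' from the reactive pool.
#'
#' @param model a [kinetic_model].
#' @param spec an [inhibition_spec()].
#' @return A new `kinetic_model`.
#' @export
add_inhibitor <- function(model, spec) {
  stopifnot(inherits(model, "kinetic_model"), inherits(spec, "inhibition_spec"))
  unknown <- setdiff(spec$targets, names(model$species))
  if (length(unknown)) {
    stop("unknown inhibition target(s): ", paste(unknown, collapse = ", "))
  }
  species <- model$species
  species[spec$name] <- spec$concentration
  reactions <- model$reactions
  for (tg in spec$targets) {
    cx <- paste(tg, spec$name, sep = "_")
    species[cx] <- 0
    reactions[[length(reactions) + 1]] <- list(
      id = paste0("bind_", cx),
      reactants = stats::setNames(c(1L, 1L), c(tg, spec$name)),
      products = stats::setNames(1L, cx),
      rate = spec$k_on, reverse_rate = spec$k_off)
  }
  kinetic_model(species, reactions)
}

#' Concentration at an arbitrary time
#'
#' Linear interpolation between trajectory grid points; exact at grid
#' points.
#'
#' @param traj a `kinetic_trajectory`.
#' @param species a species name present in the trajectory.
#' @param t query time in \[0, t_end\].
#' @return Concentration in uM.
#' @export
concentration_at <- function(traj, species, t) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  if (!species %in% colnames(traj$conc)) stop("unknown species: ", species)
  if (any(t < min(traj$time) | t > max(traj$time))) {
    stop("time outside the simulated range")
  }
  stats::approx(traj$time, traj$conc[, species], xout = t)$y
}

#' Load a kinetic model
#'
#' Accepts an SBML level-2 file restricted to mass-action kinetic laws (see
#' [read_sbml()]), a list with `species`/`reactions` elements, or a
#' `kinetic_model` (returned unchanged).
#'
#' @param source file path, list spec, or `kinetic_model`.
#' @return A [kinetic_model].
#' @export
load_model <- function(source) {
  if (inherits(source, "kinetic_model")) return(source)
  if (is.character(source) && length(source) == 1) return(read_sbml(source))
  if (is.list(source) && !is.null(source$species)) {
    return(kinetic_model(source$species,
                         if (is.null(source$reactions)) list() else source$reactions))
  }
  stop("load_model: unsupported source")
}
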