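# Kinetic ODE simulation: the reaction network's stoichiometry-weighted
# kinetic laws define d[S]/dt; integration is adaptive Dormand-Prince 5(4)
# (compiled, src/integrators.cpp) honoring the absolute/relative
# tolerances; an independent fixed-step RK4 over mass-action arrays built
# straight from a reaction scheme serves as the reference oracle.

#' Simulation settings
#'
#' Mirrors the simulation interface's tunable fields: time window, number
#' of output points, solver tolerances (engine defaults 1e-16 absolute,
#' 1e-6 relative), parameter and initial-value overrides, and the species
#' / flux selections.
#'
#' @param t_start,t_end time window (`t_end > t_start`), in the model's
#'   time units.
#' @param n_points number of evenly spaced output points (>= 2).
#' @param abs_tol,rel_tol positive solver tolerances.
#' @param parameter_overrides named numeric vector: global parameter,
#'   compartment-size or local-parameter id -> value, applied before
#'   integration.
#' @param initial_overrides named numeric vector: species id -> strictly
#'   positive initial value (interpreted in the species' declared form).
#' @param selected_species,selected_fluxes ids to report (`NULL` = all).
#' @return a `simulation_settings` object.
#' @export
simulation_settings <- function(t_start = 0, t_end = 10, n_points = 100L,
                                abs_tol = 1e-16, rel_tol = 1e-6,
                                parameter_overrides = numeric(),
                                initial_overrides = numeric(),
                                selected_species = NULL,
                                selected_fluxes = NULL) {
  if (!(t_end > t_start))
    stop_sbml("sbmlfuse_settings_error", "t_end must exceed t_start")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2)
    stop_sbml("sbmlfuse_settings_error", "n_points must be at least 2")
  if (abs_tol <= 0 || rel_tol <= 0)
    stop_sbml("sbmlfuse_settings_error", "tolerances must be positive")
  if (length(initial_overrides) && any(initial_overrides <= 0))
    stop_sbml("sbmlfuse_settings_error",
              "initial overrides must be strictly positive")
  structure(list(t_start = t_start, t_end = t_end, n_points = n_points,
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 parameter_overrides = parameter_overrides,
                 initial_overrides = initial_overrides,
                 selected_species = selected_species,
                 selected_fluxes = selected_fluxes),
            class = "simulation_settings")
}

parse_fundefs <- function(model) {
  defs <- list()
  for (e in model$other_elements) {
    if (e$container != "listOfFunctionDefinitions") next
    node <- xml2::read_xml(e$xml)
    math <- xml2::xml_find_first(node, "./*[local-name()='math']")
    if (inherits(math, "xml_missing")) next
    defs[[e$id]] <- parse_mathml(math)
  }
  defs
}

reject_unsupported <- function(model) {
  for (e in model$other_elements) {
    if (e$container == "listOfEvents")
      stop_sbml("sbmlfuse_unsupported_error",
                "events are unsupported for simulation")
    if (e$container == "listOfInitialAssignments")
      stop_sbml("sbmlfuse_unsupported_error",
                "initial assignments are unsupported for simulation")
    if (e$container == "listOfRules" &&
        e$tag %in% c("rateRule", "algebraicRule"))
      stop_sbml("sbmlfuse_unsupported_error", sprintf(
        "%s is unsupported for simulation", e$tag))
  }
}

parse_assignment_rules <- function(model, fundefs) {
  rules <- list()
  for (e in model$other_elements) {
    if (e$container != "listOfRules" || e$tag != "assignmentRule") next
    node <- xml2::read_xml(e$xml)
    math <- xml2::xml_find_first(node, "./*[local-name()='math']")
    rules[[length(rules) + 1L]] <- list(
      variable = xml2::xml_attr(node, "variable"),
      expr = math_to_rexpr(parse_mathml(math), fundefs))
  }
  rules
}

#' Build the ODE system implied by a model's reactions
#'
#' For each non-boundary, non-constant species S,
#' `d[S]/dt = sum_r nu_{S,r} v_r / size(compartment(S))` (no compartment
#' division for species carrying only substance units, whose state is an
#' amount). Boundary and constant species get zero derivative but still
#' enter rate laws. Assignment rules are evaluated before every
#' derivative call; events, rate/algebraic rules, initial assignments and
#' delays are rejected.
#'
#' @param model an `sbml_model`; every reaction must have a kinetic law
#'   and every math identifier must resolve to a species, parameter
#'   (global or local), compartment, or time.
#' @return an `ode_system`: state ids and initial values, `deriv(t, y)`,
#'   per-reaction `rates(t, y)`, and reaction ids.
#' @export
build_ode_system <- function(model) {
  reject_unsupported(model)
  validate_model(model)
  fundefs <- parse_fundefs(model)
  rules <- parse_assignment_rules(model, fundefs)

  sp_ids <- element_ids(model$species)
  comp_size <- stats::setNames(
    vapply(model$compartments, function(cp) cp$size %||% 1, numeric(1)),
    element_ids(model$compartments))

  env <- new.env(parent = baseenv())
  for (cid in names(comp_size)) assign(cid, comp_size[[cid]], envir = env)
  for (p in model$parameters)
    assign(p$id, if (is.na(p$value)) 0 else p$value, envir = env)
  env$.time_ <- 0

  rule_vars <- vapply(rules, `[[`, character(1), "variable")

  # state: concentration unless hasOnlySubstanceUnits (then amount)
  init <- numeric(length(sp_ids))
  amount_state <- logical(length(sp_ids))
  fixed <- logical(length(sp_ids))
  size_of <- numeric(length(sp_ids))
  for (i in seq_along(model$species)) {
    s <- model$species[[i]]
    size <- comp_size[[s$compartment]]
    size_of[i] <- size
    amount_state[i] <- s$has_only_substance_units
    v <- s$initial$value
    init[i] <- if (s$has_only_substance_units) {
      if (s$initial$type == "amount") v else v * size
    } else {
      if (s$initial$type == "amount") v / size else v
    }
    fixed[i] <- s$boundary_condition || s$constant || s$id %in% rule_vars
  }
  names(init) <- sp_ids

  rxn_ids <- element_ids(model$reactions)
  n_sp <- length(sp_ids); n_rx <- length(model$reactions)
  N <- matrix(0, n_sp, n_rx, dimnames = list(sp_ids, rxn_ids))
  rate_exprs <- vector("list", n_rx)
  rate_envs <- vector("list", n_rx)
  known <- c(sp_ids, names(comp_size), element_ids(model$parameters),
             names(fundefs), rule_vars, "time")
  for (j in seq_len(n_rx)) {
    r <- model$reactions[[j]]
    if (is.null(r$kinetic_law) || is.null(r$kinetic_law$math))
      stop_sbml("sbmlfuse_simulation_error",
                sprintf("reaction '%s' has no kinetic law", r$id))
    for (ref in r$reactants)
      N[ref$species, j] <- N[ref$species, j] - ref$stoichiometry
    for (ref in r$products)
      N[ref$species, j] <- N[ref$species, j] + ref$stoichiometry
    locals <- r$kinetic_law$parameters
    local_ids <- element_ids(locals)
    for (ident in math_identifiers(r$kinetic_law$math, include_calls = FALSE))
      if (!ident %in% c(known, local_ids))
        stop_sbml("sbmlfuse_simulation_error", sprintf(
          "reaction '%s': unresolved identifier '%s' in kinetic law",
          r$id, ident))
    rate_exprs[[j]] <- math_to_rexpr(r$kinetic_law$math, fundefs)
    # local parameters shadow globals within their law
    renv <- if (length(locals)) {
      le <- new.env(parent = env)
      for (p in locals) assign(p$id, if (is.na(p$value)) 0 else p$value,
                               envir = le)
      le
    } else env
    rate_envs[[j]] <- renv
  }

  apply_rules <- function(t, y) {
    env$.time_ <- t
    for (i in seq_len(n_sp)) assign(sp_ids[i], y[i], envir = env)
    for (rl in rules)
      assign(rl$variable, eval(rl$expr, envir = env), envir = env)
  }
  rates <- function(t, y) {
    apply_rules(t, y)
    vapply(seq_len(n_rx),
           function(j) as.numeric(eval(rate_exprs[[j]],
                                       envir = rate_envs[[j]])),
           numeric(1))
  }
  scale <- ifelse(amount_state, 1, 1 / size_of)
  deriv <- function(t, y) {
    v <- rates(t, y)
    dy <- as.numeric(N %*% v) * scale
    dy[fixed] <- 0
    dy
  }

  structure(list(state_ids = sp_ids, init = init, deriv = deriv,
                 rates = rates, reaction_ids = rxn_ids,
                 stoichiometry = N, fixed = fixed, env = env),
            class = "ode_system")
}

apply_overrides <- function(model, settings) {
  po <- settings$parameter_overrides
  for (nm in names(po)) {
    hit <- FALSE
    for (i in seq_along(model$parameters))
      if (model$parameters[[i]]$id == nm) {
        model$parameters[[i]]$value <- po[[nm]]; hit <- TRUE
      }
    for (i in seq_along(model$compartments))
      if (model$compartments[[i]]$id == nm) {
        model$compartments[[i]]$size <- po[[nm]]; hit <- TRUE
      }
    for (i in seq_along(model$reactions)) {
      kl <- model$reactions[[i]]$kinetic_law
      if (is.null(kl)) next
      for (k in seq_along(kl$parameters))
        if (kl$parameters[[k]]$id == nm) {
          model$reactions[[i]]$kinetic_law$parameters[[k]]$value <- po[[nm]]
          hit <- TRUE
        }
    }
    if (!hit)
      stop_sbml("sbmlfuse_settings_error",
                sprintf("parameter override '%s' matches nothing", nm))
  }
  io <- settings$initial_overrides
  for (nm in names(io)) {
    idx <- which(element_ids(model$species) == nm)
    if (!length(idx))
      stop_sbml("sbmlfuse_settings_error",
                sprintf("initial override '%s' matches no species", nm))
    model$species[[idx]]$initial$value <- io[[nm]]
  }
  model
}

#' Simulate a model's time course
#'
#' Applies the settings' overrides, builds the ODE system and integrates
#' it with the adaptive Dormand-Prince 5(4) solver honoring
#' `abs_tol`/`rel_tol`, sampling the solution on `n_points` evenly spaced
#' times. Fluxes are the selected reactions' kinetic-law values along the
#' trajectory.
#'
#' @param model an `sbml_model`.
#' @param settings a [simulation_settings()].
#' @return a `simulation_result`: `time`, `species` (matrix, one column
#'   per selected species), `fluxes` (matrix, one column per selected
#'   reaction) and solver `diagnostics`.
#' @export
simulate_model <- function(model, settings = simulation_settings()) {
  model <- apply_overrides(model, settings)
  sys <- build_ode_system(model)
  tgrid <- seq(settings$t_start, settings$t_end,
               length.out = settings$n_points)
  res <- tryCatch(
    ode_dopri5(sys$deriv, sys$init, tgrid, settings$abs_tol,
               settings$rel_tol, 0, 1000000L),
    error = function(e) stop_sbml(
      "sbmlfuse_simulation_error",
      paste0("integration failed: ", conditionMessage(e))))
  y <- res$y
  colnames(y) <- sys$state_ids
  if (!all(is.finite(y)))
    stop_sbml("sbmlfuse_simulation_error",
              "integration produced non-finite state")
  fl <- matrix(0, length(tgrid), length(sys$reaction_ids),
               dimnames = list(NULL, sys$reaction_ids))
  for (i in seq_along(tgrid))
    fl[i, ] <- sys$rates(tgrid[i], y[i, ])

  keep_sp <- settings$selected_species %||% sys$state_ids
  keep_fl <- settings$selected_fluxes %||% sys$reaction_ids
  structure(list(
    time = tgrid,
    species = y[, intersect(colnames(y), keep_sp), drop = FALSE],
    fluxes = fl[, intersect(colnames(fl), keep_fl), drop = FALSE],
    diagnostics = list(n_steps = res$n_steps, n_accept = res$n_accept,
                       n_reject = res$n_reject)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d points on [%s, %s]; %d species, %d flux(es)\n",
    length(x$time), fmt_num(x$time[1]), fmt_num(x$time[length(x$time)]),
    ncol(x$species), ncol(x$fluxes)))
  cat(sprintf("  solver: %d accepted / %d rejected steps\n",
              x$diagnostics$n_accept, x$diagnostics$n_reject))
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  data.frame(time = x$time, x$species, x$fluxes, check.names = FALSE)
}

#' Independent fixed-step reference trajectory for a reaction scheme
#'
#' Oracle route: mass-action rate arrays are built directly from the
#' parsed scheme (bypassing SBML, MathML and the adaptive solver
#' entirely) and integrated with a fixed-step classical RK4 in compiled
#' code. Used to cross-check [simulate_model()] on generated fixtures.
#'
#' @param scheme a [parse_scheme()] result.
#' @param rate_constants numeric vector as consumed by
#'   [scheme_to_model()] (one value per irreversible reaction, two per
#'   reversible one).
#' @param tgrid output time points (first entry is the initial time).
#' @param h fixed step size.
#' @param init named initial concentrations (default 1 for every label).
#' @return matrix of concentrations, one column per species label.
#' @export
reference_trajectory <- function(scheme, rate_constants, tgrid, h,
                                 init = NULL) {
  labels <- scheme$species
  n_sp <- length(labels); n_rx <- length(scheme$reactions)
  y0 <- stats::setNames(rep(1, n_sp), labels)
  if (!is.null(init)) y0[names(init)] <- init
  net <- matrix(0, n_sp, n_rx)
  ordR <- matrix(0, n_sp, n_rx)
  ordP <- matrix(0, n_sp, n_rx)
  kf <- numeric(n_rx); kr <- numeric(n_rx)
  ki <- 1L
  for (j in seq_len(n_rx)) {
    rx <- scheme$reactions[[j]]
    for (term in rx$reactants) {
      i <- match(term$label, labels)
      net[i, j] <- net[i, j] - term$stoichiometry
      ordR[i, j] <- ordR[i, j] + term$stoichiometry
    }
    for (term in rx$products) {
      i <- match(term$label, labels)
      net[i, j] <- net[i, j] + term$stoichiometry
      ordP[i, j] <- ordP[i, j] + term$stoichiometry
    }
    kf[j] <- rate_constants[ki]; ki <- ki + 1L
    if (rx$reversible) { kr[j] <- rate_constants[ki]; ki <- ki + 1L }
  }
  boundary <- labels %in% scheme$boundary
  y <- ode_rk4_mass_action(net, ordR, ordP, kf, kr, boundary,
                           unname(y0), tgrid, h)
  colnames(y) <- labels
  y
}

#' Load experimental time-course data from CSV
#'
#' First column is time; remaining columns are keyed by their header
#' label (positional labels `col1`, `col2`, ... when there is no header
#' row). Rows are sorted by time, which must then be strictly increasing.
#'
#' @param x path to a CSV file, or the CSV text itself.
#' @return an `experimental_series` with `time` and `columns`.
#' @export
load_experimental_csv <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE)
  else strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop_sbml("sbmlfuse_csv_error", "empty CSV input")
  dequote <- function(x) sub('^"(.*)"$', "\\1", x)
  cells <- lapply(lines, function(l)
    dequote(trimws(strsplit(l, ",", fixed = TRUE)[[1]])))
  ncols <- length(cells[[1]])
  first_numeric <- !anyNA(suppressWarnings(as.numeric(cells[[1]])))
  labels <- if (first_numeric) {
    c("time", paste0("col", seq_len(ncols - 1)))
  } else {
    hdr <- cells[[1]]; cells <- cells[-1]
    hdr
  }
  if (!length(cells))
    stop_sbml("sbmlfuse_csv_error", "CSV has a header but no data rows")
  rows <- matrix(NA_real_, length(cells), ncols)
  for (i in seq_along(cells)) {
    row_no <- i + if (first_numeric) 0L else 1L
    if (length(cells[[i]]) != ncols)
      stop_sbml("sbmlfuse_csv_error", sprintf(
        "ragged CSV: row %d has %d field(s), expected %d",
        row_no, length(cells[[i]]), ncols))
    vals <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(vals))
      stop_sbml("sbmlfuse_csv_error",
                sprintf("non-numeric cell in CSV row %d", row_no))
    rows[i, ] <- vals
  }
  ord <- order(rows[, 1])
  rows <- rows[ord, , drop = FALSE]
  if (any(diff(rows[, 1]) <= 0))
    stop_sbml("sbmlfuse_csv_error", "time column must be strictly increasing")
  cols <- lapply(seq_len(ncols - 1) + 1L, function(j) rows[, j])
  names(cols) <- labels[-1]
  structure(list(time = rows[, 1], columns = cols),
            class = "experimental_series")
}

#' Overlay a simulation with experimental data
#'
#' Builds a table on the union time grid of the simulation and the
#' experimental series; simulated series are linearly interpolated at the
#' experimental time points, and the per-column root-mean-square
#' deviation is reported for every experimental label matching a species
#' or flux id. Unmatched labels are carried and flagged.
#'
#' @param result a `simulation_result`.
#' @param exp an `experimental_series` (or `NULL`).
#' @return an `overlay_table`: `table` (data frame on the union grid),
#'   `rms` (named numeric), `unmatched` (character).
#' @export
overlay <- function(result, exp = NULL) {
  sim_cols <- cbind(result$species, result$fluxes)
  if (is.null(exp) || !length(exp$time)) {
    tab <- data.frame(time = result$time, sim_cols, check.names = FALSE)
    return(structure(list(table = tab, rms = stats::setNames(
      numeric(), character()), unmatched = character()),
      class = "overlay_table"))
  }
  tu <- sort(union(result$time, exp$time))
  interp <- function(y, at) stats::approx(result$time, y, xout = at,
                                          rule = 2)$y
  tab <- data.frame(time = tu)
  for (nm in colnames(sim_cols)) tab[[nm]] <- interp(sim_cols[, nm], tu)
  rms <- numeric(); unmatched <- character()
  for (nm in names(exp$columns)) {
    col <- rep(NA_real_, length(tu))
    col[match(exp$time, tu)] <- exp$columns[[nm]]
    tab[[paste0(nm, ".exp")]] <- col
    if (nm %in% colnames(sim_cols)) {
      pred <- interp(sim_cols[, nm], exp$time)
      rms[nm] <- sqrt(mean((pred - exp$columns[[nm]])^2))
    } else unmatched <- c(unmatched, nm)
  }
  structure(list(table = tab, rms = rms, unmatched = unmatched),
            class = "overlay_table")
}

#' @export
print.overlay_table <- function(x, ...) {
  cat(sprintf("<overlay_table> %d rows, %d column(s)\n", nrow(x$table),
              ncol(x$table) - 1))
  if (length(x$rms))
    cat(sprintf("  RMS %s: %s\n", names(x$rms),
                vapply(x$rms, fmt_num, character(1))), sep = "")
  if (length(x$unmatched))
    cat("  unmatched label(s):", paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}
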