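# Workbench: serialization of circuits, mechanisms and scans; schematic
# square-wave rhythm generators; and the deterministic fixture suite that
# makes every module testable without long evolutionary runs.

CIRCUIT_DB_SCHEMA <- "pyloricnet/circuit-db/1"
MECH_DB_SCHEMA <- "pyloricnet/mechanism-db/1"
SCAN_SCHEMA <- "pyloricnet/scan/1"

#' Flatten a circuit to the serialization key set
#' @param circuit a [circuit_params()] object.
#' @return named list with keys `tau_LP`, ..., `theta_LP`, ...,
#'   `w_LP_to_LP`, ..., `w_PD_to_PD`.
#' @export
circuit_to_flat <- function(circuit) {
  out <- c(as.list(setNames(circuit$tau, paste0("tau_", NEURONS))),
           as.list(setNames(circuit$theta, paste0("theta_", NEURONS))))
  for (i in NEURONS) for (j in NEURONS)
    out[[paste0("w_", i, "_to_", j)]] <- unname(circuit$w[i, j])
  out
}

#' Rebuild a circuit from its flat representation
#' @param flat named list/vector as produced by [circuit_to_flat()].
#' @param weight_range allowed weight range.
#' @return a [circuit_params()] object.
#' @export
flat_to_circuit <- function(flat, weight_range = c(-16, 16)) {
  g <- function(k) {
    if (is.null(flat[[k]])) stop("missing field ", k, " in circuit record")
    as.numeric(flat[[k]])
  }
  circuit_params(
    tau = setNames(vapply(paste0("tau_", NEURONS), g, numeric(1)), NEURONS),
    theta = setNames(vapply(paste0("theta_", NEURONS), g, numeric(1)),
                     NEURONS),
    w = setNames(unlist(lapply(NEURONS, function(i)
      lapply(NEURONS, function(j) g(paste0("w_", i, "_to_", j))))),
      unlist(lapply(NEURONS, function(i)
        paste0("w_", i, "_to_", NEURONS)))),
    weight_range = weight_range)
}

stop_schema <- function(path, expected, found) {
  stop("file ", path, " is not a valid ", expected, " file (schema: ",
       if (is.null(found)) "missing" else found, ")")
}

read_json_checked <- function(path, expected_schema) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("cannot parse ", path, " (truncated or not JSON): ",
                         conditionMessage(e)))
  if (!identical(obj$schema, expected_schema))
    stop_schema(path, expected_schema, obj$schema)
  obj
}

#' Write / read a circuit database
#'
#' A circuit database is a JSON object with a schema tag, free-form
#' provenance metadata, and an array of flat circuit records (each
#' optionally carrying its own provenance, e.g. GA seed and fitness).
#'
#' @param circuits list of [circuit_params()] or of lists with elements
#'   `circuit` and `provenance`.
#' @param path output file.
#' @param meta named list of database-level metadata (seeds, configs, ...).
#' @return `path`, invisibly.
#' @export
write_circuit_db <- function(circuits, path, meta = list()) {
  recs <- lapply(circuits, function(x) {
    if (inherits(x, "circuit_params")) {
      circuit_to_flat(x)
    } else {
      c(circuit_to_flat(x$circuit), list(provenance = x$provenance))
    }
  })
  jsonlite::write_json(list(schema = CIRCUIT_DB_SCHEMA, meta = meta,
                            circuits = recs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_circuit_db
#' @param weight_range allowed weight range for validation on read.
#' @return for the reader: list with `circuits` (list of
#'   [circuit_params()]), `provenance` per record and the `meta` list.
#' @export
read_circuit_db <- function(path, weight_range = c(-16, 16)) {
  obj <- read_json_checked(path, CIRCUIT_DB_SCHEMA)
  circuits <- lapply(obj$circuits, flat_to_circuit,
                     weight_range = weight_range)
  prov <- lapply(obj$circuits, function(r) r$provenance)
  list(circuits = circuits, provenance = prov, meta = obj$meta)
}

mechanism_to_flat <- function(m) {
  list(regulated = as.list(m$regulated), LB = as.list(m$LB),
       delta = as.list(m$delta), s = as.list(m$s),
       tau_theta = as.list(m$tau_theta),
       bias_range = as.list(m$bias_range))
}

flat_to_mechanism <- function(r) {
  reg <- unlist(r$regulated)
  adhp_mechanism(regulated = reg,
                 LB = setNames(unlist(r$LB), reg),
                 delta = setNames(unlist(r$delta), reg),
                 s = setNames(unlist(r$s), reg),
                 tau_theta = setNames(unlist(r$tau_theta), reg),
                 bias_range = unlist(r$bias_range))
}

#' Write / read a mechanism database
#' @param mechanisms list of [adhp_mechanism()] or of lists with elements
#'   `mechanism` and `provenance`.
#' @inheritParams write_circuit_db
#' @export
write_mechanism_db <- function(mechanisms, path, meta = list()) {
  recs <- lapply(mechanisms, function(x) {
    if (inherits(x, "adhp_mechanism")) mechanism_to_flat(x)
    else c(mechanism_to_flat(x$mechanism), list(provenance = x$provenance))
  })
  jsonlite::write_json(list(schema = MECH_DB_SCHEMA, meta = meta,
                            mechanisms = recs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mechanism_db
#' @export
read_mechanism_db <- function(path) {
  obj <- read_json_checked(path, MECH_DB_SCHEMA)
  mechs <- lapply(obj$mechanisms, flat_to_mechanism)
  prov <- lapply(obj$mechanisms, function(r) r$provenance)
  list(mechanisms = mechs, provenance = prov, meta = obj$meta)
}

# small deterministic string hash (djb2), used for scan integrity and
# fixture-suite identity
djb2 <- function(s) {
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", h)
}

scan_payload_hash <- function(scan) {
  djb2(paste(c(scan$axes, sprintf("%.6g", unlist(scan$values)),
               sprintf("%.6g", unlist(lapply(scan$obar, as.vector))),
               as.integer(as.vector(scan$pyloric))), collapse = ","))
}

#' Write / read a grid scan
#'
#' The scan is stored as a single JSON document (axes, grid values, flat
#' arrays) with an integrity checksum over the payload; the reader
#' re-computes the checksum and refuses silently corrupted files.
#'
#' @param scan a [scan_subspace()] result.
#' @param path output file.
#' @export
write_scan <- function(scan, path) {
  payload <- list(
    schema = SCAN_SCHEMA, axes = as.list(scan$axes),
    values = scan$values, dims = as.list(unname(scan$dims)),
    step = scan$step, bounds = as.list(scan$bounds),
    obar = lapply(scan$obar, as.vector),
    period = as.vector(scan$period),
    oscillatory = as.vector(scan$oscillatory),
    pyloric = as.vector(scan$pyloric),
    one_per_cycle = as.vector(scan$one_per_cycle),
    tie = as.vector(scan$tie),
    n_bursting = as.vector(scan$n_bursting),
    dynamics = as.vector(scan$dynamics),
    circuit = circuit_to_flat(scan$circuit),
    checksum = scan_payload_hash(scan))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  obj <- read_json_checked(path, SCAN_SCHEMA)
  dims <- unlist(obj$dims)
  arr <- function(v, mode = "numeric") {
    v <- vapply(v, function(x) {
      if (is.null(x) || (is.character(x) && x %in% c("NA", "NaN")))
        NA_real_ else as.numeric(x) # JSON null (or legacy "NA") -> NA
    }, numeric(1))
    v <- if (mode == "logical") as.logical(v)
         else if (mode == "integer") as.integer(v) else v
    array(v, dim = dims)
  }
  axes <- unlist(obj$axes)
  values <- lapply(obj$values, function(v) as.numeric(unlist(v)))
  names(values) <- axes
  scan <- structure(list(
    circuit = flat_to_circuit(obj$circuit),
    axes = axes, values = values, dims = setNames(dims, axes),
    step = obj$step, bounds = unlist(obj$bounds),
    obar = setNames(lapply(obj$obar, arr), names(obj$obar)),
    period = arr(obj$period),
    oscillatory = arr(obj$oscillatory, "logical"),
    pyloric = arr(obj$pyloric, "logical"),
    one_per_cycle = arr(obj$one_per_cycle, "logical"),
    tie = arr(obj$tie, "logical"),
    n_bursting = arr(obj$n_bursting, "integer"),
    dynamics = arr(obj$dynamics, "integer"),
    settled = arr(obj$dynamics, "integer") != 2L,
    config = sim_config()), class = "grid_scan")
  if (!identical(scan_payload_hash(scan), obj$checksum))
    stop("integrity error: checksum mismatch in scan file ", path)
  scan
}

#' Export a trajectory as CSV
#' @param trajectory a `ctrnn_trajectory`.
#' @param path output file (columns: time, y_*, o_*).
#' @export
write_rhythm_csv <- function(trajectory, path) {
  df <- data.frame(time = trajectory$time)
  for (nm in NEURONS) df[[paste0("y_", nm)]] <- trajectory$y[, nm]
  for (nm in NEURONS) df[[paste0("o_", nm)]] <- trajectory$o[, nm]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Schematic square-wave rhythm
#'
#' Builds a synthetic trajectory realizing a given burst-event ordering as
#' a square-wave pattern (outputs `lo`/`hi` around the 0.5 threshold), for
#' testing the rhythm classifier without simulating a circuit. Event
#' phases can be given explicitly to realize specific duty cycles and
#' phases; by default the six events are evenly spaced.
#'
#' @param ordering an ordering string (see [enumerate_orderings()]).
#' @param period rhythm period in seconds.
#' @param n_cycles number of cycles generated.
#' @param dt sample step.
#' @param lo,hi output levels outside/inside bursts.
#' @param phases optional named numeric of all six event phases in
#'   `[0, 1)` (names `LP_S`, `LP_E`, `PY_S`, `PY_E`, `PD_S`, `PD_E`);
#'   overrides `ordering`.
#' @return a `ctrnn_trajectory`-like object (time, `o`, `y = logit(o)`).
#' @export
square_wave_rhythm <- function(ordering = featured_ordering(), period = 1,
                               n_cycles = 8, dt = 0.001, lo = 0.1,
                               hi = 0.9, phases = NULL) {
  if (is.null(phases)) {
    ev <- strsplit(ordering, " ")[[1]]
    stopifnot(length(ev) == 6L, ev[1] == "LP_S",
              setequal(ev, EVENT_NAMES))
    phases <- setNames((seq_along(ev) - 1) / 6, ev)
  }
  stopifnot(setequal(names(phases), EVENT_NAMES))
  time <- seq(0, n_cycles * period, by = dt)
  ph <- (time / period) %% 1
  o <- matrix(lo, length(time), 3, dimnames = list(NULL, NEURONS))
  for (nm in NEURONS) {
    s <- phases[[paste0(nm, "_S")]]
    e <- phases[[paste0(nm, "_E")]]
    inb <- if (s < e) ph >= s & ph < e else ph >= s | ph < e
    o[inb, nm] <- hi
  }
  structure(list(time = time, o = o, y = logit(o), dt = dt,
                 config = sim_config(dt = dt)),
            class = "ctrnn_trajectory")
}

#' Deterministic fixture suite
#'
#' Loads the certified fixture circuits shipped with the package: a
#' zero-weight analytic circuit and pyloric oscillators covering the
#' regulatability archetypes (fully-regulatable/separable, 2D-inseparable,
#' and pyloric-unstable). Each record carries its construction recipe and
#' certified properties; certifications are re-verified in the test suite.
#'
#' @return list of fixture records (`id`, `circuit`, `certified`,
#'   `recipe`).
#' @export
fixture_suite <- function() {
  path <- system.file("extdata", "fixture_circuits.json",
                      package = "pyloricnet")
  if (!nzchar(path)) stop("fixture suite not found in installed package")
  obj <- read_json_checked(path, CIRCUIT_DB_SCHEMA)
  lapply(obj$circuits, function(r) {
    list(id = r$provenance$id, circuit = flat_to_circuit(r),
         certified = r$provenance$certified, recipe = r$provenance$recipe)
  })
}

#' Generate and certify a fixture suite
#'
#' Reproducibly builds the fixture suite from a seed: the zero-weight
#' analytic circuit, the ten square-wave generators (one per pyloric
#' ordering), and — when `archetypes` is `TRUE` — pyloric oscillators
#' found by short seeded GA runs and certified by scanning their
#' theta_LP/theta_PD plane until one circuit per requested regulatability
#' archetype is found or the run budget is exhausted (the suite is then
#' marked `partial`).
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param archetypes character vector of [separability()] verdicts to
#'   search for.
#' @param max_runs GA run budget for the archetype search.
#' @param ga a [ga_config()] template for each search run (the seed field
#'   is overridden deterministically per run).
#' @param sim a [sim_config()] for evaluation.
#' @param scan_step grid step used for certification scans.
#' @return list with `zero_weight`, `square_waves`, `archetypes` (found
#'   records), `partial` flag, `diagnostics`, and a deterministic `hash`
#'   of the suite.
#' @export
generate_fixtures <- function(seed = 1,
                              archetypes = c("fully-regulatable",
                                             "partially-regulatable",
                                             "unregulatable"),
                              max_runs = 20,
                              ga = ga_config(pop_size = 40,
                                             generations = 30),
                              sim = sim_config(), scan_step = 1) {
  zero_weight <- circuit_params(tau = 1, theta = 0, w = matrix(0, 3, 3))
  orderings <- enumerate_orderings()$pyloric
  square_waves <- lapply(orderings, function(o)
    list(ordering = o, make = function() square_wave_rhythm(o)))
  names(square_waves) <- orderings

  found <- list()
  diagnostics <- character(0)
  remaining <- archetypes
  run <- 0L
  while (length(remaining) && run < max_runs) {
    run <- run + 1L
    cfg <- ga
    cfg$seed <- as.integer((seed * 1000L + run) %% .Machine$integer.max)
    ev <- evolve_circuits(cfg, mode = "base", sim = sim)
    if (!ev$admit_base) {
      diagnostics <- c(diagnostics,
                       sprintf("run %d: not pyloric (P_b=%.2f)", run,
                               ev$breakdown$P_b))
      next
    }
    scan <- scan_subspace(ev$circuit, c("LP", "PD"), step = scan_step,
                          config = sim)
    verdict <- separability(scan)$verdict
    diagnostics <- c(diagnostics, sprintf("run %d: pyloric, %s", run,
                                          verdict))
    if (verdict %in% remaining) {
      found[[verdict]] <- list(id = verdict, circuit = ev$circuit,
                               certified = list(pyloric = TRUE,
                                                verdict = verdict,
                                                scan_step = scan_step),
                               recipe = list(seed = cfg$seed,
                                             pop_size = cfg$pop_size,
                                             generations = cfg$generations))
      remaining <- setdiff(remaining, verdict)
    }
  }
  suite <- list(zero_weight = zero_weight, square_waves = names(square_waves),
                archetypes = found, partial = length(remaining) > 0,
                missing = remaining, diagnostics = diagnostics)
  suite$hash <- djb2(paste(
    c(unlist(circuit_to_flat(zero_weight)), names(square_waves),
      unlist(lapply(found, function(f) unlist(circuit_to_flat(f$circuit)))),
      as.character(seed)), collapse = ","))
  suite
}
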