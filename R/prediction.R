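# Predictive framework: map the ADHP-accessible bias subspace by grid
# scanning (cycle-averaged outputs + pyloric status per cell), derive
# homeostatic nullclines and predicted endpoints from the averaged flow,
# classify their stability, and decide regulatability and generalization.
#
# Averaged slow flow per regulated dimension i:
#   d theta_i / dt  ∝  (T1 + T - T2) LB_i + (T - T2) Delta_i
#                      - ∫_below o_i dt - ∫_above o_i dt
# which equals the cycle mean of rho(o_i); for a zero-width target range it
# reduces to B_i - mean(o_i). A nullcline crossing along axis i is stable
# when the flow is positive on the low-theta side and negative on the
# high-theta side (equivalently d mean(o_i)/d theta_i > 0 there). The hard
# bias bounds act as extra nullclines, stable where the flow points
# outward.

#' Scan an ADHP-accessible bias subspace
#'
#' For every grid point of the regulated biases (all other parameters
#' frozen at the circuit's values), the network is equilibrated and the
#' cycle-averaged outputs, rhythm period, pyloric status and dynamics
#' class are recorded.
#'
#' @param circuit a [circuit_params()] object.
#' @param axes regulated bias axes, a subset of `c("LP", "PY", "PD")`.
#' @param step grid step in bias units.
#' @param bounds bias range covered (default the full hard range).
#' @param config a [sim_config()]; its transient is the per-cell
#'   equilibration time.
#' @param initial initial fast state used for every cell (one initial
#'   condition per cell; multistable cells resolve to the limit set reached
#'   from it).
#' @return object of class `grid_scan`.
#' @export
scan_subspace <- function(circuit, axes = c("LP", "PD"), step = 0.25,
                          bounds = c(-16, 16), config = sim_config(),
                          initial = network_state()) {
  stopifnot(inherits(circuit, "circuit_params"),
            all(axes %in% NEURONS), !anyDuplicated(axes))
  check_dt(circuit, config)
  if (!inherits(initial, "network_state")) initial <- network_state(initial)
  values <- lapply(axes, function(a) seq(bounds[1], bounds[2], by = step))
  names(values) <- axes
  dims <- vapply(values, length, integer(1))
  res <- cpp_scan(circuit$tau, circuit$theta, circuit$w,
                  match(axes, NEURONS) - 1L, unname(values), initial$y,
                  config$dt, config$transient, config$record,
                  config$threshold, config$nonosc_window, config$period_tol,
                  config$dt, config$min_gap, method_code(config))
  arr <- function(v) array(v, dim = unname(dims), dimnames = NULL)
  obar <- lapply(NEURONS, function(nm) arr(res$obar[, nm]))
  names(obar) <- NEURONS
  structure(list(circuit = circuit, axes = axes, values = values,
                 dims = dims, step = step, bounds = bounds,
                 obar = obar, period = arr(res$period),
                 oscillatory = arr(res$oscillatory),
                 pyloric = arr(res$pyloric),
                 one_per_cycle = arr(res$one_per_cycle),
                 tie = arr(res$tie), n_bursting = arr(res$n_bursting),
                 # 0 fixed point, 1 oscillatory, 2 unclassified (neither a
                 # detected rhythm nor settled within the cell budget)
                 dynamics = arr(res$dynamics),
                 settled = arr(res$dynamics != 2L),
                 config = config),
            class = "grid_scan")
}

#' @export
print.grid_scan <- function(x, ...) {
  cat("<grid_scan> axes:", paste(x$axes, collapse = " x "),
      sprintf(" (%s cells, step %.3g)\n",
              paste(x$dims, collapse = "x"), x$step))
  cat("  pyloric cells:", sum(x$pyloric, na.rm = TRUE), "of",
      prod(x$dims), "\n")
  invisible(x)
}

#' Net homeostatic flow from an output trace or fixed-point value
#'
#' The cycle-averaged regulation drive: the mean of [rho()] over one cycle
#' of the sampled output (a scalar input is treated as a fixed-point
#' value). Its sign is the direction of slow bias change; zero-range
#' mechanisms reduce to `B - mean(o)`.
#'
#' @param o output samples over one cycle (uniformly sampled), or a single
#'   fixed-point output value.
#' @param LB,UB target range bounds.
#' @return list with `value` (mean drive) and `sign`.
#' @export
flow_sign <- function(o, LB, UB = LB) {
  v <- mean(rho(o, LB, UB))
  list(value = v, sign = sign(v))
}

# Flow field arrays over a scan for a mechanism, one per regulated axis.
# Zero-range: exact (B - obar). Positive-width ranges: the sign is exact
# for cells with obar outside [LB, UB] and for fixed-point cells; for
# oscillatory cells whose mean lies inside the target range the averaged
# drive cannot be recovered from the mean alone and is NA (ambiguous).
scan_flow_field <- function(scan, mechanism) {
  stopifnot(inherits(scan, "grid_scan"), inherits(mechanism,
                                                  "adhp_mechanism"))
  if (!setequal(mechanism$regulated, scan$axes))
    stop("mechanism must regulate exactly the scanned axes (",
         paste(scan$axes, collapse = ", "), ")")
  settled <- scan$settled %||% array(TRUE, dim = dim(scan$obar[[1]]))
  out <- lapply(scan$axes, function(a) {
    lb <- mechanism$LB[[a]]
    ub <- mechanism$UB[[a]]
    ob <- scan$obar[[a]]
    if (ub - lb < 1e-12) {
      F <- lb - ob
    } else {
      F <- array(NA_real_, dim = dim(ob))
      F[ob < lb] <- lb - ob[ob < lb]
      F[ob > ub] <- ub - ob[ob > ub]
      inr <- !is.na(ob) & ob >= lb & ob <= ub
      F[inr & !scan$oscillatory] <- 0
    }
    # cells that neither oscillate nor settle have no asymptotic average:
    # their flow is unknown, not a number
    F[!settled] <- NA_real_
    F
  })
  names(out) <- scan$axes
  out
}

# stable crossing along an axis: flow positive (or zero) below, negative
# (or zero) above, excluding flat zero (the dead-zone case is handled
# separately for wide target ranges)
stable_cross <- function(Fl, Fh) {
  !is.na(Fl) & !is.na(Fh) & Fl >= 0 & Fh <= 0 & (Fl > 0 | Fh < 0)
}

slice_arr <- function(A, d, idx) {
  args <- lapply(dim(A), seq_len)
  args[[d]] <- idx
  do.call(`[`, c(list(A), args, list(drop = FALSE)))
}

# average an array over adjacent index pairs along each dim in `ds`
# (each such dim shrinks by one)
block_avg <- function(A, ds) {
  for (e in ds) {
    n <- dim(A)[e]
    A <- (slice_arr(A, e, seq_len(n - 1)) + slice_arr(A, e, 1 + seq_len(n - 1))) / 2
  }
  A
}

# logical OR over adjacent index pairs along each dim in `ds`
block_or <- function(A, ds) {
  for (e in ds) {
    n <- dim(A)[e]
    A <- slice_arr(A, e, seq_len(n - 1)) | slice_arr(A, e, 1 + seq_len(n - 1))
  }
  A
}

#' Homeostatic nullclines of a mechanism over a scan
#'
#' Locates, per regulated axis, the sign changes of the averaged flow
#' between adjacent cells along that axis (sub-cell position by linear
#' interpolation), tagged stable (positive-to-negative, the attracting
#' arrangement) or unstable. The hard bias bounds are reported as boundary
#' nullclines wherever the flow points outward (those lines attract and
#' can pin the bias).
#'
#' @param scan a [scan_subspace()] result.
#' @param mechanism an [adhp_mechanism()] regulating the scanned axes.
#' @return list with per-axis data frames of crossing points (grid
#'   coordinates of all axes plus `position`, the interpolated coordinate
#'   along the crossing axis, and `stable`), and `boundary`, a data frame
#'   of outward-flow boundary conditions per axis and side.
#' @export
nullclines <- function(scan, mechanism) {
  Fs <- scan_flow_field(scan, mechanism)
  nd <- length(scan$axes)
  per_axis <- list()
  for (d in seq_len(nd)) {
    F <- Fs[[d]]
    n <- dim(F)[d]
    lo <- slice_arr(F, d, seq_len(n - 1))
    hi <- slice_arr(F, d, 1 + seq_len(n - 1))
    cross <- !is.na(lo) & !is.na(hi) &
      ((lo > 0 & hi <= 0) | (lo < 0 & hi >= 0) | (lo == 0 & hi != 0))
    idx <- which(cross, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      per_axis[[scan$axes[d]]] <- data.frame()
      next
    }
    frac <- lo[cross] / (lo[cross] - hi[cross])
    v <- scan$values[[d]]
    pos <- v[idx[, d]] + frac * (v[idx[, d] + 1] - v[idx[, d]])
    df <- as.data.frame(idx)
    names(df) <- paste0("i_", scan$axes)
    df$position <- pos
    df$stable <- lo[cross] > 0
    for (dd in seq_len(nd)) {
      df[[paste0("theta_", scan$axes[dd])]] <-
        if (dd == d) pos else scan$values[[dd]][idx[, dd]]
    }
    per_axis[[scan$axes[d]]] <- df
  }
  boundary <- do.call(rbind, lapply(seq_len(nd), function(d) {
    F <- Fs[[d]]
    n <- dim(F)[d]
    low_out <- slice_arr(F, d, 1) < 0    # flow pushes below the lower bound
    high_out <- slice_arr(F, d, n) > 0   # flow pushes above the upper bound
    data.frame(axis = scan$axes[d], side = c("low", "high"),
               value = scan$bounds,
               n_outward_cells = c(sum(low_out, na.rm = TRUE),
                                   sum(high_out, na.rm = TRUE)))
  }))
  list(interior = per_axis, boundary = boundary)
}

# Locate predicted endpoints: interior stable intersections of all
# nullclines, plus boundary endpoints where a subset of axes is pinned at
# an outward-flow bound and the remaining axes cross their nullclines
# stably. A sign change between two cells of different dynamics class is
# a jump across a bifurcation line, not a nullcline crossing (the average
# never passes through the target there): such crossings are suppressed
# and reported via the "suppressed" attribute — they are the flip-flop
# regime that can trap trajectories in large parametric limit cycles.
# Returns a data frame of endpoints.
locate_endpoints <- function(scan, Fs) {
  nd <- length(scan$axes)
  dyn_full <- scan$dynamics %||% (scan$oscillatory * 1L)
  rows <- list()
  suppressed <- FALSE
  sides <- expand.grid(rep(list(c("free", "low", "high")), nd),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(sides))) {
    st <- as.character(sides[r, ])
    pinned <- which(st != "free")
    free <- which(st == "free")
    G <- Fs
    P <- scan$pyloric
    D <- dyn_full
    for (p in pinned) {
      k <- if (st[p] == "low") 1L else dim(G[[1]])[p]
      G <- lapply(G, slice_arr, d = p, idx = k)
      P <- slice_arr(P, p, k)
      D <- slice_arr(D, p, k)
    }
    if (length(free) == 0L) {
      okc <- TRUE
      for (p in pinned) {
        v <- G[[p]][1]
        okc <- okc && !is.na(v) &&
          ((st[p] == "low" && v < 0) || (st[p] == "high" && v > 0))
      }
      if (okc && length(pinned) > 0) {
        coord <- vapply(seq_len(nd), function(d)
          if (st[d] == "low") scan$bounds[1] else scan$bounds[2],
          numeric(1))
        pylv <- as.logical(P[1])
        rows[[length(rows) + 1L]] <- make_ep_row(scan, coord, pylv, TRUE)
      }
      next
    }
    cond <- NULL
    cond_any <- NULL
    faces <- list()
    for (d in free) {
      n <- dim(G[[d]])[d]
      lo <- slice_arr(G[[d]], d, seq_len(n - 1))
      hi <- slice_arr(G[[d]], d, 1 + seq_len(n - 1))
      dl <- slice_arr(D, d, seq_len(n - 1))
      dh <- slice_arr(D, d, 1 + seq_len(n - 1))
      eq <- !is.na(dl) & !is.na(dh) & dl == dh
      # a stable crossing either of the block faces on average or of any
      # corner pair — face means alone miss nullclines cutting the block
      # diagonally, corner pairs alone miss shallow crossings
      sc <- stable_cross(lo, hi)
      Fl <- block_avg(lo, setdiff(free, d))
      Fh <- block_avg(hi, setdiff(free, d))
      anyc <- block_or(sc, setdiff(free, d)) | stable_cross(Fl, Fh)
      valid <- block_or(sc & eq, setdiff(free, d)) |
        (stable_cross(Fl, Fh) & block_or(eq, setdiff(free, d)))
      faces[[as.character(d)]] <- list(lo = Fl, hi = Fh)
      cond <- if (is.null(cond)) valid else cond & valid
      cond_any <- if (is.null(cond_any)) anyc else cond_any & anyc
    }
    for (p in pinned) {
      Pv <- block_avg(G[[p]], free)
      cd <- if (st[p] == "low") !is.na(Pv) & Pv < 0 else !is.na(Pv) & Pv > 0
      cond <- cond & cd
      cond_any <- cond_any & cd
    }
    if (any(cond_any & !cond, na.rm = TRUE)) suppressed <- TRUE
    hit <- which(cond, arr.ind = TRUE)
    if (is.null(dim(hit))) hit <- matrix(hit, ncol = length(dim(cond)))
    if (nrow(hit) == 0L) next
    for (h in seq_len(nrow(hit))) {
      bi <- hit[h, ]
      coord <- numeric(nd)
      cell_idx <- integer(nd)
      for (d in seq_len(nd)) {
        if (st[d] != "free") {
          coord[d] <- if (st[d] == "low") scan$bounds[1] else scan$bounds[2]
          cell_idx[d] <- if (st[d] == "low") 1L else scan$dims[d]
        } else {
          fl <- faces[[as.character(d)]]$lo[matrix(bi, 1)]
          fh <- faces[[as.character(d)]]$hi[matrix(bi, 1)]
          frac <- if (is.finite(fl) && is.finite(fh) && fl != fh)
            min(max(fl / (fl - fh), 0), 1) else 0.5
          v <- scan$values[[d]]
          coord[d] <- v[bi[d]] + frac * (v[bi[d] + 1] - v[bi[d]])
          cell_idx[d] <- bi[d] + as.integer(frac > 0.5)
        }
      }
      pylv <- as.logical(scan$pyloric[matrix(cell_idx, 1)])
      rows[[length(rows) + 1L]] <- make_ep_row(scan, coord, pylv,
                                               length(pinned) > 0)
    }
  }
  if (!length(rows)) {
    return(structure(data.frame(), suppressed = suppressed))
  }
  eps <- do.call(rbind, rows)
  # a nullcline passing exactly through a grid point is detected from both
  # adjacent blocks: de-duplicate coincident endpoints
  key <- apply(round(eps[, paste0("theta_", scan$axes), drop = FALSE], 9),
               1, paste, collapse = "|")
  structure(eps[!duplicated(paste(key, eps$boundary)), , drop = FALSE],
            suppressed = suppressed)
}

make_ep_row <- function(scan, coord, pyloric, boundary) {
  df <- as.data.frame(as.list(setNames(coord,
                                       paste0("theta_", scan$axes))))
  df$pyloric <- pyloric
  df$boundary <- boundary
  df
}

#' Predict homeostatic endpoints and the regulation category
#'
#' Intersects the stable branches of all regulated-axis nullclines
#' (including outward-flow boundary segments of the hard bias bounds) over
#' the scanned subspace, labels each predicted endpoint with the pyloric
#' status of a frozen-parameter probe at the interpolated endpoint (more
#' robust than the surrounding cells' flags near sharp pyloric
#' boundaries), and assigns an overall category:
#' `"reliable"` (endpoints exist, all pyloric), `"mixed"` (both),
#' `"fail"` (only non-pyloric), `"no-steady-state"` (none). Caveat flags
#' mark boundary-pinned endpoints and flip-flop risk (adjacent fixed-point
#' branches straddling the target with the unstable flow arrangement, the
#' regime that can spawn large parametric limit cycles which this static
#' framework does not predict).
#'
#' @inheritParams nullclines
#' @return object of class `prediction_report`.
#' @export
predict_endpoints <- function(scan, mechanism) {
  Fs <- scan_flow_field(scan, mechanism)
  eps <- locate_endpoints(scan, Fs)
  # wide-range mechanisms additionally capture whole dead-zone fixed-point
  # cells (zero drive everywhere inside the target range)
  static_capture <- 0L
  if (any(mechanism$delta > 1e-12)) {
    dead <- !scan$oscillatory
    for (d in seq_along(scan$axes)) dead <- dead & !is.na(Fs[[d]]) &
        Fs[[d]] == 0
    static_capture <- sum(dead, na.rm = TRUE)
    if (static_capture > 0) {
      idx <- which(dead, arr.ind = TRUE)
      if (is.null(dim(idx))) idx <- matrix(idx, ncol = length(scan$dims))
      caps <- lapply(seq_len(nrow(idx)), function(h) {
        coord <- vapply(seq_along(scan$axes), function(d)
          scan$values[[d]][idx[h, d]], numeric(1))
        make_ep_row(scan, coord, as.logical(scan$pyloric[matrix(idx[h, ], 1)]),
                    FALSE)
      })
      caps <- do.call(rbind, caps)
      eps <- if (nrow(eps)) rbind(eps, caps) else caps
    }
  }
  n_ep <- if (nrow(eps)) nrow(eps) else 0L
  # pyloric status of each endpoint from a frozen-parameter probe at the
  # interpolated coordinates — the nearest scan cell can mislabel an
  # endpoint sitting on a sharp pyloric boundary
  if (n_ep > 0) {
    for (k in seq_len(n_ep)) {
      theta_ep <- setNames(as.numeric(
        eps[k, paste0("theta_", scan$axes)]), scan$axes)
      st <- tryCatch({
        bd <- evaluate_circuit(set_biases(scan$circuit, theta_ep),
                               scan$config)
        abs(bd$P_b - 0.3) < 1e-12
      }, error = function(e) NA)
      if (!is.na(st)) eps$pyloric[k] <- st
    }
  }
  pyl <- if (n_ep) eps$pyloric else logical(0)
  categorize <- function(p) {
    if (length(p) == 0L) "no-steady-state"
    else if (all(p, na.rm = TRUE) && !anyNA(p)) "reliable"
    else if (any(p, na.rm = TRUE)) "mixed"
    else "fail"
  }
  category <- categorize(pyl)
  # flip-flop risk: a would-be intersection was suppressed because its
  # crossing jumps a bifurcation (dynamics-class) line, or an unstable
  # flow arrangement exists between adjacent fixed-point cells — both are
  # regimes where trajectories can be trapped in large parametric limit
  # cycles that the static framework does not predict
  flip <- isTRUE(attr(eps, "suppressed"))
  if (!flip) {
    for (d in seq_along(scan$axes)) {
      F <- Fs[[d]]
      n <- dim(F)[d]
      lo <- slice_arr(F, d, seq_len(n - 1))
      hi <- slice_arr(F, d, 1 + seq_len(n - 1))
      fx_lo <- slice_arr(!scan$oscillatory, d, seq_len(n - 1))
      fx_hi <- slice_arr(!scan$oscillatory, d, 1 + seq_len(n - 1))
      bad <- !is.na(lo) & !is.na(hi) & lo < 0 & hi > 0 & fx_lo & fx_hi
      if (any(bad, na.rm = TRUE)) { flip <- TRUE; break }
    }
  }
  ambiguous <- any(vapply(Fs, function(F) anyNA(F), logical(1)))
  # boundary pinning is an anomaly when it manufactures a pyloric
  # endpoint the nullcline framework alone could not vouch for
  boundary_dep <- n_ep > 0 && any(eps$boundary & (eps$pyloric %in% TRUE))
  structure(list(endpoints = eps, category = category,
                 flags = list(boundary_dependence = boundary_dep,
                              flip_flop_risk = flip,
                              ambiguous_flow = ambiguous),
                 static_capture = static_capture,
                 mechanism = mechanism, axes = scan$axes),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> category:", x$category, "\n")
  cat("  endpoints:", nrow(x$endpoints), " boundary:",
      sum(x$endpoints$boundary %||% logical(0)), "\n")
  cat("  flags:", paste(names(x$flags), unlist(x$flags), sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bin_key <- function(obar_mat, resolution) {
  r <- round(obar_mat / resolution)
  apply(r, 1, paste, collapse = "|")
}

# per-cell stability for zero-range regulation along each scanned axis:
# d mean(o_axis)/d theta_axis > 0 (central differences, one-sided at the
# edges)
cell_stability <- function(scan) {
  stable <- array(TRUE, dim = scan$dims)
  for (d in seq_along(scan$axes)) {
    ob <- scan$obar[[scan$axes[d]]]
    n <- dim(ob)[d]
    lo <- slice_arr(ob, d, pmax(seq_len(n) - 1, 1))
    hi <- slice_arr(ob, d, pmin(seq_len(n) + 1, n))
    stable <- stable & !is.na(lo) & !is.na(hi) & (hi - lo > 0)
  }
  stable
}

#' Separability verdict for a scanned subspace
#'
#' Rounds every cell's regulated-neuron average activities to a bin
#' resolution and asks whether some bin is occupied exclusively by pyloric,
#' regulation-stable cells. Verdicts: `"fully-regulatable"` (such a bin
#' exists — a zero-range mechanism targeting it recovers pyloricness from
#' anywhere in the subspace), `"partially-regulatable"` (stable pyloric
#' bins exist but all are shared with non-pyloric cells), or
#' `"unregulatable"` (no stable pyloric bin at all, e.g. when raising a
#' bias paradoxically lowers that neuron's average activity throughout the
#' pyloric region).
#'
#' @inheritParams nullclines
#' @param resolution activity bin width (default 0.01).
#' @return list with `verdict`, the bin sets, and the bin `resolution`.
#' @export
separability <- function(scan, resolution = 0.01) {
  nd <- length(scan$axes)
  ob <- vapply(scan$axes, function(a) as.vector(scan$obar[[a]]),
               numeric(prod(scan$dims)))
  keys <- bin_key(ob, resolution)
  pyl <- as.vector(scan$pyloric)
  stab <- as.vector(cell_stability(scan))
  settled <- as.vector(scan$settled %||% rep(TRUE, length(pyl)))
  ok <- !is.na(pyl) & !apply(ob, 1, anyNA) & settled
  pyl_stable_bins <- unique(keys[ok & pyl & stab])
  pyl_bins <- unique(keys[ok & pyl])
  nonpyl_bins <- unique(keys[ok & !pyl])
  exclusive <- setdiff(pyl_stable_bins, nonpyl_bins)
  verdict <- if (length(exclusive)) "fully-regulatable"
  else if (length(pyl_stable_bins)) "partially-regulatable"
  else "unregulatable"
  list(verdict = verdict, exclusive_bins = exclusive,
       pyloric_stable_bins = pyl_stable_bins, pyloric_bins = pyl_bins,
       nonpyloric_bins = nonpyl_bins, resolution = resolution)
}

#' Generalization of regulation across a circuit pair
#'
#' Compares the exclusively-pyloric stable activity bins of two scans on
#' the same regulated axes: `"mutual"` when the exclusive sets overlap (a
#' single mechanism reliably regulates both circuits), `"partial"` when an
#' exclusive bin of one at least lies among the pyloric bins of the other,
#' `"none"` otherwise.
#'
#' @param scan_a,scan_b [scan_subspace()] results on identical axes.
#' @param resolution activity bin width.
#' @return list with `category`, the `overlap` bin set, and both
#'   separability reports.
#' @export
generalization <- function(scan_a, scan_b, resolution = 0.01) {
  if (!identical(scan_a$axes, scan_b$axes))
    stop("scans must share the same regulated axes")
  sa <- separability(scan_a, resolution)
  sb <- separability(scan_b, resolution)
  overlap <- intersect(sa$exclusive_bins, sb$exclusive_bins)
  category <- if (length(overlap)) "mutual"
  else if (length(intersect(sa$exclusive_bins, sb$pyloric_bins)) ||
           length(intersect(sb$exclusive_bins, sa$pyloric_bins))) "partial"
  else "none"
  list(category = category, overlap = overlap, a = sa, b = sb)
}

#' Predicted category of a zero-range target from average-space occupancy
#'
#' Classifies a zero-range target vector the way the subspace maps are
#' read: find the scanned cells whose cycle-averaged activities match the
#' targets (within `tol`), keep the regulation-stable ones (these are the
#' configurations the mechanism can stabilize), and ask whether they are
#' all pyloric (`"reliable"`), a pyloric/non-pyloric mixture (`"mixed"`),
#' all non-pyloric (`"fail"`), or absent/unstable (`"no-steady-state"`).
#' This is the separability argument applied to a single mechanism; it is
#' robust to the block-geometry artifacts that nullcline-intersection
#' detection suffers near sharp features.
#'
#' @inheritParams nullclines
#' @param B named numeric of target activity values (one per scanned
#'   axis).
#' @param tol activity matching tolerance (default the 0.01 binning
#'   resolution).
#' @return list with `category`, the numbers of matching stable pyloric /
#'   non-pyloric cells, and the matched cell count.
#' @export
predict_category <- function(scan, B, tol = 0.01) {
  nd <- length(scan$axes)
  ob <- vapply(scan$axes, function(a) as.vector(scan$obar[[a]]),
               numeric(prod(scan$dims)))
  B <- B[scan$axes]
  settled <- as.vector(scan$settled %||% rep(TRUE, nrow(ob)))
  ok <- settled & !apply(ob, 1, anyNA)
  match_cells <- ok
  for (d in seq_len(nd)) {
    match_cells <- match_cells & abs(ob[, d] - B[[d]]) <= tol + 1e-12
  }
  stab <- as.vector(cell_stability(scan))
  pyl <- as.vector(scan$pyloric)
  S <- which(match_cells & stab & !is.na(pyl))
  n_pyl <- sum(pyl[S])
  n_non <- length(S) - n_pyl
  category <- if (length(S) == 0L) "no-steady-state"
  else if (n_non == 0L) "reliable"
  else if (n_pyl > 0L) "mixed"
  else "fail"
  list(category = category, n_pyloric = n_pyl, n_nonpyloric = n_non,
       n_matched = sum(match_cells))
}

#' Compare predicted categories with simulated recovery
#'
#' For a lattice of zero-range target combinations, compares the category
#' predicted from the scan with the outcome of direct regulation
#' simulations from a perturbation grid (`"full"` recovery of all
#' perturbations, `"partial"`, or `"none"`). Cells flagged for boundary
#' pinning or flip-flop risk are excluded from the agreement rate and
#' reported separately — the static framework knowingly cannot predict
#' those regimes.
#'
#' @inheritParams nullclines
#' @param targets numeric vector of target activity values per axis
#'   (a full lattice is formed), or a matrix/data.frame of target
#'   combinations with one column per scanned axis.
#' @param perturb_values bias values of the perturbation grid.
#' @param duration regulation time per simulation (seconds).
#' @param tau_theta regulation time constant used for every probe.
#' @param config simulation settings for the probes (may use a coarser
#'   `dt` than the scan when the circuit's time constants allow it).
#' @param equil pre-regulation equilibration (seconds).
#' @return list with the per-target `table`, `agreement` on unflagged
#'   cells, and the `flagged` subset.
#' @export
predict_vs_simulate <- function(scan, targets = seq(0, 1, by = 0.1),
                                perturb_values = c(-10, -5, 0, 5, 10),
                                duration = 50000, tau_theta = 150,
                                config = NULL, equil = 250) {
  circuit <- scan$circuit
  if (is.null(config)) config <- scan$config
  check_dt(circuit, config)
  nd <- length(scan$axes)
  if (is.null(dim(targets))) {
    targets <- as.matrix(do.call(expand.grid,
                                 rep(list(targets), nd)))
  } else {
    targets <- as.matrix(targets)
  }
  colnames(targets) <- scan$axes
  pert <- as.matrix(do.call(expand.grid, rep(list(perturb_values), nd)))
  reg_idx <- match(scan$axes, NEURONS) - 1L
  rows <- vector("list", nrow(targets))
  for (k in seq_len(nrow(targets))) {
    B <- setNames(as.numeric(targets[k, ]), scan$axes)
    mech <- zero_range_mechanism(B, tau_theta = tau_theta)
    # category from average-space occupancy (the way the subspace maps
    # are read); anomaly flags from the nullcline/endpoint geometry
    pred <- predict_category(scan, B)
    geom <- predict_endpoints(scan, mech)
    flagged <- geom$flags$boundary_dependence || geom$flags$flip_flop_risk
    rec <- 0L
    for (p in seq_len(nrow(pert))) {
      theta0 <- circuit$theta
      theta0[scan$axes] <- pert[p, ]
      res <- cpp_adhp_recover(circuit$tau, theta0, circuit$w, c(0, 0, 0),
                              reg_idx, mech$LB, mech$UB, mech$s,
                              mech$tau_theta, config$dt, equil, duration,
                              mech$bias_range[1], mech$bias_range[2],
                              method_code(config), TRUE,
                              config$transient, config$record,
                              config$threshold, config$nonosc_window,
                              config$period_tol, config$dt, config$min_gap)
      if (isTRUE(res$pyloric)) rec <- rec + 1L
    }
    simulated <- if (rec == nrow(pert)) "full" else if (rec > 0) "partial"
                 else "none"
    agree <- switch(pred$category,
                    reliable = simulated == "full",
                    mixed = simulated == "partial",
                    simulated == "none")
    row <- as.data.frame(as.list(setNames(as.numeric(targets[k, ]),
                                          paste0("B_", scan$axes))))
    row$predicted <- pred$category
    row$recovered <- rec
    row$n_perturb <- nrow(pert)
    row$simulated <- simulated
    row$flagged <- flagged
    row$agree <- agree
    rows[[k]] <- row
  }
  tab <- do.call(rbind, rows)
  unflagged <- tab[!tab$flagged, ]
  list(table = tab,
       agreement = if (nrow(unflagged)) mean(unflagged$agree) else NA_real_,
       n_unflagged = nrow(unflagged),
       flagged = tab[tab$flagged, ])
}
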