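# Parameter-sweep driver: maps vortex-formation bifurcations over
# Reynolds number, trabecula height and inflow mode.

#' Specification of a bifurcation sweep
#'
#' Defaults reproduce the study conditions: steady Reynolds numbers
#' spanning five orders of magnitude, pulsatile Re in {0.1, 1, 10, 100}
#' at dimensionless frequency 0.10, and relative trabecula heights
#' hT/bV from 0 to 0.16 (the biologically relevant height is 0.08).
#'
#' @param Re Reynolds numbers; defaults depend on `mode`
#' @param hT_bV relative trabecula heights `hT / bV`
#' @param mode `"steady"` or `"pulsatile"`
#' @param phases snapshot phase fractions for pulsatile cells
#' @param grid `fluid_grid` (resolution tier), default 128 x 64
#' @param ib `ib_params`
#' @param n_cycles pulsatile cycles, default 4
#' @return object of class `sweep_spec`
#' @export
sweep_spec <- function(Re = NULL,
                       hT_bV = seq(0, 0.16, by = 0.02),
                       mode = c("steady", "pulsatile"),
                       phases = c(.05, .1, .2, .4, .5, .8, .9, .95, 1),
                       grid = fluid_grid(128, 64),
                       ib = ib_params(),
                       n_cycles = 4) {
  mode <- match.arg(mode)
  if (is.null(Re)) {
    Re <- if (mode == "steady")
      c(0.01, 0.05, 0.1, 0.5, 1, 5, 10, 20, 30, 40, 50, 100)
    else c(0.1, 1, 10, 100)
  }
  if (!length(Re) || !length(hT_bV)) stop("sweep axes must be non-empty")
  structure(list(Re = Re, hT_bV = hT_bV, mode = mode, phases = phases,
                 grid = grid, ib = ib, n_cycles = as.integer(n_cycles)),
            class = "sweep_spec")
}

# Stable hash of an R object: canonicalize (sort names recursively),
# deparse, md5 of the text.
config_hash <- function(x) {
  canon <- function(o) {
    if (is.list(o)) {
      if (!is.null(names(o)) && all(nzchar(names(o))))
        o <- o[order(names(o))]
      lapply(o, canon)
    } else o
  }
  txt <- paste(deparse(canon(unclass(x)), control = "all"), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

cell_key <- function(spec, Re, hT_bV) {
  config_hash(list(Re = Re, hT_bV = hT_bV, mode = spec$mode,
                   phases = spec$phases, n_cycles = spec$n_cycles,
                   Nx = spec$grid$Nx, Ny = spec$grid$Ny,
                   Lx = spec$grid$Lx, Ly = spec$grid$Ly,
                   ib = unclass(spec$ib)))
}

# Default per-cell runner: simulate and classify.  Returns a list of
# per-phase records (steady cells have one pseudo-phase NA).
run_cell <- function(spec, Re, hT_bV) {
  gp <- geometry_params(hT = hT_bV * 0.8)
  cv <- build_idealized_chamber(gp, spec$grid$h)
  masks <- region_masks(cv, spec$grid)
  classify <- function(state, phase) {
    vr <- detect_vortices(state, cv, masks)
    n_ic <- sum(vr$class == "intracardial")
    n_it <- sum(vr$class == "intertrabecular")
    cls <- if (n_ic > 0 && n_it > 0) "both"
           else if (n_ic > 0) "intracardial-only"
           else if (n_it > 0) "intertrabecular-only"
           else "none"
    wt <- wall_tangential_velocity(state, cv)
    data.frame(Re = Re, hT_bV = hT_bV, mode = spec$mode, phase = phase,
               class = cls, n_intracardial = n_ic, n_intertrabecular = n_it,
               senses = paste(vr$sense, collapse = "/"),
               max_extent = if (nrow(vr)) max(vr$extent) else 0,
               wall_reversal = min(wt$ut) < -0.02 * max(abs(wt$ut), 1e-12),
               stringsAsFactors = FALSE)
  }
  if (spec$mode == "steady") {
    fl <- flow_params(Re = Re, mode = "steady")
    st <- run_steady(cv, fl, spec$grid, spec$ib, on_nonconvergence = "warn")
    out <- classify(st, NA_real_)
    out$converged <- st$converged
    out$deviation_pct <- 100 * st$max_deviation / (2 * gp$aV)
  } else {
    fl <- flow_params(Re = Re, mode = "pulsatile", n_cycles = spec$n_cycles)
    pr <- suppressWarnings(run_pulsatile(cv, fl, spec$grid, spec$ib,
                                         phases = spec$phases))
    out <- do.call(rbind, Map(classify, pr$snapshots, spec$phases))
    out$converged <- pr$converged
    out$deviation_pct <- 100 * pr$max_deviation / (2 * gp$aV)
  }
  out
}

#' Run a bifurcation sweep
#'
#' Simulates every (Re, hT/bV) cell of the spec, classifies vortices per
#' cell (per phase snapshot for pulsatile cells), and assembles the
#' bifurcation table.  Cells are cached on disk keyed by a hash of the
#' cell configuration; rerunning an identical spec reruns no solver.
#' Per-cell failures are recorded (`class = "failed"`) and the sweep
#' continues.
#'
#' @param spec `sweep_spec`
#' @param cache_dir directory for per-cell result caches; `NULL` disables
#'   caching
#' @param runner cell runner `function(spec, Re, hT_bV)`; the default
#'   runs the immersed-boundary solver (replaceable for testing)
#' @param progress print one line per cell
#' @return `bifurcation_table`: data frame with one row per cell-phase
#'   (columns `Re`, `hT_bV`, `mode`, `phase`, `class`, vortex counts and
#'   senses, `wall_reversal`, `converged`, `deviation_pct`)
#' @export
run_sweep <- function(spec, cache_dir = NULL, runner = run_cell,
                      progress = interactive()) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  rows <- list()
  for (hT in spec$hT_bV) for (Re in spec$Re) {
    key <- cell_key(spec, Re, hT)
    cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".rds"))
    rec <- NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rec <- tryCatch(readRDS(cache_file), error = function(e) NULL)
      if (!is.null(rec) && !identical(attr(rec, "key"), key)) rec <- NULL
    }
    if (is.null(rec)) {
      rec <- tryCatch(runner(spec, Re, hT), error = function(e) {
        data.frame(Re = Re, hT_bV = hT, mode = spec$mode, phase = NA_real_,
                   class = "failed", n_intracardial = NA, n_intertrabecular = NA,
                   senses = conditionMessage(e), max_extent = NA,
                   wall_reversal = NA, converged = FALSE, deviation_pct = NA,
                   stringsAsFactors = FALSE)
      })
      attr(rec, "key") <- key
      if (!is.null(cache_file)) saveRDS(rec, cache_file)
    }
    if (progress)
      message(sprintf("cell Re=%g hT/bV=%g: %s", Re, hT,
                      paste(unique(rec$class), collapse = ",")))
    rows[[length(rows) + 1]] <- rec
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "spec") <- spec
  class(tab) <- c("bifurcation_table", "data.frame")
  tab
}

# Cycle-level roll-up of a cell: a vortex class is credited if it occurs
# at any phase.
cell_rollup <- function(rows) {
  if (any(rows$class == "failed")) return("failed")
  ic <- any(rows$n_intracardial > 0, na.rm = TRUE)
  it <- any(rows$n_intertrabecular > 0, na.rm = TRUE)
  if (ic && it) "both" else if (ic) "intracardial-only"
  else if (it) "intertrabecular-only" else "none"
}

#' Summarize a bifurcation table as a phase-diagram grid
#'
#' One class code per (Re, hT/bV) cell; pulsatile cells are rolled up
#' over the cycle (a vortex class counts if present at any phase).
#'
#' @param object `bifurcation_table`
#' @param ... unused
#' @return matrix of class codes (rows = Re, columns = hT/bV) with class
#'   `sweep_summary`
#' @export
summary.bifurcation_table <- function(object, ...) {
  spec <- attr(object, "spec")
  Res <- sort(unique(object$Re))
  hts <- sort(unique(object$hT_bV))
  m <- matrix(NA_character_, length(Res), length(hts),
              dimnames = list(Re = vapply(Res, as.character, ""),
                              hT_bV = vapply(hts, as.character, "")))
  for (i in seq_along(Res)) for (j in seq_along(hts)) {
    rows <- object[object$Re == Res[i] & object$hT_bV == hts[j], ]
    if (nrow(rows)) m[i, j] <- cell_rollup(rows)
  }
  structure(m, class = c("sweep_summary", "matrix"), mode = spec$mode)
}

#' @export
print.sweep_summary <- function(x, ...) {
  code <- c(none = ".", `intertrabecular-only` = "t",
            `intracardial-only` = "C", both = "B", failed = "x")
  m <- matrix(code[unclass(x)], nrow(x), ncol(x), dimnames = dimnames(x))
  cat(sprintf("Vortex phase diagram (%s inflow): . none | t intertrabecular | C intracardial | B both\n",
              attr(x, "mode") %||% "?"))
  print(m, quote = FALSE)
  invisible(x)
}

#' @export
print.bifurcation_table <- function(x, ...) {
  cat(sprintf("Bifurcation table: %d cell-phase rows (%s inflow)\n",
              nrow(x), unique(x$mode)))
  print(summary(x))
  invisible(x)
}

#' Write a bifurcation table (one row per cell-phase) as CSV
#' @param table `bifurcation_table`
#' @param path output CSV path; a JSON sidecar `<path>.meta.json` records
#'   the spec hash, resolution and tolerances
#' @return `path`, invisibly
#' @export
write_sweep_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  spec <- attr(table, "spec")
  meta <- list(spec_hash = config_hash(list(spec$Re, spec$hT_bV, spec$mode,
                                            spec$phases, spec$n_cycles)),
               Nx = spec$grid$Nx, Ny = spec$grid$Ny,
               tol_steady = spec$ib$tol_steady,
               deviation_target = spec$ib$deviation_target)
  writeLines(as.character(yaml::as.yaml(meta)), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Locate a bifurcation threshold by bisection
#'
#' Bisects the control parameter between a bracket where `classifier`
#' changes value, until the bracket width is at most `tol`; returns the
#' bracket midpoint.  With `tol` equal to the initial width, no
#' refinement is performed.
#'
#' @param classifier `function(x) -> logical` (e.g. "does a closed
#'   intracardial vortex form at Re = x?"); must differ between `lo` and
#'   `hi`
#' @param lo,hi bracketing parameter values
#' @param tol bracket width at which to stop
#' @param ... passed to `classifier`
#' @return list with `threshold` (midpoint), `bracket`, `evaluations`
#' @export
onset_threshold <- function(classifier, lo, hi, tol, ...) {
  f_lo <- classifier(lo, ...)
  f_hi <- classifier(hi, ...)
  if (identical(f_lo, f_hi))
    stop("classifier does not change across the bracket [lo, hi]")
  n_eval <- 2L
  while ((hi - lo) > tol) {
    mid <- (lo + hi) / 2
    f_mid <- classifier(mid, ...)
    n_eval <- n_eval + 1L
    if (identical(f_mid, f_lo)) lo <- mid else hi <- mid
  }
  list(threshold = (lo + hi) / 2, bracket = c(lo, hi), evaluations = n_eval)
}
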