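## Simulation drivers ----------------------------------------------------

new_trajectory <- function(times, snapshots, lineage, events, final) {
  structure(list(times = times, snapshots = snapshots,
                 lineage = lineage, events = events, final = final),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory: ", length(x$times), " samples over [",
      format(min(x$times)), ", ", format(max(x$times)), "], ",
      nrow(x$lineage %||% data.frame()), " divisions>\n", sep = "")
  invisible(x)
}

#' Concentrations at a sampled time
#'
#' @param traj A `trajectory`.
#' @param time Requested time (nearest sample is returned).
#' @return The cells x species concentration matrix of that snapshot.
#' @export
conc_at <- function(traj, time) {
  i <- which.min(abs(traj$times - time))
  traj$snapshots[[i]]$conc
}

clip_negative <- function(C) {
  if (any(C < -1e-9))
    warning(sprintf("concentrations clipped at 0 (min %.3g)", min(C)),
            call. = FALSE)
  C[C < 0] <- 0
  C
}

#' Run a static simulation
#'
#' The tissue shape is frozen; only the chemical state evolves.
#'
#' @param model A [model_spec()] without grow/divide arrows.
#' @param t A `tissue`.
#' @param t_end End time (span is `[0, t_end]`).
#' @param save_at Sample times (default 51 evenly spaced).
#' @param init Optional initial concentration matrix (cells x species)
#'   overriding the model's per-species `init`.
#' @param rtol,atol Integrator tolerances.
#' @param ... Passed to [ode_rk45()].
#' @return A `trajectory`: snapshots carry `time`, `conc`, `tissue`.
#' @export
run_static <- function(model, t, t_end, save_at = NULL, init = NULL,
                       rtol = 1e-6, atol = 1e-9, ...) {
  sys <- compile_model(model, t, static = TRUE)
  C0 <- init %||% init_conc(model, t, sys$geom)
  save_at <- save_at %||% seq(0, t_end, length.out = 51L)
  sol <- ode_rk45(sys$rhs, sys$pack(C0), 0, t_end, rtol = rtol,
                  atol = atol, save_at = save_at, ...)
  snaps <- lapply(seq_along(sol$t), function(i) {
    list(time = sol$t[i],
         conc = clip_negative(sys$unpack(sol$y[i, ])$C),
         tissue = t)
  })
  new_trajectory(sol$t, snaps, NULL, list(),
                 list(conc = snaps[[length(snaps)]]$conc, tissue = t,
                      system = sys))
}

## threshold variable value per cell
threshold_value <- function(spec, C, G) {
  if (identical(spec$variable, "area")) G$area else C[, spec$variable]
}

#' Run a growing simulation with cell division
#'
#' Integrates chemistry, vertex mechanics and rest-length growth jointly;
#' watches each cell's threshold variable (area by default) for an
#' upcrossing of its birth threshold, stops at the located event time,
#' divides the triggering cell (wall placed per the model's
#' [division_spec()]), recompiles, and resumes.  Runs are deterministic
#' given `seed`: one RNG stream drives threshold draws and tie-breaks in
#' event order.
#'
#' @param model A [model_spec()] with a [grow_arrow()] (and usually a
#'   [division_spec()]).
#' @param t A `tissue`.
#' @param t_end End time.
#' @param seed RNG seed.
#' @param save_at Snapshot times.
#' @param init Optional initial concentration matrix.
#' @param rtol,atol Integrator tolerances.
#' @param max_divisions Abort ceiling for runaway division storms.
#' @param stop_after_divisions Optionally end the run early once this
#'   many divisions have occurred (in total, including a resumed run's).
#' @param progress Emit a message every `progress` divisions (0 = quiet).
#' @param resume The `final` element of a previous trajectory from the
#'   same model: the run continues from that state (including the RNG
#'   stream), so a chunked run is bit-identical to an uninterrupted one
#'   when chunks end at division events.
#' @return A `trajectory`; snapshots carry `time`, `conc`, `tissue`
#'   (with current vertex positions), `ids`; `lineage` is the division
#'   record table; `final` holds the end state.
#' @export
run_growing <- function(model, t, t_end, seed = 1L, save_at = NULL,
                        init = NULL, rtol = 1e-6, atol = 1e-9,
                        max_divisions = 5000L,
                        stop_after_divisions = Inf, progress = 0L,
                        resume = NULL) {
  if (is.null(model$grow)) stop_tessella("model has no grow arrow")
  spec <- model$divide
  if (is.null(resume)) {
    set.seed(seed)
    sys <- compile_model(model, t, static = FALSE)
    C <- init %||% init_conc(model, t, sys$geom)
    V <- t$V
    delta <- sys$mech$delta
    ids <- seq_len(n_cells(t))
    next_id <- max(ids) + 1L
    thresholds <- if (!is.null(spec)) sample_threshold(spec, n_cells(t))
    lineage <- list()
    t_now <- 0
    n_div <- 0L
  } else {
    assign(".Random.seed", resume$rng, envir = globalenv())
    t <- resume$tissue
    sys <- compile_model(model, t, static = FALSE)
    sys$mech$delta <- resume$delta   # live delta travels in the state
    C <- resume$conc
    V <- t$V
    delta <- resume$delta
    ids <- resume$ids
    next_id <- resume$next_id
    thresholds <- resume$thresholds
    lineage <- resume$lineage_list %||% list()
    t_now <- resume$time
    n_div <- resume$n_divisions %||% 0L
  }
  events_log <- list()
  save_at <- sort(unique(save_at %||% seq(0, t_end, length.out = 21L)))
  snaps <- list(); snap_times <- numeric(0)
  take_snaps <- function(sol, sys, t_cur) {
    for (i in seq_along(sol$t)) {
      st <- sys$unpack(sol$y[i, ])
      tt <- sys$tissue; tt$V <- st$V
      snaps[[length(snaps) + 1L]] <<- list(
        time = sol$t[i], conc = clip_negative(st$C), tissue = tt,
        ids = ids)
      snap_times[length(snap_times) + 1L] <<- sol$t[i]
    }
  }
  repeat {
    ## immediate divisions: daughters (or initial cells) already above
    ## threshold divide before any integration, in cell-index order
    if (!is.null(spec)) {
      guard <- 0L
      repeat {
        G <- compute_geometry(sys$tissue, V)
        over <- which(threshold_value(spec, C, G) >= thresholds)
        if (!length(over)) break
        ci <- over[1L]
        res <- do_division(sys, ci, V, C, delta, thresholds, ids,
                           next_id, spec, model, t_now)
        if (is.null(res)) { thresholds[ci] <- Inf; next }
        sys <- res$sys; V <- res$V; C <- res$C; delta <- res$delta
        thresholds <- res$thresholds; ids <- res$ids
        next_id <- res$next_id
        lineage[[length(lineage) + 1L]] <- res$lineage
        n_div <- n_div + 1L
        if (progress > 0L && n_div %% progress == 0L)
          message("division ", n_div, " at t=", signif(t_now, 4),
                  " (", n_cells(sys$tissue), " cells)")
        guard <- guard + 1L
        if (n_div >= max_divisions || guard > n_cells(sys$tissue) + 10L)
          stop_tessella(
            "division storm: %d divisions by t=%.4g; aborting", n_div,
            t_now)
      }
    }
    if (n_div >= stop_after_divisions || t_now >= t_end) break
    ev_fn <- if (!is.null(spec)) {
      force(sys)
      function(tt, y) {
        st <- sys$unpack(y)
        G <- geom_metrics(sys$geom, sys$tissue$E, st$V)
        threshold_value(spec, st$C, c(sys$geom["n_cells"], G)) - thresholds
      }
    }
    sol <- ode_rk45(sys$rhs, sys$pack(C, V, delta), t_now, t_end,
                    rtol = rtol, atol = atol,
                    save_at = save_at[save_at >= t_now - 1e-12],
                    events = ev_fn)
    take_snaps(sol, sys, t_now)
    if (is.null(sol$event)) {
      st <- sys$unpack(sol$y_final)
      C <- clip_negative(st$C); V <- st$V; delta <- st$delta
      t_now <- t_end
      break
    }
    ## division event located
    t_now <- sol$event$time
    st <- sys$unpack(sol$event$state)
    C <- clip_negative(st$C); V <- st$V; delta <- st$delta
    events_log[[length(events_log) + 1L]] <-
      list(time = t_now, cell = sol$event$index, id = ids[sol$event$index])
    if (n_div >= max_divisions)
      stop_tessella("division storm: %d divisions by t=%.4g", n_div, t_now)
  }
  lin <- if (length(lineage)) do.call(rbind, lineage)
  final_t <- sys$tissue; final_t$V <- V
  new_trajectory(snap_times, snaps, lin, events_log,
                 list(conc = C, tissue = final_t, delta = delta,
                      thresholds = thresholds, ids = ids, time = t_now,
                      next_id = next_id, n_divisions = n_div,
                      lineage_list = lineage,
                      rng = get(".Random.seed", envir = globalenv()),
                      system = sys))
}

## Perform one division of cell ci and recompile. Returns NULL if the
## wall placement aborts (degenerate daughter); the caller then disables
## that cell's threshold.
do_division <- function(sys, ci, V, C, delta, thresholds, ids, next_id,
                        spec, model, t_now) {
  tis <- sys$tissue; tis$V <- V
  P <- cell_polygon(tis, ci)
  wall <- if (spec$model == "errera") {
    errera_wall(P)
  } else {
    loop <- cell_loop_vertices(tis, ci)
    G <- compute_geometry(tis)
    m <- sys$mech; m$delta <- delta
    vel <- tryCatch(vertex_velocities(tis, G, m, C,
                                      ctx = list(geom = G, V = V)),
                    error = function(e) NULL)
    potential_wall(P, spec,
                   velocities = if (!is.null(vel))
                     vel[loop, , drop = FALSE])
  }
  res <- withCallingHandlers(
    divide_cell(tis, ci, wall,
                state = list(conc = C, delta = delta,
                             thresholds = thresholds, spec = spec,
                             ids = ids, next_id = next_id,
                             time = t_now)),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(res)) return(NULL)
  sys2 <- compile_model(model, res$tissue, static = FALSE,
                        mech = {
                          m <- sys$mech; m$delta <- res$state$delta; m
                        })
  list(sys = sys2, V = res$tissue$V, C = res$state$conc,
       delta = res$state$delta, thresholds = res$state$thresholds,
       ids = res$state$ids, next_id = res$state$next_id,
       lineage = res$lineage)
}

#' Export trajectory snapshots to CSV
#'
#' Writes, for each requested time, the tissue in FLAT dialect
#' (`tissue_<k>.csv`), a per-cell concentration table
#' (`conc_<k>.csv`, columns `cell_id` + species), plus `lineage.csv`
#' and `events.json` once.  Snapshots round-trip through
#' [read_tissue()].
#'
#' @param traj A `trajectory`.
#' @param times Times to export (nearest snapshots; default all).
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
snapshot <- function(traj, times = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  times <- times %||% traj$times
  for (k in seq_along(times)) {
    i <- which.min(abs(traj$times - times[k]))
    sn <- traj$snapshots[[i]]
    write_tissue(sn$tissue, file.path(dir, sprintf("tissue_%03d.csv", k)),
                 dialect = "flat")
    df <- data.frame(cell_id = sn$ids %||% seq_len(nrow(sn$conc)),
                     time = sn$time, sn$conc, check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("conc_%03d.csv", k)),
                     row.names = FALSE)
  }
  if (!is.null(traj$lineage))
    utils::write.csv(traj$lineage, file.path(dir, "lineage.csv"),
                     row.names = FALSE)
  jsonlite::write_json(traj$events, file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Trace every cell id back to its root ancestor
#'
#' @param ids Cell ids present at the end of a run.
#' @param lineage The trajectory's lineage table.
#' @return Integer vector of root ancestor ids (clone labels), one per
#'   entry of `ids`.
#' @export
clone_roots <- function(ids, lineage) {
  parent_of <- integer(0)
  if (!is.null(lineage))
    for (i in seq_len(nrow(lineage))) {
      parent_of[as.character(lineage$daughter1[i])] <- lineage$parent[i]
      parent_of[as.character(lineage$daughter2[i])] <- lineage$parent[i]
    }
  vapply(ids, function(id) {
    key <- as.character(id)
    while (key %in% names(parent_of)) {
      id <- parent_of[[key]]
      key <- as.character(id)
    }
    as.integer(id)
  }, integer(1))
}
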