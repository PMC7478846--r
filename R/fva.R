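#' Flux balance analysis: maximize the biomass objective
#'
#' Solves the linear program max \eqn{v_{obj}} subject to steady-state mass
#' balance \eqn{S v = 0} and the model's flux bounds.
#'
#' @param model a validated [metabolic_model()].
#' @return An `fba_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, and `fluxes`
#'   (named vector; one optimizer among possibly many alternate optima).
#'   Infeasibility is reported through `status`, never as an error.
#' @export
#' @examples
#' fba_maximize(toy_network("chain"))$objective_value  # 10
fba_maximize <- function(model) {
  validate_model(model)
  obj <- as.numeric(colnames(model$S) == model$objective)
  res <- lp_solve(obj, model$S, rep(0, nrow(model$S)), model$lb, model$ub,
                  maximize = TRUE)
  fluxes <- if (identical(res$status, "optimal")) {
    stats::setNames(res$x, colnames(model$S))
  } else NULL
  structure(list(status = res$status,
                 objective_value = if (is.null(fluxes)) NA_real_ else res$objective,
                 fluxes = fluxes),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("fba_solution: status %s, objective %.6g\n",
              x$status, x$objective_value))
  invisible(x)
}

#' Define a (possibly composite) flux target
#'
#' A flux target is a named linear combination of reaction fluxes; a single
#' reaction is the special case of one unit weight.
#'
#' @param name target label.
#' @param weights named numeric vector: reaction id to coefficient.
#' @return A `flux_target`.
#' @export
flux_target <- function(name, weights) {
  weights <- unlist(weights)
  stopifnot(is.numeric(weights), length(weights) > 0,
            !is.null(names(weights)))
  structure(list(name = name, weights = weights), class = "flux_target")
}

as_flux_targets <- function(targets, model) {
  if (inherits(targets, "flux_target")) targets <- list(targets)
  if (is.character(targets)) {
    targets <- lapply(targets, function(id) {
      flux_target(id, stats::setNames(1, id))
    })
  }
  rxns <- colnames(model$S)
  for (tg in targets) {
    bad <- setdiff(names(tg$weights), rxns)
    if (length(bad)) {
      stop("target '", tg$name, "' references unknown reaction(s): ",
           paste(bad, collapse = ", "))
    }
  }
  targets
}

#' Flux variability analysis at a fraction of the biomass optimum
#'
#' First maximizes biomass, then requires the objective flux to stay at or
#' above `fraction` of that optimum, and for every target minimizes and
#' maximizes the target's linear combination of fluxes. With the default
#' `fraction = 0.99` the envelopes span the solution space supporting 99%
#' of maximum feasible growth.
#'
#' @param model a [metabolic_model()].
#' @param targets a character vector of reaction ids and/or a list of
#'   [flux_target()]s.
#' @param fraction fraction of the biomass optimum in (0, 1]; default 0.99.
#' @return A data frame with columns `target`, `min_flux`, `max_flux`,
#'   `fraction`, `status` (`"ok"` or `"invalid"` when one of the per-target
#'   LPs failed; the run continues over remaining targets).
#' @export
#' @examples
#' run_fva(toy_network("chain"), "R1")  # interior reaction: [9.9, 10]
run_fva <- function(model, targets, fraction = 0.99) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  targets <- as_flux_targets(targets, model)
  base <- fba_maximize(model)
  if (!identical(base$status, "optimal")) {
    stop("base model FBA is ", base$status,
         "; cannot run flux variability analysis")
  }
  jobj <- match(model$objective, colnames(model$S))
  model$lb[jobj] <- max(model$lb[jobj], fraction * base$objective_value)
  n <- length(targets)
  out <- data.frame(
    target = vapply(targets, `[[`, "", "name"),
    min_flux = rep(NA_real_, n), max_flux = rep(NA_real_, n),
    fraction = fraction, status = rep("ok", n),
    stringsAsFactors = FALSE
  )
  rhs <- rep(0, nrow(model$S))
  for (i in seq_len(n)) {
    w <- numeric(ncol(model$S))
    w[match(names(targets[[i]]$weights), colnames(model$S))] <-
      targets[[i]]$weights
    lo <- lp_solve(w, model$S, rhs, model$lb, model$ub, maximize = FALSE)
    hi <- lp_solve(w, model$S, rhs, model$lb, model$ub, maximize = TRUE)
    if (identical(lo$status, "optimal") && identical(hi$status, "optimal")) {
      out$min_flux[i] <- lo$objective
      out$max_flux[i] <- hi$objective
    } else if (identical(lo$status, "unbounded") ||
               identical(hi$status, "unbounded")) {
      # report at the default big bound rather than as infinities
      out$min_flux[i] <- if (identical(lo$status, "unbounded")) -1000 else lo$objective
      out$max_flux[i] <- if (identical(hi$status, "unbounded")) 1000 else hi$objective
      out$status[i] <- "unbounded"
    } else {
      out$status[i] <- "invalid"
    }
  }
  attr(out, "objective_value") <- base$objective_value
  out
}

#' Build per-reaction serine flux targets
#'
#' One single-reaction target for every reaction whose stoichiometry touches
#' any of the listed serine species, weighted by the reaction's total serine
#' coefficient so that a positive target value means net serine production
#' and a negative value net consumption. Reactions whose serine coefficients
#' cancel (e.g. transport between two listed compartments) are excluded by
#' default.
#'
#' @param model a [metabolic_model()].
#' @param serine_ids metabolite ids of the serine species to track (list all
#'   compartments explicitly).
#' @param include_zero keep reactions with a net zero serine coefficient?
#'   Default `FALSE`.
#' @return List of [flux_target()]s; empty (with a warning) when no
#'   reaction touches serine.
#' @export
serine_reaction_panel <- function(model, serine_ids, include_zero = FALSE) {
  missing <- setdiff(serine_ids, rownames(model$S))
  if (length(missing)) {
    stop("serine species not in the model: ", paste(missing, collapse = ", "))
  }
  sub <- model$S[serine_ids, , drop = FALSE]
  touches <- colSums(sub != 0) > 0
  netcoef <- colSums(sub)
  keep <- touches & (include_zero | abs(netcoef) > 1e-12)
  if (!any(keep)) {
    warning("no reaction touches the listed serine species")
    return(list())
  }
  lapply(which(keep), function(j) {
    flux_target(colnames(model$S)[j],
                stats::setNames(netcoef[j], colnames(model$S)[j]))
  })
}

#' Net serine-flux envelope over a reaction set
#'
#' Computes the flux variability envelope of the single linear combination
#' \eqn{\sum_r c_r v_r}, where \eqn{c_r} is reaction r's net serine
#' coefficient, by optimizing the combination directly (not by summing
#' per-reaction envelopes, which would overstate the range).
#'
#' @param model a [metabolic_model()].
#' @param reactions nonempty character vector of reaction ids.
#' @param serine_ids serine species defining the weights; alternatively pass
#'   explicit `weights`.
#' @param fraction fraction of optimum, as in [run_fva()].
#' @param weights optional named numeric vector overriding the serine-derived
#'   coefficients.
#' @param name target label; default `"net"`.
#' @return One-row data frame as from [run_fva()].
#' @export
net_flux_envelope <- function(model, reactions, serine_ids = NULL,
                              fraction = 0.99, weights = NULL,
                              name = "net") {
  stopifnot(length(reactions) > 0)
  bad <- setdiff(reactions, colnames(model$S))
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  if (is.null(weights)) {
    if (is.null(serine_ids)) stop("provide serine_ids or explicit weights")
    sub <- model$S[serine_ids, reactions, drop = FALSE]
    weights <- stats::setNames(colSums(sub), reactions)
  } else {
    weights <- weights[reactions]
  }
  run_fva(model, list(flux_target(name, weights)), fraction = fraction)
}

#' Scan flux envelopes over a grid of serine uptake rates
#'
#' For each uptake rate on the grid the exchange reaction is constrained to
#' that rate (`mode = "fixed"` pins the flux exactly, matching envelopes at
#' exact uptake rates; `mode = "max"` merely allows up to the rate), biomass
#' is re-maximized under the new constraint, and the targets' flux
#' variability is computed at `fraction` of that per-point optimum.
#' Re-optimizing per point keeps low-uptake points feasible instead of
#' judging them against an optimum they cannot reach.
#'
#' @param model a [metabolic_model()].
#' @param exchange exchange reaction id to scan (e.g. the serine exchange).
#' @param grid nonnegative, strictly increasing uptake rates (mmol/gDW/h).
#' @param targets targets as in [run_fva()].
#' @param fraction fraction of the per-point biomass optimum; default 0.99.
#' @param mode `"fixed"` (default) or `"max"`.
#' @return An `uptake_scan` object; its `envelopes` data frame has columns
#'   `uptake_rate`, `target`, `min_flux`, `max_flux`, `max_biomass`,
#'   `status`. Infeasible grid points are marked `"invalid"` and the scan
#'   continues.
#' @export
uptake_scan <- function(model, exchange, grid, targets, fraction = 0.99,
                        mode = c("fixed", "max")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(grid), length(grid) > 0, all(grid >= 0),
            all(diff(grid) > 0) || length(grid) == 1L)
  targets <- as_flux_targets(targets, model)
  tnames <- vapply(targets, `[[`, "", "name")
  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    mk <- set_exchange_bound(model, exchange, grid[k], mode = mode)
    base <- fba_maximize(mk)
    if (!identical(base$status, "optimal")) {
      rows[[k]] <- data.frame(uptake_rate = grid[k], target = tnames,
                              min_flux = NA_real_, max_flux = NA_real_,
                              max_biomass = NA_real_, status = "invalid",
                              stringsAsFactors = FALSE)
      next
    }
    env <- run_fva(mk, targets, fraction = fraction)
    rows[[k]] <- data.frame(uptake_rate = grid[k], target = env$target,
                            min_flux = env$min_flux, max_flux = env$max_flux,
                            max_biomass = base$objective_value,
                            status = env$status, stringsAsFactors = FALSE)
  }
  structure(list(exchange = exchange, grid = grid, mode = mode,
                 fraction = fraction,
                 envelopes = do.call(rbind, rows)),
            class = "uptake_scan")
}

#' @export
print.uptake_scan <- function(x, ...) {
  cat(sprintf(
    "uptake_scan of %s: %d grid points (%s mode), fraction %.2f\n",
    x$exchange, length(x$grid), x$mode, x$fraction))
  print(utils::head(x$envelopes, 12))
  if (nrow(x$envelopes) > 12) cat("...\n")
  invisible(x)
}

#' Write scan envelopes to CSV
#'
#' @param scan an [uptake_scan()] result.
#' @param path output CSV path; a header comment states the flux units.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fluxes and uptake rates in mmol/gDW/h", con)
  utils::write.csv(scan$envelopes, con, row.names = FALSE)
  invisible(path)
}

#' Exhaustive flux-variability oracle by vertex enumeration
#'
#' Independent cross-check for [run_fva()] on small networks: enumerates
#' every vertex of the flux polytope \eqn{\{S v = 0, lb \le v \le ub\}}
#' (optionally after imposing the fraction-of-optimum floor on the biomass
#' flux) by solving all basis/bound assignments, then reads the envelope of
#' each target off the vertex set. Linear objectives attain their extrema at
#' vertices, so this is exact for bounded polytopes. Cost grows
#' combinatorially; intended for networks of at most ~10 reactions.
#'
#' @param model a [metabolic_model()] with finite bounds.
#' @param targets targets as in [run_fva()].
#' @param fraction fraction of optimum, or `NULL` to skip the biomass floor.
#' @param tol feasibility tolerance on the vertex check.
#' @return Data frame with `target`, `min_flux`, `max_flux`; `NULL` when the
#'   polytope is empty.
#' @export
fva_brute_force <- function(model, targets, fraction = 0.99, tol = 1e-7) {
  stopifnot(all(is.finite(model$lb)), all(is.finite(model$ub)))
  targets <- as_flux_targets(targets, model)
  verts <- polytope_vertices(model$S, model$lb, model$ub, tol = tol)
  if (is.null(verts)) return(NULL)
  jobj <- match(model$objective, colnames(model$S))
  if (!is.null(fraction)) {
    zstar <- max(verts[jobj, ])
    lb <- model$lb; lb[jobj] <- max(lb[jobj], fraction * zstar)
    verts <- polytope_vertices(model$S, lb, model$ub, tol = tol)
    if (is.null(verts)) return(NULL)
  }
  do.call(rbind, lapply(targets, function(tg) {
    w <- numeric(ncol(model$S))
    w[match(names(tg$weights), colnames(model$S))] <- tg$weights
    vals <- drop(crossprod(verts, w))
    data.frame(target = tg$name, min_flux = min(vals), max_flux = max(vals),
               stringsAsFactors = FALSE)
  }))
}

# All vertices of {v: A v = 0, lb <= v <= ub}; columns of the returned
# matrix are flux vectors. Enumerate size-r column bases (r = rank) and all
# 2^(n-r) assignments of the remaining variables to their bounds.
polytope_vertices <- function(A, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- if (nrow(A)) qr(A)$rank else 0L
  if (r > 0L) {
    keep <- qr(t(A))$pivot[seq_len(r)]
    A <- A[keep, , drop = FALSE]
  } else {
    A <- matrix(0, nrow = 0, ncol = n)
  }
  found <- list()
  subsets <- if (r == 0L) list(integer(0)) else utils::combn(n, r, simplify = FALSE)
  for (B in subsets) {
    if (r > 0L) {
      SB <- A[, B, drop = FALSE]
      if (abs(det(SB)) < 1e-10) next
    }
    N <- setdiff(seq_len(n), B)
    grid <- expand.grid(lapply(N, function(j) unique(c(lb[j], ub[j]))),
                        KEEP.OUT.ATTRS = FALSE)
    if (nrow(grid) == 0L) grid <- data.frame(row.names = 1)
    for (i in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(N)) v[N] <- as.numeric(grid[i, ])
      if (r > 0L) {
        rhs <- if (length(N)) -A[, N, drop = FALSE] %*% v[N] else rep(0, r)
        v[B] <- drop(solve(SB, rhs))
      }
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        found[[length(found) + 1L]] <- v
      }
    }
  }
  if (!length(found)) return(NULL)
  out <- do.call(cbind, found)
  rownames(out) <- colnames(A)
  out
}
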