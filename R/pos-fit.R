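# The central fitting function: registry records in, POS estimates out.

#' Estimate clinical-phase success probabilities from a trial registry
#'
#' Runs the full path-reconstruction pipeline: groups records into
#' drug-indication development programs, classifies per-phase states with
#' the elapsed-time termination heuristic, imputes interior missing phases,
#' tabulates phase transitions, and computes the path-by-path and
#' phase-by-phase POS estimators with binomial standard errors.
#'
#' @param records validated trial records (from [read_registry()],
#'   [simulate_registry()], or a conforming data.frame).
#' @param approvals optional drug-indication approval table.
#' @param snapshot_date the registry snapshot (right-censoring) date;
#'   mandatory unless `thresholds` is given.
#' @param thresholds a [pos_thresholds] object; defaults to the standard
#'   360/540/900-day thresholds at `snapshot_date`.
#' @param group_key program grouping key, see [build_programs()].
#' @param phase4_implies_approval treat Phase 4 trials as approval
#'   evidence.
#' @return An object of class `pos_fit` with components `programs`,
#'   `states`, `counts`, and `estimates` (named lists of [pos_estimate]
#'   objects for both methods). Methods: `print`, `summary`, `coef`,
#'   `plot`, `simulate`.
#' @examples
#' sim <- simulate_registry(registry_config(n_drugs = 80), seed = 7)
#' fit <- pos_fit(sim$records, sim$approvals, snapshot_date = "2015-10-31")
#' summary(fit)
#' coef(fit)
#' @export
pos_fit <- function(records, approvals = NULL, snapshot_date = NULL,
                    thresholds = NULL,
                    group_key = c("drug-indication", "drug-indication-sponsor"),
                    phase4_implies_approval = TRUE) {
  cl <- match.call()
  group_key <- match.arg(group_key)
  if (is.null(thresholds)) {
    thresholds <- pos_thresholds(snapshot_date)
  }
  stopifnot(inherits(thresholds, "pos_thresholds"))
  records <- as_trial_records(records)
  programs <- build_programs(records, approvals, group_key = group_key,
                             phase4_implies_approval = phase4_implies_approval)
  states <- classify_phase_states(programs, thresholds)
  counts <- tabulate_transitions(states)

  safe <- function(expr) tryCatch(expr, pathpos_undefined_estimate = function(e) NULL)
  estimates <- list(
    path = list(
      phase1_2 = safe(pos_path(counts, 1L)),
      phase2_3 = safe(pos_path(counts, 2L)),
      phase3_app = safe(pos_path(counts, 3L)),
      to_approval_2 = safe(pos_to_approval(counts, 2L)),
      to_approval_3 = safe(pos_to_approval(counts, 3L)),
      overall = safe(pos_path_overall(counts))
    ),
    phase = list(
      phase1_2 = safe(pos_phase(counts, 1L)),
      phase2_3 = safe(pos_phase(counts, 2L)),
      phase3_app = safe(pos_phase(counts, 3L)),
      overall = safe(tryCatch(pos_phase_overall(counts),
                              pathpos_undefined_estimate = function(e) NULL))
    )
  )
  structure(list(call = cl, n_records = nrow(records), programs = programs,
                 states = states, counts = counts, estimates = estimates,
                 thresholds = thresholds),
            class = "pos_fit")
}

#' @export
print.pos_fit <- function(x, ...) {
  ov <- x$estimates$path$overall
  cat("Development-path POS fit\n")
  cat(sprintf("  %d records, %d programs, %d approvals; snapshot %s\n",
              x$n_records, nrow(x$programs$programs), x$counts$n_approval,
              format(x$thresholds$snapshot_date)))
  if (!is.null(ov)) {
    cat(sprintf("  Overall POS (Phase 1 -> approval, path-by-path): %.1f%% (SE %.1f%%)\n",
                100 * ov$value, 100 * ov$se))
  }
  cat("  Use summary() for the per-phase table.\n")
  invisible(x)
}

#' @export
summary.pos_fit <- function(object, ...) {
  e <- object$estimates
  row <- function(est) {
    if (is.null(est)) return(c(NA, NA, NA, NA))
    c(est$denominator, 100 * est$value, 100 * est$se, est$numerator)
  }
  tab <- rbind(
    `Phase 1 to 2` = c(row(e$path$phase1_2)[1:3], row(e$phase$phase1_2)[2:3]),
    `Phase 2 to 3` = c(row(e$path$phase2_3)[1:3], row(e$phase$phase2_3)[2:3]),
    `Phase 3 to APP` = c(row(e$path$phase3_app)[1:3], row(e$phase$phase3_app)[2:3]),
    `Phase 1 to APP` = c(row(e$path$overall)[1:3], row(e$phase$overall)[2:3])
  )
  colnames(tab) <- c("paths", "path-by-path %", "(SE %)",
                     "phase-by-phase %", "(SE %)")
  out <- list(table = tab, counts = object$counts,
              snapshot = object$thresholds$snapshot_date,
              to_approval = list(from2 = e$path$to_approval_2,
                                 from3 = e$path$to_approval_3))
  class(out) <- "summary.pos_fit"
  out
}

#' @export
print.summary.pos_fit <- function(x, ...) {
  cat("Probability of success by clinical phase (snapshot",
      format(x$snapshot), ")\n\n")
  print(round(x$table, 1))
  cat("\nTransition counts:\n")
  print(x$counts)
  invisible(x)
}

#' @export
coef.pos_fit <- function(object, method = c("path", "phase"), ...) {
  method <- match.arg(method)
  e <- object$estimates[[method]]
  keys <- c("phase1_2", "phase2_3", "phase3_app", "overall")
  vals <- vapply(keys, function(k) {
    if (is.null(e[[k]])) NA_real_ else e[[k]]$value
  }, numeric(1))
  names(vals) <- c("POS1,2", "POS2,3", "POS3,APP", "POS1,APP")
  vals
}

#' @export
plot.pos_fit <- function(x, ...) {
  keys <- c("phase1_2", "phase2_3", "phase3_app", "overall")
  labs <- c("1 to 2", "2 to 3", "3 to APP", "1 to APP")
  get <- function(method) {
    lapply(x$estimates[[method]][keys], function(e) {
      if (is.null(e)) c(NA, NA) else c(e$value, e$se)
    })
  }
  pa <- do.call(rbind, get("path"))
  ph <- do.call(rbind, get("phase"))
  xs <- seq_along(keys)
  graphics::plot(NA, xlim = c(0.5, 4.5), ylim = c(0, 1), xaxt = "n",
                 xlab = "Phase transition", ylab = "POS",
                 main = "Path-by-path vs phase-by-phase POS", ...)
  graphics::axis(1, at = xs, labels = labs)
  off <- 0.08
  graphics::points(xs - off, pa[, 1], pch = 16, col = "firebrick")
  graphics::arrows(xs - off, pa[, 1] - pa[, 2], xs - off, pa[, 1] + pa[, 2],
                   angle = 90, code = 3, length = 0.03, col = "firebrick")
  graphics::points(xs + off, ph[, 1], pch = 17, col = "steelblue")
  graphics::arrows(xs + off, ph[, 1] - ph[, 2], xs + off, ph[, 1] + ph[, 2],
                   angle = 90, code = 3, length = 0.03, col = "steelblue")
  graphics::legend("topright", legend = c("path-by-path", "phase-by-phase"),
                   pch = c(16, 17), col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(x)
}

#' Simulate registries from a fitted POS model
#'
#' Draws synthetic registries whose true per-phase advancement
#' probabilities equal the fitted path-by-path estimates, handy for
#' parametric-bootstrap style checks of the pipeline.
#'
#' @param object a `pos_fit`.
#' @param nsim number of registries.
#' @param seed integer seed; registry k uses `seed + k - 1`.
#' @param n_drugs drugs per simulated registry.
#' @param ... further arguments passed to [registry_config()].
#' @return A list of `registry_sim` objects (length `nsim`).
#' @importFrom stats simulate
#' @export
simulate.pos_fit <- function(object, nsim = 1, seed = 1L, n_drugs = 500L, ...) {
  theta <- coef(object, "path")[1:3]
  if (anyNA(theta)) {
    stop_pathpos("cannot simulate: some per-phase estimates are undefined",
                 "pathpos_undefined_estimate")
  }
  cfg <- registry_config(n_drugs = n_drugs, theta = unname(theta),
                         snapshot_date = object$thresholds$snapshot_date, ...)
  lapply(seq_len(nsim), function(k) simulate_registry(cfg, seed = seed + k - 1L))
}

#' Tidy table of all estimates from a fit
#'
#' @param fit a `pos_fit`.
#' @return data.frame with one row per estimate (method, phases, value,
#'   SE, numerator, denominator), mirroring the layout of published POS
#'   tables.
#' @export
pos_estimates_table <- function(fit) {
  stopifnot(inherits(fit, "pos_fit"))
  rows <- list()
  for (method in names(fit$estimates)) {
    for (nm in names(fit$estimates[[method]])) {
      est <- fit$estimates[[method]][[nm]]
      if (!is.null(est)) rows[[paste(method, nm)]] <- as.data.frame(est)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
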