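#' Per-atom B-factors from fitted fluctuations
#'
#' \eqn{B_i = (8\pi^2/3)\,\langle \|r_i - \bar r_i\|^2 \rangle} over the
#' fitted frames, with \eqn{\bar r_i} the per-atom mean of the fitted
#' frames.  This is the "atomicfluct" convention: under isotropy the
#' one-dimensional \eqn{\langle u^2 \rangle} is one third of the 3D
#' mean-square fluctuation, so this equals \eqn{8\pi^2\langle u^2\rangle}.
#'
#' @param fit a [two_step_average_fit()] result (or any list with a
#'   `fitted` frames x atoms x 3 array).
#' @return Per-atom B-factor vector, A^2.
#' @export
bfactors_from_fit <- function(fit) {
  fitted <- fit$fitted
  d <- dim(fitted)
  if (is.null(d) || d[1L] < 2L) {
    stop("B-factors need at least 2 frames (zero-variance undefined)")
  }
  mean_coords <- apply(fitted, c(2L, 3L), mean)
  msf <- numeric(d[2L])
  for (f in seq_len(d[1L])) {
    msf <- msf + rowSums((matrix(fitted[f, , ], ncol = 3L) - mean_coords)^2)
  }
  (8 * pi^2 / 3) * msf / d[1L]
}

#' Aggregate per-simulation B-factors across an ensemble
#'
#' The ensemble B-factor of an atom is the mean of its per-simulation
#' values; the standard error is the sample standard deviation across the N
#' simulations (N - 1 denominator) divided by \eqn{\sqrt N}.
#'
#' @param per_sim_B N x atoms matrix of per-simulation B-factors (A^2), or
#'   a list of per-simulation vectors of equal length.
#' @param atoms optional data frame of atom metadata (one row per column).
#' @param window optional list describing the sampling window (nominal fs,
#'   cadence) recorded as metadata.
#' @return Object of class `bfactor_profile`.
#' @export
aggregate_ensemble <- function(per_sim_B, atoms = NULL, window = NULL) {
  if (is.list(per_sim_B) && !is.matrix(per_sim_B)) {
    len <- unique(lengths(per_sim_B))
    if (length(len) != 1L) stop("per-simulation profiles differ in atom count")
    per_sim_B <- do.call(rbind, per_sim_B)
  }
  N <- nrow(per_sim_B)
  if (N < 2L) stop("ensemble SE needs at least 2 simulations")
  if (any(per_sim_B < 0)) stop("negative B-factor in input")
  if (!is.null(atoms) && nrow(atoms) != ncol(per_sim_B)) {
    stop("atom metadata does not match the B matrix")
  }
  mean_B <- colMeans(per_sim_B)
  se_B <- apply(per_sim_B, 2L, sd) / sqrt(N)
  structure(list(per_sim_B = per_sim_B, mean_B = mean_B, se_B = se_B,
                 n_sims = N, atoms = atoms, window = window,
                 se_formula = "sd(N-1)/sqrt(N)"),
            class = "bfactor_profile")
}

#' @export
print.bfactor_profile <- function(x, ...) {
  cat(sprintf("bfactor_profile: %d atoms, %d simulations\n",
              length(x$mean_B), x$n_sims))
  cat(sprintf("  mean B %.3g A^2 (range %.3g-%.3g), median SE %.3g A^2\n",
              mean(x$mean_B), min(x$mean_B), max(x$mean_B),
              stats::median(x$se_B)))
  invisible(x)
}

#' @export
summary.bfactor_profile <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("B-factor profile over %d simulations (SE = %s)\n",
              object$n_sims, object$se_formula))
  if (!is.null(object$window)) {
    cat(sprintf("  window: %g fs nominal, cadence %d steps\n",
                object$window$nominal_fs, object$window$save_interval_steps))
  }
  print(summary(df[, c("B_mean", "B_se")]))
  invisible(df)
}

#' @export
as.data.frame.bfactor_profile <- function(x, ...) {
  meta <- if (!is.null(x$atoms)) {
    x$atoms[, intersect(c("serial", "name", "resname", "resid"),
                        names(x$atoms)), drop = FALSE]
  } else {
    data.frame(serial = seq_along(x$mean_B), name = "CA", resname = "UNK",
               resid = seq_along(x$mean_B))
  }
  cbind(meta, B_mean = x$mean_B, B_se = x$se_B, n_sims = x$n_sims)
}

#' @export
plot.bfactor_profile <- function(x, expt = NULL, ...) {
  idx <- if (!is.null(x$atoms)) x$atoms$resid else seq_along(x$mean_B)
  graphics::plot(idx, x$mean_B, type = "l", xlab = "residue",
                 ylab = expression(B ~ (ring(A)^2)), ...)
  graphics::arrows(idx, x$mean_B - x$se_B, idx, x$mean_B + x$se_B,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  if (!is.null(expt)) {
    graphics::lines(idx, expt, col = "red")
    graphics::legend("topright", legend = c("calculated", "experimental"),
                     col = c("black", "red"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Write a B-factor profile as TSV
#'
#' Columns: serial, name, resname, resid, B_mean, B_se, n_sims.
#'
#' @param profile a `bfactor_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bfactor_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate an ensemble to a sampling window
#'
#' Sampling windows (e.g. 25, 50, 100 ps nominal) are realised by keeping
#' the saved frames up to the window, never by re-running.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param window_ps window length in nominal clock ps.
#' @return A truncated `trajectory_ensemble`.
#' @export
truncate_window <- function(ensemble, window_ps) {
  frame_dt_fs <- ensemble$nominal_timestep * ensemble$save_interval_steps
  keep <- floor(window_ps * 1000 / frame_dt_fs)
  nf <- dim(ensemble$trajectories[[1L]])[1L]
  if (keep < 2L) stop("window shorter than two saved frames")
  if (keep > nf) stop(sprintf("window needs %d frames; only %d available",
                              keep, nf))
  ensemble$trajectories <- lapply(ensemble$trajectories,
                                  function(t) t[seq_len(keep), , , drop = FALSE])
  ensemble
}
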