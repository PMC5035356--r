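#' Root-mean-square deviation between two B-factor profiles
#'
#' @param calc,expt equal-length numeric vectors of per-atom B-factors
#'   (A^2), paired by atom.
#' @return RMSD in A^2.
#' @export
bfactor_rmsd <- function(calc, expt) {
  if (length(calc) != length(expt)) stop("profile lengths differ")
  if (length(calc) < 1L) stop("empty profiles")
  sqrt(mean((calc - expt)^2))
}

#' Ensemble-mean RMSD with standard error
#'
#' Computes the RMSD of each simulation's profile against the experimental
#' one, then the mean and standard error of the mean (N - 1 variance) across
#' the N simulations — the same SE treatment as for a B-factor itself.
#'
#' @param per_sim_B N x atoms matrix (N >= 2) of per-simulation B-factors.
#' @param expt experimental per-atom B-factors (length = atoms).
#' @return List with `mean`, `se`, and `per_sim` RMSDs (A^2).
#' @export
rmsd_with_se <- function(per_sim_B, expt) {
  if (!is.matrix(per_sim_B)) per_sim_B <- do.call(rbind, per_sim_B)
  N <- nrow(per_sim_B)
  if (N < 2L) stop("SE of the RMSD needs at least 2 simulations")
  per_sim <- apply(per_sim_B, 1L, bfactor_rmsd, expt = expt)
  list(mean = mean(per_sim), se = sd(per_sim) / sqrt(N), per_sim = per_sim)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3); constant input is
#'   an error (r undefined), never silently 0.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("vector lengths differ")
  if (length(x) < 3L) stop("correlation needs at least 3 points")
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined for constant input")
  }
  cor(x, y, method = "pearson")
}

#' Compare a calculated B-factor profile with experiment
#'
#' Matches atoms by the (chain, resid, name) triple when both sides carry
#' metadata; unmatched atoms are dropped with a logged count.  Reports both
#' RMSD readouts — the mean of per-simulation RMSDs with its SE, and the
#' RMSD of the ensemble-mean profile — plus the Pearson correlation of the
#' ensemble-mean profile against experiment.
#'
#' @param profile a `bfactor_profile`.
#' @param expt experimental B-factors: an `md_structure` (whose `bfactor`
#'   column is used) or a bare numeric vector already paired with the
#'   profile.
#' @param selection selection used to pull experimental atoms when `expt`
#'   is a structure (default the profile's atoms are matched directly).
#' @param label free-text label stored in the report.
#' @return Object of class `bfactor_comparison`.
#' @export
compare_bfactors <- function(profile, expt, selection = NULL, label = "") {
  stopifnot(inherits(profile, "bfactor_profile"))
  n_dropped <- 0L
  if (inherits(expt, "md_structure")) {
    ea <- expt$atoms
    if (!is.null(selection)) {
      ea <- ea[select_atoms(expt, selection), , drop = FALSE]
    }
    pa <- profile$atoms
    if (is.null(pa)) stop("profile carries no atom metadata to match on")
    key <- function(a) paste(a$chain, a$resid, a$name, sep = "|")
    m <- match(key(pa), key(ea))
    keep <- which(!is.na(m))
    n_dropped <- nrow(pa) - length(keep)
    if (n_dropped > 0L) {
      message(sprintf("dropping %d unmatched atoms", n_dropped))
    }
    if (length(keep) < 3L) stop("fewer than 3 matched atoms")
    expt_B <- ea$bfactor[m[keep]]
    per_sim <- profile$per_sim_B[, keep, drop = FALSE]
    mean_B <- profile$mean_B[keep]
  } else {
    expt_B <- as.numeric(expt)
    if (length(expt_B) != length(profile$mean_B)) {
      stop("experimental profile length does not match")
    }
    per_sim <- profile$per_sim_B
    mean_B <- profile$mean_B
  }
  r <- rmsd_with_se(per_sim, expt_B)
  structure(list(
    rmsd_mean = r$mean, rmsd_se = r$se,
    rmsd_of_mean_profile = bfactor_rmsd(mean_B, expt_B),
    pcc = pearson_cc(mean_B, expt_B),
    n_atoms = length(expt_B), n_dropped = n_dropped,
    label = label, calc_B = mean_B, expt_B = expt_B),
    class = "bfactor_comparison")
}

#' @export
print.bfactor_comparison <- function(x, ...) {
  cat(sprintf("B-factor comparison%s (%d atoms)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n_atoms))
  cat(sprintf("  RMSD (mean of per-sim +/- SE): %.3g +/- %.2g A^2\n",
              x$rmsd_mean, x$rmsd_se))
  cat(sprintf("  RMSD of ensemble-mean profile: %.3g A^2\n",
              x$rmsd_of_mean_profile))
  cat(sprintf("  Pearson r (mean profile vs experiment): %.3f\n", x$pcc))
  invisible(x)
}

#' Write a comparison report as JSON (plus optional scatter TSV)
#'
#' @param report a `bfactor_comparison`.
#' @param path JSON output path.
#' @param scatter_path optional TSV of (atom index, B_calc, B_expt) pairs
#'   for scatter plotting.
#' @return Invisibly, `path`.
#' @export
write_comparison_json <- function(report, path, scatter_path = NULL) {
  out <- report[c("rmsd_mean", "rmsd_se", "rmsd_of_mean_profile", "pcc",
                  "n_atoms", "n_dropped", "label")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(scatter_path)) {
    write.table(data.frame(atom = seq_along(report$calc_B),
                           B_calc = report$calc_B, B_expt = report$expt_B),
                scatter_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
plot.bfactor_comparison <- function(x, ...) {
  graphics::plot(x$expt_B, x$calc_B,
                 xlab = expression(B[expt] ~ (ring(A)^2)),
                 ylab = expression(B[calc] ~ (ring(A)^2)), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = sprintf("r = %.2f", x$pcc), bty = "n")
  invisible(x)
}
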