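#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the unweighted
#' least-squares deviation of `mobile` from `target`.  SVD-based, with the
#' determinant sign correction that forbids reflections.
#'
#' @param mobile n x 3 coordinate matrix (n >= 3, not collinear).
#' @param target n x 3 coordinate matrix, paired row-by-row with `mobile`.
#' @return Object of class `rigid_transform`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), and `rmsd` after superposition (A).
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target))) stop("coordinate sets differ in size")
  n <- nrow(mobile)
  if (n < 3L) stop("rigid-body fit requires at least 3 atoms")
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[2L] < 1e-8 * max(1, sv[1L])) {
    stop("mobile coordinates are collinear; rigid-body fit is degenerate")
  }
  H <- crossprod(X, Y)           # 3 x 3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - cm %*% t(R)),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: post-fit RMSD %.4g A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform a `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Two-step average-conformation superposition of a trajectory
#'
#' The procedure that precedes fluctuation calculation: step 1 aligns every
#' saved frame onto the first saved one (on the selected atoms) and averages
#' the selected coordinates; step 2 refits every original frame onto that
#' average conformation.  Exactly one averaging pass is made — there is no
#' iteration to convergence.
#'
#' @param frames frames x atoms x 3 array.
#' @param sel integer indices of the atoms used both for fitting and for the
#'   subsequent fluctuation computation; defaults to all atoms.
#' @return Object of class `fit_result`: `fitted` (frames x length(sel) x 3),
#'   `average_coords`, `rmsd_to_reference` (per-frame RMSD to the average
#'   after step 2), `rmsd_step1` (per-frame RMSD to frame 1 after step 1),
#'   `sel`.
#' @export
two_step_average_fit <- function(frames, sel = NULL) {
  d <- dim(frames)
  if (length(d) != 3L || d[1L] < 2L) stop("need at least 2 frames")
  if (is.null(sel)) sel <- seq_len(d[2L])
  if (length(sel) < 3L) stop("selection must contain at least 3 atoms")
  nf <- d[1L]
  get_frame <- function(f) matrix(frames[f, sel, ], ncol = 3L)

  ref <- get_frame(1L)
  fitted1 <- array(NA_real_, c(nf, length(sel), 3L))
  rmsd1 <- numeric(nf)
  fitted1[1L, , ] <- ref
  for (f in seq_len(nf)[-1L]) {
    mob <- get_frame(f)
    tr <- kabsch_fit(mob, ref)
    fitted1[f, , ] <- apply_rigid_transform(mob, tr)
    rmsd1[f] <- tr$rmsd
  }
  avg <- apply(fitted1, c(2L, 3L), mean)

  fitted2 <- array(NA_real_, c(nf, length(sel), 3L))
  rmsd2 <- numeric(nf)
  for (f in seq_len(nf)) {
    mob <- get_frame(f)
    tr <- kabsch_fit(mob, avg)
    fitted2[f, , ] <- apply_rigid_transform(mob, tr)
    rmsd2[f] <- tr$rmsd
  }
  structure(list(fitted = fitted2, average_coords = avg,
                 rmsd_to_reference = rmsd2, rmsd_step1 = rmsd1, sel = sel),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: %d frames x %d atoms; mean RMSD to average %.4g A\n",
    dim(x$fitted)[1L], dim(x$fitted)[2L], mean(x$rmsd_to_reference)))
  invisible(x)
}
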