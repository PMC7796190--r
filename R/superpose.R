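## Kabsch least-squares superposition with explicit reflection handling,
## RMSD over named selections, and per-region RMSD series over ensembles.

#' Kabsch superposition of two corresponded point sets
#'
#' Least-squares rigid superposition of `P` onto `Q` (correspondence by row
#' order). With `allow_reflection = FALSE` (the default) the returned
#' transform is a proper rotation (determinant +1), which preserves
#' chirality; with `TRUE` an improper transform is permitted whenever it
#' lowers the RMSD, which makes the mirror image of a chiral set
#' superposable at RMSD 0.
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3.
#' @param allow_reflection permit an improper (determinant -1) transform?
#' @return object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3; the fit is `P %*% t(rotation) + translation`),
#'   `proper` (logical), `rmsd` (Angstrom) and `n` (atoms used).
#' @export
kabsch_superpose <- function(P, Q, allow_reflection = FALSE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) {
    stop("correspondence error: point sets of size ", nrow(P), " vs ", nrow(Q))
  }
  if (nrow(P) < 3) stop("correspondence error: need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  s <- svd_cond <- sv$d
  if (s[2] < 1e-8 * max(s[1], 1)) {
    warning("conditioning warning: (near-)collinear point set in superposition")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, if (allow_reflection) 1 else d))
  ## if reflection is allowed, pick the unconstrained optimum (which is
  ## improper exactly when d < 0)
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cq - drop(R %*% cp)
  fitted <- xform(P, R, tr)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = tr,
                 proper = det(R) > 0, rmsd = rmsd, n = nrow(P)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd ", format(x$rmsd, digits = 4), " A over ",
      x$n, " atoms (", if (x$proper) "proper rotation" else "improper/reflection",
      ")\n", sep = "")
  invisible(x)
}

## Plain coordinate RMSD with fixed correspondence.
rmsd_xyz <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' RMSD between two structures over a named selection
#'
#' @param a,b `rna_structure` objects whose selections resolve to identical
#'   atom lists (chain, residue, atom name).
#' @param selection selection list (`chain`, `resi`, `atoms` fields), or
#'   `NULL` for all atoms.
#' @param superpose superpose on the selection first?
#' @param allow_reflection passed to [kabsch_superpose()]. Comparing
#'   enantiomers with `TRUE` gives the trivial RMSD 0; chirality-sensitive
#'   comparisons keep the default `FALSE`.
#' @return RMSD in Angstrom, with attribute `n` (atom count used).
#' @export
rmsd_selection <- function(a, b, selection = NULL, superpose = TRUE,
                           allow_reflection = FALSE) {
  ia <- select_atoms(a, selection)
  ib <- select_atoms(b, selection)
  ka <- paste(a$atoms$chain[ia], a$atoms$resi[ia], a$atoms$name[ia])
  kb <- paste(b$atoms$chain[ib], b$atoms$resi[ib], b$atoms$name[ib])
  if (length(ka) != length(kb) || any(ka != kb)) {
    off <- union(setdiff(ka, kb), setdiff(kb, ka))
    stop("selection error: atom lists differ (",
         paste(utils::head(off, 5), collapse = "; "), ")")
  }
  if (length(ia) == 0) stop("selection error: empty selection")
  A <- coords(a)[ia, , drop = FALSE]
  B <- coords(b)[ib, , drop = FALSE]
  if (superpose) {
    fit <- kabsch_superpose(A, B, allow_reflection = allow_reflection)
    r <- fit$rmsd
  } else {
    r <- rmsd_xyz(A, B)
  }
  attr(r, "n") <- length(ia)
  r
}

#' Per-region RMSD series across an ensemble
#'
#' For every frame and every named region, the RMSD to a reference frame
#' after superposition on that region (ribose-phosphate backbone atoms by
#' default, O2' excluded).
#'
#' @param ensemble an `rna_ensemble`.
#' @param regions named list of selection lists; defaults to the whole
#'   structure as region `all`.
#' @param reference reference frame index (default 1).
#' @param atoms atom-name filter applied inside each region; default the
#'   ribose-phosphate backbone.
#' @param allow_reflection passed to the superposition.
#' @return data frame with columns `frame`, `region`, `rmsd`, `n_atoms`.
#' @export
region_rmsd_series <- function(ensemble, regions = list(all = NULL),
                               reference = 1L,
                               atoms = backbone_selection(),
                               allow_reflection = FALSE) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  ref <- ensemble$models[[reference]]
  out <- list()
  for (rg in names(regions)) {
    sel <- regions[[rg]]
    sel$atoms <- if (is.null(atoms)) sel$atoms else atoms
    idx <- select_atoms(ref, sel)
    if (length(idx) == 0) stop("selection error: empty region ", rg)
    for (f in seq_along(ensemble$models)) {
      r <- rmsd_selection(ensemble$models[[f]], ref, sel,
                          superpose = TRUE, allow_reflection = allow_reflection)
      out[[length(out) + 1L]] <- data.frame(
        frame = f, region = rg, rmsd = as.numeric(r), n_atoms = attr(r, "n"))
    }
  }
  do.call(rbind, out)
}
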