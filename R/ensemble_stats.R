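## Ensemble and comparison statistics: circular summaries of P and chi,
## per-residue conformer distributions (violin-ready), and per-residue
## angle-difference profiles between topology-identical complexes.

#' Circular median of angles
#'
#' Wrapped-median definition: the angle minimizing the mean absolute
#' circular deviation. When several data angles tie (the minimizing set is
#' an arc, as for even sample sizes), the midpoint of that arc is returned;
#' this keeps the median exactly antisymmetric under negation of the data,
#' so mirror symmetry propagates through ensemble statistics.
#'
#' @param theta angles in degrees (NA dropped).
#' @return median angle in degrees, wrapped to (-180, 180].
#' @export
circular_median <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (!length(theta)) return(NA_real_)
  cand <- wrap180(theta)
  dev <- vapply(cand, function(m) mean(abs(wrap180(theta - m))), numeric(1))
  best <- cand[dev <= min(dev) + 1e-9]
  rel <- wrap180(best - best[1])
  wrap180(best[1] + (min(rel) + max(rel)) / 2)
}

## Circular quartiles around the circular median: quartiles of the wrapped
## deviations, mapped back.
circular_quartiles <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (!length(theta)) return(c(q1 = NA_real_, med = NA_real_, q3 = NA_real_))
  med <- circular_median(theta)
  d <- sort(wrap180(theta - med))
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  c(q1 = wrap180(med + q[1]), med = med, q3 = wrap180(med + q[2]))
}

#' Per-residue conformer distribution of an ensemble
#'
#' Circular median and quartiles of pseudorotation phase P and glycosidic
#' chi per residue across frames, with the fraction of S-type puckers and
#' of syn conformers. Residues whose P is undefined in every frame are
#' flagged and excluded from the phase statistics. The table is shaped for
#' violin-style plotting and CSV export.
#'
#' @param ensemble an `rna_ensemble`.
#' @return data frame: chain, resi, resn, n, P_med/P_q1/P_q3 (degrees in
#'   \[0, 360)), chi_med/chi_q1/chi_q3 (degrees in (-180, 180\]),
#'   frac_S, frac_syn, all_P_undefined.
#' @export
conformer_distribution <- function(ensemble) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  ct <- conformation_table(ensemble)
  sp <- split(ct, list(ct$chain, ct$resi), drop = TRUE)
  out <- lapply(sp, function(g) {
    Pq <- circular_quartiles(g$P)
    cq <- circular_quartiles(g$chi)
    S <- mean(g$pucker == "S", na.rm = TRUE)
    syn <- mean(g$glycosidic == "syn", na.rm = TRUE)
    data.frame(chain = g$chain[1], resi = g$resi[1], resn = g$resn[1],
               n = nrow(g),
               P_med = wrap360(Pq["med"]), P_q1 = wrap360(Pq["q1"]),
               P_q3 = wrap360(Pq["q3"]),
               chi_med = cq["med"], chi_q1 = cq["q1"], chi_q3 = cq["q3"],
               frac_S = if (all(is.na(g$pucker))) NA_real_ else S,
               frac_syn = syn,
               all_P_undefined = all(is.na(g$P)))
  })
  df <- do.call(rbind, out)
  df <- df[order(df$chain, df$resi), ]
  rownames(df) <- NULL
  df
}

#' Per-residue angle differences between two topology-identical complexes
#'
#' Wrapped differences (a minus b, in (-180, 180]) of every backbone
#' torsion, chi and P, per residue -- the angle-difference profile used to
#' compare homo- and heterochiral models.
#'
#' @param a,b `rna_structure` objects with identical chains/residues.
#' @return data frame: chain, resi, resn, then one delta column per angle.
#' @export
torsion_difference_profile <- function(a, b) {
  ta <- conformation_table(a)
  tb <- conformation_table(b)
  if (nrow(ta) != nrow(tb) ||
      any(ta$chain != tb$chain) || any(ta$resi != tb$resi) ||
      any(ta$resn != tb$resn)) {
    stop("comparison error: topology mismatch between structures")
  }
  angs <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi", "P")
  out <- ta[, c("chain", "resi", "resn")]
  for (an in angs) {
    out[[paste0("d_", an)]] <- wrap180(ta[[an]] - tb[[an]])
  }
  out
}

#' Tidy circular summary of labelled complexes
#'
#' One row per (complex label, chain, residue) with pseudorotation phase
#' and glycosidic chi -- the polar-plot-ready table. When two labels are
#' designated as a mirror pair the symmetry report checks P' = P + 180 and
#' chi' = -chi residue by residue.
#'
#' @param complexes named list of `rna_structure` objects.
#' @param mirror_pairs optional list of 2-element character vectors naming
#'   label pairs expected to be mirror images.
#' @param tol tolerance (degrees) for the symmetry report.
#' @return data frame (label, chain, resi, resn, P, chi) with attribute
#'   `symmetry` (data frame per mirror pair: max deviations and verdict).
#' @export
circular_summary <- function(complexes, mirror_pairs = NULL, tol = 1e-3) {
  stopifnot(length(names(complexes)) == length(complexes))
  tabs <- lapply(names(complexes), function(lb) {
    ct <- conformation_table(complexes[[lb]])
    data.frame(label = lb, ct[, c("chain", "resi", "resn", "P", "chi")])
  })
  df <- do.call(rbind, tabs)
  rownames(df) <- NULL
  sym <- NULL
  if (!is.null(mirror_pairs)) {
    sym <- do.call(rbind, lapply(mirror_pairs, function(pp) {
      a <- df[df$label == pp[1], ]
      b <- df[df$label == pp[2], ]
      stopifnot(nrow(a) == nrow(b))
      dP <- max(abs(wrap180(b$P - a$P - 180)), na.rm = TRUE)
      dchi <- max(abs(wrap180(b$chi + a$chi)), na.rm = TRUE)
      data.frame(label_a = pp[1], label_b = pp[2],
                 max_dP = dP, max_dchi = dchi,
                 verdict = if (dP <= tol && dchi <= tol) {
                   "full symmetry"
                 } else {
                   "asymmetric"
                 })
    }))
  }
  attr(df, "symmetry") <- sym
  df
}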