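## Per-residue conformational descriptors: backbone torsions alpha..zeta,
## glycosidic chi with syn/anti classes, Altona-Sundaralingam pseudorotation
## (P, numax) with N/S pucker classes and 18-degree conformer bins, and
## intra-strand P-P distances.

PUCKER_NAMES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                  "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

## amplitude floor below which P is reported undefined
AMPLITUDE_FLOOR <- 5

#' Backbone torsions of every residue of a chain
#'
#' alpha: O3'(i-1)-P-O5'-C5'; beta: P-O5'-C5'-C4'; gamma: O5'-C5'-C4'-C3';
#' delta: C5'-C4'-C3'-O3'; epsilon: C4'-C3'-O3'-P(i+1); zeta:
#' C3'-O3'-P(i+1)-O5'(i+1). Angles undefined at a terminus (or with a
#' missing atom) are `NA`, never zero.
#'
#' @param x an `rna_structure`.
#' @param chain chain id; defaults to the first chain.
#' @return data frame: chain, resi, resn, alpha..zeta (degrees).
#' @export
backbone_torsions <- function(x, chain = x$chains[1]) {
  a <- x$atoms[x$atoms$chain == chain, ]
  res <- unique(a[, c("resi", "resn")])
  res <- res[order(res$resi), ]
  get <- function(resi, name) {
    row <- a[a$resi == resi & a$name == name, ]
    if (nrow(row) != 1) return(NULL)
    c(row$x, row$y, row$z)
  }
  tors <- function(p) {
    if (any(vapply(p, is.null, logical(1)))) return(NA_real_)
    dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
  }
  out <- lapply(seq_len(nrow(res)), function(k) {
    i <- res$resi[k]
    data.frame(
      chain = chain, resi = i, resn = res$resn[k],
      alpha = tors(list(get(i - 1, "O3'"), get(i, "P"), get(i, "O5'"), get(i, "C5'"))),
      beta = tors(list(get(i, "P"), get(i, "O5'"), get(i, "C5'"), get(i, "C4'"))),
      gamma = tors(list(get(i, "O5'"), get(i, "C5'"), get(i, "C4'"), get(i, "C3'"))),
      delta = tors(list(get(i, "C5'"), get(i, "C4'"), get(i, "C3'"), get(i, "O3'"))),
      epsilon = tors(list(get(i, "C4'"), get(i, "C3'"), get(i, "O3'"), get(i + 1, "P"))),
      zeta = tors(list(get(i, "C3'"), get(i, "O3'"), get(i + 1, "P"), get(i + 1, "O5'"))))
  })
  do.call(rbind, out)
}

#' Glycosidic torsion chi of one residue
#'
#' O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines.
#'
#' @param x an `rna_structure`.
#' @param chain chain id.
#' @param resi residue index.
#' @return chi in degrees, (-180, 180].
#' @export
glycosidic_chi <- function(x, chain, resi) {
  res <- residue_atoms(x, chain, resi)
  if (nrow(res) == 0) stop("no such residue: ", chain, resi)
  code <- res$resn[1]
  n_g <- glyc_n(code)
  cc <- if (is_purine(code)) "C4" else "C2"
  m <- residue_xyz(x, chain, resi, c("O4'", "C1'", n_g, cc))
  dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
}

#' Classify a glycosidic angle as syn or anti
#'
#' `anti` iff |chi| >= 90 degrees after wrapping to (-180, 180]; the
#' boundary |chi| = 90 is assigned to anti.
#'
#' @param chi glycosidic angle(s), degrees.
#' @return character vector `"syn"`/`"anti"`.
#' @export
classify_syn_anti <- function(chi) {
  ifelse(abs(wrap180(chi)) >= 90, "anti", "syn")
}

#' Pseudorotation phase and amplitude of a sugar ring
#'
#' Altona-Sundaralingam analysis of the five endocyclic torsions
#' (nu0: C4'-O4'-C1'-C2', ..., nu4: C3'-C4'-O4'-C1'):
#' `tan P = ((nu4+nu1) - (nu3+nu0)) / (2 nu2 (sin 36 + sin 72))`, with 180
#' degrees added when nu2 < 0, P wrapped to \[0, 360), and
#' `numax = nu2 / cos P >= 0`. Rings with amplitude below 5 degrees are
#' reported as flat: P is `NA` (undefined).
#'
#' @param x an `rna_structure`.
#' @param chain chain id.
#' @param resi residue index.
#' @return list with `P` (degrees, or NA when undefined), `numax` (degrees)
#'   and `nu` (the five torsions).
#' @export
pseudorotation <- function(x, chain, resi) {
  m <- residue_xyz(x, chain, resi, c("C4'", "O4'", "C1'", "C2'", "C3'"))
  nu <- c(dihedral(m["C4'", ], m["O4'", ], m["C1'", ], m["C2'", ]),
          dihedral(m["O4'", ], m["C1'", ], m["C2'", ], m["C3'", ]),
          dihedral(m["C1'", ], m["C2'", ], m["C3'", ], m["C4'", ]),
          dihedral(m["C2'", ], m["C3'", ], m["C4'", ], m["O4'", ]),
          dihedral(m["C3'", ], m["C4'", ], m["O4'", ], m["C1'", ]))
  ph <- as_phase(nu)
  if (ph$numax < AMPLITUDE_FLOOR) {
    return(list(P = NA_real_, numax = ph$numax, nu = nu))
  }
  list(P = ph$P, numax = ph$numax, nu = nu)
}

#' Classify a pseudorotation phase into N/S and an 18-degree conformer bin
#'
#' N iff P in \[315, 360) U \[0, 45); S iff P in \[135, 225); `other`
#' otherwise. The conformer name comes from the twenty 18-degree
#' envelope/twist bins (C3'-endo is \[0, 36), C2'-endo is \[144, 180), ...).
#'
#' @param P pseudorotation phase, degrees in \[0, 360); `NA` is refused.
#' @return list with `class` (`"N"`, `"S"` or `"other"`) and `conformer`.
#' @export
classify_pucker <- function(P) {
  if (is.na(P)) stop("classification refused: undefined pseudorotation phase")
  P <- wrap360(P)
  cls <- if (P >= 315 || P < 45) "N" else if (P >= 135 && P < 225) "S" else "other"
  bin <- floor(P / 36) %% 10 + 1
  list(class = cls, conformer = PUCKER_NAMES[bin])
}

#' Consecutive intra-strand phosphorus-phosphorus distances
#'
#' @param x an `rna_structure`.
#' @param chain chain id; defaults to the first chain.
#' @return numeric vector of Euclidean P-P distances in 5' to 3' order
#'   (empty when the chain has fewer than two phosphates).
#' @export
phosphate_distances <- function(x, chain = x$chains[1]) {
  a <- x$atoms[x$atoms$chain == chain & x$atoms$name == "P", ]
  a <- a[order(a$resi), ]
  if (nrow(a) < 2) return(numeric(0))
  m <- as.matrix(a[, c("x", "y", "z")])
  sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
}

#' Full conformational record of every residue
#'
#' One row per residue (per model when given an ensemble): backbone
#' torsions, chi with syn/anti class, pseudorotation P and numax with
#' pucker class and conformer name. The shape exported to CSV for
#' downstream angle-difference and violin-style reports.
#'
#' @param x an `rna_structure` or `rna_ensemble`.
#' @return data frame with one row per residue (and a `model` column for
#'   ensembles).
#' @export
conformation_table <- function(x) {
  if (inherits(x, "rna_ensemble")) {
    out <- lapply(seq_along(x$models), function(m) {
      cbind(model = m, conformation_table(x$models[[m]]))
    })
    return(do.call(rbind, out))
  }
  out <- list()
  for (ch in x$chains) {
    bt <- backbone_torsions(x, ch)
    bt$chi <- NA_real_
    bt$glycosidic <- NA_character_
    bt$P <- NA_real_
    bt$numax <- NA_real_
    bt$pucker <- NA_character_
    bt$conformer <- NA_character_
    for (k in seq_len(nrow(bt))) {
      chi <- tryCatch(glycosidic_chi(x, ch, bt$resi[k]), error = function(e) NA_real_)
      bt$chi[k] <- chi
      if (!is.na(chi)) bt$glycosidic[k] <- classify_syn_anti(chi)
      ps <- tryCatch(pseudorotation(x, ch, bt$resi[k]),
                     error = function(e) list(P = NA_real_, numax = NA_real_))
      bt$P[k] <- ps$P
      bt$numax[k] <- ps$numax
      if (!is.na(ps$P)) {
        pc <- classify_pucker(ps$P)
        bt$pucker[k] <- pc$class
        bt$conformer[k] <- pc$conformer
      }
    }
    out[[ch]] <- bt
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
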