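## Mirror (Z-negation) operations, D/L classification from sugar chiral
## centers, and structure-wide chirality/geometry validation reports.

#' Mirror a structure through the z = 0 plane
#'
#' Every atomic position (x, y, z) maps to (x, y, -z). All pairwise
#' distances are preserved exactly (coordinate negation is exact in floating
#' point), every torsion angle negates, and D residues become L (and vice
#' versa). The operation is an involution.
#'
#' @param x an `rna_structure` or `rna_ensemble`.
#' @return the mirrored object.
#' @export
mirror_structure <- function(x) {
  if (inherits(x, "rna_ensemble")) {
    return(rna_ensemble(lapply(x$models, mirror_structure)))
  }
  stopifnot(inherits(x, "rna_structure"))
  x$atoms$z <- -x$atoms$z
  x
}

#' Classify the sugar chirality of one residue
#'
#' Computes the signed volume of each of the four sugar chiral centers
#' (C1', C2', C3', C4') and compares the signs with the template's
#' D-reference signs: `D` when all match, `L` when all are opposite,
#' `invalid` otherwise.
#'
#' @param x an `rna_structure`.
#' @param chain chain id.
#' @param resi residue index.
#' @return character scalar `"D"`, `"L"` or `"invalid"`, with attribute
#'   `volumes` (named signed volumes, Angstrom^3).
#' @export
classify_residue_chirality <- function(x, chain, resi) {
  res <- residue_atoms(x, chain, resi)
  if (nrow(res) == 0) stop("no such residue: ", chain, resi)
  code <- res$resn[1]
  tpl <- residue_templates()[[code]]
  centers <- tpl$chiral_centers
  need <- unique(c(names(centers), unlist(centers)))
  m <- residue_xyz(x, chain, resi, need)
  vols <- vapply(names(centers), function(ctr) {
    s <- centers[[ctr]]
    chiral_volume(m[ctr, ], m[s[1], ], m[s[2], ], m[s[3], ])
  }, numeric(1))
  match_ref <- sign(vols) == sign(tpl$ref_signs)
  label <- if (all(match_ref)) "D" else if (all(!match_ref)) "L" else "invalid"
  attr(label, "volumes") <- vols
  label
}

## Bond-length and bond-angle violations of one residue against template
## ideals (inter-residue O3'-P bonds are checked at chain level).
residue_geometry_violations <- function(x, chain, resi, bond_tol = 0.1,
                                        angle_tol = 10) {
  res <- residue_atoms(x, chain, resi)
  code <- res$resn[1]
  ideals <- template_ideals(code)
  have <- res$name
  viol <- list()
  xyzm <- as.matrix(res[, c("x", "y", "z")])
  rownames(xyzm) <- res$name
  b <- ideals$bonds[ideals$bonds$a1 %in% have & ideals$bonds$a2 %in% have, ]
  if (nrow(b)) {
    dl <- sqrt(rowSums((xyzm[b$a1, , drop = FALSE] - xyzm[b$a2, , drop = FALSE])^2))
    bad <- abs(dl - b$d0) > bond_tol
    if (any(bad)) {
      viol$bonds <- data.frame(chain = chain, resi = resi,
                               a1 = b$a1[bad], a2 = b$a2[bad],
                               value = dl[bad], ideal = b$d0[bad])
    }
  }
  an <- ideals$angles[ideals$angles$a1 %in% have & ideals$angles$ctr %in% have &
                        ideals$angles$a2 %in% have, ]
  if (nrow(an)) {
    th <- vapply(seq_len(nrow(an)), function(k) {
      bond_angle(xyzm[an$a1[k], ], xyzm[an$ctr[k], ], xyzm[an$a2[k], ])
    }, numeric(1))
    bad <- abs(th - an$th0) > angle_tol
    if (any(bad)) {
      viol$angles <- data.frame(chain = chain, resi = resi,
                                a1 = an$a1[bad], ctr = an$ctr[bad],
                                a2 = an$a2[bad], value = th[bad],
                                ideal = an$th0[bad])
    }
  }
  viol
}

#' Validate chirality and covalent geometry of a complex
#'
#' Per-residue D/L classification from sugar chiral-center signed volumes,
#' plus bond-length (tolerance +/- 0.1 Angstrom) and bond-angle (+/- 10
#' degrees) checks against the template ideals. The overall verdict is
#' `all-D`, `all-L`, `mixed` (chains of uniform but differing chirality --
#' the heterochiral case), or `invalid`.
#'
#' @param x an `rna_structure`.
#' @param bond_tol,angle_tol violation tolerances (Angstrom, degrees).
#' @return object of class `chirality_report`: list with `residues` (data
#'   frame: chain, resi, resn, chirality), `volumes`, `bond_violations`,
#'   `angle_violations`, `verdict`.
#' @export
validate_chirality <- function(x, bond_tol = 0.1, angle_tol = 10) {
  rt <- residue_table(x)
  labels <- character(nrow(rt))
  vols <- list()
  bond_v <- list(); angle_v <- list()
  for (k in seq_len(nrow(rt))) {
    lab <- tryCatch(classify_residue_chirality(x, rt$chain[k], rt$resi[k]),
                    error = function(e) structure("invalid", volumes = NULL))
    labels[k] <- as.character(lab)
    v <- attr(lab, "volumes")
    if (!is.null(v)) {
      vols[[k]] <- data.frame(chain = rt$chain[k], resi = rt$resi[k],
                              center = names(v), volume = unname(v))
    }
    gv <- residue_geometry_violations(x, rt$chain[k], rt$resi[k],
                                      bond_tol, angle_tol)
    if (!is.null(gv$bonds)) bond_v[[length(bond_v) + 1L]] <- gv$bonds
    if (!is.null(gv$angles)) angle_v[[length(angle_v) + 1L]] <- gv$angles
  }
  residues <- cbind(rt, chirality = labels)
  verdict <- if (any(labels == "invalid")) {
    "invalid"
  } else if (all(labels == "D")) {
    "all-D"
  } else if (all(labels == "L")) {
    "all-L"
  } else {
    "mixed"
  }
  structure(list(residues = residues,
                 volumes = do.call(rbind, vols),
                 bond_violations = if (length(bond_v)) do.call(rbind, bond_v) else NULL,
                 angle_violations = if (length(angle_v)) do.call(rbind, angle_v) else NULL,
                 verdict = verdict),
            class = "chirality_report")
}

#' @export
print.chirality_report <- function(x, ...) {
  cat("<chirality_report> verdict: ", x$verdict, "\n", sep = "")
  tab <- table(x$residues$chain, x$residues$chirality)
  print(tab)
  nb <- if (is.null(x$bond_violations)) 0L else nrow(x$bond_violations)
  na <- if (is.null(x$angle_violations)) 0L else nrow(x$angle_violations)
  cat("bond violations: ", nb, ", angle violations: ", na, "\n", sep = "")
  invisible(x)
}

#' Serialize a chirality report to JSON
#' @param report a `chirality_report`.
#' @param path output file.
#' @export
write_chirality_report <- function(report, path) {
  jsonlite::write_json(
    list(verdict = report$verdict,
         residues = report$residues,
         bond_violations = report$bond_violations,
         angle_violations = report$angle_violations),
    path, auto_unbox = TRUE, digits = 6, null = "null")
  invisible(path)
}
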