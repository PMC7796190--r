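## Parametric construction of single ribonucleotides: a furanose ring built
## to a prescribed Altona-Sundaralingam pseudorotation phase P and amplitude
## numax, base attached at a prescribed glycosidic chi, backbone attached by
## pinned torsions. All local bond lengths, bond angles and rigid-offset
## torsions come from the pinned residue templates, so a template-built
## residue is D by construction.

## Internal-coordinate table of one residue code, derived from its template.
nt_internal <- function(code) {
  key <- paste0("ic_", code)
  if (!is.null(.template_env[[key]])) return(.template_env[[key]])
  tpl <- residue_templates()[[code]]
  xyz <- tpl$xyz
  d <- function(a, b) vnorm(xyz[a, ] - xyz[b, ])
  a <- function(p, q, r) bond_angle(xyz[p, ], xyz[q, ], xyz[r, ])
  t4 <- function(p, q, r, s) dihedral(xyz[p, ], xyz[q, ], xyz[r, ], xyz[s, ])
  nu <- c(t4("C4'", "O4'", "C1'", "C2'"),
          t4("O4'", "C1'", "C2'", "C3'"),
          t4("C1'", "C2'", "C3'", "C4'"),
          t4("C2'", "C3'", "C4'", "O4'"),
          t4("C3'", "C4'", "O4'", "C1'"))
  n_g <- glyc_n(code)
  chi_atom <- if (is_purine(code)) "C4" else "C2"
  chi2_atom <- if (is_purine(code)) "C8" else "C6"
  ic <- list(
    code = code, n_g = n_g, chi_atom = chi_atom, chi2_atom = chi2_atom,
    ring_d = c(d("O4'", "C1'"), d("C1'", "C2'"), d("C2'", "C3'"),
               d("C3'", "C4'"), d("C4'", "O4'")),
    ring_a = c(a("O4'", "C1'", "C2'"), a("C1'", "C2'", "C3'"),
               a("C2'", "C3'", "C4'")),
    ## glycosidic N: rigid offset from nu0 about the O4'-C1' bond
    d_N = d("C1'", n_g), a_N = a("O4'", "C1'", n_g),
    off_N = wrap180(t4("C4'", "O4'", "C1'", n_g) - nu[1]),
    d_chi = d(n_g, chi_atom), a_chi = a("C1'", n_g, chi_atom),
    d_chi2 = d(n_g, chi2_atom), a_chi2 = a("C1'", n_g, chi2_atom),
    off_chi2 = wrap180(t4("O4'", "C1'", n_g, chi2_atom) -
                       t4("O4'", "C1'", n_g, chi_atom)),
    d_O2 = d("C2'", "O2'"), a_O2 = a("C1'", "C2'", "O2'"),
    off_O2 = wrap180(t4("O4'", "C1'", "C2'", "O2'") - nu[2]),
    d_O3 = d("C3'", "O3'"), a_O3 = a("C2'", "C3'", "O3'"),
    off_O3 = wrap180(t4("C1'", "C2'", "C3'", "O3'") - nu[3]),
    d_C5 = d("C4'", "C5'"), a_C5 = a("C3'", "C4'", "C5'"),
    off_C5 = wrap180(t4("C2'", "C3'", "C4'", "C5'") - nu[4]),
    d_O5 = d("C5'", "O5'"), a_O5 = a("C4'", "C5'", "O5'"),
    d_P = d("O5'", "P"), a_P = a("C5'", "O5'", "P"),
    d_OP1 = d("P", "OP1"), a_OP1 = a("O5'", "P", "OP1"),
    t_OP1 = t4("C5'", "O5'", "P", "OP1"),
    d_OP2 = d("P", "OP2"), a_OP2 = a("O5'", "P", "OP2"),
    t_OP2 = t4("C5'", "O5'", "P", "OP2"),
    base_atoms = tpl$base_atoms,
    base_xyz = xyz[tpl$base_atoms, , drop = FALSE]
  )
  .template_env[[key]] <- ic
  ic
}

## Altona-Sundaralingam ring torsions for a phase/amplitude pair.
as_ring_torsions <- function(P, numax) {
  j <- 0:4
  numax * cos((P + 144 * (j - 2)) / DEG)
}

## Robust inversion: (P, numax) from five ring torsions.
as_phase <- function(nu) {
  B <- ((nu[5] + nu[2]) - (nu[4] + nu[1])) /
    (2 * (sin(36 / DEG) + sin(72 / DEG)))
  A <- nu[3]
  list(P = wrap360(atan2(B, A) * DEG), numax = sqrt(A^2 + B^2))
}

## Build the five ring atoms (rows O4', C1', C2', C3', C4') at a target
## phase/amplitude. Construction: NeRF chain with free torsions (v1, v2),
## exact two-bond closure of C4', then Newton iteration driving the measured
## (P, numax) onto the target.
ring_from_pucker <- function(P, numax, ic) {
  dd <- ic$ring_d; aa <- ic$ring_a
  build <- function(v) {
    O4 <- c(0, 0, 0)
    C1 <- c(dd[1], 0, 0)
    ang <- aa[1] / DEG
    C2 <- C1 + dd[2] * c(-cos(ang), sin(ang), 0)
    C3 <- drop(place_atom(O4, C1, C2, dd[3], aa[2], v[1]))
    C4r <- drop(place_atom(C1, C2, C3, dd[4], aa[3], v[2]))
    ## exact closure: |C4-C3| = dd[4], |C4-O4| = dd[5], nearest to C4r
    u <- O4 - C3
    L <- vnorm(u); uh <- u / L
    x <- (L^2 + dd[4]^2 - dd[5]^2) / (2 * L)
    r2 <- dd[4]^2 - x^2
    if (r2 <= 0) stop("generation error: infeasible ring closure")
    ctr <- C3 + x * uh
    w <- C4r - ctr
    w <- w - sum(w * uh) * uh
    if (vnorm(w) < 1e-9) stop("generation error: degenerate ring closure")
    C4 <- ctr + sqrt(r2) * (w / vnorm(w))
    m <- rbind(O4, C1, C2, C3, C4)
    rownames(m) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
    m
  }
  measure <- function(m) {
    nu <- c(dihedral(m["C4'", ], m["O4'", ], m["C1'", ], m["C2'", ]),
            dihedral(m["O4'", ], m["C1'", ], m["C2'", ], m["C3'", ]),
            dihedral(m["C1'", ], m["C2'", ], m["C3'", ], m["C4'", ]),
            dihedral(m["C2'", ], m["C3'", ], m["C4'", ], m["O4'", ]),
            dihedral(m["C3'", ], m["C4'", ], m["O4'", ], m["C1'", ]))
    as_phase(nu)
  }
  tgt <- as_ring_torsions(P, numax)
  v <- tgt[2:3]
  err <- function(v) {
    ph <- measure(build(v))
    c(wrap180(ph$P - P), ph$numax - numax)
  }
  e <- err(v)
  for (iter in 1:12) {
    if (max(abs(e)) < 1e-6) break
    h <- 0.05
    J <- cbind((err(v + c(h, 0)) - e) / h, (err(v + c(0, h)) - e) / h)
    step <- tryCatch(solve(J, e), error = function(...) e * 0.5)
    v <- v - step
    e <- err(v)
  }
  build(v)
}

## Memoized ring construction (a duplex build reuses one pucker many times;
## the cache is bounded and cleared when it grows past 512 entries).
ring_cached <- function(P, numax, ic) {
  if (is.null(.template_env$rings)) .template_env$rings <- new.env(parent = emptyenv())
  key <- paste(ic$code, signif(P, 10), signif(numax, 10))
  hit <- .template_env$rings[[key]]
  if (!is.null(hit)) return(hit)
  r <- ring_from_pucker(P, numax, ic)
  if (length(ls(.template_env$rings)) > 512) {
    .template_env$rings <- new.env(parent = emptyenv())
  }
  .template_env$rings[[key]] <- r
  r
}

#' Build one ribonucleotide at a prescribed conformation
#'
#' Constructs the heavy atoms of a single D-ribonucleotide in a local frame:
#' furanose ring at pseudorotation phase `P` (amplitude `numax`), base
#' attached at glycosidic angle `chi`, backbone placed with torsions `gamma`
#' and `beta`. Bond lengths, bond angles and the rigid torsion offsets that
#' encode the D configuration come from the pinned residue templates.
#'
#' @param code residue code (A/C/G/U).
#' @param P target pseudorotation phase, degrees in \[0, 360).
#' @param numax pucker amplitude, degrees.
#' @param chi glycosidic torsion (O4'-C1'-N9-C4 or O4'-C1'-N1-C2), degrees.
#' @param gamma,beta backbone torsions O5'-C5'-C4'-C3' and P-O5'-C5'-C4',
#'   degrees.
#' @param with_phosphate include the 5' phosphate group (P, OP1, OP2)?
#' @return matrix of atom coordinates with atom-name rownames, template
#'   atom order.
#' @export
build_nucleotide <- function(code, P = 18, numax = 38, chi = -158,
                             gamma = 54, beta = 178, with_phosphate = TRUE) {
  ic <- nt_internal(code)
  ring <- ring_cached(P, numax, ic)
  nu <- c(dihedral(ring["C4'", ], ring["O4'", ], ring["C1'", ], ring["C2'", ]),
          dihedral(ring["O4'", ], ring["C1'", ], ring["C2'", ], ring["C3'", ]),
          dihedral(ring["C1'", ], ring["C2'", ], ring["C3'", ], ring["C4'", ]),
          dihedral(ring["C2'", ], ring["C3'", ], ring["C4'", ], ring["O4'", ]),
          dihedral(ring["C3'", ], ring["C4'", ], ring["O4'", ], ring["C1'", ]))
  pos <- list()
  for (nm in rownames(ring)) pos[[nm]] <- ring[nm, ]
  ## glycosidic N and base anchors
  pos[[ic$n_g]] <- drop(place_atom(pos[["C4'"]], pos[["O4'"]], pos[["C1'"]],
                                   ic$d_N, ic$a_N, nu[1] + ic$off_N))
  pos[[ic$chi_atom]] <- drop(place_atom(pos[["O4'"]], pos[["C1'"]], pos[[ic$n_g]],
                                        ic$d_chi, ic$a_chi, chi))
  pos[[ic$chi2_atom]] <- drop(place_atom(pos[["O4'"]], pos[["C1'"]], pos[[ic$n_g]],
                                         ic$d_chi2, ic$a_chi2, chi + ic$off_chi2))
  ## remaining base atoms: rigid fit of the template base onto the three
  ## placed anchors (exact, identical internal geometry)
  anchors <- c(ic$n_g, ic$chi_atom, ic$chi2_atom)
  fit <- kabsch_superpose(ic$base_xyz[anchors, , drop = FALSE],
                          rbind(pos[[anchors[1]]], pos[[anchors[2]]],
                                pos[[anchors[3]]]))
  placed_base <- xform(ic$base_xyz, fit$rotation, fit$translation)
  for (nm in ic$base_atoms) pos[[nm]] <- placed_base[nm, ]
  ## sugar substituents and backbone
  pos[["O2'"]] <- drop(place_atom(pos[["O4'"]], pos[["C1'"]], pos[["C2'"]],
                                  ic$d_O2, ic$a_O2, nu[2] + ic$off_O2))
  pos[["O3'"]] <- drop(place_atom(pos[["C1'"]], pos[["C2'"]], pos[["C3'"]],
                                  ic$d_O3, ic$a_O3, nu[3] + ic$off_O3))
  pos[["C5'"]] <- drop(place_atom(pos[["C2'"]], pos[["C3'"]], pos[["C4'"]],
                                  ic$d_C5, ic$a_C5, nu[4] + ic$off_C5))
  pos[["O5'"]] <- drop(place_atom(pos[["C3'"]], pos[["C4'"]], pos[["C5'"]],
                                  ic$d_O5, ic$a_O5, gamma))
  if (with_phosphate) {
    pos[["P"]] <- drop(place_atom(pos[["C4'"]], pos[["C5'"]], pos[["O5'"]],
                                  ic$d_P, ic$a_P, beta))
    pos[["OP1"]] <- drop(place_atom(pos[["C5'"]], pos[["O5'"]], pos[["P"]],
                                    ic$d_OP1, ic$a_OP1, ic$t_OP1))
    pos[["OP2"]] <- drop(place_atom(pos[["C5'"]], pos[["O5'"]], pos[["P"]],
                                    ic$d_OP2, ic$a_OP2, ic$t_OP2))
  }
  order_names <- rownames(residue_templates()[[code]]$xyz)
  if (!with_phosphate) order_names <- setdiff(order_names, PHOSPHATE_ATOMS)
  out <- do.call(rbind, pos[order_names])
  rownames(out) <- order_names
  out
}
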