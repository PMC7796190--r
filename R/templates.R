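## Residue templates: ideal heavy-atom ribonucleotide geometry pinned in
## inst/extdata/residue_templates.csv (derived from the public PDB Chemical
## Component Dictionary ideal coordinates; hydrogens and OP3 removed).
## Everything template-derived (atom sets, bond/angle ideals, D-reference
## chiral signs) is computed from that one file.

BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                    "C3'", "O3'", "C2'", "O2'", "C1'")
PHOSPHATE_ATOMS <- c("P", "OP1", "OP2")

BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

## Watson-Crick donor/acceptor heavy-atom pairs, first atom on the purine
## (or on the first-named residue for G-C / A-U ordering).
WC_HBONDS <- list(
  "G-C" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  "A-U" = list(c("N6", "O4"), c("N1", "N3"))
)

## Sugar chiral centers: center atom + three ranked heavy substituents.
## The glycosidic nitrogen of C1' is N9 for purines, N1 for pyrimidines.
CHIRAL_CENTERS <- function(code) {
  n_glyc <- if (code %in% c("A", "G")) "N9" else "N1"
  list(
    "C1'" = c("O4'", n_glyc, "C2'"),
    "C2'" = c("O2'", "C1'", "C3'"),
    "C3'" = c("O3'", "C2'", "C4'"),
    "C4'" = c("O4'", "C3'", "C5'")
  )
}

## Intra-residue heavy-atom bonds (by name); inter-residue bond is
## O3'(i-1)-P(i). Base bonds listed per code.
SUGAR_BONDS <- list(
  c("P", "OP1"), c("P", "OP2"), c("P", "O5'"), c("O5'", "C5'"),
  c("C5'", "C4'"), c("C4'", "O4'"), c("C4'", "C3'"), c("O4'", "C1'"),
  c("C3'", "O3'"), c("C3'", "C2'"), c("C2'", "O2'"), c("C2'", "C1'")
)

BASE_BONDS <- list(
  A = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
           c("C5", "C6"), c("C6", "N6"), c("C6", "N1"), c("N1", "C2"),
           c("C2", "N3"), c("N3", "C4"), c("C4", "C5"), c("C4", "N9")),
  G = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
           c("C5", "C6"), c("C6", "O6"), c("C6", "N1"), c("N1", "C2"),
           c("C2", "N2"), c("C2", "N3"), c("N3", "C4"), c("C4", "C5"),
           c("C4", "N9")),
  C = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
           c("N3", "C4"), c("C4", "N4"), c("C4", "C5"), c("C5", "C6"),
           c("C6", "N1")),
  U = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
           c("N3", "C4"), c("C4", "O4"), c("C4", "C5"), c("C5", "C6"),
           c("C6", "N1"))
)

.template_env <- new.env(parent = emptyenv())

#' Residue templates for A, C, G, U
#'
#' Returns the pinned ideal heavy-atom geometry of the four ribonucleotides,
#' as a named list with one entry per residue code. Each entry carries the
#' atom table (name, element, x, y, z), the base-atom subset, the chiral
#' centers with their D-reference signed volumes, and the Watson-Crick
#' donor/acceptor table.
#'
#' @return named list of templates, one per code in `A`, `C`, `G`, `U`.
#' @export
residue_templates <- function() {
  if (!is.null(.template_env$templates)) return(.template_env$templates)
  path <- system.file("extdata", "residue_templates.csv", package = "chiralhh")
  if (path == "") path <- file.path("inst", "extdata", "residue_templates.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  templates <- lapply(c(A = "A", C = "C", G = "G", U = "U"), function(code) {
    at <- tab[tab$code == code, c("name", "elem", "x", "y", "z")]
    rownames(at) <- at$name
    xyz <- as.matrix(at[, c("x", "y", "z")])
    centers <- CHIRAL_CENTERS(code)
    ref_signs <- vapply(names(centers), function(ctr) {
      s <- centers[[ctr]]
      sign(chiral_volume(xyz[ctr, ], xyz[s[1], ], xyz[s[2], ], xyz[s[3], ]))
    }, numeric(1))
    list(code = code,
         atoms = at,
         xyz = xyz,
         base_atoms = BASE_ATOMS[[code]],
         chiral_centers = centers,
         ref_signs = ref_signs,
         bonds = c(SUGAR_BONDS, BASE_BONDS[[code]]))
  })
  .template_env$templates <- templates
  templates
}

#' Ideal heavy-atom count of one residue
#' @param code residue code, one of `A`, `C`, `G`, `U`.
#' @param five_prime_phosphate logical; `FALSE` drops P, OP1, OP2 (5'-OH
#'   terminus).
#' @return integer atom count.
#' @export
template_atom_count <- function(code, five_prime_phosphate = TRUE) {
  base_n <- length(BASE_ATOMS[[code]])
  if (is.null(BASE_ATOMS[[code]])) stop("unknown residue code: ", code)
  base_n + if (five_prime_phosphate) 12L else 9L
}

## Ideal bond lengths / bond angles of a residue template, as data frames
## keyed by atom names. Used as restraint targets by restrained_refine().
template_ideals <- function(code) {
  tpl <- residue_templates()[[code]]
  xyz <- tpl$xyz
  bl <- do.call(rbind, lapply(tpl$bonds, function(b) {
    data.frame(a1 = b[1], a2 = b[2],
               d0 = vnorm(xyz[b[1], ] - xyz[b[2], ]),
               stringsAsFactors = FALSE)
  }))
  ## angles: every pair of bonds sharing an atom
  adj <- lapply(tpl$bonds, identity)
  ang <- list()
  atoms <- rownames(xyz)
  nbrs <- lapply(atoms, function(a) {
    unique(unlist(lapply(adj, function(b) {
      if (b[1] == a) b[2] else if (b[2] == a) b[1] else NULL
    })))
  })
  names(nbrs) <- atoms
  for (ctr in atoms) {
    nb <- nbrs[[ctr]]
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (k in seq_len(ncol(cmb))) {
      ang[[length(ang) + 1L]] <- data.frame(
        a1 = cmb[1, k], ctr = ctr, a2 = cmb[2, k],
        th0 = bond_angle(xyz[cmb[1, k], ], xyz[ctr, ], xyz[cmb[2, k], ]),
        stringsAsFactors = FALSE)
    }
  }
  list(bonds = bl, angles = do.call(rbind, ang))
}

#' Signed volume of a chiral center
#'
#' Scalar triple product `(s1-c) . ((s2-c) x (s3-c))` in cubic Angstrom.
#' Its sign flips under reflection and is preserved by proper rotations.
#'
#' @param center,s1,s2,s3 numeric 3-vectors: the center atom and its three
#'   ranked substituents.
#' @return signed volume, Angstrom^3.
#' @export
chiral_volume <- function(center, s1, s2, s3) {
  u <- s1 - center; v <- s2 - center; w <- s3 - center
  if (vnorm(u) < 1e-6 || vnorm(v) < 1e-6 || vnorm(w) < 1e-6) {
    stop("degenerate geometry: coincident atoms in chiral center")
  }
  sum(u * vcross(v, w))
}

is_purine <- function(code) code %in% c("A", "G")

glyc_n <- function(code) if (is_purine(code)) "N9" else "N1"

complement_base <- function(code) c(A = "U", U = "A", G = "C", C = "G")[code]
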