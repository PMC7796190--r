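## Core data model: an `rna_structure` is an atom table (one row per heavy
## atom) plus per-chain metadata; an `rna_ensemble` is an ordered list of
## topology-identical structures (frames/models).

#' Construct an RNA structure from an atom table
#'
#' @param atoms data frame with columns `chain` (single character), `resi`
#'   (1-based residue index within chain, 5' to 3'), `resn` (residue code
#'   A/C/G/U), `name` (PDB v3 atom name, prime as `'`), `elem` (element
#'   symbol), `x`, `y`, `z` (Angstrom).
#' @param five_prime_phosphate named logical vector, one entry per chain;
#'   `FALSE` marks a free 5'-OH terminus. Inferred from the atom table when
#'   omitted.
#' @return object of class `rna_structure`.
#' @export
rna_structure <- function(atoms, five_prime_phosphate = NULL) {
  req <- c("chain", "resi", "resn", "name", "elem", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atom table must have columns: ", paste(req, collapse = ", "))
  }
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resi), ]
  rownames(atoms) <- NULL
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atomic coordinates")
  }
  bad <- !atoms$resn %in% c("A", "C", "G", "U")
  if (any(bad)) {
    stop("unknown residue code(s): ", paste(unique(atoms$resn[bad]), collapse = ", "))
  }
  dup <- duplicated(atoms[, c("chain", "resi", "name")])
  if (any(dup)) {
    stop("duplicate atom name within residue: ",
         paste(utils::head(paste0(atoms$chain[dup], atoms$resi[dup], "/",
                                  atoms$name[dup]), 3), collapse = ", "))
  }
  chains <- unique(atoms$chain)
  if (is.null(five_prime_phosphate)) {
    five_prime_phosphate <- vapply(chains, function(ch) {
      first <- atoms[atoms$chain == ch & atoms$resi == min(atoms$resi[atoms$chain == ch]), ]
      "P" %in% first$name
    }, logical(1))
    names(five_prime_phosphate) <- chains
  }
  structure(list(atoms = atoms, chains = chains,
                 five_prime_phosphate = five_prime_phosphate),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", length(x$chains), " chain(s), ",
      n_residues(x), " residues, ", nrow(x$atoms), " heavy atoms\n", sep = "")
  for (ch in x$chains) {
    cat("  chain ", ch, ": 5'-", sequence_of(x, ch), "-3' (",
        if (isTRUE(x$five_prime_phosphate[[ch]])) "5'-P" else "5'-OH",
        ")\n", sep = "")
  }
  invisible(x)
}

#' Number of residues in a structure (or one chain of it)
#' @param x an `rna_structure`.
#' @param chain optional chain id.
#' @return integer.
#' @export
n_residues <- function(x, chain = NULL) {
  a <- x$atoms
  if (!is.null(chain)) a <- a[a$chain == chain, ]
  nrow(unique(a[, c("chain", "resi")]))
}

#' Coordinates of a structure as an n x 3 matrix
#' @param x an `rna_structure`.
#' @return numeric matrix, one row per atom in table order.
#' @export
coords <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' Replace the coordinates of a structure
#' @param x an `rna_structure`.
#' @param value n x 3 matrix matching the atom table.
#' @return the modified structure.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nrow(x$atoms), ncol(value) == 3)
  x$atoms$x <- value[, 1]; x$atoms$y <- value[, 2]; x$atoms$z <- value[, 3]
  x
}

#' Sequence of a chain, 5' to 3'
#' @param x an `rna_structure`.
#' @param chain chain id; defaults to the first chain.
#' @return character scalar (possibly empty).
#' @export
sequence_of <- function(x, chain = x$chains[1]) {
  a <- x$atoms[x$atoms$chain == chain, ]
  if (nrow(a) == 0) return("")
  res <- unique(a[, c("resi", "resn")])
  paste(res$resn[order(res$resi)], collapse = "")
}

## Atom rows of one residue.
residue_atoms <- function(x, chain, resi) {
  x$atoms[x$atoms$chain == chain & x$atoms$resi == resi, ]
}

## Coordinates of named atoms of one residue; errors listing what is missing.
residue_xyz <- function(x, chain, resi, names) {
  a <- residue_atoms(x, chain, resi)
  idx <- match(names, a$name)
  if (anyNA(idx)) {
    stop("incomplete residue ", chain, resi, ": missing atom(s) ",
         paste(names[is.na(idx)], collapse = ", "))
  }
  m <- as.matrix(a[idx, c("x", "y", "z")])
  rownames(m) <- names
  m
}

## data frame of (chain, resi, resn) for all residues in table order.
residue_table <- function(x) {
  unique(x$atoms[, c("chain", "resi", "resn")])
}

#' Construct a model ensemble
#'
#' @param structures list of `rna_structure` objects sharing identical
#'   topology (chains, residues, atom names, order).
#' @return object of class `rna_ensemble`.
#' @export
rna_ensemble <- function(structures) {
  if (length(structures) < 1) stop("ensemble needs at least one member")
  key <- function(s) paste(s$atoms$chain, s$atoms$resi, s$atoms$name, sep = "|")
  ref <- key(structures[[1]])
  for (i in seq_along(structures)) {
    ki <- key(structures[[i]])
    if (length(ki) != length(ref) || any(ki != ref)) {
      d <- if (length(ki) != length(ref)) {
        setdiff(union(ref, ki), intersect(ref, ki))
      } else ref[ki != ref]
      stop("ensemble topology mismatch at model ", i, " near atom ",
           d[1])
    }
  }
  structure(list(models = structures), class = "rna_ensemble")
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat("<rna_ensemble> ", length(x$models), " model(s)\n", sep = "")
  print(x$models[[1]])
  invisible(x)
}

#' @export
length.rna_ensemble <- function(x) length(x$models)

## Resolve a selection to atom row indices of a structure.
## A selection is a list with optional fields: chain (vector), resi (per-chain
## list or vector applied to all named chains), atoms (atom-name vector).
select_atoms <- function(x, selection = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
  if (!is.null(selection$resi)) {
    if (is.list(selection$resi)) {
      k2 <- rep(FALSE, nrow(a))
      for (ch in names(selection$resi)) {
        k2 <- k2 | (a$chain == ch & a$resi %in% selection$resi[[ch]])
      }
      keep <- keep & k2
    } else {
      keep <- keep & a$resi %in% selection$resi
    }
  }
  if (!is.null(selection$atoms)) keep <- keep & a$name %in% selection$atoms
  which(keep)
}

## Ribose-phosphate backbone atom names (O2' excluded by default; the sugar
## hydroxyl is configurable because conventions differ).
backbone_selection <- function(include_o2p = FALSE) {
  n <- BACKBONE_ATOMS
  if (!include_o2p) n <- setdiff(n, "O2'")
  n
}
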