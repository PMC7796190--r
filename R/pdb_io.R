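## PDB (multi-model) reading and writing. The reader normalizes atom names
## (prime characters ' / ′ / * all accepted, ' emitted), maps residue-name
## dialects (ADE/CYT/GUA/URA, RA/RC/RG/RU) to A/C/G/U, discards hydrogens,
## and renumbers residues 1..n per chain preserving file order.

RESN_DIALECTS <- c(A = "A", C = "C", G = "G", U = "U",
                   ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U",
                   RA = "A", RC = "C", RG = "G", RU = "U",
                   RA3 = "A", RC3 = "C", RG3 = "G", RU3 = "U",
                   RA5 = "A", RC5 = "C", RG5 = "G", RU5 = "U")

normalize_atom_name <- function(name) {
  name <- gsub("′", "'", name, fixed = TRUE)
  name <- gsub("*", "'", name, fixed = TRUE)
  ## historic OP naming
  name[name == "O1P"] <- "OP1"
  name[name == "O2P"] <- "OP2"
  name
}

is_hydrogen <- function(name, elem) {
  e <- toupper(trimws(elem))
  ifelse(e != "", e %in% c("H", "D"),
         grepl("^[0-9]*[HD]", toupper(trimws(name))))
}

#' Read a (multi-model) PDB file
#'
#' Hydrogens are discarded, atom names normalized to PDB v3 with `'` primes,
#' residue-name dialects mapped to A/C/G/U, and residues renumbered 1..n per
#' chain preserving file order. Residues that are not standard ribonucleotides
#' are reported via a warning and excluded.
#'
#' @param path PDB file.
#' @param model_policy `"all"` reads every MODEL block, `"first"` only the
#'   first (or the sole unblocked model).
#' @return an [rna_ensemble()].
#' @export
read_pdb <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- list()
  in_model <- FALSE
  n_model <- 0L
  unknown <- character(0)
  flush_model <- function(cur) {
    if (length(cur) == 0) return(NULL)
    do.call(rbind, cur)
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      if (length(cur)) { models[[length(models) + 1L]] <- flush_model(cur); cur <- list() }
      in_model <- TRUE
      n_model <- n_model + 1L
      if (model_policy == "first" && length(models) >= 1L) break
    } else if (r == "ENDMDL") {
      models[[length(models) + 1L]] <- flush_model(cur)
      cur <- list()
      if (model_policy == "first") break
    } else if (r == "ATOM  " || r == "HETATM") {
      ln <- lines[i]
      name <- normalize_atom_name(trimws(substr(ln, 13, 16)))
      resn_raw <- trimws(substr(ln, 18, 20))
      chain <- substr(ln, 22, 22)
      resseq <- trimws(substr(ln, 23, 26))
      xs <- trimws(substr(ln, 31, 38))
      ys <- trimws(substr(ln, 39, 46))
      zs <- trimws(substr(ln, 47, 54))
      elem <- trimws(substr(ln, 77, 78))
      xyz <- suppressWarnings(as.numeric(c(xs, ys, zs)))
      if (anyNA(xyz)) {
        stop("PDB format error at line ", i, ": unparsable coordinates")
      }
      if (is_hydrogen(name, elem)) next
      resn <- unname(RESN_DIALECTS[resn_raw])
      if (is.na(resn)) {
        unknown <- c(unknown, resn_raw)
        next
      }
      cur[[length(cur) + 1L]] <- data.frame(
        chain = if (chain == " ") "A" else chain,
        resseq = resseq, resn = resn, name = name,
        elem = if (elem == "") substr(name, 1, 1) else elem,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- flush_model(cur)
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop("PDB format error: no atoms read from ", path)
  if (length(unknown)) {
    warning("unknown residue(s) skipped: ",
            paste(unique(unknown), collapse = ", "))
  }
  structures <- lapply(models, function(df) {
    ## renumber residues 1..n per chain in order of appearance
    df$resi <- NA_integer_
    key <- paste(df$chain, df$resseq)
    for (ch in unique(df$chain)) {
      sel <- df$chain == ch
      df$resi[sel] <- match(key[sel], unique(key[sel]))
    }
    rna_structure(df[, c("chain", "resi", "resn", "name", "elem", "x", "y", "z")])
  })
  tryCatch(rna_ensemble(structures), error = function(e) {
    stop("ensemble error: ", conditionMessage(e))
  })
}

pdb_atom_field <- function(name) {
  ## names of 1-3 characters start in column 14; 4-character names in 13
  ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
}

format_model <- function(x, serial0 = 0L) {
  a <- x$atoms
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial0 + seq_len(nrow(a)), pdb_atom_field(a$name), a$resn,
          a$chain, a$resi, a$x, a$y, a$z, 1, 0, a$elem)
}

#' Write a structure or ensemble to a PDB file
#'
#' Ensembles with more than one member are written as MODEL/ENDMDL blocks;
#' a single structure (or 1-member ensemble) is written without MODEL
#' records. Atom names are emitted with `'` primes in fixed PDB columns.
#'
#' @param x an `rna_structure` or `rna_ensemble`.
#' @param path output file.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "rna_structure")) x <- rna_ensemble(list(x))
  if (!inherits(x, "rna_ensemble")) stop("x must be an rna_structure or rna_ensemble")
  if (nrow(x$models[[1]]$atoms) > 99999) {
    stop("unsupported size: more than 99999 atoms")
  }
  out <- character(0)
  multi <- length(x$models) > 1
  for (m in seq_along(x$models)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, format_model(x$models[[m]]), "TER")
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Read RNA sequences from FASTA or plain text
#'
#' FASTA files are parsed with Biostrings when available; a bare sequence
#' string (possibly with whitespace) is accepted directly. T is mapped to U
#' and the result validated against the A/C/G/U alphabet.
#'
#' @param path file containing one or more sequences.
#' @return named character vector of RNA sequences.
#' @export
read_sequences <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, ">") && requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (startsWith(first, ">")) {
      ## minimal fallback when Biostrings is unavailable
      hdr <- grepl("^>", lines)
      grp <- cumsum(hdr)
      seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
      names(seqs) <- sub("^>", "", lines[hdr])
      seqs <- toupper(seqs)
    } else {
      seqs <- toupper(paste(gsub("\\s", "", lines), collapse = ""))
      names(seqs) <- basename(path)
    }
  }
  seqs <- gsub("\\s", "", seqs)
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) stop("sequence error: non-ACGU letters in ", names(seqs)[bad][1])
  seqs
}
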